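#' Packaged benchmark channel tables
#'
#' The package ships the published triplicate-mean channel table for the
#' tartrazine MIP sensor (standards at 1-30 mg/L and five soda samples
#' M1-M5, mean +/- SD per channel), the UHPLC reference concentrations for
#' the soda samples, and the smartphone-method found concentrations used in
#' the method comparison. These are the canonical fixtures for the
#' synthetic reconstruction and for worked examples.
#'
#' Note: the 1 mg/L standard row is internally inconsistent (its printed I
#' does not equal the mean of its printed R, G, B, and its B SD of 23.4 is
#' an order of magnitude above all other rows). It is kept verbatim here;
#' downstream defaults that are sensitive to it (the image-response knots)
#' exclude it.
#'
#' @param which `"all"`, `"standards"` (rows with a concentration) or
#'   `"samples"` (the unknowns M1-M5).
#' @return A data frame with columns `sample_id`, `concentration` (mg/L,
#'   `NA` for unknowns), the 8 channel means `R,G,B,I,H,S,V,L`, and their
#'   replicate SDs `R_sd ... L_sd`.
#' @export
tartrazine_channels <- function(which = c("all", "standards", "samples")) {
  which <- match.arg(which)
  tab <- utils::read.csv(
    system.file("extdata", "tartrazine_channels.csv", package = "dicolor",
                mustWork = TRUE),
    stringsAsFactors = FALSE)
  switch(which,
         all = tab,
         standards = tab[!is.na(tab$concentration), ],
         samples = tab[is.na(tab$concentration), ])
}

#' @rdname tartrazine_channels
#' @return `uhplc_reference()`: data frame `sample_id`,
#'   `reference_mg_L`, `reference_sd`.
#' @export
uhplc_reference <- function() {
  utils::read.csv(
    system.file("extdata", "uhplc_reference.csv", package = "dicolor",
                mustWork = TRUE),
    stringsAsFactors = FALSE)
}

#' @rdname tartrazine_channels
#' @return `soda_found()`: data frame `sample_id`, `found_mg_L`,
#'   `found_sd`, `n` (smartphone-method results for M1-M5).
#' @export
soda_found <- function() {
  utils::read.csv(
    system.file("extdata", "soda_found.csv", package = "dicolor",
                mustWork = TRUE),
    stringsAsFactors = FALSE)
}
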