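#' Figures of merit for a colorimetric calibration
#'
#' Limit of detection from the residual scatter of the predicted-vs-measured
#' regression, repeatability as percent relative standard deviation, and
#' accuracy as signed relative error against a reference method.
#'
#' @name merit
NULL

#' Limit of detection
#'
#' A straight line is fitted to predicted versus measured concentration
#' over the training set; the LOD is `multiplier * s_res / b`, where
#' `s_res` is the residual standard deviation of that line and `b` its
#' slope. The default multiplier 3.3 is the ICH detection-limit convention
#' (10 would give a quantification limit).
#'
#' @param model a fitted `pls_model`.
#' @param data the `calibration_set` it was trained on (>= 3 levels).
#' @param multiplier sigma multiplier (default 3.3).
#' @return LOD in mg/L.
#' @export
lod <- function(model, data, multiplier = 3.3) {
  stopifnot(inherits(model, "pls_model"), inherits(data, "calibration_set"))
  if (length(unique(data$y)) < 3)
    stop("LOD needs at least 3 concentration levels", call. = FALSE)
  pred <- predict(model, data$X)
  fit <- stats::lm(pred ~ data$y)
  b <- stats::coef(fit)[2]
  s_res <- summary(fit)$sigma
  if (!is.finite(b) || abs(b) < 1e-8)
    stop("uninformative calibration: predicted-vs-measured slope is ~0",
         call. = FALSE)
  unname(multiplier * s_res / b)
}

#' Repeatability of replicate determinations
#'
#' @param found numeric vector of found concentrations (mg/L), `n >= 2`.
#' @return List with `n`, `mean` and `rsd` (percent relative SD,
#'   `100 * sd / mean` with the n-1 SD).
#' @export
repeatability <- function(found) {
  found <- as.numeric(found)
  if (length(found) < 2) stop("repeatability needs n >= 2", call. = FALSE)
  m <- mean(found)
  if (m == 0) stop("%RSD undefined: mean of found values is 0", call. = FALSE)
  list(n = length(found), mean = m, rsd = 100 * stats::sd(found) / m)
}

#' Signed relative error against a reference value
#'
#' `100 * (found - reference) / reference`; positive when the candidate
#' method over-reads the reference.
#'
#' @param found,reference concentrations (mg/L); `reference != 0`.
#' @return Relative error in percent (vectorized).
#' @export
relative_error <- function(found, reference) {
  if (any(reference == 0))
    stop("relative error undefined for reference == 0", call. = FALSE)
  100 * (found - reference) / reference
}

#' Compare found concentrations against a reference method
#'
#' Joins the candidate-method results to reference-method results by
#' `sample_id` and reports per-sample relative error and the %RSD of the
#' found replicates. The found table either carries replicate rows
#' (repeated `sample_id`, column `found_mg_L`) which are aggregated here,
#' or pre-aggregated columns `found_mg_L` and `found_sd`.
#'
#' @param found data frame with `sample_id`, `found_mg_L` and optionally
#'   `found_sd`.
#' @param reference data frame with `sample_id`, `reference_mg_L` and
#'   optionally `reference_sd`.
#' @return Data frame with one row per sample: found mean and SD, reference
#'   mean and SD, `relative_error_pct`, `rsd_pct`.
#' @export
method_comparison <- function(found, reference) {
  need_f <- c("sample_id", "found_mg_L")
  need_r <- c("sample_id", "reference_mg_L")
  if (!all(need_f %in% names(found)))
    stop("found table needs columns: ", paste(need_f, collapse = ", "),
         call. = FALSE)
  if (!all(need_r %in% names(reference)))
    stop("reference table needs columns: ", paste(need_r, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(found$sample_id)) {
    agg <- stats::aggregate(found_mg_L ~ sample_id, found,
                            function(v) c(mean = mean(v), sd = stats::sd(v)))
    found <- data.frame(sample_id = agg$sample_id,
                        found_mg_L = agg$found_mg_L[, "mean"],
                        found_sd = agg$found_mg_L[, "sd"])
  } else if (is.null(found$found_sd)) {
    found$found_sd <- NA_real_
  }
  orphans <- c(setdiff(found$sample_id, reference$sample_id),
               setdiff(reference$sample_id, found$sample_id))
  if (length(orphans) > 0)
    stop("unmatched sample id(s): ", paste(unique(orphans), collapse = ", "),
         call. = FALSE)
  if (is.null(reference$reference_sd)) reference$reference_sd <- NA_real_
  tab <- merge(found, reference[, c("sample_id", "reference_mg_L",
                                    "reference_sd")],
               by = "sample_id", sort = FALSE)
  tab$relative_error_pct <- relative_error(tab$found_mg_L, tab$reference_mg_L)
  tab$rsd_pct <- 100 * tab$found_sd / tab$found_mg_L
  tab
}

#' Render a merit report
#'
#' Human-readable text mirroring the usual figures-of-merit layout: one
#' block for LOD/repeatability, one table for method comparison. Values are
#' rounded to one decimal for display; full precision is kept in the
#' returned data.
#'
#' @param comparison output of [method_comparison()].
#' @param lod_value optional LOD (mg/L).
#' @param repeat_records optional data frame with columns `nominal_mg_L`,
#'   `n`, `found_mg_L`, `rsd_pct`.
#' @return Character vector of report lines (also printed with `cat` when
#'   `quiet = FALSE`).
#' @param quiet suppress printing.
#' @export
merit_report <- function(comparison = NULL, lod_value = NULL,
                         repeat_records = NULL, quiet = FALSE) {
  lines <- character()
  if (!is.null(lod_value))
    lines <- c(lines, sprintf("Limit of detection: %.1f mg/L", lod_value))
  if (!is.null(repeat_records)) {
    lines <- c(lines, "Repeatability:",
               "  nominal(mg/L)  n  found(mg/L)  %RSD",
               sprintf("  %13.1f %2d %12.1f %5.1f",
                       repeat_records$nominal_mg_L, repeat_records$n,
                       repeat_records$found_mg_L, repeat_records$rsd_pct))
  }
  if (!is.null(comparison)) {
    lines <- c(lines, "Method comparison:",
               "  sample   found(mg/L)  reference(mg/L)  rel.err(%)  %RSD",
               sprintf("  %-8s %11.1f %16.1f %11.1f %5.1f",
                       comparison$sample_id, comparison$found_mg_L,
                       comparison$reference_mg_L,
                       comparison$relative_error_pct, comparison$rsd_pct))
  }
  if (!quiet) cat(lines, sep = "\n")
  invisible(lines)
}
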