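#' Synthetic sensor data
#'
#' Two generators cover the whole pipeline without any real captures:
#' `reconstruct_replicates()` draws replicate channel tables whose
#' statistics match the published triplicate means and SDs, and
#' `render_patch()` produces sensor-patch images under a
#' concentration-to-color response model so the imaging front end can be
#' exercised end to end. All stochastic entry points require an explicit
#' seed and are bit-reproducible.
#'
#' @name synthdata
NULL

#' Specify a synthetic experiment
#'
#' Defaults reproduce the published study conditions: the standard grid
#' 1, 5, 10, 15, 20, 25, 30 mg/L in triplicate, with per-level Gaussian SDs
#' on R, G, B taken from the published replicate SDs. Capture-level noise
#' (`noise`, one RGB SD triple per level) models replicate-to-replicate
#' variation of the patch color; `pixel_noise_sd` models sensor noise
#' within one capture; `gradient` adds a linear illumination ramp across
#' the rendered frame (amplitude in 0-255 units, 0 = flat field).
#'
#' @param grid concentration grid in mg/L.
#' @param replicates replicates per level (>= 1).
#' @param noise data frame with columns `concentration`, `R_sd`, `G_sd`,
#'   `B_sd`, one row per grid level; defaults to the published SDs.
#' @param pixel_noise_sd per-pixel Gaussian SD for rendered images
#'   (0-255 units).
#' @param gradient illumination-gradient amplitude for rendered images.
#' @param quantize round channel values to 8-bit integers (emulates
#'   integer pixel readout; off by default, the channel math is
#'   real-valued).
#' @param image_size rendered frame side length in pixels.
#' @param seed integer seed; mandatory, every stochastic call consumes it
#'   deterministically.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(grid = NULL, replicates = 3, noise = NULL,
                           pixel_noise_sd = 1, gradient = 0,
                           quantize = FALSE, image_size = 64L, seed) {
  if (missing(seed) || !is.finite(seed))
    stop("an explicit integer seed is mandatory", call. = FALSE)
  std <- tartrazine_channels("standards")
  grid <- grid %||% std$concentration
  if (is.null(noise))
    noise <- data.frame(concentration = std$concentration,
                        R_sd = std$R_sd, G_sd = std$G_sd, B_sd = std$B_sd)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (any(noise$R_sd < 0 | noise$G_sd < 0 | noise$B_sd < 0))
    stop("noise SDs must be >= 0", call. = FALSE)
  missing_lv <- setdiff(grid, noise$concentration)
  if (length(missing_lv) > 0)
    stop("no noise entry for grid level(s): ",
         paste(missing_lv, collapse = ", "), call. = FALSE)
  structure(list(grid = sort(grid), replicates = as.integer(replicates),
                 noise = noise, pixel_noise_sd = pixel_noise_sd,
                 gradient = gradient, quantize = isTRUE(quantize),
                 image_size = as.integer(image_size),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Reconstruct replicate channel tables
#'
#' Per concentration level, replicate RGB triples are drawn from
#' `Gaussian(published mean, published SD)`, clipped to \[0, 255\], and the
#' five derived channels recomputed from each replicate's RGB
#' (`mode = "consistent"`, the default, which guarantees every replicate is
#' a valid channel vector). The alternative `mode = "independent"` draws
#' all eight channels independently from their printed means and SDs; it
#' mimics the printed derived-channel SDs (which embed external conversion
#' rounding) but breaks the functional link between RGB and the derived
#' channels, and is intended only for stress-testing the regression.
#'
#' @param spec a [synthetic_spec()]; its seed drives the draws.
#' @param mode `"consistent"` (default) or `"independent"`.
#' @param means optional override of the knot table (same columns as
#'   [tartrazine_channels()]); defaults to the packaged standards.
#' @return A `calibration_set`; attribute `mode` records the generation
#'   mode.
#' @export
reconstruct_replicates <- function(spec, mode = c("consistent", "independent"),
                                   means = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  mode <- match.arg(mode)
  std <- means %||% tartrazine_channels("standards")
  missing_lv <- setdiff(spec$grid, std$concentration)
  if (length(missing_lv) > 0)
    stop("no published means for grid level(s): ",
         paste(missing_lv, collapse = ", "), call. = FALSE)
  tab <- withr::with_seed(spec$seed, {
    rows <- lapply(spec$grid, function(cc) {
      mrow <- std[std$concentration == cc, ]
      nrow_ <- spec$noise[spec$noise$concentration == cc, ]
      if (mode == "consistent") {
        rgb <- cbind(
          stats::rnorm(spec$replicates, mrow$R, nrow_$R_sd),
          stats::rnorm(spec$replicates, mrow$G, nrow_$G_sd),
          stats::rnorm(spec$replicates, mrow$B, nrow_$B_sd))
        rgb <- pmin(pmax(rgb, 0), 255)
        if (spec$quantize) rgb <- round(rgb)
        ch <- expand_channels(rgb)
      } else {
        ch <- as.data.frame(lapply(stats::setNames(CHANNEL_NAMES,
                                                   CHANNEL_NAMES),
          function(nm) stats::rnorm(spec$replicates, mrow[[nm]],
                                    mrow[[paste0(nm, "_sd")]])))
        ch[c("R", "G", "B", "I")] <-
          lapply(ch[c("R", "G", "B", "I")], function(v) pmin(pmax(v, 0), 255))
        ch[c("S", "V", "L")] <-
          lapply(ch[c("S", "V", "L")], function(v) pmin(pmax(v, 0), 100))
        ch$H <- ch$H %% 360
      }
      cbind(concentration = cc, ch)
    })
    do.call(rbind, rows)
  })
  ids <- sprintf("c%g_r%d", tab$concentration,
                 sequence(rep(spec$replicates, length(spec$grid))))
  out <- calibration_set(tab[CHANNEL_NAMES], tab$concentration, ids)
  attr(out, "mode") <- mode
  out
}

#' Concentration-to-color response model
#'
#' Piecewise-linear interpolation of mean patch RGB between knot
#' concentrations. Default knots are the published standards from 5 mg/L
#' upward (the 1 mg/L row is excluded: its printed channels are internally
#' inconsistent); over this span R and G decrease monotonically as the
#' yellow patch deepens.
#'
#' @param knots data frame with columns `concentration`, `R`, `G`, `B`.
#' @param extend_lower optional concentration below the first knot; the
#'   first segment is extended linearly down to it (clipped to \[0, 255\])
#'   and added as a synthetic knot, so patches can be rendered over a
#'   working range that starts below the lowest usable standard.
#' @return An object of class `response_model`.
#' @export
response_model <- function(knots = NULL, extend_lower = NULL) {
  if (is.null(knots)) {
    std <- tartrazine_channels("standards")
    knots <- std[std$concentration >= 5,
                 c("concentration", "R", "G", "B")]
  }
  knots <- knots[order(knots$concentration), ]
  if (!is.null(extend_lower)) {
    if (extend_lower >= min(knots$concentration))
      stop("extend_lower must lie below the first knot", call. = FALSE)
    k1 <- knots[1, ]; k2 <- knots[2, ]
    f <- (extend_lower - k1$concentration) /
      (k2$concentration - k1$concentration)
    ext <- data.frame(
      concentration = extend_lower,
      R = min(max(k1$R + f * (k2$R - k1$R), 0), 255),
      G = min(max(k1$G + f * (k2$G - k1$G), 0), 255),
      B = min(max(k1$B + f * (k2$B - k1$B), 0), 255))
    knots <- rbind(ext, knots)
  }
  if (nrow(knots) < 2) stop("need >= 2 knots", call. = FALSE)
  if (any(knots$R < 0 | knots$R > 255 | knots$G < 0 | knots$G > 255 |
          knots$B < 0 | knots$B > 255))
    stop("knot RGB must be in [0, 255]", call. = FALSE)
  structure(list(knots = knots), class = "response_model")
}

#' Interpolate patch color at a concentration
#'
#' @param model a `response_model`.
#' @param conc concentration in mg/L, inside the knot span.
#' @return Named numeric RGB triple.
#' @export
response_rgb <- function(model, conc) {
  stopifnot(inherits(model, "response_model"))
  k <- model$knots
  if (conc < min(k$concentration) || conc > max(k$concentration))
    stop("concentration ", conc, " outside the response span [",
         min(k$concentration), ", ", max(k$concentration), "] mg/L",
         call. = FALSE)
  c(R = stats::approx(k$concentration, k$R, conc)$y,
    G = stats::approx(k$concentration, k$G, conc)$y,
    B = stats::approx(k$concentration, k$B, conc)$y)
}

#' Render a synthetic sensor-patch image
#'
#' The frame is filled with the interpolated patch color for the requested
#' concentration plus per-pixel Gaussian sensor noise, an optional
#' left-to-right linear ramp emulating uneven illumination, and 8-bit
#' quantization when the spec requests it. Optionally (`capture_noise =
#' TRUE`) a capture-level Gaussian color offset, with SD interpolated from
#' the spec's per-level noise model, emulates replicate-to-replicate
#' variation of the whole patch; it is off by default, so repeated renders
#' at one concentration differ only by sensor noise.
#'
#' @param conc concentration in mg/L.
#' @param model a [response_model()].
#' @param spec a [synthetic_spec()]; `pixel_noise_sd`, `gradient`,
#'   `quantize`, `image_size` and the per-level noise model are taken from
#'   it. The spec's seed is used unless `seed` overrides it.
#' @param capture_noise draw the capture-level color offset (default
#'   `FALSE`: the patch color is exactly the interpolated response).
#' @param seed optional seed override for this single render.
#' @return An `image_record` whose metadata records the ground-truth
#'   concentration and render settings.
#' @export
render_patch <- function(conc, model = response_model(), spec,
                         capture_noise = FALSE, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  target <- response_rgb(model, conc)
  cap_sd <- if (capture_noise) {
    nz <- spec$noise
    c(stats::approx(nz$concentration, nz$R_sd, conc, rule = 2)$y,
      stats::approx(nz$concentration, nz$G_sd, conc, rule = 2)$y,
      stats::approx(nz$concentration, nz$B_sd, conc, rule = 2)$y)
  } else c(0, 0, 0)
  sz <- spec$image_size
  px <- withr::with_seed(seed %||% spec$seed, {
    color <- if (capture_noise) stats::rnorm(3, target, cap_sd) else target
    a <- array(rep(color, each = sz * sz), dim = c(sz, sz, 3))
    if (spec$pixel_noise_sd > 0)
      a <- a + stats::rnorm(length(a), 0, spec$pixel_noise_sd)
    if (spec$gradient != 0) {
      ramp <- spec$gradient * (seq_len(sz) - (sz + 1) / 2) / sz
      a <- a + rep(ramp, each = sz)  # varies along columns
    }
    a <- pmin(pmax(a, 0), 255)
    if (spec$quantize) a <- round(a)
    a
  })
  image_record(px, path = sprintf("<synthetic %g mg/L>", conc),
               metadata = list(concentration = conc,
                               capture_noise = capture_noise,
                               pixel_noise_sd = spec$pixel_noise_sd,
                               gradient = spec$gradient,
                               quantize = spec$quantize))
}

#' Simulate a repeatability experiment
#'
#' Runs `n` independent capture-extract-predict cycles at one
#' concentration: render a patch (fresh capture and pixel noise each
#' cycle), take the centered ROI mean RGB, expand to the 8-channel vector,
#' and predict with the supplied calibration model.
#'
#' @param conc nominal concentration in mg/L.
#' @param n number of cycles.
#' @param pls a fitted `pls_model`.
#' @param model a [response_model()].
#' @param spec a [synthetic_spec()] (seed, noise and render settings).
#' @param roi ROI used for extraction (default centered 16 x 16).
#' @return Numeric vector of `n` found concentrations (mg/L).
#' @export
simulate_repeatability <- function(conc, n, pls, model = response_model(),
                                   spec, roi = roi_spec()) {
  stopifnot(inherits(pls, "pls_model"), inherits(spec, "synthetic_spec"))
  seeds <- withr::with_seed(spec$seed,
                            sample.int(.Machine$integer.max, n))
  vapply(seeds, function(s) {
    img <- render_patch(conc, model, spec, seed = s)
    rgb <- roi_mean_rgb(extract_roi(img, roi))$mean
    predict(pls, as_feature_matrix(expand_channels(rgb)))
  }, numeric(1))
}
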