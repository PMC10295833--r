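#' PLS1 calibration on color-channel features
#'
#' The calibration relates the eight-channel color vector of a sensor patch
#' to analyte concentration with a single-response partial least squares
#' (PLS1) model, fitted by the classical NIPALS algorithm on autoscaled
#' features. The number of latent components is chosen by leave-one-out
#' cross-validation (highest validation R-squared, ties broken toward the
#' smaller model), and the working range can be truncated by re-running the
#' whole selection pipeline on candidate upper concentration bounds.
#'
#' @name plscal
NULL

#' Assemble a calibration set
#'
#' @param channels data frame or matrix of channel features with columns
#'   `R,G,B,I,H,S,V,L` (extra columns are ignored).
#' @param concentration numeric vector of concentrations (mg/L), one per
#'   row; must be non-negative.
#' @param sample_id optional sample labels.
#' @return An object of class `calibration_set` with elements `X` (n x 8
#'   feature matrix, hue sentinel resolved), `y`, `sample_id`.
#' @export
calibration_set <- function(channels, concentration, sample_id = NULL) {
  X <- as_feature_matrix(channels)
  y <- as.numeric(concentration)
  if (nrow(X) != length(y))
    stop("channels and concentration lengths differ", call. = FALSE)
  if (any(!is.finite(y)) || any(y < 0))
    stop("concentrations must be finite and >= 0", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("calibration needs at least 2 concentration levels", call. = FALSE)
  if (is.null(sample_id))
    sample_id <- sprintf("s%02d", seq_along(y))
  structure(list(X = X, y = y, sample_id = as.character(sample_id)),
            class = "calibration_set")
}

#' Resolve channel features into a numeric matrix
#'
#' The undefined-hue sentinel (`NA` in the `H` column, produced for
#' achromatic patches) is mapped to 0 degrees here, with a warning, so that
#' the resolution is explicit and logged rather than silent. A set mixing
#' defined and sentinel hues additionally gets a data-quality warning.
#'
#' @param channels data frame or matrix with the 8 channel columns.
#' @return Numeric n x 8 matrix with columns `R,G,B,I,H,S,V,L`.
#' @export
as_feature_matrix <- function(channels) {
  channels <- as.data.frame(channels)
  missing_cols <- setdiff(CHANNEL_NAMES, names(channels))
  if (length(missing_cols) > 0)
    stop("missing channel column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  X <- as.matrix(channels[, CHANNEL_NAMES])
  storage.mode(X) <- "double"
  nah <- is.na(X[, "H"])
  if (any(nah)) {
    warning(sum(nah), " undefined hue value(s) mapped to 0 degrees",
            call. = FALSE)
    if (!all(nah))
      warning("feature set mixes defined and undefined hues; ",
              "hue may be uninformative for these data", call. = FALSE)
    X[nah, "H"] <- 0
  }
  if (any(!is.finite(X)))
    stop("channel features contain missing or non-finite values",
         call. = FALSE)
  X
}

# NIPALS PLS1 on an already autoscaled X and centered y. For a single
# response the weight step is closed-form (no inner iteration). Only X is
# deflated; y deflation is redundant in PLS1 because scores are orthogonal.
#
# When deflation exhausts X (the residual covariance with y falls to
# numerical zero relative to the first component) the decomposition has
# saturated: higher orders cannot change the fit, so their coefficient
# columns repeat the saturated solution. This happens routinely here
# because all 8 channels are smooth functions of 3 RGB levels, capping the
# effective rank well below p.
nipals_pls1 <- function(Xs, yc, ncomp) {
  p <- ncol(Xs)
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  Xa <- Xs
  nw0 <- NULL
  a_eff <- 0L
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xa, yc))
    nw <- sqrt(sum(w^2))
    if (a == 1) {
      if (nw < 1e-12)
        stop("degenerate feature matrix: no covariance between X and y",
             call. = FALSE)
      nw0 <- nw
    }
    if (nw < 1e-8 * nw0) break  # saturated: X deflated to numerical zero
    w <- w / nw
    tt <- drop(Xa %*% w)
    t2 <- sum(tt^2)
    P[, a] <- drop(crossprod(Xa, tt)) / t2
    q[a] <- sum(yc * tt) / t2
    W[, a] <- w
    Xa <- Xa - tcrossprod(tt, P[, a])
    a_eff <- a
  }
  W <- W[, seq_len(a_eff), drop = FALSE]
  P <- P[, seq_len(a_eff), drop = FALSE]
  q <- q[seq_len(a_eff)]
  # coefficients on the scaled space, one column per model order 1..ncomp
  R <- W %*% solve(crossprod(P, W))
  Bs <- vapply(seq_len(ncomp), function(a) {
    a <- min(a, a_eff)
    drop(R[, seq_len(a), drop = FALSE] %*% q[seq_len(a)])
  }, numeric(p))
  list(W = W, P = P, q = q, ncomp_effective = a_eff,
       B_scaled = matrix(Bs, nrow = p))
}

#' Fit a PLS1 calibration model
#'
#' Features are autoscaled (column mean-centered and scaled to unit SD) and
#' the response mean-centered before NIPALS. Columns with zero variance
#' carry no information after autoscaling and are dropped with a message.
#'
#' @param data a `calibration_set`, or a feature matrix/data frame (then
#'   `y` must be given).
#' @param ncomp number of latent components A, `1 <= A <= min(n-1, p)`.
#' @param y concentrations when `data` is a bare matrix.
#' @param range optional numeric length-2 training concentration range
#'   recorded on the model; defaults to `range(y)`.
#' @return An object of class `pls_model` with centering/scaling constants,
#'   NIPALS weights/loadings, the regression coefficients mapped back to
#'   the original feature scale, and the training range.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
#' y <- 2 * X[, 1] + rnorm(10, sd = 0.01)
#' m <- fit_pls(X, ncomp = 1, y = y)
#' r_squared(y, predict(m, X))
#' @export
fit_pls <- function(data, ncomp, y = NULL, range = NULL) {
  if (inherits(data, "calibration_set")) {
    X <- data$X; y <- data$y
  } else {
    X <- as.matrix(data)
    storage.mode(X) <- "double"
    if (is.null(y)) stop("y is required when data is a matrix", call. = FALSE)
  }
  n <- nrow(X)
  keep <- apply(X, 2, stats::sd) > 0
  if (!all(keep))
    message("dropping constant feature column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  if (!any(keep)) stop("all feature columns are constant", call. = FALSE)
  Xk <- X[, keep, drop = FALSE]
  p <- ncol(Xk)
  if (length(ncomp) != 1 || ncomp < 1 || ncomp > min(n - 1, p))
    stop("ncomp must be in 1..min(n-1, p) = ", min(n - 1, p), call. = FALSE)
  x_center <- colMeans(Xk)
  x_scale <- apply(Xk, 2, stats::sd)
  Xs <- scale(Xk, center = x_center, scale = x_scale)
  y_center <- mean(y)
  fit <- nipals_pls1(Xs, y - y_center, ncomp)
  b_scaled <- fit$B_scaled[, ncomp]
  coef_orig <- stats::setNames(numeric(ncol(X)), colnames(X))
  coef_orig[keep] <- b_scaled / x_scale
  intercept <- y_center - sum(coef_orig[keep] * x_center)
  structure(list(
    features = colnames(X), kept = keep,
    x_center = x_center, x_scale = x_scale, y_center = y_center,
    weights = fit$W, x_loadings = fit$P, y_loadings = fit$q,
    coefficients = coef_orig, intercept = intercept,
    ncomp = as.integer(ncomp),
    ncomp_effective = fit$ncomp_effective,
    range = as.numeric(range %||% base::range(y))
  ), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS1 model: %d component(s), %d/%d features, range %g-%g mg/L\n",
              x$ncomp, sum(x$kept), length(x$kept), x$range[1], x$range[2]))
  invisible(x)
}

#' Predict concentration from channel features
#'
#' Predictions are returned as-is, without clipping: negative values and
#' values beyond the training range are legitimate model outputs (clipping
#' would bias detection-limit estimation). Use [flag_range()] to annotate
#' them.
#'
#' @param object a `pls_model`.
#' @param newdata feature matrix/data frame with the training feature
#'   columns, or a single named/ordered numeric vector.
#' @param ... unused.
#' @return Numeric vector of predicted concentrations (mg/L).
#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) {
    if (length(newdata) != length(object$features))
      stop("feature vector has length ", length(newdata), ", expected ",
           length(object$features), call. = FALSE)
    newdata <- matrix(newdata, nrow = 1,
                      dimnames = list(NULL, names(newdata) %||% object$features))
  }
  newdata <- as.data.frame(newdata)
  missing_cols <- setdiff(object$features, names(newdata))
  if (length(missing_cols) > 0)
    stop("newdata is missing feature(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  storage.mode(X) <- "double"
  drop(X %*% object$coefficients) + object$intercept
}

#' Flag predictions against the training range
#'
#' @param model a `pls_model`.
#' @param predicted numeric predictions.
#' @return Character vector: `"in-range"`, `"below-range"` or
#'   `"above-range"`.
#' @export
flag_range <- function(model, predicted) {
  ifelse(predicted < model$range[1], "below-range",
         ifelse(predicted > model$range[2], "above-range", "in-range"))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`, sums of squares taken about the mean of the
#' observed values.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return R-squared (can be negative for predictions worse than the mean).
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed values are constant", call. = FALSE)
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Leave-one-out cross-validation over model orders
#'
#' For each candidate number of components `1..a_max`, every sample is held
#' out in turn, the model refitted on the remainder (including re-centering
#' and re-scaling), and the held-out sample predicted. The validation
#' R-squared pools all held-out predictions; the calibration R-squared comes
#' from the full-data fit of the same order.
#'
#' @param data a `calibration_set` (or feature matrix with `y`).
#' @param a_max largest model order to scan; at most `min(n-2, p)`.
#' @inheritParams fit_pls
#' @return A data frame of class `pls_cv` with columns `ncomp`, `r2_cal`,
#'   `r2_val`.
#' @export
loo_cv <- function(data, a_max, y = NULL) {
  if (inherits(data, "calibration_set")) {
    X <- data$X; y <- data$y
  } else {
    X <- as.matrix(data)
    if (is.null(y)) stop("y is required when data is a matrix", call. = FALSE)
  }
  n <- nrow(X)
  if (n < 3) stop("leave-one-out CV needs n >= 3", call. = FALSE)
  keep <- apply(X, 2, stats::sd) > 0
  p <- sum(keep)
  if (a_max < 1 || a_max > min(n - 2, p))
    stop("a_max must be in 1..min(n-2, p) = ", min(n - 2, p), call. = FALSE)
  fit_block <- function(Xtr, ytr) {
    xc <- colMeans(Xtr); xs <- apply(Xtr, 2, stats::sd)
    xs[xs == 0] <- 1  # a column constant only within one fold: no signal
    list(xc = xc, xs = xs, yc = mean(ytr),
         B = nipals_pls1(scale(Xtr, xc, xs), ytr - mean(ytr), a_max)$B_scaled)
  }
  Xk <- X[, keep, drop = FALSE]
  full <- fit_block(Xk, y)
  pred_with <- function(blk, Xnew) {
    Z <- scale(Xnew, blk$xc, blk$xs)
    sweep(Z %*% blk$B, 2, -blk$yc)  # adds y-center back per model order
  }
  cal <- pred_with(full, Xk)
  val <- matrix(NA_real_, n, a_max)
  for (i in seq_len(n)) {
    blk <- fit_block(Xk[-i, , drop = FALSE], y[-i])
    val[i, ] <- pred_with(blk, Xk[i, , drop = FALSE])
  }
  out <- data.frame(
    ncomp = seq_len(a_max),
    r2_cal = apply(cal, 2, function(pr) r_squared(y, pr)),
    r2_val = apply(val, 2, function(pr) r_squared(y, pr))
  )
  class(out) <- c("pls_cv", "data.frame")
  out
}

#' Select the number of latent components
#'
#' The model order with the highest cross-validated R-squared; exact ties
#' are broken toward the smaller (more parsimonious) model.
#'
#' @param cv a `pls_cv` table from [loo_cv()].
#' @return Integer model order.
#' @export
select_components <- function(cv) {
  if (!is.data.frame(cv) || nrow(cv) == 0 || is.null(cv$r2_val))
    stop("cv must be a non-empty pls_cv table", call. = FALSE)
  as.integer(cv$ncomp[which.max(cv$r2_val)])
}

#' Scan candidate working ranges
#'
#' Re-runs the full calibration pipeline (LOO-CV, component selection) on
#' each candidate upper concentration bound and reports the bound whose
#' selected model has the highest validation R-squared. Truncation is
#' explicit: the returned model records its training range, and no data are
#' silently discarded from the input set.
#'
#' @param data a `calibration_set`.
#' @param upper_bounds numeric candidate upper bounds (mg/L).
#' @param a_max cap on the model orders scanned (default: the per-range
#'   maximum `min(n-2, p)`).
#' @return A list with `best_upper`, `best_model` (a `pls_model` fitted on
#'   the winning range with its selected order), `summary` (one row per
#'   candidate: upper bound, n, selected A, R-squared values) and `cv`
#'   (per-candidate `pls_cv` tables).
#' @export
working_range_scan <- function(data, upper_bounds, a_max = NULL) {
  stopifnot(inherits(data, "calibration_set"))
  upper_bounds <- sort(unique(upper_bounds))
  rows <- list(); cvs <- list()
  for (ub in upper_bounds) {
    sel <- data$y <= ub
    if (length(unique(data$y[sel])) < 3) {
      warning("candidate upper bound ", ub,
              " leaves fewer than 3 concentration levels; skipped",
              call. = FALSE)
      next
    }
    sub <- calibration_set(data$X[sel, , drop = FALSE], data$y[sel],
                           data$sample_id[sel])
    amx <- min(sum(sel) - 2, ncol(sub$X), a_max %||% Inf)
    cv <- loo_cv(sub, amx)
    a <- select_components(cv)
    rows[[as.character(ub)]] <- data.frame(
      upper = ub, n = sum(sel), ncomp = a,
      r2_cal = cv$r2_cal[a], r2_val = cv$r2_val[a])
    cvs[[as.character(ub)]] <- cv
  }
  if (length(rows) == 0)
    stop("no candidate upper bound leaves >= 3 concentration levels",
         call. = FALSE)
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  best <- summary[which.max(summary$r2_val), ]
  sel <- data$y <= best$upper
  best_model <- fit_pls(
    calibration_set(data$X[sel, , drop = FALSE], data$y[sel],
                    data$sample_id[sel]),
    ncomp = best$ncomp, range = c(min(data$y[sel]), best$upper))
  list(best_upper = best$upper, best_model = best_model,
       summary = summary, cv = cvs)
}

#' Save / load a PLS model as JSON
#'
#' The JSON file carries all centering/scaling constants, NIPALS weights and
#' loadings, coefficients, the model order and training range at full
#' numeric precision, plus a provenance block (package version, optional
#' MD5 of the training CSV). `load_pls()` restores a model whose
#' predictions are bit-identical to the saved one.
#'
#' @param model a `pls_model`.
#' @param path output JSON path.
#' @param training_csv optional path of the training channel table, hashed
#'   into the provenance block.
#' @return `save_pls`: `path` invisibly. `load_pls`: a `pls_model`.
#' @export
save_pls <- function(model, path, training_csv = NULL) {
  stopifnot(inherits(model, "pls_model"))
  obj <- unclass(model)
  obj$weights <- as.vector(obj$weights)
  obj$x_loadings <- as.vector(obj$x_loadings)
  obj$provenance <- list(
    package = "dicolor",
    version = as.character(utils::packageVersion("dicolor")),
    training_csv_md5 = if (!is.null(training_csv))
      unname(tools::md5sum(training_csv)) else NA_character_
  )
  # 17 significant digits round-trip binary64 exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_pls
#' @export
load_pls <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- sum(obj$kept)
  structure(list(
    features = obj$features, kept = stats::setNames(obj$kept, obj$features),
    x_center = obj$x_center, x_scale = obj$x_scale, y_center = obj$y_center,
    weights = matrix(obj$weights, nrow = p),
    x_loadings = matrix(obj$x_loadings, nrow = p),
    y_loadings = obj$y_loadings,
    coefficients = stats::setNames(obj$coefficients, obj$features),
    intercept = obj$intercept,
    ncomp = as.integer(obj$ncomp),
    ncomp_effective = as.integer(obj$ncomp_effective),
    range = obj$range
  ), class = "pls_model")
}
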