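# Independent oracles used to cross-check the package's own algorithms.
# These deliberately do not share code with the implementation under test.

# Ordinary least-squares predictions (closed form via lm).
ols_predict <- function(X, y, newX = X) {
  df <- as.data.frame(X)
  fit <- lm(y ~ ., data = df)
  unname(predict(fit, as.data.frame(newX)))
}

# SIMPLS (de Jong 1993) for a single response, with autoscaling of X and
# centering of y done internally. Returns predictions for newX. For PLS1
# the SIMPLS and NIPALS model subspaces coincide, so predictions must
# agree to numerical precision.
simpls1_predict <- function(X, y, ncomp, newX = X) {
  xc <- colMeans(X); xs <- apply(X, 2, sd)
  Z <- scale(X, xc, xs)
  yc <- mean(y)
  s <- crossprod(Z, y - yc)
  p <- ncol(Z)
  Rmat <- matrix(0, p, ncomp)
  Vmat <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    r <- s
    t <- Z %*% r
    nt <- sqrt(sum(t^2))
    t <- t / nt; r <- r / nt
    pv <- crossprod(Z, t)
    q[a] <- sum((y - yc) * t)
    v <- pv
    if (a > 1) {
      Vp <- Vmat[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pv)
    }
    v <- v / sqrt(sum(v^2))
    Vmat[, a] <- v
    s <- s - v %*% crossprod(v, s)
    Rmat[, a] <- r
  }
  beta_scaled <- Rmat %*% q
  drop(scale(newX, xc, xs) %*% beta_scaled) + yc
}

# Naive leave-one-out loop over the public fit/predict API; the quantity
# checked against loo_cv(), which uses its own internal block computation.
loo_brute_r2val <- function(X, y, ncomp) {
  n <- nrow(X)
  held <- vapply(seq_len(n), function(i) {
    m <- fit_pls(X[-i, , drop = FALSE], ncomp = ncomp, y = y[-i])
    predict(m, X[i, , drop = FALSE])
  }, numeric(1))
  r_squared(y, held)
}

# Round half away from zero, the convention used in printed tables
# (base round() rounds half to even).
round_half_up <- function(x, digits = 1) {
  # the 1e-9 nudge keeps decimal halves (e.g. 6.25) that sit a few ulp
  # below .5 in binary from rounding down
  sign(x) * floor(abs(x) * 10^digits + 0.5 + 1e-9) / 10^digits
}

# Random full-rank regression data.
make_linear_data <- function(n = 12, p = 4, sigma = 0.1, seed = 42) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    beta <- seq_len(p)
    y <- drop(X %*% beta) + rnorm(n, sd = sigma)
    list(X = X, y = y, beta = beta, sigma = sigma)
  })
}

# Random RGB triples for colorspace property checks.
random_triples <- function(n, seed = 7) {
  withr::with_seed(seed,
    matrix(runif(n * 3, 0, 255), n, 3, dimnames = list(NULL, c("R", "G", "B"))))
}

# Pad an arbitrary feature matrix out to the 8 named channel columns
# expected by calibration_set; unused channels are filled with independent
# noise (they carry no signal and exercise the selection machinery).
as_channels8 <- function(X) {
  X <- as.matrix(X)
  out <- matrix(rnorm(nrow(X) * 8), nrow(X), 8,
                dimnames = list(NULL, c("R", "G", "B", "I", "H", "S", "V", "L")))
  out[, seq_len(ncol(X))] <- X
  as.data.frame(out)
}

# Tiny rendered-PNG fixture on disk; returns the path.
write_png_fixture <- function(arr255, path = tempfile(fileext = ".png")) {
  png::writePNG(arr255 / 255, path)
  path
}
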