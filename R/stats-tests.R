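#' Welch's unequal-variance two-sample t-test
#'
#' Two-sided Welch t with Satterthwaite degrees of freedom and a 95%
#' confidence interval on the mean difference using the same standard
#' error and df.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param conf_level Confidence level (0.95).
#' @return One-row tibble: `estimate` (mean(x) - mean(y)), `statistic`,
#'   `df`, `p_value`, `conf_low`, `conf_high`.
#' @export
welch_test <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("zero variance in both samples")
  tt <- stats::t.test(x, y, var.equal = FALSE, conf.level = conf_level)
  tibble::tibble(estimate = unname(diff(rev(tt$estimate))),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 conf_low = tt$conf.int[1], conf_high = tt$conf.int[2])
}

#' Cohen's d with Hedges-Olkin confidence interval
#'
#' `d` is the mean difference divided by the pooled standard deviation
#' (with `n - 1` weights); the CI uses the Hedges-Olkin large-sample
#' variance `var(d) = (nx + ny)/(nx * ny) + d^2 / (2 (nx + ny))` and normal
#' quantiles.
#'
#' @inheritParams welch_test
#' @return One-row tibble: `d`, `conf_low`, `conf_high`.
#' @export
cohens_d <- function(x, y, conf_level = 0.95) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2, ny >= 2)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2))
  if (sp == 0) stop("pooled SD is zero")
  d <- (mean(x) - mean(y)) / sp
  v <- (nx + ny) / (nx * ny) + d^2 / (2 * (nx + ny))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(d = d, conf_low = d - z * sqrt(v), conf_high = d + z * sqrt(v))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Textbook step-up adjusted values with enforced monotonicity, capped at
#' 1; applied within one family (here: one metric's 13 bands).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of adjusted q-values.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Robust linear regression by iteratively reweighted least squares
#'
#' M-estimation with the Tukey bisquare weight function (tuning constant
#' 4.685), scale estimated as `MAD(residuals) / 0.6745`, iterated to a
#' relative coefficient change below `tol`. Standard errors use the
#' classical M-estimator covariance with Huber's small-sample correction;
#' p-values use the t distribution with `n - p` df.
#'
#' @param y Response vector.
#' @param X Design matrix including the intercept column.
#' @param tol Relative coefficient-change convergence tolerance (1e-8).
#' @param max_iter Maximum IRLS iterations.
#' @return A `robust_fit` object: tibble `coefficients` (`term`,
#'   `estimate`, `std_error`, `statistic`, `p_value`), `weights`, `scale`,
#'   `fitted`, `residuals`, `converged`.
#' @export
robust_fit <- function(y, X, tol = 1e-8, max_iter = 200) {
  core <- irls_core(y, as.matrix(X), tol = tol, max_iter = max_iter)
  terms <- colnames(as.matrix(X)) %||% paste0("x", seq_along(core$beta))
  n <- length(y)
  structure(list(
    coefficients = tibble::tibble(
      term = terms, estimate = unname(core$beta),
      std_error = unname(core$se), statistic = unname(core$tstat),
      p_value = 2 * stats::pt(-abs(unname(core$tstat)),
                              df = n - length(core$beta))),
    weights = core$weights, scale = core$scale,
    fitted = core$fitted, residuals = core$residuals,
    converged = core$converged, n = n), class = "robust_fit")
}

# IRLS workhorse returning plain vectors (also used inside permutation
# loops where tibble assembly would dominate the runtime)
irls_core <- function(y, X, tol = 1e-8, max_iter = 200) {
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n > p)
  qr_x <- qr(X)
  if (qr_x$rank < p)
    stop("design is rank deficient; collinear column(s): ",
         paste(colnames(X)[qr_x$pivot[(qr_x$rank + 1):p]], collapse = ", "))
  cc <- 4.685
  beta <- qr.coef(qr_x, y)
  w <- rep(1, n)
  scale <- NA_real_
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    r <- y - drop(X %*% beta)
    scale <- stats::mad(r, center = 0, constant = 1) / 0.6745
    if (scale < 1e-12 * max(1, stats::mad(y, constant = 1)))
      break  # (near-)exact fit; weights undefined, keep current beta
    u <- r / (cc * scale)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w > 0) < p) break  # redescending weights killed the fit; keep beta
    fit <- stats::lm.wfit(X, y, w)
    new_beta <- fit$coefficients
    if (anyNA(new_beta)) break
    if (max(abs(new_beta - beta)) <= tol * max(abs(beta), 1e-12)) {
      beta <- new_beta; converged <- TRUE; break
    }
    beta <- new_beta
  }
  r <- y - drop(X %*% beta)
  # classical M-estimator covariance with Huber's small-sample correction:
  # V = K^2 s^2 [sum psi(u)^2 / (n-p)] / [mean psi'(u)]^2 (X'X)^-1
  if (is.finite(scale) && scale > 0) {
    u <- r / scale
    inb <- abs(u) < cc
    psi <- ifelse(inb, u * (1 - (u / cc)^2)^2, 0)
    dpsi <- ifelse(inb, (1 - (u / cc)^2) * (1 - 5 * (u / cc)^2), 0)
    m1 <- mean(dpsi)
    K <- 1 + p / n * stats::var(dpsi) / m1^2
    s2 <- scale^2 * sum(psi^2) / (n - p) / m1^2
    V <- tryCatch(K^2 * s2 * chol2inv(chol(crossprod(X))),
                  error = function(e) matrix(NA, p, p))
  } else {
    # degenerate scale: fall back to the OLS covariance
    s2 <- sum(r^2) / (n - p)
    V <- tryCatch(s2 * chol2inv(chol(crossprod(X))),
                  error = function(e) matrix(NA, p, p))
  }
  se <- sqrt(diag(V))
  list(beta = beta, se = se, tstat = beta / se, weights = w, scale = scale,
       fitted = drop(X %*% beta), residuals = r, converged = converged)
}

#' @export
print.robust_fit <- function(x, ...) {
  cat("<robust IRLS fit> n =", x$n, "\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.robust_fit <- function(x, ...) x$coefficients

#' Freedman-Lane permutation test for one regressor
#'
#' Tests the regressor(s) in `X_full` absent from `X_reduced` while
#' controlling for the reduced-model covariates: residuals of the reduced
#' fit are permuted and added back to the reduced fitted values, the full
#' model is refit on each surrogate response, and the observed |t| of the
#' tested coefficient is compared with its permutation distribution
#' (two-sided, add-one estimator).
#'
#' @param y Response.
#' @param X_full Full design matrix (intercept + covariates + tested term).
#' @param X_reduced Reduced design (columns must be a subset of `X_full`).
#' @param term Column name (or index into `X_full`) of the tested
#'   coefficient; defaults to the column absent from `X_reduced`.
#' @param B Number of permutations (10,000; a warning is logged below 100).
#' @param seed Integer seed.
#' @param fitter `"robust"` (IRLS, the default) or `"ols"`.
#' @return List: `p_perm`, `t_obs`, `B`, `t_perm`.
#' @export
freedman_lane <- function(y, X_full, X_reduced, term = NULL, B = 10000,
                          seed = 1, fitter = c("robust", "ols")) {
  fitter <- match.arg(fitter)
  X_full <- as.matrix(X_full); X_reduced <- as.matrix(X_reduced)
  if (!all(colnames(X_reduced) %in% colnames(X_full)))
    stop("X_reduced columns must be a subset of X_full")
  if (B < 100) warning("B = ", B, " permutations is very low")
  if (is.null(term)) {
    term <- setdiff(colnames(X_full), colnames(X_reduced))
    if (length(term) != 1)
      stop("cannot infer tested term; supply `term`")
  }
  k <- if (is.character(term)) match(term, colnames(X_full)) else as.integer(term)

  tstat_of <- function(yy) {
    if (fitter == "robust") irls_core(yy, X_full)$tstat[k]
    else {
      f <- stats::lm.fit(X_full, yy)
      r <- f$residuals
      s2 <- sum(r^2) / (length(yy) - ncol(X_full))
      se <- sqrt(diag(chol2inv(chol(crossprod(X_full)))) * s2)
      f$coefficients[k] / se[k]
    }
  }
  t_obs <- tstat_of(y)

  red <- if (fitter == "robust") {
    f <- irls_core(y, X_reduced)
    list(fitted = f$fitted, residuals = f$residuals)
  } else {
    f <- stats::lm.fit(X_reduced, y)
    list(fitted = f$fitted.values, residuals = f$residuals)
  }

  t_perm <- with_seed(seed, vapply(seq_len(B), function(b) {
    y_star <- red$fitted + sample(red$residuals)
    tstat_of(y_star)
  }, numeric(1)))
  list(p_perm = (1 + sum(abs(t_perm) >= abs(t_obs))) / (1 + B),
       t_obs = t_obs, B = B, t_perm = t_perm)
}

#' Group tests for broadband complexity (LZC)
#'
#' Welch t, Mann-Whitney U, and a label-swap permutation test on the
#' difference of means, plus Cohen's d.
#'
#' @inheritParams welch_test
#' @param B Label-swap permutations (10,000).
#' @param seed Integer seed.
#' @return One-row tibble: `p_welch`, `p_mann_whitney`, `p_perm`, `d`,
#'   `estimate`.
#' @export
lzc_tests <- function(x, y, B = 10000, seed = 1) {
  w <- welch_test(x, y)
  mw <- stats::wilcox.test(x, y, exact = (length(x) < 50 && length(y) < 50))
  obs <- mean(x) - mean(y)
  pooled <- c(x, y); nx <- length(x)
  perm <- with_seed(seed, vapply(seq_len(B), function(b) {
    idx <- sample(length(pooled), nx)
    mean(pooled[idx]) - mean(pooled[-idx])
  }, numeric(1)))
  tibble::tibble(p_welch = w$p_value, p_mann_whitney = mw$p.value,
                 p_perm = (1 + sum(abs(perm) >= abs(obs))) / (1 + B),
                 d = cohens_d(x, y)$d, estimate = obs)
}
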