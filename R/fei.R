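#' Functional excitation-inhibition ratio (fE/I)
#'
#' Quantifies the coupling between oscillation amplitude and the scaling of
#' its fluctuations. The envelope is cut into fixed-length windows (5 s,
#' 80% overlap); for each window the mean amplitude `wAmp` is recorded, the
#' amplitude is normalized by `wAmp`, integrated into a profile
#' (cumulative sum of normalized amplitude minus one), linearly detrended,
#' and summarized by its RMS, the windowed detrended normalized fluctuation
#' `wDNF`. Then `fE/I = 1 - cor(wAmp, wDNF)` (Pearson), pooling windows
#' across segments; windows never straddle segment joins. Values near 1
#' indicate balanced excitation-inhibition dynamics, above/below 1
#' excitation-/inhibition-dominance.
#'
#' The estimate is only interpretable when the envelope carries long-range
#' temporal correlations, so it is gated on the DFA exponent: when
#' `alpha <= gate` (0.6) the value is reported invalid (`NA`).
#'
#' @param envelope An `envelope` object, or numeric vector with `fs`.
#' @param window Window length in seconds (5).
#' @param overlap Fractional window overlap (0.8).
#' @param gate DFA-exponent validity threshold (0.6).
#' @param dfa_result Optional precomputed [dfa()] result for the same
#'   envelope; computed internally when missing.
#' @param fs Sampling rate for bare numeric input.
#' @return A `fei_result`: `value` (`NA` when gated out), `valid`, `alpha`,
#'   `wAmp`, `wDNF`, `reason`.
#' @export
fei <- function(envelope, window = 5, overlap = 0.8, gate = 0.6,
                dfa_result = NULL, fs = NULL) {
  if (inherits(envelope, "envelope")) {
    x <- envelope$amp; fs <- envelope$fs
    bounds <- envelope$segment_bounds
  } else {
    x <- if (is.matrix(envelope)) envelope else matrix(envelope, nrow = 1)
    if (is.null(fs)) stop("fs required for bare numeric input")
    bounds <- cbind(start = 1L, end = ncol(x))
  }
  if (is.null(dfa_result)) dfa_result <- dfa(envelope, fs = fs)
  alpha <- dfa_result$alpha

  w <- as.integer(round(window * fs))
  step <- max(1L, as.integer(round(w * (1 - overlap))))
  t <- seq_len(w); tc <- t - mean(t); stt <- sum(tc^2)

  wAmp <- c(); wDNF <- c()
  for (ch in seq_len(nrow(x))) {
    for (s in seq_len(nrow(bounds))) {
      seg <- x[ch, bounds[s, 1]:bounds[s, 2]]
      if (length(seg) < w) next
      starts <- seq(1L, length(seg) - w + 1L, by = step)
      M <- vapply(starts, function(s0) seg[s0:(s0 + w - 1L)], numeric(w))
      mu <- colMeans(M)
      ok <- mu > 0
      if (!any(ok)) next
      M <- M[, ok, drop = FALSE]; mu <- mu[ok]
      # profile of normalized amplitude, detrended per window
      P <- apply(sweep(M, 2, mu, "/") - 1, 2, cumsum)
      P <- P - matrix(colMeans(P), w, ncol(P), byrow = TRUE)
      beta <- drop(crossprod(tc, P)) / stt
      R <- P - outer(tc, beta)
      wAmp <- c(wAmp, mu)
      wDNF <- c(wDNF, sqrt(colMeans(R^2)))
    }
  }

  if (length(wAmp) < 10)
    return(fei_invalid(alpha, wAmp, wDNF, "fewer than 10 windows"))
  if (stats::sd(wAmp) == 0 || stats::sd(wDNF) == 0)
    return(fei_invalid(alpha, wAmp, wDNF, "zero variance in wAmp or wDNF"))
  if (!is.finite(alpha) || alpha <= gate)
    return(fei_invalid(alpha, wAmp, wDNF,
                       sprintf("DFA exponent %.3f <= gate %.2f", alpha, gate)))

  structure(list(
    value = 1 - stats::cor(wAmp, wDNF), valid = TRUE, alpha = alpha,
    wAmp = wAmp, wDNF = wDNF, reason = NULL), class = "fei_result")
}

fei_invalid <- function(alpha, wAmp, wDNF, reason) {
  structure(list(value = NA_real_, valid = FALSE, alpha = alpha,
                 wAmp = wAmp, wDNF = wDNF, reason = reason),
            class = "fei_result")
}

#' @export
print.fei_result <- function(x, ...) {
  if (x$valid)
    cat("<fE/I> ", signif(x$value, 4), " (alpha = ", signif(x$alpha, 3),
        ", ", length(x$wAmp), " windows)\n", sep = "")
  else
    cat("<fE/I> invalid: ", x$reason, "\n", sep = "")
  invisible(x)
}

#' @export
glance.fei_result <- function(x, ...) {
  tibble::tibble(fei = x$value, valid = x$valid, alpha = x$alpha,
                 n_windows = length(x$wAmp))
}
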