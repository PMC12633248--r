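#' Detrended fluctuation analysis of a band envelope
#'
#' Estimates the long-range temporal correlation (Hurst) exponent of the
#' amplitude envelope. Per segment the envelope is demeaned and cumulatively
#' summed into a profile; the profile is cut into windows of length `s`
#' advanced with 50% overlap; each window is linearly detrended and its RMS
#' residual computed. `F(s)` is the RMS over all windows pooled across
#' segments, and the exponent is the least-squares slope of
#' `log10 F(s)` on `log10 s` over `n_sizes` geometrically spaced window
#' lengths in `[s_min, s_max]`. Windows never straddle segment joins.
#'
#' The default `s_min` follows the rule `max(1, 8 / f_lo)` seconds (at
#' least eight cycles of the band's slowest component per window) when the
#' input is a band envelope carrying its frequency range.
#'
#' @param envelope An `envelope` object, or a numeric vector with `fs`.
#' @param s_min Smallest window length in seconds (see Details for default).
#' @param s_max Largest window length in seconds (30).
#' @param overlap Fractional window overlap (0.5).
#' @param n_sizes Number of geometrically spaced window lengths (10).
#' @param fs Sampling rate when `envelope` is a bare vector.
#' @return A `dfa_result`: `alpha`, `s` (window lengths, s), `F` (fluctuation
#'   function), `fit_range`, `r_squared`, `n_windows` per size.
#' @export
dfa <- function(envelope, s_min = NULL, s_max = 30, overlap = 0.5,
                n_sizes = 10, fs = NULL) {
  if (inherits(envelope, "envelope")) {
    x <- envelope$amp; fs <- envelope$fs
    bounds <- envelope$segment_bounds
    if (is.null(s_min)) s_min <- max(1, 8 / envelope$band[1])
  } else {
    x <- if (is.matrix(envelope)) envelope else matrix(envelope, nrow = 1)
    if (is.null(fs)) stop("fs required for bare numeric input")
    bounds <- cbind(start = 1L, end = ncol(x))
    if (is.null(s_min)) s_min <- 1
  }
  if (s_min >= s_max) stop("s_min (", s_min, ") must be < s_max (", s_max, ")")
  if (all(apply(x, 1, stats::sd) == 0)) stop("constant envelope: zero variance")

  sizes_s <- exp(seq(log(s_min), log(s_max), length.out = n_sizes))
  sizes <- unique(pmax(4L, as.integer(round(sizes_s * fs))))

  # mean squared residual of each window, pooled over channels and segments
  Fs <- vapply(sizes, function(w) {
    step <- max(1L, as.integer(round(w * (1 - overlap))))
    ms <- c(); nw <- 0L
    for (ch in seq_len(nrow(x))) {
      for (s in seq_len(nrow(bounds))) {
        seg <- x[ch, bounds[s, 1]:bounds[s, 2]]
        prof <- cumsum(seg - mean(seg))
        if (length(prof) < w) next
        starts <- seq(1L, length(prof) - w + 1L, by = step)
        ms <- c(ms, window_msr(prof, starts, w))
        nw <- nw + length(starts)
      }
    }
    if (nw < 2) return(c(NA_real_, nw))
    c(sqrt(mean(ms)), nw)
  }, numeric(2))

  if (any(is.na(Fs[1, ])))
    stop("fewer than 2 windows at window length ",
         max(sizes[is.na(Fs[1, ])]) / fs, " s")

  lx <- log10(sizes / fs); ly <- log10(Fs[1, ])
  fit <- stats::lm.fit(cbind(1, lx), ly)
  alpha <- fit$coefficients[2]
  r2 <- 1 - sum(fit$residuals^2) / sum((ly - mean(ly))^2)
  structure(list(
    alpha = unname(alpha), s = sizes / fs, F = Fs[1, ],
    fit_range = c(s_min, s_max), r_squared = r2, n_windows = Fs[2, ]
  ), class = "dfa_result")
}

# mean squared residual of linear detrend for windows of length w starting
# at `starts` within profile `prof`; vectorized over windows
window_msr <- function(prof, starts, w) {
  t <- seq_len(w)
  tc <- t - mean(t)
  stt <- sum(tc^2)
  M <- vapply(starts, function(s0) prof[s0:(s0 + w - 1L)], numeric(w))
  M <- M - matrix(colMeans(M), w, length(starts), byrow = TRUE)
  beta <- drop(crossprod(tc, M)) / stt
  res <- M - outer(tc, beta)
  colMeans(res^2)
}

#' Count DFA windows available over a segment layout
#'
#' @param segments Segment lengths in seconds (e.g. `c(49, 60, 60, 60, 49)`).
#' @param s Window length in seconds.
#' @param overlap Fractional overlap between successive windows (0 =
#'   non-overlapping, the convention used when counting independent windows).
#' @return Integer window count.
#' @examples
#' dfa_window_count(c(49, 60, 60, 60, 49), 30)  # 8 independent windows
#' @export
dfa_window_count <- function(segments, s, overlap = 0) {
  step <- s * (1 - overlap)
  sum(vapply(segments, function(L) {
    if (L < s) 0L else as.integer(floor((L - s) / step) + 1)
  }, integer(1)))
}

#' @export
print.dfa_result <- function(x, ...) {
  cat("<DFA> alpha =", signif(x$alpha, 3),
      " fit range", paste(signif(x$fit_range, 3), collapse = "-"),
      "s  R^2 =", signif(x$r_squared, 3), "\n")
  invisible(x)
}

#' @export
tidy.dfa_result <- function(x, ...) {
  tibble::tibble(s = x$s, fluctuation = x$F, n_windows = x$n_windows)
}

#' @export
glance.dfa_result <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, r_squared = x$r_squared,
                 s_min = x$fit_range[1], s_max = x$fit_range[2])
}
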