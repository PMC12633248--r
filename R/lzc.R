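#' Lempel-Ziv complexity of a signal
#'
#' Binarizes the signal at its median and counts the number of distinct
#' patterns `c(n)` under LZ76 exhaustive-history parsing, normalized as
#' `C = c(n) * log2(n) / n` so that an i.i.d. fair-coin sequence approaches
#' `C = 1` asymptotically. Higher values indicate a more irregular signal.
#'
#' @param series Single-channel numeric vector (length >= 64), or an
#'   already-binary integer vector of 0/1 (used as-is).
#' @param threshold Binarization threshold; defaults to the median.
#' @return An `lzc_result`: `c_n` (pattern count), `complexity`
#'   (normalized), `n`, `threshold`, `degenerate` (constant input).
#' @examples
#' lzc(sin(seq(0, 20 * pi, length.out = 1024)))
#' @export
lzc <- function(series, threshold = NULL) {
  stopifnot(is.numeric(series), length(series) >= 64, all(is.finite(series)))
  n <- length(series)
  if (all(series %in% c(0L, 1L))) {
    b <- as.integer(series)
    thr <- NA_real_
  } else {
    thr <- threshold %||% stats::median(series)
    b <- as.integer(series > thr)
  }
  degenerate <- length(unique(b)) < 2L
  c_n <- if (degenerate) 1L else lz76_count(b)
  structure(list(c_n = c_n, complexity = c_n * log2(n) / n, n = n,
                 threshold = thr, degenerate = degenerate),
            class = "lzc_result")
}

#' Broadband Lempel-Ziv complexity of a harmonized recording
#'
#' Band-passes each channel to 1-45 Hz (zero-phase, per segment), computes
#' per-channel [lzc()] on the concatenated broadband signal, and averages
#' across channels.
#'
#' @param series A `harmonized` object.
#' @param band Broadband range in Hz (default `c(1, 45)`).
#' @return Mean normalized complexity across channels.
#' @export
lzc_broadband <- function(series, band = c(1, 45)) {
  stopifnot(inherits(series, "harmonized"))
  bf <- signal::butter(2, band / (series$fs / 2), type = "pass")
  vals <- apply(series$samples, 1, function(ch) {
    filt <- unlist(lapply(seq_len(nrow(series$segment_bounds)), function(s) {
      idx <- series$segment_bounds[s, 1]:series$segment_bounds[s, 2]
      signal::filtfilt(bf, ch[idx])
    }))
    lzc(filt)$complexity
  })
  mean(vals)
}

#' @export
print.lzc_result <- function(x, ...) {
  cat("<LZC> c(n) =", x$c_n, " C =", signif(x$complexity, 4),
      " (n =", x$n, ")\n")
  invisible(x)
}

#' @export
glance.lzc_result <- function(x, ...) {
  tibble::tibble(c_n = x$c_n, complexity = x$complexity, n = x$n,
                 degenerate = x$degenerate)
}
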