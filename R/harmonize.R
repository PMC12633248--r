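#' Harmonize a recording into the common five-segment eyes-closed series
#'
#' Builds the 4.65-minute (278.8 s) eyes-closed series used by all metrics.
#' Healthy-control recordings arrive as five 60-s epochs which are
#' concatenated in order; patient recordings arrive as one continuous
#' eyes-closed record which is split into five 60-s epochs and reordered
#' 1-3-5-2-4 before concatenation. In both paths 10.6 s are then trimmed
#' from each end, yielding segment lengths of (49.4, 60, 60, 60, 49.4) s
#' (reported as 49/60/60/60/49 s) and identical total duration for both
#' groups.
#'
#' @param recording A `recording` object (see [gen_subject()] /
#'   [read_recording()]).
#' @param mode `"HC"` (epoch-wise path) or `"MDD"` (continuous path).
#'   Defaults to the recording's group label.
#' @param trim Seconds removed from each end after concatenation (10.6).
#' @return A `harmonized` object: list with `samples` (channels x time),
#'   `fs`, `labels`, `segments` (segment lengths in s), `segment_bounds`
#'   (start/end sample indices per segment), `mode`.
#' @export
harmonize <- function(recording, mode = NULL, trim = 10.6) {
  stopifnot(inherits(recording, "recording"))
  fs <- recording$fs
  mode <- mode %||% recording$group
  mode <- match.arg(toupper(mode), c("HC", "MDD"))
  ep_len <- as.integer(round(60 * fs))
  x <- recording$samples

  if (mode == "HC") {
    eb <- recording$epochs
    if (is.null(eb) || nrow(eb) < 5)
      stop("HC path needs five epochs; recording has ",
           if (is.null(eb)) 0 else nrow(eb))
    short <- which((eb[, 2] - eb[, 1] + 1) < ep_len)
    if (length(short))
      stop("epoch(s) ", paste(short, collapse = ", "), " shorter than 60 s (",
           "need ", ep_len, " samples, have ",
           paste(eb[short, 2] - eb[short, 1] + 1, collapse = ", "), ")")
    parts <- lapply(1:5, function(i) x[, eb[i, 1]:(eb[i, 1] + ep_len - 1L), drop = FALSE])
  } else {
    need <- 5L * ep_len
    if (ncol(x) < need)
      stop("MDD path needs a continuous record of >= 300 s (", need,
           " samples); have ", ncol(x), " (short by ", need - ncol(x), ")")
    parts <- lapply(1:5, function(i)
      x[, ((i - 1L) * ep_len + 1L):(i * ep_len), drop = FALSE])
    parts <- parts[c(1, 3, 5, 2, 4)]
  }

  y <- do.call(cbind, parts)
  ntrim <- as.integer(round(trim * fs))
  y <- y[, (ntrim + 1L):(ncol(y) - ntrim), drop = FALSE]

  # segment boundaries in the trimmed series: the five epochs survive as
  # (60 - trim, 60, 60, 60, 60 - trim) s pieces
  seg_len <- c(ep_len - ntrim, ep_len, ep_len, ep_len, ep_len - ntrim)
  ends <- cumsum(seg_len)
  starts <- c(1L, ends[-5] + 1L)
  structure(list(
    samples = y, fs = fs, labels = recording$labels,
    segments = seg_len / fs,
    segment_bounds = cbind(start = starts, end = ends),
    mode = mode, subject = recording$subject
  ), class = "harmonized")
}

#' Construct the 13 log-spaced frequency bands
#'
#' One delta bin (1-4 Hz) followed by 12 geometrically spaced bins from
#' 4 Hz to 73 Hz (common ratio `(f_max/4)^(1/12)`). Adjacent bins share
#' edges exactly; displayed edges are rounded to 0.1 Hz.
#'
#' @param f_min Lower edge of the first bin (Hz).
#' @param f_max Upper edge of the last bin (Hz).
#' @param n_geometric Number of geometric bins above the first bin.
#' @return A tibble with columns `band` (label `"flo-fhi"` rounded to
#'   0.1 Hz), `f_lo`, `f_hi` (exact edges, Hz).
#' @examples
#' make_bands()   # 13 bins spanning 1-73 Hz
#' @export
make_bands <- function(f_min = 1, f_max = 73, n_geometric = 12) {
  stopifnot(f_min < f_max, f_min > 0, n_geometric >= 1)
  anchor <- 4
  edges <- c(f_min, anchor * (f_max / anchor)^((0:n_geometric) / n_geometric))
  tibble::tibble(
    band = paste0(round(edges[-length(edges)], 1), "-", round(edges[-1], 1)),
    f_lo = edges[-length(edges)],
    f_hi = edges[-1]
  )
}

#' @export
print.harmonized <- function(x, ...) {
  cat("<harmonized series> ", nrow(x$samples), " channel(s), ",
      ncol(x$samples), " samples @ ", x$fs, " Hz (",
      round(ncol(x$samples) / x$fs, 1), " s; segments ",
      paste(round(x$segments, 1), collapse = "/"), " s; path ", x$mode, ")\n",
      sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
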