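#' Generate one synthetic resting-state EEG recording
#'
#' Builds a multichannel recording as the sum of narrowband components --
#' one per requested band, each realized from its [envelope_profile()] --
#' plus a broadband 1/f background 20 dB below the oscillatory components.
#' The epoch plan is five contiguous 60-s eyes-closed epochs, recorded in
#' `epochs`. Channels are independent realizations sharing the subject's
#' profile parameters. Deterministic under `seed`.
#'
#' @param band_profiles Named list mapping band label (`"flo-fhi"`, as in
#'   [make_bands()]) or a list of `list(band = c(f_lo, f_hi), profile = ...)`
#'   entries. May be empty (pure 1/f background).
#' @param fs Sampling rate (Hz).
#' @param n_channels Number of channels.
#' @param n_epochs,epoch_s Epoch plan (five 60-s epochs).
#' @param subject Subject id string.
#' @param group Group label (`"HC"` or `"MDD"`).
#' @param age,sex Covariates stored in the recording.
#' @param background_db Background level relative to the oscillatory
#'   components, in dB (-20).
#' @param seed Integer seed.
#' @return A `recording` object: `samples` (channels x time), `fs`,
#'   `labels`, `subject`, `group`, `age`, `sex`, `epochs` (start/end
#'   sample indices).
#' @export
gen_subject <- function(band_profiles = list(), fs = 200, n_channels = 1,
                        n_epochs = 5, epoch_s = 60,
                        subject = "sub-01", group = "HC",
                        age = NA_real_, sex = NA_character_,
                        background_db = -20, seed = 1) {
  bands <- normalize_band_profiles(band_profiles)
  if (length(bands)) {
    keys <- vapply(bands, function(b) paste(signif(b$band, 6), collapse = "-"),
                   character(1))
    if (anyDuplicated(keys))
      stop("duplicate band specification: ", keys[duplicated(keys)][1])
  }
  n <- as.integer(n_epochs * epoch_s * fs)
  samples <- matrix(0, n_channels, n)
  for (ch in seq_len(n_channels)) {
    ch_seed <- child_seed(seed, "subject", subject, "channel", ch)
    samples[ch, ] <- with_seed(ch_seed, {
      x <- numeric(n)
      for (b in bands) {
        g <- gen_band_signal(b$band, b$profile, n_epochs * epoch_s, fs)
        x <- x + g$signal
      }
      osc_rms <- if (length(bands)) sqrt(mean(x^2)) else 1
      bg <- pink_noise(n) * osc_rms * 10^(background_db / 20)
      x + bg
    })
  }
  ep_len <- as.integer(epoch_s * fs)
  starts <- seq(1L, by = ep_len, length.out = n_epochs)
  structure(list(
    samples = samples, fs = fs,
    labels = paste0("ch", seq_len(n_channels)),
    subject = subject, group = group, age = age, sex = sex,
    epochs = cbind(start = starts, end = starts + ep_len - 1L)
  ), class = "recording")
}

# spectrally synthesized 1/f (power) noise, unit RMS
pink_noise <- function(n) {
  nf <- n %/% 2
  f <- seq_len(nf)
  amp <- 1 / sqrt(f)
  phase <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- c(0, spec, if (n %% 2 == 0) Conj(rev(spec[-nf])) else Conj(rev(spec)))
  x <- Re(stats::fft(full, inverse = TRUE))
  x <- x[seq_len(n)]
  x / sqrt(mean(x^2))
}

normalize_band_profiles <- function(band_profiles) {
  if (!length(band_profiles)) return(list())
  bands <- make_bands()
  lapply(seq_along(band_profiles), function(i) {
    bp <- band_profiles[[i]]
    if (inherits(bp, "envelope_profile")) {
      lbl <- names(band_profiles)[i]
      if (is.null(lbl) || !nzchar(lbl))
        stop("band_profiles entries given as profiles must be named by band label")
      row <- match(lbl, bands$band)
      if (is.na(row)) stop("unknown band label '", lbl, "'; see make_bands()")
      list(band = c(bands$f_lo[row], bands$f_hi[row]), profile = bp)
    } else {
      stopifnot(is.list(bp), !is.null(bp$band), !is.null(bp$profile))
      bp
    }
  })
}

#' @export
print.recording <- function(x, ...) {
  cat("<recording ", x$subject, "> ", nrow(x$samples), " channel(s) x ",
      ncol(x$samples), " samples @ ", x$fs, " Hz; group ", x$group,
      if (!is.na(x$age)) paste0("; age ", x$age), "\n", sep = "")
  invisible(x)
}
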