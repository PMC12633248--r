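#' Compute the full metric table for a cohort
#'
#' For every recording: harmonize into the common five-segment series,
#' decompose into the 13 log-spaced band envelopes, and compute per channel
#' the five band-wise indices -- bistability (BiS), DFA exponent, high/low
#' occupancy ratio (E/I_HLP), fE/I, high/low separation (E+I_HLS) -- plus
#' broadband Lempel-Ziv complexity. Channel values are averaged (fE/I over
#' valid channels only; a subject's cell is `NA` when every channel is
#' gated out by the DFA criterion).
#'
#' @param recordings A list of `recording` objects, or the list returned by
#'   [gen_cohort()] (its `$recordings` is used).
#' @param bands Band table from [make_bands()].
#' @param fei_gate DFA-exponent validity threshold for fE/I (0.6).
#' @param em_restarts EM restarts for the biexponential fit (20).
#' @param verbose Print one line per subject.
#' @return A tibble (the metric table): `subject`, `group`, `age`, `sex`,
#'   then one column per metric x band named `"metric@band"`
#'   (`bis@`, `dfa@`, `ei_hlp@`, `fei@`, `ei_hls@`), and `lzc`.
#' @export
compute_metrics <- function(recordings, bands = make_bands(), fei_gate = 0.6,
                            em_restarts = 20, verbose = FALSE) {
  if (is.list(recordings) && !is.null(recordings$recordings))
    recordings <- recordings$recordings
  if (inherits(recordings, "recording")) recordings <- list(recordings)
  rows <- lapply(recordings, function(rec) {
    if (verbose) cat("metrics:", rec$subject, "\n")
    vals <- subject_metrics(rec, bands = bands, fei_gate = fei_gate,
                            em_restarts = em_restarts)
    tibble::tibble(subject = rec$subject, group = rec$group,
                   age = rec$age, sex = rec$sex, !!!as.list(vals))
  })
  dplyr::bind_rows(rows)
}

#' Band-wise metrics for a single recording
#'
#' @inheritParams compute_metrics
#' @param recording A `recording`.
#' @return Named numeric vector: `metric@band` for the five band-wise
#'   metrics plus `lzc`.
#' @export
subject_metrics <- function(recording, bands = make_bands(), fei_gate = 0.6,
                            em_restarts = 20) {
  harm <- harmonize(recording)
  n_ch <- nrow(harm$samples)
  metrics <- c("bis", "dfa", "ei_hlp", "fei", "ei_hls")
  acc <- matrix(NA_real_, n_ch, length(metrics) * nrow(bands))
  colnames(acc) <- as.vector(outer(metrics, bands$band, paste, sep = "@"))

  for (ch in seq_len(n_ch)) {
    one <- harm
    one$samples <- harm$samples[ch, , drop = FALSE]
    for (b in seq_len(nrow(bands))) {
      band <- c(bands$f_lo[b], bands$f_hi[b])
      env <- band_envelope(one, band)
      d <- dfa(env)
      fe <- fei(env, gate = fei_gate, dfa_result = d)
      fit <- fit_biexp(env, restarts = em_restarts)
      lbl <- bands$band[b]
      acc[ch, paste0("dfa@", lbl)] <- d$alpha
      acc[ch, paste0("fei@", lbl)] <- fe$value
      acc[ch, paste0("bis@", lbl)] <- bistability_index(fit)
      if (isTRUE(fit$identified)) {
        acc[ch, paste0("ei_hlp@", lbl)] <- ei_hlp(fit)
        acc[ch, paste0("ei_hls@", lbl)] <- ei_hls(fit)
      } else {
        # collapsed mixture: no separation between states -- degenerate
        # values keep missingness confined to the gated fE/I cells
        acc[ch, paste0("ei_hlp@", lbl)] <- 1
        acc[ch, paste0("ei_hls@", lbl)] <- 0
      }
    }
  }
  out <- colMeans(acc, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  # fE/I cells must be NA (not numeric) when all channels are gated out;
  # other metrics keep NA only if no channel produced a value
  c(out, lzc = lzc_broadband(harm))
}
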