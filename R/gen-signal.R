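#' Envelope dynamics profiles for synthetic band signals
#'
#' An `envelope_profile` describes the dynamics of the amplitude envelope a
#' synthetic narrowband oscillation is modulated by:
#'
#' * `"fractional"`: lognormal envelope driven by fractional Gaussian noise
#'   with Hurst exponent `H` -- steers the DFA exponent.
#' * `"bistable"`: two-state continuous-time Markov chain on power levels
#'   with exponentially distributed within-mode power (mean powers
#'   `mu_lo < mu_hi`, high-mode occupancy `w_hi`, mean dwell time `dwell`
#'   seconds) -- produces the bimodal exponential power mixture the
#'   bistability index detects.
#' * `"coupled"`: long-range-correlated amplitude levels with
#'   within-window fluctuation scaling tied to the window's mean amplitude
#'   at target Pearson correlation `rho` -- steers fE/I towards `1 - rho`.
#' * `"composite"`: all of the above combined (used by the cohort
#'   generator); any subset of knobs may be given.
#'
#' @param kind Profile kind (see above).
#' @param H Hurst exponent in (0,1).
#' @param mu_lo,mu_hi Mean power of the low/high mode (`0 < mu_lo < mu_hi`).
#' @param w_hi High-mode occupancy in (0,1).
#' @param dwell Mean dwell time per mode in seconds.
#' @param rho Target amplitude-fluctuation coupling in \[-1, 1\].
#' @param baseline Baseline envelope amplitude (arbitrary units).
#' @param sigma Log-amplitude SD of the fractional modulation.
#' @return An `envelope_profile` list.
#' @export
envelope_profile <- function(kind = c("fractional", "bistable", "coupled", "composite"),
                             H = 0.75, mu_lo = 1, mu_hi = 32, w_hi = 0.4,
                             dwell = 1, rho = 0, baseline = 1, sigma = 0.3) {
  kind <- match.arg(kind)
  stopifnot(H > 0, H < 1, mu_lo > 0, mu_hi > mu_lo, w_hi > 0, w_hi < 1,
            dwell > 0, rho >= -1, rho <= 1, baseline > 0, sigma >= 0)
  structure(list(kind = kind, H = H, mu_lo = mu_lo, mu_hi = mu_hi,
                 w_hi = w_hi, dwell = dwell, rho = rho,
                 baseline = baseline, sigma = sigma),
            class = "envelope_profile")
}

#' Generate a narrowband oscillation with programmed envelope dynamics
#'
#' A band-limited random-phase carrier (a sinusoid at the band's geometric
#' centre with random initial phase) is multiplied by a strictly positive
#' envelope realized from `profile`. A deterministic carrier is used so the
#' Hilbert envelope of the product recovers the programmed envelope exactly,
#' keeping the generator's knobs (Hurst exponent, bimodality, coupling) in
#' one-to-one correspondence with the downstream metrics.
#'
#' @param band Numeric `(f_lo, f_hi)` in Hz with `0 < f_lo < f_hi < fs/2`.
#' @param profile An [envelope_profile()].
#' @param duration Signal duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed (reproducible draws).
#' @return List with `signal`, `envelope` (the programmed envelope), `fs`.
#' @export
gen_band_signal <- function(band, profile, duration, fs, seed = NULL) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1], band[2] < fs / 2)
  n <- as.integer(round(duration * fs))
  if (duration * band[1] < 10)
    stop("duration ", duration, " s gives fewer than 10 cycles of f_lo = ",
         band[1], " Hz")
  run <- function() {
    env <- realize_envelope(profile, n, fs)
    # band-limit the envelope to half the band width so modulation
    # sidebands of the product stay inside the band instead of leaking
    # into neighbouring analysis bands
    cut <- (band[2] - band[1]) / 2
    if (cut < fs / 2) {
      lp <- signal::butter(4, cut / (fs / 2), type = "low")
      env <- signal::filtfilt(lp, env)
      env <- pmax(env, 0.02 * stats::median(abs(env)))
    }
    fc <- sqrt(band[1] * band[2])
    phase <- stats::runif(1, 0, 2 * pi)
    carrier <- sin(2 * pi * fc * (0:(n - 1)) / fs + phase)
    list(signal = env * carrier, envelope = env, fs = fs)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Realize an envelope of n samples at fs from a profile. Always strictly
# positive. RNG is taken from the current stream.
realize_envelope <- function(profile, n, fs) {
  p <- profile
  env <- rep(p$baseline, n)
  if (p$kind %in% c("fractional", "composite")) {
    g <- gen_fgn(p$H, n)
    env <- env * exp(p$sigma * (g - mean(g)) / stats::sd(g))
  }
  if (p$kind == "bistable") {
    env <- env * sqrt(markov_power(n, fs, p$mu_lo, p$mu_hi, p$w_hi, p$dwell))
  }
  if (p$kind == "composite") {
    # switching driven by threshold crossings of smoothed fGn(H): the
    # two-state structure keeps the bimodal exponential power mixture while
    # the switching dynamics inherit the subject's long-range persistence,
    # so H remains steerable with bistability active
    env <- env * sqrt(threshold_power(n, fs, p$mu_lo, p$mu_hi, p$w_hi,
                                      p$dwell, p$H))
  }
  if (p$kind == "coupled") {
    env <- env * coupled_modulation(n, fs, p$rho)
  }
  if (p$kind == "composite") {
    # couple amplitude to fluctuation on the combined envelope: scaling a
    # separate multiplicative factor would be drowned by the switching
    # fluctuations, so the window-wise gain acts on the full log-envelope
    env <- compose_coupling(env, fs, p$rho)
  }
  env
}

# Two-state Markov-modulated exponential power process. Dwell times are
# exponential with means chosen so the stationary high-mode occupancy is
# w_hi and the overall mean dwell is `dwell`. Within-mode power has an
# exponential marginal (mean mu_state) with ~0.1-s correlation time,
# obtained by mapping an AR(1) Gaussian through its CDF.
markov_power <- function(n, fs, mu_lo, mu_hi, w_hi, dwell) {
  tau_hi <- 2 * dwell * w_hi
  tau_lo <- 2 * dwell * (1 - w_hi)
  state <- integer(0)
  cur <- stats::runif(1) < w_hi  # start from stationary occupancy
  while (length(state) < n) {
    len <- stats::rexp(1, rate = 1 / (if (cur) tau_hi else tau_lo)) * fs
    state <- c(state, rep(as.integer(cur), max(1L, as.integer(round(len)))))
    cur <- !cur
  }
  state <- state[seq_len(n)]
  # exponential marginal with short-range smoothness
  a <- exp(-1 / (0.1 * fs))
  z <- stats::filter(stats::rnorm(n, sd = sqrt(1 - a^2)), a, "recursive",
                     init = stats::rnorm(1))
  u <- stats::pnorm(as.numeric(z))
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  mu <- ifelse(state == 1L, mu_hi, mu_lo)
  stats::qexp(u, rate = 1) * mu
}

# Two-state power process with persistent switching: the state is the
# indicator of a smoothed fractional Gaussian noise exceeding the
# occupancy threshold qnorm(1 - w_hi); the smoothing window (~dwell
# seconds) sets the switching timescale. Within-mode power is exponential
# as in markov_power().
threshold_power <- function(n, fs, mu_lo, mu_hi, w_hi, dwell, H) {
  g <- gen_fgn(H, n)
  k <- max(3L, as.integer(round(dwell * fs)))
  kern <- stats::dnorm(seq(-2, 2, length.out = k))
  g <- std(fft_smooth(g, kern / sum(kern)))
  state <- as.integer(g > stats::qnorm(1 - w_hi))
  a <- exp(-1 / (0.1 * fs))
  z <- stats::filter(stats::rnorm(n, sd = sqrt(1 - a^2)), a, "recursive",
                     init = stats::rnorm(1))
  u <- pmin(pmax(stats::pnorm(as.numeric(z)), 1e-12), 1 - 1e-12)
  stats::qexp(u, rate = 1) * ifelse(state == 1L, mu_hi, mu_lo)
}

# Multiplicative modulation with controlled coupling between windowed mean
# amplitude and within-window fluctuation scale. Window levels carry
# long-range temporal correlations (H = 0.85) so the DFA validity gate for
# fE/I passes; within each window the envelope is lognormally modulated by
# a persistent (H = 0.8) standardized waveform whose gain is a monotone
# function of `rho * level + orthogonal noise`, built so the target sample
# correlation between level and gain holds exactly on the generation grid.
# The lognormal form exp(g f - g^2/2) keeps the within-window mean at 1
# for every gain, so the gain cannot leak into the window mean amplitude.
coupled_modulation <- function(n, fs, rho, window = 10, level_sd = 0.25,
                               gain0 = 0.1, gain_pow = 0.5,
                               level_H = 0.85, wave_H = 0.8) {
  w <- as.integer(round(window * fs))
  nwin <- max(2L, as.integer(ceiling(n / w)))
  zL <- std(gen_fgn(level_H, nwin))
  eta <- stats::rnorm(nwin)
  zeta <- std(stats::residuals(stats::lm.fit(cbind(1, zL), eta)))
  v <- rho * zL + sqrt(max(0, 1 - rho^2)) * zeta
  L <- exp(level_sd * zL)
  gain <- gain0 * exp(gain_pow * v)
  f <- std(gen_fgn(wave_H, w))
  out <- numeric(nwin * w)
  for (i in seq_len(nwin)) {
    idx <- ((i - 1L) * w + 1L):(i * w)
    out[idx] <- L[i] * exp(gain[i] * f - gain[i]^2 / 2)
  }
  out[seq_len(n)]
}

std <- function(x) (x - mean(x)) / stats::sd(x)

# centred moving-kernel smoothing by zero-padded FFT convolution
fft_smooth <- function(x, kern) {
  n <- length(x); k <- length(kern)
  m <- stats::nextn(n + k, c(2, 3, 5))
  y <- Re(stats::fft(stats::fft(c(x, numeric(m - n))) *
                     stats::fft(c(kern, numeric(m - k))), inverse = TRUE)) / m
  y[(k %/% 2 + 1):(k %/% 2 + n)]
}

# Window-wise amplitude-fluctuation coupling applied to an existing
# envelope: within each window the log-envelope deviations from the window
# mean are scaled by a gain whose sample correlation with the window level
# is exactly rho; the lognormal mean correction (g^2 - 1) s^2 / 2 keeps the
# window mean amplitude invariant to the gain so the coupling cannot leak
# into wAmp directly.
compose_coupling <- function(env, fs, rho, window = 10, gain_pow = 0.4) {
  n <- length(env)
  w <- as.integer(round(window * fs))
  nwin <- n %/% w
  if (nwin < 2 || rho == 0 && gain_pow == 0) return(env)
  le <- log(env)
  idx <- split(seq_len(nwin * w), rep(seq_len(nwin), each = w))
  m <- vapply(idx, function(i) mean(le[i]), numeric(1))
  s2 <- vapply(idx, function(i) stats::var(le[i]), numeric(1))
  zL <- std(m)
  eta <- stats::rnorm(nwin)
  zeta <- std(stats::residuals(stats::lm.fit(cbind(1, zL), eta)))
  v <- rho * zL + sqrt(max(0, 1 - rho^2)) * zeta
  g <- exp(gain_pow * v)
  out <- le
  for (i in seq_len(nwin))
    out[idx[[i]]] <- m[i] + g[i] * (le[idx[[i]]] - m[i]) -
      (g[i]^2 - 1) * s2[i] / 2
  exp(out)
}

#' @export
print.envelope_profile <- function(x, ...) {
  knobs <- switch(x$kind,
    fractional = sprintf("H = %.2f", x$H),
    bistable = sprintf("mu_lo = %.3g, mu_hi = %.3g, w_hi = %.2f, dwell = %.2g s",
                       x$mu_lo, x$mu_hi, x$w_hi, x$dwell),
    coupled = sprintf("rho = %.2f", x$rho),
    composite = sprintf("H = %.2f, mu_hi/mu_lo = %.3g, w_hi = %.2f, dwell = %.2g s, rho = %.2f",
                        x$H, x$mu_hi / x$mu_lo, x$w_hi, x$dwell, x$rho))
  cat("<envelope profile: ", x$kind, "> ", knobs, "\n", sep = "")
  invisible(x)
}
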