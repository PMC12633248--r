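test_that("fGn synthesis matches its exact covariance structure", {
  # H = 0.5 is white noise: lag-1 autocorrelation ~ 0
  x <- gen_fgn(0.5, 2^14, seed = 1)
  expect_lt(abs(cor(x[-1], x[-length(x)])), 3 / sqrt(length(x)))

  # closed-form lag-1 autocorrelation 2^(2H-1) - 1; sample ACF and variance
  # converge at the usual sqrt(n) rate only for H < 0.75, so the strongly
  # persistent case gets the wider long-memory tolerance
  for (H in c(0.3, 0.6, 0.7)) {
    x <- gen_fgn(H, 2^16, seed = round(10 * H))
    r1 <- cor(x[-1], x[-length(x)])
    expect_lt(abs(r1 - (2^(2 * H - 1) - 1)), 3 / sqrt(length(x)) * 3,
              label = paste("acf1 error at H =", H))
    expect_lt(abs(var(x) - 1), 0.1)
  }
  x <- gen_fgn(0.9, 2^16, seed = 9)
  expect_lt(abs(cor(x[-1], x[-length(x)]) - (2^0.8 - 1)), 0.05)
  expect_lt(abs(var(x) - 1), 0.2)
})

test_that("fGn DFA exponent recovers H on a fixed draw", {
  x <- gen_fgn(0.8, 2^16, seed = 42)
  expect_lt(abs(dfa(x, fs = 100, s_min = 0.1, s_max = 50)$alpha - 0.8), 0.05)
})

test_that("fGn generation is deterministic under seed and validates inputs", {
  expect_identical(gen_fgn(0.7, 512, seed = 9), gen_fgn(0.7, 512, seed = 9))
  expect_error(gen_fgn(1.2, 100))
  expect_error(gen_fgn(0.5, 1))
})

test_that("band signals realize their envelope profile", {
  fs <- 200; dur <- 300; band <- c(8.3, 10.5)
  # bistable profile: two-mode fit preferred, bimodal on log scale
  g <- gen_band_signal(band, envelope_profile("bistable", mu_lo = 1,
                                              mu_hi = 100, w_hi = 0.4),
                       dur, fs, seed = 3)
  expect_true(all(g$envelope > 0))
  fit <- fit_biexp(band_envelope(g$signal, band, fs = fs))
  expect_true(fit$identified)
  expect_lt(fit$bic2, fit$bic1)   # mixture preferred

  # fractional profile with H = 0.5: envelope DFA ~ 0.5 (wide band so the
  # analysis filter does not smooth the modulation)
  wband <- c(13.4, 27.7)
  a <- vapply(1:5, function(i) {
    g <- gen_band_signal(wband, envelope_profile("fractional", H = 0.5),
                         dur, fs, seed = i)
    dfa(band_envelope(g$signal, wband, fs = fs))$alpha
  }, numeric(1))
  expect_lt(abs(mean(a) - 0.5), 0.05)

  # too short for 10 cycles of f_lo
  expect_error(gen_band_signal(c(1, 4), envelope_profile(), 5, fs, seed = 1),
               "10 cycles")
})

test_that("subjects assemble epochs, background and determinism correctly", {
  # 19 channels at fs = 512: five 60-s epochs = 19 x 153,600 samples
  rec <- gen_subject(fs = 512, n_channels = 19, seed = 5)
  expect_identical(dim(rec$samples), c(19L, 153600L))
  expect_identical(nrow(rec$epochs), 5L)
  expect_false(anyNA(rec$samples))

  # same seed -> bit-identical
  p <- list("8.3-10.5" = envelope_profile("fractional", H = 0.7))
  r1 <- gen_subject(p, fs = 200, seed = 11)
  r2 <- gen_subject(p, fs = 200, seed = 11)
  expect_identical(r1$samples, r2$samples)

  # duplicate band specification rejected
  b <- list(band = c(8.3, 10.5), profile = envelope_profile())
  expect_error(gen_subject(list(b, b), fs = 200, seed = 1), "duplicate")

  # 0 bands: pure 1/f background; band envelope DFA stays near uncorrelated
  bg <- gen_subject(fs = 200, seed = 21)
  env <- band_envelope(harmonize(bg), c(13.4, 27.7))
  expect_lt(dfa(env)$alpha, 0.68)
  expect_gt(dfa(env)$alpha, 0.42)
})

test_that("cohort spec validates sizes, bands and steerable axes", {
  expect_identical(cohort_spec()$n_hc, 133)
  expect_identical(cohort_spec()$n_mdd, 183)
  expect_error(cohort_spec(n_hc = 1), "n_hc")
  expect_error(cohort_spec(effect_map = list("nope" = c(bis = 1))),
               "band labels")
  expect_error(cohort_spec(effect_map = list("8.3-10.5" = c(lzc = 1))),
               "steerable")
})

test_that("cohorts have the requested composition and are reproducible", {
  spec <- cohort_spec(n_hc = 4, n_mdd = 5, bands = "8.3-10.5", seed = 7)
  coh <- gen_cohort(spec)
  expect_length(coh$recordings, 9)
  expect_identical(sum(coh$manifest$group == "HC"), 4L)
  expect_identical(sum(coh$manifest$group == "MDD"), 5L)
  expect_true(all(coh$manifest$age >= 18 & coh$manifest$age <= 80))
  expect_true(all(coh$manifest$sex %in% c("male", "female")))
  # per-subject determinism independent of cohort assembly
  again <- gen_cohort(spec)
  expect_identical(coh$recordings[[3]]$samples, again$recordings[[3]]$samples)
  expect_identical(coh$manifest, again$manifest)
  # envelope positivity / finite samples
  expect_true(all(is.finite(coh$recordings[[1]]$samples)))
})

test_that("default cohort sizes match the study composition", {
  coh <- gen_cohort(cohort_spec(bands = character(0), seed = 1))
  expect_length(coh$recordings, 316)
  expect_identical(sum(coh$manifest$group == "HC"), 133L)
  expect_identical(sum(coh$manifest$group == "MDD"), 183L)
})

test_that("each metric axis responds monotonically to its generator knob", {
  fs <- 200; dur <- 300
  band <- c(13.4, 27.7)
  reps <- 20

  # BiS rises with mode separation (bistable profile)
  bis_at <- function(ratio) mean(vapply(seq_len(reps), function(i) {
    g <- gen_band_signal(band, envelope_profile("bistable", mu_lo = 1,
                                                mu_hi = ratio, w_hi = 0.4),
                         dur, fs, seed = 1000 * ratio + i)
    bistability_index(fit_biexp(band_envelope(g$signal, band, fs = fs)))
  }, numeric(1)))
  b3 <- vapply(c(3, 30, 300), bis_at, numeric(1))
  expect_true(all(diff(b3) > 0))

  # DFA exponent rises with H (fractional profile)
  dfa_at <- function(H) mean(vapply(seq_len(reps), function(i) {
    g <- gen_band_signal(band, envelope_profile("fractional", H = H),
                         dur, fs, seed = 2000 * H + i)
    dfa(band_envelope(g$signal, band, fs = fs))$alpha
  }, numeric(1)))
  a3 <- vapply(c(0.55, 0.7, 0.85), dfa_at, numeric(1))
  expect_true(all(diff(a3) > 0))

  # fE/I falls with the coupling rho (coupled profile)
  fei_at <- function(rho) mean(vapply(seq_len(reps), function(i) {
    g <- gen_band_signal(band, envelope_profile("coupled", rho = rho),
                         dur, fs, seed = 3000 * (rho + 2) + i)
    fei(band_envelope(g$signal, band, fs = fs))$value
  }, numeric(1)), na.rm = TRUE)
  f3 <- vapply(c(-0.5, 0, 0.5), fei_at, numeric(1))
  expect_true(all(diff(f3) < 0))
  # antisymmetry of the coupling around the balanced point
  expect_lt(abs(f3[1] + f3[3] - 2), 0.12)
})
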