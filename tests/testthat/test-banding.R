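test_that("harmonization yields the 4.65-min five-segment series", {
  rec <- marker_recording(fs = 100)
  h <- harmonize(rec, mode = "HC")
  expect_equal(ncol(h$samples) / h$fs, 278.8)              # 4.65 min
  expect_equal(h$segments, c(49.4, 60, 60, 60, 49.4))
  expect_equal(round(h$segments), c(49, 60, 60, 60, 49))   # as reported
})

test_that("the continuous path splits, reorders 1-3-5-2-4 and trims alike", {
  rec <- marker_recording(fs = 100)
  h <- harmonize(rec, mode = "MDD")
  expect_equal(ncol(h$samples) / h$fs, 278.8)
  # epoch markers must appear in order A C E B D after reordering
  seg_label <- vapply(seq_len(5), function(s)
    floor(median(h$samples[1, h$segment_bounds[s, 1]:h$segment_bounds[s, 2]])),
    numeric(1))
  expect_equal(seg_label, c(1, 3, 5, 2, 4))
  # both group paths give identical total duration
  expect_identical(ncol(h$samples),
                   ncol(harmonize(rec, mode = "HC")$samples))
})

test_that("harmonization refuses insufficient recordings, naming the shortfall", {
  rec <- marker_recording(fs = 100)
  short <- rec
  short$samples <- rec$samples[, 1:20000, drop = FALSE]
  expect_error(harmonize(short, mode = "MDD"), "short by")
  short2 <- rec
  short2$epochs[5, 2] <- short2$epochs[5, 1] + 100L
  expect_error(harmonize(short2, mode = "HC"), "shorter than 60")
})

test_that("the default band scheme has 13 contiguous bins with the printed edges", {
  b <- make_bands()
  expect_identical(nrow(b), 13L)
  expect_equal(b$f_lo[1], 1)
  expect_equal(b$f_hi[1], 4)
  expect_equal(b$f_hi[13], 73)
  # shared edges, no gaps, strictly increasing
  expect_equal(b$f_lo[-1], b$f_hi[-13])
  expect_true(all(diff(c(b$f_lo, 73)) > 0))
  # printed edges from the feature listing, within 0.2 Hz
  printed <- c(5.1, 6.5, 8.3, 10.5, 13.4, 17.0, 27.6, 35.2)
  nearest <- vapply(printed, function(e) min(abs(b$f_hi - e)), numeric(1))
  expect_true(all(nearest <= 0.2))
})

test_that("band construction is contiguous for other ranges too", {
  for (fmax in c(45, 60, 73, 100)) {
    b <- make_bands(f_max = fmax)
    expect_equal(b$f_lo[-1], b$f_hi[-nrow(b)])
    expect_equal(b$f_hi[nrow(b)], fmax)
  }
})

test_that("band envelopes recover programmed amplitude modulation", {
  fs <- 200
  t <- seq(0, 299.995, by = 1 / fs)
  band <- c(8.3, 10.5)
  f0 <- sqrt(prod(band))

  # pure sinusoid: envelope constant within 1%
  rec <- marker_recording(fs = fs)
  rec$samples <- matrix(2.5 * sin(2 * pi * f0 * t), nrow = 1)
  h <- harmonize(rec, mode = "MDD")
  env <- band_envelope(h, band)
  expect_true(all(env$amp >= 0))
  expect_lt(max(abs(env$amp - 2.5)) / 2.5, 0.01)

  # slow AM: envelope tracks a(t) with relative RMSE < 5%
  a_t <- 1 + 0.5 * sin(2 * pi * 0.1 * t)
  rec$samples <- matrix(a_t * sin(2 * pi * f0 * t), nrow = 1)
  h <- harmonize(rec, mode = "MDD")
  env <- band_envelope(h, band)
  # rebuild the programmed a(t) on the trimmed sample grid
  idx <- env_sample_index(fs)
  expect_lt(sqrt(mean((env$amp[1, ] - a_t[idx])^2)) / mean(a_t), 0.05)

  # out-of-band tone attenuated by >= 20 dB
  rec$samples <- matrix(sin(2 * pi * 20 * t), nrow = 1)
  h <- harmonize(rec, mode = "MDD")
  out <- band_envelope(h, band)
  expect_lt(10 * log10(mean(out$amp^2)), -20)

  expect_error(band_envelope(h, c(8, 8.0001)), "too narrow")
  expect_error(band_envelope(h, c(8, 150)), "Nyquist")
})

test_that("envelope extraction is channel-permutation equivariant", {
  fs <- 200
  set.seed(1)
  rec <- gen_subject(list("8.3-10.5" = envelope_profile()), fs = fs,
                     n_channels = 3, seed = 2)
  h <- harmonize(rec)
  e1 <- band_envelope(h, c(8.3, 10.5))
  h2 <- h
  h2$samples <- h$samples[c(3, 1, 2), ]
  e2 <- band_envelope(h2, c(8.3, 10.5))
  expect_equal(e2$amp, e1$amp[c(3, 1, 2), ])
})

test_that("the analytic signal is exact on DFT-aligned sinusoid mixtures", {
  # for cosines at integer numbers of cycles the analytic signal has the
  # closed form sum a_k exp(i (w_k t + phi_k))
  for (n in c(1024, 1001)) {   # even and odd lengths
    t <- 0:(n - 1)
    ks <- c(3, 17, 40)
    a <- c(2, 1, 0.5); phi <- c(0.3, -1.2, 2.0)
    x <- Reduce(`+`, lapply(1:3, function(j)
      a[j] * cos(2 * pi * ks[j] * t / n + phi[j])))
    expected <- Reduce(`+`, lapply(1:3, function(j)
      a[j] * exp(1i * (2 * pi * ks[j] * t / n + phi[j]))))
    expect_equal(neurocrit:::analytic_signal(x), expected, tolerance = 1e-10)
  }
})
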