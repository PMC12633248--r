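test_that("Welch test matches the closed-form oracle to 1e-12", {
  set.seed(30)
  x <- rnorm(17, 1, 2); y <- rnorm(23, 0, 0.5)
  w <- welch_test(x, y)
  o <- welch_oracle(x, y)
  expect_equal(w$statistic, o$t, tolerance = 1e-12)
  expect_equal(w$df, o$df, tolerance = 1e-12)
  expect_equal(w$p_value, o$p, tolerance = 1e-12)
  expect_equal(c(w$conf_low, w$conf_high), o$ci, tolerance = 1e-12)

  # null identity and swap symmetry
  z <- rnorm(10)
  expect_equal(welch_test(z, z)$statistic, 0)
  expect_equal(welch_test(z, z)$p_value, 1)
  ws <- welch_test(y, x)
  expect_equal(ws$statistic, -w$statistic)
  expect_equal(ws$p_value, w$p_value)
  expect_error(welch_test(rep(1, 5), rep(1, 5)), "zero variance")
})

test_that("Cohen's d and the Hedges-Olkin CI follow their definitions", {
  set.seed(31)
  x <- rnorm(12); y <- rnorm(15)
  d <- cohens_d(x, y)
  sp <- sqrt(((11) * var(x) + (14) * var(y)) / 25)
  d0 <- (mean(x) - mean(y)) / sp
  v0 <- (12 + 15) / (12 * 15) + d0^2 / (2 * 27)
  expect_equal(d$d, d0, tolerance = 1e-12)
  expect_equal(d$conf_low, d0 - qnorm(0.975) * sqrt(v0), tolerance = 1e-12)

  # equal means -> d = 0, CI symmetric
  d1 <- cohens_d(c(1, 2, 3), c(3, 2, 1))
  expect_equal(d1$d, 0)
  expect_equal(d1$conf_low, -d1$conf_high)

  # means one pooled SD apart -> d = 1
  x2 <- c(-1, 0, 1)
  d2 <- cohens_d(x2 + 1, x2)
  expect_equal(d2$d, 1)
  expect_error(cohens_d(rep(1, 4), rep(1, 4)), "pooled SD")
})

test_that("BH adjustment equals the literal step-up rule", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_fdr(p), bh_oracle(p))
  set.seed(32)
  for (i in 1:20) {
    p <- runif(13)^2
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p))          # step-up never decreases
    expect_true(all(q <= 1))
  }
  expect_equal(bh_fdr(0.2), 0.2)                  # single p
  expect_equal(bh_fdr(rep(0.03, 5)), rep(0.03, 5))  # identical ps
})

test_that("IRLS matches OLS on clean data and MASS::rlm generally", {
  set.seed(33)
  n <- 80
  X <- cbind(`(Intercept)` = 1, g = rbinom(n, 1, 0.5), a = rnorm(n))
  y <- drop(X %*% c(1, 0.5, -0.3)) + rnorm(n)
  rf <- robust_fit(y, X)
  ols <- lm.fit(X, y)
  expect_lt(max(abs(rf$coefficients$estimate - ols$coefficients) /
                  rf$coefficients$std_error), 2)
  expect_gt(mean(rf$weights), 0.85)  # bisquare mildly downweights even clean data

  # agreement with the reference IRLS implementation
  mrlm <- MASS::rlm(X, y, psi = MASS::psi.bisquare, scale.est = "MAD",
                    maxit = 100)
  expect_equal(rf$coefficients$estimate, unname(coef(mrlm)), tolerance = 5e-3)

  # rank deficiency is reported with the offending column
  Xbad <- cbind(X, dup = X[, "g"])
  expect_error(robust_fit(y, Xbad), "dup")
})

test_that("the robust slope resists gross outliers better than OLS", {
  set.seed(34)
  err_r <- err_o <- numeric(30)
  for (i in 1:30) {
    n <- 40
    X <- cbind(1, rnorm(n))
    y <- drop(X %*% c(0, 1)) + rnorm(n)
    y[1] <- y[1] + 20
    err_r[i] <- abs(robust_fit(y, X)$coefficients$estimate[2] - 1)
    err_o[i] <- abs(lm.fit(X, y)$coefficients[2] - 1)
  }
  expect_lt(mean(err_r), mean(err_o))
})

test_that("robust group CIs cover the null at the nominal rate", {
  set.seed(35)
  cover <- vapply(1:200, function(i) {
    n <- 50
    X <- cbind(1, g = rbinom(n, 1, 0.5), a = rnorm(n))
    y <- 0.4 * X[, "a"] + rnorm(n)
    co <- robust_fit(y, X)$coefficients
    ci <- co$estimate[2] + c(-1, 1) * qt(0.975, n - 3) * co$std_error[2]
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})

test_that("Freedman-Lane reduces to label permutation without covariates", {
  set.seed(36)
  n <- 40
  g <- rbinom(n, 1, 0.5)
  y <- 0.3 * g + rnorm(n)
  X_full <- cbind(`(Intercept)` = 1, group = g)
  X_red <- X_full[, 1, drop = FALSE]
  fl <- freedman_lane(y, X_full, X_red, B = 2000, seed = 1, fitter = "ols")
  # direct label permutation of the same statistic
  t_obs <- summary(lm(y ~ g))$coefficients[2, 3]
  perm <- vapply(1:2000, function(b) {
    gp <- sample(g)
    summary(lm(y ~ gp))$coefficients[2, 3]
  }, numeric(1))
  p_lab <- (1 + sum(abs(perm) >= abs(t_obs))) / 2001
  expect_lt(abs(fl$p_perm - p_lab), 0.05)

  # resolution floor under an overwhelming effect
  y2 <- 10 * g + rnorm(n, sd = 0.1)
  fl2 <- freedman_lane(y2, X_full, X_red, B = 300, seed = 2, fitter = "ols")
  expect_equal(fl2$p_perm, 1 / 301)

  expect_warning(freedman_lane(y, X_full, X_red, B = 50, seed = 3,
                               fitter = "ols"), "low")
})

test_that("LZC group tests agree with exact small-sample distributions", {
  # fully separated samples: Mann-Whitney p equals the exact enumeration
  x <- c(1, 2, 3, 4); y <- c(5, 6, 7, 8)
  res <- lzc_tests(x, y, B = 500, seed = 1)
  expect_equal(res$p_mann_whitney, 2 / choose(8, 4), tolerance = 1e-12)
  expect_lt(res$p_perm, 0.05)
  expect_lt(res$d, -2)

  # near-identical groups: nothing significant
  set.seed(37)
  a <- rnorm(20); b <- a + rnorm(20, sd = 1e-3)
  res2 <- lzc_tests(a, b, B = 500, seed = 2)
  expect_gt(res2$p_welch, 0.5)
  expect_gt(res2$p_perm, 0.5)
})

test_that("group-label swap flips signed statistics and preserves p-values", {
  set.seed(38)
  tbl <- tibble::tibble(
    subject = sprintf("s%02d", 1:40),
    group = rep(c("HC", "MDD"), each = 20),
    age = rnorm(40, 45, 10),
    sex = sample(c("male", "female"), 40, replace = TRUE),
    `bis@1-4` = rnorm(40) + 0.5 * (group == "MDD"),
    lzc = rnorm(40)
  )
  ct <- band_contrasts(tbl, B = 200, seed = 1)
  swapped <- tbl
  swapped$group <- ifelse(tbl$group == "HC", "MDD", "HC")
  ct2 <- band_contrasts(swapped, B = 200, seed = 1)
  expect_equal(ct2$statistic, -ct$statistic, tolerance = 1e-10)
  expect_equal(ct2$d, -ct$d, tolerance = 1e-10)
  expect_equal(ct2$beta_group, -ct$beta_group, tolerance = 1e-6)
  expect_equal(ct2$p_value, ct$p_value, tolerance = 1e-10)
})

test_that("band_contrasts assembles the full inferential record per cell", {
  set.seed(39)
  n <- 60
  tbl <- tibble::tibble(
    subject = sprintf("s%02d", 1:n),
    group = rep(c("HC", "MDD"), each = n / 2),
    age = rnorm(n, 45, 12),
    sex = sample(c("male", "female"), n, replace = TRUE),
    `dfa@1-4` = rnorm(n),
    `dfa@4-5.1` = rnorm(n) - 0.9 * (group == "MDD"),
    `fei@1-4` = replace(rnorm(n), sample(n, 8), NA),  # gated subjects
    lzc = rnorm(n)
  )
  ct <- band_contrasts(tbl, B = 300, seed = 4)
  expect_identical(nrow(ct), 4L)
  expect_true(all(ct$p_value >= 0 & ct$p_value <= 1))
  expect_true(all(ct$q_value >= ct$p_value - 1e-12))
  expect_true(all(ct$df > 0))
  # fE/I cells drop gated subjects cell-wise
  fei_row <- ct[ct$metric == "fei", ]
  expect_identical(fei_row$n_hc + fei_row$n_mdd, as.integer(n - 8))
  # the implanted dfa cell is detected and signed correctly
  hit <- ct[ct$metric == "dfa" & ct$band == "4-5.1", ]
  expect_gt(hit$d, 0)
  expect_lt(hit$q_value, 0.05)
  expect_lt(hit$p_perm, 0.05)
})
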