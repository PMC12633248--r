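# a small synthetic metric table with known informative columns
make_table <- function(n_hc = 60, n_mdd = 60, seed = 1) {
  set.seed(seed)
  n <- n_hc + n_mdd
  grp <- rep(c("HC", "MDD"), c(n_hc, n_mdd))
  bands <- make_bands()$band
  cols <- list()
  for (m in c("bis", "dfa", "ei_hlp", "fei", "ei_hls"))
    for (b in bands)
      cols[[paste0(m, "@", b)]] <- rnorm(n)
  tbl <- tibble::tibble(
    subject = sprintf("s%03d", 1:n), group = grp,
    age = rnorm(n, 45, 12),
    sex = sample(c("male", "female"), n, replace = TRUE), !!!cols,
    lzc = rnorm(n))
  tbl
}

test_that("feature assembly applies the inclusion rules and counts", {
  tbl <- make_table()
  fm <- assemble_features(tbl)
  expect_identical(ncol(fm$X), 43L)          # 4 metrics x 10 bands + 3
  expect_false(any(grepl("^dfa@", colnames(fm$X))))
  expect_false(any(grepl("@35.3-45|@45-57.3|@57.3-73", colnames(fm$X))))
  expect_true(all(c("lzc", "age", "sex") %in% colnames(fm$X)))

  expect_identical(ncol(assemble_features(tbl, include_dfa = TRUE)$X), 53L)
  expect_identical(ncol(assemble_features(tbl, max_band_hz = 73)$X), 55L)

  tbl2 <- tbl
  tbl2$`fei@1-4` <- NA_real_
  expect_warning(fm2 <- assemble_features(tbl2), "all-missing")
  expect_identical(ncol(fm2$X), 42L)
})

test_that("stratified splits preserve proportions and partition subjects", {
  groups <- rep(c("HC", "MDD"), c(133, 183))
  sp <- split_stratified(groups, seed = 5)
  expect_identical(sort(c(sp$train, sp$test)), seq_along(groups))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_lte(abs(sum(groups[sp$train] == "HC") - 93), 1)
  expect_lte(abs(sum(groups[sp$train] == "MDD") - 128), 1)
  expect_identical(sp, split_stratified(groups, seed = 5))
  expect_error(split_stratified(c("HC", "MDD", "MDD")), ">= 2")
})

test_that("the lasso path starts empty and saturates on separable data", {
  set.seed(40)
  n <- 80
  X <- scale(matrix(rnorm(n * 10), n))
  colnames(X) <- paste0("f", 1:10)
  y <- as.numeric(X[, 1] + 0.2 * rnorm(n) > 0)
  path <- lasso_path(X, y)
  B <- as.matrix(path$fit$beta)
  expect_true(all(B[, 1] == 0))              # all zero at lambda_max
  expect_gt(mean((predict(path$fit, X, s = min(path$lambda),
                          type = "response") > 0.5) == y), 0.97)
  # the informative column enters the path first
  first_nz <- apply(B != 0, 1, function(r) if (any(r)) which(r)[1] else Inf)
  expect_identical(unname(which.min(first_nz)), 1L)
})

test_that("cross-validated lambda selection obeys the 1-SE rule", {
  set.seed(41)
  n <- 120
  X <- scale(matrix(rnorm(n * 15), n))
  y <- as.numeric(X[, 1] - X[, 2] + rnorm(n) > 0)
  l1 <- cv_select(X, y, folds = 5, rule = "1se", seed = 2)
  lm_ <- cv_select(X, y, folds = 5, rule = "min", seed = 2)
  expect_gte(l1$lambda, lm_$lambda)
  expect_identical(l1$foldid, cv_select(X, y, folds = 5, seed = 2)$foldid)

  # pure noise: the 1-SE rule selects the null model most of the time
  nulls <- vapply(1:10, function(i) {
    set.seed(100 + i)
    Xn <- scale(matrix(rnorm(60 * 10), 60))
    yn <- rbinom(60, 1, 0.5)
    sel <- cv_select(Xn, yn, folds = 5, seed = i)
    sum(as.numeric(coef(glmnet::glmnet(Xn, yn, family = "binomial",
                                       lambda = sel$lambda,
                                       standardize = FALSE))[-1]) != 0)
  }, numeric(1))
  expect_gte(mean(nulls == 0), 0.8)
})

test_that("evaluation metrics match brute-force oracles and invariances", {
  labs <- c(1, 1, 1, 0, 0, 1, 0, 0, 1, 0)
  sco <- c(0.9, 0.8, 0.8, 0.8, 0.3, 0.6, 0.2, 0.6, 0.4, 0.1)
  ev <- evaluate_scores(sco, labs)
  expect_equal(ev$auc, auc_brute(sco, labs), tolerance = 1e-12)
  # invariant under strictly monotone transforms
  ev2 <- evaluate_scores(plogis(5 * sco - 2), labs)
  expect_equal(ev2$auc, ev$auc, tolerance = 1e-12)
  # perfect and random scores
  expect_equal(evaluate_scores(labs, labs)$auc, 1)
  expect_equal(evaluate_scores(labs, labs)$accuracy, 1)
  set.seed(42)
  big <- evaluate_scores(runif(4000), rbinom(4000, 1, 0.5))
  expect_lt(abs(big$auc - 0.5), 0.05)
  # ROC endpoints and monotonicity
  expect_equal(unlist(ev$roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(ev$roc[nrow(ev$roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(ev$roc$fpr) >= 0), all(diff(ev$roc$tpr) >= 0))
  expect_error(evaluate_scores(c(0.2, 0.8), c(1, 1)), "single class")
})

test_that("AUC agrees with the reference implementation", {
  set.seed(43)
  sco <- runif(200); labs <- rbinom(200, 1, 0.4)
  ref <- as.numeric(pROC::auc(pROC::roc(labs, sco, quiet = TRUE,
                                        direction = "<")))
  expect_equal(evaluate_scores(sco, labs)$auc, ref, tolerance = 1e-12)
})

test_that("no test-set information leaks into preprocessing or selection", {
  tbl <- make_table(40, 40, seed = 44)
  tbl$`fei@1-4`[sample(80, 10)] <- NA
  clf <- fit_group_classifier(tbl, folds = 5, seed = 9)
  # corrupt the held-out rows only; training-derived state must not move
  tbl2 <- tbl
  test_rows <- clf$split$test
  mcols <- grep("@|^lzc$|^age$", names(tbl2))
  for (j in mcols) tbl2[[j]][test_rows] <- tbl2[[j]][test_rows] + 100
  clf2 <- fit_group_classifier(tbl2, folds = 5, seed = 9)
  expect_identical(clf2$split, clf$split)
  expect_equal(clf2$preprocess, clf$preprocess)
  expect_equal(clf2$lambda, clf$lambda)
  expect_equal(clf2$coefficients, clf$coefficients)
  expect_equal(clf2$train$auc, clf$train$auc)
})

test_that("the end-to-end classifier finds implanted structure", {
  tbl <- make_table(80, 80, seed = 45)
  # implant standardized shifts on four included cells
  hot <- c("bis@8.3-10.5", "fei@5.1-6.5", "ei_hls@10.5-13.4",
           "ei_hlp@17.1-21.8")
  for (h in hot) tbl[[h]] <- tbl[[h]] + 1.2 * (tbl$group == "MDD")
  clf <- fit_group_classifier(tbl, seed = 10)
  expect_gt(clf$test$auc, 0.8)
  sel <- setdiff(clf$coefficients$feature, c("age", "sex"))
  expect_gte(mean(sel %in% hot), 0.6)
})
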