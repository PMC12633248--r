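#' Assemble the classifier feature matrix from a metric table
#'
#' Applies the feature-inclusion rules: the four envelope/criticality
#' metrics (BiS, E/I_HLP, fE/I, E+I_HLS) over the bands whose (rounded)
#' upper edge does not exceed `max_band_hz` -- the default 35.2 Hz keeps
#' 10 bands and excludes the mid/high-gamma bins -- plus broadband LZC,
#' age and sex (male = 1): 43 columns by default. DFA columns are appended
#' only when `include_dfa = TRUE` (53 columns). Missing fE/I cells are
#' imputed later with training-column means (see [fit_group_classifier()]);
#' here they remain `NA` and are recorded in the imputation mask.
#'
#' @param table Metric table from [compute_metrics()].
#' @param include_dfa Include DFA band features (FALSE).
#' @param max_band_hz Highest admissible band upper edge in Hz (35.2),
#'   compared on edges rounded to 0.1 Hz.
#' @return List: `X` (numeric matrix, subjects x features), `y` (1 =
#'   second group level), `groups`, `subjects`, `mask` (logical NA mask),
#'   `feature_info` tibble.
#' @export
assemble_features <- function(table, include_dfa = FALSE, max_band_hz = 35.2) {
  bands <- make_bands()
  # edges are compared at display precision: bin 10's exact upper edge is
  # 35.32 Hz but prints as 35.2-35.3, and it is retained at the 35.2 cutoff
  keep_bands <- bands$band[bands$f_hi <= max_band_hz + 0.15]
  metrics <- c("bis", "ei_hlp", "fei", "ei_hls")
  if (include_dfa) metrics <- c(metrics, "dfa")
  want <- as.vector(outer(metrics, keep_bands, paste, sep = "@"))
  present <- intersect(want, names(table))
  dropped <- setdiff(want, names(table))
  if (length(dropped))
    warning("feature column(s) absent from table: ",
            paste(dropped, collapse = ", "))
  all_na <- present[vapply(present, function(cl) all(is.na(table[[cl]])),
                           logical(1))]
  if (length(all_na)) {
    warning("dropping all-missing column(s): ", paste(all_na, collapse = ", "))
    present <- setdiff(present, all_na)
  }
  X <- cbind(as.matrix(table[present]),
             lzc = table$lzc,
             age = table$age,
             sex = as.numeric(table$sex == "male"))
  groups <- table$group
  lv <- sort(unique(groups))
  list(X = X, y = as.numeric(groups == lv[2]), groups = groups,
       subjects = table$subject, mask = is.na(X),
       feature_info = tibble::tibble(
         feature = colnames(X),
         metric = sub("@.*", "", colnames(X)),
         band = ifelse(grepl("@", colnames(X)),
                       sub(".*@", "", colnames(X)), NA_character_)))
}

#' Stratified train/test split
#'
#' @param meta Data frame with a `group` column (one row per subject), or a
#'   character vector of group labels.
#' @param train_frac Training fraction (0.7).
#' @param seed Integer seed.
#' @return List of integer row indices `train`, `test` (disjoint,
#'   exhaustive; per-group proportions preserved to within one subject).
#' @export
split_stratified <- function(meta, train_frac = 0.7, seed = 1) {
  groups <- if (is.data.frame(meta)) meta$group else meta
  lv <- unique(groups)
  if (any(table(groups) < 2)) stop("each group needs >= 2 subjects")
  train <- with_seed(seed, unlist(lapply(lv, function(g) {
    idx <- which(groups == g)
    sample(idx, round(length(idx) * train_frac))
  })))
  list(train = sort(train), test = sort(setdiff(seq_along(groups), train)))
}

#' LASSO-regularized logistic coefficient path
#'
#' Penalized logistic regression over a 100-point geometric lambda grid
#' descending four decades from `lambda_max` (the smallest lambda at which
#' every penalized coefficient is zero, `max |X'(y - ybar)| / n`), with an
#' unpenalized intercept. Fit by coordinate descent (glmnet) at
#' convergence tolerance 1e-7. `X` is expected already z-scored by
#' training statistics.
#'
#' @param X Feature matrix (z-scored; no NA).
#' @param y Binary 0/1 response.
#' @param lambda Optional lambda grid; computed from `X, y` when missing.
#' @param n_lambda,decades Grid size and extent.
#' @return A `lasso_path` object: glmnet fit plus `lambda`.
#' @export
lasso_path <- function(X, y, lambda = NULL, n_lambda = 100, decades = 4) {
  stopifnot(!anyNA(X), all(y %in% c(0, 1)))
  if (is.null(lambda)) lambda <- lasso_lambda_grid(X, y, n_lambda, decades)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                        lambda = lambda, standardize = FALSE, thresh = 1e-7)
  if (fit$jerr != 0) stop("glmnet failed to converge (jerr = ", fit$jerr, ")")
  structure(list(fit = fit, lambda = lambda), class = "lasso_path")
}

lasso_lambda_grid <- function(X, y, n_lambda = 100, decades = 4) {
  lambda_max <- max(abs(crossprod(X, y - mean(y)))) / nrow(X)
  exp(seq(log(lambda_max), log(lambda_max * 10^(-decades)),
          length.out = n_lambda))
}

#' Select lambda by cross-validated deviance and the 1-SE rule
#'
#' Stratified k-fold cross-validation of the binomial deviance over the
#' lambda grid; `rule = "1se"` returns the largest lambda whose mean CV
#' deviance is within one standard error of the minimum (the simplest
#' model statistically indistinguishable from the best), `rule = "min"`
#' the minimizer itself.
#'
#' @inheritParams lasso_path
#' @param folds Number of CV folds (10).
#' @param rule `"1se"` or `"min"`.
#' @param seed Integer seed for fold assignment.
#' @return List: `lambda`, `rule`, `cv` (tibble lambda/mean/se), `foldid`.
#' @export
cv_select <- function(X, y, folds = 10, rule = c("1se", "min"), seed = 1,
                      lambda = NULL) {
  rule <- match.arg(rule)
  stopifnot(folds >= 2)
  if (is.null(lambda)) lambda <- lasso_lambda_grid(X, y)
  foldid <- with_seed(seed, {
    id <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    id
  })
  if (any(vapply(seq_len(folds), function(f)
    length(unique(y[foldid == f])) < 2, logical(1))))
    stop("a fold contains a single class; reduce `folds`")
  cvfit <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 1,
                             lambda = lambda, foldid = foldid,
                             type.measure = "deviance", standardize = FALSE,
                             thresh = 1e-7)
  sel <- if (rule == "1se") cvfit$lambda.1se else cvfit$lambda.min
  list(lambda = sel, rule = rule,
       cv = tibble::tibble(lambda = cvfit$lambda, mean = cvfit$cvm,
                           se = cvfit$cvsd),
       foldid = foldid, cvfit = cvfit)
}

#' Evaluate a fitted classifier on scores and labels
#'
#' AUC by the rank (Mann-Whitney) statistic with tie correction;
#' accuracy, sensitivity and specificity at probability threshold 0.5;
#' full ROC and precision-recall point lists.
#'
#' @param scores Predicted probabilities (or any monotone scores for AUC).
#' @param labels Binary 0/1 labels (1 = positive class).
#' @param threshold Classification threshold on the probability (0.5).
#' @return An `eval_report`: `auc`, `accuracy`, `sensitivity`,
#'   `specificity`, `roc` (tibble fpr/tpr), `pr` (tibble recall/precision).
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stop("test set contains a single class; AUC undefined")
  rk <- rank(scores)
  auc <- (sum(rk[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  pred <- as.numeric(scores >= threshold)
  sens <- mean(pred[labels == 1] == 1)
  spec <- mean(pred[labels == 0] == 0)
  acc <- mean(pred == labels)

  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord] == 1); fp <- cumsum(labels[ord] == 0)
  # one ROC/PR point per distinct score (step curve vertices)
  last <- !duplicated(scores[ord], fromLast = TRUE)
  roc <- tibble::tibble(fpr = c(0, fp[last] / nneg), tpr = c(0, tp[last] / npos))
  pr <- tibble::tibble(recall = tp[last] / npos,
                       precision = tp[last] / pmax(tp[last] + fp[last], 1))
  structure(list(auc = auc, accuracy = acc, sensitivity = sens,
                 specificity = spec, roc = roc, pr = pr,
                 n = length(labels)), class = "eval_report")
}

#' Fit and evaluate the sparse group classifier end to end
#'
#' The full supervised workflow on a metric table: assemble features,
#' stratified 70/30 split, training-only preprocessing (fE/I gap imputation
#' by training-column means, z-scoring by training statistics), LASSO
#' logistic path, 10-fold cross-validated lambda by the 1-SE rule, and
#' evaluation on the held-out test set. No test-set information enters
#' imputation, scaling, fold assignment or lambda selection.
#'
#' @inheritParams assemble_features
#' @param train_frac Training fraction (0.7).
#' @param folds CV folds (10).
#' @param rule Lambda rule (`"1se"`).
#' @param seed Master seed (split, folds).
#' @return A `group_classifier` object: `model` (lasso_path), `lambda`,
#'   `coefficients` (nonzero at selection), `train`/`test` eval reports,
#'   `split`, `preprocess` (imputation means, centers, scales), `features`.
#' @export
fit_group_classifier <- function(table, include_dfa = FALSE,
                                 max_band_hz = 35.2, train_frac = 0.7,
                                 folds = 10, rule = "1se", seed = 1) {
  fm <- assemble_features(table, include_dfa = include_dfa,
                          max_band_hz = max_band_hz)
  sp <- split_stratified(fm$groups, train_frac = train_frac,
                         seed = child_seed(seed, "split"))
  Xtr <- fm$X[sp$train, , drop = FALSE]
  Xte <- fm$X[sp$test, , drop = FALSE]

  imp <- colMeans(Xtr, na.rm = TRUE)
  imp[!is.finite(imp)] <- 0  # no observed training values: impute a constant
  fill <- function(M) { for (j in seq_len(ncol(M))) M[is.na(M[, j]), j] <- imp[j]; M }
  Xtr <- fill(Xtr); Xte <- fill(Xte)
  ctr <- colMeans(Xtr)
  scl <- apply(Xtr, 2, stats::sd); scl[scl == 0] <- 1
  Ztr <- scale(Xtr, ctr, scl); Zte <- scale(Xte, ctr, scl)

  ytr <- fm$y[sp$train]; yte <- fm$y[sp$test]
  lambda <- lasso_lambda_grid(Ztr, ytr)
  path <- lasso_path(Ztr, ytr, lambda = lambda)
  cv <- cv_select(Ztr, ytr, folds = folds, rule = rule, seed = child_seed(seed, "cv"),
                  lambda = lambda)
  coefs <- stats::coef(path$fit, s = cv$lambda)
  nz <- which(as.numeric(coefs)[-1] != 0)
  score <- function(Z) drop(stats::predict(path$fit, Z, s = cv$lambda,
                                           type = "response"))
  structure(list(
    model = path, lambda = cv$lambda, cv = cv$cv, rule = rule,
    coefficients = tibble::tibble(
      feature = rownames(coefs)[-1][nz],
      weight = as.numeric(coefs)[-1][nz]),
    intercept = as.numeric(coefs)[1],
    train = evaluate_scores(score(Ztr), ytr),
    test = evaluate_scores(score(Zte), yte),
    split = sp, preprocess = list(impute = imp, center = ctr, scale = scl),
    features = fm$feature_info, seed = seed), class = "group_classifier")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval> AUC = %.3f  acc = %.3f  sens = %.3f  spec = %.3f  (n = %d)\n",
              x$auc, x$accuracy, x$sensitivity, x$specificity, x$n))
  invisible(x)
}

#' @export
print.group_classifier <- function(x, ...) {
  cat("<group classifier> lambda =", signif(x$lambda, 4),
      "(", x$rule, "rule ),", nrow(x$coefficients), "nonzero feature(s)\n")
  cat("  train: "); print(x$train)
  cat("  test:  "); print(x$test)
  invisible(x)
}

#' @export
tidy.group_classifier <- function(x, ...) x$coefficients

#' @export
glance.group_classifier <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, n_features = nrow(x$coefficients),
                 auc_train = x$train$auc, auc_test = x$test$auc,
                 accuracy_test = x$test$accuracy,
                 sensitivity_test = x$test$sensitivity,
                 specificity_test = x$test$specificity)
}
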