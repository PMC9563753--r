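#' Fit log10 + Pareto scaling statistics on training rows
#'
#' Lipid features are log10-transformed, then Pareto-scaled:
#' (v - mean) / sqrt(sd), with mean and sd (n-1 denominator) estimated on
#' the training rows only. Features with zero training sd are dropped with
#' a warning.
#'
#' @param x Training feature matrix (already on the log scale for
#'   [pareto_scale_fit()]; [preprocess_fit()] handles the log step).
#' @return List with `center`, `scale` (sqrt sd) and `keep` (retained
#'   column names).
#' @export
pareto_scale_fit <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  keep <- sdv > 0
  if (any(!keep))
    warning("dropping constant feature(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
  list(center = mu[keep], scale = sqrt(sdv[keep]),
       keep = colnames(x)[keep])
}

#' Apply fitted Pareto scaling to new rows
#' @param x Feature matrix on the same scale the fit saw.
#' @param fit Result of [pareto_scale_fit()].
#' @return Scaled matrix restricted to the retained columns.
#' @export
pareto_scale_apply <- function(x, fit) {
  x <- x[, fit$keep, drop = FALSE]
  sweep(sweep(x, 2, fit$center), 2, fit$scale, `/`)
}

#' Fit the preprocessing transform (log10 + Pareto) on training rows
#'
#' Lipid columns must be strictly positive; covariate columns named in
#' `linear_features` (gender 0/1, BMI) skip the log step but are Pareto-
#' scaled with the rest. Missing BMI values must already be imputed (see
#' [impute_bmi()]).
#'
#' @param x Training feature matrix.
#' @param linear_features Columns excluded from the log transform.
#' @return Preprocessing object to pass to [preprocess_apply()].
#' @export
preprocess_fit <- function(x, linear_features = c("gender", "bmi")) {
  lip <- setdiff(colnames(x), linear_features)
  if (any(x[, lip, drop = FALSE] <= 0))
    stop("nonpositive lipid feature; preprocessing expects imputed data")
  lx <- x
  lx[, lip] <- log10(x[, lip, drop = FALSE])
  fit <- pareto_scale_fit(lx)
  fit$linear_features <- intersect(linear_features, colnames(x))
  fit$log_features <- lip
  class(fit) <- "sphingodx_preprocess"
  fit
}

#' Apply a fitted preprocessing transform (training statistics only)
#' @param x Feature matrix.
#' @param fit Result of [preprocess_fit()].
#' @return Transformed matrix.
#' @export
preprocess_apply <- function(x, fit) {
  lip <- intersect(fit$log_features, colnames(x))
  if (any(x[, lip, drop = FALSE] <= 0)) stop("nonpositive lipid feature")
  lx <- x
  lx[, lip] <- log10(x[, lip, drop = FALSE])
  pareto_scale_apply(lx, fit)
}

#' Impute missing BMI by the within-group median
#' @param bmi Numeric vector with NAs.
#' @param groups Group labels (N/T); the median is taken within each.
#' @return Imputed vector.
#' @export
impute_bmi <- function(bmi, groups) {
  for (g in unique(groups)) {
    i <- groups == g
    med <- stats::median(bmi[i], na.rm = TRUE)
    bmi[i & is.na(bmi)] <- med
  }
  bmi
}

#' Model specification for a classification task
#'
#' @param split_fraction Training fraction (default 0.6).
#' @param cv_folds Cross-validation folds (default 5).
#' @param lambda_grid Ridge penalties; default 50 values log-spaced over
#'   `[1e-4, 1e2]` (spans the null-to-saturated regimes on standardized
#'   features).
#' @param seed RNG seed controlling the split, upsampling and folds.
#' @param upsample Balance training classes by resampling the minority
#'   with replacement (default TRUE).
#' @return List of class `model_spec`.
#' @export
model_spec <- function(split_fraction = 0.6, cv_folds = 5,
                       lambda_grid = 10^seq(-4, 2, length.out = 50),
                       seed = 1L, upsample = TRUE) {
  stopifnot(split_fraction > 0, split_fraction < 1, cv_folds >= 2,
            length(lambda_grid) >= 1, all(lambda_grid > 0))
  structure(list(split_fraction = split_fraction, cv_folds = cv_folds,
                 lambda_grid = sort(lambda_grid, decreasing = TRUE),
                 seed = as.integer(seed), upsample = upsample),
            class = "model_spec")
}

#' Stratified train/test split with minority upsampling in the training set
#'
#' The split is stratified by label at the configured fraction; the
#' minority class among the training rows is then resampled with
#' replacement up to the majority count. Test rows are never duplicated or
#' resampled.
#'
#' @param y Binary labels (0/1 or two-level factor).
#' @param spec A [model_spec()].
#' @return List with integer row indices `train` (after upsampling,
#'   indices may repeat), `train_unique`, and `test`.
#' @export
split_upsample <- function(y, spec) {
  y <- as.integer(as.factor(y)) - 1L
  if (length(unique(y)) != 2L) stop("both classes must be present")
  set.seed(spec$seed)
  train <- integer(0)
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    n_tr <- round(spec$split_fraction * length(idx))
    train <- c(train, sort(sample(idx, n_tr)))
  }
  test <- setdiff(seq_along(y), train)
  if (length(unique(y[train])) < 2L || length(unique(y[test])) < 2L)
    stop("a class is absent from a partition; enlarge the cohort")
  up <- train
  if (spec$upsample) {
    tab <- table(y[train])
    minority <- as.integer(names(tab)[which.min(tab)])
    need <- max(tab) - min(tab)
    if (need > 0) {
      pool <- train[y[train] == minority]
      up <- c(train, sample(pool, need, replace = TRUE))
    }
  }
  list(train = up, train_unique = train, test = test)
}

# mean negative log-likelihood + (lambda/2) ||beta||^2, intercept unpenalized
ridge_objective <- function(theta, X, y, lambda) {
  eta <- drop(cbind(1, X) %*% theta)
  nll <- mean(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta)
  nll + lambda / 2 * sum(theta[-1]^2)
}

#' Ridge-penalized logistic regression by Newton / IRLS
#'
#' Minimizes mean negative log-likelihood + lambda/2 ||beta||^2 with an
#' unpenalized intercept, by damped Newton steps until the gradient norm
#' falls below `tol`. Features are expected standardized (the penalty is
#' scale-sensitive).
#'
#' @param X Numeric feature matrix.
#' @param y 0/1 labels.
#' @param lambda Ridge penalty (>= 0; 0 on separable data is guarded by
#'   the iteration cap).
#' @param tol Gradient-norm convergence threshold (default 1e-8).
#' @param max_iter Newton iteration cap (default 100).
#' @param init Optional warm-start coefficient vector (intercept first).
#' @return List with `coef` (named, intercept first), `converged`,
#'   `iterations`, `lambda`.
#' @export
ridge_logistic <- function(X, y, lambda, tol = 1e-8, max_iter = 100,
                           init = NULL) {
  X <- as.matrix(X)
  stopifnot(all(y %in% c(0, 1)), lambda >= 0)
  n <- nrow(X); p <- ncol(X)
  Xi <- cbind(`(intercept)` = 1, X)
  theta <- if (is.null(init)) numeric(p + 1) else init
  pen <- c(0, rep(lambda, p))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Xi %*% theta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(Xi, mu - y)) / n + pen * theta
    if (sqrt(sum(grad^2)) < tol) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), 1e-10)
    Hm <- crossprod(Xi * w, Xi) / n + diag(pen, p + 1)
    step <- solve(Hm, grad)
    # halving line search on the penalized objective
    f0 <- ridge_objective(theta, X, y, lambda)
    alpha <- 1
    repeat {
      cand <- theta - alpha * step
      if (ridge_objective(cand, X, y, lambda) <= f0 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    theta <- cand
  }
  names(theta) <- colnames(Xi)
  list(coef = theta, converged = converged, iterations = it, lambda = lambda)
}

#' Predicted class-1 probabilities from a ridge-logistic fit
#' @param fit Result of [ridge_logistic()].
#' @param X Feature matrix with the columns the fit saw.
#' @return Probability vector.
#' @export
predict_ridge <- function(fit, X) {
  stats::plogis(drop(cbind(1, as.matrix(X)[, names(fit$coef)[-1], drop = FALSE]) %*% fit$coef))
}

#' Select the ridge penalty by out-of-fold cross-validated AUC
#'
#' Splits the training rows into `cv_folds` stratified folds; per fold and
#' lambda, the preprocessing is refit on the in-fold rows, the model
#' trained, and the held-out AUC recorded. The lambda with the highest
#' mean out-of-fold AUC wins; the model is then refit on all training rows
#' at that lambda. Warm starts run down the (decreasing) lambda path.
#'
#' @param x_raw Raw (untransformed) training feature matrix, already
#'   upsampled if requested.
#' @param y Training labels (0/1).
#' @param spec A [model_spec()].
#' @param linear_features Columns excluded from the log transform.
#' @return List with `lambda`, `cv_auc` (lambda-indexed means), `fit`
#'   (final refit), `prep` (preprocessing fitted on all training rows),
#'   `skipped` (lambdas dropped for non-convergence).
#' @export
cv_ridge_auc <- function(x_raw, y, spec, linear_features = c("gender", "bmi")) {
  set.seed(spec$seed + 1L)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(spec$cv_folds), length(idx)))
  }
  lam <- spec$lambda_grid
  aucs <- matrix(NA_real_, nrow = spec$cv_folds, ncol = length(lam))
  ok <- matrix(TRUE, nrow = spec$cv_folds, ncol = length(lam))
  for (f in seq_len(spec$cv_folds)) {
    tr <- folds != f; te <- !tr
    if (length(unique(y[te])) < 2L) next
    prep <- preprocess_fit(x_raw[tr, , drop = FALSE], linear_features)
    Xtr <- preprocess_apply(x_raw[tr, , drop = FALSE], prep)
    Xte <- preprocess_apply(x_raw[te, , drop = FALSE], prep)
    init <- NULL
    for (j in seq_along(lam)) {
      fit <- ridge_logistic(Xtr, y[tr], lam[j], init = init)
      if (!fit$converged) { ok[f, j] <- FALSE; next }
      init <- fit$coef
      aucs[f, j] <- auc_rank(predict_ridge(fit, Xte), y[te])
    }
  }
  lam_ok <- colSums(!ok) == 0 & colSums(!is.na(aucs)) > 0
  if (!any(lam_ok)) stop("no lambda converged in cross-validation")
  mean_auc <- colMeans(aucs, na.rm = TRUE)
  best <- which(lam_ok)[which.max(mean_auc[lam_ok])]
  prep <- preprocess_fit(x_raw, linear_features)
  Xall <- preprocess_apply(x_raw, prep)
  final <- ridge_logistic(Xall, y, lam[best])
  list(lambda = lam[best], cv_auc = stats::setNames(mean_auc, signif(lam, 6)),
       fit = final, prep = prep, skipped = lam[!lam_ok])
}

#' AUC by the Mann-Whitney rank statistic (ties counted one half)
#' @param scores Numeric scores.
#' @param labels 0/1 labels (1 = positive).
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve, AUC and DeLong 95% confidence interval
#'
#' ROC points are computed at every distinct score threshold; the AUC is
#' the rank (Mann-Whitney) statistic and its CI follows DeLong's
#' placement-value variance estimate, clipped to [0, 1].
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels 0/1 labels.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `roc` (data frame threshold/FPR/TPR), `auc`,
#'   `ci_lower`, `ci_upper`, `se`.
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  labels <- as.integer(labels)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) stop("both classes required")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(neg >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(pos >= t), numeric(1))
  )
  auc <- auc_rank(scores, labels)
  # DeLong placements
  v10 <- vapply(pos, function(x) mean(x > neg) + 0.5 * mean(x == neg), numeric(1))
  v01 <- vapply(neg, function(y) mean(pos > y) + 0.5 * mean(pos == y), numeric(1))
  se <- sqrt(stats::var(v10) / length(pos) + stats::var(v01) / length(neg))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(roc = roc, auc = auc,
       ci_lower = max(0, auc - z * se), ci_upper = min(1, auc + z * se),
       se = se)
}

#' Confusion matrix at a probability threshold with exact binomial CIs
#'
#' Accuracy, sensitivity and specificity at the given threshold, each with
#' the Clopper-Pearson exact binomial 95% CI.
#'
#' @param probabilities Predicted class-1 probabilities.
#' @param labels 0/1 labels.
#' @param threshold Decision threshold (default 0.5).
#' @param conf_level Confidence level (default 0.95).
#' @return List with the 2x2 `confusion` table (predicted x actual) and
#'   per-metric point estimates and CI bounds.
#' @export
confusion_with_cis <- function(probabilities, labels, threshold = 0.5,
                               conf_level = 0.95) {
  stopifnot(all(probabilities >= 0 & probabilities <= 1))
  labels <- as.integer(labels)
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0); fp <- sum(pred == 1 & labels == 0)
  cp <- function(x, n) {
    if (n == 0) return(c(est = NA_real_, lower = NA_real_, upper = NA_real_))
    bt <- stats::binom.test(x, n, conf.level = conf_level)
    c(est = x / n, lower = bt$conf.int[1], upper = bt$conf.int[2])
  }
  list(
    confusion = matrix(c(tn, fp, fn, tp), 2, 2,
                       dimnames = list(predicted = c("0", "1"),
                                       actual = c("0", "1"))),
    accuracy = cp(tp + tn, length(labels)),
    sensitivity = cp(tp, tp + fn),
    specificity = cp(tn, tn + fp),
    threshold = threshold
  )
}

#' Run one full classification task
#'
#' Stratified 60/40 split, minority upsampling of the training rows, lambda
#' selection by 5-fold out-of-fold AUC, refit, and train/test ROC, AUC
#' (DeLong CI), and confusion metrics (Clopper-Pearson CIs) at probability
#' 0.5. All preprocessing statistics come from training rows only.
#'
#' @param x_raw Raw feature matrix (relative lipid concentrations + gender
#'   + BMI), one row per subject.
#' @param y 0/1 labels (1 = case).
#' @param spec A [model_spec()].
#' @param task Free-text task name stored in the report.
#' @param linear_features Columns excluded from the log transform.
#' @return List of class `classifier_report`.
#' @export
run_task <- function(x_raw, y, spec = model_spec(), task = "T vs N",
                     linear_features = c("gender", "bmi")) {
  y <- as.integer(y)
  if (!length(y) || length(unique(y)) < 2L) stop("empty or single-class task subset")
  parts <- split_upsample(y, spec)
  xtr <- x_raw[parts$train, , drop = FALSE]
  ytr <- y[parts$train]
  cv <- cv_ridge_auc(xtr, ytr, spec, linear_features)
  eval_set <- function(idx) {
    Xs <- preprocess_apply(x_raw[idx, , drop = FALSE], cv$prep)
    pr <- predict_ridge(cv$fit, Xs)
    ra <- roc_auc(pr, y[idx])
    cm <- confusion_with_cis(pr, y[idx])
    list(probabilities = pr, roc = ra$roc,
         auc = ra$auc, auc_ci = c(ra$ci_lower, ra$ci_upper),
         accuracy = cm$accuracy, sensitivity = cm$sensitivity,
         specificity = cm$specificity, confusion = cm$confusion,
         n = length(idx))
  }
  report <- list(
    task = task, spec = spec, lambda = cv$lambda,
    coefficients = cv$fit$coef, cv_auc = cv$cv_auc,
    train = eval_set(parts$train_unique),
    test = eval_set(parts$test),
    n_train = length(parts$train_unique),
    n_train_upsampled = length(parts$train),
    n_test = length(parts$test)
  )
  class(report) <- "classifier_report"
  report
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("classifier_report:", x$task, "\n")
  cat(sprintf("  lambda = %.4g (CV by AUC over %d values)\n",
              x$lambda, length(x$cv_auc)))
  for (s in c("train", "test")) {
    e <- x[[s]]
    cat(sprintf("  %s (n=%d): AUC %.3f (%.3f-%.3f), acc %.3f, sens %.3f, spec %.3f\n",
                s, e$n, e$auc, e$auc_ci[1], e$auc_ci[2],
                e$accuracy[["est"]], e$sensitivity[["est"]], e$specificity[["est"]]))
  }
  invisible(x)
}

#' Serialize a classifier report to JSON plus ROC-point tables
#' @param report A `classifier_report`.
#' @param path JSON output path; ROC tables go to `<path>.train.roc.tsv`
#'   and `<path>.test.roc.tsv`.
#' @export
write_report <- function(report, path) {
  out <- report
  out$spec <- unclass(out$spec)
  for (s in c("train", "test")) {
    utils::write.table(out[[s]]$roc,
                       paste0(path, ".", s, ".roc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out[[s]]$roc <- NULL
    out[[s]]$confusion <- as.list(as.data.frame(out[[s]]$confusion))
  }
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
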