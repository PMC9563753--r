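test_that("log10 + Pareto preprocessing uses training statistics only", {
  x_tr <- matrix(c(1, 10, 100), 3, 1, dimnames = list(NULL, "a"))
  prep <- preprocess_fit(x_tr, linear_features = character(0))
  expect_equal(unname(drop(preprocess_apply(x_tr, prep))), c(-1, 0, 1))
  x_te <- matrix(10, 1, 1, dimnames = list(NULL, "a"))
  expect_equal(unname(drop(preprocess_apply(x_te, prep))), 0)  # train stats
  # constant feature dropped with warning
  x2 <- cbind(x_tr, b = rep(7, 3))
  expect_warning(prep2 <- preprocess_fit(x2, linear_features = character(0)),
                 "constant")
  expect_equal(prep2$keep, "a")
  expect_error(preprocess_fit(matrix(c(-1, 2, 3), 3, 1,
                                     dimnames = list(NULL, "a")),
                              linear_features = character(0)),
               "nonpositive")
})

test_that("BMI imputation fills by within-group median", {
  bmi <- c(20, 30, NA, 10, NA, 50)
  g <- c("N", "N", "N", "T", "T", "T")
  expect_equal(impute_bmi(bmi, g), c(20, 30, 25, 10, 30, 50))
})

test_that("stratified split and upsampling reproduce the cohort arithmetic", {
  y <- rep(c(0, 1), c(207, 143))
  parts <- split_upsample(y, model_spec(seed = 3))
  expect_equal(sum(y[parts$train_unique] == 0), 124)
  expect_equal(sum(y[parts$train_unique] == 1), 86)
  expect_equal(sum(y[parts$train] == 1), 124)  # minority upsampled
  expect_equal(sort(unique(parts$train)), sort(parts$train_unique))
  expect_length(intersect(parts$test, parts$train), 0)
  expect_equal(sort(c(parts$train_unique, parts$test)), seq_along(y))
  expect_false(anyDuplicated(parts$test) > 0)
  # balanced input: upsampling is a no-op
  yb <- rep(c(0, 1), each = 50)
  pb <- split_upsample(yb, model_spec(seed = 3))
  expect_equal(sort(pb$train), sort(pb$train_unique))
})

test_that("ridge logistic matches glmnet on its shared objective", {
  skip_if_not_installed("glmnet")
  set.seed(14)
  n <- 300; p <- 6
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  beta <- c(1.2, -0.8, 0.5, 0, 0, 0.3)
  y <- rbinom(n, 1, plogis(0.4 + X %*% beta))
  for (lam in c(0.01, 0.1, 1)) {
    fit <- ridge_logistic(X, y, lam)
    expect_true(fit$converged)
    gn <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                         lambda = lam, standardize = FALSE,
                         thresh = 1e-14)
    expect_equal(unname(fit$coef),
                 unname(as.numeric(coef(gn))), tolerance = 1e-4)
  }
})

test_that("ridge coefficients vanish and shrink monotonically with lambda", {
  set.seed(15)
  X <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rbinom(100, 1, plogis(X[, 1] - X[, 2]))
  fit_big <- ridge_logistic(X, y, 1e4)
  expect_lt(max(abs(fit_big$coef[-1])), 1e-3)
  expect_equal(mean(predict_ridge(fit_big, X)), mean(y), tolerance = 1e-2)
  norms <- vapply(10^seq(-3, 2, length.out = 12), function(l)
    sqrt(sum(ridge_logistic(X, y, l)$coef[-1]^2)), numeric(1))
  expect_false(is.unsorted(rev(norms)))
  # separable toy at lambda 0: coefficients run off toward the separating
  # direction but the iteration cap keeps the fit finite
  Xs <- matrix(c(-2, -1, 1, 2), 4, 1, dimnames = list(NULL, "f"))
  fit0 <- ridge_logistic(Xs, c(0, 0, 1, 1), 0, max_iter = 30)
  expect_true(all(is.finite(fit0$coef)))
  expect_gt(abs(fit0$coef[["f"]]), 5)
  expect_lte(fit0$iterations, 30)
})

test_that("ridge recovers generating coefficients at small lambda", {
  set.seed(16)
  n <- 1000; p <- 5
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  beta <- c(0.9, -0.7, 0.5, 0.4, -0.3)
  y <- rbinom(n, 1, plogis(drop(X %*% beta)))
  fit <- ridge_logistic(X, y, 1e-6)
  rel_err <- sqrt(sum((fit$coef[-1] - beta)^2)) / sqrt(sum(beta^2))
  expect_lt(rel_err, 0.15)
  # 2-feature Gaussian toy: direction within 5 degrees of the Bayes discriminant
  n2 <- 2000
  X2 <- rbind(matrix(rnorm(n2, 0, 1), n2 / 2, 2),
              matrix(rnorm(n2, 1, 1), n2 / 2, 2))
  colnames(X2) <- c("u", "v")
  y2 <- rep(c(0, 1), each = n2 / 2)
  f2 <- ridge_logistic(X2, y2, 1e-4)
  b <- f2$coef[-1]
  angle <- acos(sum(b * c(1, 1)) / sqrt(sum(b^2) * 2)) * 180 / pi
  expect_lt(angle, 5)
})

test_that("rank AUC equals pair counting and behaves at the extremes", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1.0)
  set.seed(17)
  for (i in 1:20) {
    s <- sample(seq(0, 1, 0.05), 30, replace = TRUE)  # with ties
    l <- rbinom(30, 1, 0.5)
    if (length(unique(l)) < 2) next
    expect_equal(auc_rank(s, l), oracle_auc_pairs(s, l))
  }
  expect_error(auc_rank(1:5, rep(1, 5)), "both classes")
})

test_that("ROC/DeLong output agrees with pROC and covers the null", {
  skip_if_not_installed("pROC")
  set.seed(18)
  s <- rnorm(120); l <- rbinom(120, 1, 0.5)
  ra <- roc_auc(s, l)
  pr <- pROC::roc(l, s, quiet = TRUE, direction = "<",
                  levels = c("0", "1"))
  ci <- pROC::ci.auc(pr, method = "delong")
  expect_equal(ra$auc, as.numeric(pROC::auc(pr)))
  expect_equal(ra$ci_lower, ci[1], tolerance = 1e-8)
  expect_equal(ra$ci_upper, ci[3], tolerance = 1e-8)
  expect_true(ra$ci_lower <= 0.5 && ra$ci_upper >= 0.5)
  # ROC points: monotone staircase from (0,0) to (1,1)
  expect_equal(ra$roc$fpr[1], 0); expect_equal(ra$roc$tpr[1], 0)
  expect_equal(rev(ra$roc$fpr)[1], 1); expect_equal(rev(ra$roc$tpr)[1], 1)
  expect_false(is.unsorted(ra$roc$fpr))
  expect_false(is.unsorted(ra$roc$tpr))
})

test_that("confusion metrics carry exact Clopper-Pearson intervals", {
  p <- c(rep(0.9, 20), rep(0.1, 15))
  y <- rep(c(1, 0), c(20, 15))
  cm <- confusion_with_cis(p, y)
  expect_equal(unname(cm$sensitivity[["est"]]), 1)
  expect_equal(unname(cm$sensitivity[["lower"]]), 0.025^(1 / 20),
               tolerance = 1e-9)
  expect_equal(sum(cm$confusion), 35)
  # swapping polarity swaps sensitivity and specificity
  cm2 <- confusion_with_cis(1 - p, 1 - y)
  expect_equal(cm2$sensitivity[["est"]], cm$specificity[["est"]])
  expect_equal(cm2$specificity[["est"]], cm$sensitivity[["est"]])
})

test_that("no test-set row influences the fitted model (leakage guard)", {
  set.seed(19)
  n <- 80
  x <- matrix(rlnorm(n * 6, log(20), 0.5), n, 6,
              dimnames = list(paste0("S", 1:n), paste0("L", 1:6)))
  x <- cbind(x, gender = rbinom(n, 1, 0.5), bmi = rnorm(n, 27, 4))
  y <- rbinom(n, 1, 0.5); y[1:3] <- 0; y[4:6] <- 1
  spec <- model_spec(seed = 23, lambda_grid = 10^seq(-3, 1, length.out = 8))
  r1 <- run_task(x, y, spec)
  parts <- split_upsample(y, spec)  # same seed -> same partition
  x2 <- x
  x2[parts$test, seq_len(6)] <- x2[parts$test, seq_len(6)] * 5  # perturb test rows
  r2 <- run_task(x2, y, spec)
  expect_identical(r1$coefficients, r2$coefficients)
  expect_identical(r1$lambda, r2$lambda)
})

test_that("task runner separates informative cohorts and is seed-deterministic", {
  set.seed(20)
  n <- 60
  signal <- rep(c(0, 1.6), each = n)
  x <- matrix(rlnorm(2 * n * 5, log(30) + rep(signal, 5) * 0.4, 0.4), 2 * n, 5,
              dimnames = list(paste0("S", 1:(2 * n)), paste0("L", 1:5)))
  x <- cbind(x, gender = rbinom(2 * n, 1, 0.5), bmi = rnorm(2 * n, 27, 4))
  y <- rep(c(0, 1), each = n)
  spec <- model_spec(seed = 29, lambda_grid = 10^seq(-3, 1, length.out = 10))
  rep1 <- run_task(x, y, spec)
  expect_gt(rep1$test$auc, 0.8)
  rep2 <- run_task(x, y, spec)
  expect_identical(serialize(rep1, NULL), serialize(rep2, NULL))
  expect_error(run_task(x, rep(1, 2 * n), spec), "single-class")
  # report serialization writes JSON + ROC tables
  path <- tempfile(fileext = ".json")
  write_report(rep1, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".test.roc.tsv")))
  js <- jsonlite::read_json(path)
  expect_equal(js$lambda, rep1$lambda)
})
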