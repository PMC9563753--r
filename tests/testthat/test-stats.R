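test_that("Hodges-Lehmann fold change matches brute-force ratio medians", {
  expect_equal(hl_fold_change(c(2, 4), c(1, 2)), 2.0)  # median of 2,1,4,2
  x <- c(3.2, 1.1, 7.4, 2.2)
  expect_equal(hl_fold_change(x, x), 1.0)
  expect_equal(hl_fold_change(2 * x, x), 2.0)
  set.seed(11)
  for (i in 1:25) {
    a <- rlnorm(sample(1:7, 1)); b <- rlnorm(sample(1:7, 1))
    expect_equal(hl_fold_change(a, b), oracle_hl_fc(a, b))
  }
  # scale equivariance holds for any positive constant
  for (c_ in c(0.25, 1, 3.7)) {
    v <- rlnorm(9)
    expect_equal(hl_fold_change(c_ * v, v), c_, tolerance = 1e-12)
  }
  expect_error(hl_fold_change(c(1, -2), c(1, 2)), "nonpositive")
  # paired variant uses only aligned ratios
  expect_equal(hl_fold_change(c(2, 8), c(1, 2), paired = TRUE), 3)
})

test_that("Mann-Whitney matches enumeration exactly and is symmetric", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)      # 2/20 rank assignments as extreme
  expect_equal(mw$method, "exact")
  x <- c(1.2, 5.3, 2.2); y <- c(0.4, 7.7, 3.1, 9.9)
  expect_equal(mann_whitney(x, y)$p, mann_whitney(y, x)$p)
  expect_equal(mann_whitney(c(2, 2, 2), c(2, 2))$p, 1)
})

test_that("signed-rank test matches sign-pattern enumeration", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6))$p, 2 / 64)
  d <- c(-3, -1, 1, 3)  # antisymmetric multiset centers the statistic
  expect_equal(wilcoxon_signed_rank(d)$p, 1, tolerance = 1e-9)
  d2 <- c(0.3, -1.2, 2.5, 0.7, -0.1)
  expect_equal(wilcoxon_signed_rank(d2)$p, wilcoxon_signed_rank(-d2)$p)
  expect_equal(wilcoxon_signed_rank(c(0, 0, 0))$p, 1)
})

test_that("rank-biserial r counts pairs with ties as half", {
  expect_equal(rank_biserial(c(5, 6, 7), c(1, 2, 3)), 1.0)
  expect_equal(rank_biserial(c(1, 2, 3), c(1, 2, 3)), 0.0)
  expect_equal(rank_biserial(c(1, 3), c(2, 4)), -0.5)
  set.seed(4)
  x <- rnorm(12); y <- rnorm(15)
  wins <- 0
  for (a in x) for (b in y) wins <- wins + (a > b) + 0.5 * (a == b)
  expect_equal(rank_biserial(x, y), 2 * wins / (12 * 15) - 1)
})

test_that("Kruskal-Wallis H and epsilon-squared follow the rank formulas", {
  g0 <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  kw0 <- kruskal_wallis(g0)
  expect_equal(kw0$H, 0)
  expect_equal(kw0$epsilon_sq, 0)
  # direct rank computation: ranks 1..6, H = 12/42 * 89.5 - 21
  kw <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(kw$H, 12 / 42 * (2 * 1.5^2 + 2 * 3.5^2 + 2 * 5.5^2) - 21,
               tolerance = 1e-12)
  expect_equal(kw$epsilon_sq, kw$H / 5, tolerance = 1e-12)
  g <- list(rnorm(5), rnorm(7), rnorm(6))
  expect_equal(kruskal_wallis(g)$H, kruskal_wallis(rev(g))$H)
  expect_error(kruskal_wallis(list(1:5)), "two nonempty groups")
})

test_that("Conover post hoc separates separated groups and is symmetric", {
  ident <- list(a = c(1, 5, 9, 2), b = c(5, 9, 1, 2), c = c(9, 1, 2, 5))
  res0 <- conover_posthoc(ident)
  expect_true(all(res0$p_adj[upper.tri(res0$p_adj)] > 0.9))
  set.seed(6)
  g <- list(a = rnorm(10, 0), b = rnorm(10, 3), c = rnorm(10, 6))
  res <- conover_posthoc(g)
  expect_equal(res$p_adj, t(res$p_adj))
  expect_equal(unname(diag(res$p_adj)), rep(1, 3))
  expect_true(all(res$p_adj[upper.tri(res$p_adj)] < 0.05))
  expect_true(all(res$p_adj >= res$p_raw - 1e-12))
})

test_that("BH adjustment reproduces the hand step-up computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(2)
  p <- runif(40)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_false(is.unsorted(q[order(p)]))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("presence tables run Fisher for fluids and exact McNemar for tissues", {
  # 24/143 cases vs 2/207 controls present
  pres <- matrix(FALSE, 350, 1, dimnames = list(NULL, "SHex2Cer 42:2;O2"))
  groups <- rep(c("T", "N"), c(143, 207))
  pres[c(1:24, 143 + 1:2), 1] <- TRUE
  ft <- presence_tables(pres, groups = groups)
  expect_lt(ft$p, 1e-6)
  expect_equal(ft$p, oracle_fisher_p(2, 24, 205, 119), tolerance = 1e-9)
  expect_lt(ft$odds_ratio, 1)  # presence rarer in group_1 = N

  # paired tissues: b = 6 discordant toward nontumor, c = 0
  pres2 <- matrix(c(rep(TRUE, 6), rep(FALSE, 4),    # nontumor rows
                    rep(FALSE, 10)),                # tumor rows
                  ncol = 1, dimnames = list(NULL, "L"))
  mt <- presence_tables(pres2, pair_ids = rep(1:10, 2),
                        tissue_type = rep(c("nontumor", "tumor"), each = 10))
  expect_equal(mt$p, 2 / 64)
  # b = c gives the maximal two-sided binomial p
  pres3 <- matrix(c(rep(c(TRUE, FALSE), 5), rep(c(FALSE, TRUE), 5)),
                  ncol = 1, dimnames = list(NULL, "L"))
  mt3 <- presence_tables(pres3, pair_ids = rep(1:10, 2),
                         tissue_type = rep(c("nontumor", "tumor"), each = 10))
  expect_equal(mt3$p, 1)
  # no discordant pairs
  pres4 <- matrix(TRUE, 8, 1, dimnames = list(NULL, "L"))
  mt4 <- presence_tables(pres4, pair_ids = rep(1:4, 2),
                         tissue_type = rep(c("nontumor", "tumor"), each = 4))
  expect_equal(mt4$p, 1)
})

test_that("Spearman screen reports rho with missing-data reasons", {
  conc <- cbind(up = (1:10)^2, down = exp(-(1:10)), flat = rep(2, 10))
  rownames(conc) <- paste0("S", 1:10)
  res <- spearman_screen(1:10, conc)
  expect_equal(res$rho[res$lipid == "up"], 1)
  expect_equal(res$rho[res$lipid == "down"], -1)
  expect_equal(res$note[res$lipid == "flat"], "constant input")
  res2 <- spearman_screen(c(1, 2, 3, rep(NA, 7)), conc)
  expect_true(all(res2$note == "fewer than 4 complete pairs"))
})

test_that("Ward clustering matches the naive agglomeration oracle and z-scores standardize", {
  set.seed(13)
  for (n in c(4, 7, 10)) {
    x <- matrix(rlnorm(n * 5, log(50), 0.6), n, 5,
                dimnames = list(paste0("S", 1:n), paste0("L", 1:5)))
    cs <- cluster_summary(x)
    orc <- oracle_ward(pareto_scale_apply(log10(x), pareto_scale_fit(log10(x))))
    expect_equal(hclust_merge_sets(cs$hclust), orc$merges)
    expect_equal(unname(cs$hclust$height), orc$heights, tolerance = 1e-9)
    expect_equal(unname(colMeans(cs$zscores)), rep(0, 5), tolerance = 1e-12)
    expect_equal(unname(apply(cs$zscores, 2, sd)), rep(1, 5), tolerance = 1e-12)
  }
  # duplicated sample blocks merge first at height zero
  x <- matrix(rlnorm(4 * 3, log(100), 0.5), 4, 3,
              dimnames = list(paste0("S", 1:4), paste0("L", 1:3)))
  x[2, ] <- x[1, ]
  cs <- cluster_summary(x)
  expect_equal(cs$hclust$height[1], 0)
  expect_setequal(cs$hclust$merge[1, ], c(-1, -2))
  expect_match(cs$newick, "^\\(")
  expect_error(cluster_summary(x[1, , drop = FALSE]), "2 samples")
})

test_that("the two-group stat table wires FC, tests, FDR and effect sizes together", {
  set.seed(31)
  n <- 30
  conc <- cbind(up = c(rlnorm(n, log(10), 0.3), rlnorm(n, log(20), 0.3)),
                null = rlnorm(2 * n, log(5), 0.3))
  rownames(conc) <- paste0("S", seq_len(2 * n))
  groups <- rep(c("N", "T"), each = n)
  st <- stat_table(conc, groups)
  expect_s3_class(st, "stat_table")
  expect_true(all(st$q_fdr >= st$p_raw))
  up <- st[st$lipid == "up", ]
  expect_gt(up$fold_change, 1.5)
  expect_lt(up$q_fdr, 0.01)
  expect_gt(up$effect_size, 0.5)
  expect_equal(st$log2_fc, log2(st$fold_change))
  expect_equal(significance_stars(c(0.6, 0.2, 0.05, 0.9),
                                  c(0.01, 0.01, 0.01, 0.5)),
               c("***", "*", "", ""))
})
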