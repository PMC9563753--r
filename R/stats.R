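#' Hodges-Lehmann-type fold change
#'
#' The median of all pairwise between-group ratios x_T[i]/x_N[j]; robust to
#' outliers and equivariant under scaling (FC(c x, x) = c). An even ratio
#' count takes the mean of the central pair.
#'
#' @param x_t,x_n Positive value vectors for the case and reference group.
#' @param paired If TRUE, only the elementwise ratios of aligned pairs are
#'   used (tissue tumor/nontumor option); default uses all pairs.
#' @return Fold change (dimensionless, > 0).
#' @export
hl_fold_change <- function(x_t, x_n, paired = FALSE) {
  if (!length(x_t) || !length(x_n)) stop("empty group")
  if (any(x_t <= 0) || any(x_n <= 0))
    stop("nonpositive values; fold changes require floor-imputed data")
  if (paired) {
    stopifnot(length(x_t) == length(x_n))
    return(stats::median(x_t / x_n))
  }
  stats::median(outer(x_t, x_n, `/`))
}

#' Mann-Whitney U test
#'
#' Two-sided; exact when both groups have at most 8 observations and there
#' are no ties (enumeration is cheap there), otherwise the normal
#' approximation with tie and continuity correction. Returns the U statistic
#' for `x` (number of (x, y) pairs won by x, ties counted 1/2).
#'
#' @param x,y Value vectors.
#' @param exact_max Largest per-group n for the exact branch (default 8).
#' @return List with `U`, `p`, `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 8) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0L
  if (length(unique(c(x, y))) == 1L) {
    u <- length(x) * length(y) / 2
    return(list(U = u, p = 1, method = "degenerate"))
  }
  use_exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
  )
  list(U = unname(wt$statistic), p = min(1, wt$p.value),
       method = if (use_exact) "exact" else "normal_approx")
}

#' Wilcoxon signed-rank test for paired differences
#'
#' Two-sided; zero differences are dropped; exact when at most 15 nonzero
#' pairs without tied magnitudes, else normal approximation with tie and
#' continuity correction.
#'
#' @param d Vector of paired differences (e.g. tumor minus nontumor).
#' @param exact_max Largest pair count for the exact branch (default 15).
#' @return List with `V` (sum of positive ranks), `p`, `n_used`, `method`.
#' @export
wilcoxon_signed_rank <- function(d, exact_max = 15) {
  d <- d[d != 0]
  if (!length(d)) return(list(V = 0, p = 1, n_used = 0L, method = "degenerate"))
  ties <- anyDuplicated(abs(d)) > 0L
  use_exact <- !ties && length(d) <= exact_max
  wt <- suppressWarnings(stats::wilcox.test(d, exact = use_exact, correct = TRUE))
  list(V = unname(wt$statistic), p = min(1, wt$p.value), n_used = length(d),
       method = if (use_exact) "exact" else "normal_approx")
}

#' Rank-biserial correlation effect size for the Mann-Whitney test
#'
#' r = 2 U_x / (n_x n_y) - 1 where U_x counts (x > y) pairs with ties as
#' one half; r in [-1, 1], positive when x tends to exceed y.
#'
#' @param x,y Value vectors.
#' @return Rank-biserial r.
#' @export
rank_biserial <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  r <- rank(c(x, y))
  rx <- sum(r[seq_along(x)])
  u_x <- rx - length(x) * (length(x) + 1) / 2
  2 * u_x / (length(x) * length(y)) - 1
}

#' Kruskal-Wallis test with epsilon-squared effect size
#'
#' H with tie correction, p from the chi-square reference with k-1 df, and
#' epsilon squared = H / (n - 1).
#'
#' @param groups List of >= 2 nonempty value vectors.
#' @return List with `H`, `df`, `p`, `epsilon_sq`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2L) stop("need at least two nonempty groups")
  kt <- stats::kruskal.test(groups)
  n <- sum(lengths(groups))
  H <- unname(kt$statistic)
  list(H = H, df = unname(kt$parameter), p = kt$p.value,
       epsilon_sq = H / (n - 1), n = n)
}

#' Conover-Iman post hoc test after Kruskal-Wallis
#'
#' t statistics on pooled ranks with the tie-corrected pooled variance
#' S2 = (sum R^2 - n (n+1)^2 / 4) / (n - 1), comparing mean ranks with
#' variance scaled by (n - 1 - H) / (n - k); two-sided p from the t
#' distribution with n - k df, then BH-adjusted across the pairs.
#'
#' @param groups Named list of value vectors.
#' @return List with symmetric matrices `p_raw` and `p_adj` (unit
#'   diagonal) and the mean-rank vector.
#' @export
conover_posthoc <- function(groups) {
  k <- length(groups)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  sizes <- lengths(groups)
  if (any(sizes == 0L)) {
    # pairs with an empty member are reported as missing
    good <- sizes > 0L
  } else good <- rep(TRUE, k)
  n <- sum(sizes)
  r <- rank(unlist(groups))
  idx <- rep(seq_len(k), sizes)
  rbar <- tapply(r, idx, mean)
  H <- kruskal_wallis(groups[good])$H
  S2 <- (sum(r^2) - n * (n + 1)^2 / 4) / (n - 1)
  scale2 <- S2 * (n - 1 - H) / (n - k)
  p <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  diag(p) <- 1
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!good[i] || !good[j]) next
    se <- sqrt(scale2 * (1 / sizes[i] + 1 / sizes[j]))
    tt <- (rbar[[as.character(i)]] - rbar[[as.character(j)]]) / se
    pv <- if (is.finite(tt)) 2 * stats::pt(-abs(tt), df = n - k) else 1
    p[i, j] <- p[j, i] <- min(1, pv)
  }
  up <- upper.tri(p)
  padj <- p
  padj[up] <- bh_fdr(p[up])
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  list(p_raw = p, p_adj = padj, mean_ranks = stats::setNames(as.numeric(rbar),
                                                             names(groups)[good]))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q_i = min over j >= i of m p_(j) / j, clipped at 1, mapped back
#' to input order. NAs propagate.
#'
#' @param p Vector of p values in [0, 1].
#' @return q values, same order as input.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p values must lie in [0, 1]")
  out <- p
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Presence/absence contingency analysis for low-prevalence lipids
#'
#' Lipids failing inclusion criterion 1 are coded present (intensity above
#' the floor) / absent. For unpaired fluids a 2x2 table against N/T with the
#' two-sided Fisher exact test (conditional-MLE odds ratio); for paired
#' tissues the discordant counts b (present only in nontumor) and c
#' (present only in tumor) with the exact binomial McNemar p (two-sided
#' binomial test of b in b + c at 1/2).
#'
#' @param present Logical samples x lipids matrix (or intensity matrix with
#'   `floor` to threshold on).
#' @param groups Two-level labels ("N"/"T") for the unpaired design, or
#'   NULL for paired.
#' @param pair_ids For the paired design, the subject id per row (each
#'   subject exactly one nontumor and one tumor row; `tissue_type` then
#'   distinguishes them).
#' @param tissue_type For the paired design, "nontumor"/"tumor" per row.
#' @param floor Intensity threshold if `present` is numeric (default 8000).
#' @return Data frame with one row per lipid: counts, test name, p value
#'   and (unpaired) the conditional-MLE odds ratio.
#' @export
presence_tables <- function(present, groups = NULL, pair_ids = NULL,
                            tissue_type = NULL, floor = 8000) {
  if (is.numeric(present)) present <- present > floor
  lipids <- colnames(present)
  if (!is.null(groups)) {
    groups <- as.character(groups)
    lv <- sort(unique(groups))
    stopifnot(length(lv) == 2L)
    rows <- lapply(lipids, function(l) {
      tab <- table(factor(present[, l], c(TRUE, FALSE)),
                   factor(groups, lv))
      ft <- stats::fisher.test(tab)
      data.frame(lipid = l,
                 n_present_1 = tab[1, 1], n_total_1 = sum(tab[, 1]),
                 n_present_2 = tab[1, 2], n_total_2 = sum(tab[, 2]),
                 group_1 = lv[1], group_2 = lv[2],
                 odds_ratio = unname(ft$estimate), p = ft$p.value,
                 test_name = "fisher_exact", stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  stopifnot(!is.null(pair_ids), !is.null(tissue_type))
  nt <- present[tissue_type == "nontumor", , drop = FALSE]
  tu <- present[tissue_type == "tumor", , drop = FALSE]
  nt <- nt[order(pair_ids[tissue_type == "nontumor"]), , drop = FALSE]
  tu <- tu[order(pair_ids[tissue_type == "tumor"]), , drop = FALSE]
  rows <- lapply(lipids, function(l) {
    b <- sum(nt[, l] & !tu[, l])   # present only in nontumor
    cc <- sum(!nt[, l] & tu[, l])  # present only in tumor
    p <- if (b + cc == 0) 1 else stats::binom.test(b, b + cc, 0.5)$p.value
    data.frame(lipid = l, b_nontumor_only = b, c_tumor_only = cc,
               n_pairs = nrow(nt), p = min(1, p),
               test_name = if (b + cc == 0) "mcnemar_exact (no discordant pairs)"
                           else "mcnemar_exact",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spearman correlation screen of a clinical covariate against all lipids
#'
#' Pairwise-complete Spearman rho with two-sided p from the t
#' approximation; lipids with fewer than 4 complete pairs or a constant
#' covariate are reported as missing with a reason.
#'
#' @param covariate Numeric vector (age or BMI; NAs allowed).
#' @param conc Samples x lipids concentration matrix.
#' @return Data frame lipid / rho / p / n / note.
#' @export
spearman_screen <- function(covariate, conc) {
  stopifnot(length(covariate) == nrow(conc))
  rows <- lapply(colnames(conc), function(l) {
    ok <- !is.na(covariate) & !is.na(conc[, l])
    n <- sum(ok)
    if (n < 4)
      return(data.frame(lipid = l, rho = NA_real_, p = NA_real_, n = n,
                        note = "fewer than 4 complete pairs"))
    if (length(unique(covariate[ok])) == 1L || length(unique(conc[ok, l])) == 1L)
      return(data.frame(lipid = l, rho = NA_real_, p = NA_real_, n = n,
                        note = "constant input"))
    ct <- suppressWarnings(
      stats::cor.test(covariate[ok], conc[ok, l], method = "spearman",
                      exact = FALSE)
    )
    data.frame(lipid = l, rho = unname(ct$estimate), p = ct$p.value, n = n,
               note = "")
  })
  do.call(rbind, rows)
}

#' Ward clustering summary with z-score matrix and Newick export
#'
#' Log10-transforms and Pareto-scales the selected relative concentrations
#' (per lipid across samples), computes Euclidean distances, applies Ward's
#' agglomeration (`hclust` ward.D2, i.e. the Lance-Williams Ward update on
#' squared distances), and returns the merge tree plus the per-lipid
#' z-score matrix used for heat maps.
#'
#' @param conc Samples x lipids relative-concentration matrix (positive).
#' @param lipids Columns to cluster on (default all).
#' @param newick_path Optional path; when given the tree is written in
#'   Newick format via ape.
#' @return List with `hclust` (merge tree over samples), `zscores`
#'   (samples x lipids matrix with per-lipid mean 0, sd 1), and `newick`
#'   (Newick string).
#' @export
cluster_summary <- function(conc, lipids = colnames(conc), newick_path = NULL) {
  x <- conc[, lipids, drop = FALSE]
  if (nrow(x) < 2L) stop("clustering needs at least 2 samples")
  if (any(x <= 0)) stop("nonpositive concentrations; impute first")
  lx <- log10(x)
  sc <- pareto_scale_fit(lx)
  px <- pareto_scale_apply(lx, sc)
  hc <- stats::hclust(stats::dist(px), method = "ward.D2")
  z <- scale(lx)   # per-lipid z-scores of the log concentrations
  phy <- ape::as.phylo(hc)
  nwk <- ape::write.tree(phy)
  if (!is.null(newick_path)) writeLines(nwk, newick_path)
  list(hclust = hc, zscores = z, newick = nwk)
}

#' Per-lipid inference table for a two-group comparison
#'
#' For every lipid: Hodges-Lehmann fold change (case over reference),
#' Mann-Whitney (unpaired) or Wilcoxon signed-rank (paired) p, BH q across
#' the panel, rank-biserial effect size, and presence counts.
#'
#' @param conc Samples x lipids concentration matrix (positive values).
#' @param groups Two-level labels per row; `case_level` is the numerator
#'   of the fold change.
#' @param case_level,ref_level Labels of the case and reference group.
#' @param paired If TRUE rows must be aligned pairs (all `ref_level` rows
#'   matching `case_level` rows in subject order).
#' @param comparison Free-text tag stored in the table.
#' @param presence Optional logical matrix of raw-intensity presence for
#'   the presence counts; defaults to all-present (post-imputation data).
#' @return Data frame of class `stat_table`, one row per lipid, with
#'   volcano-ready `log2_fc` and `neglog10_q` columns.
#' @export
stat_table <- function(conc, groups, case_level = "T", ref_level = "N",
                       paired = FALSE, comparison = paste(case_level, "vs", ref_level),
                       presence = NULL) {
  groups <- as.character(groups)
  it <- groups == case_level; in_ <- groups == ref_level
  stopifnot(any(it), any(in_))
  rows <- lapply(colnames(conc), function(l) {
    xt <- conc[it, l]; xn <- conc[in_, l]
    fc <- hl_fold_change(xt, xn, paired = paired)
    if (paired) {
      tst <- wilcoxon_signed_rank(xt - xn)
      test_name <- "wilcoxon_signed_rank"
    } else {
      tst <- mann_whitney(xt, xn)
      test_name <- "mann_whitney"
    }
    pr <- if (is.null(presence)) NULL else presence[, l]
    data.frame(
      lipid = l, comparison = comparison,
      fold_change = fc, p_raw = tst$p, q_fdr = NA_real_,
      effect_size = rank_biserial(xt, xn),
      n_present_case = if (is.null(pr)) sum(it) else sum(pr[it]),
      n_total_case = sum(it),
      n_present_ref = if (is.null(pr)) sum(in_) else sum(pr[in_]),
      n_total_ref = sum(in_),
      test_name = test_name, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$q_fdr <- bh_fdr(out$p_raw)
  out$log2_fc <- log2(out$fold_change)
  out$neglog10_q <- -log10(pmax(out$q_fdr, .Machine$double.xmin))
  class(out) <- c("stat_table", "data.frame")
  out
}

#' Multi-group (stage-bracket) inference table
#'
#' Kruskal-Wallis across the given groups per lipid with epsilon-squared
#' and BH-FDR; lipids passing the gate get Conover post hoc pairwise
#' adjusted p values.
#'
#' @param conc Samples x lipids concentration matrix.
#' @param groups Labels with >= 2 levels (e.g. N / T1-2 / T3-4).
#' @param gate_q Run the post hoc only when the Kruskal-Wallis BH q is
#'   below this (default 0.05).
#' @return List with `table` (lipid, H, p, q, epsilon_sq) and `posthoc`
#'   (named list of Conover results for gated lipids).
#' @export
stage_table <- function(conc, groups, gate_q = 0.05) {
  groups <- as.character(groups)
  lv <- unique(groups)
  rows <- lapply(colnames(conc), function(l) {
    g <- split(conc[, l], factor(groups, lv))
    kw <- kruskal_wallis(g)
    data.frame(lipid = l, H = kw$H, p_raw = kw$p, q_fdr = NA_real_,
               epsilon_sq = kw$epsilon_sq, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q_fdr <- bh_fdr(tab$p_raw)
  post <- list()
  for (i in which(tab$q_fdr < gate_q)) {
    l <- tab$lipid[i]
    post[[l]] <- conover_posthoc(split(conc[, l], factor(groups, lv)))
  }
  list(table = tab, posthoc = post)
}

#' Significance grading stars from effect size and FDR
#'
#' Artifact convention for figure annotation: `***` when q below `q_max`
#' and |r| at least `large`, `**`/`*` at the medium/small bounds, empty
#' otherwise.
#'
#' @param effect_size Rank-biserial r values.
#' @param q BH q values.
#' @param large,medium,small |r| thresholds (defaults 0.5 / 0.3 / 0.1).
#' @param q_max FDR gate (default 0.05).
#' @return Character vector of star gradings.
#' @export
significance_stars <- function(effect_size, q, large = 0.5, medium = 0.3,
                               small = 0.1, q_max = 0.05) {
  r <- abs(effect_size)
  out <- rep("", length(r))
  sig <- !is.na(q) & q < q_max
  out[sig & r >= small] <- "*"
  out[sig & r >= medium] <- "**"
  out[sig & r >= large] <- "***"
  out
}
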