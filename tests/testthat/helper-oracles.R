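# Independent brute-force oracles used across the suite. These never call
# the package functions they check.

# masses re-stated independently of the package's table
ORACLE_MASS <- c(C = 12, H = 1.00782503, N = 14.0030740, O = 15.9949146,
                 P = 30.9737615, S = 31.9720707)
ORACLE_ELECTRON <- 0.00054858

oracle_formula_mass <- function(counts) {
  s <- 0
  for (el in names(counts)) s <- s + ORACLE_MASS[[el]] * counts[[el]]
  s
}

oracle_anion_mz <- function(counts, remove) {
  oracle_formula_mass(counts) - oracle_formula_mass(remove) + ORACLE_ELECTRON
}

# median of all pairwise ratios by explicit double loop
oracle_hl_fc <- function(x_t, x_n) {
  r <- numeric(0)
  for (a in x_t) for (b in x_n) r <- c(r, a / b)
  sort(r)
  stats::median(r)
}

# AUC by explicit pair counting, ties as 1/2
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  wins <- 0
  for (a in pos) for (b in neg)
    wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(pos) * length(neg))
}

# exact two-sided Mann-Whitney p by enumeration of all rank assignments
oracle_mw_exact_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  ranks <- seq_len(nx + ny)
  us <- apply(combos, 2, function(idx) sum(ranks[idx]) - nx * (nx + 1) / 2)
  if (u_obs <= nx * ny / 2) p <- 2 * mean(us <= u_obs)
  else p <- 2 * mean(us >= u_obs)
  min(p, 1)
}

# exact two-sided signed-rank p by enumeration of all sign patterns
oracle_signrank_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- drop(signs %*% r)
  if (v_obs <= n * (n + 1) / 4) p <- 2 * mean(vs <= v_obs)
  else p <- 2 * mean(vs >= v_obs)
  min(p, 1)
}

# two-sided Fisher exact p by hypergeometric enumeration: sum of the
# probabilities of all tables (same margins) no more likely than observed
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c; n_ <- b + d; k <- a + b
  lo <- max(0, k - n_); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# naive O(n^3) Ward agglomeration: Lance-Williams on squared Euclidean
# distances, merge height = sqrt of the Ward criterion (ward.D2 convention)
oracle_ward <- function(x) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  active <- seq_len(n)
  members <- as.list(seq_len(n))
  sizes <- rep(1, n)
  merges <- list()
  heights <- numeric(0)
  cl_id <- -seq_len(n)  # hclust convention: negatives = singletons
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bestv <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      i <- active[ii]; j <- active[jj]
      if (d2[i, j] < bestv) { bestv <- d2[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- sqrt(bestv)
    merges[[step]] <- sort(c(members[[i]], members[[j]]))
    for (k in setdiff(active, c(i, j))) {
      d2[i, k] <- d2[k, i] <-
        ((sizes[i] + sizes[k]) * d2[i, k] + (sizes[j] + sizes[k]) * d2[j, k] -
           sizes[k] * d2[i, j]) / (sizes[i] + sizes[j] + sizes[k])
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  list(merges = merges, heights = heights)
}

# member sets at each hclust merge, for comparison with oracle_ward
hclust_merge_sets <- function(hc) {
  n <- length(hc$order)
  sets <- list()
  for (step in seq_len(n - 1)) {
    grab <- function(v) if (v < 0) -v else sets[[v]]
    sets[[step]] <- sort(c(grab(hc$merge[step, 1]), grab(hc$merge[step, 2])))
  }
  sets
}

# small synthetic cohorts used by several files
tiny_cfg <- function(seed = 5, matrix = "plasma", n_n = 30, n_t = 30, ...) {
  generator_config(seed = seed, matrix = matrix, n_controls = n_n,
                   n_cases = n_t, qc_n = 4, decoy_peaks = 3, ...)
}
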