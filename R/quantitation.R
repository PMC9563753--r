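#' Quantitation configuration
#'
#' Bundles the inclusion-criteria thresholds and internal-standard
#' declarations used by the filtering and normalization steps.
#'
#' @param presence_min_fraction Minimum fraction of samples per group in
#'   which a lipid must be present (intensity above the floor) to be kept;
#'   the bound is inclusive. Default 0.5.
#' @param qc_cv_max Maximum coefficient of variation of raw QC intensities;
#'   the bound is exclusive. Default 0.35.
#' @param floor_intensity Lowest reproducible intensity; zero / sub-LOQ
#'   values are floor-imputed to it. Default 8000.
#' @param subject_exclusion_fraction A sample is excluded when MORE than
#'   this fraction of panel lipids is below LOQ. Default 0.5.
#' @param is_declarations Named numeric vector: internal-standard channel
#'   name -> spiked amount in nmol per mL.
#' @param is_class_map Named character vector: lipid class -> IS channel
#'   name used for molar normalization of that class.
#' @return A list of class `quant_config`.
#' @export
quant_config <- function(presence_min_fraction = 0.5,
                         qc_cv_max = 0.35,
                         floor_intensity = 8000,
                         subject_exclusion_fraction = 0.5,
                         is_declarations = numeric(0),
                         is_class_map = character(0)) {
  stopifnot(presence_min_fraction > 0, presence_min_fraction <= 1,
            subject_exclusion_fraction > 0, subject_exclusion_fraction <= 1,
            qc_cv_max > 0, floor_intensity > 0)
  structure(list(presence_min_fraction = presence_min_fraction,
                 qc_cv_max = qc_cv_max,
                 floor_intensity = floor_intensity,
                 subject_exclusion_fraction = subject_exclusion_fraction,
                 is_declarations = is_declarations,
                 is_class_map = is_class_map),
            class = "quant_config")
}

panel_columns <- function(m) setdiff(colnames(m$intensity), m$is_channels)

#' Inclusion criterion 1: presence in at least half of each group
#'
#' A lipid is retained iff its presence fraction (intensity above the floor)
#' is at least `presence_min_fraction` in the control group AND in the case
#' group. Internal-standard channels are exempt.
#'
#' @param m An `intensity_matrix`.
#' @param groups Character/factor vector over rows of `m` with two levels
#'   (e.g. "N"/"T").
#' @param cfg A [quant_config()].
#' @return Character vector of retained lipid names.
#' @export
filter_presence <- function(m, groups, cfg = quant_config()) {
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(m$intensity))
  lv <- unique(groups)
  if (length(lv) != 2L) stop("presence filter needs exactly two groups")
  if (any(table(factor(groups, lv)) == 0L)) stop("empty group")
  lipids <- panel_columns(m)
  present <- m$intensity[, lipids, drop = FALSE] > cfg$floor_intensity
  keep <- vapply(lipids, function(l) {
    all(vapply(lv, function(g)
      mean(present[groups == g, l]) >= cfg$presence_min_fraction,
      logical(1)))
  }, logical(1))
  lipids[keep]
}

#' Inclusion criterion 2: QC coefficient of variation below 35%
#'
#' CV = sd/mean of the raw (unimputed) QC intensities, sample sd with n-1
#' denominator. Lipids with zero QC mean are dropped with a message.
#'
#' @param m An `intensity_matrix` containing the QC rows.
#' @param qc_sample_ids Row names of the pooled-QC samples (at least 3).
#' @param cfg A [quant_config()].
#' @return Character vector of retained lipid names.
#' @export
filter_qc_cv <- function(m, qc_sample_ids, cfg = quant_config()) {
  qc_sample_ids <- intersect(qc_sample_ids, rownames(m$intensity))
  if (length(qc_sample_ids) < 3L) stop("need at least 3 QC samples")
  lipids <- panel_columns(m)
  q <- m$intensity[qc_sample_ids, lipids, drop = FALSE]
  mu <- colMeans(q)
  keep <- rep(FALSE, length(lipids))
  for (i in seq_along(lipids)) {
    if (mu[i] == 0) {
      message("QC mean 0 for ", lipids[i], "; dropped")
      next
    }
    keep[i] <- stats::sd(q[, i]) / mu[i] < cfg$qc_cv_max
  }
  lipids[keep]
}

#' Inclusion criterion 3: subject exclusion on censored panels or lost IS
#'
#' A sample is excluded when strictly more than
#' `subject_exclusion_fraction` of the panel lipids lie below LOQ, or when
#' any internal-standard channel falls below LOQ (high matrix effect).
#'
#' @param m An `intensity_matrix` with at least one IS channel.
#' @param cfg A [quant_config()].
#' @param lipids Panel lipids to assess (default all non-IS columns).
#' @return List with `keep` (retained sample ids) and `excluded` (data
#'   frame of sample id + reason code `low_panel` / `is_below_loq`).
#' @export
exclude_subjects <- function(m, cfg = quant_config(), lipids = panel_columns(m)) {
  if (!length(m$is_channels)) stop("intensity matrix has no IS channel")
  x <- m$intensity[, lipids, drop = FALSE]
  frac_below <- rowMeans(x < m$loq)
  is_low <- apply(m$intensity[, m$is_channels, drop = FALSE] < m$loq, 1, any)
  out <- character(0); reason <- character(0)
  drop <- frac_below > cfg$subject_exclusion_fraction | is_low
  for (i in which(drop)) {
    out <- c(out, rownames(m$intensity)[i])
    reason <- c(reason, if (frac_below[i] > cfg$subject_exclusion_fraction)
      "low_panel" else "is_below_loq")
  }
  list(keep = setdiff(rownames(m$intensity), out),
       excluded = data.frame(sample_id = out, reason = reason,
                             stringsAsFactors = FALSE))
}

#' Floor imputation of zero / sub-LOQ intensities
#'
#' Every cell below the LOQ (including unassigned zeros) is replaced by the
#' floor intensity (8000, the lowest reproducible signal). Idempotent.
#'
#' @param m An `intensity_matrix`.
#' @param cfg A [quant_config()].
#' @return The imputed `intensity_matrix` (mask preserved via the original
#'   `loq`-based mask stored in attribute `imputed`).
#' @export
impute_floor <- function(m, cfg = quant_config()) {
  mask <- m$intensity < m$loq
  m$intensity[mask] <- cfg$floor_intensity
  attr(m, "imputed") <- TRUE
  m$imputed_mask <- mask
  m
}

#' Molar concentrations via internal-standard normalization
#'
#' conc = intensity / intensity(IS of the lipid's class) x spiked amount
#' (nmol/mL).
#'
#' @param m A floor-imputed `intensity_matrix`.
#' @param cfg A [quant_config()] with `is_declarations` and `is_class_map`.
#' @return Samples x lipids matrix of nmol/mL concentrations (class
#'   `concentration_matrix`, mode "molar").
#' @export
to_molar <- function(m, cfg) {
  lipids <- panel_columns(m)
  out <- matrix(NA_real_, nrow(m$intensity), length(lipids),
                dimnames = list(rownames(m$intensity), lipids))
  for (l in lipids) {
    cls <- m$class_map[[l]]
    is_name <- if (cls %in% names(cfg$is_class_map))
      cfg$is_class_map[[cls]] else NA_character_
    if (is.na(is_name))
      stop("no internal standard declared for class ", cls)
    amount <- cfg$is_declarations[[is_name]]
    out[, l] <- m$intensity[, l] / m$intensity[, is_name] * amount
  }
  structure(out, mode = "molar", class_map = m$class_map[lipids],
            class = c("concentration_matrix", "matrix", "array"))
}

#' Relative concentrations as percent within lipid class
#'
#' Each intensity is divided by the per-sample sum of all panel lipids of
#' the same class and multiplied by 100; IS channels never enter class sums.
#' Per sample and class the values sum to exactly 100.
#'
#' @param m A floor-imputed `intensity_matrix`.
#' @param lipids Lipids to include (default all non-IS columns).
#' @return Samples x lipids percent matrix (class `concentration_matrix`,
#'   mode "relative").
#' @export
relative_within_class <- function(m, lipids = panel_columns(m)) {
  x <- m$intensity[, lipids, drop = FALSE]
  cls <- m$class_map[lipids]
  if (any(is.na(cls) | !nzchar(cls)))
    stop("lipid(s) without class mapping: ",
         paste(lipids[is.na(cls) | !nzchar(cls)], collapse = ", "))
  out <- x
  for (cl in unique(cls)) {
    cols <- which(cls == cl)
    s <- rowSums(x[, cols, drop = FALSE])
    if (any(s <= 0)) stop("nonpositive class sum for class ", cl,
                          " (run impute_floor first)")
    out[, cols] <- 100 * x[, cols, drop = FALSE] / s
  }
  structure(out, mode = "relative", class_map = cls,
            class = c("concentration_matrix", "matrix", "array"))
}

#' Run the full quantitation flow in the published order
#'
#' presence filter -> QC-CV filter -> subject exclusion -> floor imputation
#' -> relative (and optionally molar) concentrations. QC rows are used for
#' criterion 2 and then dropped from the outputs.
#'
#' @param m An `intensity_matrix` containing cohort and QC rows.
#' @param groups Named group labels ("N"/"T") for the cohort rows (names =
#'   sample ids).
#' @param qc_sample_ids Row names of the QC samples.
#' @param cfg A [quant_config()].
#' @param molar Also compute molar concentrations (needs IS declarations).
#' @return List with `relative`, optionally `molar`, `retained_lipids`,
#'   `kept_samples`, `excluded` (exclusion report), `groups` (labels of the
#'   kept samples).
#' @export
quantify <- function(m, groups, qc_sample_ids, cfg = quant_config(),
                     molar = FALSE) {
  cohort_ids <- setdiff(rownames(m$intensity), qc_sample_ids)
  if (is.null(names(groups))) names(groups) <- cohort_ids
  mc <- subset_matrix(m, cohort_ids)

  keep1 <- filter_presence(mc, groups[cohort_ids], cfg)
  keep2 <- filter_qc_cv(m, qc_sample_ids, cfg)
  retained <- intersect(keep1, keep2)
  if (!length(retained)) stop("no lipid passes the inclusion criteria")

  excl <- exclude_subjects(mc, cfg, lipids = retained)
  mk <- subset_matrix(mc, excl$keep)
  mk <- impute_floor(mk, cfg)

  res <- list(
    relative = relative_within_class(mk, retained),
    retained_lipids = retained,
    kept_samples = excl$keep,
    excluded = excl$excluded,
    groups = groups[excl$keep]
  )
  if (molar) {
    mm <- mk; mm$intensity <- mm$intensity[, c(retained, m$is_channels), drop = FALSE]
    res$molar <- to_molar(mm, cfg)[, retained, drop = FALSE]
  }
  res
}

subset_matrix <- function(m, sample_ids) {
  m$intensity <- m$intensity[sample_ids, , drop = FALSE]
  m
}
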