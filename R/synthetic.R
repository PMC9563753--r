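#' Quantitation class grouping of a lipid class
#'
#' Relative percentages and IS normalization group the two sulfatide
#' classes (mono- and dihexosyl) into one "sulfatide" class; SM and StS
#' stand alone.
#' @param lipid_class Character vector of lipid classes.
#' @return Character vector of quantitation classes.
#' @export
quant_class <- function(lipid_class) {
  ifelse(lipid_class %in% c("SHexCer", "SHex2Cer"), "sulfatide", lipid_class)
}

#' Default lipid panel for a sample matrix
#'
#' Plasma: 16 SM and 17 SHexCer quantified channels plus the low-abundance
#' SHex2Cer 42:2;O2 presence channel and two internal standards
#' (SHexCer 18:1;O2/12:0 at 0.1 nmol/mL, SM 18:1;O2/12:0 at 43.3 nmol/mL).
#' Urine: 18 SHexCer, 4 SHex2Cer and 11 sterol-sulfate channels (StS
#' compositions are unpublished, so their m/z values are synthetic
#' placeholders spaced > 50 ppm apart) plus SHexCer IS (0.04 nmol/mL) and
#' deuterated taurocholic acid (0.55 nmol/mL, supplied m/z). Tissue: the
#' plasma sphingolipid channels plus four SHex2Cer channels and the
#' SHexCer IS. Baseline medians and log-sds define the log-normal
#' between-subject intensity model.
#'
#' @param matrix One of "plasma", "urine", "tissue".
#' @return Data frame with columns `name`, `class`, `mz` (NA where derived
#'   from the formula), `baseline_median`, `sdlog`, `is_channel`,
#'   `spiked_nmol_ml`.
#' @export
default_panel <- function(matrix = c("plasma", "urine", "tissue")) {
  matrix <- match.arg(matrix)
  sm <- paste0("SM ", c("32:1", "33:1", "34:1", "34:2", "35:1", "36:0",
                        "36:1", "36:2", "38:1", "39:1", "40:1", "41:1",
                        "41:2", "42:1", "42:2", "42:3"), ";O2")
  shex <- c(paste0("SHexCer ", c("34:1", "36:1", "38:1", "40:1", "42:1",
                                 "42:2", "42:3"), ";O2"),
            paste0("SHexCer ", c("34:1", "36:1", "40:1", "41:1", "42:1",
                                 "42:2", "42:3", "43:1", "44:1"), ";O3"),
            "SHexCer 40:1;O4")
  shex2_urine <- paste0("SHex2Cer ", c("34:1", "40:1", "42:1", "42:2"), ";O2")
  sts <- data.frame(
    name = paste("StS", 1:11),
    class = "StS",
    mz = c(433.2986, 447.3142, 463.3091, 465.3247, 467.3040, 481.3196,
           483.3353, 497.3145, 499.3302, 511.3302, 513.3458),
    stringsAsFactors = FALSE
  )
  row <- function(name, class = NA, mz = NA, baseline, sdlog = 0.5,
                  is_channel = FALSE, spiked = NA)
    data.frame(name = name, class = class, mz = mz,
               baseline_median = baseline, sdlog = sdlog,
               is_channel = is_channel, spiked_nmol_ml = spiked,
               stringsAsFactors = FALSE)
  # deterministic baseline ladder: abundant SM, mid-range SHexCer,
  # low-abundance SHex2Cer
  ladder <- function(names, lo, hi) {
    b <- 10^seq(log10(lo), log10(hi), length.out = length(names))
    # interleave so that neighboring masses differ in abundance
    b[order(order(rank(names)))]
  }
  if (matrix == "plasma") {
    p <- rbind(
      row(sm, baseline = ladder(sm, 2e5, 5e6)),
      row(shex, baseline = ladder(shex, 5e4, 1.2e6)),
      row("SHex2Cer 42:2;O2", baseline = 2500),
      row("SHexCer 18:1;O2/12:0", baseline = 4e5, sdlog = 0,
          is_channel = TRUE, spiked = 0.1),
      row("SM 18:1;O2/12:0", baseline = 3e6, sdlog = 0,
          is_channel = TRUE, spiked = 43.3)
    )
  } else if (matrix == "urine") {
    shex18 <- c(shex, "SHexCer 38:1;O3")
    p <- rbind(
      row(shex18, baseline = ladder(shex18, 4e4, 8e5)),
      row(shex2_urine, baseline = ladder(shex2_urine, 2e4, 8e4)),
      row(sts$name, class = "StS", mz = sts$mz,
          baseline = ladder(sts$name, 5e4, 6e5)),
      row("SHexCer 18:1;O2/12:0", baseline = 3e5, sdlog = 0,
          is_channel = TRUE, spiked = 0.04),
      row("D4-taurocholic acid", class = "StS", mz = 518.3136,
          baseline = 6e5, sdlog = 0, is_channel = TRUE, spiked = 0.55)
    )
  } else {
    p <- rbind(
      row(sm[seq(1, 16, 2)], baseline = ladder(sm[seq(1, 16, 2)], 2e5, 3e6)),
      row(shex, baseline = ladder(shex, 6e4, 1.5e6)),
      row(shex2_urine, baseline = ladder(shex2_urine, 2e4, 1e5)),
      row("SHexCer 18:1;O2/12:0", baseline = 4e5, sdlog = 0,
          is_channel = TRUE, spiked = 0.1)
    )
  }
  rownames(p) <- NULL
  p
}

#' Default per-lipid dysregulation map
#'
#' Directions reproduce the dysregulation pattern the analysis targets:
#' long-chain SM and hydroxylated sulfatides (;O3/;O4) down in cases,
#' polyunsaturated SHexCer and lactosylsulfatides (SHex2Cer) up; in urine
#' additionally two cortisol-like StS channels up and two lithocholic-like
#' StS channels down. Magnitudes are generator defaults: the late-stage
#' (T3-4) multiplier is 2.0 (up) or 0.5 (down) and the early-stage (T1-2)
#' multiplier is its square root, emulating the gradual stage trend.
#'
#' @param matrix One of "plasma", "urine", "tissue".
#' @param up_t34,down_t34 Late-stage multipliers for up-/downregulated
#'   channels (defaults 2.0 and 0.5).
#' @return Data frame `lipid`, `direction` (up/down/null), `mult_t12`,
#'   `mult_t34` covering every non-IS panel channel.
#' @export
default_effect_map <- function(matrix = c("plasma", "urine", "tissue"),
                               up_t34 = 2.0, down_t34 = 0.5) {
  matrix <- match.arg(matrix)
  panel <- default_panel(matrix)
  lipids <- panel$name[!panel$is_channel]
  down <- up <- character(0)
  if (matrix == "plasma") {
    down <- c(paste0("SM ", c("41:1", "40:1", "39:1", "38:1", "33:1", "32:1"), ";O2"),
              paste0("SHexCer ", c("40:1;O3", "41:1;O3", "42:1;O3",
                                   "40:1;O2", "40:1;O4")))
    up <- c("SHexCer 42:3;O2", "SHexCer 42:3;O3", "SHexCer 42:2;O2",
            "SHex2Cer 42:2;O2")
  } else if (matrix == "urine") {
    down <- c(lipids[grepl("^SHexCer .*;O[34]$", lipids)], "StS 8", "StS 11")
    up <- c(lipids[grepl("^SHex2Cer", lipids)], "StS 3", "StS 4")
  } else {
    down <- c("SM 41:1;O2", lipids[grepl("^SHexCer .*;O[34]$", lipids)])
    up <- c("SHexCer 42:2;O2", "SHexCer 42:3;O2",
            lipids[grepl("^SHex2Cer", lipids)])
  }
  down <- intersect(down, lipids); up <- intersect(up, lipids)
  dir <- rep("null", length(lipids))
  dir[lipids %in% down] <- "down"
  dir[lipids %in% up] <- "up"
  m34 <- ifelse(dir == "up", up_t34, ifelse(dir == "down", down_t34, 1))
  data.frame(lipid = lipids, direction = dir,
             mult_t12 = sqrt(m34), mult_t34 = m34,
             stringsAsFactors = FALSE)
}

#' Generator configuration for a synthetic cohort
#'
#' Defaults mirror the cohort the analysis assumes: 207 controls / 143
#' cases for plasma, 70 / 100 pre-exclusion for urine (with 3 control and
#' 24 case subjects designated low-signal for criterion-3 exclusion), and
#' 77 tumor/nontumor pairs for tissue. Five replicate depositions per
#' sample at 10% replicate CV, pooled QC samples at 15% CV, LOQ 8000,
#' 2 ppm mass jitter.
#'
#' @param seed RNG seed (all outputs are deterministic given seed+config).
#' @param matrix "plasma", "urine" or "tissue".
#' @param n_controls,n_cases Cohort sizes (tissue: `n_cases` pairs).
#' @param stage_probs Stage distribution over T1..T4 for cases.
#' @param panel Panel data frame as from [default_panel()].
#' @param effect_map Data frame as from [default_effect_map()].
#' @param replicate_cv Multiplicative CV of replicate depositions.
#' @param qc_n,qc_cv Number of pooled QC samples and their CV.
#' @param loq Limit of quantitation (raw intensity).
#' @param low_signal_n Named counts `c(N = ..., T = ...)` of subjects
#'   designated low-signal (criterion-3 exclusion ground truth).
#' @param missing_bmi_fraction Fraction of subjects with missing BMI.
#' @param ppm_jitter Mass jitter half-width in ppm for emitted peaks.
#' @param decoy_peaks Unassignable decoy peaks per replicate spectrum.
#' @param pair_sdlog Tissue only: sd of the shared per-subject log effect
#'   inducing the paired correlation.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             matrix = c("plasma", "urine", "tissue"),
                             n_controls = NULL, n_cases = NULL,
                             stage_probs = c(T1 = 0.45, T2 = 0.12,
                                             T3 = 0.35, T4 = 0.08),
                             panel = NULL, effect_map = NULL,
                             replicate_cv = 0.10,
                             qc_n = 8, qc_cv = 0.15,
                             loq = 8000,
                             low_signal_n = NULL,
                             missing_bmi_fraction = 0.10,
                             ppm_jitter = 2,
                             decoy_peaks = 20,
                             pair_sdlog = 0.4) {
  matrix <- match.arg(matrix)
  defaults <- list(
    plasma = list(n = c(207L, 143L), low = c(N = 0L, T = 0L)),
    urine  = list(n = c(70L, 100L),  low = c(N = 3L, T = 24L)),
    tissue = list(n = c(0L, 77L),    low = c(N = 0L, T = 0L))
  )[[matrix]]
  if (is.null(n_controls)) n_controls <- defaults$n[1]
  if (is.null(n_cases)) n_cases <- defaults$n[2]
  if (is.null(low_signal_n)) low_signal_n <- defaults$low
  if (is.null(panel)) panel <- default_panel(matrix)
  if (is.null(effect_map)) effect_map <- default_effect_map(matrix)
  stopifnot(n_controls >= 0, n_cases >= 0, all(stage_probs >= 0),
            replicate_cv >= 0, qc_cv >= 0, ppm_jitter >= 0,
            all(effect_map$mult_t12 > 0), all(effect_map$mult_t34 > 0))
  structure(list(seed = as.integer(seed), matrix = matrix,
                 n_controls = n_controls, n_cases = n_cases,
                 stage_probs = stage_probs / sum(stage_probs),
                 panel = panel, effect_map = effect_map,
                 replicate_cv = replicate_cv, qc_n = qc_n, qc_cv = qc_cv,
                 loq = loq, low_signal_n = low_signal_n,
                 missing_bmi_fraction = missing_bmi_fraction,
                 ppm_jitter = ppm_jitter, decoy_peaks = decoy_peaks,
                 pair_sdlog = pair_sdlog),
            class = "generator_config")
}

#' Generate subject metadata for a synthetic cohort
#'
#' Cases skew older and more often male than controls (mirroring the
#' epidemiology the analysis adjusts for); BMI is near-identical between
#' groups with a small case shift; a configured fraction of BMI values is
#' missing. Tissue mode emits one tumor and one nontumor row per subject.
#'
#' @param cfg A [generator_config()].
#' @return List with `cohort` (data frame: sample_id, subject_id, group,
#'   matrix, gender, age, bmi, stage, grade, tissue_type, low_signal) and
#'   `truth` (effect map, designated low-signal ids, seed).
#' @export
generate_cohort <- function(cfg) {
  set.seed(cfg$seed)
  n_n <- cfg$n_controls; n_t <- cfg$n_cases
  subj <- function(group, i) sprintf("%s%03d", group, i)
  ids <- c(vapply(seq_len(n_n), function(i) subj("N", i), character(1)),
           vapply(seq_len(n_t), function(i) subj("T", i), character(1)))
  group <- c(rep("N", n_n), rep("T", n_t))
  gender <- ifelse(stats::runif(n_n + n_t) <
                     ifelse(group == "T", 0.67, 0.45), "M", "F")
  age <- round(ifelse(group == "T", stats::rnorm(n_n + n_t, 63, 10),
                      stats::rnorm(n_n + n_t, 48, 12)))
  age <- pmin(pmax(age, 20), 90)
  bmi <- round(stats::rnorm(n_n + n_t, ifelse(group == "T", 28.3, 27.2), 4.3), 1)
  bmi <- pmax(bmi, 16)
  bmi[stats::runif(n_n + n_t) < cfg$missing_bmi_fraction] <- NA
  stage <- rep(NA_character_, n_n + n_t)
  stage[group == "T"] <- sample(names(cfg$stage_probs), n_t, replace = TRUE,
                                prob = cfg$stage_probs)
  grade <- rep(NA_character_, n_n + n_t)
  grade[group == "T"] <- sample(paste0("G", 1:4), n_t, replace = TRUE,
                                prob = c(0.15, 0.45, 0.30, 0.10))
  low <- rep(FALSE, n_n + n_t)
  for (g in c("N", "T")) {
    k <- cfg$low_signal_n[[g]]
    if (k > 0) low[sample(which(group == g), k)] <- TRUE
  }
  cohort <- data.frame(subject_id = ids, group = group, matrix = cfg$matrix,
                       gender = gender, age = age, bmi = bmi,
                       stage = stage, grade = grade, low_signal = low,
                       stringsAsFactors = FALSE)
  if (cfg$matrix == "tissue") {
    cases <- cohort[cohort$group == "T", , drop = FALSE]
    cohort <- rbind(
      transform(cases, tissue_type = "nontumor",
                sample_id = paste0(subject_id, "_NT")),
      transform(cases, tissue_type = "tumor",
                sample_id = paste0(subject_id, "_TU"))
    )
    cohort <- cohort[order(cohort$subject_id, cohort$tissue_type), ]
  } else {
    cohort$tissue_type <- NA_character_
    cohort$sample_id <- cohort$subject_id
  }
  rownames(cohort) <- NULL
  list(cohort = cohort,
       truth = list(effect_map = cfg$effect_map,
                    low_signal_ids = cohort$sample_id[cohort$low_signal],
                    seed = cfg$seed))
}

cv_to_sdlog <- function(cv) sqrt(log1p(cv^2))

stage_bracket <- function(stage) {
  ifelse(is.na(stage), NA_character_,
         ifelse(stage %in% c("T1", "T2"), "T1-2", "T3-4"))
}

#' Generate per-sample intensities (and replicate depositions)
#'
#' Each lipid's subject-level intensity is log-normal around the panel
#' baseline, multiplied for cases by the stage-bracket effect multiplier
#' (T3-4 farther from 1 than T1-2). Five replicate depositions add
#' multiplicative noise at the replicate CV; the per-sample value is the
#' replicate median with sub-LOQ replicates counted as 0. Designated
#' low-signal samples are globally attenuated (strong matrix effect) so
#' that most channels censor. IS channels are spiked at fixed abundance;
#' pooled QC samples are drawn around the panel baseline at the QC CV.
#' Tissue pairs share a per-subject log-normal effect.
#'
#' @param cohort_obj Result of [generate_cohort()].
#' @param cfg The same [generator_config()].
#' @param keep_replicates Keep the replicate array (needed for peak-list
#'   emission).
#' @return List with `matrix` (an [intensity_matrix()] over cohort + QC
#'   rows), `replicates` (samples x lipids x 5 array, pre-censoring, when
#'   requested), `qc_ids`, and `truth` (augmented with per-sample
#'   multipliers).
#' @export
generate_intensities <- function(cohort_obj, cfg, keep_replicates = FALSE) {
  cohort <- cohort_obj$cohort   # force before seeding (lazy evaluation)
  set.seed(cfg$seed + 1L)
  panel <- cfg$panel
  if (any(is.na(panel$mz) & !grepl("^(SM|SHexCer|SHex2Cer) ", panel$name)))
    stop("panel lipid without formula rule and without explicit m/z")
  n <- nrow(cohort)
  L <- nrow(panel)
  lipids <- panel$name
  emap <- cfg$effect_map
  mult <- matrix(1, n, L, dimnames = list(cohort$sample_id, lipids))
  br <- stage_bracket(cohort$stage)
  for (j in seq_len(L)) {
    k <- match(lipids[j], emap$lipid)
    if (is.na(k)) next
    is_case <- cohort$group == "T" &
      (is.na(cohort$tissue_type) | cohort$tissue_type == "tumor")
    mult[is_case & br == "T1-2", j] <- emap$mult_t12[k]
    mult[is_case & br == "T3-4", j] <- emap$mult_t34[k]
  }
  base <- matrix(rep(panel$baseline_median, each = n), n, L)
  sdl <- matrix(rep(panel$sdlog, each = n), n, L)
  subject_noise <- matrix(stats::rnorm(n * L), n, L) * sdl
  if (cfg$matrix == "tissue") {
    # shared per-subject effect induces the paired correlation
    eff <- stats::rnorm(length(unique(cohort$subject_id)), 0, cfg$pair_sdlog)
    names(eff) <- unique(cohort$subject_id)
    subject_noise <- subject_noise + eff[cohort$subject_id]
  }
  level <- base * exp(subject_noise) * mult
  level[cohort$low_signal, ] <- level[cohort$low_signal, , drop = FALSE] * 0.01
  # QC rows: pooled baseline at QC CV (IS included at fixed abundance)
  qc_ids <- if (cfg$qc_n > 0) sprintf("QC%02d", seq_len(cfg$qc_n)) else character(0)
  qc_level <- matrix(rep(panel$baseline_median, each = cfg$qc_n), cfg$qc_n, L) *
    exp(matrix(stats::rnorm(cfg$qc_n * L), cfg$qc_n, L) *
          cv_to_sdlog(cfg$qc_cv))
  all_level <- rbind(level, qc_level)
  rownames(all_level) <- c(cohort$sample_id, qc_ids)
  # five replicate depositions with multiplicative noise
  rep_sd <- cv_to_sdlog(cfg$replicate_cv)
  reps <- array(0, dim = c(nrow(all_level), L, 5),
                dimnames = list(rownames(all_level), lipids, NULL))
  for (r in 1:5)
    reps[, , r] <- all_level *
      exp(matrix(stats::rnorm(length(all_level)), nrow(all_level), L) * rep_sd)
  censored <- reps
  censored[censored < cfg$loq] <- 0
  med <- apply(censored, c(1, 2), stats::median)
  cmap <- stats::setNames(quant_class(ifelse(is.na(panel$class),
                                             sub(" .*$", "", panel$name),
                                             panel$class)), lipids)
  m <- intensity_matrix(med, loq = cfg$loq,
                        is_channels = panel$name[panel$is_channel],
                        class_map = cmap)
  truth <- cohort_obj$truth
  truth$multipliers <- mult
  list(matrix = m,
       replicates = if (keep_replicates) reps else NULL,
       qc_ids = qc_ids, truth = truth)
}

#' Emit replicate peak lists from a generated replicate array
#'
#' Each above-LOQ replicate intensity becomes one peak at the channel's
#' theoretical m/z perturbed by uniform jitter within +/- `ppm_jitter`;
#' sub-LOQ signals are not detected. Configurable decoy peaks are placed
#' at random m/z at least 50 ppm away from every channel. The `lipid`
#' column is the per-peak ground truth ("" for decoys).
#'
#' @param reps Replicate array from [generate_intensities()].
#' @param db Annotation database for the same panel (source of ion m/z).
#' @param cfg The [generator_config()].
#' @return `peak_data` frame with columns sample_id, replicate_id, mz,
#'   intensity, lipid.
#' @export
generate_peak_lists <- function(reps, db, cfg) {
  lipids <- dimnames(reps)[[2]]   # force before seeding (lazy evaluation)
  force(db)
  set.seed(cfg$seed + 2L)
  mz_theo <- db$ion_mz[match(lipids, db$name)]
  if (anyNA(mz_theo)) stop("panel channel missing from database: ",
                           paste(lipids[is.na(mz_theo)], collapse = ", "))
  samples <- dimnames(reps)[[1]]
  out <- vector("list", length(samples) * 5L)
  k <- 0L
  for (s in seq_along(samples)) for (r in 1:5) {
    inten <- reps[s, , r]
    hit <- inten >= cfg$loq
    mz <- mz_theo[hit] *
      (1 + stats::runif(sum(hit), -cfg$ppm_jitter, cfg$ppm_jitter) * 1e-6)
    lipid <- lipids[hit]
    if (cfg$decoy_peaks > 0) {
      dm <- numeric(0)
      while (length(dm) < cfg$decoy_peaks) {
        cand <- stats::runif(cfg$decoy_peaks, 400, 2000)
        far <- vapply(cand, function(x)
          all(abs(x - mz_theo) / mz_theo * 1e6 > 50), logical(1))
        dm <- c(dm, cand[far])
      }
      dm <- dm[seq_len(cfg$decoy_peaks)]
      mz <- c(mz, dm)
      inten_d <- stats::rlnorm(cfg$decoy_peaks, log(2e4), 1)
      lipid <- c(lipid, rep("", cfg$decoy_peaks))
      inten <- c(inten[hit], inten_d)
    } else inten <- inten[hit]
    k <- k + 1L
    ord <- order(mz)
    out[[k]] <- data.frame(sample_id = samples[s], replicate_id = r,
                           mz = mz[ord], intensity = inten[ord],
                           lipid = lipid[ord], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("peak_data", "data.frame")
  res
}

#' Annotation database for a generator panel
#' @param cfg A [generator_config()].
#' @param tolerance_ppm Matching window (default 5).
#' @return An [build_database()] annotation database.
#' @export
panel_database <- function(cfg, tolerance_ppm = 5) {
  build_database(cfg$panel[, c("name", "class", "mz")],
                 tolerance_ppm = tolerance_ppm,
                 is_names = cfg$panel$name[cfg$panel$is_channel])
}

#' Quantitation config matching a generator config
#' @param cfg A [generator_config()].
#' @return A [quant_config()] with the panel's IS declarations wired to
#'   the quantitation classes.
#' @export
quant_config_for <- function(cfg) {
  p <- cfg$panel
  isd <- stats::setNames(p$spiked_nmol_ml[p$is_channel], p$name[p$is_channel])
  cmap <- character(0)
  for (i in which(p$is_channel)) {
    cls <- quant_class(if (!is.na(p$class[i])) p$class[i]
                       else sub(" .*$", "", p$name[i]))
    cmap[cls] <- p$name[i]
  }
  if (!"sulfatide" %in% names(cmap) && any(grepl("^SHexCer", names(isd))))
    cmap["sulfatide"] <- grep("^SHexCer", names(isd), value = TRUE)[1]
  quant_config(floor_intensity = cfg$loq, is_declarations = isd,
               is_class_map = cmap)
}

#' Simulate a full study to delimited text files
#'
#' Writes cohort table, replicate peak lists, QC manifest, IS declarations
#' and ground-truth effect map under `dir`, each with the seed recorded in
#' a header comment. All outputs are byte-identical for a fixed
#' seed/config.
#'
#' @param cfg A [generator_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of written paths.
#' @export
simulate_study <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  co <- generate_cohort(cfg)
  gen <- generate_intensities(co, cfg, keep_replicates = TRUE)
  db <- panel_database(cfg)
  peaks <- generate_peak_lists(gen$replicates, db, cfg)
  w <- function(df, file) {
    path <- file.path(dir, file)
    con <- file(path, "w")
    writeLines(sprintf("# sphingodx synthetic study; seed=%d; matrix=%s",
                       cfg$seed, cfg$matrix), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    path
  }
  p <- cfg$panel
  paths <- c(
    w(co$cohort, "cohort.tsv"),
    w(peaks[, c("sample_id", "replicate_id", "mz", "intensity")], "peaks.tsv"),
    w(peaks, "peaks_truth.tsv"),
    w(data.frame(sample_id = gen$qc_ids), "qc_manifest.tsv"),
    w(p[p$is_channel, c("name", "spiked_nmol_ml")], "is_declarations.tsv"),
    w(cfg$effect_map, "effect_map.tsv")
  )
  invisible(paths)
}
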