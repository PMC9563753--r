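make_im <- function(values, loq = 8000, is_channels = character(0),
                    classes = NULL) {
  m <- as.matrix(values)
  if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  cm <- if (is.null(classes))
    setNames(rep("SM", ncol(m)), colnames(m)) else classes
  intensity_matrix(m, loq = loq, is_channels = is_channels, class_map = cm)
}

test_that("presence filter requires half of both groups, inclusively", {
  set.seed(3)
  n <- 20  # 20 N + 20 T
  groups <- rep(c("N", "T"), each = n)
  mk_col <- function(frac_n, frac_t) {
    c(ifelse(seq_len(n) <= frac_n * n, 50000, 0),
      ifelse(seq_len(n) <= frac_t * n, 50000, 0))
  }
  m <- make_im(cbind(a = mk_col(0.60, 0.55), b = mk_col(0.90, 0.40),
                     c = mk_col(0.50, 0.50), d = mk_col(0.45, 1.00)))
  kept <- filter_presence(m, groups, quant_config())
  expect_setequal(kept, c("a", "c"))
  expect_error(filter_presence(m, rep("N", 2 * n)), "two groups")
})

test_that("QC CV filter uses sd/mean on raw intensities with the 35% bound", {
  qc <- rbind(c(10000, 10000, 1000), c(11000, 10000, 10000),
              c(9000, 10000, 19000))
  colnames(qc) <- c("a", "b", "c")
  rownames(qc) <- paste0("QC", 1:3)
  m <- make_im(qc)
  expect_equal(sd(qc[, "a"]) / mean(qc[, "a"]), 0.1, tolerance = 1e-9)
  expect_equal(sd(qc[, "c"]) / mean(qc[, "c"]), 0.9, tolerance = 1e-9)
  kept <- filter_qc_cv(m, paste0("QC", 1:3), quant_config())
  expect_setequal(kept, c("a", "b"))  # CV 0.1 and 0 retained, 0.9 dropped
  expect_error(filter_qc_cv(m, paste0("QC", 1:2), quant_config()), "3 QC")
  # zero-mean channel dropped with a message
  qc0 <- cbind(qc, z = 0)
  expect_message(kept0 <- filter_qc_cv(make_im(qc0), paste0("QC", 1:3),
                                       quant_config()), "QC mean 0")
  expect_false("z" %in% kept0)
})

test_that("subject exclusion is disjunctive and strictly more-than-half", {
  vals <- rbind(
    S1 = c(rep(0, 6), rep(50000, 4), 50000),   # 60% of panel below -> out
    S2 = c(rep(50000, 10), 100),               # IS below LOQ -> out
    S3 = c(rep(0, 5), rep(50000, 5), 50000),   # exactly 50% below -> kept
    S4 = c(rep(50000, 10), 50000)              # clean
  )
  colnames(vals) <- c(paste0("L", 1:10), "IS")
  m <- make_im(vals, is_channels = "IS")
  res <- exclude_subjects(m, quant_config())
  expect_setequal(res$excluded$sample_id, c("S1", "S2"))
  expect_equal(res$excluded$reason[res$excluded$sample_id == "S1"], "low_panel")
  expect_equal(res$excluded$reason[res$excluded$sample_id == "S2"], "is_below_loq")
  expect_setequal(res$keep, c("S3", "S4"))
  expect_error(exclude_subjects(make_im(vals[, 1:10]), quant_config()),
               "no IS channel")
})

test_that("floor imputation replaces sub-LOQ cells with 8000 and is idempotent", {
  m <- make_im(rbind(c(0, 9500, 7999), c(12000, 0, 8001)))
  m1 <- impute_floor(m, quant_config())
  expect_equal(unname(m1$intensity[1, ]), c(8000, 9500, 8000))
  expect_equal(unname(m1$intensity[2, ]), c(12000, 8000, 8001))
  m2 <- impute_floor(m1, quant_config())
  expect_equal(m2$intensity, m1$intensity)
})

test_that("molar normalization scales by the class IS and its spiked amount", {
  vals <- cbind(a = c(4e5, 8e5), b = c(3e6, 6e6),
                shex_is = c(4e5, 4e5), sm_is = c(3e6, 3e6))
  m <- make_im(vals, is_channels = c("shex_is", "sm_is"),
               classes = c(a = "sulfatide", b = "SM",
                           shex_is = "sulfatide", sm_is = "SM"))
  cfg <- quant_config(
    is_declarations = c(shex_is = 0.1, sm_is = 43.3),
    is_class_map = c(sulfatide = "shex_is", SM = "sm_is"))
  conc <- to_molar(m, cfg)
  expect_equal(unname(conc[, "a"]), c(0.1, 0.2))    # ratio 1 and 2
  expect_equal(unname(conc[, "b"]), c(43.3, 86.6))
  cfg_bad <- quant_config(is_declarations = c(shex_is = 0.1),
                          is_class_map = c(sulfatide = "shex_is"))
  expect_error(to_molar(m, cfg_bad), "internal standard")
})

test_that("relative concentrations sum to 100 within class and exclude the IS", {
  vals <- cbind(a = c(8000, 100), b = c(8000, 100), c = c(16000, 200),
                x = c(500, 500), is1 = c(1e6, 1e6))
  m <- make_im(vals, is_channels = "is1",
               classes = c(a = "sulfatide", b = "sulfatide", c = "sulfatide",
                           x = "SM", is1 = "sulfatide"))
  rel <- relative_within_class(m)
  expect_equal(unname(rel[1, c("a", "b", "c")]), c(25, 25, 50))
  expect_equal(unname(rel[2, c("a", "b", "c")]), c(25, 25, 50))
  expect_equal(unname(rel[, "x"]), c(100, 100))  # single-lipid class
  sums <- rowSums(rel[, c("a", "b", "c")])
  expect_equal(unname(sums), c(100, 100), tolerance = 1e-9)
})

test_that("relative concentrations are invariant to per-sample global scaling", {
  set.seed(8)
  vals <- matrix(runif(5 * 6, 1e4, 1e6), 5, 6,
                 dimnames = list(paste0("S", 1:5), paste0("L", 1:6)))
  classes <- setNames(rep(c("SM", "sulfatide"), each = 3), colnames(vals))
  r1 <- relative_within_class(make_im(vals, classes = classes))
  scaled <- vals * matrix(runif(5, 0.1, 10), 5, 6)
  r2 <- relative_within_class(make_im(scaled, classes = classes))
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("the frozen quantitation flow is reproducible and flags designated subjects", {
  cfg <- generator_config(seed = 21, matrix = "urine", n_controls = 25,
                          n_cases = 25, qc_n = 4,
                          low_signal_n = c(N = 2, T = 3))
  co <- generate_cohort(cfg)
  gen <- generate_intensities(co, cfg)
  groups <- setNames(co$cohort$group, co$cohort$sample_id)
  q1 <- suppressMessages(quantify(gen$matrix, groups, gen$qc_ids,
                                  quant_config_for(cfg)))
  expect_setequal(q1$excluded$sample_id, gen$truth$low_signal_ids)
  # byte-identical rerun of the frozen pipeline
  gen2 <- generate_intensities(generate_cohort(cfg), cfg)
  q2 <- suppressMessages(quantify(gen2$matrix, groups, gen2$qc_ids,
                                  quant_config_for(cfg)))
  expect_identical(serialize(q1, NULL), serialize(q2, NULL))
})
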