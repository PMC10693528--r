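# hand-built one-metabolite table with controllable metrics
qc_fixture <- function(n_study = 60, n_missing = 0, study_value = 100,
                       blank_value = 5, slope_sign = 1, ref_values = c(98, 100, 102)) {
  study <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:n_study), sample_kind = "study",
    plate_id = "p1", well = sprintf("B%d", 1:n_study), metabolite_id = "m",
    value = c(rep(NA_real_, n_missing), rep(study_value, n_study - n_missing)),
    nominal_amount = NA_real_, scale = "raw"
  )
  blank <- tibble::tibble(
    sample_id = sprintf("bl%d", 1:6), sample_kind = "blank", plate_id = "p1",
    well = sprintf("C%d", 1:6), metabolite_id = "m", value = blank_value,
    nominal_amount = NA_real_, scale = "raw"
  )
  refs <- tibble::tibble(
    sample_id = sprintf("r%d", seq_along(ref_values)), sample_kind = "reference",
    plate_id = "p1", well = NA_character_, metabolite_id = "m",
    value = ref_values, nominal_amount = NA_real_, scale = "raw"
  )
  nominals <- rep(c(0.5, 1, 2), each = 2)
  series <- tibble::tibble(
    sample_id = sprintf("ser%d", seq_along(nominals)), sample_kind = "reference_series",
    plate_id = "p1", well = NA_character_, metabolite_id = "m",
    value = slope_sign * 100 * nominals, nominal_amount = nominals, scale = "raw"
  )
  dplyr::bind_rows(study, blank, refs, series)
}

test_that("QC metrics compute coverage, blank contribution and linearity", {
  rec <- compute_qc_metrics(qc_fixture(n_study = 60, n_missing = 6), "m")
  expect_equal(rec$coverage, 0.9)
  expect_equal(rec$blank_contribution, 0.05)
  expect_gt(rec$slope, 0)
  expect_equal(rec$linearity_r2, 1, tolerance = 1e-12)
  expect_equal(rec$variability_rsd, rsd_from_replicates(c(98, 100, 102))$rsd)

  # blanks all zero with positive study median
  rec0 <- compute_qc_metrics(qc_fixture(blank_value = 0), "m")
  expect_equal(rec0$blank_contribution, 0)
})

test_that("missing inputs make metrics non-computable and the gate fails them", {
  tab <- qc_fixture()
  no_blank <- tab[tab$sample_kind != "blank", ]
  rec <- apply_qc_gate(compute_qc_metrics(no_blank, "m"))
  expect_false(rec$passed)
  expect_true(any(grepl("non_computable:blank_contribution", rec$failed_criteria[[1]])))

  no_series <- tab[tab$sample_kind != "reference_series", ]
  rec2 <- apply_qc_gate(compute_qc_metrics(no_series, "m"))
  expect_false(rec2$passed)
  expect_true(any(grepl("non_computable:linearity", rec2$failed_criteria[[1]])))
})

gate_verdict <- function(coverage, blank, slope, r2, rsd) {
  rec <- tibble::tibble(
    metabolite_id = "m", coverage = coverage, blank_contribution = blank,
    slope = slope, linearity_r2 = r2, variability_rsd = rsd,
    non_computable = list(character()), passed = NA,
    failed_criteria = list(character())
  )
  apply_qc_gate(rec)
}

test_that("the printed gate thresholds decide pass/fail as stated", {
  expect_true(gate_verdict(0.9, 0.1, 1.0, 0.9, 0.2)$passed)
  # passes only via condition (d)
  rec_d <- gate_verdict(0.9, 0.1, 1.0, 0.70, 0.5)
  expect_true(rec_d$passed)
  expect_identical(rec_d$conditions_met[[1]], "d")
  # R2 too low for any condition
  rec_f <- gate_verdict(0.9, 0.1, 1.0, 0.60, 0.1)
  expect_false(rec_f$passed)
  expect_true(any(grepl("linearity", rec_f$failed_criteria[[1]])))
  # strict inequalities at the printed boundaries
  expect_false(gate_verdict(0.8, 0.1, 1.0, 0.9, 0.2)$passed)
  expect_false(gate_verdict(0.9, 0.4, 1.0, 0.9, 0.2)$passed)
  expect_false(gate_verdict(0.9, 0.1, 0.0, 0.9, 0.2)$passed)
  expect_false(gate_verdict(0.9, 0.1, 1.0, 0.64, 0.2)$passed)
  expect_false(gate_verdict(0.9, 0.1, 1.0, 0.9, 0.6)$passed)
})

test_that("the four linearity/variability conditions collapse to (d)", {
  for (r2 in seq(0, 1, by = 0.04)) {
    for (rsd in seq(0, 1, by = 0.04)) {
      rec <- gate_verdict(0.9, 0.1, 1.0, r2, rsd)
      expect_identical(rec$passed, r2 > 0.64 && rsd < 0.6)
      # each condition that fired is consistent with its printed thresholds
      conds <- rec$conditions_met[[1]]
      expect_identical("a" %in% conds, r2 > 0.8 && rsd < 0.3)
      expect_identical("d" %in% conds, r2 > 0.64 && rsd < 0.6)
    }
  }
})

test_that("improving any single metric never flips pass to fail", {
  set.seed(42)
  for (i in 1:200) {
    m <- list(
      coverage = runif(1), blank = runif(1), slope = runif(1, -1, 2),
      r2 = runif(1), rsd = runif(1)
    )
    before <- gate_verdict(m$coverage, m$blank, m$slope, m$r2, m$rsd)$passed
    if (!before) next
    better <- list(
      gate_verdict(min(m$coverage + 0.1, 1), m$blank, m$slope, m$r2, m$rsd),
      gate_verdict(m$coverage, m$blank * 0.5, m$slope, m$r2, m$rsd),
      gate_verdict(m$coverage, m$blank, m$slope + 1, m$r2, m$rsd),
      gate_verdict(m$coverage, m$blank, m$slope, min(m$r2 + 0.1, 1), m$rsd),
      gate_verdict(m$coverage, m$blank, m$slope, m$r2, m$rsd * 0.5)
    )
    for (rec in better) expect_true(rec$passed)
  }
})

test_that("all panel metabolites pass QC on clean synthetic data", {
  ex <- generate_experiment(two_substance_design()[1, ],
                            noise = noise_model(0.001, 0, 0, 0), seed = 6)
  report <- qc_report(ex$measurements)
  expect_true(all(report$passed))
  expect_equal(nrow(report), 221)
})
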