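test_that("Welch test matches the direct-formula oracle on random samples", {
  set.seed(7)
  for (i in 1:1000) {
    a <- rnorm(sample(3:8, 1), mean = runif(1, -1, 1), sd = runif(1, 0.2, 2))
    b <- rnorm(sample(3:8, 1), mean = runif(1, -1, 1), sd = runif(1, 0.2, 2))
    got <- welch_test(a, b)
    want <- welch_oracle(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("equal-mean groups give t = 0 and p = 1", {
  got <- welch_test(c(1, 2, 3), c(3, 2, 1))
  expect_equal(got$t, 0)
  expect_equal(got$p, 1)
  # worked pair on raw scale after log transform, against the oracle
  a <- log10(c(1, 2, 3)); b <- log10(c(2, 4, 6))
  got2 <- welch_test(a, b)
  want2 <- welch_oracle(a, b)
  expect_equal(got2$t, want2$t, tolerance = 1e-12)
  expect_equal(got2$p, want2$p, tolerance = 1e-12)
})

test_that("untestable groups are flagged rather than raising", {
  expect_false(welch_test(c(1), c(1, 2, 3))$testable)
  expect_false(welch_test(c(2, 2, 2), c(2, 2, 2))$testable)
  expect_true(is.na(welch_test(c(1), c(1, 2, 3))$p))
})

test_that("RSD back-transform follows the printed formula and round-trips", {
  expect_equal(rsd_from_replicates(c(5, 5, 5))$rsd, 0)
  # sd_log10 = 1 gives RSD = 0.9
  vals <- 10^c(-1, 1)  # sd of log10 = sqrt(2); construct sd exactly 1
  x <- 10^c(0, 1, 2)   # log10 sd = 1
  expect_equal(rsd_from_replicates(x)$sd_log10, 1)
  expect_equal(rsd_from_replicates(x)$rsd, 0.9)
  # round trip: sd_log10 = -log10(1 - rsd)
  r <- rsd_from_replicates(c(90, 100, 113))
  expect_equal(-log10(1 - r$rsd), r$sd_log10, tolerance = 1e-12)
  expect_error(rsd_from_replicates(c(1, -1)), "positive")
  expect_error(rsd_from_replicates(5), "at least 2")
})

test_that("small-sigma RSD matches the CV expansion ln(10)*sigma", {
  set.seed(3)
  sigma <- 0.005
  vals <- 10^rnorm(5000, 2, sigma)
  r <- rsd_from_replicates(vals)
  expect_equal(r$rsd, log(10) * sigma, tolerance = 0.05)
  direct_cv <- sd(vals) / mean(vals)
  expect_equal(r$rsd, direct_cv, tolerance = 0.05)
})

test_that("null Welch simulations reject at close to the nominal rate", {
  set.seed(11)
  n_rep <- 2000
  p <- replicate(n_rep, welch_test(10^rnorm(6, 0, 0.05), 10^rnorm(12, 0, 0.05))$p)
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.035)
  expect_lt(rate, 0.065)
})

test_that("a planted 0.3 log10 effect is detected with high power", {
  set.seed(12)
  hits <- replicate(200, {
    welch_test(rnorm(6, 0.3, 0.05), rnorm(12, 0, 0.05))$p < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("differential profiles report fold changes and directions", {
  ex <- generate_experiment(two_substance_design()[1, ], seed = 21)
  nm <- normalize_both(ex)
  res <- differential_profile(nm, "acifluorfen", 3)
  expect_equal(nrow(res), 221)
  # fold change consistent with the mean log10 difference
  expect_equal(res$fold_change,
               10^(res$mean_log10_ratio_treated - res$mean_log10_ratio_control),
               tolerance = 1e-12)
  # planted signature members significant with the planted direction
  planted_down <- c("propionylcarnitine", "creatine", "carnitine")
  expect_true(all(res$direction[res$metabolite_id %in% planted_down] == "down"))
  expect_identical(res$direction[res$metabolite_id == "n_acetylaspartate"], "up")
  expect_true(all(res$direction[res$significant] != "none"))
  expect_true(all(res$direction[!res$significant] == "none"))
  # BH adjustment is available and only shrinks the significant set
  res_bh <- differential_profile(nm, "acifluorfen", 3, adjust = "bh")
  expect_lte(sum(res_bh$significant), sum(res$significant))
})

test_that("identical treated and control values give p = 1 throughout", {
  ex <- generate_experiment(two_substance_design()[1, ],
                            signatures = null_signatures(),
                            noise = noise_model(0, 0, 0, 0), seed = 22)
  nm <- normalize_both(ex)
  res <- differential_profile(nm, "acifluorfen", 3)
  expect_false(any(res$significant))
  expect_true(all(!res$testable))  # zero variance everywhere
})

test_that("class enrichment counts partition the significant set", {
  ex <- generate_experiment(two_substance_design()[1, ], seed = 23)
  nm <- normalize_both(ex)
  res <- differential_profile(nm, "acifluorfen", 3)
  enr <- class_enrichment(res, ex$panel)
  expect_equal(sum(enr$n_significant), sum(res$significant))
  expect_equal(sum(enr$n_total), nrow(res))
  expect_equal(enr$n_significant, enr$n_up + enr$n_down)
  # no significant metabolites -> all zero
  res0 <- res
  res0$significant <- FALSE
  res0$direction <- "none"
  enr0 <- class_enrichment(res0, ex$panel)
  expect_true(all(enr0$n_significant == 0))
  expect_error(class_enrichment(dplyr::mutate(res, metabolite_id = paste0("x_", metabolite_id)),
                                ex$panel), "missing from panel")
})

test_that("planted-metabolite detections increase with concentration level", {
  ex <- generate_experiment(two_substance_design()[1, ], seed = 24)
  nm <- normalize_both(ex)
  sig <- default_signatures()$peroxisome_proliferation
  planted <- unique(c(names(sig$effects), names(sig$shared_effects)))
  detected <- sapply(1:5, function(l) {
    res <- differential_profile(nm, "acifluorfen", l)
    sum(res$significant[res$metabolite_id %in% planted])
  })
  expect_true(all(diff(detected) >= 0))
  expect_gt(detected[5], detected[1])
})
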