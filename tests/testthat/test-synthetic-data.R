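test_that("generated panel reproduces the 221/156/65 split across 12 classes", {
  panel <- generate_panel(221, 65, seed = 1)
  expect_equal(nrow(panel), 221)
  expect_equal(sum(panel$annotation_status == "unknown"), 65)
  expect_equal(sum(panel$annotation_status != "unknown"), 156)
  expect_length(unique(panel$ontology_class), 12)
  expect_silent(validate_panel(panel))
  # curated signature metabolites are panel members
  expect_true(all(curated_metabolites()$metabolite_id %in% panel$metabolite_id))
})

test_that("panel generation is deterministic and validates its arguments", {
  expect_identical(generate_panel(seed = 7), generate_panel(seed = 7))
  small <- generate_panel(10, 0, class_names = "one class", seed = 1)
  expect_equal(nrow(small), 10)
  expect_true(all(small$ontology_class == "one class"))
  expect_true(all(small$annotation_status != "unknown"))
  expect_error(generate_panel(10, 11, seed = 1), "n_unknown")
  expect_error(generate_panel(10, 0, class_names = character(), seed = 1), "non-empty")
})

test_that("identical parameters and seed give identical experiments", {
  subs <- two_substance_design()
  a <- generate_experiment(subs, seed = 123)
  b <- generate_experiment(subs, seed = 123)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$viability, b$viability)
  c <- generate_experiment(subs, seed = 124)
  expect_false(identical(a$measurements$value, c$measurements$value))
})

test_that("zero noise and zero effects reproduce baselines exactly", {
  subs <- two_substance_design()[1, ]
  ex <- generate_experiment(subs, signatures = null_signatures(),
                            noise = noise_model(0, 0, 0, 0), seed = 3)
  base <- 10^ex$truth$log_baseline
  study <- ex$measurements[ex$measurements$sample_kind %in% c("study", "reference"), ]
  expect_equal(study$value, unname(base[study$metabolite_id]), tolerance = 1e-12)
  series <- ex$measurements[ex$measurements$sample_kind == "reference_series", ]
  expect_equal(series$value,
               unname(base[series$metabolite_id]) * series$nominal_amount,
               tolerance = 1e-12)
})

test_that("the cell-number factor is one multiplier shared by a whole sample", {
  subs <- two_substance_design()[1, ]
  ex <- generate_experiment(subs, signatures = null_signatures(),
                            noise = noise_model(0, 0, 0, 0.1), seed = 4)
  base <- 10^ex$truth$log_baseline
  study <- ex$measurements[ex$measurements$sample_kind == "study", ]
  ratio <- study$value / base[study$metabolite_id]
  per_sample_spread <- tapply(ratio, study$sample_id, function(v) diff(range(v)))
  expect_lt(max(per_sample_spread), 1e-9)
  # but factors differ between samples
  per_sample_level <- tapply(ratio, study$sample_id, mean)
  expect_gt(diff(range(per_sample_level)), 0.01)
})

test_that("default noise puts vehicle-well RSD in the 8-11% control band", {
  rsds <- sapply(1:20, function(seed) {
    ex <- generate_experiment(two_substance_design()[1, ],
                              signatures = null_signatures(), seed = seed)
    nm <- normalize_to_reference(ex$measurements, layouts = ex$layouts)
    veh <- nm$sample_info$sample_id[nm$sample_info$role == "vehicle_control"]
    mean(apply(nm$values[veh, ], 2, function(v) rsd_from_replicates(v)$rsd))
  })
  # reference-ratio RSD of vehicle wells; generator calibrated to ~8-11%
  expect_gt(mean(rsds), 0.08)
  expect_lt(mean(rsds), 0.12)
  # technical replicates a touch tighter (8-10% band)
  ex <- generate_experiment(two_substance_design()[1, ],
                            signatures = null_signatures(), seed = 99)
  ref <- ex$measurements[ex$measurements$sample_kind == "reference", ]
  tech <- tapply(ref$value, ref$metabolite_id, function(v) rsd_from_replicates(v)$rsd)
  expect_gt(mean(tech), 0.06)
  expect_lt(mean(tech), 0.11)
})

test_that("default MoA signatures are mutually non-proportional", {
  sigs <- default_signatures()
  mets <- unique(unlist(lapply(sigs, function(s) names(s$effects))))
  vecs <- sapply(sigs, function(s) {
    v <- setNames(numeric(length(mets)), mets)
    v[names(s$effects)] <- s$effects
    v
  })
  for (i in 1:2) {
    for (j in (i + 1):3) {
      cosine <- sum(vecs[, i] * vecs[, j]) /
        sqrt(sum(vecs[, i]^2) * sum(vecs[, j]^2))
      expect_lt(abs(cosine), 0.9)
    }
  }
})

test_that("signatures referencing unknown metabolites are rejected", {
  subs <- two_substance_design()[1, ]
  bad <- list(peroxisome_proliferation = effect_signature(
    "peroxisome_proliferation", c(not_a_metabolite = 0.5)
  ))
  expect_error(generate_experiment(subs, signatures = bad, seed = 1),
               "absent from panel")
  expect_error(effect_signature("m", numeric(), dose_scaling = c(2, 1)),
               "non-decreasing")
})

test_that("simulated viability follows the ground-truth W1.3 curve", {
  subs <- two_substance_design()[1, ]
  ex <- generate_experiment(subs, viability_sd = 0, seed = 8)
  fit <- w13_fit(subs$b, subs$d, subs$e)
  expected <- w13_response(unique(ex$viability$concentration_uM), fit)
  observed <- tapply(ex$viability$viability_pct, ex$viability$level, mean)
  expect_equal(as.numeric(observed), as.numeric(expected), tolerance = 1e-10)
})
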