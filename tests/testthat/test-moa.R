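# minimal differential-result stub
result_stub <- function(sig_up = character(), sig_down = character(),
                        all_mets = c("m1", "m2", "m3", "m4")) {
  tibble::tibble(
    metabolite_id = all_mets,
    significant = all_mets %in% c(sig_up, sig_down),
    direction = ifelse(all_mets %in% sig_up, "up",
                       ifelse(all_mets %in% sig_down, "down", "none"))
  )
}

test_that("fingerprints are strict direction-consistent intersections", {
  res <- list(
    s1 = result_stub(sig_up = "m1", sig_down = c("m2", "m3")),
    s2 = result_stub(sig_up = "m1", sig_down = c("m2", "m4")),
    s3 = result_stub(sig_up = c("m1", "m4"), sig_down = "m2")
  )
  fp <- derive_fingerprint(res, "test_moa")
  expect_identical(fp$increased, "m1")
  expect_identical(fp$decreased, "m2")  # m3 only in 2 of 3 -> excluded
  expect_false(fp$single_substance)
  expect_error(derive_fingerprint(list(), "x"), "no differential results")

  # direction flip excludes: m4 up in s3 but down in s2
  expect_false("m4" %in% c(fp$increased, fp$decreased))
})

test_that("fingerprints shrink as substances are added", {
  set.seed(9)
  mets <- paste0("m", 1:30)
  results <- lapply(1:5, function(i) {
    up <- sample(mets, 12)
    down <- sample(setdiff(mets, up), 8)
    result_stub(up, down, mets)
  })
  names(results) <- paste0("s", 1:5)
  for (k in 2:5) {
    smaller <- derive_fingerprint(results[1:k], "moa")
    larger <- derive_fingerprint(results[1:(k - 1)], "moa")
    expect_true(all(smaller$increased %in% larger$increased))
    expect_true(all(smaller$decreased %in% larger$decreased))
  }
})

test_that("general markers require direction consistency across all MoAs", {
  fps <- list(
    derive_fingerprint(list(a = result_stub("m1", "m2")), "moa_a"),
    derive_fingerprint(list(b = result_stub(c("m1", "m3"), "m2")), "moa_b")
  )
  gm <- derive_general_markers(fps)
  expect_identical(gm$increased, "m1")
  expect_identical(gm$decreased, "m2")
  # m3 only in one MoA -> not general; removed from nothing else
  expect_identical(gm$specific_fingerprints$moa_b$increased, "m3")
  expect_identical(gm$specific_fingerprints$moa_a$increased, character(0))

  # opposite directions never become general markers
  fps2 <- list(
    derive_fingerprint(list(a = result_stub("m1", character())), "moa_a"),
    derive_fingerprint(list(b = result_stub(character(), "m1")), "moa_b")
  )
  gm2 <- derive_general_markers(fps2)
  expect_length(gm2$increased, 0)
  expect_length(gm2$decreased, 0)
  expect_error(derive_general_markers(fps[1]), "at least 2")
})

full_experiment_fingerprints <- function(seed) {
  subs <- default_study_substances()
  ex <- generate_experiment(subs, seed = seed)
  nm <- normalize_both(ex)
  levels <- setNames(rep(3L, nrow(subs)), subs$substance_id)
  results <- lapply(subs$substance_id, function(s) {
    differential_profile(nm, s, levels[[s]])
  })
  names(results) <- subs$substance_id
  moa_map <- setNames(subs$moa_id, subs$substance_id)
  fps <- lapply(split(subs$substance_id, subs$moa_id), function(members) {
    derive_fingerprint(results[members], moa_map[[members[1]]])
  })
  list(ex = ex, nm = nm, results = results, fps = fps)
}

test_that("planted shared markers are recovered exactly as general markers", {
  run <- full_experiment_fingerprints(seed = 41)
  gm <- derive_general_markers(run$fps)
  shared <- default_shared_effects()
  expect_identical(gm$decreased, sort(names(shared[shared < 0])))
  expect_identical(gm$increased, sort(names(shared[shared > 0])))
})

test_that("multi-substance fingerprints recover exactly the planted signatures", {
  run <- full_experiment_fingerprints(seed = 42)
  sigs <- default_signatures()
  shared <- default_shared_effects()
  for (moa in c("peroxisome_proliferation", "enzyme_induction")) {
    eff <- sigs[[moa]]$effects
    planted_up <- sort(unique(c(names(eff[eff > 0]), names(shared[shared > 0]))))
    planted_down <- sort(unique(c(names(eff[eff < 0]), names(shared[shared < 0]))))
    expect_identical(run$fps[[moa]]$increased, planted_up)
    expect_identical(run$fps[[moa]]$decreased, planted_down)
  }
  # single-substance MoA is flagged and contains its planted members
  ki <- run$fps$enzyme_inhibition
  expect_true(ki$single_substance)
  eff <- sigs$enzyme_inhibition$effects
  expect_true(all(names(eff[eff > 0]) %in% ki$increased))
  expect_true(all(names(eff[eff < 0]) %in% ki$decreased))
})

test_that("compounds classify to their generating MoA in PC space", {
  subs <- default_study_substances()
  run <- full_experiment_fingerprints(seed = 43)
  prof <- treatment_mean_profiles(run$nm, setNames(rep(3L, 7), subs$substance_id))
  moa_map <- setNames(subs$moa_id, subs$substance_id)

  # leave-one-substance-out over the multi-member MoAs
  correct <- 0; total <- 0
  for (s in subs$substance_id) {
    ref <- build_moa_reference(prof[setdiff(rownames(prof), s), ], moa_map)
    call <- classify_compound(prof[s, ], ref)
    total <- total + 1
    correct <- correct + (call$moa_id == moa_map[[s]])
  }
  # ketoconazole cannot be classified without its own MoA in the reference
  expect_gte(correct, total - 1)

  # profile at a centroid pre-image classifies with distance ~0
  ref_all <- build_moa_reference(prof, moa_map)
  call <- classify_compound(prof["ketoconazole", ], ref_all)
  expect_identical(call$moa_id, "enzyme_inhibition")
  expect_equal(min(call$distances), unname(call$distances["enzyme_inhibition"]))
})

test_that("insufficient metabolite overlap and null profiles are flagged", {
  subs <- default_study_substances()
  run <- full_experiment_fingerprints(seed = 44)
  prof <- treatment_mean_profiles(run$nm, setNames(rep(3L, 7), subs$substance_id))
  moa_map <- setNames(subs$moa_id, subs$substance_id)
  ref <- build_moa_reference(prof, moa_map)

  sparse <- prof[1, 1:50]
  expect_error(classify_compound(sparse, ref), "covers only")

  null_profile <- setNames(rep(0, ncol(prof)), colnames(prof))
  call <- classify_compound(null_profile, ref, null_threshold = 1e-6)
  expect_true(call$low_confidence)
  expect_length(call$distances, 3)
})
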