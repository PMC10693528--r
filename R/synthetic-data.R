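#' Log-normal noise model for plate metabolomics data
#'
#' All noise is multiplicative on the raw-signal scale, i.e. additive
#' Gaussian on log10. Defaults are calibrated so that the back-transformed
#' relative standard deviation (RSD, see [rsd_from_replicates()]) of
#' vehicle-control wells falls around 9-10% and that of technical
#' (reference) replicates around 9%, matching the variability a
#' well-behaved targeted LC-MS/MS platform exhibits.
#'
#' @param sigma_tech SD of technical noise on log10 scale (every sample).
#' @param sigma_bio SD of biological noise on log10 scale (study wells
#'   only; vehicle wells carry technical + biological noise).
#' @param batch_sd SD of the per-plate, per-metabolite log10 batch factor
#'   (instrument drift between analytical batches).
#' @param cellnum_sd SD of the per-well log10 cell-number factor (one
#'   multiplicative factor shared by all metabolites of a well).
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(sigma_tech = 0.040, sigma_bio = 0.018,
                        batch_sd = 0.05, cellnum_sd = 0.03) {
  vals <- c(sigma_tech, sigma_bio, batch_sd, cellnum_sd)
  if (any(!is.finite(vals)) || any(vals < 0)) stop("noise SDs must be non-negative")
  structure(
    list(sigma_tech = sigma_tech, sigma_bio = sigma_bio,
         batch_sd = batch_sd, cellnum_sd = cellnum_sd),
    class = "noise_model"
  )
}

#' @rdname noise_model
#' @export
default_noise_model <- function() noise_model()

#' Mode-of-action effect signature
#'
#' A signature describes how a treatment perturbs the metabolome: signed
#' log10 fold changes at the intermediate (reference) concentration for
#' MoA-specific metabolites (`effects`), for MoA-nonspecific
#' hepatotoxicity markers applied to every MoA (`shared_effects`), and
#' for cytotoxicity-driven changes that switch on at high-toxicity doses
#' (`cytotox_effects`). `dose_scaling` maps concentration level 1-5 to a
#' non-decreasing multiplier of the MoA/shared effects; the cytotoxic
#' term instead follows a steep logistic gate centred between levels 3
#' and 4, reproducing the qualitative change of direction of metabolome
#' responses at overtly toxic doses.
#'
#' @param moa_id Mode-of-action identifier.
#' @param effects Named numeric, metabolite_id -> log10 effect.
#' @param shared_effects Named numeric of shared hepatotoxicity markers.
#' @param cytotox_effects Named numeric of high-dose cytotoxicity markers.
#' @param dose_scaling Numeric multiplier per level, non-decreasing.
#' @return Object of class `effect_signature`.
#' @export
effect_signature <- function(moa_id, effects, shared_effects = numeric(),
                             cytotox_effects = numeric(),
                             dose_scaling = c(0.25, 0.5, 1, 1.5, 2)) {
  if (is.unsorted(dose_scaling)) stop("dose_scaling must be non-decreasing")
  if (any(dose_scaling < 0)) stop("dose_scaling must be non-negative")
  stopifnot(length(moa_id) == 1)
  structure(
    list(moa_id = moa_id, effects = effects, shared_effects = shared_effects,
         cytotox_effects = cytotox_effects, dose_scaling = dose_scaling),
    class = "effect_signature"
  )
}

# logistic cytotoxicity gate: ~0 at levels <= 3, ~1 at levels >= 4
cytotox_gate <- function(level, center = 3.5, steepness = 8) {
  1 / (1 + exp(-steepness * (level - center)))
}

#' Shared hepatotoxicity marker effects
#'
#' The five MoA-nonspecific markers: creatine, carnitine and pantothenic
#' acid decrease while lysophosphatidylcholine and
#' lysophosphatidylethanolamine increase under every hepatotoxic MoA.
#'
#' @param magnitude Absolute log10 effect size at the reference level.
#' @return Named numeric vector of signed log10 effects.
#' @export
default_shared_effects <- function(magnitude = 0.25) {
  c(
    creatine = -1, carnitine = -1, pantothenic_acid = -1,
    lpc_18_1 = 1, lpe_18_1 = 1
  ) * magnitude
}

default_cytotox_effects <- function() {
  c(
    lactate = 0.40, glutathione = -0.30, spermidine = 0.25,
    glycerophosphocholine = 0.30, lpc_18_1 = 0.20
  )
}

#' Default mode-of-action effect signatures
#'
#' Three signatures encoding the qualitative direction of the
#' characteristic metabolite changes of each hepatotoxicity MoA:
#' peroxisome proliferators deplete short/medium acylcarnitines,
#' ketoleucine, taurine and related energy metabolites while raising
#' N-acetylaspartate and some triacylglycerols; enzyme inducers raise
#' tyrosine, redox carriers (FAD, glutathione) and cysteinylglycine while
#' depleting proline, myo-inositol, N-acetylglucosamine and
#' O-acetylcarnitine; the enzyme inhibitor raises long-chain
#' acylcarnitines, taurine, choline and sphingomyelin while depleting
#' amino acids, antioxidants and ceramides. Magnitudes are generator
#' calibrations (directions are the biology; sizes are configurable).
#'
#' @param dose_scaling Per-level effect multiplier (non-decreasing).
#' @param shared Shared hepatotoxicity effects
#'   ([default_shared_effects()]).
#' @param cytotox High-dose cytotoxicity effects.
#' @return Named list of [effect_signature()] objects keyed by moa_id.
#' @export
default_signatures <- function(dose_scaling = c(0.25, 0.5, 1, 1.5, 2),
                               shared = default_shared_effects(),
                               cytotox = default_cytotox_effects()) {
  pp <- c(
    propionylcarnitine = -0.30, hexanoylcarnitine = -0.30,
    ketoleucine = -0.25, taurine = -0.25,
    s_adenosylhomocysteine = -0.20, deoxycytidine = -0.20,
    glycerol_3_phosphate = -0.20, n_acetylaspartate = 0.30,
    tag_52_2 = 0.25, phosphatidylcholine_34_1 = -0.20,
    ceramide_d18_1_16_0 = -0.20, sphingomyelin_34_1 = -0.20
  )
  ei <- c(
    tyrosine = 0.30, flavin_adenine_dinucleotide = 0.25,
    glutathione = 0.30, cysteinylglycine = 0.25,
    proline = -0.25, myo_inositol = -0.25, n_acetylglucosamine = -0.25,
    o_acetylcarnitine = -0.30, deoxycytidine = -0.20,
    propionylcarnitine = -0.20, hexanoylcarnitine = -0.20, tag_54_3 = -0.20
  )
  ki <- c(
    tetradecanoylcarnitine = 0.30, hexadecanoylcarnitine = 0.30,
    octadecenoylcarnitine = 0.25, taurine = 0.25, choline = 0.25,
    sphingomyelin_34_1 = 0.30, threonine = -0.25, glutamate = -0.25,
    proline = -0.20, glutathione = -0.20, coenzyme_q10 = -0.25,
    pyridoxal = -0.20, ceramide_d18_1_16_0 = -0.25,
    cholesteryl_ester_18_2 = -0.25
  )
  list(
    peroxisome_proliferation = effect_signature(
      "peroxisome_proliferation", pp, shared, cytotox, dose_scaling
    ),
    enzyme_induction = effect_signature(
      "enzyme_induction", ei, shared, cytotox, dose_scaling
    ),
    enzyme_inhibition = effect_signature(
      "enzyme_inhibition", ki, shared, cytotox, dose_scaling
    )
  )
}

#' Curated named analytes of the synthetic panel
#'
#' Metabolites referenced by the default effect signatures, with their
#' ontology classes. These are always placed at the head of a generated
#' panel (annotation status `confirmed`) so that signatures refer to real
#' panel members.
#'
#' @return Tibble with `metabolite_id`, `display_name`, `ontology_class`.
#' @export
curated_metabolites <- function() {
  tibble::tribble(
    ~metabolite_id, ~display_name, ~ontology_class,
    "creatine", "Creatine", "amino acids and related",
    "carnitine", "Carnitine", "carnitines and acylcarnitines",
    "pantothenic_acid", "Pantothenic acid", "vitamins and cofactors",
    "lpc_18_1", "LPC(18:1)", "lysophospholipids",
    "lpe_18_1", "LPE(18:1)", "lysophospholipids",
    "propionylcarnitine", "Propionylcarnitine", "carnitines and acylcarnitines",
    "hexanoylcarnitine", "Hexanoylcarnitine", "carnitines and acylcarnitines",
    "o_acetylcarnitine", "O-Acetylcarnitine", "carnitines and acylcarnitines",
    "tetradecanoylcarnitine", "Tetradecanoylcarnitine", "carnitines and acylcarnitines",
    "hexadecanoylcarnitine", "Hexadecanoylcarnitine", "carnitines and acylcarnitines",
    "octadecenoylcarnitine", "Octadecenoylcarnitine", "carnitines and acylcarnitines",
    "ketoleucine", "Ketoleucine", "energy metabolism and organic acids",
    "taurine", "Taurine", "amino acids and related",
    "n_acetylaspartate", "N-Acetylaspartate", "amino acids and related",
    "s_adenosylhomocysteine", "S-Adenosylhomocysteine", "nucleobases and nucleosides",
    "deoxycytidine", "Deoxycytidine", "nucleobases and nucleosides",
    "glycerol_3_phosphate", "Glycerol-3-phosphate", "energy metabolism and organic acids",
    "tyrosine", "Tyrosine", "amino acids and related",
    "threonine", "Threonine", "amino acids and related",
    "glutamate", "Glutamate", "amino acids and related",
    "proline", "Proline", "amino acids and related",
    "cysteinylglycine", "Cysteinylglycine", "amino acids and related",
    "glutathione", "Glutathione", "amino acids and related",
    "flavin_adenine_dinucleotide", "FAD", "vitamins and cofactors",
    "coenzyme_q10", "Coenzyme Q10", "vitamins and cofactors",
    "pyridoxal", "Pyridoxal", "vitamins and cofactors",
    "myo_inositol", "myo-Inositol", "energy metabolism and organic acids",
    "n_acetylglucosamine", "N-Acetylglucosamine", "energy metabolism and organic acids",
    "choline", "Choline", "energy metabolism and organic acids",
    "lactate", "Lactate", "energy metabolism and organic acids",
    "spermidine", "Spermidine", "amino acids and related",
    "glycerophosphocholine", "Glycerophosphocholine", "glycerophospholipids",
    "phosphatidylcholine_34_1", "PC(34:1)", "glycerophospholipids",
    "sphingomyelin_34_1", "SM(34:1)", "sphingolipids",
    "ceramide_d18_1_16_0", "Cer(d18:1/16:0)", "ceramides",
    "tag_52_2", "TAG(52:2)", "triacylglycerols",
    "tag_54_3", "TAG(54:3)", "triacylglycerols",
    "cholesteryl_ester_18_2", "CE(18:2)", "sterols and steroids"
  )
}

#' Generate a synthetic metabolite panel
#'
#' Produces a panel of `n_total` analytes of which `n_unknown` are
#' unknowns (defined analytical parameters, no chemical identity); the
#' default emulates the 221-analyte targeted panel with 156 annotated and
#' 65 unknown analytes across 12 ontology classes. The curated,
#' signature-referenced metabolites head the panel when their classes are
#' available; filler analytes are assigned classes cyclically, with every
#' fifth filler marked `plausible` rather than `confirmed`.
#'
#' @param n_total Total analytes (default 221).
#' @param n_unknown Unknown analytes (default 65).
#' @param class_names Ontology classes ([default_ontology_classes()]).
#' @param seed Integer seed (class assignment shuffling).
#' @return Validated panel tibble.
#' @export
generate_panel <- function(n_total = 221, n_unknown = 65,
                           class_names = default_ontology_classes(),
                           seed = 1) {
  if (n_unknown > n_total || n_unknown < 0) {
    stop("n_unknown must lie between 0 and n_total")
  }
  if (length(class_names) == 0) stop("class_names must be non-empty")
  withr::local_seed(seed)

  n_annotated <- n_total - n_unknown
  curated <- curated_metabolites()
  if (!all(curated$ontology_class %in% class_names)) curated <- curated[0, ]
  curated <- utils::head(curated, n_annotated)

  annotated_classes <- setdiff(class_names, "unknown")
  if (length(annotated_classes) == 0) annotated_classes <- class_names
  n_fill <- n_annotated - nrow(curated)
  fill <- tibble::tibble(
    metabolite_id = sprintf("met_%03d", seq_len(max(n_fill, 0))),
    display_name = sprintf("Metabolite %03d", seq_len(max(n_fill, 0))),
    annotation_status = ifelse(seq_len(max(n_fill, 0)) %% 5 == 0, "plausible", "confirmed"),
    ontology_class = sample(rep_len(annotated_classes, max(n_fill, 0)))
  )

  unknown_class <- if ("unknown" %in% class_names) "unknown" else
    rep_len(class_names, n_unknown)
  unk <- tibble::tibble(
    metabolite_id = sprintf("unknown_%03d", seq_len(n_unknown)),
    display_name = sprintf("Unknown %03d", seq_len(n_unknown)),
    annotation_status = "unknown",
    ontology_class = unknown_class
  )

  panel <- dplyr::bind_rows(
    dplyr::mutate(curated, annotation_status = "confirmed",
                  .after = "display_name"),
    fill, unk
  )
  panel <- panel[c("metabolite_id", "display_name", "annotation_status", "ontology_class")]
  validate_panel(panel, classes = class_names)
  panel
}

#' Default seven-substance study design
#'
#' The reference compound set: three peroxisome proliferators
#' (bezafibrate, acifluorfen, wy-14643), three liver enzyme inducers
#' (aroclor 1254, pendimethalin, beta-naphthoflavone) and one liver
#' enzyme inhibitor (ketoconazole), each with a plausible W1.3
#' ground-truth ATP dose-response (upper asymptote 100%).
#'
#' @return Tibble with `substance_id`, `moa_id`, `b`, `d`, `e`.
#' @export
default_study_substances <- function() {
  tibble::tribble(
    ~substance_id, ~moa_id, ~b, ~d, ~e,
    "bezafibrate", "peroxisome_proliferation", 1.3, 100, 900,
    "acifluorfen", "peroxisome_proliferation", 1.1, 100, 600,
    "wy_14643", "peroxisome_proliferation", 0.9, 100, 600,
    "aroclor_1254", "enzyme_induction", 1.4, 100, 110,
    "pendimethalin", "enzyme_induction", 1.3, 100, 110,
    "beta_naphthoflavone", "enzyme_induction", 0.55, 100, 150,
    "ketoconazole", "enzyme_inhibition", 1.2, 100, 60
  )
}

#' Simulate a range-finder viability experiment
#'
#' Draws replicate percent-viability readings around a W1.3 ground-truth
#' curve with additive Gaussian noise (percentage points), as produced by
#' an ATP endpoint in a range-finder run.
#'
#' @param fit Ground-truth [w13_fit()].
#' @param doses Concentrations tested (uM).
#' @param n_rep Replicates per dose (default 6).
#' @param sd_pct Noise SD in percentage points (default 3).
#' @param seed Integer seed.
#' @return Tibble `dose`, `replicate`, `viability_pct`.
#' @export
simulate_range_finder <- function(fit, doses, n_rep = 6, sd_pct = 3, seed = 1) {
  withr::local_seed(seed)
  mu <- w13_response(doses, fit)
  tibble::tibble(
    dose = rep(doses, each = n_rep),
    replicate = rep(seq_len(n_rep), times = length(doses)),
    viability_pct = rep(mu, each = n_rep) + stats::rnorm(length(doses) * n_rep) * sd_pct
  )
}

#' Generate a complete synthetic plate experiment
#'
#' Builds, for one or several substances (one 96-well plate each), the
#' full data bundle the analysis pipeline consumes: a metabolite panel,
#' plate layouts, a raw long-format measurement table (study wells,
#' blanks, per-plate lyophilized reference replicates and a reference
#' concentration series) and a viability table, plus the complete
#' generating truth.
#'
#' For a study well of metabolite m the generated signal is
#' `log10(value) = log10(baseline_m) + batch(plate, m) + cellnum(well) +
#' s(level) * (effect_m + shared_m) + gate(level) * cytotox_m + N(0, sigma)`
#' with `sigma^2 = sigma_tech^2 + sigma_bio^2`. Blanks draw from a
#' configurable fraction (default 5%) of baseline with technical noise;
#' reference samples carry baseline, batch and technical noise only;
#' reference-series values are proportional to their nominal amount.
#' Viability replicates are drawn around each substance's ground-truth
#' W1.3 curve at its five (unrounded) effective concentrations
#' EC1/EC5/EC15/EC50/EC85.
#'
#' @param substances Tibble as [default_study_substances()], or a single
#'   substance_id string (then `moa_id` and `fit` must be given).
#' @param moa_id,fit MoA and ground-truth [w13_fit()] when `substances`
#'   is a single id.
#' @param panel Metabolite panel; generated from `seed` when `NULL`.
#' @param signatures Named list of [effect_signature()] per moa_id.
#' @param noise [noise_model()].
#' @param design [default_plate_design()] counts.
#' @param n_reference Reference replicates per plate (default 6).
#' @param series_nominals Relative nominal amounts of the reference
#'   concentration series (default 0.25, 0.5, 1, 2, 4).
#' @param n_series_rep Replicates per series point (default 2).
#' @param blank_fraction Blank signal as fraction of baseline (default 0.05).
#' @param dropout_rate Probability a study value is missing (default 0).
#' @param viability_sd Viability noise, percentage points (default 3).
#' @param positive_scaling Effect multiplier for positive-control wells
#'   (bezafibrate 1000 uM; default 1.25).
#' @param seed Integer seed; the experiment is bit-reproducible under it.
#' @return Object of class `simulated_experiment`: list with `panel`,
#'   `layouts` (named list per plate), `layout_table`, `measurements`,
#'   `viability`, `truth`.
#' @export
generate_experiment <- function(substances, moa_id = NULL, fit = NULL,
                                panel = NULL,
                                signatures = default_signatures(),
                                noise = default_noise_model(),
                                design = default_plate_design(),
                                n_reference = 6,
                                series_nominals = c(0.25, 0.5, 1, 2, 4),
                                n_series_rep = 2,
                                blank_fraction = 0.05,
                                dropout_rate = 0,
                                viability_sd = 3,
                                positive_scaling = 1.25,
                                seed = 1) {
  if (is.character(substances)) {
    if (is.null(moa_id) || is.null(fit)) {
      stop("single-substance call requires moa_id and fit")
    }
    substances <- tibble::tibble(
      substance_id = substances, moa_id = moa_id,
      b = fit$b, d = fit$d, e = fit$e
    )
  }
  missing_moa <- setdiff(unique(substances$moa_id), names(signatures))
  if (length(missing_moa) > 0) {
    stop("no signature for moa_id: ", paste(missing_moa, collapse = ", "))
  }
  withr::local_seed(seed)
  if (is.null(panel)) panel <- generate_panel(seed = seed)
  mets <- panel$metabolite_id
  n_m <- length(mets)
  for (sig in signatures) {
    bad <- setdiff(
      c(names(sig$effects), names(sig$shared_effects), names(sig$cytotox_effects)),
      mets
    )
    if (length(bad) > 0) {
      stop("signature references metabolites absent from panel: ",
           paste(bad, collapse = ", "))
    }
  }

  log_baseline <- stats::rnorm(n_m, mean = 4.5, sd = 0.5)
  names(log_baseline) <- mets

  pos_sig <- signatures[["peroxisome_proliferation"]]
  if (is.null(pos_sig)) pos_sig <- signatures[[1]]

  as_full <- function(v) {
    out <- stats::setNames(numeric(n_m), mets)
    out[names(v)] <- v
    out
  }

  measurements <- vector("list", nrow(substances))
  layouts <- vector("list", nrow(substances))
  viability <- vector("list", nrow(substances))
  batch <- matrix(0, nrow(substances), n_m,
                  dimnames = list(substances$substance_id, mets))
  cellnum_truth <- list()

  for (i in seq_len(nrow(substances))) {
    sub <- substances$substance_id[i]
    sig <- signatures[[substances$moa_id[i]]]
    truth_fit <- w13_fit(substances$b[i], substances$d[i], substances$e[i])
    plate_id <- paste0("plate_", sub)
    layout <- build_plate_layout(sub, plate_id = plate_id, design = design)
    layouts[[i]] <- layout

    batch[i, ] <- stats::rnorm(n_m) * noise$batch_sd

    used <- layout[layout$role != "unused", ]
    has_cells <- used$role %in% c("treatment", "vehicle_control", "positive_control")
    cellnum <- ifelse(has_cells, 1, 0) * stats::rnorm(nrow(used)) * noise$cellnum_sd
    names(cellnum) <- used$well
    cellnum_truth[[plate_id]] <- cellnum

    spec_full <- as_full(sig$effects)
    shared_full <- as_full(sig$shared_effects)
    cyto_full <- as_full(sig$cytotox_effects)
    pos_full <- as_full(pos_sig$effects) + as_full(pos_sig$shared_effects)
    pos_cyto <- as_full(pos_sig$cytotox_effects)

    # effect per well x metabolite (wells as rows)
    eff <- matrix(0, nrow(used), n_m)
    for (w in seq_len(nrow(used))) {
      eff[w, ] <- switch(used$role[w],
        treatment = {
          l <- used$concentration_level[w]
          sig$dose_scaling[l] * (spec_full + shared_full) +
            cytotox_gate(l) * cyto_full
        },
        positive_control = positive_scaling * pos_full +
          cytotox_gate(3) * pos_cyto,
        numeric(n_m)
      )
    }

    is_blank <- used$role == "blank"
    sigma_study <- sqrt(noise$sigma_tech^2 + noise$sigma_bio^2)
    n_cells <- nrow(used) * n_m
    eps <- matrix(stats::rnorm(n_cells, 0, 1), nrow(used), n_m)
    log_val <- matrix(log_baseline, nrow(used), n_m, byrow = TRUE) +
      matrix(batch[i, ], nrow(used), n_m, byrow = TRUE) +
      cellnum + eff +
      eps * ifelse(is_blank, noise$sigma_tech, sigma_study)
    log_val[is_blank, ] <- log_val[is_blank, ] -
      eff[is_blank, , drop = FALSE] + log10(blank_fraction)

    vals <- as.vector(t(10^log_val))
    if (dropout_rate > 0) {
      vals[stats::runif(length(vals)) < dropout_rate] <- NA_real_
    }
    study_tbl <- tibble::tibble(
      sample_id = rep(paste0(plate_id, "_", used$well), each = n_m),
      sample_kind = rep(ifelse(is_blank, "blank", "study"), each = n_m),
      plate_id = plate_id,
      well = rep(used$well, each = n_m),
      metabolite_id = rep(mets, times = nrow(used)),
      value = vals,
      nominal_amount = NA_real_,
      scale = "raw"
    )

    # lyophilized reference replicates: baseline + batch + technical noise
    ref_log <- matrix(log_baseline + batch[i, ], n_reference, n_m, byrow = TRUE) +
      matrix(stats::rnorm(n_reference * n_m), n_reference, n_m) * noise$sigma_tech
    ref_tbl <- tibble::tibble(
      sample_id = rep(sprintf("%s_ref_%d", plate_id, seq_len(n_reference)), each = n_m),
      sample_kind = "reference",
      plate_id = plate_id,
      well = NA_character_,
      metabolite_id = rep(mets, times = n_reference),
      value = as.vector(t(10^ref_log)),
      nominal_amount = NA_real_,
      scale = "raw"
    )

    # reference concentration series: value proportional to nominal amount
    nominals <- rep(series_nominals, each = n_series_rep)
    ser_log <- matrix(log_baseline + batch[i, ], length(nominals), n_m, byrow = TRUE) +
      log10(nominals) +
      matrix(stats::rnorm(length(nominals) * n_m),
             length(nominals), n_m) * noise$sigma_tech
    ser_tbl <- tibble::tibble(
      sample_id = rep(sprintf("%s_series_%g_%d", plate_id, nominals,
                              rep(seq_len(n_series_rep), times = length(series_nominals))),
                      each = n_m),
      sample_kind = "reference_series",
      plate_id = plate_id,
      well = NA_character_,
      metabolite_id = rep(mets, times = length(nominals)),
      value = as.vector(t(10^ser_log)),
      nominal_amount = rep(nominals, each = n_m),
      scale = "raw"
    )

    measurements[[i]] <- dplyr::bind_rows(study_tbl, ref_tbl, ser_tbl)

    doses <- ec_from_fit(truth_fit, c(1, 5, 15, 50, 85))
    mu <- w13_response(doses, truth_fit)
    viability[[i]] <- tibble::tibble(
      substance_id = sub,
      concentration_uM = rep(doses, each = design$n_per_conc),
      level = rep(1:5, each = design$n_per_conc),
      replicate = rep(seq_len(design$n_per_conc), times = 5),
      viability_pct = rep(mu, each = design$n_per_conc) +
        stats::rnorm(5 * design$n_per_conc) * viability_sd
    )
  }

  meas <- dplyr::bind_rows(measurements)
  validate_measurements(meas)
  names(layouts) <- paste0("plate_", substances$substance_id)
  structure(
    list(
      panel = panel,
      layouts = layouts,
      layout_table = dplyr::bind_rows(layouts),
      measurements = meas,
      viability = dplyr::bind_rows(viability),
      truth = list(
        substances = substances,
        log_baseline = log_baseline,
        batch = batch,
        cellnum = cellnum_truth,
        signatures = signatures,
        noise = noise,
        design = design,
        blank_fraction = blank_fraction,
        positive_scaling = positive_scaling,
        seed = seed
      )
    ),
    class = "simulated_experiment"
  )
}

#' @export
print.simulated_experiment <- function(x, ...) {
  cat(sprintf(
    "Simulated plate experiment: %d substance(s), %d analytes, %d measurement records\n",
    length(x$layouts), nrow(x$panel), nrow(x$measurements)
  ))
  invisible(x)
}
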