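#' Default pipeline run configuration
#'
#' Every field has a default; [load_run_config()] rejects unknown keys.
#' Fields: `seed` (fans out to per-stage substreams so toggling one stage
#' does not perturb another's randomness), `alpha` and `adjust` for the
#' differential tests, `viability_threshold` (percent, for the
#' MoA-concentration rule), `noise` overrides for [noise_model()],
#' `design` overrides for [default_plate_design()], `n_bootstrap` and
#' `pca_components` for the multivariate stage, `dropout_rate`, and
#' boolean stage toggles under `stages`.
#'
#' @return Nested named list.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    alpha = 0.05,
    adjust = "none",
    viability_threshold = 80,
    dropout_rate = 0,
    noise = list(sigma_tech = 0.040, sigma_bio = 0.018,
                 batch_sd = 0.05, cellnum_sd = 0.03),
    design = list(n_levels = 5L, n_per_conc = 6L, n_vehicle = 12L,
                  n_positive = 6L, n_blank = 6L),
    n_bootstrap = 1000L,
    pca_components = 10L,
    stages = list(qc = TRUE, stats = TRUE, pca = TRUE, hca = TRUE,
                  fingerprint = TRUE)
  )
}

merge_config <- function(defaults, overrides, path = character()) {
  for (key in names(overrides)) {
    if (!key %in% names(defaults)) {
      stop("unknown config key: ", paste(c(path, key), collapse = "."))
    }
    if (is.list(defaults[[key]]) && is.list(overrides[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], overrides[[key]], c(path, key))
    } else {
      defaults[[key]] <- overrides[[key]]
    }
  }
  defaults
}

#' Load a pipeline configuration
#'
#' Reads a YAML file of overrides and merges it onto
#' [default_run_config()]; unknown keys are rejected.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides Named list applied after the file.
#' @return Complete configuration list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  config <- default_run_config()
  if (!is.null(path)) config <- merge_config(config, yaml::read_yaml(path))
  merge_config(config, overrides)
}

stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, hca = 211L, classify = 307L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full plate-metabolomics pipeline
#'
#' Orchestrates simulate -> dose-response -> QC -> normalize -> stats ->
#' PCA/HCA -> fingerprints on a synthetic seven-substance experiment,
#' writing every stage's artifact plus a manifest (config hash, seed,
#' record counts, file checksums) into `out_dir`. Identical config and
#' seed yield byte-identical outputs.
#'
#' @param config Configuration from [load_run_config()] /
#'   [default_run_config()].
#' @param out_dir Output directory (created if missing).
#' @param substances Study design tibble (default
#'   [default_study_substances()]).
#' @param quiet Suppress stage messages.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(),
                         out_dir = tempfile("moaplate_run_"),
                         substances = default_study_substances(),
                         quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  counts <- list()

  # --- simulate -------------------------------------------------------
  noise <- do.call(noise_model, config$noise)
  design <- do.call(default_plate_design, config$design)
  experiment <- generate_experiment(
    substances, noise = noise, design = design,
    dropout_rate = config$dropout_rate,
    seed = stage_seed(config$seed, "simulate")
  )
  write_panel(experiment$panel, file.path(out_dir, "panel.csv"))
  write_csv_exact(experiment$layout_table, file.path(out_dir, "layouts.csv"))
  write_measurement_table(experiment$measurements, file.path(out_dir, "measurements_raw.csv"))
  write_viability_table(experiment$viability, file.path(out_dir, "viability.csv"))
  counts$measurement_records <- nrow(experiment$measurements)
  counts$panel_metabolites <- nrow(experiment$panel)
  say("simulate: %d substances, %d measurement records",
      nrow(substances), nrow(experiment$measurements))

  # --- dose-response --------------------------------------------------
  fits <- fit_viability_table(experiment$viability)
  fits_flat <- fits[c("substance_id", "b", "d", "e", "residual_sse", "converged")]
  ec_mat <- do.call(rbind, fits$ec)
  colnames(ec_mat) <- paste0("EC", c(1, 5, 15, 50, 85))
  rounded <- lapply(fits$ec, function(ec) {
    tryCatch(select_test_concentrations(ec), error = function(e) rep(NA_real_, 5))
  })
  rd_mat <- do.call(rbind, rounded)
  colnames(rd_mat) <- paste0("C", 1:5)
  write_csv_exact(dplyr::bind_cols(fits_flat, tibble::as_tibble(ec_mat),
                                   tibble::as_tibble(rd_mat)),
                  file.path(out_dir, "dose_response.csv"))
  say("dose-response: fitted %d substances", nrow(fits))

  # selected MoA-analysis level per substance from simulated viability
  viab_means <- dplyr::summarise(
    dplyr::group_by(experiment$viability, .data$substance_id, .data$level),
    mean_viability = mean(.data$viability_pct), .groups = "drop"
  )
  selected_levels <- vapply(split(viab_means, viab_means$substance_id), function(v) {
    select_moa_concentration(v$mean_viability[order(v$level)],
                             threshold = config$viability_threshold)
  }, integer(1))
  counts$selected_levels <- as.list(selected_levels)

  # --- qc -------------------------------------------------------------
  qc <- NULL
  if (isTRUE(config$stages$qc)) {
    qc <- qc_report(experiment$measurements)
    write_qc_report(qc, file.path(out_dir, "qc_report.csv"))
    counts$qc_passed <- sum(qc$passed)
    say("qc: %d/%d metabolites pass", sum(qc$passed), nrow(qc))
  }

  # --- normalize ------------------------------------------------------
  ratio <- normalize_to_reference(experiment$measurements, qc = qc,
                                  layouts = experiment$layouts)
  normalized <- normalize_within_sample(ratio)
  write_measurement_table(normalized_to_table(normalized),
                          file.path(out_dir, "measurements_normalized.csv"))
  jsonlite::write_json(
    list(
      stage = normalized$stage,
      dropped = normalized$provenance$dropped,
      dropped_samples = normalized$provenance$dropped_samples,
      n_reference_medians = length(normalized$provenance$reference_medians)
    ),
    file.path(out_dir, "normalization_provenance.json"),
    auto_unbox = TRUE, digits = NA
  )
  counts$normalized_samples <- nrow(normalized$values)
  counts$normalized_metabolites <- ncol(normalized$values)
  say("normalize: %d samples x %d metabolites", nrow(normalized$values),
      ncol(normalized$values))

  # --- stats ----------------------------------------------------------
  results_per_substance <- NULL
  if (isTRUE(config$stages$stats)) {
    results_per_substance <- lapply(names(selected_levels), function(sub) {
      differential_profile(normalized, sub, selected_levels[[sub]],
                           alpha = config$alpha, adjust = config$adjust)
    })
    names(results_per_substance) <- names(selected_levels)
    all_results <- dplyr::bind_rows(results_per_substance)
    write_csv_exact(all_results, file.path(out_dir, "differential_results.csv"))

    veh_ids <- normalized$sample_info$sample_id[
      !is.na(normalized$sample_info$role) &
        normalized$sample_info$role == "vehicle_control"
    ]
    variability <- variability_report(
      normalized$values[veh_ids, , drop = FALSE], "vehicle_control"
    )
    write_csv_exact(variability, file.path(out_dir, "variability_report.csv"))

    enrichment <- class_enrichment(all_results, experiment$panel)
    write_csv_exact(enrichment, file.path(out_dir, "class_enrichment.csv"))
    counts$significant_per_substance <- lapply(results_per_substance, function(r) {
      sum(r$significant)
    })
    say("stats: %s significant metabolites per substance",
        paste(unlist(counts$significant_per_substance), collapse = "/"))
  }

  # --- multivariate ---------------------------------------------------
  profiles <- treatment_mean_profiles(normalized, selected_levels)
  if (isTRUE(config$stages$pca)) {
    pca <- run_pca(normalized, n_components = config$pca_components)
    scores <- dplyr::bind_cols(
      tibble::tibble(sample_id = rownames(pca$scores)),
      tibble::as_tibble(pca$scores)
    )
    write_csv_exact(scores, file.path(out_dir, "pca_scores.csv"))
    write_csv_exact(
      tibble::tibble(component = seq_along(pca$explained_variance_pct),
                     explained_variance_pct = pca$explained_variance_pct),
      file.path(out_dir, "pca_explained_variance.csv")
    )
    say("pca: PC1 explains %.1f%%", pca$explained_variance_pct[1])
  }
  hca <- NULL
  if (isTRUE(config$stages$hca)) {
    hca <- run_hca(profiles, n_bootstrap = config$n_bootstrap,
                   seed = stage_seed(config$seed, "hca"))
    hca_to_newick(hca, file.path(out_dir, "hca_tree.nwk"))
    say("hca: %d leaves, %d bootstrap replicates", length(hca$labels),
        hca$n_bootstrap)
  }

  # --- fingerprints ---------------------------------------------------
  n_fingerprints <- 0L
  if (isTRUE(config$stages$fingerprint) && !is.null(results_per_substance)) {
    moa_map <- stats::setNames(substances$moa_id, substances$substance_id)
    fingerprints <- lapply(split(names(moa_map), moa_map[names(moa_map)]), function(subs) {
      derive_fingerprint(results_per_substance[subs], moa_map[[subs[1]]])
    })
    write_fingerprints(fingerprints, file.path(out_dir, "fingerprints.csv"))
    general <- derive_general_markers(fingerprints)
    jsonlite::write_json(
      list(
        general_increased = general$increased,
        general_decreased = general$decreased,
        fingerprints = lapply(fingerprints, function(fp) {
          list(moa_id = fp$moa_id, increased = fp$increased,
               decreased = fp$decreased,
               member_substances = fp$member_substances)
        })
      ),
      file.path(out_dir, "fingerprint_summary.json"), auto_unbox = TRUE, digits = NA
    )
    n_fingerprints <- length(fingerprints)
    counts$n_fingerprints <- n_fingerprints
    say("fingerprint: %d MoA fingerprints, %d general markers",
        n_fingerprints, length(general$increased) + length(general$decreased))
  }

  # --- manifest -------------------------------------------------------
  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("moaplate")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    config = config,
    counts = counts,
    checksums = as.list(tools::md5sum(file.path(out_dir, files))),
    out_dir = out_dir
  )
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Summarize a pipeline run from its manifest
#'
#' Recomputes record counts from the artifact files, verifies their
#' checksums against the manifest, and returns a human-readable summary.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return List with `summary` (character lines), `counts`,
#'   `checksum_ok`, `tampered` (files whose checksum mismatches).
#' @export
describe_run <- function(run_dir) {
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path)) stop("no manifest.json in ", run_dir)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)

  tampered <- character()
  for (f in names(manifest$checksums)) {
    path <- file.path(run_dir, f)
    actual <- if (file.exists(path)) unname(tools::md5sum(path)) else NA_character_
    if (!identical(actual, manifest$checksums[[f]])) tampered <- c(tampered, f)
  }

  recomputed <- list()
  meas_path <- file.path(run_dir, "measurements_raw.csv")
  if (file.exists(meas_path) && !"measurements_raw.csv" %in% tampered) {
    recomputed$measurement_records <- nrow(read_measurement_table(meas_path))
  }
  qc_path <- file.path(run_dir, "qc_report.csv")
  if (file.exists(qc_path)) {
    qc <- utils::read.csv(qc_path)
    recomputed$qc_passed <- sum(qc$passed == "TRUE" | qc$passed == TRUE)
  }
  dr_path <- file.path(run_dir, "differential_results.csv")
  if (file.exists(dr_path)) {
    dr <- utils::read.csv(dr_path)
    recomputed$significant_per_substance <-
      lapply(split(dr, dr$substance_id), function(x) sum(x$significant == "TRUE" | x$significant == TRUE))
  }

  lines <- c(
    sprintf("Run %s (seed %s, config %s)", run_dir, manifest$seed, manifest$config_hash),
    sprintf("  stages with artifacts: %s", paste(names(manifest$checksums), collapse = ", ")),
    sprintf("  measurement records: %s", manifest$counts$measurement_records),
    sprintf("  metabolites passing QC: %s",
            manifest$counts$qc_passed %||% "(qc disabled)"),
    sprintf("  normalized matrix: %s samples x %s metabolites",
            manifest$counts$normalized_samples, manifest$counts$normalized_metabolites),
    if (length(tampered) > 0) {
      sprintf("  WARNING checksum mismatch: %s", paste(tampered, collapse = ", "))
    } else "  checksums verified"
  )
  list(
    summary = lines, counts = manifest$counts, recomputed = recomputed,
    checksum_ok = length(tampered) == 0, tampered = tampered
  )
}
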