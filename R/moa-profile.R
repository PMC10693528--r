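#' Derive a mode-of-action metabolite fingerprint
#'
#' A MoA fingerprint is the set of metabolites commonly changed across
#' every substance of the MoA: `increased` is the intersection over
#' member substances of their significantly increased metabolites,
#' `decreased` likewise for decreased. The intersection is strict —
#' adding a substance can only shrink the fingerprint — and a metabolite
#' with inconsistent directions across members is excluded. A
#' single-substance fingerprint is permitted but flagged
#' (`single_substance = TRUE`), since common change cannot be assessed.
#'
#' @param results_per_substance Named list (by substance_id) of
#'   differential-result tibbles at each substance's MoA-analysis
#'   concentration ([differential_profile()]).
#' @param moa_id Mode-of-action identifier.
#' @return Object of class `moa_fingerprint` with `increased`,
#'   `decreased`, `member_substances`.
#' @export
derive_fingerprint <- function(results_per_substance, moa_id) {
  if (length(results_per_substance) == 0) stop("no differential results supplied")
  up_sets <- lapply(results_per_substance, function(r) {
    r$metabolite_id[r$significant & r$direction == "up"]
  })
  down_sets <- lapply(results_per_substance, function(r) {
    r$metabolite_id[r$significant & r$direction == "down"]
  })
  increased <- sort(Reduce(intersect, up_sets))
  decreased <- sort(Reduce(intersect, down_sets))
  structure(
    list(
      moa_id = moa_id,
      increased = increased,
      decreased = decreased,
      member_substances = names(results_per_substance),
      single_substance = length(results_per_substance) == 1
    ),
    class = "moa_fingerprint"
  )
}

#' @export
print.moa_fingerprint <- function(x, ...) {
  cat(sprintf(
    "MoA fingerprint '%s' (%d substance%s): %d increased, %d decreased%s\n",
    x$moa_id, length(x$member_substances),
    if (length(x$member_substances) == 1) "" else "s",
    length(x$increased), length(x$decreased),
    if (isTRUE(x$single_substance)) " [single-substance: not a common-change set]" else ""
  ))
  invisible(x)
}

#' General (MoA-nonspecific) hepatotoxicity markers
#'
#' Metabolites present with the same direction in every MoA fingerprint
#' cannot be regarded as MoA specific; they form the general
#' hepatotoxicity marker set. The returned object also carries a
#' "specific-only" view of each input fingerprint with the general
#' markers removed.
#'
#' @param fingerprints List of >= 2 [derive_fingerprint()] objects.
#' @return Object of class `general_markers` with `increased`,
#'   `decreased` and `specific_fingerprints`.
#' @export
derive_general_markers <- function(fingerprints) {
  if (length(fingerprints) < 2) stop("need at least 2 fingerprints")
  increased <- sort(Reduce(intersect, lapply(fingerprints, `[[`, "increased")))
  decreased <- sort(Reduce(intersect, lapply(fingerprints, `[[`, "decreased")))
  specific <- lapply(fingerprints, function(fp) {
    fp$increased <- setdiff(fp$increased, increased)
    fp$decreased <- setdiff(fp$decreased, decreased)
    fp
  })
  names(specific) <- vapply(fingerprints, `[[`, character(1), "moa_id")
  structure(
    list(increased = increased, decreased = decreased,
         specific_fingerprints = specific),
    class = "general_markers"
  )
}

#' @export
print.general_markers <- function(x, ...) {
  cat(sprintf(
    "General hepatotoxicity markers: %d increased (%s), %d decreased (%s)\n",
    length(x$increased), paste(x$increased, collapse = ", "),
    length(x$decreased), paste(x$decreased, collapse = ", ")
  ))
  invisible(x)
}

#' Build a PC-space mode-of-action reference
#'
#' Runs PCA on reference treatment-mean profiles (substances x
#' metabolites log10 ratios) and computes per-MoA centroids in the space
#' of the first `n_components` score dimensions, for nearest-centroid
#' classification of new compounds.
#'
#' @param profiles Substances x metabolites matrix
#'   ([treatment_mean_profiles()]).
#' @param moa_map Named character vector, substance_id -> moa_id.
#' @param n_components Score dimensions used (default 3, mirroring the
#'   PC1-PC3 separation of the three reference MoAs).
#' @return Object of class `moa_reference` with `pca`, `centroids`,
#'   `n_components`.
#' @export
build_moa_reference <- function(profiles, moa_map, n_components = 3) {
  missing_sub <- setdiff(rownames(profiles), names(moa_map))
  if (length(missing_sub) > 0) {
    stop("no moa_id for substances: ", paste(missing_sub, collapse = ", "))
  }
  # profiles are already log10 ratios; PCA runs on the linear-ratio scale
  # container convention, so back-transform before handing over.
  # Centered-only PCA: mean profiles share one dimensionless scale, and
  # autoscaling would amplify analytes carrying no treatment signal.
  pca <- run_pca(10^profiles, n_components = min(n_components, nrow(profiles) - 1),
                 scale_unit = FALSE)
  k <- ncol(pca$scores)
  moa <- moa_map[rownames(pca$scores)]
  centroids <- do.call(rbind, lapply(split(seq_along(moa), moa), function(idx) {
    colMeans(pca$scores[idx, , drop = FALSE])
  }))
  structure(
    list(pca = pca, centroids = centroids, n_components = k, moa_map = moa_map),
    class = "moa_reference"
  )
}

#' Project a profile into a reference PC space
#'
#' @param profile Named numeric vector of log10 ratios per metabolite.
#' @param reference A [build_moa_reference()] object.
#' @param min_overlap Minimum fraction of the reference loadings'
#'   metabolites the profile must cover (default 0.8).
#' @return Score vector in the reference space.
#' @export
project_profile <- function(profile, reference, min_overlap = 0.8) {
  pca <- reference$pca
  mets <- rownames(pca$loadings)
  present <- intersect(names(profile)[!is.na(profile)], mets)
  if (length(present) / length(mets) < min_overlap) {
    stop(sprintf(
      "profile covers only %.0f%% of reference metabolites (need >= %.0f%%)",
      100 * length(present) / length(mets), 100 * min_overlap
    ))
  }
  x <- stats::setNames(pca$center, mets)  # missing analytes fall back to the center
  x[present] <- profile[present]
  z <- (x - pca$center) / pca$scale
  drop(z %*% pca$loadings)
}

#' Classify a compound by nearest MoA centroid
#'
#' Projects a compound's treatment-mean metabolite profile into the
#' reference PC space and assigns the MoA of the nearest centroid
#' (Euclidean distance over the first `n_components` scores). When a
#' null-distance threshold is supplied (e.g. the 95th percentile of
#' distances of no-effect profiles), classifications whose nearest
#' distance exceeds it are flagged low-confidence.
#'
#' @param profile Named numeric vector of log10 ratios.
#' @param reference A [build_moa_reference()] object.
#' @param null_threshold Optional distance above which the call is
#'   flagged low-confidence.
#' @param min_overlap Passed to [project_profile()].
#' @return List with `moa_id`, `distances` (named, all MoAs), `scores`,
#'   `low_confidence`.
#' @export
classify_compound <- function(profile, reference, null_threshold = NULL,
                              min_overlap = 0.8) {
  z <- project_profile(profile, reference, min_overlap = min_overlap)
  d <- apply(reference$centroids, 1, function(cen) sqrt(sum((z - cen)^2)))
  best <- names(d)[which.min(d)]
  list(
    moa_id = best,
    distances = d,
    scores = z,
    low_confidence = if (is.null(null_threshold)) NA else min(d) > null_threshold
  )
}

#' Serialize fingerprints to a long CSV
#'
#' @param fingerprints List of [derive_fingerprint()] objects.
#' @param path Output CSV (`moa_id`, `metabolite_id`, `direction`).
#' @export
write_fingerprints <- function(fingerprints, path) {
  rows <- lapply(fingerprints, function(fp) {
    tibble::tibble(
      moa_id = fp$moa_id,
      metabolite_id = c(fp$increased, fp$decreased),
      direction = c(rep("up", length(fp$increased)), rep("down", length(fp$decreased)))
    )
  })
  write_csv_exact(dplyr::bind_rows(rows), path)
}
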