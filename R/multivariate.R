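#' PCA of log10 normalized ratios
#'
#' Principal component analysis of the log10-transformed ratio matrix
#' with column-wise mean centering and unit-variance (standard) scaling.
#' Columns that are constant after the log transform are dropped (logged
#' in the result); missing values are imputed with the column mean of the
#' log10 ratios, with the imputation count logged.
#'
#' @param matrix A [normalized_matrix()] or a plain samples x metabolites
#'   matrix of positive ratios.
#' @param n_components Components to retain (default: all).
#' @param scale_unit Scale columns to unit variance (default `TRUE`, the
#'   standard-scaling convention for sample-level PCA). Centered-only
#'   (covariance) PCA is used for treatment-mean profiles, where
#'   autoscaling would inflate analytes that carry no treatment signal.
#' @return Object of class `plate_pca` with `scores`, `loadings`,
#'   `explained_variance_pct`, `center`, `scale`, `dropped_columns`,
#'   `n_imputed`, `sample_info`.
#' @export
run_pca <- function(matrix, n_components = NULL, scale_unit = TRUE) {
  values <- if (inherits(matrix, "normalized_matrix")) matrix$values else matrix
  info <- if (inherits(matrix, "normalized_matrix")) matrix$sample_info else NULL
  if (nrow(values) < 2 || ncol(values) < 2) stop("need >= 2 samples and >= 2 metabolites")
  x <- log10(values)

  n_imputed <- sum(is.na(x))
  if (n_imputed > 0) {
    cm <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- cm[idx[, 2]]
  }
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[!is.finite(sds) | sds == 0]
  if (length(dropped) > 0) x <- x[, !colnames(x) %in% dropped, drop = FALSE]
  if (ncol(x) < 2) stop("fewer than 2 non-constant metabolites")

  pc <- stats::prcomp(x, center = TRUE, scale. = scale_unit)
  k <- min(n_components %||% ncol(pc$x), ncol(pc$x))
  expl <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  scale_vec <- if (isFALSE(pc$scale)) {
    stats::setNames(rep(1, ncol(x)), colnames(x))
  } else {
    pc$scale
  }
  structure(
    list(
      scores = pc$x[, seq_len(k), drop = FALSE],
      loadings = pc$rotation[, seq_len(k), drop = FALSE],
      explained_variance_pct = expl[seq_len(k)],
      sdev = pc$sdev,
      center = pc$center,
      scale = scale_vec,
      dropped_columns = dropped,
      n_imputed = n_imputed,
      sample_info = info
    ),
    class = "plate_pca"
  )
}

#' @export
print.plate_pca <- function(x, ...) {
  cat(sprintf(
    "PCA: %d samples, %d components; PC1-PC3 explain %s%%\n",
    nrow(x$scores), ncol(x$scores),
    paste(sprintf("%.1f", utils::head(x$explained_variance_pct, 3)), collapse = "/")
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# leaf sets of every internal node of an hclust merge matrix,
# as sorted character vectors of leaf labels
hclust_leaf_sets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    take <- function(j) if (j < 0) hc$labels[-j] else sets[[j]]
    sets[[i]] <- sort(c(take(hc$merge[i, 1]), take(hc$merge[i, 2])))
  }
  sets
}

#' Hierarchical clustering with bootstrap cluster probabilities
#'
#' Agglomerative clustering of entity profiles with Ward.D2 linkage on
#' Manhattan distances, plus ordinary bootstrap probabilities (BP): for
#' each internal node of the dendrogram, the fraction of trees built from
#' metabolite-resampled (columns, with replacement) replicates in which
#' the node's exact leaf set reappears.
#'
#' @param profiles Entities x metabolites matrix of log10 ratios (rows
#'   are the clustered entities; input is used as-is, no further log
#'   transform).
#' @param n_bootstrap Bootstrap replicates (default 10000).
#' @param seed Optional integer seed for the resampling.
#' @return Object of class `plate_hca` with the `hclust` tree, per-node
#'   `bootstrap_probability`, node `leaf_sets` and `n_bootstrap`.
#' @export
run_hca <- function(profiles, n_bootstrap = 10000, seed = NULL) {
  if (nrow(profiles) < 3) stop("need at least 3 entities to cluster")
  if (is.null(rownames(profiles))) rownames(profiles) <- paste0("entity_", seq_len(nrow(profiles)))
  hc <- stats::hclust(stats::dist(profiles, method = "manhattan"), method = "ward.D2")
  sets <- hclust_leaf_sets(hc)
  keys <- vapply(sets, paste, character(1), collapse = "\r")

  bp <- rep(0, length(sets))
  if (n_bootstrap > 0) {
    if (!is.null(seed)) withr::local_seed(seed)
    p <- ncol(profiles)
    for (b in seq_len(n_bootstrap)) {
      cols <- sample.int(p, p, replace = TRUE)
      hb <- stats::hclust(
        stats::dist(profiles[, cols, drop = FALSE], method = "manhattan"),
        method = "ward.D2"
      )
      kb <- vapply(hclust_leaf_sets(hb), paste, character(1), collapse = "\r")
      bp <- bp + (keys %in% kb)
    }
    bp <- bp / n_bootstrap
  }
  structure(
    list(
      hclust = hc, labels = hc$labels, leaf_sets = sets,
      bootstrap_probability = bp, n_bootstrap = n_bootstrap
    ),
    class = "plate_hca"
  )
}

#' @export
print.plate_hca <- function(x, ...) {
  cat(sprintf(
    "HCA (Ward.D2 / Manhattan): %d leaves, %d bootstrap replicates\n",
    length(x$labels), x$n_bootstrap
  ))
  invisible(x)
}

#' Export an HCA tree as Newick with bootstrap node labels
#'
#' @param hca A `plate_hca` object.
#' @param path Optional file to write to.
#' @return Newick string (invisibly when `path` given).
#' @export
hca_to_newick <- function(hca, path = NULL) {
  hc <- hca$hclust
  build <- function(i, parent_h) {
    if (i < 0) {
      sprintf("%s:%g", hc$labels[-i], parent_h)
    } else {
      h <- hc$height[i]
      sprintf(
        "(%s,%s)%g:%g",
        build(hc$merge[i, 1], h), build(hc$merge[i, 2], h),
        hca$bootstrap_probability[i], parent_h - h
      )
    }
  }
  n <- nrow(hc$merge)
  nwk <- sprintf(
    "(%s,%s)%g;",
    build(hc$merge[n, 1], hc$height[n]), build(hc$merge[n, 2], hc$height[n]),
    hca$bootstrap_probability[n]
  )
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Treatment-mean metabolite profiles
#'
#' Per-substance mean log10 normalized ratio per metabolite at the
#' selected (MoA analysis) concentration level, the entity profiles used
#' for mode-of-action clustering and fingerprinting.
#'
#' @param matrix A [normalized_matrix()] with role metadata.
#' @param selected_levels Named integer vector, substance_id -> level.
#' @return Substances x metabolites matrix of mean log10 ratios.
#' @export
treatment_mean_profiles <- function(matrix, selected_levels) {
  info <- matrix$sample_info
  if (!"role" %in% names(info)) {
    stop("sample_info lacks well roles; pass layouts to normalize_to_reference()")
  }
  out <- lapply(names(selected_levels), function(sub) {
    lvl <- selected_levels[[sub]]
    ids <- info$sample_id[
      !is.na(info$role) & info$role == "treatment" &
        info$substance_id == sub & info$concentration_level == lvl
    ]
    ids <- ids[!is.na(ids)]
    if (length(ids) == 0) stop("no wells for ", sub, " at level ", lvl)
    colMeans(log10(matrix$values[ids, , drop = FALSE]), na.rm = TRUE)
  })
  profiles <- do.call(rbind, out)
  rownames(profiles) <- names(selected_levels)
  profiles
}
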