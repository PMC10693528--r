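#' Normalized data matrix
#'
#' Container for the samples x metabolites grid of dimensionless ratios
#' produced by the two-tier normalization, together with its stage
#' (`ratio` after reference normalization, `ratio_cellnorm` after the
#' within-sample median step), sample metadata, and provenance (the
#' reference medians and per-sample medians used, plus dropped analytes
#' and samples with reasons).
#'
#' @param values Numeric matrix, samples in rows, metabolites in columns.
#' @param stage `"ratio"` or `"ratio_cellnorm"`.
#' @param sample_info Tibble keyed by `sample_id` with `plate_id`,
#'   `well`, and (when layouts were supplied) `role`, `substance_id`,
#'   `concentration_level`.
#' @param provenance List of normalization provenance records.
#' @return Object of class `normalized_matrix`.
#' @export
normalized_matrix <- function(values, stage, sample_info, provenance = list()) {
  stopifnot(stage %in% c("ratio", "ratio_cellnorm"))
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  structure(
    list(values = values, stage = stage, sample_info = sample_info,
         provenance = provenance),
    class = "normalized_matrix"
  )
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf(
    "Normalized matrix (%s): %d samples x %d metabolites\n",
    x$stage, nrow(x$values), ncol(x$values)
  ))
  invisible(x)
}

as_layout_table <- function(layouts) {
  if (is.null(layouts)) return(NULL)
  if (is.data.frame(layouts)) return(layouts)
  dplyr::bind_rows(layouts)
}

#' Reference-sample ratio normalization
#'
#' First normalization tier: each study value is divided by the median of
#' the same metabolite across the lyophilized reference samples measured
#' on the same plate, yielding dimensionless ratios that cancel per-plate
#' (batch) instrumental factors. Analytes failing QC are dropped before
#' normalization; analytes whose reference median is zero or missing on
#' some plate are dropped with a logged reason.
#'
#' @param table Raw measurement tibble (study, blank, reference,
#'   reference_series records).
#' @param qc Optional QC report from [qc_report()]; only passing analytes
#'   are kept.
#' @param layouts Optional plate layout(s) used to attach well roles to
#'   the sample metadata.
#' @return A [normalized_matrix()] at stage `"ratio"` containing the
#'   study samples.
#' @export
normalize_to_reference <- function(table, qc = NULL, layouts = NULL) {
  if (measurement_scale(table) != "raw") stop("expected a raw-scale table")
  keep_mets <- unique(table$metabolite_id)
  dropped <- list()
  if (!is.null(qc)) {
    passing <- qc$metabolite_id[qc$passed]
    dropped$qc_failed <- setdiff(keep_mets, passing)
    keep_mets <- intersect(keep_mets, passing)
  }

  ref <- table[table$sample_kind == "reference" & table$metabolite_id %in% keep_mets, ]
  if (nrow(ref) == 0) stop("no reference samples in table")
  ref_med <- stats::aggregate(
    value ~ plate_id + metabolite_id, data = ref,
    FUN = stats::median, na.rm = TRUE, na.action = stats::na.pass
  )

  bad <- ref_med$metabolite_id[is.na(ref_med$value) | ref_med$value <= 0]
  if (length(bad) > 0) {
    dropped$reference_median_invalid <- unique(bad)
    keep_mets <- setdiff(keep_mets, bad)
    ref_med <- ref_med[!ref_med$metabolite_id %in% bad, ]
  }
  if (length(keep_mets) == 0) stop("no metabolites left after QC/reference filtering")

  study <- table[table$sample_kind == "study" & table$metabolite_id %in% keep_mets, ]
  merged <- dplyr::left_join(
    study, stats::setNames(ref_med, c("plate_id", "metabolite_id", "ref_median")),
    by = c("plate_id", "metabolite_id")
  )
  no_ref <- unique(merged$metabolite_id[is.na(merged$ref_median)])
  if (length(no_ref) > 0) {
    dropped$no_reference_on_plate <- no_ref
    merged <- merged[!merged$metabolite_id %in% no_ref, ]
    keep_mets <- setdiff(keep_mets, no_ref)
  }
  merged$ratio <- merged$value / merged$ref_median

  wide <- tidyr::pivot_wider(
    merged[c("sample_id", "metabolite_id", "ratio")],
    names_from = "metabolite_id", values_from = "ratio"
  )
  values <- as.matrix(wide[, -1])
  rownames(values) <- wide$sample_id
  values <- values[, keep_mets[keep_mets %in% colnames(values)], drop = FALSE]

  info <- dplyr::distinct(study[c("sample_id", "plate_id", "well")])
  lt <- as_layout_table(layouts)
  if (!is.null(lt)) {
    info <- dplyr::left_join(
      info,
      lt[c("plate_id", "well", "role", "substance_id", "concentration_level")],
      by = c("plate_id", "well")
    )
  }
  info <- info[match(rownames(values), info$sample_id), ]

  ref_medians <- stats::setNames(ref_med$value, paste(ref_med$plate_id, ref_med$metabolite_id))
  normalized_matrix(
    values, "ratio", tibble::as_tibble(info),
    provenance = list(reference_medians = ref_medians, dropped = dropped)
  )
}

#' Within-sample median normalization
#'
#' Second normalization tier: each sample's ratios are divided by that
#' sample's median across the included metabolites, correcting for
#' per-well differences in cell number (a common multiplicative factor
#' across all analytes of a well). After this step every sample's median
#' is exactly 1; the step is idempotent and invariant to rescaling any
#' single sample.
#'
#' @param matrix A [normalized_matrix()] at stage `"ratio"` (applying it
#'   to `"ratio_cellnorm"` input is a no-op by idempotence).
#' @param min_metabolites Minimum non-missing analytes a sample needs
#'   (default 3); samples below are dropped with a logged reason.
#' @return A [normalized_matrix()] at stage `"ratio_cellnorm"`.
#' @export
normalize_within_sample <- function(matrix, min_metabolites = 3) {
  stopifnot(inherits(matrix, "normalized_matrix"))
  values <- matrix$values
  n_present <- rowSums(!is.na(values))
  drop_samples <- rownames(values)[n_present < min_metabolites]
  if (length(drop_samples) > 0) {
    values <- values[!rownames(values) %in% drop_samples, , drop = FALSE]
  }
  if (nrow(values) == 0) stop("no samples left after dropping all-missing samples")
  med <- apply(values, 1, stats::median, na.rm = TRUE)
  values <- sweep(values, 1, med, "/")
  info <- matrix$sample_info[matrix$sample_info$sample_id %in% rownames(values), ]
  prov <- matrix$provenance
  prov$sample_medians <- med
  prov$dropped_samples <- drop_samples
  normalized_matrix(values, "ratio_cellnorm", info, prov)
}

#' Export a normalized matrix as a long measurement table
#'
#' @param matrix A [normalized_matrix()].
#' @return Long tibble in the measurement-table dialect
#'   (`sample_kind = "study"`, `scale` from the stage).
#' @export
normalized_to_table <- function(matrix) {
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(
      tibble::tibble(sample_id = rownames(matrix$values)),
      tibble::as_tibble(matrix$values)
    ),
    cols = -1, names_to = "metabolite_id", values_to = "value"
  )
  info <- matrix$sample_info[c("sample_id", "plate_id", "well")]
  out <- dplyr::left_join(long, info, by = "sample_id")
  tibble::tibble(
    sample_id = out$sample_id,
    sample_kind = "study",
    plate_id = out$plate_id,
    well = out$well,
    metabolite_id = out$metabolite_id,
    value = out$value,
    nominal_amount = NA_real_,
    scale = matrix$stage
  )
}
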