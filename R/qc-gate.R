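#' Per-metabolite quality-control metrics
#'
#' Computes, from a raw long-format measurement table, the metrics the QC
#' gate evaluates for one analyte:
#' \itemize{
#'   \item coverage: fraction of study samples with a present
#'     (non-missing) value; blanks are not counted in the denominator;
#'   \item blank_contribution: median blank signal / median study signal;
#'   \item slope and linearity_r2: ordinary least squares (with
#'     intercept, linear scale) of the reference concentration-series
#'     signal on nominal amount;
#'   \item variability_rsd: back-transformed RSD of the lyophilized
#'     reference replicates, `1 - 10^(-SD of log10 values)`.
#' }
#' A metric that cannot be computed (no blanks, no series, fewer than two
#' positive reference replicates, zero study median) is returned as `NA`
#' and recorded in `non_computable`; the gate fails such analytes with a
#' named reason.
#'
#' @param table Raw measurement tibble.
#' @param metabolite_id Analyte to evaluate.
#' @return One-row tibble of metrics (verdict columns unset).
#' @export
compute_qc_metrics <- function(table, metabolite_id) {
  if (measurement_scale(table) != "raw") stop("QC metrics are computed on raw data")
  x <- table[table$metabolite_id == metabolite_id, ]
  if (nrow(x) == 0) stop("metabolite not in table: ", metabolite_id)
  non_computable <- character()

  study <- x$value[x$sample_kind == "study"]
  coverage <- if (length(study) == 0) {
    non_computable <- c(non_computable, "coverage")
    NA_real_
  } else {
    mean(!is.na(study))
  }

  blank <- x$value[x$sample_kind == "blank"]
  study_med <- stats::median(study, na.rm = TRUE)
  blank_contribution <- if (length(blank) == 0 || !is.finite(study_med) || study_med <= 0) {
    non_computable <- c(non_computable, "blank_contribution")
    NA_real_
  } else {
    stats::median(blank, na.rm = TRUE) / study_med
  }

  ser <- x[x$sample_kind == "reference_series" & !is.na(x$value), ]
  if (nrow(ser) >= 3 && length(unique(ser$nominal_amount)) >= 2) {
    fit <- stats::lm(value ~ nominal_amount, data = ser)
    slope <- unname(stats::coef(fit)[2])
    ss_tot <- sum((ser$value - mean(ser$value))^2)
    linearity_r2 <- if (ss_tot == 0) {
      NA_real_  # constant response: linearity undefined
    } else {
      1 - sum(stats::resid(fit)^2) / ss_tot
    }
    if (is.na(linearity_r2)) non_computable <- c(non_computable, "linearity")
  } else {
    non_computable <- c(non_computable, "linearity")
    slope <- NA_real_
    linearity_r2 <- NA_real_
  }

  ref <- x$value[x$sample_kind == "reference" & !is.na(x$value)]
  variability_rsd <- if (length(ref) >= 2 && all(ref > 0)) {
    rsd_from_replicates(ref)$rsd
  } else {
    non_computable <- c(non_computable, "variability")
    NA_real_
  }

  tibble::tibble(
    metabolite_id = metabolite_id,
    coverage = coverage,
    blank_contribution = blank_contribution,
    slope = slope,
    linearity_r2 = linearity_r2,
    variability_rsd = variability_rsd,
    non_computable = list(non_computable),
    passed = NA,
    failed_criteria = list(character())
  )
}

#' Apply the QC pass/fail gate
#'
#' An analyte passes when coverage > 80%, blank contribution < 40%,
#' slope > 0, and any of four linearity/variability conditions holds:
#' (a) R2 > 0.8 and RSD < 0.3; (b) R2 > 0.64 and RSD < 0.3;
#' (c) R2 > 0.8 and RSD < 0.6; (d) R2 > 0.64 and RSD < 0.6.
#' As printed the four conditions are mutually redundant — their
#' disjunction collapses to condition (d) — but the gate records which
#' condition(s) fired for traceability. All thresholds are strict
#' inequalities. Failing analytes are excluded from all downstream
#' analysis; a non-computable metric fails with a named reason.
#'
#' @param record One-row metrics tibble from [compute_qc_metrics()].
#' @return The record with `passed`, `failed_criteria` and
#'   `conditions_met` filled.
#' @export
apply_qc_gate <- function(record) {
  failed <- character()
  nc <- record$non_computable[[1]]
  if (length(nc) > 0) failed <- c(failed, paste0("non_computable:", nc))

  chk <- function(value, ok, label) {
    if (is.na(value)) return(invisible(NULL))
    if (!ok) failed <<- c(failed, label)
    invisible(NULL)
  }
  chk(record$coverage, isTRUE(record$coverage > 0.8), "coverage <= 80%")
  chk(record$blank_contribution, isTRUE(record$blank_contribution < 0.4),
      "blank contribution >= 40%")
  chk(record$slope, isTRUE(record$slope > 0), "slope <= 0")

  r2 <- record$linearity_r2
  rsd <- record$variability_rsd
  conds <- character()
  if (!is.na(r2) && !is.na(rsd)) {
    if (r2 > 0.8 && rsd < 0.3) conds <- c(conds, "a")
    if (r2 > 0.64 && rsd < 0.3) conds <- c(conds, "b")
    if (r2 > 0.8 && rsd < 0.6) conds <- c(conds, "c")
    if (r2 > 0.64 && rsd < 0.6) conds <- c(conds, "d")
    if (length(conds) == 0) {
      failed <- c(failed, "linearity/variability: none of conditions a-d met")
    }
  }

  record$passed <- length(failed) == 0
  record$failed_criteria <- list(failed)
  record$conditions_met <- list(conds)
  record
}

#' QC report for every analyte of a measurement table
#'
#' @param table Raw measurement tibble.
#' @param metabolite_ids Analytes to evaluate (default: all in table).
#' @return Tibble, one gated [compute_qc_metrics()] row per analyte.
#' @export
qc_report <- function(table, metabolite_ids = unique(table$metabolite_id)) {
  dplyr::bind_rows(lapply(metabolite_ids, function(m) {
    apply_qc_gate(compute_qc_metrics(table, m))
  }))
}

#' Write a QC report CSV
#'
#' List-columns (`failed_criteria`, `conditions_met`, `non_computable`)
#' are collapsed with `";"`.
#'
#' @param report QC report tibble.
#' @param path Output CSV path.
#' @export
write_qc_report <- function(report, path) {
  flat <- report
  for (col in c("non_computable", "failed_criteria", "conditions_met")) {
    if (col %in% names(flat)) {
      flat[[col]] <- vapply(flat[[col]], paste, character(1), collapse = ";")
    }
  }
  write_csv_exact(flat, path)
}
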