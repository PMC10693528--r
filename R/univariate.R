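#' Welch two-sample test on log10 ratios
#'
#' Heteroscedastic (Welch) t test with Welch-Satterthwaite degrees of
#' freedom and a two-sided p value. Groups need at least two non-missing
#' values each and non-zero pooled variance; otherwise the result is
#' marked untestable (`NA` statistics) rather than raising, so callers
#' can exclude it from significance sets.
#'
#' @param group_a,group_b Numeric vectors (log10 ratios).
#' @return List with `t`, `df`, `p`, `testable`.
#' @export
welch_test <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (length(a) < 2 || length(b) < 2 ||
      (stats::var(a) == 0 && stats::var(b) == 0)) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_, testable = FALSE))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(
    t = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value, testable = TRUE
  )
}

#' Back-transformed relative standard deviation of replicates
#'
#' Variability of positive replicate signals is summarized on the log10
#' scale and back-transformed to a linear-scale relative standard
#' deviation via `RSD = 1 - 10^(-SDlog)`. For small SDs this
#' approximates the ordinary coefficient of variation
#' (`RSD ~ ln(10) * SDlog`).
#'
#' @param values Positive replicate values (>= 2).
#' @return List with `sd_log10` and `rsd`.
#' @export
rsd_from_replicates <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 replicate values")
  if (any(values <= 0)) stop("RSD back-transform requires strictly positive values")
  sd_log10 <- stats::sd(log10(values))
  list(sd_log10 = sd_log10, rsd = 1 - 10^(-sd_log10))
}

#' Variability report for a sample group
#'
#' Per-metabolite log10 SD and back-transformed RSD for a group of
#' samples (e.g. vehicle controls or reference replicates) of a
#' normalized matrix or raw table.
#'
#' @param values Samples x metabolites matrix of positive values.
#' @param group_id Label for the group.
#' @return Tibble `group_id`, `metabolite_id`, `sd_log10`, `rsd`.
#' @export
variability_report <- function(values, group_id = "group") {
  res <- lapply(colnames(values), function(m) {
    v <- values[, m]
    v <- v[!is.na(v) & v > 0]
    if (length(v) < 2) {
      tibble::tibble(group_id = group_id, metabolite_id = m,
                     sd_log10 = NA_real_, rsd = NA_real_)
    } else {
      r <- rsd_from_replicates(v)
      tibble::tibble(group_id = group_id, metabolite_id = m,
                     sd_log10 = r$sd_log10, rsd = r$rsd)
    }
  })
  dplyr::bind_rows(res)
}

#' Differential metabolite profile for one substance and level
#'
#' Compares treated wells of a substance at one concentration level with
#' the vehicle-control wells of the same plate(s) by Welch test on log10
#' normalized ratios. Fold change is `10^(mean log10 difference)`;
#' direction follows the sign of the mean difference for significant
#' analytes.
#'
#' @param matrix A [normalized_matrix()] whose `sample_info` carries well
#'   roles (supply `layouts` to [normalize_to_reference()]).
#' @param substance_id Substance to test.
#' @param level Concentration level (1-5).
#' @param alpha Significance level on the selected p value (default 0.05).
#' @param adjust `"none"` (default; significance on raw p) or `"bh"`
#'   (Benjamini-Hochberg across the profile's metabolites).
#' @return Tibble of per-metabolite `DifferentialResult` rows.
#' @export
differential_profile <- function(matrix, substance_id, level,
                                 alpha = 0.05, adjust = c("none", "bh")) {
  adjust <- match.arg(adjust)
  info <- matrix$sample_info
  if (!"role" %in% names(info)) {
    stop("sample_info lacks well roles; pass layouts to normalize_to_reference()")
  }
  treated_ids <- info$sample_id[
    !is.na(info$role) & info$role == "treatment" &
      info$substance_id == substance_id &
      info$concentration_level == level
  ]
  treated_ids <- treated_ids[!is.na(treated_ids)]
  plates <- unique(info$plate_id[info$sample_id %in% treated_ids])
  control_ids <- info$sample_id[
    !is.na(info$role) & info$role == "vehicle_control" & info$plate_id %in% plates
  ]
  if (length(treated_ids) < 2 || length(control_ids) < 2) {
    stop("need >= 2 treated and >= 2 vehicle samples for ", substance_id,
         " level ", level)
  }
  lt <- log10(matrix$values[treated_ids, , drop = FALSE])
  lc <- log10(matrix$values[control_ids, , drop = FALSE])

  res <- lapply(colnames(matrix$values), function(m) {
    a <- lt[, m]; b <- lc[, m]
    wt <- welch_test(a, b)
    mean_a <- mean(a, na.rm = TRUE)
    mean_b <- mean(b, na.rm = TRUE)
    diff <- mean_a - mean_b
    tibble::tibble(
      metabolite_id = m,
      substance_id = substance_id,
      concentration_level = as.integer(level),
      mean_log10_ratio_treated = mean_a,
      mean_log10_ratio_control = mean_b,
      fold_change = 10^diff,
      t_statistic = wt$t,
      degrees_freedom = wt$df,
      p_value = wt$p,
      testable = wt$testable
    )
  })
  out <- dplyr::bind_rows(res)
  out$adjusted_p <- if (adjust == "bh") stats::p.adjust(out$p_value, "BH") else NA_real_
  p_sel <- if (adjust == "bh") out$adjusted_p else out$p_value
  out$significant <- !is.na(p_sel) & p_sel < alpha & out$testable
  out$direction <- ifelse(
    !out$significant, "none",
    ifelse(out$fold_change > 1, "up", "down")
  )
  out
}

#' Ontology-class enrichment counts
#'
#' Counts, per ontology class of the panel, how many analytes were
#' tested, how many changed significantly, and the split into increased
#' and decreased. Optionally adds a hypergeometric over-representation p
#' value per class (off by default).
#'
#' @param results Differential results ([differential_profile()]).
#' @param panel Metabolite panel.
#' @param test Add a hypergeometric over-representation test per class.
#' @return Tibble `ontology_class`, `n_total`, `n_significant`, `n_up`,
#'   `n_down` (and `p_over` when `test = TRUE`).
#' @export
class_enrichment <- function(results, panel, test = FALSE) {
  missing_mets <- setdiff(results$metabolite_id, panel$metabolite_id)
  if (length(missing_mets) > 0) {
    stop("metabolites missing from panel: ",
         paste(utils::head(missing_mets, 5), collapse = ", "))
  }
  merged <- dplyr::left_join(
    results, panel[c("metabolite_id", "ontology_class")], by = "metabolite_id"
  )
  out <- dplyr::summarise(
    dplyr::group_by(merged, .data$ontology_class),
    n_total = dplyr::n(),
    n_significant = sum(.data$significant),
    n_up = sum(.data$direction == "up"),
    n_down = sum(.data$direction == "down"),
    .groups = "drop"
  )
  if (test) {
    N <- nrow(merged); K <- sum(merged$significant)
    out$p_over <- mapply(function(n_tot, n_sig) {
      stats::phyper(n_sig - 1, K, N - K, n_tot, lower.tail = FALSE)
    }, out$n_total, out$n_significant)
  }
  out
}
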