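#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

SAMPLE_KINDS <- c("study", "blank", "reference", "reference_series")
MEASUREMENT_SCALES <- c("raw", "ratio", "ratio_cellnorm")
WELL_ROLES <- c("treatment", "vehicle_control", "positive_control", "blank", "unused")

MEASUREMENT_COLUMNS <- c(
  "sample_id", "sample_kind", "plate_id", "well",
  "metabolite_id", "value", "nominal_amount", "scale"
)

#' Default metabolite ontology classes
#'
#' The twelve ontology classes used to group analytes of the targeted
#' HepG2 panel, spanning polar metabolites through lipid species, plus an
#' `"unknown"` class for analytes with defined analytical parameters but
#' no chemical identity.
#'
#' @return Character vector of 12 class names.
#' @export
default_ontology_classes <- function() {
  c(
    "amino acids and related",
    "carnitines and acylcarnitines",
    "lysophospholipids",
    "glycerophospholipids",
    "sphingolipids",
    "ceramides",
    "triacylglycerols",
    "sterols and steroids",
    "nucleobases and nucleosides",
    "vitamins and cofactors",
    "energy metabolism and organic acids",
    "unknown"
  )
}

#' Validate a metabolite panel
#'
#' A panel is a tibble with one row per analyte: `metabolite_id`,
#' `display_name`, `annotation_status` (one of `confirmed`, `plausible`,
#' `unknown`) and `ontology_class`.
#'
#' @param panel Panel tibble.
#' @param classes Allowed ontology classes (default
#'   [default_ontology_classes()]).
#' @return The panel, invisibly; errors on violation.
#' @export
validate_panel <- function(panel, classes = default_ontology_classes()) {
  required <- c("metabolite_id", "display_name", "annotation_status", "ontology_class")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0) {
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(panel$metabolite_id)) {
    dup <- unique(panel$metabolite_id[duplicated(panel$metabolite_id)])
    stop("duplicate metabolite_id in panel: ", paste(dup, collapse = ", "))
  }
  bad_status <- setdiff(unique(panel$annotation_status), c("confirmed", "plausible", "unknown"))
  if (length(bad_status) > 0 || anyNA(panel$annotation_status)) {
    stop("invalid annotation_status: ", paste(bad_status, collapse = ", "))
  }
  bad_class <- setdiff(unique(panel$ontology_class), classes)
  if (length(bad_class) > 0) {
    stop("ontology_class not in configured class list: ", paste(bad_class, collapse = ", "))
  }
  invisible(panel)
}

#' Build a 96-well plate layout
#'
#' Wells are laid out in the standard plate-reader convention (rows A-H,
#' columns 1-12). The outer rows and columns are left unused (filled with
#' PBS in the wet-lab design to limit evaporation); the 60 interior wells
#' hold the treatment series (default 6 replicates at each of 5
#' concentration levels), 12 vehicle controls, 6 positive controls and 6
#' blanks, leaving 6 interior wells unused.
#'
#' @param substance_id Substance dosed on the treatment wells.
#' @param plate_id Plate identifier.
#' @param design Design counts, see [default_plate_design()].
#' @return Tibble with columns `plate_id`, `row`, `column`, `well`,
#'   `role`, `substance_id`, `concentration_level`.
#' @export
build_plate_layout <- function(substance_id, plate_id = paste0("plate_", substance_id),
                               design = default_plate_design()) {
  rows <- LETTERS[1:8]
  grid <- expand.grid(row = rows, column = 1:12, stringsAsFactors = FALSE)
  grid <- grid[order(grid$column, grid$row), ]
  interior <- grid$row %in% rows[2:7] & grid$column %in% 2:11

  n_treat <- design$n_levels * design$n_per_conc
  roles <- c(
    rep("treatment", n_treat),
    rep("vehicle_control", design$n_vehicle),
    rep("positive_control", design$n_positive),
    rep("blank", design$n_blank)
  )
  n_interior <- sum(interior)
  if (length(roles) > n_interior) {
    stop("design requires ", length(roles), " wells but only ", n_interior,
         " interior wells are available")
  }
  roles <- c(roles, rep("unused", n_interior - length(roles)))

  layout <- tibble(
    plate_id = plate_id,
    row = grid$row,
    column = grid$column,
    well = paste0(grid$row, grid$column),
    role = "unused",
    substance_id = NA_character_,
    concentration_level = NA_integer_
  )
  layout$role[interior] <- roles
  is_treat <- layout$role == "treatment"
  layout$substance_id[is_treat] <- substance_id
  layout$concentration_level[is_treat] <-
    rep(seq_len(design$n_levels), each = design$n_per_conc)
  layout$substance_id[layout$role == "positive_control"] <- design$positive_substance
  as_tibble(layout)
}

#' Default plate design counts
#'
#' @param n_levels Number of concentration levels (5).
#' @param n_per_conc Treatment replicates per level (6).
#' @param n_vehicle Vehicle-control wells (12; 0.5% DMSO).
#' @param n_positive Positive-control wells (6; bezafibrate 1000 uM).
#' @param n_blank Blank wells (6; medium without cells).
#' @param positive_substance Identifier of the positive-control compound.
#' @return Named list of design counts.
#' @export
default_plate_design <- function(n_levels = 5L, n_per_conc = 6L, n_vehicle = 12L,
                                 n_positive = 6L, n_blank = 6L,
                                 positive_substance = "bezafibrate") {
  list(
    n_levels = as.integer(n_levels), n_per_conc = as.integer(n_per_conc),
    n_vehicle = as.integer(n_vehicle), n_positive = as.integer(n_positive),
    n_blank = as.integer(n_blank), positive_substance = positive_substance
  )
}

#' Validate a plate layout
#'
#' Checks the layout against the experiment-design invariants and returns
#' the violations found (an empty character vector means the layout is
#' valid). Violations are returned, not raised, so callers can report all
#' problems at once.
#'
#' @param layout Layout tibble from [build_plate_layout()].
#' @param design Expected design counts ([default_plate_design()]).
#' @return Character vector of violation messages.
#' @export
validate_layout <- function(layout, design = default_plate_design()) {
  violations <- character()
  if (nrow(layout) != 96) {
    violations <- c(violations, sprintf("well count %d != 96", nrow(layout)))
  }
  coords <- paste(layout$row, layout$column)
  if (anyDuplicated(coords)) {
    violations <- c(violations, "duplicate well coordinates")
  }
  bad_role <- setdiff(unique(layout$role), WELL_ROLES)
  if (length(bad_role) > 0) {
    violations <- c(violations, paste("unknown role:", paste(bad_role, collapse = ", ")))
  }
  outer <- layout$row %in% c("A", "H") | layout$column %in% c(1, 12)
  bad_outer <- outer & layout$role != "unused"
  if (any(bad_outer)) {
    violations <- c(violations, sprintf(
      "outer well not unused: %s",
      paste(layout$well[bad_outer], collapse = ", ")
    ))
  }
  is_treat <- layout$role == "treatment"
  if (any(is_treat & (is.na(layout$substance_id) | is.na(layout$concentration_level)))) {
    violations <- c(violations, "treatment well missing substance_id or concentration_level")
  }
  lvl <- layout$concentration_level[is_treat]
  if (any(!is.na(lvl) & (lvl < 1 | lvl > design$n_levels))) {
    violations <- c(violations, "concentration_level outside 1..n_levels")
  }
  for (l in seq_len(design$n_levels)) {
    n <- sum(is_treat & !is.na(layout$concentration_level) & layout$concentration_level == l)
    if (n != design$n_per_conc) {
      violations <- c(violations, sprintf(
        "treatment count at level %d is %d != %d", l, n, design$n_per_conc
      ))
    }
  }
  counts <- c(
    vehicle_control = design$n_vehicle,
    positive_control = design$n_positive,
    blank = design$n_blank
  )
  for (role in names(counts)) {
    n <- sum(layout$role == role)
    if (n != counts[[role]]) {
      violations <- c(violations, sprintf("%s count %d != %d", role, n, counts[[role]]))
    }
  }
  violations
}

#' Validate a long-format measurement table
#'
#' @param x Measurement tibble with columns `sample_id`, `sample_kind`,
#'   `plate_id`, `well`, `metabolite_id`, `value`, `nominal_amount`,
#'   `scale`. Missing values are `NA`, never 0 (zero is a legal signal).
#' @return The table, invisibly; errors name the offending rows.
#' @export
validate_measurements <- function(x) {
  missing_cols <- setdiff(MEASUREMENT_COLUMNS, names(x))
  if (length(missing_cols) > 0) {
    stop("measurement table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  key <- paste(x$sample_id, x$metabolite_id)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop(
      "duplicate (sample_id, metabolite_id) pairs: ",
      paste(utils::head(dup, 5), collapse = "; "),
      if (length(dup) > 5) sprintf(" (and %d more)", length(dup) - 5) else ""
    )
  }
  bad_kind <- setdiff(unique(x$sample_kind), SAMPLE_KINDS)
  if (length(bad_kind) > 0) {
    stop("invalid sample_kind: ", paste(bad_kind, collapse = ", "))
  }
  scales <- unique(x$scale)
  if (length(scales) != 1 || !scales %in% MEASUREMENT_SCALES) {
    stop("scale must be a single value among ", paste(MEASUREMENT_SCALES, collapse = ", "))
  }
  neg <- !is.na(x$value) & x$value < 0
  if (any(neg)) {
    stop(
      "negative values for rows: ",
      paste(utils::head(paste(x$sample_id[neg], x$metabolite_id[neg]), 5), collapse = "; ")
    )
  }
  if (scales != "raw") {
    nonpos <- !is.na(x$value) & x$value <= 0
    if (any(nonpos)) {
      stop("values on ratio scales must be strictly positive")
    }
  }
  series <- x$sample_kind == "reference_series"
  if (any(series & (is.na(x$nominal_amount) | x$nominal_amount <= 0))) {
    stop("reference_series rows require a positive nominal_amount")
  }
  invisible(x)
}

measurement_scale <- function(x) unique(x$scale)

#' Read / write long-format measurement CSVs
#'
#' The canonical on-disk form is a long CSV, one record per sample x
#' metabolite. Missing values are written as empty fields (never 0), and
#' doubles are serialized with full precision so write-read round-trips
#' are exact.
#'
#' @param path CSV file path.
#' @return `read_measurement_table()` returns a validated tibble;
#'   `write_measurement_table()` returns `path` invisibly.
#' @export
read_measurement_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, colClasses = c(
    sample_id = "character", sample_kind = "character", plate_id = "character",
    well = "character", metabolite_id = "character", value = "numeric",
    nominal_amount = "numeric", scale = "character"
  ), na.strings = "")
  validate_measurements(as_tibble(x))
}

#' @rdname read_measurement_table
#' @param x Measurement tibble.
#' @export
write_measurement_table <- function(x, path) {
  validate_measurements(x)
  write_csv_exact(x[MEASUREMENT_COLUMNS], path)
}

# Full-precision CSV writer: numerics via format(digits = 17) trimmed of
# trailing zeros by as.character round-trip; NA as empty field.
write_csv_exact <- function(x, path) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.double(x[[j]])) {
      x[[j]] <- vapply(x[[j]], function(v) {
        if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = FALSE, trim = TRUE)
      }, character(1))
    }
  }
  has_comma <- vapply(x, function(col) is.character(col) && any(grepl(",", col), na.rm = TRUE), logical(1))
  if (any(has_comma)) stop("CSV dialect does not support embedded commas in: ",
                           paste(names(x)[has_comma], collapse = ", "))
  utils::write.csv(x, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read / write a metabolite panel CSV
#'
#' @param path CSV path with columns `metabolite_id`, `display_name`,
#'   `annotation_status`, `ontology_class`.
#' @return Validated panel tibble.
#' @export
read_panel <- function(path) {
  x <- as_tibble(utils::read.csv(path, colClasses = "character", na.strings = ""))
  validate_panel(x, classes = unique(x$ontology_class))
  x
}

#' @rdname read_panel
#' @param panel Panel tibble.
#' @export
write_panel <- function(panel, path) {
  write_csv_exact(panel[c("metabolite_id", "display_name", "annotation_status", "ontology_class")], path)
}

#' Read / write a viability CSV
#'
#' Long table of per-well ATP viability as percent of the vehicle-control
#' mean (columns `substance_id`, `concentration_uM`, `replicate`,
#' `viability_pct`).
#'
#' @param path CSV path.
#' @return Viability tibble.
#' @export
read_viability_table <- function(path) {
  x <- as_tibble(utils::read.csv(path, colClasses = c(
    substance_id = "character", concentration_uM = "numeric",
    replicate = "integer", viability_pct = "numeric"
  ), na.strings = ""))
  x
}

#' @rdname read_viability_table
#' @param x Viability tibble.
#' @export
write_viability_table <- function(x, path) {
  write_csv_exact(x[c("substance_id", "concentration_uM", "replicate", "viability_pct")], path)
}

#' Published ATP viability summary for the seven-compound screen
#'
#' Mean and SD of ATP-based viability (percent of vehicle control, n = 6)
#' for six hepatotoxicants at their five selected concentration levels
#' C1-C5, as measured on the metabolomics plates of the HepG2 screening
#' platform this package models. Bezafibrate served as the on-plate
#' positive control (1000 uM) and therefore has no C1-C5 series. These
#' printed summaries drive the worked examples for the mode-of-action
#' concentration-selection rule.
#'
#' @return Tibble with columns `substance_id`, `moa_id`, `level`,
#'   `viability_mean_pct`, `viability_sd_pct`.
#' @export
hepg2_viability_summary <- function() {
  path <- system.file("extdata", "hepg2_viability_summary.csv", package = "moaplate",
                      mustWork = TRUE)
  as_tibble(utils::read.csv(path, colClasses = c(
    substance_id = "character", moa_id = "character", level = "integer",
    viability_mean_pct = "numeric", viability_sd_pct = "numeric"
  )))
}
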