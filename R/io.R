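#' @keywords internal
well_roles <- c("background", "vehicle_bfgf", "chemical_bfgf")

plate_cols <- c("plate_id", "well", "time_h", "chemical",
                "concentration_ug_ml", "role", "replicate", "luminescence")

viability_cols <- c("chemical", "concentration_ug_ml", "replicate",
                    "abs_sample", "abs_blank", "abs_vehicle")

# sentinel chemical name for control wells; case-insensitive variants of it
# are rejected for real chemicals to prevent silent control/condition mixing
VEHICLE <- "VEHICLE"

validate_plate <- function(plate, call_site = "read_plate_csv") {
  missing_cols <- setdiff(plate_cols, names(plate))
  if (length(missing_cols)) {
    abort(paste0("Plate data is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "abc_error_schema")
  }
  if (nrow(plate) == 0) {
    warn("Plate file contains a header but no records.")
    return(as_tibble(plate))
  }
  bad_lum <- which(!is.finite(plate$luminescence) | plate$luminescence <= 0)
  if (length(bad_lum)) {
    abort(sprintf("Non-positive luminescence in row(s): %s",
                  paste(head(bad_lum, 5), collapse = ", ")),
          class = "abc_error_value")
  }
  if (any(plate$time_h < -1)) {
    abort("time_h must be >= -1 h (chemical exposure time).",
          class = "abc_error_value")
  }
  if (any(plate$concentration_ug_ml < 0)) {
    abort("Concentrations must be >= 0.", class = "abc_error_value")
  }
  bad_role <- setdiff(unique(plate$role), well_roles)
  if (length(bad_role)) {
    abort(paste0("Unknown well role(s): ", paste(bad_role, collapse = ", ")),
          class = "abc_error_schema")
  }
  ctrl <- plate$role %in% c("background", "vehicle_bfgf")
  if (any(plate$chemical[ctrl] != VEHICLE | plate$concentration_ug_ml[ctrl] != 0)) {
    abort("Control wells (background / vehicle_bfgf) must have chemical 'VEHICLE' and concentration 0.",
          class = "abc_error_value")
  }
  fake_vehicle <- !ctrl & toupper(plate$chemical) == VEHICLE
  if (any(fake_vehicle)) {
    abort("'VEHICLE' (any case) is reserved for control wells.",
          class = "abc_error_value")
  }
  # times within one plate must form a shared grid across wells
  for (pid in unique(plate$plate_id)) {
    p <- plate[plate$plate_id == pid, ]
    grid <- sort(unique(p$time_h))
    by_well <- split(p$time_h, interaction(p$well, p$chemical,
                                           p$concentration_ug_ml, p$replicate,
                                           p$role, drop = TRUE))
    ragged <- !vapply(by_well, function(tt) {
      length(tt) == length(grid) && all(sort(tt) == grid)
    }, TRUE)
    if (any(ragged)) {
      abort(sprintf("Plate '%s' has ragged time grids (e.g. series %s).",
                    pid, names(by_well)[which(ragged)[1]]),
            class = "abc_error_grid")
    }
  }
  as_tibble(plate)
}

#' Read a plate-reader luminescence time-series CSV
#'
#' Expects the long-format schema
#' `plate_id,well,time_h,chemical,concentration_ug_ml,role,replicate,luminescence`
#' with one row per well and time point. Three well roles are recognised:
#' `background` (vehicle, no stimulus), `vehicle_bfgf` (vehicle + stimulus) and
#' `chemical_bfgf` (chemical + stimulus). Control wells must carry the reserved
#' chemical name `"VEHICLE"` and concentration 0, and all wells of a plate must
#' share one time grid.
#'
#' @param path Path to a CSV file.
#' @returns A tibble of well records (a message reports the record count).
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "abc_error_io")
  }
  plate <- readr::read_csv(
    path,
    col_types = readr::cols(
      plate_id = readr::col_character(),
      well = readr::col_character(),
      time_h = readr::col_double(),
      chemical = readr::col_character(),
      concentration_ug_ml = readr::col_double(),
      role = readr::col_character(),
      replicate = readr::col_integer(),
      luminescence = readr::col_double()
    )
  )
  plate <- validate_plate(plate)
  if (nrow(plate) > 0) {
    message(sprintf("Ingested %d well records (%d chemical(s), %d plate(s)).",
                    nrow(plate),
                    length(setdiff(unique(plate$chemical), VEHICLE)),
                    n_distinct(plate$plate_id)))
  }
  plate
}

#' @rdname read_plate_csv
#' @param plate A plate tibble as produced by [simulate_timecourse()] or
#'   [read_plate_csv()].
#' @export
write_plate_csv <- function(plate, path) {
  validate_plate(plate)
  readr::write_csv(plate[, plate_cols], path)
  invisible(path)
}

#' Read / write an endpoint viability CSV
#'
#' Schema:
#' `chemical,concentration_ug_ml,replicate,abs_sample,abs_blank,abs_vehicle`.
#' The blank is a cell-free control and the vehicle column the solvent-only
#' control; viability is computed by [cell_viability()].
#'
#' @param path Path to a CSV file.
#' @returns A tibble of viability records.
#' @export
read_viability_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "abc_error_io")
  }
  x <- readr::read_csv(path, col_types = readr::cols(
    chemical = readr::col_character(),
    concentration_ug_ml = readr::col_double(),
    replicate = readr::col_integer(),
    abs_sample = readr::col_double(),
    abs_blank = readr::col_double(),
    abs_vehicle = readr::col_double()
  ))
  missing_cols <- setdiff(viability_cols, names(x))
  if (length(missing_cols)) {
    abort(paste0("Viability data is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "abc_error_schema")
  }
  if (any(x$abs_vehicle <= x$abs_blank)) {
    abort("abs_vehicle must exceed abs_blank in every record.",
          class = "abc_error_value")
  }
  as_tibble(x)
}

#' @rdname read_viability_csv
#' @param records A viability tibble.
#' @export
write_viability_csv <- function(records, path) {
  readr::write_csv(records[, viability_cols], path)
  invisible(path)
}

#' Reference classification table for the 18 ECVAM panel chemicals
#'
#' Loads the packaged validation table: for each of the 18 chemicals tested,
#' the published sum-of-ABC score, the animal-study developmental-toxicity
#' label (`P`/`N`), and whether the chemical is an established limb/digit
#' malformation toxicant. These scores and labels are the fixture against
#' which the ROC and classification stages are validated.
#'
#' @param path CSV path; defaults to the copy shipped with the package.
#'   Schema: `chemical,abbreviation,sum_abc,animal_label,limb_flag`.
#' @returns A tibble with one row per chemical.
#' @export
#' @examples
#' tab <- read_validation_table()
#' table(tab$animal_label)
read_validation_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ecvam_validation.csv",
                                package = "abcscreen", mustWork = TRUE)
  x <- readr::read_csv(path, col_types = readr::cols(
    chemical = readr::col_character(),
    abbreviation = readr::col_character(),
    sum_abc = readr::col_double(),
    animal_label = readr::col_character(),
    limb_flag = readr::col_logical()
  ))
  if (anyDuplicated(x$chemical) || anyDuplicated(x$abbreviation)) {
    abort("Duplicate chemical in validation table.",
          class = "abc_error_value")
  }
  if (!all(x$animal_label %in% c("P", "N"))) {
    abort("animal_label must be 'P' or 'N'.", class = "abc_error_value")
  }
  as_tibble(x)
}

#' Study-design table for the 18 ECVAM panel chemicals
#'
#' Packaged copy of the tested chemicals with their vehicles and the maximum
#' exposure concentrations used in the assay (IC50-derived where estimable,
#' otherwise capped by solubility and the vehicle-fraction limits).
#'
#' @param path CSV path; defaults to the packaged copy.
#' @returns A tibble with columns `chemical`, `abbreviation`, `cas`,
#'   `vehicle`, `max_conc_ug_ml`, `animal_label`.
#' @export
read_study_design <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ecvam_chemicals.csv",
                                package = "abcscreen", mustWork = TRUE)
  x <- readr::read_csv(path, col_types = readr::cols(
    chemical = readr::col_character(),
    abbreviation = readr::col_character(),
    cas = readr::col_character(),
    vehicle = readr::col_character(),
    max_conc_ug_ml = readr::col_double(),
    animal_label = readr::col_character()
  ))
  if (!all(x$vehicle %in% c("PBS", "DMSO"))) {
    abort("vehicle must be 'PBS' or 'DMSO'.", class = "abc_error_value")
  }
  if (any(x$max_conc_ug_ml <= 0)) {
    abort("max_conc_ug_ml must be positive.", class = "abc_error_value")
  }
  as_tibble(x)
}

#' Descending serial-dilution concentration series
#'
#' Helper to build the exposure series for one chemical: `n` concentrations
#' from `max_conc` downward with a constant dilution factor.
#'
#' @param max_conc Top concentration (ug/mL).
#' @param n Number of concentrations.
#' @param dilution Fold-dilution between steps (default 2).
#' @returns Numeric vector, descending.
#' @export
concentration_series <- function(max_conc, n = 5, dilution = 2) {
  if (max_conc <= 0 || n < 1 || dilution <= 1) {
    abort("Need max_conc > 0, n >= 1, dilution > 1.",
          class = "abc_error_value")
  }
  max_conc / dilution^(seq_len(n) - 1)
}
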