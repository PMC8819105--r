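#' Relative light units: background-normalize raw luminescence
#'
#' Divides every read by the mean of the background wells (vehicle, no
#' stimulus) at the same time point on the same plate, yielding the relative
#' light unit (RLU).
#'
#' @param plate A plate tibble (see [read_plate_csv()]).
#' @returns The plate tibble with an `rlu` column added.
#' @export
compute_rlu <- function(plate) {
  plate <- validate_plate(plate)
  if (!any(plate$role == "background")) {
    abort("Plate has no background wells.", class = "abc_error_value")
  }
  bg <- plate |>
    filter(.data$role == "background") |>
    group_by(.data$plate_id, .data$time_h) |>
    summarise(bg_mean = mean(.data$luminescence), .groups = "drop")
  out <- left_join(plate, bg, by = c("plate_id", "time_h"))
  if (any(is.na(out$bg_mean))) {
    t_bad <- unique(out$time_h[is.na(out$bg_mean)])
    abort(sprintf("No background reads at time(s): %s",
                  paste(head(t_bad, 5), collapse = ", ")),
          class = "abc_error_value")
  }
  if (any(out$bg_mean <= 0)) {
    abort("Background mean is zero or negative at some time point.",
          class = "abc_error_value")
  }
  out |>
    mutate(rlu = .data$luminescence / .data$bg_mean) |>
    select(-"bg_mean")
}

# vector min-max scaler used by min_max_scale()
scale_min_max <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!all(is.finite(r)) || r[1] == r[2]) {
    abort("Degenerate scale: all values identical, min-max scaling undefined.",
          class = "abc_error_scale")
  }
  (x - r[1]) / (r[2] - r[1])
}

#' Min-max scale RLU values within each experiment
#'
#' Rescales a value column to `[0, 1]` so that the minimum over the whole
#' experiment maps to 0 and the maximum to 1. The scaling scope is one
#' experiment (plate): all conditions, replicates and time points are pooled,
#' which preserves cross-condition comparability within the plate.
#'
#' @param data A tibble with the value column (typically the output of
#'   [compute_rlu()]).
#' @param value Column to scale (default `rlu`).
#' @param by Grouping column defining one experiment (default `plate_id`).
#' @returns `data` with a `scaled` column added. Attributes `scale_min` and
#'   `scale_max` record the per-experiment extremes.
#' @export
min_max_scale <- function(data, value = "rlu", by = "plate_id") {
  if (!value %in% names(data)) {
    abort(sprintf("Column '%s' not found.", value), class = "abc_error_schema")
  }
  groups <- if (by %in% names(data)) split(seq_len(nrow(data)), data[[by]])
            else list(seq_len(nrow(data)))
  scaled <- rep(NA_real_, nrow(data))
  mins <- maxs <- numeric(0)
  for (idx in groups) {
    x <- data[[value]][idx]
    scaled[idx] <- scale_min_max(x)
    mins <- c(mins, min(x)); maxs <- c(maxs, max(x))
  }
  out <- mutate(data, scaled = scaled)
  attr(out, "scale_min") <- mins
  attr(out, "scale_max") <- maxs
  out
}

#' Vehicle-referenced fold change of scaled time courses
#'
#' For each chemical condition (and for each vehicle replicate, which provides
#' the control spline's own data), computes at every time point
#' `fc(t) = (s(t) + eps) / (mean s_vehicle(t) + eps)` where the mean is over
#' stimulated vehicle replicates at that time and `eps` is the configured
#' ratio floor; then `log_fc = log(fc)` in the configured base.
#'
#' @param data Output of [min_max_scale()]: scaled plate data including
#'   `vehicle_bfgf` rows.
#' @param config An [run_config()] object.
#' @returns A tibble with columns `plate_id`, `chemical`,
#'   `concentration_ug_ml`, `replicate`, `time_h`, `scaled`, `fold_change`,
#'   `log_fc`, restricted to the monitoring window. Vehicle rows keep
#'   `chemical = "VEHICLE"`.
#' @export
fold_change <- function(data, config = run_config()) {
  stopifnot(inherits(config, "abc_config"))
  need <- c("plate_id", "chemical", "concentration_ug_ml", "replicate",
            "time_h", "role", "scaled")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "abc_error_schema")
  }
  eps <- config$epsilon_ratio_floor
  win <- config$window
  data <- filter(data, .data$time_h >= win[1], .data$time_h <= win[2])
  veh <- data |>
    filter(.data$role == "vehicle_bfgf") |>
    group_by(.data$plate_id, .data$time_h) |>
    summarise(veh_mean = mean(.data$scaled), .groups = "drop")
  if (nrow(veh) == 0) {
    abort("No stimulated vehicle (vehicle_bfgf) wells present.",
          class = "abc_error_value")
  }
  out <- data |>
    filter(.data$role %in% c("vehicle_bfgf", "chemical_bfgf")) |>
    left_join(veh, by = c("plate_id", "time_h"))
  if (any(is.na(out$veh_mean))) {
    abort("Vehicle reference missing at some time points (grid mismatch).",
          class = "abc_error_grid")
  }
  out |>
    mutate(fold_change = (.data$scaled + eps) / (.data$veh_mean + eps),
           log_fc = log_in_base(.data$fold_change, config$log_base)) |>
    select("plate_id", "chemical", "concentration_ug_ml", "replicate",
           "time_h", "scaled", "fold_change", "log_fc")
}

#' Full normalization chain for a raw plate
#'
#' Convenience wrapper running [compute_rlu()], [min_max_scale()] and
#' [fold_change()] in sequence.
#'
#' @inheritParams fold_change
#' @param plate Raw plate tibble.
#' @returns The log fold-change tibble of [fold_change()], with normalization
#'   metadata (scaling extremes, ratio floor, log base) in attribute
#'   `abc_meta`.
#' @export
#' @examples
#' plate <- simulate_timecourse(signal_params(noise_sd = 0), 10,
#'                              config = run_config(), seed = 1)
#' norm <- normalize_plate(plate)
#' head(norm)
normalize_plate <- function(plate, config = run_config()) {
  scaled <- min_max_scale(compute_rlu(plate))
  out <- fold_change(scaled, config)
  attr(out, "abc_meta") <- list(
    scale_min = attr(scaled, "scale_min"),
    scale_max = attr(scaled, "scale_max"),
    epsilon_ratio_floor = config$epsilon_ratio_floor,
    log_base = config$log_base
  )
  out
}

#' Write / read normalized series with a metadata header
#'
#' The CSV carries the normalization decisions (scaling extremes, ratio floor,
#' log base) as `#`-prefixed header lines so downstream ABC values are
#' interpretable without the originating session.
#'
#' @param normalized Output of [normalize_plate()].
#' @param path File path.
#' @returns `write_normalized_csv()` returns `path` invisibly;
#'   `read_normalized_csv()` returns the tibble with the `abc_meta` attribute
#'   restored (numeric fields only).
#' @export
write_normalized_csv <- function(normalized, path) {
  meta <- attr(normalized, "abc_meta")
  hdr <- character(0)
  if (!is.null(meta)) {
    hdr <- c(
      sprintf("# scale_min: %s",
              paste(format(meta$scale_min, digits = 17), collapse = " ")),
      sprintf("# scale_max: %s",
              paste(format(meta$scale_max, digits = 17), collapse = " ")),
      sprintf("# epsilon_ratio_floor: %g", meta$epsilon_ratio_floor),
      sprintf("# log_base: %s", meta$log_base)
    )
  }
  writeLines(hdr, path)
  readr::write_csv(as_tibble(normalized), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' @rdname write_normalized_csv
#' @export
read_normalized_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  body <- paste(grep("^#", lines, value = TRUE, invert = TRUE), collapse = "\n")
  out <- readr::read_csv(I(body), show_col_types = FALSE)
  get_meta <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    sub(paste0("^# ", key, ":\\s*"), "", ln[1])
  }
  meta <- list(
    scale_min = as.numeric(strsplit(get_meta("scale_min") %||% "", " +")[[1]]),
    scale_max = as.numeric(strsplit(get_meta("scale_max") %||% "", " +")[[1]]),
    epsilon_ratio_floor = as.numeric(get_meta("epsilon_ratio_floor")),
    log_base = get_meta("log_base")
  )
  attr(out, "abc_meta") <- meta
  out
}

#' Endpoint cell viability from absorbance reads
#'
#' Computes the viability fraction
#' `(abs_sample - abs_blank) / (abs_vehicle - abs_blank)` for every record.
#' Values above 1 are retained (the dose-response upper asymptote absorbs
#' them).
#'
#' @param records A viability tibble (see [read_viability_csv()]).
#' @returns The tibble with a `viability` column added.
#' @export
cell_viability <- function(records) {
  missing_cols <- setdiff(c("abs_sample", "abs_blank", "abs_vehicle"),
                          names(records))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "abc_error_schema")
  }
  if (any(records$abs_vehicle <= records$abs_blank)) {
    abort("abs_vehicle must exceed abs_blank (denominator positivity).",
          class = "abc_error_value")
  }
  mutate(as_tibble(records),
         viability = (.data$abs_sample - .data$abs_blank) /
           (.data$abs_vehicle - .data$abs_blank))
}
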