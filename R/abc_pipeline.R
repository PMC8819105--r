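#' Per-concentration ABC disruption scores
#'
#' Fits the control spline `a(t)` and one chemical spline `b(t)` per
#' (chemical, concentration) condition from vehicle-referenced log fold
#' changes, then computes the trapezoid ABC and its signed decomposition on
#' the configured evaluation grid.
#'
#' The control curve is fitted from the stimulated vehicle replicates' own log
#' fold changes against the vehicle mean (near zero but not identically zero)
#' unless `config$control_curve == "zero"`, in which case `a(t) = 0`.
#'
#' @param normalized Output of [normalize_plate()] (or any tibble with
#'   `plate_id`, `chemical`, `concentration_ug_ml`, `replicate`, `time_h`,
#'   `log_fc`).
#' @param config An [run_config()] object.
#' @param by_replicate If `TRUE`, fit one chemical spline per replicate
#'   against the pooled control curve (used for effect-size inputs); otherwise
#'   replicates are pooled per condition.
#' @returns A tibble with one row per condition (and replicate, if requested):
#'   `plate_id`, `chemical`, `concentration_ug_ml`, (`replicate`,) `abc`,
#'   `area_pos`, `area_neg`, `net_area`, `endpoint_score`, and the spline
#'   effective df.
#' @export
#' @examples
#' plate <- simulate_timecourse(signal_params(noise_sd = 0), c(5, 10),
#'                              config = run_config(), seed = 1)
#' compute_abc(normalize_plate(plate))
compute_abc <- function(normalized, config = run_config(),
                        by_replicate = FALSE) {
  stopifnot(inherits(config, "abc_config"))
  need <- c("plate_id", "chemical", "concentration_ug_ml", "replicate",
            "time_h", "log_fc")
  missing_cols <- setdiff(need, names(normalized))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "abc_error_schema")
  }
  grid <- seq(config$window[1], config$window[2],
              by = config$eval_grid_step_h)
  out <- list()
  for (pid in unique(normalized$plate_id)) {
    p <- filter(normalized, .data$plate_id == pid)
    veh <- filter(p, .data$chemical == VEHICLE)
    control <- if (config$control_curve == "zero" || nrow(veh) == 0) {
      constant_spline(grid, 0)
    } else {
      fit_spline(veh, df = config$spline_df, grid = grid, config = config)
    }
    chem <- filter(p, .data$chemical != VEHICLE)
    keys <- if (by_replicate) {
      distinct(chem, .data$chemical, .data$concentration_ug_ml, .data$replicate)
    } else {
      distinct(chem, .data$chemical, .data$concentration_ug_ml)
    }
    res <- pmap(keys, function(chemical, concentration_ug_ml, replicate = NULL) {
      d <- chem[chem$chemical == chemical &
                  chem$concentration_ug_ml == concentration_ug_ml, ]
      if (!is.null(replicate)) d <- d[d$replicate == replicate, ]
      curve <- fit_spline(d, df = config$spline_df, grid = grid,
                          config = config)
      row <- abc_between(control, curve)
      row$endpoint_score <- endpoint_score(control, curve,
                                           at = config$window[2])
      row$effective_df <- curve$effective_df
      row
    })
    out[[pid]] <- bind_rows(
      mutate(keys, plate_id = pid, .before = 1),
      .id = NULL
    ) |>
      dplyr::bind_cols(bind_rows(res))
  }
  bind_rows(out) |>
    arrange(.data$plate_id, .data$chemical, .data$concentration_ug_ml)
}

direction_from_net <- function(net_areas) {
  # zero net signed area counts as positive (tie rule)
  signs <- ifelse(net_areas >= 0, 1L, -1L)
  if (all(signs == 1L)) "uniform_positive"
  else if (all(signs == -1L)) "uniform_negative"
  else "mixed"
}

#' Per-chemical disruption summary
#'
#' Aggregates per-concentration ABC results into the chemical-level score used
#' for classification: the sum of ABC values over the concentration series,
#' the analogous single-endpoint comparator sum, the direction profile of the
#' signed net areas, per-replicate sums (each replicate's chemical curves
#' against the pooled control curve), and the Jonckheere-Terpstra
#' concentration-trend test on the per-replicate ABC values.
#'
#' @inheritParams compute_abc
#' @returns A tibble with one row per (plate, chemical): `sum_abc`,
#'   `endpoint_score_24h`, `direction_profile`, `n_concentrations`,
#'   `replicate_sums` (list column of per-replicate sum-of-ABC values),
#'   `jt_statistic`, `trend_p_value`, `trend_significant`.
#' @export
summarise_chemicals <- function(normalized, config = run_config()) {
  pooled <- compute_abc(normalized, config, by_replicate = FALSE)
  reps <- compute_abc(normalized, config, by_replicate = TRUE)
  keys <- distinct(pooled, .data$plate_id, .data$chemical)
  rows <- pmap(keys, function(plate_id, chemical) {
    pc <- pooled[pooled$plate_id == plate_id & pooled$chemical == chemical, ]
    rc <- reps[reps$plate_id == plate_id & reps$chemical == chemical, ]
    rep_sums <- tapply(rc$abc, rc$replicate, sum)
    trend <- if (n_distinct(pc$concentration_ug_ml) >= 2) {
      groups <- split(rc$abc, rc$concentration_ug_ml) # ordered by concentration
      jt_test(groups)
    } else {
      list(statistic = NA_real_, p_value = NA_real_)
    }
    tibble(
      plate_id = plate_id,
      chemical = chemical,
      n_concentrations = n_distinct(pc$concentration_ug_ml),
      sum_abc = sum(pc$abc),
      endpoint_score_24h = sum(pc$endpoint_score),
      direction_profile = direction_from_net(pc$net_area),
      replicate_sums = list(as.numeric(rep_sums)),
      n_replicates = length(rep_sums),
      jt_statistic = trend$statistic,
      trend_p_value = trend$p_value,
      trend_significant = !is.na(trend$p_value) &
        trend$p_value < config$jt_alpha
    )
  })
  bind_rows(rows)
}
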