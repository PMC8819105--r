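#' Plot normalized log fold-change time courses
#'
#' One panel per chemical, colour by concentration, with the per-condition
#' smoothing-spline curves overlaid.
#'
#' @param normalized Output of [normalize_plate()].
#' @param config An [run_config()] object.
#' @param chemicals Optional subset of chemicals to show.
#' @returns A ggplot object.
#' @export
plot_timecourse <- function(normalized, config = run_config(),
                            chemicals = NULL) {
  d <- filter(normalized, .data$chemical != VEHICLE)
  if (!is.null(chemicals)) d <- filter(d, .data$chemical %in% chemicals)
  grid <- seq(config$window[1], config$window[2],
              by = config$eval_grid_step_h)
  curves <- d |>
    group_by(.data$plate_id, .data$chemical, .data$concentration_ug_ml) |>
    dplyr::group_modify(function(g, key) {
      s <- fit_spline(g, df = config$spline_df, grid = grid, config = config)
      tibble(time_h = s$grid, log_fc = s$values)
    }) |>
    ungroup()
  ggplot(d, aes(x = .data$time_h, y = .data$log_fc,
                colour = factor(.data$concentration_ug_ml))) +
    geom_point(alpha = 0.4, size = 0.8) +
    geom_line(data = curves) +
    facet_wrap(~chemical) +
    labs(x = "Time after stimulus (h)", y = "log fold change",
         colour = expression(paste("Conc. (", mu, "g/mL)"))) +
    theme_minimal()
}

#' Plot the area between the control and chemical curves
#'
#' Shades the region between the control spline and one chemical condition's
#' spline, distinguishing positive (chemical above control) and negative
#' accumulation.
#'
#' @param normalized Output of [normalize_plate()].
#' @param chemical Chemical to display.
#' @param concentration Concentration to display (defaults to the highest
#'   present).
#' @param config An [run_config()] object.
#' @returns A ggplot object.
#' @export
plot_abc <- function(normalized, chemical, concentration = NULL,
                     config = run_config()) {
  d <- filter(normalized, .data$chemical == .env$chemical)
  if (nrow(d) == 0) {
    abort(sprintf("Chemical '%s' not found.", chemical),
          class = "abc_error_value")
  }
  concentration <- concentration %||% max(d$concentration_ug_ml)
  d <- filter(d, .data$concentration_ug_ml == concentration)
  grid <- seq(config$window[1], config$window[2],
              by = config$eval_grid_step_h)
  veh <- filter(normalized, .data$chemical == VEHICLE)
  control <- if (config$control_curve == "zero" || nrow(veh) == 0) {
    constant_spline(grid, 0)
  } else {
    fit_spline(veh, df = config$spline_df, grid = grid, config = config)
  }
  curve <- fit_spline(d, df = config$spline_df, grid = grid, config = config)
  band <- tibble(
    time_h = grid,
    a = control$values,
    b = curve$values,
    part = ifelse(curve$values >= control$values, "positive", "negative")
  )
  res <- abc_between(control, curve)
  ggplot(band, aes(x = .data$time_h)) +
    geom_ribbon(aes(ymin = pmin(.data$a, .data$b),
                    ymax = pmax(.data$a, .data$b), fill = .data$part),
                alpha = 0.4) +
    geom_line(aes(y = .data$a), colour = "grey30") +
    geom_line(aes(y = .data$b), colour = "steelblue") +
    scale_fill_manual(values = c(positive = "grey75", negative = "grey40")) +
    labs(x = "Time after stimulus (h)", y = "log fold change",
         fill = "Accumulation",
         title = sprintf("%s at %g µg/mL: ABC = %.2f", chemical,
                         concentration, res$abc)) +
    theme_minimal()
}
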