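#' Smoothing-spline fit of a log fold-change time course
#'
#' Fits a penalized cubic smoothing spline (roughness penalty on the second
#' derivative, knots at the observed times) with the smoothing level chosen so
#' that the trace of the smoother matrix equals the requested effective
#' degrees of freedom. Replicates are pooled as independent observations.
#'
#' @param data A tibble holding one condition's time course (replicates
#'   stacked).
#' @param df Effective degrees of freedom (> 1 and less than the number of
#'   distinct time points).
#' @param grid Evaluation grid in hours; defaults to the configured window at
#'   the configured step.
#' @param time,value Column names of the time and response.
#' @param config An [run_config()] object used for the default grid and `df`.
#' @returns An object of class `"abc_spline"`: list with `grid`, `values`,
#'   `effective_df`, `df_target`, `n_obs`, and the underlying
#'   [stats::smooth.spline] fit.
#' @export
#' @examples
#' d <- tibble::tibble(time_h = rep(0:24, 3),
#'                     log_fc = rep(0.02 * (0:24), 3))
#' s <- fit_spline(d, df = 6, grid = 0:24)
#' s$effective_df
fit_spline <- function(data, df = config$spline_df, grid = NULL,
                       time = "time_h", value = "log_fc",
                       config = run_config()) {
  missing_cols <- setdiff(c(time, value), names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "abc_error_schema")
  }
  tt <- data[[time]]
  yy <- data[[value]]
  keep <- is.finite(tt) & is.finite(yy)
  tt <- tt[keep]; yy <- yy[keep]
  if (df <= 1) {
    abort("`df` must exceed 1.", class = "abc_error_value")
  }
  n_t <- length(unique(tt))
  if (n_t < max(4, ceiling(df) + 1)) {
    abort(sprintf("Need at least %d distinct time points for df = %.3g (got %d).",
                  max(4, ceiling(df) + 1), df, n_t),
          class = "abc_error_value")
  }
  grid <- grid %||%
    seq(config$window[1], config$window[2], by = config$eval_grid_step_h)
  fit <- smooth.spline(tt, yy, df = df, all.knots = TRUE, cv = FALSE,
                       keep.stuff = FALSE)
  structure(
    list(grid = grid,
         values = predict(fit, grid)$y,
         effective_df = fit$df,
         df_target = df,
         n_obs = length(tt),
         fit = fit),
    class = "abc_spline"
  )
}

#' Constant curve on a grid
#'
#' Builds an `"abc_spline"` representing a flat curve, used as the control
#' when `control_curve = "zero"` and convenient for constructing closed-form
#' test cases for [abc_between()].
#'
#' @param grid Evaluation grid (hours).
#' @param value Constant level (log-fold units).
#' @returns An `"abc_spline"` object.
#' @export
constant_spline <- function(grid, value = 0) {
  structure(
    list(grid = grid, values = rep(value, length(grid)),
         effective_df = NA_real_, df_target = NA_real_, n_obs = 0L,
         fit = NULL),
    class = "abc_spline"
  )
}

#' @export
print.abc_spline <- function(x, ...) {
  cat(sprintf("<abc_spline> grid [%g, %g] h (%d points), effective df %.3f\n",
              min(x$grid), max(x$grid), length(x$grid),
              x$effective_df))
  invisible(x)
}

#' @export
predict.abc_spline <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$values)
  if (is.null(object$fit)) return(rep(object$values[1], length(newdata)))
  predict(object$fit, newdata)$y
}

check_same_grid <- function(control, chemical) {
  if (length(control$grid) != length(chemical$grid) ||
      any(abs(control$grid - chemical$grid) > 1e-9)) {
    abort("Control and chemical splines are on different grids.",
          class = "abc_error_grid")
  }
}

#' Area between the control and chemical spline curves
#'
#' The disruption statistic: with control curve `a(t)` and chemical curve
#' `b(t)` evaluated on a common grid, the per-node distances are
#' `h_i = |a(t_i) - b(t_i)|` and the ABC is the trapezoid sum
#' `sum_i (h_{i+1} + h_i)/2 * dt_i`. The signed decomposition accumulates the
#' positive part of `b - a` into `area_pos` and the negative part (stored
#' `>= 0`) into `area_neg`; sign changes are handled at grid nodes with no
#' sub-grid root finding, so `abc = area_pos + area_neg` exactly.
#'
#' @param control,chemical `"abc_spline"` objects on identical grids.
#' @returns A one-row tibble: `abc`, `area_pos`, `area_neg`, `net_area`
#'   (`area_pos - area_neg`), and list columns `h` (node distances) and `dt`
#'   (grid spacings).
#' @export
#' @examples
#' g <- 0:24
#' a <- constant_spline(g, 0)
#' b <- constant_spline(g, 0.5)
#' abc_between(a, b)$abc # 0.5 * 24
abc_between <- function(control, chemical) {
  stopifnot(inherits(control, "abc_spline"), inherits(chemical, "abc_spline"))
  check_same_grid(control, chemical)
  a <- control$values
  b <- chemical$values
  d <- b - a
  h <- abs(d)
  dt <- diff(control$grid)
  trap <- function(v) sum((v[-1] + v[-length(v)]) / 2 * dt)
  area_pos <- trap(pmax(d, 0))
  area_neg <- trap(pmax(-d, 0))
  tibble(
    abc = trap(h),
    area_pos = area_pos,
    area_neg = area_neg,
    net_area = area_pos - area_neg,
    h = list(h),
    dt = list(dt)
  )
}

#' Single-endpoint comparator score
#'
#' The absolute difference between the chemical and control curves at the last
#' monitored time point (24 h). This is the quantity a fixed-time endpoint
#' assay would report; chemicals whose disruption peaks early and decays by
#' 24 h score near zero here even when their ABC is large.
#'
#' @inheritParams abc_between
#' @param at Endpoint time in hours (default 24; must be on the grid).
#' @returns Absolute curve difference at `at`, in log-fold units.
#' @export
endpoint_score <- function(control, chemical, at = 24) {
  stopifnot(inherits(control, "abc_spline"), inherits(chemical, "abc_spline"))
  check_same_grid(control, chemical)
  i <- which(abs(control$grid - at) < 1e-9)
  if (!length(i)) {
    abort(sprintf("Grid does not include t = %g h.", at),
          class = "abc_error_grid")
  }
  abs(chemical$values[i[1]] - control$values[i[1]])
}
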