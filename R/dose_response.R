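# four-parameter log-logistic response function
ll4_fun <- function(b, c, d, e) {
  function(x) c + (d - c) / (1 + exp(b * (log(x) - log(e))))
}

#' Fit a four-parameter log-logistic dose-response model
#'
#' Least-squares fit of `f(x; b, c, d, e) = c + (d - c) / (1 + exp(b *
#' (log(x) - log(e))))` to viability fractions, where `b` is the slope, `c`
#' and `d` the lower and upper asymptotes, and `e` the inflection dose. The
#' optimizer is a deterministic multi-start: Levenberg-Marquardt refinement
#' ([minpack.lm::nls.lm], parameterised in `log(e)` to keep `e > 0`) from a
#' fixed grid of slope values and inflection doses spanning the dose range;
#' the start with the lowest residual sum of squares wins. Viabilities above 1
#' are not clipped.
#'
#' @param data A tibble of viability measurements (e.g. from
#'   [cell_viability()]).
#' @param dose,response Names of the dose and response columns.
#' @returns An object of class `"abc_4pl"` with elements `b`, `c`, `d`, `e`,
#'   `residual_sd`, `converged`, `n`, and the fitting data. Non-convergence
#'   across all starts is reported via `converged = FALSE`, not an error.
#' @export
#' @examples
#' viab <- simulate_viability(c(b = 2, c = 0, d = 1, e = 10),
#'                            concentrations = 10^seq(-1, 3, length.out = 8),
#'                            noise_sd = 0, seed = 1)
#' fit <- fit_4pl(cell_viability(viab))
#' round(coef(fit), 3)
fit_4pl <- function(data, dose = "concentration_ug_ml", response = "viability") {
  missing_cols <- setdiff(c(dose, response), names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "abc_error_schema")
  }
  x <- data[[dose]]
  y <- data[[response]]
  keep <- is.finite(x) & is.finite(y) & x > 0
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 4) {
    abort("fit_4pl needs at least 4 distinct positive doses.",
          class = "abc_error_value")
  }
  b_grid <- c(-4, -2, -1, -0.5, 0.5, 1, 2, 4)
  e_grid <- exp(quantile(log(unique(x)), c(0.25, 0.5, 0.75), names = FALSE))
  c0 <- min(y); d0 <- max(y)
  if (d0 - c0 < .Machine$double.eps) d0 <- c0 + 1e-6

  lx <- log(x)
  residual_fn <- function(p) {
    y - (p[2] + (p[3] - p[2]) / (1 + exp(p[1] * (lx - p[4]))))
  }
  best <- NULL
  best_sse <- Inf
  for (b0 in b_grid) {
    for (e0 in e_grid) {
      fit <- tryCatch(
        suppressWarnings(minpack.lm::nls.lm(
          par = c(b0, c0, d0, log(e0)), fn = residual_fn,
          control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                               ptol = 1e-14)
        )),
        error = function(e) NULL
      )
      if (is.null(fit) || !fit$info %in% 1:4) next
      sse <- fit$deviance
      if (sse < best_sse - 1e-15) {
        best_sse <- sse
        best <- fit
      }
    }
  }
  if (is.null(best)) {
    out <- list(b = NA_real_, c = NA_real_, d = NA_real_, e = NA_real_,
                residual_sd = NA_real_, converged = FALSE,
                n = length(x), dose = x, response = y)
    class(out) <- "abc_4pl"
    return(out)
  }
  cf <- best$par
  b <- cf[1]; cl <- cf[2]; d <- cf[3]; e <- exp(cf[4])
  # keep (c, d) ordered as (lower, upper); flipping both asymptotes and the
  # slope sign leaves f unchanged
  if (cl > d) {
    tmp <- cl; cl <- d; d <- tmp; b <- -b
  }
  out <- list(
    b = b, c = cl, d = d, e = e,
    residual_sd = sqrt(best_sse / max(1, length(x) - 4)),
    converged = TRUE, n = length(x), dose = x, response = y
  )
  class(out) <- "abc_4pl"
  out
}

#' @export
print.abc_4pl <- function(x, ...) {
  cat("<abc_4pl> four-parameter log-logistic fit\n")
  if (!x$converged) {
    cat("  did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("  b = %.4g, c = %.4g, d = %.4g, e = %.4g (n = %d, resid SD %.3g)\n",
              x$b, x$c, x$d, x$e, x$n, x$residual_sd))
  invisible(x)
}

#' @export
coef.abc_4pl <- function(object, ...) {
  c(b = object$b, c = object$c, d = object$d, e = object$e)
}

#' @export
predict.abc_4pl <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$dose
       else if (is.data.frame(newdata)) newdata[[1]] else newdata
  if (!object$converged) return(rep(NA_real_, length(x)))
  ll4_fun(object$b, object$c, object$d, object$e)(x)
}

#' @export
tidy.abc_4pl <- function(x, ...) {
  tibble(term = c("b", "c", "d", "e"),
         estimate = c(x$b, x$c, x$d, x$e))
}

#' @export
glance.abc_4pl <- function(x, ...) {
  tibble(residual_sd = x$residual_sd, converged = x$converged, n = x$n)
}

#' @export
autoplot.abc_4pl <- function(object, n_grid = 200, ...) {
  df <- tibble(dose = object$dose, viability = object$response)
  p <- ggplot(df, aes(x = .data$dose, y = .data$viability)) +
    geom_point(alpha = 0.7) +
    scale_x_log10() +
    labs(x = "Concentration (µg/mL)", y = "Viability fraction") +
    theme_minimal()
  if (object$converged) {
    grid <- exp(seq(log(min(object$dose)), log(max(object$dose)),
                    length.out = n_grid))
    p <- p + geom_line(
      data = tibble(dose = grid, viability = predict(object, grid)),
      colour = "steelblue"
    )
  }
  p
}

#' Estimate the IC50 from a fitted dose-response curve
#'
#' The IC50 is the smallest dose in `range` at which the fitted viability
#' curve crosses 0.5 (absolute half-maximal growth inhibition, not the
#' relative inflection parameter `e`; the two coincide when `c = 0, d = 1`).
#' Solved by bisection on the log-dose scale to a relative tolerance of 1e-6.
#'
#' @param fit A converged [fit_4pl()] object.
#' @param range Dose interval to search; defaults to the fitted data's range.
#' @returns The IC50 in ug/mL, or `NA_real_` when the curve never crosses 0.5
#'   on the range (not estimable).
#' @export
estimate_ic50 <- function(fit, range = NULL) {
  stopifnot(inherits(fit, "abc_4pl"))
  if (!fit$converged) {
    abort("Cannot estimate IC50 from a non-converged fit.",
          class = "abc_error_value")
  }
  range <- range %||% base::range(fit$dose)
  f <- ll4_fun(fit$b, fit$c, fit$d, fit$e)
  lo <- log(range[1]); hi <- log(range[2])
  g <- function(lx) f(exp(lx)) - 0.5
  glo <- g(lo); ghi <- g(hi)
  if (glo == 0) return(exp(lo))
  if (ghi == 0) return(exp(hi))
  if (glo * ghi > 0) return(NA_real_) # no crossing on the tested range
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (gm == 0) break
    if (gm * glo < 0) { hi <- mid; ghi <- gm } else { lo <- mid; glo <- gm }
    if ((hi - lo) < 1e-9 * max(1, abs(mid))) break
  }
  exp((lo + hi) / 2)
}

#' Maximum exposure concentration for the signalling assay
#'
#' Applies the exposure-planning rule: the top tested concentration is the
#' IC50 when one is estimable, otherwise the maximum soluble concentration;
#' in either case the vehicle content at the top dose may not exceed 1% for
#' PBS or 0.1% for DMSO.
#'
#' @param chemical Chemical name (carried through).
#' @param ic50 IC50 in ug/mL, or `NA`/`NULL` when not estimable.
#' @param solubility_limit Maximum soluble concentration in medium (ug/mL), or
#'   `NULL`.
#' @param vehicle `"PBS"` or `"DMSO"`.
#' @param vehicle_fraction_at_top Volume fraction of vehicle in the medium at
#'   the top dose (e.g. 0.005 for 0.5%); `NULL` if unknown, in which case the
#'   cap is assumed respected.
#' @returns One-row tibble: `chemical`, `max_concentration`, `source`
#'   (`"ic50"` or `"solubility_cap"`), `vehicle`, `vehicle_cap_ok`.
#' @export
max_concentration <- function(chemical = NA_character_, ic50 = NULL,
                              solubility_limit = NULL,
                              vehicle = c("PBS", "DMSO"),
                              vehicle_fraction_at_top = NULL) {
  vehicle <- match.arg(vehicle)
  ic50_ok <- !is.null(ic50) && length(ic50) == 1 && is.finite(ic50) && ic50 > 0
  sol_ok <- !is.null(solubility_limit) && is.finite(solubility_limit) &&
    solubility_limit > 0
  if (!ic50_ok && !sol_ok) {
    abort("Neither an IC50 nor a solubility cap is available.",
          class = "abc_error_plan")
  }
  cap <- if (vehicle == "PBS") 0.01 else 0.001
  tibble(
    chemical = chemical,
    max_concentration = if (ic50_ok) ic50 else solubility_limit,
    source = if (ic50_ok) "ic50" else "solubility_cap",
    vehicle = vehicle,
    vehicle_cap_ok = is.null(vehicle_fraction_at_top) ||
      vehicle_fraction_at_top <= cap
  )
}
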