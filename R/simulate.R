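#' Parameters of the synthetic reporter-signal model
#'
#' The generator emulates an FGF-stimulated luciferase response: background
#' wells sit at a constant baseline `B`; stimulated vehicle wells follow
#' `L_v(t) = B * (1 + A * g(t))` with the unit-peak impulse response
#' `g(t) = (t/t_p) * exp(1 - t/t_p)` peaking at `t_p` hours; chemical wells
#' multiply the vehicle mean by `exp(delta(c) * w(t))`, where
#' `delta(c) = delta_max * c^h / (c^h + ec50^h)` is a Hill function of
#' concentration and `w(t)` a unit-peak disruption profile. Observed reads are
#' the mean times `exp(eps)` with `eps ~ N(0, noise_sd^2)` per read
#' (multiplicative lognormal noise; the instrument noise model is an
#' assumption of the generator, not a measured property).
#'
#' @param baseline Baseline luminescence `B` (detector units, > 0).
#' @param amplitude Stimulus response amplitude `A` (fold over baseline at the
#'   peak, >= 0). Default 100: live-cell NanoLuc reporters driven by serum
#'   response elements have a dynamic range of roughly two orders of
#'   magnitude, and the scaled fold-change normalization is only faithful to
#'   the underlying log disruption when induction is strong (see the methods
#'   vignette).
#' @param peak_time_h Time of the stimulated response peak `t_p` in hours
#'   (default 5; responses peak at about 4--6 h post stimulus).
#' @param delta_max Signed maximal disruption in log-fold units.
#' @param ec50 Concentration of half-maximal disruption (ug/mL).
#' @param hill Hill slope (> 0).
#' @param profile Disruption time profile: `"sustained"`
#'   (`w(t) = 1 - exp(-t/4)`, ramps up and holds, like retinoic-acid- or
#'   methoxyacetic-acid-type responses), `"transient"`
#'   (`w(t) = (t/4) * exp(1 - t/4)`, peaks near 4 h then decays, like a
#'   methylmercury-type response) or `"constant"` (`w(t) = 1`, a testing
#'   hook).
#' @param noise_sd Log-scale standard deviation of the multiplicative read
#'   noise (>= 0).
#' @param bfgf_dose_ng_ml Stimulus dose recorded as metadata (default 2).
#'
#' @returns A list of class `"signal_params"`.
#' @export
signal_params <- function(baseline = 1000,
                          amplitude = 100,
                          peak_time_h = 5,
                          delta_max = 0.5,
                          ec50 = 10,
                          hill = 1,
                          profile = c("sustained", "transient", "constant"),
                          noise_sd = 0.05,
                          bfgf_dose_ng_ml = 2) {
  profile <- match.arg(profile)
  if (baseline <= 0) {
    abort("`baseline` must be > 0.", class = "abc_error_param")
  }
  if (amplitude < 0) abort("`amplitude` must be >= 0.", class = "abc_error_param")
  if (peak_time_h <= 0 || peak_time_h >= 24) {
    abort("`peak_time_h` must lie in (0, 24).", class = "abc_error_param")
  }
  if (hill <= 0) abort("`hill` must be > 0.", class = "abc_error_param")
  if (ec50 <= 0) abort("`ec50` must be > 0.", class = "abc_error_param")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.", class = "abc_error_param")
  structure(
    list(baseline = baseline, amplitude = amplitude, peak_time_h = peak_time_h,
         delta_max = delta_max, ec50 = ec50, hill = hill, profile = profile,
         noise_sd = noise_sd, bfgf_dose_ng_ml = bfgf_dose_ng_ml),
    class = "signal_params"
  )
}

# unit-peak stimulated response
impulse_response <- function(t, peak_time_h) {
  (t / peak_time_h) * exp(1 - t / peak_time_h)
}

# disruption time profiles (unit scale)
disruption_profile <- function(t, profile) {
  switch(profile,
         sustained = 1 - exp(-t / 4),
         transient = (t / 4) * exp(1 - t / 4),
         constant = rep(1, length(t)))
}

# Hill disruption magnitude at concentration c (log-fold units, signed)
hill_disruption <- function(concentration, params) {
  c_ <- concentration
  ifelse(c_ <= 0, 0,
         params$delta_max * c_^params$hill /
           (c_^params$hill + params$ec50^params$hill))
}

#' Simulate a reporter-assay plate time series
#'
#' Generates one plate in the long plate-CSV schema: `n_replicates` background
#' wells, `n_replicates` stimulated vehicle wells, and `n_replicates`
#' stimulated chemical wells at each requested concentration, all read on a
#' shared time grid. Replicate noise is drawn in a fixed well order from a
#' single RNG stream, so a given seed always reproduces the same plate.
#'
#' @param params A [signal_params()] object.
#' @param concentrations Numeric vector of exposure concentrations (ug/mL).
#' @param config An [run_config()] object; supplies the replicate count and
#'   monitoring window.
#' @param seed Integer seed (required).
#' @param chemical Chemical name for the exposure wells.
#' @param plate_id Plate identifier.
#' @param sample_times Measurement times in hours; defaults to the window at
#'   the configured grid step.
#'
#' @returns A plate tibble (see [read_plate_csv()] for the schema).
#' @export
#' @examples
#' plate <- simulate_timecourse(signal_params(noise_sd = 0),
#'                              concentrations = c(5, 10),
#'                              config = run_config(), seed = 1)
#' dplyr::count(plate, role)
simulate_timecourse <- function(params, concentrations,
                                config = run_config(), seed,
                                chemical = "CHEM", plate_id = "plate1",
                                sample_times = NULL) {
  stopifnot(inherits(params, "signal_params"), inherits(config, "abc_config"))
  if (missing(seed) || is.null(seed)) {
    abort("An explicit integer `seed` is required.", class = "abc_error_param")
  }
  if (length(concentrations) < 1 || any(concentrations < 0)) {
    abort("Need at least one non-negative concentration.",
          class = "abc_error_param")
  }
  if (toupper(chemical) == VEHICLE) {
    abort("'VEHICLE' is reserved for control wells.", class = "abc_error_param")
  }
  t <- sample_times %||%
    seq(config$window[1], config$window[2], by = config$eval_grid_step_h)
  n_rep <- config$n_replicates
  g <- impulse_response(t, params$peak_time_h)
  w <- disruption_profile(t, params$profile)
  mean_bg <- rep(params$baseline, length(t))
  mean_veh <- params$baseline * (1 + params$amplitude * g)

  conditions <- bind_rows(
    tibble(chemical = VEHICLE, concentration_ug_ml = 0, role = "background"),
    tibble(chemical = VEHICLE, concentration_ug_ml = 0, role = "vehicle_bfgf"),
    tibble(chemical = chemical, concentration_ug_ml = sort(concentrations),
           role = "chemical_bfgf")
  )

  withr_seed <- function(expr) { # deterministic stream, restore RNG state
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
    set.seed(as.integer(seed))
    expr
  }

  withr_seed({
    rows <- vector("list", nrow(conditions) * n_rep)
    k <- 0L
    well_i <- 0L
    for (i in seq_len(nrow(conditions))) {
      cond <- conditions[i, ]
      mu <- switch(cond$role,
        background = mean_bg,
        vehicle_bfgf = mean_veh,
        chemical_bfgf = mean_veh *
          exp(hill_disruption(cond$concentration_ug_ml, params) * w)
      )
      for (r in seq_len(n_rep)) {
        well_i <- well_i + 1L
        eps <- if (params$noise_sd > 0) rnorm(length(t), 0, params$noise_sd)
               else numeric(length(t))
        k <- k + 1L
        rows[[k]] <- tibble(
          plate_id = plate_id,
          well = sprintf("W%02d", well_i),
          time_h = t,
          chemical = cond$chemical,
          concentration_ug_ml = cond$concentration_ug_ml,
          role = cond$role,
          replicate = as.integer(r),
          luminescence = mu * exp(eps)
        )
      }
    }
    validate_plate(bind_rows(rows))
  })
}

#' Simulate an endpoint viability dataset
#'
#' Draws absorbance reads from the four-parameter log-logistic model
#' `f(x; b, c, d, e)` (see [fit_4pl()]):
#' `abs_sample = abs_blank + (abs_vehicle - abs_blank) * f(x) + noise`.
#'
#' @param truth Named numeric vector `c(b=, c=, d=, e=)` of the generating
#'   model.
#' @param concentrations Dose series (ug/mL, > 0).
#' @param noise_sd Additive absorbance noise SD.
#' @param seed Integer seed.
#' @param chemical Chemical label.
#' @param n_replicates Replicates per dose.
#' @param abs_blank,abs_vehicle Blank and vehicle-control absorbances
#'   (`abs_vehicle` must exceed `abs_blank`).
#' @returns A viability tibble (see [read_viability_csv()]).
#' @export
simulate_viability <- function(truth, concentrations, noise_sd = 0.02, seed,
                               chemical = "CHEM", n_replicates = 3,
                               abs_blank = 0.08, abs_vehicle = 1.0) {
  stopifnot(all(c("b", "c", "d", "e") %in% names(truth)))
  if (abs_vehicle <= abs_blank) {
    abort("abs_vehicle must exceed abs_blank.", class = "abc_error_param")
  }
  if (missing(seed) || is.null(seed)) {
    abort("An explicit integer `seed` is required.", class = "abc_error_param")
  }
  if (any(concentrations <= 0)) {
    abort("Viability doses must be > 0.", class = "abc_error_param")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  set.seed(as.integer(seed))
  grid <- tidyr::expand_grid(concentration_ug_ml = sort(concentrations,
                                                        decreasing = TRUE),
                             replicate = seq_len(n_replicates))
  f <- ll4_fun(truth[["b"]], truth[["c"]], truth[["d"]], truth[["e"]])
  viab <- f(grid$concentration_ug_ml)
  tibble(
    chemical = chemical,
    concentration_ug_ml = grid$concentration_ug_ml,
    replicate = as.integer(grid$replicate),
    abs_sample = abs_blank + (abs_vehicle - abs_blank) * viab +
      (if (noise_sd > 0) rnorm(nrow(grid), 0, noise_sd) else 0),
    abs_blank = abs_blank,
    abs_vehicle = abs_vehicle
  )
}

#' Analytic ABC of the generating model (noise-free oracle)
#'
#' Under the generator, the true log fold change of a chemical condition is
#' exactly `delta(c) * w(t)`, so the area between the control and chemical
#' curves over the monitoring window is `|delta(c)| * integral of w`. The
#' integral is evaluated by fine-grid trapezoid quadrature (step 0.005 h).
#' Used as the ground truth in parameter-recovery checks; read noise plays no
#' role.
#'
#' @param params A [signal_params()] object.
#' @param concentration Single exposure concentration (ug/mL).
#' @param config An [run_config()] object (window).
#' @returns The true ABC in `|log-fold| * hours`.
#' @export
noiseless_abc_truth <- function(params, concentration, config = run_config()) {
  stopifnot(inherits(params, "signal_params"))
  tt <- seq(config$window[1], config$window[2], by = 0.005)
  w <- disruption_profile(tt, params$profile)
  delta <- hill_disruption(concentration, params)
  int_w <- sum((w[-1] + w[-length(w)]) / 2 * diff(tt))
  # the generator disrupts in natural-log units; rescale to the configured base
  scale_to_base <- switch(config$log_base, natural = 1,
                          `2` = 1 / log(2), `10` = 1 / log(10))
  abs(delta) * int_w * scale_to_base
}
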