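#' Analysis run configuration
#'
#' Collects every tunable of the disruption-scoring pipeline in one validated
#' list, so a whole run can be reproduced from a single object (or a flat
#' key-value text file, see [read_config()]).
#'
#' @param spline_df Effective degrees of freedom of the smoothing splines
#'   fitted to each log fold-change time course. Must be > 1 and smaller than
#'   the number of distinct time points in the data it is applied to.
#' @param eval_grid_step_h Spacing, in hours, of the grid on which spline
#'   curves are evaluated and the trapezoid ABC is accumulated. Must divide the
#'   monitoring window exactly.
#' @param window Two-element numeric, the monitored interval in hours after
#'   stimulus addition. The assay design exposes cells to chemical at -1 h,
#'   adds the growth-factor stimulus at 0 h and reads luminescence over
#'   0--24 h, so the default is `c(0, 24)`.
#' @param log_base Base of the fold-change logarithm: `"natural"`, `"2"` or
#'   `"10"`. Changing the base rescales every ABC value by a constant; the
#'   base is recorded in output metadata.
#' @param epsilon_ratio_floor Small additive floor applied to numerator and
#'   denominator of the scaled-value ratio. Min-max scaling maps the plate
#'   minimum to exactly 0, so an unguarded ratio can blow up; the floor is
#'   expressed as a fraction of the scaled range (default 1e-3).
#' @param n_replicates Default number of replicate wells per condition.
#' @param rng_seed Optional integer seed recorded with the run.
#' @param jt_alpha Significance level of the Jonckheere-Terpstra
#'   concentration-trend test (default 0.001).
#' @param hedges_g_min_effect Minimum Hedge's g treated as a meaningful
#'   effect (default 0.2).
#' @param control_curve How the vehicle-control spline `a(t)` is obtained:
#'   `"replicates"` fits a spline to the vehicle replicates' own log fold
#'   changes against the vehicle mean (near zero, but not identically zero);
#'   `"zero"` fixes `a(t) = 0`.
#'
#' @returns A list of class `"abc_config"`.
#' @seealso [read_config()], [write_config()]
#' @export
#' @examples
#' cfg <- run_config(spline_df = 6)
#' cfg$eval_grid_step_h
run_config <- function(spline_df = 6,
                       eval_grid_step_h = 0.5,
                       window = c(0, 24),
                       log_base = c("natural", "2", "10"),
                       epsilon_ratio_floor = 1e-3,
                       n_replicates = 3L,
                       rng_seed = NULL,
                       jt_alpha = 0.001,
                       hedges_g_min_effect = 0.2,
                       control_curve = c("replicates", "zero")) {
  log_base <- match.arg(as.character(log_base[1]), c("natural", "2", "10"))
  control_curve <- match.arg(control_curve)
  if (!is.numeric(spline_df) || length(spline_df) != 1 || spline_df <= 1) {
    abort("`spline_df` must be a single number > 1.", class = "abc_error_config")
  }
  if (length(window) != 2 || window[2] <= window[1]) {
    abort("`window` must be an increasing pair of hours.", class = "abc_error_config")
  }
  span <- window[2] - window[1]
  if (eval_grid_step_h <= 0 ||
      abs(span / eval_grid_step_h - round(span / eval_grid_step_h)) > 1e-8) {
    abort("`eval_grid_step_h` must be positive and divide the window exactly.",
          class = "abc_error_config")
  }
  if (epsilon_ratio_floor < 0) {
    abort("`epsilon_ratio_floor` must be >= 0.", class = "abc_error_config")
  }
  if (n_replicates < 1) {
    abort("`n_replicates` must be a positive integer.", class = "abc_error_config")
  }
  structure(
    list(
      spline_df = spline_df,
      eval_grid_step_h = eval_grid_step_h,
      window = as.numeric(window),
      log_base = log_base,
      epsilon_ratio_floor = epsilon_ratio_floor,
      n_replicates = as.integer(n_replicates),
      rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed),
      jt_alpha = jt_alpha,
      hedges_g_min_effect = hedges_g_min_effect,
      control_curve = control_curve
    ),
    class = "abc_config"
  )
}

#' @export
print.abc_config <- function(x, ...) {
  cat("<abc_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = " ")))
  }
  invisible(x)
}

# numeric log in the configured base
log_in_base <- function(x, log_base) {
  switch(log_base,
         natural = log(x),
         `2` = log2(x),
         `10` = log10(x))
}

#' Read / write a run configuration as a flat key-value file
#'
#' The on-disk format is one `key: value` pair per line; `window` is stored as
#' two comma-separated numbers. Unknown keys are rejected.
#'
#' @param path File path.
#' @returns `read_config()` returns an `abc_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path), class = "abc_error_io")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(p) paste(p[-1], collapse = ":"), ""))
  allowed <- names(formals(run_config))
  bad <- setdiff(keys, allowed)
  if (length(bad)) {
    abort(paste0("Unknown config key(s): ", paste(bad, collapse = ", ")),
          class = "abc_error_config")
  }
  args <- setNames(as.list(vals), keys)
  num_keys <- c("spline_df", "eval_grid_step_h", "epsilon_ratio_floor",
                "jt_alpha", "hedges_g_min_effect")
  for (k in intersect(names(args), num_keys)) args[[k]] <- as.numeric(args[[k]])
  for (k in intersect(names(args), c("n_replicates", "rng_seed"))) {
    args[[k]] <- as.integer(args[[k]])
  }
  if ("window" %in% names(args)) {
    args$window <- as.numeric(strsplit(args$window, ",")[[1]])
  }
  do.call(run_config, args)
}

#' @rdname read_config
#' @param config An `abc_config` object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "abc_config"))
  fmt <- function(v) paste(format(v, scientific = FALSE, trim = TRUE),
                           collapse = ",")
  keep <- !vapply(config, is.null, TRUE)
  writeLines(sprintf("%s: %s", names(config)[keep],
                     vapply(config[keep], fmt, "")), path)
  invisible(path)
}
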