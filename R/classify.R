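# Jonckheere-Terpstra machinery ------------------------------------------

# JT statistic for a list of groups in increasing dose order:
# sum over i < j of #{x in g_i, y in g_j : y > x} + 1/2 #{ties}
jt_statistic <- function(groups) {
  s <- 0
  k <- length(groups)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      cmp <- outer(groups[[j]], groups[[i]], "-")
      s <- s + sum(cmp > 0) + 0.5 * sum(cmp == 0)
    }
  }
  s
}

# null mean and tie-corrected variance of the JT statistic
jt_moments <- function(groups) {
  n_i <- lengths(groups)
  N <- sum(n_i)
  pooled <- unlist(groups, use.names = FALSE)
  t_j <- as.numeric(table(pooled)) # tie-group sizes
  mu <- (N^2 - sum(n_i^2)) / 4
  v1 <- (N * (N - 1) * (2 * N + 5) -
           sum(n_i * (n_i - 1) * (2 * n_i + 5)) -
           sum(t_j * (t_j - 1) * (2 * t_j + 5))) / 72
  v2 <- sum(n_i * (n_i - 1) * (n_i - 2)) * sum(t_j * (t_j - 1) * (t_j - 2)) /
    (36 * N * (N - 1) * (N - 2))
  v3 <- sum(n_i * (n_i - 1)) * sum(t_j * (t_j - 1)) / (8 * N * (N - 1))
  list(mean = mu, var = v1 + v2 + v3)
}

# exact one-sided p by full enumeration of group assignments (multiset
# permutation distribution); feasible for small total n
jt_exact_p <- function(groups) {
  pooled <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  obs <- jt_statistic(groups)
  count <- c(ge = 0, total = 0)
  recurse <- function(values, remaining_sizes, acc) {
    if (!length(remaining_sizes)) {
      count["total"] <<- count["total"] + 1
      if (jt_statistic(acc) >= obs - 1e-9) count["ge"] <<- count["ge"] + 1
      return(invisible())
    }
    n1 <- remaining_sizes[1]
    idx <- utils::combn(length(values), n1, simplify = FALSE)
    for (sel in idx) {
      recurse(values[-sel], remaining_sizes[-1],
              c(acc, list(values[sel])))
    }
  }
  recurse(pooled, sizes, list())
  unname(count["ge"] / count["total"])
}

# internal JT engine shared by the tidy front end and the pipeline
jt_test <- function(groups, method = c("auto", "normal", "exact"),
                    exact_n_max = 8) {
  method <- match.arg(method)
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    abort("Jonckheere-Terpstra needs >= 2 nonempty dose groups.",
          class = "abc_error_value")
  }
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  stat <- jt_statistic(groups)
  mom <- jt_moments(groups)
  if (length(unique(pooled)) == 1) {
    # fully tied degenerate case: no evidence either way
    return(list(statistic = stat, z = 0, p_value = 0.5, method = "degenerate"))
  }
  use_exact <- method == "exact" || (method == "auto" && N <= exact_n_max)
  if (use_exact) {
    p <- jt_exact_p(groups)
    z <- if (mom$var > 0) (stat - mom$mean) / sqrt(mom$var) else 0
    return(list(statistic = stat, z = z, p_value = p, method = "exact"))
  }
  if (mom$var <= 0) {
    return(list(statistic = stat, z = 0, p_value = 0.5, method = "degenerate"))
  }
  # one-sided (increasing trend), continuity-corrected normal approximation
  z <- (stat - mom$mean - 0.5) / sqrt(mom$var)
  list(statistic = stat, z = z, p_value = pnorm(z, lower.tail = FALSE),
       method = "normal")
}

#' Jonckheere-Terpstra trend test across concentration-ordered groups
#'
#' Tests for a monotone increase of a response (here, per-replicate ABC
#' values) across dose groups ordered by concentration. The statistic counts
#' concordant between-group pairs, with ties counted 1/2. The one-sided
#' p-value comes from exact enumeration of the permutation distribution when
#' the total sample size is at most `exact_n_max` (default 8), and otherwise
#' from a continuity-corrected normal approximation with tie-corrected
#' variance. When every observation is identical the test is degenerate and
#' `p = 0.5` by convention.
#'
#' @param data A tibble in long format.
#' @param value Name of the response column.
#' @param group Name of the ordering column (numeric concentration, or a
#'   factor whose level order is the dose order).
#' @param method `"auto"` (default), `"normal"` or `"exact"`.
#' @param exact_n_max Largest total n for which `"auto"` enumerates exactly.
#' @param alpha Significance level for the `significant` flag (default the
#'   0.001 used for concentration-trend calls).
#' @returns A one-row tibble: `jt_statistic`, `z`, `p_value`, `method`,
#'   `significant`.
#' @export
#' @examples
#' d <- tibble::tibble(conc = rep(c(1, 10, 100), each = 2),
#'                     abc = c(1, 2, 3, 4, 5, 6))
#' jonckheere_terpstra(d, value = "abc", group = "conc")
jonckheere_terpstra <- function(data, value, group,
                                method = c("auto", "normal", "exact"),
                                exact_n_max = 8, alpha = 0.001) {
  missing_cols <- setdiff(c(value, group), names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "abc_error_schema")
  }
  g <- data[[group]]
  ord <- if (is.factor(g)) g else factor(g, levels = sort(unique(g)))
  groups <- split(data[[value]], ord, drop = TRUE)
  res <- jt_test(groups, method = method, exact_n_max = exact_n_max)
  tibble(jt_statistic = res$statistic, z = res$z, p_value = res$p_value,
         method = res$method, significant = res$p_value < alpha)
}

# ROC / threshold machinery ----------------------------------------------

#' ROC analysis of per-chemical disruption scores
#'
#' Builds the empirical ROC over all distinct cutpoints of the score (each
#' realized as the midpoint between adjacent distinct scores, plus sentinels
#' below the minimum and above the maximum), computes the AUC as the
#' pair-concordance probability (ties counted 1/2), and selects the operating
#' threshold closest to the ideal corner at (false positive 0, true positive
#' 1). The call rule is `score >= threshold -> positive`; corner-distance ties
#' are broken toward higher specificity.
#'
#' @param data A tibble of chemicals with a score and a reference label.
#' @param score Name of the score column (default `sum_abc`).
#' @param label Name of the label column.
#' @param positive Value of `label` denoting a true positive (default `"P"`).
#' @returns An object of class `"abc_roc"`: list with `points` (tibble of
#'   threshold, tpr, fpr, sensitivity, specificity, accuracy, corner
#'   distance), `auc`, `optimal_threshold`, `sensitivity`, `specificity`,
#'   `accuracy`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' tab <- read_validation_table()
#' roc <- roc_abc(tab, score = "sum_abc", label = "animal_label")
#' round(roc$auc, 2)
roc_abc <- function(data, score = "sum_abc", label = "animal_label",
                    positive = "P") {
  missing_cols <- setdiff(c(score, label), names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "abc_error_schema")
  }
  s <- data[[score]]
  y <- data[[label]] == positive
  if (!any(y) || all(y)) {
    abort("Both classes must be present to build a ROC curve.",
          class = "abc_error_value")
  }
  n_pos <- sum(y); n_neg <- sum(!y)
  # AUC as pair concordance with ties = 1/2
  diffs <- outer(s[y], s[!y], "-")
  auc <- (sum(diffs > 0) + 0.5 * sum(diffs == 0)) / (n_pos * n_neg)

  ss <- sort(unique(s))
  cutpoints <- c(ss[1] - 1, (ss[-1] + ss[-length(ss)]) / 2,
                 ss[length(ss)] + 1)
  points <- purrr::map_dfr(cutpoints, function(th) {
    pred <- s >= th
    tp <- sum(pred & y); fn <- sum(!pred & y)
    fp <- sum(pred & !y); tn <- sum(!pred & !y)
    sens <- tp / n_pos; spec <- tn / n_neg
    tibble(threshold = th, tpr = sens, fpr = 1 - spec,
           sensitivity = sens, specificity = spec,
           accuracy = (tp + tn) / length(s),
           corner_distance = sqrt((1 - sens)^2 + (1 - spec)^2))
  })
  # closest-to-corner threshold; ties broken toward higher specificity,
  # then toward the higher cutpoint
  best <- points |>
    arrange(.data$corner_distance, dplyr::desc(.data$specificity),
            dplyr::desc(.data$threshold)) |>
    head(1)
  structure(
    list(points = arrange(points, .data$fpr, .data$tpr),
         auc = auc,
         optimal_threshold = best$threshold,
         sensitivity = best$sensitivity,
         specificity = best$specificity,
         accuracy = best$accuracy,
         n_pos = n_pos, n_neg = n_neg),
    class = "abc_roc"
  )
}

#' @export
print.abc_roc <- function(x, ...) {
  cat(sprintf("<abc_roc> %d positives vs %d negatives\n", x$n_pos, x$n_neg))
  cat(sprintf("  AUC %.4f; optimal threshold %.4g (sens %.3f, spec %.3f, acc %.3f)\n",
              x$auc, x$optimal_threshold, x$sensitivity, x$specificity,
              x$accuracy))
  invisible(x)
}

#' @export
tidy.abc_roc <- function(x, ...) x$points

#' @export
glance.abc_roc <- function(x, ...) {
  tibble(auc = x$auc, optimal_threshold = x$optimal_threshold,
         sensitivity = x$sensitivity, specificity = x$specificity,
         accuracy = x$accuracy, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @export
autoplot.abc_roc <- function(object, ...) {
  best <- filter(object$points,
                 .data$threshold == object$optimal_threshold)
  ggplot(object$points, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_step(direction = "hv", colour = "steelblue") +
    geom_point(data = best, colour = "firebrick", size = 2) +
    coord_equal() +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("AUC = %.2f", object$auc)) +
    theme_minimal()
}

#' Optimal operating point of a ROC curve
#'
#' Convenience accessor returning the closest-to-corner threshold and its
#' operating characteristics from an [roc_abc()] object.
#'
#' @param roc An `"abc_roc"` object.
#' @returns One-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `accuracy`.
#' @export
optimal_threshold <- function(roc) {
  stopifnot(inherits(roc, "abc_roc"))
  tibble(threshold = roc$optimal_threshold,
         sensitivity = roc$sensitivity,
         specificity = roc$specificity,
         accuracy = roc$accuracy)
}

# Effect size and calls --------------------------------------------------

#' Hedge's g of replicate disruption scores against a threshold
#'
#' One-sample standardized difference of a chemical's replicate sum-of-ABC
#' values from the classification threshold, with the small-sample bias
#' correction `J = 1 - 3 / (4(n - 1) - 1)`:
#' `g = J * (mean(x) - threshold) / sd(x)`.
#'
#' @param x Numeric vector of per-replicate sum-of-ABC scores (n >= 2).
#' @param threshold Classification threshold.
#' @returns The signed effect size (dimensionless).
#' @export
#' @examples
#' hedges_g(c(40, 42, 44), 38) # 4/7 * 4 / 2
hedges_g <- function(x, threshold) {
  n <- length(x)
  if (n < 2) {
    abort("Hedge's g needs at least 2 replicate scores.",
          class = "abc_error_value")
  }
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort("Hedge's g is undefined for zero replicate variance.",
          class = "abc_error_value")
  }
  j <- 1 - 3 / (4 * (n - 1) - 1)
  j * (mean(x) - threshold) / s
}

#' Classify chemicals against the disruption threshold
#'
#' Applies the decision rule `sum_abc >= threshold -> P` (a score exactly at
#' the threshold is called positive) and attaches Hedge's g effect sizes of
#' the replicate sums against the threshold, with the flag for effects at or
#' above the configured minimum (default 0.2).
#'
#' @param summary A per-chemical tibble with `sum_abc` and (optionally) a
#'   `replicate_sums` list column, e.g. from [summarise_chemicals()].
#' @param threshold Classification threshold (e.g.
#'   `optimal_threshold(roc)$threshold`).
#' @param config An [run_config()] object (minimum effect size).
#' @returns `summary` with columns `call` (`"P"`/`"N"`), `hedges_g` and
#'   `exceeds_min_effect` added.
#' @export
classify_chemicals <- function(summary, threshold, config = run_config()) {
  if (!"sum_abc" %in% names(summary)) {
    abort("`summary` must contain a sum_abc column.",
          class = "abc_error_schema")
  }
  out <- mutate(as_tibble(summary),
                call = ifelse(.data$sum_abc >= threshold, "P", "N"))
  if ("replicate_sums" %in% names(summary)) {
    out$hedges_g <- map_dbl(summary$replicate_sums, function(x) {
      if (length(x) < 2 || sd(x) == 0) NA_real_ else hedges_g(x, threshold)
    })
    out$exceeds_min_effect <- !is.na(out$hedges_g) &
      out$hedges_g >= config$hedges_g_min_effect
  }
  out
}
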