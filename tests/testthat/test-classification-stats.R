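test_that("JT statistic and exact p match hand-enumerated cases", {
  # three groups of two in strict increasing order: maximal statistic,
  # one arrangement in 90 achieves it
  d <- tibble::tibble(g = rep(1:3, each = 2), v = c(1, 2, 3, 4, 5, 6))
  r <- jonckheere_terpstra(d, value = "v", group = "g")
  expect_equal(r$jt_statistic, 12)
  expect_equal(r$p_value, 1 / 90, tolerance = 1e-12)
  expect_equal(r$method, "exact")

  # fully tied data: degenerate, p = 0.5 by convention
  tied <- tibble::tibble(g = rep(1:3, each = 2), v = rep(7, 6))
  rt <- jonckheere_terpstra(tied, value = "v", group = "g")
  expect_equal(rt$p_value, 0.5)
  n_i <- c(2, 2, 2)
  expect_equal(rt$jt_statistic, (sum(n_i)^2 - sum(n_i^2)) / 4)

  # two groups: JT reduces to the one-sided Mann-Whitney pair count
  d2 <- tibble::tibble(g = rep(1:2, each = 4),
                       v = c(3, 1, 4, 1, 5, 9, 2, 6))
  r2 <- jonckheere_terpstra(d2, value = "v", group = "g")
  x <- d2$v[d2$g == 1]; y <- d2$v[d2$g == 2]
  mw <- sum(outer(y, x, ">")) + 0.5 * sum(outer(y, x, "=="))
  expect_equal(r2$jt_statistic, mw)

  expect_error(jonckheere_terpstra(tibble::tibble(g = 1, v = 1),
                                   value = "v", group = "g"),
               class = "abc_error_value")
})

test_that("exact JT p agrees with brute-force enumeration over group shapes", {
  shapes <- list(c(1, 1, 1), c(2, 2, 2), c(1, 3, 3), c(2, 3, 3), c(4, 4),
                 c(2, 2, 2, 2))
  set.seed(17)
  for (shape in shapes) {
    # integer-valued data so ties occur
    vals <- sample(1:4, sum(shape), replace = TRUE)
    groups <- split(vals, rep(seq_along(shape), shape))
    d <- tibble::tibble(g = rep(seq_along(shape), shape), v = vals)
    r <- jonckheere_terpstra(d, value = "v", group = "g", method = "exact")
    if (length(unique(vals)) == 1) next # degenerate convention tested above
    expect_equal(r$p_value, enumerate_jt_p(groups), tolerance = 1e-12)
  }
})

test_that("JT normal approximation holds its size under the null", {
  set.seed(99)
  rej <- mean(replicate(2000, {
    d <- tibble::tibble(g = rep(1:4, each = 3), v = rnorm(12))
    jonckheere_terpstra(d, "v", "g", method = "normal",
                        alpha = 0.05)$significant
  }))
  # continuity-corrected approximation is near-nominal, slightly conservative
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.07)
})

test_that("pair-concordance AUC matches brute force on random instances", {
  set.seed(31)
  for (i in 1:40) {
    n <- sample(6:50, 1)
    labs <- c("P", "N", sample(c("P", "N"), n - 2, replace = TRUE))
    scores <- round(rnorm(n), sample(c(1, 2), 1)) # rounding induces ties
    d <- tibble::tibble(sum_abc = scores, animal_label = labs)
    roc <- roc_abc(d)
    expect_equal(roc$auc, brute_force_auc(scores, labs == "P"),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(5)
  d <- tibble::tibble(sum_abc = rexp(30),
                      animal_label = sample(c("P", "N"), 30, replace = TRUE,
                                            prob = c(0.6, 0.4)))
  base_auc <- roc_abc(d)$auc
  for (f in list(function(x) 3 * x + 1, log1p, function(x) x^3)) {
    d2 <- d
    d2$sum_abc <- f(d$sum_abc)
    expect_equal(roc_abc(d2)$auc, base_auc, tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(13)
  d <- tibble::tibble(sum_abc = round(rnorm(40), 1),
                      animal_label = sample(c("P", "N"), 40, replace = TRUE))
  ours <- roc_abc(d)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = d$animal_label, predictor = d$sum_abc,
    levels = c("N", "P"), direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("ROC handles separation and degenerate label sets", {
  sep <- tibble::tibble(sum_abc = c(1, 2, 3, 10, 11, 12),
                        animal_label = rep(c("N", "P"), each = 3))
  roc <- roc_abc(sep)
  expect_equal(roc$auc, 1)
  expect_equal(roc$sensitivity, 1)
  expect_equal(roc$specificity, 1)
  expect_equal(min(roc$points$corner_distance), 0)

  one_class <- tibble::tibble(sum_abc = 1:3, animal_label = "P")
  expect_error(roc_abc(one_class), class = "abc_error_value")
})

test_that("closest-to-corner threshold reproduces the reference calls", {
  tab <- read_validation_table()
  roc <- roc_abc(tab)
  th <- optimal_threshold(roc)

  # brute force over every cutpoint as an independent oracle
  cand <- sort(unique(tab$sum_abc))
  cuts <- c(cand[1] - 1, (cand[-1] + cand[-length(cand)]) / 2,
            cand[length(cand)] + 1)
  dist <- vapply(cuts, function(ct) {
    pred <- tab$sum_abc >= ct
    sens <- sum(pred & tab$animal_label == "P") / sum(tab$animal_label == "P")
    spec <- sum(!pred & tab$animal_label == "N") / sum(tab$animal_label == "N")
    sqrt((1 - sens)^2 + (1 - spec)^2)
  }, 0)
  expect_equal(th$threshold, cuts[which.min(dist)])

  # the cutpoint separates AcA (37.09) from SA (38.69)
  expect_gt(th$threshold, 37.09)
  expect_lte(th$threshold, 38.69)
  expect_equal(th$sensitivity, 9 / 12)
  expect_equal(th$specificity, 5 / 6)
})

test_that("Hedge's g follows its small-sample-corrected formula", {
  expect_equal(hedges_g(c(40, 42, 44), 38), (4 / 7) * 4 / 2)
  expect_equal(hedges_g(c(10, 12, 14), 12), 0)

  # the correction factor J vanishes at n = 2, so the sign property is
  # informative only from n = 3 upward
  expect_equal(hedges_g(c(1, 2), 0), 0)
  set.seed(2)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1), mean = runif(1, -5, 5))
    th <- runif(1, -5, 5)
    g <- hedges_g(x, th)
    expect_equal(sign(g), sign(mean(x) - th))
  }

  expect_error(hedges_g(c(3, 3, 3), 1), class = "abc_error_value")
  expect_error(hedges_g(5, 1), class = "abc_error_value")
})

test_that("classification applies the boundary convention score >= threshold", {
  summ <- tibble::tibble(
    chemical = c("MAA", "6-AN", "edge"),
    sum_abc = c(225.30, 24.88, 38),
    replicate_sums = list(c(220, 225, 230), c(24, 25, 26), c(37, 38, 39))
  )
  calls <- classify_chemicals(summ, threshold = 38)
  expect_equal(calls$call, c("P", "N", "P"))
  expect_equal(calls$hedges_g[3], 0)
  expect_false(calls$exceeds_min_effect[3])
  expect_true(calls$exceeds_min_effect[1])
})

test_that("tidy, glance and autoplot expose the ROC object", {
  roc <- roc_abc(read_validation_table())
  pts <- tidy(roc)
  expect_true(all(c("threshold", "tpr", "fpr") %in% names(pts)))
  expect_true(all(diff(pts$fpr) >= 0 | diff(pts$tpr) >= 0))
  gl <- glance(roc)
  expect_equal(gl$n_pos, 12)
  expect_equal(gl$n_neg, 6)
  p <- ggplot2::autoplot(roc)
  expect_s3_class(p, "ggplot")
})
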