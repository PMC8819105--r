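# shared fixture builders -------------------------------------------------

# minimal hand-built plate on a coarse shared grid
make_tiny_plate <- function(times = seq(0, 24, by = 6), chemicals = "chemA",
                            concentrations = 10, n_rep = 3,
                            lum = function(role, conc, t, r) {
                              switch(role, background = 100,
                                     vehicle_bfgf = 100 + 50 * t,
                                     chemical_bfgf = 100 + 60 * t)
                            }) {
  rows <- list()
  add <- function(chem, conc, well_role) {
    for (r in seq_len(n_rep)) {
      lums <- vapply(times, function(t) lum(well_role, conc, t, r), 0)
      rows[[length(rows) + 1]] <<- tibble::tibble(
        plate_id = "p1",
        well = sprintf("%s_%g_%s_%d", chem, conc, well_role, r),
        time_h = times,
        chemical = chem,
        concentration_ug_ml = conc,
        role = well_role,
        replicate = as.integer(r),
        luminescence = lums
      )
    }
  }
  add("VEHICLE", 0, "background")
  add("VEHICLE", 0, "vehicle_bfgf")
  for (chem in chemicals) for (cc in concentrations) {
    add(chem, cc, "chemical_bfgf")
  }
  dplyr::bind_rows(rows)
}

# scaled long tibble ready for fold_change(); vehicle + one chemical
make_scaled_frame <- function(times = 0:4, veh = rep(0.5, 5),
                              chem = rep(1.0, 5), n_rep = 2) {
  grid <- tidyr::expand_grid(replicate = seq_len(n_rep), i = seq_along(times))
  dplyr::bind_rows(
    tibble::tibble(plate_id = "p1", chemical = "VEHICLE",
                   concentration_ug_ml = 0, replicate = grid$replicate,
                   time_h = times[grid$i], role = "vehicle_bfgf",
                   scaled = veh[grid$i]),
    tibble::tibble(plate_id = "p1", chemical = "chemA",
                   concentration_ug_ml = 10, replicate = grid$replicate,
                   time_h = times[grid$i], role = "chemical_bfgf",
                   scaled = chem[grid$i])
  )
}

# spline object with prescribed values on a grid (for ABC arithmetic tests)
curve_on_grid <- function(grid, values) {
  s <- abcscreen::constant_spline(grid, 0)
  s$values <- values
  s
}

# brute-force pairwise concordance AUC (independent of roc_abc internals)
brute_force_auc <- function(scores, is_pos) {
  num <- 0
  for (sp in scores[is_pos]) {
    for (sn in scores[!is_pos]) {
      num <- num + (sp > sn) + 0.5 * (sp == sn)
    }
  }
  num / (sum(is_pos) * sum(!is_pos))
}

# brute-force one-sided exact JT p-value by enumerating every permutation of
# the pooled values over the group layout
enumerate_jt_p <- function(groups) {
  pooled <- unlist(groups)
  sizes <- lengths(groups)
  jt <- function(gr) {
    s <- 0
    for (i in seq_len(length(gr) - 1)) {
      for (j in (i + 1):length(gr)) {
        cmp <- outer(gr[[j]], gr[[i]], "-")
        s <- s + sum(cmp > 0) + 0.5 * sum(cmp == 0)
      }
    }
    s
  }
  obs <- jt(groups)
  perms <- combinat_perms(length(pooled))
  stats <- apply(perms, 1, function(ix) {
    v <- pooled[ix]
    jt(split(v, rep(seq_along(sizes), sizes)))
  })
  mean(stats >= obs - 1e-9)
}

# all permutations of 1..n as a matrix (n <= 8)
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- combinat_perms(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  k <- 1
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                   sub[, seq(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
    out[seq(k, k + nrow(sub) - 1), ] <- block
    k <- k + nrow(sub)
  }
  out
}
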