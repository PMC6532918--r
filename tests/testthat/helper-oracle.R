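# Test helpers: stylized parameter sets and a deterministic expected-value
# cohort recursion used as an independent oracle for the micro-simulation.

# Reference set reduced to a stylized disease process: no DCIS, a single
# (local) stage everywhere, constant hazards, homogeneous risk.
stylized_params <- function(p_onset = 0.004, p_bc_death = 0.10,
                            p_other_death = 0.02) {
  p <- reference_parameters()
  ages <- names(p$incidence_base)
  p$incidence_base[] <- p_onset
  p$dcis_incidence[] <- 0
  p$dcis_to_invasive <- 0
  p$background_mortality[] <- p_other_death
  p$stage_distribution[, , , 1] <- 1
  p$stage_distribution[, , , 2] <- 0
  p$stage_distribution[, , , 3] <- 0
  p$stage_survival[, ] <- p_bc_death
  p$rr_table$density[] <- 1
  p$rr_table$family_history <- 1
  p$rr_table$biopsy <- 1
  p
}

# a parameter set with no disease and no deaths: every woman survives to
# end_age and only screening-pathway events can occur
eventless_params <- function() {
  p <- stylized_params(p_onset = 0, p_bc_death = 0, p_other_death = 0)
  p$overdiagnosis_per_screen <- 0
  p
}

# Deterministic cohort recursion under NO screening, reproducing the
# engine's cycle order (density update, onset/progression, diagnosis,
# breast-cancer death, other-cause death, time-since-diagnosis increment)
# on expected values. Handles risk-factor heterogeneity by enumerating the
# four (family history x biopsy) strata and tracking density jointly with
# the healthy/DCIS states. Returns expected fractions.
cohort_oracle <- function(params) {
  sa <- params$start_age
  T <- params$end_age - sa
  inc <- unname(params$incidence_base)
  dinc <- unname(params$dcis_incidence)
  bmort <- unname(params$background_mortality)
  ssurv <- params$stage_survival
  sdist <- params$stage_distribution
  trans <- params$density_transition
  dens0 <- params$density_prevalence_by_age[1, ]
  rrt <- params$rr_table

  strata <- expand.grid(fh = c(FALSE, TRUE), bx = c(FALSE, TRUE))
  strata$w <- ifelse(strata$fh, params$prevalence_family_history,
                     1 - params$prevalence_family_history) *
    ifelse(strata$bx, params$prevalence_biopsy, 1 - params$prevalence_biopsy)

  dead_bc <- 0; dead_other <- 0; alive_end <- 0

  for (s in seq_len(nrow(strata))) {
    w <- strata$w[s]
    rr_mult <- ifelse(strata$fh[s], rrt$family_history, 1) *
      ifelse(strata$bx[s], rrt$biopsy, 1)
    healthy <- dens0 * w                 # mass by density category
    dcis <- rep(0, 4)
    invasive <- matrix(0, 3, T + 1)      # stage x years-since-diagnosis
    dbc <- 0; doth <- 0

    for (t in seq_len(T)) {
      a <- sa + t - 1L
      if (a > sa && (a - sa) %% 5L == 0L) {
        healthy <- as.vector(healthy %*% trans)
        dcis <- as.vector(dcis %*% trans)
      }
      band <- if (a < 65L) 1L else 2L
      p_inv <- pmin(inc[t] * unname(rrt$density) * rr_mult, 1)
      new_inv_d <- healthy * p_inv
      new_dcis_d <- healthy * dinc[t]
      healthy <- healthy - new_inv_d - new_dcis_d
      prog_d <- dcis * params$dcis_to_invasive
      dcis <- dcis - prog_d + new_dcis_d
      onset_d <- new_inv_d + prog_d
      for (d in 1:4) {
        if (onset_d[d] > 0)
          invasive[, 1] <- invasive[, 1] + onset_d[d] * sdist[4L, d, band, ]
      }
      # breast-cancer death, then other-cause death
      for (st in 1:3) {
        ysb <- c(rep(1L, min(5, T + 1)), rep(2L, max(0, T + 1 - 5)))
        pbc <- ssurv[st, ysb]
        dbc <- dbc + sum(invasive[st, ] * pbc)
        invasive[st, ] <- invasive[st, ] * (1 - pbc)
      }
      doth <- doth + (sum(healthy) + sum(dcis) + sum(invasive)) * bmort[t]
      healthy <- healthy * (1 - bmort[t])
      dcis <- dcis * (1 - bmort[t])
      invasive <- invasive * (1 - bmort[t])
      invasive <- cbind(0, invasive[, -(T + 1), drop = FALSE])
    }
    dead_bc <- dead_bc + dbc
    dead_other <- dead_other + doth
    alive_end <- alive_end + sum(healthy) + sum(dcis) + sum(invasive)
  }
  list(dead_bc = dead_bc, dead_other = dead_other, alive = alive_end)
}

# brute-force frontier classification by dominance and convex-combination
# (extended) dominance; independent of the sweep implementation
frontier_oracle <- function(df) {
  m <- nrow(df)
  status <- rep("on-frontier", m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) next
      if (df$cost[j] <= df$cost[i] && df$effect[j] >= df$effect[i] &&
          (df$cost[j] < df$cost[i] || df$effect[j] > df$effect[i])) {
        status[i] <- "dominated"; break
      }
    }
  }
  # extended dominance: a convex combination of two other points achieves
  # the same effect at strictly lower cost (exact linear interpolation)
  for (i in seq_len(m)) {
    if (status[i] == "dominated") next
    found <- FALSE
    for (j in seq_len(m)) {
      for (k in seq_len(m)) {
        if (j == i || k == i || j >= k) next
        e1 <- df$effect[j]; e2 <- df$effect[k]
        if (e1 == e2) next
        lo <- min(e1, e2); hi <- max(e1, e2)
        if (df$effect[i] < lo || df$effect[i] > hi) next
        th <- (df$effect[i] - e2) / (e1 - e2)
        cc <- th * df$cost[j] + (1 - th) * df$cost[k]
        if (cc < df$cost[i] - 1e-12) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) status[i] <- "extendedly dominated"
  }
  status
}
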