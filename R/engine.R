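# Life-course micro-simulation engine.
#
# Annual cycles from start_age to end_age with a fixed intra-cycle event
# order: (1) 5-yearly density update, (2) screening invitation if due,
# (3) disease onset / DCIS progression, (4) diagnosis and stage assignment,
# (5) utility accrual for the cycle, (6) death draws (breast-cancer death
# before other-cause death), (7) time-since-diagnosis increment. Deaths are
# end-of-cycle: a woman alive at the start of a cycle accrues that full
# year. All randomness comes from pre-drawn uniform streams indexed by
# (woman, purpose, year), so the same seed yields identical disease and
# adherence randomness under every strategy (common random numbers).

# number of invitation-age columns (ages start..stop inclusive)
.n_inv_cols <- function(params) params$screening_stop_age - params$start_age + 1L

#' Common-random-number streams for a cohort
#'
#' Pre-draws every uniform variate the engine can consume, in a fixed
#' order and with fixed dimensions that do not depend on the strategy.
#' Running two strategies on the same streams therefore exposes each woman
#' to identical disease, adherence and work-up randomness, which is what
#' makes incremental comparisons individually matched.
#'
#' @param n cohort size.
#' @param seed integer seed.
#' @param params a \code{screen_params} (sets the age range).
#' @return a list of uniform vectors/matrices, class \code{crn_streams}.
#' @export
crn_streams <- function(n, seed, params = reference_parameters()) {
  T <- params$end_age - params$start_age
  ninv <- .n_inv_cols(params)
  ndens <- (T - 1L) %/% 5L + 1L
  set.seed(seed)
  s <- list(
    profile_density = stats::runif(n),
    profile_fh      = stats::runif(n),
    profile_bx      = stats::runif(n),
    onset   = matrix(stats::runif(n * T), n, T),
    bcdeath = matrix(stats::runif(n * T), n, T),
    other   = matrix(stats::runif(n * T), n, T),
    adh     = matrix(stats::runif(n * ninv), n, ninv),
    fp      = matrix(stats::runif(n * ninv), n, ninv),
    fu      = matrix(stats::runif(n * ninv), n, ninv),
    bx      = matrix(stats::runif(n * ninv), n, ninv),
    ov      = matrix(stats::runif(n * ninv), n, ninv),
    density = matrix(stats::runif(n * ndens), n, ndens),
    stage   = stats::runif(n),
    subtype = stats::runif(n),
    n = n, seed = seed
  )
  class(s) <- "crn_streams"
  s
}

#' Attendance draw for a screening invitation
#'
#' Each invitation is attended independently with probability
#' \code{adherence_rate}.
#'
#' @param params a \code{screen_params}.
#' @param u uniform draw(s) in [0,1]; drawn internally if absent.
#' @return logical vector.
#' @export
draw_attendance <- function(params, u = stats::runif(1)) {
  u < params$adherence_rate
}

#' Stage at diagnosis
#'
#' Draws the stage of a newly diagnosed invasive cancer from the stage
#' distribution of the woman's screening context. A woman who attended her
#' most recent invitation draws from her interval's table; a woman who did
#' not (or who is outside the screening programme) draws from the
#' no-screening table, the same distribution as women who never attend.
#'
#' @param attended_regularly logical: did she attend the invitation that
#'   would have covered this cancer?
#' @param interval her screening interval in years (1, 2 or 3); ignored
#'   when \code{attended_regularly} is \code{FALSE}.
#' @param density density category 1-4.
#' @param age age at diagnosis.
#' @param params a \code{screen_params}.
#' @param u uniform draw(s); drawn internally if absent.
#' @return integer stage (1 local, 2 regional, 3 distant). All arguments
#'   are vectorized.
#' @export
stage_at_diagnosis <- function(attended_regularly, interval, density, age,
                               params, u = stats::runif(length(density))) {
  ctx <- ifelse(attended_regularly, interval, 4L)
  if (any(is.na(ctx))) stop("missing stage table context")
  band <- ifelse(age < 65L, 1L, 2L)
  sdist <- params$stage_distribution
  p1 <- sdist[cbind(ctx, density, band, 1L)]
  p2 <- sdist[cbind(ctx, density, band, 2L)]
  if (any(is.na(p1))) stop("missing stage_distribution entry")
  ifelse(u < p1, 1L, ifelse(u < p1 + p2, 2L, 3L))
}

.default_opts <- function(adherence_mode = c("per_invitation", "per_woman"),
                          reassign_on_density_change = FALSE,
                          treatment_cost_timing = c("at_diagnosis", "phased"),
                          record_events = FALSE) {
  list(adherence_mode = match.arg(adherence_mode),
       reassign = isTRUE(reassign_on_density_change),
       timing = match.arg(treatment_cost_timing),
       record = isTRUE(record_events))
}

# core vectorized simulation; profiles rows = women; returns per-woman
# records (+ event log when opts$record)
.sim_cohort <- function(strategy, params, streams, profiles,
                        adherence = c("full", "actual"), opts = .default_opts()) {
  adherence <- match.arg(adherence)
  n <- nrow(profiles)
  sa <- params$start_age
  T <- params$end_age - sa
  stop_age <- params$screening_stop_age
  dfs <- discount_factor(params$discount_rate, 0:(T - 1))
  inc   <- unname(params$incidence_base)
  dinc  <- unname(params$dcis_incidence)
  bmort <- unname(params$background_mortality)
  uh    <- unname(params$utility_healthy)
  ucan  <- params$utility_cancer
  ssurv <- params$stage_survival
  sdist <- params$stage_distribution
  dens_cum <- t(apply(params$density_transition, 1, cumsum))
  p_fp <- 1 - params$specificity
  none <- strategy$kind == "none"

  alive <- rep(TRUE, n)
  health <- integer(n)                       # 0 healthy, 1 dcis, 2 dcis detected, 3 invasive
  stage <- rep(NA_integer_, n)
  ys <- rep(NA_integer_, n)
  overdx <- rep(FALSE, n); ov_age <- rep(NA_integer_, n)
  dead_bc <- rep(FALSE, n); dead_other <- rep(FALSE, n)
  density <- profiles$density
  rr <- profiles$combined_rr
  fh <- profiles$family_history; pbx <- profiles$prior_biopsy
  interval <- if (none) rep(NA_integer_, n) else interval_for_profile(strategy, rr)
  cluster <- interval                        # start-age cluster, fixed for reporting
  last_att <- rep(FALSE, n); last_inv_age <- rep(-999L, n)
  qaly <- numeric(n); cost <- numeric(n); ly <- numeric(n)
  s_att <- integer(n); s_inv <- integer(n)
  fp_cnt <- integer(n); fpb <- integer(n)
  dx_stage <- rep(NA_integer_, n); dx_age <- rep(NA_integer_, n)
  subtype <- draw_subtype(params, streams$subtype)
  tc_local <- unname(params$treatment_cost[cbind(subtype, 1L)])
  pend_amt <- numeric(n); pend_left <- integer(n)

  if (n == 0L) {
    return(list(women = .empty_women(), events = NULL))
  }

  if (adherence == "actual" && opts$adherence_mode == "per_woman")
    woman_attends <- streams$adh[, 1] < params$adherence_rate

  ev <- if (opts$record) new.env() else NULL
  if (opts$record) { ev$t <- numeric(0); ev$id <- integer(0)
                     ev$cat <- character(0); ev$cost <- numeric(0); ev$qaly <- numeric(0) }
  log_ev <- function(ids, t, cat, cost = 0, qaly = 0) {
    if (!opts$record || !length(ids)) return(invisible())
    m <- length(ids)
    ev$t <- c(ev$t, rep(t, m)); ev$id <- c(ev$id, ids)
    ev$cat <- c(ev$cat, rep(cat, m))
    ev$cost <- c(ev$cost, rep_len(cost, m)); ev$qaly <- c(ev$qaly, rep_len(qaly, m))
  }

  for (t in seq_len(T)) {
    a <- sa + t - 1L
    df <- dfs[t]
    tt <- t - 1L                               # years since start

    ## 1. density evolution every 5 years
    if (a > sa && (a - sa) %% 5L == 0L) {
      k <- (a - sa) %/% 5L
      idx <- which(alive & health <= 1L)
      if (length(idx)) {
        u <- streams$density[idx, k]
        nd <- density[idx]
        for (d in 1:4) {
          j <- which(nd == d)
          if (length(j)) nd[j] <- pmin(findInterval(u[j], dens_cum[d, ]) + 1L, 4L)
        }
        changed <- which(nd != density[idx])
        density[idx] <- nd
        if (length(changed)) {
          ii <- idx[changed]
          rr[ii] <- combined_relative_risk(density[ii], fh[ii], pbx[ii], params)
          if (opts$reassign && strategy$kind == "stratified")
            interval[ii] <- interval_for_profile(strategy, rr[ii])
        }
      }
    }

    ## 2. screening invitation
    if (!none && a <= stop_age) {
      k <- a - sa + 1L
      due <- which(alive & health <= 1L & !overdx & (a - sa) %% interval == 0L)
      if (length(due)) {
        s_inv[due] <- s_inv[due] + 1L
        att <- if (adherence == "full") rep(TRUE, length(due))
               else if (opts$adherence_mode == "per_woman") woman_attends[due]
               else streams$adh[due, k] < params$adherence_rate
        last_inv_age[due] <- a
        last_att[due] <- att
        ia <- due[att]
        if (length(ia)) {
          s_att[ia] <- s_att[ia] + 1L
          cost[ia] <- cost[ia] + params$cost_mammo * df
          qaly[ia] <- qaly[ia] - params$disutility_screen * df
          log_ev(ia, tt, "screen", params$cost_mammo, -params$disutility_screen)

          h0 <- ia[health[ia] == 0L & !overdx[ia]]
          # overdiagnosis: screen-detection of a never-lethal case
          ovn <- h0[streams$ov[h0, k] < params$overdiagnosis_per_screen]
          if (length(ovn)) {
            overdx[ovn] <- TRUE; ov_age[ovn] <- a
            cost[ovn] <- cost[ovn] + tc_local[ovn] * df
            log_ev(ovn, tt, "treatment", tc_local[ovn], 0)
            h0 <- setdiff(h0, ovn)
          }
          # false-positive work-up among attended, cancer-free women
          f <- h0[streams$fp[h0, k] < p_fp]
          if (length(f)) {
            fp_cnt[f] <- fp_cnt[f] + 1L
            fu <- f[streams$fu[f, k] < params$p_followup_given_fp]
            if (length(fu)) {
              cost[fu] <- cost[fu] + params$cost_followup * df
              log_ev(fu, tt, "followup", params$cost_followup, 0)
              ub <- streams$bx[fu, k]
              core <- fu[ub < params$p_core_needle]
              vac <- fu[ub >= params$p_core_needle &
                        ub < params$p_core_needle + params$p_vacuum]
              if (length(core)) {
                cost[core] <- cost[core] + params$cost_core_needle * df
                log_ev(core, tt, "biopsy", params$cost_core_needle,
                       -params$disutility_biopsy)
              }
              if (length(vac)) {
                cost[vac] <- cost[vac] + params$cost_vacuum * df
                log_ev(vac, tt, "biopsy", params$cost_vacuum,
                       -params$disutility_biopsy)
              }
              bio <- c(core, vac)
              if (length(bio)) {
                fpb[bio] <- fpb[bio] + 1L
                qaly[bio] <- qaly[bio] - params$disutility_biopsy * df
              }
            }
          }
          # DCIS detection at an attended screen
          d1 <- ia[health[ia] == 1L]
          if (length(d1)) {
            health[d1] <- 2L
            cost[d1] <- cost[d1] + tc_local[d1] * df
            log_ev(d1, tt, "treatment", tc_local[d1], 0)
          }
        }
      }
    }

    ## 3. disease onset and DCIS progression
    u <- streams$onset[, t]
    h0 <- which(alive & health == 0L)
    d1 <- which(alive & health == 1L)
    new_inv <- integer(0)
    if (length(h0)) {
      pinv <- pmin(inc[t] * rr[h0], 1)
      hit <- u[h0] < pinv
      dci <- !hit & u[h0] < pinv + dinc[t]
      new_inv <- h0[hit]
      health[h0[dci]] <- 1L
    }
    if (length(d1)) {
      prog <- d1[u[d1] < params$dcis_to_invasive]
      new_inv <- c(new_inv, prog)
    }

    ## 4. diagnosis and stage assignment
    if (length(new_inv)) {
      scr <- if (none) rep(FALSE, length(new_inv)) else
        last_att[new_inv] & (a - last_inv_age[new_inv]) <= interval[new_inv]
      st <- stage_at_diagnosis(scr, if (none) 4L else interval[new_inv],
                               density[new_inv], a, params,
                               u = streams$stage[new_inv])
      stage[new_inv] <- st
      health[new_inv] <- 3L
      ys[new_inv] <- 0L
      dx_stage[new_inv] <- st; dx_age[new_inv] <- a
      tc <- unname(params$treatment_cost[cbind(subtype[new_inv], st)])
      if (opts$timing == "at_diagnosis") {
        cost[new_inv] <- cost[new_inv] + tc * df
        log_ev(new_inv, tt, "treatment", tc, 0)
      } else {
        cost[new_inv] <- cost[new_inv] + tc / 3 * df
        log_ev(new_inv, tt, "treatment", tc / 3, 0)
        pend_amt[new_inv] <- tc / 3
        pend_left[new_inv] <- 2L
      }
    }
    if (opts$timing == "phased") {
      # installments fall in the two cycles after the diagnosis year
      pp <- which(alive & pend_left > 0L & ys > 0L)
      if (length(pp)) {
        cost[pp] <- cost[pp] + pend_amt[pp] * df
        log_ev(pp, tt, "treatment", pend_amt[pp], 0)
        pend_left[pp] <- pend_left[pp] - 1L
      }
    }

    ## 5. utility accrual for the cycle (alive at cycle start)
    al <- which(alive)
    if (length(al)) {
      ly[al] <- ly[al] + 1
      h <- health[al]
      heal <- al[h <= 2L & !overdx[al]]
      if (length(heal)) {
        qaly[heal] <- qaly[heal] + uh[t] * df
        log_ev(heal, tt, "accrual", 0, uh[t])
      }
      ovd <- al[h <= 2L & overdx[al]]
      if (length(ovd)) {
        ph <- ifelse(a - ov_age[ovd] < 1L, 1L, 2L)
        uo <- ucan[cbind(1L, ph)]
        qaly[ovd] <- qaly[ovd] + uo * df
        log_ev(ovd, tt, "accrual", 0, uo)
      }
      iv <- al[h == 3L]
      if (length(iv)) {
        ph <- ifelse(ys[iv] < 1L, 1L, 2L)
        ui <- ucan[cbind(stage[iv], ph)]
        qaly[iv] <- qaly[iv] + ui * df
        log_ev(iv, tt, "accrual", 0, ui)
      }
    }

    ## 6. death draws: breast-cancer death first, then other causes
    iv <- which(alive & health == 3L)
    if (length(iv)) {
      band <- ifelse(ys[iv] < 5L, 1L, 2L)
      pbc <- ssurv[cbind(stage[iv], band)]
      db <- iv[streams$bcdeath[iv, t] < pbc]
      if (length(db)) { dead_bc[db] <- TRUE; alive[db] <- FALSE }
    }
    oth <- which(alive)
    if (length(oth)) {
      dod <- oth[streams$other[oth, t] < bmort[t]]
      if (length(dod)) { dead_other[dod] <- TRUE; alive[dod] <- FALSE }
    }

    ## 7. time since diagnosis
    ivall <- which(health == 3L)
    if (length(ivall)) ys[ivall] <- ys[ivall] + 1L

    if (!any(alive) && t < T) {
      # everyone dead: remaining cycles contribute nothing
      if (all(dead_bc | dead_other)) break
    }
  }

  women <- data.frame(
    id = seq_len(n),
    died_bc = dead_bc, died_other = dead_other,
    life_years = ly, qaly = qaly, cost = cost,
    screens_invited = s_inv, screens_attended = s_att,
    false_positives = fp_cnt, fp_biopsies = fpb,
    overdiagnosed = overdx,
    diagnosed_stage = dx_stage, diagnosis_age = dx_age,
    cluster = cluster
  )
  events <- NULL
  if (opts$record) {
    events <- data.frame(id = ev$id, t = ev$t, category = ev$cat,
                         cost = ev$cost, qaly = ev$qaly)
  }
  list(women = women, events = events)
}

.empty_women <- function() {
  data.frame(id = integer(0), died_bc = logical(0), died_other = logical(0),
             life_years = numeric(0), qaly = numeric(0), cost = numeric(0),
             screens_invited = integer(0), screens_attended = integer(0),
             false_positives = integer(0), fp_biopsies = integer(0),
             overdiagnosed = logical(0), diagnosed_stage = integer(0),
             diagnosis_age = integer(0), cluster = integer(0))
}

#' Simulate a cohort under one strategy
#'
#' Runs the annual-cycle micro-simulation for \code{n} women under a
#' single strategy and adherence scenario. Deterministic for fixed
#' \code{(n, seed)}; because randomness is pre-drawn per woman and purpose
#' (\code{\link{crn_streams}}), the same seed makes the same woman
#' experience identical disease and adherence randomness under every
#' strategy.
#'
#' @param n cohort size (may be 0).
#' @param strategy a \code{\link{screening_strategy}}.
#' @param params a \code{screen_params}.
#' @param seed integer seed.
#' @param adherence \code{"full"} (every invitation attended) or
#'   \code{"actual"} (each invitation attended with probability
#'   \code{adherence_rate}).
#' @param streams,profiles optionally pre-built streams and risk profiles
#'   (reused across strategies for common random numbers); built from
#'   \code{seed} when absent.
#' @param adherence_mode \code{"per_invitation"} (default: an independent
#'   attendance draw per invitation) or \code{"per_woman"} (a woman either
#'   always or never attends).
#' @param reassign_on_density_change if \code{TRUE}, stratified strategies
#'   re-map a woman's screening interval when her density (hence combined
#'   relative risk) changes at a 5-year update; default \code{FALSE}
#'   (interval fixed at the start age).
#' @param treatment_cost_timing \code{"at_diagnosis"} charges the full
#'   bundle in the diagnosis year; \code{"phased"} spreads it evenly over
#'   the diagnosis year and the next two.
#' @param record_events if \code{TRUE}, also return a per-event audit log
#'   (undiscounted amounts with event times); intended for small \code{n}.
#' @return an object of class \code{cohort_tally}: list with \code{women}
#'   (per-woman records), \code{totals} (aggregates), \code{strategy},
#'   \code{adherence}, \code{n}, \code{seed} and optionally \code{events}.
#' @export
run_cohort <- function(n, strategy, params = reference_parameters(), seed = 1L,
                       adherence = c("full", "actual"),
                       streams = NULL, profiles = NULL,
                       adherence_mode = "per_invitation",
                       reassign_on_density_change = FALSE,
                       treatment_cost_timing = "at_diagnosis",
                       record_events = FALSE) {
  adherence <- match.arg(adherence)
  opts <- .default_opts(adherence_mode, reassign_on_density_change,
                        treatment_cost_timing, record_events)
  if (is.null(streams)) streams <- crn_streams(n, seed, params)
  if (is.null(profiles)) {
    profiles <- assign_risk_profiles(params, n, u = list(
      density = streams$profile_density,
      family_history = streams$profile_fh,
      biopsy = streams$profile_bx))
  }
  res <- .sim_cohort(strategy, params, streams, profiles, adherence, opts)
  w <- res$women
  totals <- list(
    n = n,
    deaths_bc = sum(w$died_bc), deaths_other = sum(w$died_other),
    alive_at_end = n - sum(w$died_bc) - sum(w$died_other),
    life_years = sum(w$life_years),
    qaly = sum(w$qaly), cost = sum(w$cost),
    screens_invited = sum(w$screens_invited),
    screens_attended = sum(w$screens_attended),
    false_positives = sum(w$false_positives),
    fp_biopsies = sum(w$fp_biopsies),
    overdiagnosed = sum(w$overdiagnosed),
    diagnosed = sum(!is.na(w$diagnosed_stage))
  )
  structure(list(women = w, totals = totals, events = res$events,
                 strategy = strategy$name, adherence = adherence,
                 n = n, seed = seed),
            class = "cohort_tally")
}

#' @export
print.cohort_tally <- function(x, ...) {
  t <- x$totals
  cat("<cohort_tally>", x$strategy, "|", x$adherence, "adherence | n =", x$n, "\n")
  if (x$n > 0) {
    cat(sprintf("  BC deaths %d (%.2f%%) | diagnosed %d | overdiagnosed %d\n",
                t$deaths_bc, 100 * t$deaths_bc / x$n, t$diagnosed, t$overdiagnosed))
    cat(sprintf("  mean QALY %.3f | mean cost EUR %.2f | FP biopsies/woman %.4f\n",
                t$qaly / x$n, t$cost / x$n, t$fp_biopsies / x$n))
  }
  invisible(x)
}

#' Simulate a single life course
#'
#' Runs the engine for one woman with a given risk profile and returns her
#' complete record together with the per-event cost/utility audit log.
#'
#' @param profile one-row data.frame (or list) with \code{density},
#'   \code{family_history}, \code{prior_biopsy}; \code{combined_rr} is
#'   derived if absent.
#' @inheritParams run_cohort
#' @return list with \code{record} (the per-woman row: breast-cancer death
#'   flag, life years, discounted QALY and cost, screens, false positives,
#'   biopsies, overdiagnosis flag, stage) and \code{events} (the audit
#'   ledger rows).
#' @export
run_life_course <- function(profile, strategy, params = reference_parameters(),
                            seed = 1L, adherence = c("full", "actual"), ...) {
  adherence <- match.arg(adherence)
  pr <- as.data.frame(profile, stringsAsFactors = FALSE)
  if (is.null(pr$combined_rr))
    pr$combined_rr <- combined_relative_risk(pr$density, pr$family_history,
                                             pr$prior_biopsy, params)
  tal <- run_cohort(1L, strategy, params, seed, adherence,
                    profiles = pr, record_events = TRUE, ...)
  list(record = tal$women[1, ], events = tal$events)
}
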