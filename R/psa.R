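# Probabilistic sensitivity analysis: repeated model evaluation over
# parameter draws, cost-effectiveness acceptability curves, CEAC dominance
# classification, expected value of perfect information, and the one-way
# tornado analysis.

#' Run a probabilistic sensitivity analysis
#'
#' For each draw: sample a perturbed parameter set from \code{spec}, run
#' every strategy and the no-screening comparator on a fresh cohort with
#' common random numbers, and record the incremental outcomes. Fully
#' reproducible from \code{seed}. The defaults are scaled down for desk
#' use; both the number of draws and the cohort size per draw are free
#' arguments.
#'
#' @param params base \code{screen_params}.
#' @param spec a \code{\link{psa_spec}}.
#' @param strategies named list of strategies (default: built-in eight).
#' @param n_draws number of parameter draws.
#' @param n_per_draw cohort size per draw.
#' @param seed master seed; per-draw sub-seeds are derived from it.
#' @param adherence scenario to evaluate (\code{"full"} or \code{"actual"}).
#' @param ... passed to \code{\link{run_cohort}}.
#' @return object of class \code{psa_result}: data.frame \code{samples}
#'   with one row per (draw, strategy) — including the comparator at zero
#'   increments — plus the call settings.
#' @export
run_psa <- function(params = reference_parameters(),
                    spec = default_psa_spec(params),
                    strategies = builtin_strategies(),
                    n_draws = 100L, n_per_draw = 50000L, seed = 1L,
                    adherence = c("full", "actual"), ...) {
  adherence <- match.arg(adherence)
  stopifnot(n_draws >= 1)
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 2L * n_draws)
  none <- screening_strategy("No screening", "none")
  rows <- vector("list", n_draws * (length(strategies) + 1L))
  ri <- 0L
  for (d in seq_len(n_draws)) {
    pd <- sample_psa_draw(params, spec, seed = sub[2L * d - 1L])
    streams <- crn_streams(n_per_draw, sub[2L * d], pd)
    profiles <- assign_risk_profiles(pd, n_per_draw, u = list(
      density = streams$profile_density,
      family_history = streams$profile_fh,
      biopsy = streams$profile_bx))
    tally0 <- run_cohort(n_per_draw, none, pd, sub[2L * d], "full",
                         streams = streams, profiles = profiles, ...)
    ri <- ri + 1L
    rows[[ri]] <- data.frame(draw = d, strategy = "No screening",
                             mortality_reduction = 0, incremental_qaly = 0,
                             fp_biopsies = 0, incremental_cost = 0)
    for (nm in names(strategies)) {
      tal <- run_cohort(n_per_draw, strategies[[nm]], pd, sub[2L * d],
                        adherence, streams = streams, profiles = profiles, ...)
      inc <- increments_vs_no_screening(tal, tally0)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(draw = d, strategy = nm,
                               mortality_reduction = inc$mortality_reduction,
                               incremental_qaly = inc$incremental_qaly,
                               fp_biopsies = inc$fp_biopsies,
                               incremental_cost = inc$incremental_cost)
    }
  }
  structure(list(samples = do.call(rbind, rows),
                 n_draws = n_draws, n_per_draw = n_per_draw,
                 seed = seed, adherence = adherence),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result>", x$n_draws, "draws x", x$n_per_draw, "women |",
      x$adherence, "adherence\n")
  s <- x$samples
  agg <- stats::aggregate(cbind(incremental_qaly, incremental_cost) ~ strategy,
                          data = s, FUN = mean)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability that a strategy is
#' optimal is the fraction of PSA draws in which it maximizes net benefit
#' \code{wtp * effect - cost} over all strategies (the comparator
#' included). Ties are broken towards the lower-cost strategy, then by
#' name, so probabilities sum to one at every grid point.
#'
#' @param psa a \code{psa_result} or its \code{samples} data.frame.
#' @param outcome effect column (\code{"incremental_qaly"} or
#'   \code{"mortality_reduction"}).
#' @param wtp numeric grid of willingness-to-pay values (default 0 to
#'   300,000 in steps of 1,000 Euros per effect unit).
#' @return object of class \code{ceac}: data.frame with \code{wtp} and one
#'   probability column per strategy; attribute \code{outcome}.
#' @export
ceac <- function(psa, outcome = "incremental_qaly",
                 wtp = seq(0, 300000, by = 1000)) {
  s <- if (inherits(psa, "psa_result")) psa$samples else psa
  stopifnot(nrow(s) >= 1)
  draws <- sort(unique(s$draw))
  strategies <- sort(unique(s$strategy))
  eff <- matrix(NA_real_, length(draws), length(strategies),
                dimnames = list(NULL, strategies))
  cst <- eff
  for (j in seq_along(strategies)) {
    ss <- s[s$strategy == strategies[j], ]
    ss <- ss[match(draws, ss$draw), ]
    eff[, j] <- ss[[outcome]]
    cst[, j] <- ss$incremental_cost
  }
  prob <- matrix(0, length(wtp), length(strategies),
                 dimnames = list(NULL, strategies))
  for (i in seq_along(wtp)) {
    nb <- wtp[i] * eff - cst
    for (d in seq_along(draws)) {
      best <- which(nb[d, ] == max(nb[d, ]))
      if (length(best) > 1) {
        best <- best[order(cst[d, best], strategies[best])][1]
      }
      prob[i, best] <- prob[i, best] + 1
    }
  }
  out <- data.frame(wtp = wtp, prob / length(draws), check.names = FALSE)
  attr(out, "outcome") <- outcome
  class(out) <- c("ceac", "data.frame")
  out
}

#' @export
plot.ceac <- function(x, ...) {
  strategies <- setdiff(names(x), "wtp")
  graphics::matplot(x$wtp, as.matrix(x[, strategies]), type = "l", lty = 1,
                    xlab = "Willingness to pay (EUR per effect unit)",
                    ylab = "Probability of being optimal", ylim = c(0, 1), ...)
  graphics::legend("topright", legend = strategies, lty = 1,
                   col = seq_along(strategies), cex = 0.7, bty = "n")
  invisible(x)
}

#' Classify the relation between two acceptability curves
#'
#' Pointwise comparison on a shared willingness-to-pay grid:
#' \code{"strictly-above"} when curve A is everywhere at least curve B and
#' somewhere strictly above, \code{"strictly-below"} for the reverse, and
#' \code{"intersecting"} otherwise, in which case the first grid point
#' where the order flips is reported as the crossing threshold.
#'
#' @param ceac_a,ceac_b numeric probability vectors on the same grid, or
#'   single-strategy columns extracted from a \code{\link{ceac}}.
#' @param wtp the shared grid (needed to report the crossing point).
#' @return list with \code{relation} and \code{crossing_wtp} (\code{NA}
#'   unless intersecting).
#' @export
ceac_dominance <- function(ceac_a, ceac_b, wtp = NULL) {
  a <- as.numeric(ceac_a); b <- as.numeric(ceac_b)
  stopifnot(length(a) == length(b))
  if (all(a >= b) && any(a > b))
    return(list(relation = "strictly-above", crossing_wtp = NA_real_))
  if (all(b >= a) && any(b > a))
    return(list(relation = "strictly-below", crossing_wtp = NA_real_))
  cross <- NA_real_
  s <- sign(a - b)
  nz <- which(s != 0)
  if (length(nz) >= 2) {
    flips <- nz[which(diff(s[nz]) != 0) + 1L]
    if (length(flips) && !is.null(wtp)) cross <- wtp[flips[1]]
    else if (length(flips)) cross <- flips[1]
  }
  list(relation = "intersecting", crossing_wtp = cross)
}

#' Expected value of perfect information
#'
#' \code{EVPI = E_draw[max_s NB(s, draw)] - max_s E_draw[NB(s, draw)]} at a
#' given willingness-to-pay, in Euros per woman: the expected gain from
#' resolving all parameter uncertainty before choosing a strategy. Always
#' non-negative; zero under a degenerate (uncertainty-free) PSA.
#'
#' @param psa a \code{psa_result} or its samples data.frame.
#' @param outcome effect column used in the net benefit.
#' @param wtp willingness-to-pay in Euros per effect unit.
#' @return EVPI in Euros per woman.
#' @export
evpi <- function(psa, outcome = "incremental_qaly", wtp = 30000) {
  s <- if (inherits(psa, "psa_result")) psa$samples else psa
  nb <- wtp * s[[outcome]] - s$incremental_cost
  per_draw_max <- tapply(nb, s$draw, max)
  per_strategy_mean <- tapply(nb, s$strategy, mean)
  mean(per_draw_max) - max(per_strategy_mean)
}

#' One-way (tornado) sensitivity analysis
#'
#' Evaluates the model once at the low and once at the high end of each
#' parameter's range, holding everything else at base values and using
#' common random numbers, and reports the absolute outcome swing per
#' parameter, sorted descending.
#'
#' @param params base \code{screen_params}.
#' @param spec a \code{\link{psa_spec}} supplying the ranges.
#' @param strategy the strategy whose incremental outcome is tracked.
#' @param outcome one of \code{"incremental_cost"}, \code{"incremental_qaly"},
#'   \code{"mortality_reduction"}, \code{"fp_biopsies"}.
#' @param n cohort size per evaluation.
#' @param seed integer seed (same streams for every evaluation).
#' @param adherence scenario.
#' @param ... passed to \code{\link{run_cohort}}.
#' @return data.frame with parameter, low/high parameter values, outcomes
#'   at both ends and \code{swing = |high - low|}, sorted by swing.
#' @export
tornado <- function(params = reference_parameters(),
                    spec = default_psa_spec(params),
                    strategy = builtin_strategies()[["Routine 2-year"]],
                    outcome = "incremental_cost",
                    n = 20000L, seed = 1L,
                    adherence = c("full", "actual"), ...) {
  adherence <- match.arg(adherence)
  none <- screening_strategy("No screening", "none")

  eval_at <- function(p) {
    streams <- crn_streams(n, seed, p)
    profiles <- assign_risk_profiles(p, n, u = list(
      density = streams$profile_density,
      family_history = streams$profile_fh,
      biopsy = streams$profile_bx))
    t0 <- run_cohort(n, none, p, seed, "full",
                     streams = streams, profiles = profiles, ...)
    ts <- run_cohort(n, strategy, p, seed, adherence,
                     streams = streams, profiles = profiles, ...)
    increments_vs_no_screening(ts, t0)[[outcome]]
  }

  set_param <- function(nm, value) {
    p <- unclass(params)
    if (nm %in% .PSA_SCALARS) {
      p[[nm]] <- value
    } else if (nm == "stage_distribution") {
      sd <- p$stage_distribution
      sd[, , , 1] <- sd[, , , 1] * value
      tot <- apply(sd, c(1, 2, 3), sum)
      for (s in 1:3) sd[, , , s] <- sd[, , , s] / tot
      p$stage_distribution <- sd
    } else {
      p[[nm]] <- p[[nm]] * value
    }
    if (nm %in% .UNIT_FIELDS) p[[nm]] <- pmin(pmax(p[[nm]], 0), 1)
    class(p) <- "screen_params"
    p
  }

  rows <- lapply(names(spec), function(nm) {
    e <- spec[[nm]]
    if (e$low == e$high) {
      lo <- hi <- eval_at(set_param(nm, e$base))
    } else {
      lo <- eval_at(set_param(nm, e$low))
      hi <- eval_at(set_param(nm, e$high))
    }
    data.frame(parameter = nm, low = e$low, high = e$high,
               outcome_low = lo, outcome_high = hi,
               swing = abs(hi - lo))
  })
  out <- do.call(rbind, rows)
  out[order(-out$swing), ]
}

#' Export CEAC and EVPI results as CSV
#'
#' @param x a \code{\link{ceac}} object.
#' @param path CSV file path.
#' @return \code{path}, invisibly.
#' @export
export_ceac <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
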