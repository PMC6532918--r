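# Decision-analytic point estimates: increments vs. no screening, ICERs,
# the efficiency frontier with extended dominance, adherence-loss and
# elasticity summaries, and the subgroup (risk-cluster) table.

#' Incremental outcomes of a strategy against its matched no-screening arm
#'
#' Both tallies must come from the same cohort (same \code{n} and seed), so
#' differences are individually matched. Mortality reduction is
#' \code{100 * (deaths0 - deaths_s) / deaths0}; QALY, cost and
#' false-positive-biopsy increments are per-woman mean differences.
#' Confidence intervals use the normal approximation on the per-woman
#' paired differences; the mortality-reduction interval uses binomial
#' variance on the paired death indicators via the delta method.
#'
#' @param tally a \code{\link{run_cohort}} result for the strategy.
#' @param tally0 the matched no-screening comparator tally.
#' @param level confidence level (default 0.95).
#' @return object of class \code{strategy_result}: a one-row data.frame
#'   with strategy, adherence, mortality_reduction (\%), incremental_qaly,
#'   fp_biopsies, incremental_cost and their confidence bounds. When the
#'   comparator has zero breast-cancer deaths the mortality reduction is
#'   \code{NA} (not applicable).
#' @export
increments_vs_no_screening <- function(tally, tally0, level = 0.95) {
  stopifnot(tally$n == tally0$n, tally$seed == tally0$seed)
  n <- tally$n
  z <- stats::qnorm(1 - (1 - level) / 2)
  ws <- tally$women; w0 <- tally0$women

  d0 <- sum(w0$died_bc); ds <- sum(ws$died_bc)
  if (n == 0 || d0 == 0) {
    mr <- NA_real_; mr_lo <- NA_real_; mr_hi <- NA_real_
  } else {
    p0 <- d0 / n; ps <- ds / n
    ratio <- ps / p0
    v0 <- stats::var(as.numeric(w0$died_bc))
    vs <- stats::var(as.numeric(ws$died_bc))
    cv <- stats::cov(as.numeric(ws$died_bc), as.numeric(w0$died_bc))
    vr <- ratio^2 * (vs / ps^2 + v0 / p0^2 - 2 * cv / (ps * p0)) / n
    vr <- max(vr, 0)
    mr <- 100 * (1 - ratio)
    mr_lo <- mr - z * 100 * sqrt(vr)
    mr_hi <- mr + z * 100 * sqrt(vr)
  }

  paired <- function(a, b) {
    d <- a - b
    m <- mean(d)
    se <- if (n > 1) stats::sd(d) / sqrt(n) else 0
    c(m, m - z * se, m + z * se)
  }
  dq <- if (n > 0) paired(ws$qaly, w0$qaly) else c(0, 0, 0)
  dc <- if (n > 0) paired(ws$cost, w0$cost) else c(0, 0, 0)
  db <- if (n > 0) paired(ws$fp_biopsies, w0$fp_biopsies) else c(0, 0, 0)

  out <- data.frame(
    strategy = tally$strategy, adherence = tally$adherence,
    mortality_reduction = mr, mr_lower = mr_lo, mr_upper = mr_hi,
    incremental_qaly = dq[1], qaly_lower = dq[2], qaly_upper = dq[3],
    fp_biopsies = db[1], fpb_lower = db[2], fpb_upper = db[3],
    incremental_cost = dc[1], cost_lower = dc[2], cost_upper = dc[3],
    deaths_comparator = d0, deaths_strategy = ds, n = n,
    stringsAsFactors = FALSE
  )
  class(out) <- c("strategy_result", "data.frame")
  out
}

#' Incremental cost-effectiveness ratio
#'
#' \code{delta_cost / delta_effect}, with display rounding to the nearest
#' Euro (the unrounded ratio is kept in the result). A zero effect
#' difference has no defined ratio and is flagged instead of returning a
#' number.
#'
#' @param delta_cost incremental cost in Euros.
#' @param delta_effect incremental effect (for example QALYs).
#' @return list with \code{icer} (rounded to the nearest Euro),
#'   \code{icer_exact} and \code{defined} (FALSE when
#'   \code{delta_effect == 0}, in which case both ratios are \code{NA}).
#' @examples
#' icer(505.66, 0.0116)$icer  # 43591
#' @export
icer <- function(delta_cost, delta_effect) {
  if (delta_effect == 0) {
    return(list(icer = NA_real_, icer_exact = NA_real_, defined = FALSE))
  }
  x <- delta_cost / delta_effect
  list(icer = round(x), icer_exact = x, defined = TRUE)
}

#' Efficiency frontier with simple and extended dominance
#'
#' Classifies strategies in the (effect, cost) plane relative to the
#' comparator at the origin. A strategy is \emph{dominated} when another
#' point (or the comparator) offers at least as much effect for no more
#' cost, with one inequality strict; it is \emph{extendedly dominated}
#' when it is excluded by the increasing-ICER sweep along the remaining
#' points (a convex combination of two other strategies beats it). The
#' frontier is the upper-left convex hull, and ICERs along it are strictly
#' increasing.
#'
#' @param results data.frame with columns \code{strategy}, \code{effect},
#'   \code{cost}; or a list of \code{strategy_result} rows plus an
#'   \code{effect} column choice.
#' @param effect,cost column names to use when \code{results} is a
#'   \code{strategy_result} table (defaults \code{"incremental_qaly"},
#'   \code{"incremental_cost"}).
#' @return object of class \code{efficiency_frontier}: the input with
#'   added columns \code{status} (\code{"on-frontier"}, \code{"dominated"},
#'   \code{"extendedly dominated"}) and \code{icer} (the frontier ICER
#'   against the previous frontier point; \code{NA} off frontier). The
#'   comparator row \code{"(no screening)"} at (0, 0) is added if absent.
#' @export
efficiency_frontier <- function(results, effect = "incremental_qaly",
                                cost = "incremental_cost") {
  if (!all(c("effect", "cost") %in% names(results))) {
    results <- data.frame(strategy = results$strategy,
                          effect = results[[effect]],
                          cost = results[[cost]],
                          stringsAsFactors = FALSE)
  }
  df <- results[, c("strategy", "effect", "cost")]
  if (!any(df$effect == 0 & df$cost == 0)) {
    df <- rbind(data.frame(strategy = "(no screening)", effect = 0, cost = 0),
                df)
  }
  m <- nrow(df)
  status <- rep("on-frontier", m)

  # simple dominance
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) next
      if (df$cost[j] <= df$cost[i] && df$effect[j] >= df$effect[i] &&
          (df$cost[j] < df$cost[i] || df$effect[j] > df$effect[i])) {
        status[i] <- "dominated"
        break
      }
    }
  }

  # increasing-ICER sweep over the non-dominated points
  repeat {
    idx <- which(status == "on-frontier")
    ord <- idx[order(df$effect[idx], df$cost[idx])]
    if (length(ord) < 3) break
    ic <- diff(df$cost[ord]) / diff(df$effect[ord])
    viol <- which(diff(ic) <= 0)
    if (!length(viol)) break
    status[ord[viol[1] + 1L]] <- "extendedly dominated"
  }

  idx <- which(status == "on-frontier")
  ord <- idx[order(df$effect[idx], df$cost[idx])]
  df$status <- status
  df$icer <- NA_real_
  if (length(ord) > 1) {
    df$icer[ord[-1]] <- diff(df$cost[ord]) / diff(df$effect[ord])
  }
  class(df) <- c("efficiency_frontier", "data.frame")
  df
}

#' @export
print.efficiency_frontier <- function(x, ...) {
  cat("Efficiency frontier (effect vs. incremental cost)\n")
  y <- as.data.frame(x)
  y$icer <- ifelse(is.na(y$icer), "", formatC(round(y$icer), format = "d", big.mark = ","))
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
plot.efficiency_frontier <- function(x, xlab = "Incremental effect",
                                     ylab = "Incremental cost (EUR)", ...) {
  on_f <- x$status == "on-frontier"
  graphics::plot(x$effect, x$cost, pch = ifelse(on_f, 19, 1),
                 xlab = xlab, ylab = ylab, ...)
  ord <- order(x$effect[on_f])
  graphics::lines(x$effect[on_f][ord], x$cost[on_f][ord])
  graphics::text(x$effect, x$cost, x$strategy, pos = 4, cex = 0.7)
  invisible(x)
}

#' Relative loss of performance due to reduced adherence
#'
#' \code{100 * (full - reduced) / full} for each outcome, with the sign
#' convention that positive numbers are losses. Returned both at full
#' precision and rounded to whole percent for display. A zero
#' full-adherence value yields \code{NA} (not applicable).
#'
#' @param full,reduced numeric vectors (or \code{strategy_result} rows) of
#'   the same outcome(s) under full and reduced adherence.
#' @return list with \code{loss_pct} (exact) and \code{loss_display}
#'   (rounded to integer percent).
#' @examples
#' adherence_loss(14.46, 8.81)$loss_display  # 39
#' @export
adherence_loss <- function(full, reduced) {
  if (inherits(full, "strategy_result")) {
    fields <- c("mortality_reduction", "incremental_qaly", "incremental_cost",
                "fp_biopsies")
    full <- unlist(full[1, fields]); reduced <- unlist(reduced[1, fields])
  }
  loss <- ifelse(full == 0, NA_real_, 100 * (full - reduced) / full)
  list(loss_pct = loss, loss_display = round(loss))
}

#' Performance change per one-point gain in adherence
#'
#' Divides the relative adherence loss by the adherence gap in percentage
#' points: the average percent of performance gained per +1\% adherence.
#'
#' @param full,reduced outcome values under full and reduced adherence.
#' @param gap adherence gap in percentage points (for example
#'   \code{100 - 54 = 46}).
#' @return elasticity in percent performance per percentage point.
#' @examples
#' round(adherence_elasticity(14.46, 8.81, 46), 2)  # 0.85
#' @export
adherence_elasticity <- function(full, reduced, gap) {
  stopifnot(gap > 0)
  loss <- adherence_loss(full, reduced)$loss_pct
  loss / gap
}

#' Subgroup performance by screening risk cluster
#'
#' For each interval cluster of a strategy (annual / biennial / triennial
#' membership at the start age): the population share, lifetime incidence,
#' mortality reduction and incremental QALY under both adherence
#' scenarios, and the relative loss columns. Increments are computed
#' against the same women in the matched no-screening arm.
#'
#' @param tally_full,tally_actual \code{cohort_tally} objects for the
#'   strategy under full and reduced adherence.
#' @param tally0 the matched no-screening tally.
#' @return data.frame with one row per non-empty cluster.
#' @export
subgroup_table <- function(tally_full, tally_actual, tally0) {
  w0 <- tally0$women
  wf <- tally_full$women
  wa <- tally_actual$women
  stopifnot(nrow(wf) == nrow(w0), nrow(wa) == nrow(w0))
  labs <- c("annual", "biennial", "triennial")
  rows <- list()
  for (k in 1:3) {
    sel <- which(wf$cluster == k)
    share <- 100 * length(sel) / nrow(wf)
    if (!length(sel)) {
      rows[[k]] <- data.frame(cluster = labs[k], population_pct = 0,
                              incidence_pct = NA, mr_full = NA, mr_actual = NA,
                              mr_loss_pct = NA, qaly_full = NA, qaly_actual = NA,
                              qaly_loss_pct = NA)
      next
    }
    d0 <- sum(w0$died_bc[sel])
    mr_f <- if (d0 > 0) 100 * (d0 - sum(wf$died_bc[sel])) / d0 else NA_real_
    mr_a <- if (d0 > 0) 100 * (d0 - sum(wa$died_bc[sel])) / d0 else NA_real_
    q_f <- mean(wf$qaly[sel] - w0$qaly[sel])
    q_a <- mean(wa$qaly[sel] - w0$qaly[sel])
    inc0 <- 100 * sum(!is.na(w0$diagnosed_stage[sel]) | w0$overdiagnosed[sel]) /
      length(sel)
    rows[[k]] <- data.frame(
      cluster = labs[k], population_pct = share, incidence_pct = inc0,
      mr_full = mr_f, mr_actual = mr_a,
      mr_loss_pct = adherence_loss(mr_f, mr_a)$loss_display,
      qaly_full = q_f, qaly_actual = q_a,
      qaly_loss_pct = adherence_loss(q_f, q_a)$loss_display
    )
  }
  do.call(rbind, rows)
}
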