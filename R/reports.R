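# Published strategy-level outcomes for the modelled German screening
# setting, and the arithmetic cross-checks built on them.

#' Published strategy-level outcomes used as cross-check inputs
#'
#' Strategy-level incremental outcomes (mortality reduction in percent,
#' incremental QALY, biopsies after false-positive screening, and
#' incremental cost in 2017 Euros, each per woman vs. no screening) as
#' published for the German mammography screening evaluation that this
#' package models, under full and 54\% adherence. These numbers are fixed
#' external inputs: the package uses them only to cross-check its
#' decision-layer arithmetic (ICERs, adherence losses, elasticities) in
#' \code{\link{worked_examples}}, never to calibrate the simulator.
#'
#' @return list with \code{strategies} (one row per strategy and
#'   adherence scenario), \code{deltas} (the published
#'   triennial-to-annual increments), and \code{subgroups} (selected
#'   published cluster rows: full/reduced mortality reduction and QALY).
#' @export
published_outcomes <- function() {
  strategies <- data.frame(
    strategy = rep(c("Routine 3-year", "Routine 2-year", "Routine 1-year",
                     "RR 2-1", "RR 1-0.5", "RR 2-0.5", "RR 1.5-1", "RR 1.5-0.5"), 2),
    adherence = rep(c("full", "actual"), each = 8),
    mortality_reduction = c(12.22, 14.46, 16.92, 14.26, 16.46, 14.64, 14.96, 15.34,
                            7.68, 8.81, 9.99, 8.63, 9.70, 8.82, 8.95, 9.14),
    incremental_qaly = c(0.033, 0.039, 0.044, 0.038, 0.043, 0.039, 0.040, 0.041,
                         0.020, 0.023, 0.026, 0.023, 0.025, 0.023, 0.024, 0.024),
    fp_biopsies = c(0.037, 0.050, 0.096, 0.048, 0.081, 0.052, 0.056, 0.060,
                    0.022, 0.030, 0.054, 0.028, 0.046, 0.030, 0.032, 0.035),
    incremental_cost = c(305.18, 427.80, 810.84, 404.48, 684.76, 438.52, 474.15, 508.42,
                         157.14, 224.12, 430.75, 211.13, 362.46, 229.97, 248.55, 267.54),
    stringsAsFactors = FALSE
  )
  # unrounded biennial QALYs and triennial-to-annual increments as published
  deltas <- list(
    qaly_biennial_full = 0.0386, qaly_biennial_actual = 0.0233,
    tri_to_annual_cost_full = 505.66, tri_to_annual_qaly_full = 0.0116,
    tri_to_annual_icer_full = 43591,
    tri_to_annual_cost_actual = 273.61, tri_to_annual_qaly_actual = 0.0057,
    tri_to_annual_icer_actual = 48001,
    adherence_gap_points = 46
  )
  subgroups <- data.frame(
    strategy = c("RR 2-1", "RR 2-0.5", "Routine 2-year", "Routine 2-year"),
    cluster = c("annual", "annual", "biennial", "biennial"),
    outcome = c("mortality_reduction", "mortality_reduction",
                "mortality_reduction", "qaly"),
    full = c(91.2, 91.9, 14.3, 0.037),
    actual = c(50.9, 51.3, 8.7, 0.022),
    reported_loss = c(44, 44, 39, 41),
    stringsAsFactors = FALSE
  )
  list(strategies = strategies, deltas = deltas, subgroups = subgroups)
}

#' Recompute the published decision-layer arithmetic
#'
#' Every worked arithmetic result in the published evaluation that is
#' derivable from its own printed tables is recomputed here with this
#' package's decision-layer functions and compared with the printed value:
#' the two triennial-to-annual ICERs (full and 54\% adherence), the
#' biennial adherence losses in mortality reduction, QALY and cost, the
#' mortality elasticity per adherence point, and selected subgroup loss
#' columns. ICERs are compared within 1 Euro (the published reduced-
#' adherence ratio is truncated rather than rounded); rounded loss
#' percentages must match exactly.
#'
#' @return data.frame with columns \code{check}, \code{computed},
#'   \code{reported}, \code{tolerance}, \code{pass}; attribute
#'   \code{all_pass}.
#' @examples
#' worked_examples()
#' @export
worked_examples <- function() {
  po <- published_outcomes()
  st <- po$strategies
  dl <- po$deltas
  g <- function(s, a, f) st[st$strategy == s & st$adherence == a, f]

  rows <- list()
  add <- function(check, computed, reported, tolerance) {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, computed = computed, reported = reported,
      tolerance = tolerance, pass = abs(computed - reported) <= tolerance)
  }

  dc_full <- g("Routine 1-year", "full", "incremental_cost") -
    g("Routine 3-year", "full", "incremental_cost")
  add("triennial-to-annual cost increment, full adherence",
      dc_full, dl$tri_to_annual_cost_full, 0.005)
  add("triennial-to-annual ICER, full adherence (EUR/QALY)",
      icer(dc_full, dl$tri_to_annual_qaly_full)$icer,
      dl$tri_to_annual_icer_full, 1)

  dc_act <- g("Routine 1-year", "actual", "incremental_cost") -
    g("Routine 3-year", "actual", "incremental_cost")
  add("triennial-to-annual cost increment, 54% adherence",
      dc_act, dl$tri_to_annual_cost_actual, 0.005)
  add("triennial-to-annual ICER, 54% adherence (EUR/QALY)",
      icer(dc_act, dl$tri_to_annual_qaly_actual)$icer,
      dl$tri_to_annual_icer_actual, 1)

  add("biennial mortality-reduction loss at 54% adherence (%)",
      adherence_loss(g("Routine 2-year", "full", "mortality_reduction"),
                     g("Routine 2-year", "actual", "mortality_reduction"))$loss_display,
      39, 0)
  add("biennial QALY loss at 54% adherence (%)",
      adherence_loss(dl$qaly_biennial_full, dl$qaly_biennial_actual)$loss_display,
      40, 0)
  add("biennial cost saving at 54% adherence (%)",
      adherence_loss(g("Routine 2-year", "full", "incremental_cost"),
                     g("Routine 2-year", "actual", "incremental_cost"))$loss_display,
      48, 0)

  add("mortality-reduction gain per +1% adherence, biennial",
      round(adherence_elasticity(g("Routine 2-year", "full", "mortality_reduction"),
                                 g("Routine 2-year", "actual", "mortality_reduction"),
                                 dl$adherence_gap_points), 2),
      0.85, 0)

  sg <- po$subgroups
  for (i in seq_len(nrow(sg))) {
    add(paste0(sg$strategy[i], " ", sg$cluster[i], " cluster ", sg$outcome[i],
               " loss (%)"),
        adherence_loss(sg$full[i], sg$actual[i])$loss_display,
        sg$reported_loss[i], 0)
  }

  out <- do.call(rbind, rows)
  attr(out, "all_pass") <- all(out$pass)
  out
}
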