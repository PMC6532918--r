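# Cost and utility accounting: discounting, screening-pathway fees,
# treatment bundles, QALY accrual, and the per-event audit ledger.

#' Discount factor
#'
#' End-of-period discounting on whole years: \code{(1 + rate)^(-t)}.
#' Applied to both costs and utilities with the same rate.
#'
#' @param rate non-negative discount rate (default 3\% per year).
#' @param t non-negative time in years since the start of simulation;
#'   vectorized.
#' @return numeric vector of discount factors in (0, 1].
#' @examples
#' discount_factor(0.03, 10)  # 0.744094
#' @export
discount_factor <- function(rate, t) {
  stopifnot(rate >= 0, all(t >= 0))
  (1 + rate)^(-t)
}

#' Cost of one screening episode along the diagnostic pathway
#'
#' Sums the fee-schedule components present in a screening event record:
#' the mammogram itself if attended, follow-up imaging if a false-positive
#' result was worked up, and a core-needle or vacuum biopsy if one was
#' performed.
#'
#' @param event list or one-row data.frame with logical fields
#'   \code{attended}, \code{followup} and a \code{biopsy} field that is
#'   \code{"none"}, \code{"core_needle"} or \code{"vacuum"}.
#' @param params a \code{screen_params} supplying the fee schedule.
#' @return cost in Euros (undiscounted).
#' @examples
#' p <- reference_parameters()
#' screening_pathway_cost(list(attended = TRUE, followup = FALSE, biopsy = "none"), p)
#' # 73.50
#' @export
screening_pathway_cost <- function(event, params) {
  if (!isTRUE(event$attended)) return(0)
  cost <- params$cost_mammo
  if (isTRUE(event$followup)) cost <- cost + params$cost_followup
  if (identical(event$biopsy, "core_needle")) cost <- cost + params$cost_core_needle
  if (identical(event$biopsy, "vacuum"))      cost <- cost + params$cost_vacuum
  cost
}

#' Treatment cost bundle for a molecular subtype and stage
#'
#' Deterministic lookup of the treatment cost bundle (surgery,
#' chemotherapy with trastuzumab for HER2-positive disease, endocrine
#' therapy, radiotherapy; the distant-stage bundle includes palliative
#' care). Bundles are monotone in stage within each subtype under the
#' reference set.
#'
#' @param subtype \code{"triple_negative"}, \code{"her2_positive"} or
#'   \code{"hormone_receptor_positive"}; or an integer index 1-3.
#' @param stage \code{"local"}, \code{"regional"} or \code{"distant"}; or
#'   an integer index 1-3.
#' @param params a \code{screen_params}.
#' @return cost in Euros.
#' @export
treatment_cost <- function(subtype, stage, params) {
  tc <- params$treatment_cost
  if (is.character(subtype) && !all(subtype %in% rownames(tc)))
    stop("unknown subtype: ", paste(setdiff(subtype, rownames(tc)), collapse = ", "))
  if (is.character(stage) && !all(stage %in% colnames(tc)))
    stop("unknown stage: ", paste(setdiff(stage, colnames(tc)), collapse = ", "))
  tc[cbind(subtype, stage)]
}

#' Draw a molecular subtype from the population mix
#'
#' @param params a \code{screen_params} with \code{subtype_mix}.
#' @param u uniform draw(s) in [0,1]; drawn internally if absent.
#' @return integer vector of subtype indices (1 = triple negative,
#'   2 = HER2-positive, 3 = hormone-receptor positive).
#' @export
draw_subtype <- function(params, u = stats::runif(1)) {
  cw <- cumsum(params$subtype_mix)
  pmin(findInterval(u, cw) + 1L, 3L)
}

#' Annual quality-of-life weight for a health state
#'
#' Healthy women and women with DCIS accrue the age-specific healthy
#' utility; women with invasive cancer accrue the stage- and phase-specific
#' cancer utility (first year after diagnosis vs. later years); the dead
#' accrue zero.
#'
#' @param health \code{"healthy"}, \code{"dcis"}, \code{"invasive"} or
#'   \code{"dead"}.
#' @param age age in years (used for healthy utility).
#' @param stage stage index 1-3 or name (invasive only).
#' @param years_since_diagnosis completed years since diagnosis (invasive
#'   only; 0 = first year).
#' @param params a \code{screen_params}.
#' @return utility weight in [0, 1].
#' @export
qaly_accrual <- function(health, age, stage = NULL, years_since_diagnosis = NULL,
                         params = reference_parameters()) {
  if (health %in% c("healthy", "dcis"))
    return(unname(params$utility_healthy[as.character(age)]))
  if (health == "invasive") {
    phase <- if (years_since_diagnosis < 1) "first_year" else "later"
    return(unname(params$utility_cancer[stage, phase]))
  }
  0
}

# ---- audit ledger ----------------------------------------------------------

#' Build an empty cost-utility ledger
#'
#' The ledger records one row per costed or utility-bearing event of a
#' single simulated life course (category: screen, followup, biopsy,
#' treatment, utility accrual, disutility), with its undiscounted amount
#' and the year it occurred. Discounted totals are always recomputable
#' from the raw entries with \code{\link{ledger_totals}}.
#'
#' @return an object of class \code{cost_utility_ledger}.
#' @export
new_ledger <- function() {
  structure(list(entries = data.frame(t = numeric(0), category = character(0),
                                      cost = numeric(0), qaly = numeric(0))),
            class = "cost_utility_ledger")
}

#' @rdname new_ledger
#' @param ledger a ledger.
#' @param t years since simulation start.
#' @param category event category.
#' @param cost undiscounted cost in Euros.
#' @param qaly undiscounted QALY delta (negative for disutilities).
#' @export
ledger_add <- function(ledger, t, category, cost = 0, qaly = 0) {
  ledger$entries <- rbind(ledger$entries,
                          data.frame(t = t, category = category,
                                     cost = cost, qaly = qaly))
  ledger
}

#' @rdname new_ledger
#' @param rate discount rate.
#' @return \code{ledger_totals}: list with discounted \code{cost} and
#'   \code{qaly} totals.
#' @export
ledger_totals <- function(ledger, rate) {
  e <- ledger$entries
  df <- discount_factor(rate, e$t)
  list(cost = sum(e$cost * df), qaly = sum(e$qaly * df))
}
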