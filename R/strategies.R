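# Screening strategies: routine fixed-interval and relative-risk-stratified.

#' Construct a screening strategy
#'
#' A strategy is either \emph{routine} (everyone screened at a fixed 1-, 2-
#' or 3-year interval), \emph{stratified} (the interval depends on a
#' woman's combined relative risk via an upper and a lower threshold), or
#' \emph{none} (the no-screening comparator).
#'
#' For stratified strategies: relative risk above \code{upper_rr} means
#' annual screening, between the thresholds (inclusive at both ends)
#' biennial, and below \code{lower_rr} triennial.
#'
#' @param name display label.
#' @param kind one of \code{"routine"}, \code{"stratified"}, \code{"none"}.
#' @param routine_interval interval in years (routine only), one of 1, 2, 3.
#' @param upper_rr,lower_rr thresholds (stratified only), \code{upper_rr >
#'   lower_rr > 0}.
#' @return an object of class \code{screening_strategy}.
#' @export
screening_strategy <- function(name, kind = c("routine", "stratified", "none"),
                               routine_interval = NULL,
                               upper_rr = NULL, lower_rr = NULL) {
  kind <- match.arg(kind)
  if (kind == "routine") {
    stopifnot(routine_interval %in% 1:3)
  } else if (kind == "stratified") {
    stopifnot(is.numeric(upper_rr), is.numeric(lower_rr),
              upper_rr > lower_rr, lower_rr > 0)
  }
  structure(list(name = name, kind = kind,
                 routine_interval = routine_interval,
                 upper_rr = upper_rr, lower_rr = lower_rr),
            class = "screening_strategy")
}

#' @export
print.screening_strategy <- function(x, ...) {
  if (x$kind == "routine") {
    cat("<strategy>", x$name, "- routine, every", x$routine_interval, "year(s)\n")
  } else if (x$kind == "stratified") {
    cat("<strategy>", x$name, "- stratified, annual if RR >", x$upper_rr,
        ", biennial in between, triennial if RR <", x$lower_rr, "\n")
  } else cat("<strategy>", x$name, "- no screening\n")
  invisible(x)
}

#' The built-in strategy set
#'
#' Three routine strategies (annual, biennial, triennial) and five
#' risk-stratified strategies built from relative-risk thresholds of 2,
#' 1.5, 1 and 0.5: RR 2-1, RR 1-0.5, RR 1.5-1, RR 1.5-0.5 and RR 2-0.5.
#'
#' @param include_comparator if \code{TRUE}, append the no-screening
#'   comparator as a ninth element.
#' @return named list of \code{\link{screening_strategy}} objects
#'   (8 screening strategies, plus the comparator if requested).
#' @examples
#' length(builtin_strategies())  # 8
#' @export
builtin_strategies <- function(include_comparator = FALSE) {
  s <- list(
    "Routine 3-year" = screening_strategy("Routine 3-year", "routine", routine_interval = 3),
    "Routine 2-year" = screening_strategy("Routine 2-year", "routine", routine_interval = 2),
    "Routine 1-year" = screening_strategy("Routine 1-year", "routine", routine_interval = 1),
    "RR 2-1"     = screening_strategy("RR 2-1",     "stratified", upper_rr = 2.0, lower_rr = 1.0),
    "RR 1-0.5"   = screening_strategy("RR 1-0.5",   "stratified", upper_rr = 1.0, lower_rr = 0.5),
    "RR 2-0.5"   = screening_strategy("RR 2-0.5",   "stratified", upper_rr = 2.0, lower_rr = 0.5),
    "RR 1.5-1"   = screening_strategy("RR 1.5-1",   "stratified", upper_rr = 1.5, lower_rr = 1.0),
    "RR 1.5-0.5" = screening_strategy("RR 1.5-0.5", "stratified", upper_rr = 1.5, lower_rr = 0.5)
  )
  if (include_comparator)
    s <- c(s, list("No screening" = screening_strategy("No screening", "none")))
  s
}

#' Screening interval implied by a combined relative risk
#'
#' For routine strategies the fixed interval is returned regardless of
#' risk. For stratified strategies: risk strictly above the upper
#' threshold maps to annual (1), strictly below the lower threshold to
#' triennial (3), and everything between — boundaries included — to
#' biennial (2). The mapping is a monotone non-increasing step function of
#' risk, and the three intervals partition the positive axis.
#'
#' @param strategy a \code{\link{screening_strategy}} (not the comparator).
#' @param combined_rr positive numeric vector of combined relative risks.
#' @return integer vector of intervals in years (1, 2 or 3).
#' @export
interval_for_profile <- function(strategy, combined_rr) {
  stopifnot(all(combined_rr > 0))
  if (strategy$kind == "routine")
    return(rep(as.integer(strategy$routine_interval), length(combined_rr)))
  if (strategy$kind == "none")
    stop("the no-screening comparator has no screening interval")
  iv <- rep(2L, length(combined_rr))
  iv[combined_rr > strategy$upper_rr] <- 1L
  iv[combined_rr < strategy$lower_rr] <- 3L
  iv
}

#' Invitation ages for a screening interval
#'
#' Invitations fall on the birthday grid: \code{start_age},
#' \code{start_age + interval}, ... up to and including the screening stop
#' age.
#'
#' @param interval years between invitations (1, 2 or 3).
#' @param params a \code{screen_params} supplying \code{start_age} and
#'   \code{screening_stop_age}.
#' @return integer vector of ages.
#' @examples
#' length(screening_ages(2, reference_parameters()))  # 10 invitations
#' @export
screening_ages <- function(interval, params = reference_parameters()) {
  stopifnot(interval %in% 1:3)
  seq(params$start_age, params$screening_stop_age, by = interval)
}
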