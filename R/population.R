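# Risk-factor profiles: assignment at simulation start, 5-yearly density
# evolution, combined relative risks, and population risk-cluster fractions.

#' Combined relative risk for a risk profile
#'
#' The combined relative risk is the product of three per-factor
#' multipliers: a density-category multiplier, a family-history multiplier
#' (applied when a first-degree relative had breast cancer) and a
#' prior-biopsy multiplier. Under the reference parameter set the joint
#' span over all 16 factor combinations is 0.33 to 2.88.
#'
#' @param density integer 1-4, the mammographic density category (1 = almost
#'   entirely fatty ... 4 = extremely dense); vectorized.
#' @param family_history,prior_biopsy logical; vectorized.
#' @param params a \code{screen_params}.
#' @return numeric vector of combined relative risks.
#' @examples
#' p <- reference_parameters()
#' combined_relative_risk(1, FALSE, FALSE, p)  # 0.33
#' combined_relative_risk(4, TRUE, TRUE, p)    # 2.88
#' @export
combined_relative_risk <- function(density, family_history, prior_biopsy, params) {
  rr <- params$rr_table
  unname(rr$density[density]) *
    ifelse(family_history, rr$family_history, 1) *
    ifelse(prior_biopsy, rr$biopsy, 1)
}

# all 16 (density x family history x biopsy) combinations with start-age
# prevalence weights and combined RR
combined_rr_grid <- function(params) {
  g <- expand.grid(density = 1:4, family_history = c(FALSE, TRUE),
                   prior_biopsy = c(FALSE, TRUE))
  dens_prev <- params$density_prevalence_by_age[1, ]
  g$weight <- dens_prev[g$density] *
    ifelse(g$family_history, params$prevalence_family_history,
           1 - params$prevalence_family_history) *
    ifelse(g$prior_biopsy, params$prevalence_biopsy, 1 - params$prevalence_biopsy)
  g$combined_rr <- combined_relative_risk(g$density, g$family_history,
                                          g$prior_biopsy, params)
  g
}

#' Assign risk profiles to a cohort of women
#'
#' Each woman is randomly assigned a risk combination at the start of the
#' simulation: a density category drawn from the start-age density
#' prevalences, and independent Bernoulli draws for family history and
#' prior biopsy. The combined relative risk is derived from the three
#' factors.
#'
#' @param params a \code{screen_params}.
#' @param n number of women; or pass \code{u} directly.
#' @param seed integer seed (ignored if \code{u} is given).
#' @param u optional list of uniform draw vectors (\code{density},
#'   \code{family_history}, \code{biopsy}), each of length \code{n}; used by
#'   the engine's common-random-number streams.
#' @return data.frame with columns \code{density} (1-4),
#'   \code{family_history}, \code{prior_biopsy} (logical) and
#'   \code{combined_rr}.
#' @export
assign_risk_profiles <- function(params, n, seed = 1L, u = NULL) {
  if (is.null(u)) {
    set.seed(seed)
    u <- list(density = stats::runif(n), family_history = stats::runif(n),
              biopsy = stats::runif(n))
  }
  cw <- cumsum(params$density_prevalence_by_age[1, ])
  density <- findInterval(u$density, cw, left.open = FALSE) + 1L
  density <- pmin(density, 4L)
  fh <- u$family_history < params$prevalence_family_history
  bx <- u$biopsy < params$prevalence_biopsy
  data.frame(density = density, family_history = fh, prior_biopsy = bx,
             combined_rr = combined_relative_risk(density, fh, bx, params))
}

#' Update breast density at a 5-year anniversary
#'
#' Breast density may change every 5 years. At ages where
#' \code{(age - start_age)} is a positive multiple of 5, the density
#' category is resampled from the transition row of the current category
#' and the combined relative risk is recomputed; at all other ages the
#' profile is returned unchanged.
#'
#' @param profiles data.frame as returned by \code{\link{assign_risk_profiles}}.
#' @param age current age in years.
#' @param params a \code{screen_params}.
#' @param u optional vector of uniforms (one per woman); drawn internally
#'   if absent.
#' @return the updated profiles data.frame.
#' @export
update_density <- function(profiles, age, params, u = NULL) {
  if (age <= params$start_age || (age - params$start_age) %% 5L != 0L)
    return(profiles)
  n <- nrow(profiles)
  if (is.null(u)) u <- stats::runif(n)
  cw <- t(apply(params$density_transition, 1, cumsum))
  new_density <- integer(n)
  for (d in 1:4) {
    idx <- which(profiles$density == d)
    if (length(idx))
      new_density[idx] <- pmin(findInterval(u[idx], cw[d, ]) + 1L, 4L)
  }
  profiles$density <- new_density
  profiles$combined_rr <- combined_relative_risk(
    new_density, profiles$family_history, profiles$prior_biopsy, params)
  profiles
}

#' Population fraction per screening interval under a strategy
#'
#' Enumerates all (density, family history, biopsy) combinations, weights
#' them by their start-age prevalences, and maps each combination's
#' combined relative risk through the strategy's thresholds. For a routine
#' strategy the whole population falls in its single interval. Fractions
#' sum to 1 exactly.
#'
#' @param params a \code{screen_params}.
#' @param strategy a \code{\link{screening_strategy}}.
#' @return named numeric vector over intervals \code{annual},
#'   \code{biennial}, \code{triennial}.
#' @export
risk_cluster_fractions <- function(params, strategy) {
  out <- c(annual = 0, biennial = 0, triennial = 0)
  if (strategy$kind == "none") return(out)
  g <- combined_rr_grid(params)
  iv <- interval_for_profile(strategy, g$combined_rr)
  for (k in 1:3) out[k] <- sum(g$weight[iv == k])
  out / sum(g$weight)
}
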