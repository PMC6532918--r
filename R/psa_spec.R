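# PSA distribution descriptors and parameter-set perturbation.

# fields that may be perturbed directly (scalars) ...
.PSA_SCALARS <- c(
  "cost_mammo", "cost_followup", "cost_core_needle", "cost_vacuum",
  "adherence_rate", "specificity", "discount_rate",
  "overdiagnosis_per_screen", "disutility_screen", "disutility_biopsy",
  "dcis_to_invasive", "p_followup_given_fp", "p_core_needle", "p_vacuum",
  "prevalence_family_history", "prevalence_biopsy"
)
# ... and curve/table fields perturbed by a sampled multiplicative factor
# (probabilities clamped to [0,1]; stage distributions renormalized)
.PSA_MULTIPLIERS <- c(
  "incidence_base", "dcis_incidence", "background_mortality",
  "stage_survival", "treatment_cost", "utility_healthy", "utility_cancer",
  "stage_distribution"
)
# fields clamped to the unit interval after scaling
.UNIT_FIELDS <- c("incidence_base", "dcis_incidence", "background_mortality",
                  "stage_survival", "utility_healthy", "utility_cancer",
                  "adherence_rate", "specificity", "overdiagnosis_per_screen",
                  "disutility_screen", "disutility_biopsy", "dcis_to_invasive",
                  "p_followup_given_fp", "p_core_needle", "p_vacuum",
                  "prevalence_family_history", "prevalence_biopsy")

#' Construct a PSA specification
#'
#' A PSA spec maps parameter names to sampling distributions. Scalar fields
#' are sampled directly on their own scale; curve and table fields (for
#' example \code{incidence_base} or \code{treatment_cost}) are scaled by a
#' sampled multiplicative factor, so their \code{base} is 1. Parameters are
#' sampled independently. A zero-width range reproduces the base value
#' exactly, so a fully degenerate spec leaves the parameter set unchanged.
#'
#' @param ... named entries, each a list with elements \code{dist} (one of
#'   \code{"uniform"}, \code{"beta"}, \code{"gamma"}, \code{"lognormal"}),
#'   \code{base}, \code{low}, \code{high}.
#' @return an object of class \code{psa_spec}.
#' @examples
#' sp <- psa_spec(cost_mammo = list(dist = "uniform", base = 73.5, low = 60, high = 90))
#' @export
psa_spec <- function(...) {
  entries <- list(...)
  if (length(entries) == 1L && is.null(names(entries)) && is.list(entries[[1]]) &&
      !is.null(names(entries[[1]])) && !"dist" %in% names(entries[[1]])) {
    entries <- entries[[1]]  # allow psa_spec(list(a = ..., b = ...))
  }
  allowed <- c(.PSA_SCALARS, .PSA_MULTIPLIERS)
  for (nm in names(entries)) {
    e <- entries[[nm]]
    if (!nm %in% allowed)
      stop("psa_spec: unknown parameter '", nm, "'")
    if (!all(c("dist", "base", "low", "high") %in% names(e)))
      stop("psa_spec entry '", nm, "' needs dist, base, low, high")
    if (!e$dist %in% c("uniform", "beta", "gamma", "lognormal"))
      stop("psa_spec entry '", nm, "': invalid distribution family '", e$dist, "'")
    if (e$high < e$low)
      stop("psa_spec entry '", nm, "': high < low")
  }
  structure(entries, class = "psa_spec")
}

#' Default PSA specification
#'
#' Plausible uncertainty ranges for the parameters that drive the model's
#' results: screening fee, adherence, discount rate, specificity,
#' overdiagnosis, screening disutility, and multiplicative uncertainty on
#' the invasive incidence curve. These ranges are this package's own
#' choices, documented in the vignette; they are not a published
#' calibration.
#'
#' @param params a \code{screen_params} object supplying base values.
#' @return a \code{psa_spec}.
#' @export
default_psa_spec <- function(params = reference_parameters()) {
  psa_spec(
    cost_mammo = list(dist = "gamma", base = params$cost_mammo,
                      low = 60, high = 90),
    adherence_rate = list(dist = "beta", base = params$adherence_rate,
                          low = 0.40, high = 0.70),
    discount_rate = list(dist = "uniform", base = params$discount_rate,
                         low = 0, high = 0.05),
    specificity = list(dist = "beta", base = params$specificity,
                       low = 0.95, high = 0.99),
    overdiagnosis_per_screen = list(dist = "beta",
                                    base = params$overdiagnosis_per_screen,
                                    low = 0, high = 0.004),
    disutility_screen = list(dist = "beta", base = params$disutility_screen,
                             low = 0, high = 0.004),
    incidence_base = list(dist = "lognormal", base = 1, low = 0.8, high = 1.25)
  )
}

# sample one value from a spec entry; degenerate range returns base exactly
.sample_entry <- function(e) {
  if (e$high == e$low) return(e$base)
  x <- switch(e$dist,
    uniform = stats::runif(1, e$low, e$high),
    beta = {
      mu <- (e$base - e$low) / (e$high - e$low)
      mu <- min(max(mu, 1e-6), 1 - 1e-6)
      kappa <- 20
      e$low + (e$high - e$low) * stats::rbeta(1, mu * kappa, (1 - mu) * kappa)
    },
    gamma = {
      m <- max(e$base, 1e-12)
      s <- (e$high - e$low) / 4
      stats::rgamma(1, shape = (m / s)^2, rate = m / s^2)
    },
    lognormal = {
      m <- max(e$base, 1e-12)
      sdlog <- log(max(e$high / m, 1 + 1e-9)) / 2
      stats::rlnorm(1, meanlog = log(m), sdlog = sdlog)
    })
  min(max(x, e$low), e$high)
}

#' Draw a perturbed parameter set for probabilistic sensitivity analysis
#'
#' Samples every parameter named in \code{spec} independently from its
#' distribution and returns a new, valid parameter set; all other fields
#' pass through unchanged. Curve and table parameters are scaled by the
#' sampled factor, probabilities are clamped to [0, 1], and stage
#' distributions are renormalized after perturbation. Deterministic for a
#' fixed seed.
#'
#' @param params base \code{screen_params}.
#' @param spec a \code{\link{psa_spec}}.
#' @param seed integer seed for the draw.
#' @return a new \code{screen_params}.
#' @export
sample_psa_draw <- function(params, spec, seed) {
  stopifnot(inherits(spec, "psa_spec"))
  out <- unclass(params)
  set.seed(seed)
  for (nm in names(spec)) {
    x <- .sample_entry(spec[[nm]])
    if (nm %in% .PSA_SCALARS) {
      out[[nm]] <- x
    } else if (nm == "stage_distribution") {
      # scale the local-stage mass, renormalize each (context,density,band)
      sd <- out$stage_distribution
      sd[, , , 1] <- sd[, , , 1] * x
      tot <- apply(sd, c(1, 2, 3), sum)
      for (s in 1:3) sd[, , , s] <- sd[, , , s] / tot
      out$stage_distribution <- sd
    } else {
      out[[nm]] <- out[[nm]] * x
    }
    if (nm %in% .UNIT_FIELDS) out[[nm]] <- pmin(pmax(out[[nm]], 0), 1)
  }
  class(out) <- "screen_params"
  viol <- validate_parameters(out)
  if (length(viol))
    stop("sample_psa_draw produced an invalid set: ", paste(viol, collapse = "; "))
  out
}
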