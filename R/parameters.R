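# Parameter set: every numeric input of the screening model, with validation,
# strict JSON (de)serialization and a fully documented reference fill.

DENSITY_CATEGORIES <- c("fatty", "scattered", "heterogeneously_dense", "extremely_dense")
STAGES             <- c("local", "regional", "distant")
SCREEN_CONTEXTS    <- c("interval-1", "interval-2", "interval-3", "no-screening")
SUBTYPES           <- c("triple_negative", "her2_positive", "hormone_receptor_positive")
AGE_BANDS_DENSITY  <- c("50-59", "60-69", "70+")

# required top-level keys of the parameter schema (strict: nothing else allowed)
.PARAM_FIELDS <- c(
  "start_age", "end_age", "screening_stop_age",
  "incidence_base", "dcis_incidence", "dcis_to_invasive",
  "background_mortality",
  "stage_distribution", "stage_survival",
  "density_prevalence_by_age", "density_transition",
  "prevalence_family_history", "prevalence_biopsy",
  "rr_table",
  "adherence_rate", "specificity",
  "p_followup_given_fp", "p_core_needle", "p_vacuum",
  "overdiagnosis_per_screen",
  "cost_mammo", "cost_followup", "cost_core_needle", "cost_vacuum",
  "treatment_cost", "subtype_mix",
  "utility_healthy", "utility_cancer",
  "disutility_screen", "disutility_biopsy",
  "discount_rate"
)

#' Reference parameter set for the German screening setting
#'
#' Builds the complete, validated parameter set used throughout the package.
#' A small number of quantities are fixed to published values for the German
#' mammography screening programme: the risk-factor prevalences (48.3\%
#' heterogeneously dense and 6.9\% extremely dense tissue at age 50, 16.1\%
#' positive family history, 28.2\% prior biopsy), the fee schedule
#' (mammography 73.50, follow-up imaging 94.45, core-needle biopsy 21.10,
#' vacuum biopsy 39.79, 2017 Euros), the observed participation rate of 54\%,
#' the 3\% discount rate, and the joint relative-risk span of 0.33 to 2.88
#' across all risk-factor combinations. Everything else (age-specific
#' incidence and background mortality, stage distributions by screening
#' interval and density, stage-specific survival, utilities, treatment cost
#' bundles, work-up branch probabilities, overdiagnosis rate) is a synthetic
#' fill: smooth, monotone in age where epidemiology forces it (incidence
#' rises with age; distant-stage survival is worst; screened stage
#' distributions are shifted towards local stage, more so for shorter
#' intervals), and internally consistent, but not a calibration to registry
#' microdata. See the package vignette for the construction of every fill.
#'
#' @param seed integer; accepted for interface stability. The reference set
#'   is fully deterministic, so every seed returns the identical object.
#' @return An object of class \code{screen_params}: a named list with the
#'   fields described in \code{\link{validate_parameters}}.
#' @examples
#' p <- reference_parameters()
#' p$prevalence_family_history  # 0.161
#' p$cost_mammo                 # 73.50
#' @seealso \code{\link{validate_parameters}}, \code{\link{write_parameters}}
#' @export
reference_parameters <- function(seed = 1L) {
  ages <- 50:99

  # invasive incidence: rises linearly with age (annual probability)
  incidence_base <- 0.0025 + 0.00003 * (ages - 50)
  names(incidence_base) <- ages

  # DCIS incidence: an order of magnitude rarer, slight rise
  dcis_incidence <- 0.00030 + 0.000003 * (ages - 50)
  names(dcis_incidence) <- ages

  # background (non-breast-cancer) mortality: Gompertz-type growth
  background_mortality <- pmin(0.002 * exp(0.095 * (ages - 50)), 0.6)
  names(background_mortality) <- ages

  # stage distribution at diagnosis: screening shifts stage towards local,
  # shorter intervals shift more; denser tissue masks, shifting later;
  # older age band slightly later.
  base_by_context <- rbind(
    "interval-1"   = c(0.78, 0.18, 0.04),
    "interval-2"   = c(0.72, 0.22, 0.06),
    "interval-3"   = c(0.66, 0.26, 0.08),
    "no-screening" = c(0.55, 0.33, 0.12)
  )
  stage_distribution <- array(
    NA_real_,
    dim = c(4L, 4L, 2L, 3L),
    dimnames = list(context = SCREEN_CONTEXTS, density = DENSITY_CATEGORIES,
                    age_band = c("50-64", "65+"), stage = STAGES)
  )
  for (ci in 1:4) for (di in 1:4) for (bi in 1:2) {
    p <- base_by_context[ci, ]
    shift <- 0.03 * (di - 1) + 0.02 * (bi - 1)  # mass moved out of local stage
    p <- c(p[1] - shift, p[2] + 0.7 * shift, p[3] + 0.3 * shift)
    stage_distribution[ci, di, bi, ] <- p / sum(p)
  }

  # annual breast-cancer death probability by stage and years-since-diagnosis
  stage_survival <- rbind(
    local    = c("0-4" = 0.010, "5+" = 0.005),
    regional = c("0-4" = 0.050, "5+" = 0.025),
    distant  = c("0-4" = 0.350, "5+" = 0.200)
  )

  # density prevalence: published values at age 50 for the two dense
  # categories; remaining mass split 10% fatty / 34.8% scattered.
  # Density declines with age.
  density_prevalence_by_age <- rbind(
    "50-59" = c(0.100, 0.348, 0.483, 0.069),
    "60-69" = c(0.140, 0.400, 0.410, 0.050),
    "70+"   = c(0.180, 0.450, 0.335, 0.035)
  )
  colnames(density_prevalence_by_age) <- DENSITY_CATEGORIES

  # 5-yearly density transition: mostly stable, mild drift towards lower
  # density with age
  density_transition <- matrix(0, 4, 4,
                               dimnames = list(DENSITY_CATEGORIES, DENSITY_CATEGORIES))
  density_transition["fatty", ]                 <- c(0.95, 0.05, 0.00, 0.00)
  density_transition["scattered", ]             <- c(0.15, 0.80, 0.05, 0.00)
  density_transition["heterogeneously_dense", ] <- c(0.00, 0.15, 0.80, 0.05)
  density_transition["extremely_dense", ]       <- c(0.00, 0.00, 0.20, 0.80)

  # per-factor relative-risk multipliers; the top density multiplier is
  # calibrated so that the joint span over all 16 combinations is exactly
  # 0.33 (fatty, no family history, no biopsy) to 2.88 (extremely dense,
  # family history, prior biopsy).
  rr_family <- 1.55
  rr_biopsy <- 1.35
  rr_density <- c(0.33, 0.90, 1.15, 2.88 / (rr_family * rr_biopsy))
  names(rr_density) <- DENSITY_CATEGORIES
  rr_table <- list(density = rr_density,
                   family_history = rr_family,
                   biopsy = rr_biopsy)

  # treatment cost bundles (2017 Euros), monotone in stage within subtype;
  # the distant bundle includes palliative care; HER2-positive carries the
  # trastuzumab premium.
  treatment_cost <- rbind(
    triple_negative           = c(local = 20000, regional = 32000, distant = 50000),
    her2_positive             = c(local = 40000, regional = 55000, distant = 80000),
    hormone_receptor_positive = c(local = 15000, regional = 25000, distant = 45000)
  )
  subtype_mix <- c(triple_negative = 0.15, her2_positive = 0.12,
                   hormone_receptor_positive = 0.73)

  # EQ-5D-style utilities: healthy by age band (expanded to single years),
  # cancer by stage and phase, ordered healthy > local > regional > distant
  uh_band <- c("50-59" = 0.87, "60-69" = 0.84, "70-79" = 0.80, "80+" = 0.74)
  utility_healthy <- unname(uh_band[cut(ages, c(49, 59, 69, 79, 200),
                                        labels = names(uh_band))])
  names(utility_healthy) <- ages
  utility_cancer <- rbind(
    local    = c(first_year = 0.70, later = 0.73),
    regional = c(first_year = 0.62, later = 0.68),
    distant  = c(first_year = 0.50, later = 0.50)
  )

  params <- list(
    start_age = 50L, end_age = 100L, screening_stop_age = 69L,
    incidence_base = incidence_base,
    dcis_incidence = dcis_incidence,
    dcis_to_invasive = 0.06,
    background_mortality = background_mortality,
    stage_distribution = stage_distribution,
    stage_survival = stage_survival,
    density_prevalence_by_age = density_prevalence_by_age,
    density_transition = density_transition,
    prevalence_family_history = 0.161,
    prevalence_biopsy = 0.282,
    rr_table = rr_table,
    adherence_rate = 0.54,
    specificity = 0.97,
    p_followup_given_fp = 1.0,
    p_core_needle = 0.15,
    p_vacuum = 0.06,
    overdiagnosis_per_screen = 0.001,
    cost_mammo = 73.50,
    cost_followup = 94.45,
    cost_core_needle = 21.10,
    cost_vacuum = 39.79,
    treatment_cost = treatment_cost,
    subtype_mix = subtype_mix,
    utility_healthy = utility_healthy,
    utility_cancer = utility_cancer,
    disutility_screen = 0.001,
    disutility_biopsy = 0.010,
    discount_rate = 0.03
  )
  class(params) <- "screen_params"
  params
}

#' Validate a parameter set
#'
#' Checks every invariant of the parameter schema: probabilities in [0, 1],
#' stage distributions, density prevalences, transition rows and the subtype
#' mix summing to one (tolerance 1e-9), non-negative costs and discount
#' rate, age range consistency, and the presence and shape of every field.
#' Violations are returned as data, not raised as errors.
#'
#' @param params a \code{screen_params} object (or plain named list).
#' @return character vector of violations, each naming the offending field
#'   and rule; \code{character(0)} if the set is valid.
#' @examples
#' validate_parameters(reference_parameters())  # character(0)
#' @export
validate_parameters <- function(params) {
  v <- character(0)
  bad <- function(msg) v <<- c(v, msg)

  missing <- setdiff(.PARAM_FIELDS, names(params))
  if (length(missing)) {
    return(paste0("missing field: ", missing))
  }

  prob01 <- function(x, name) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
      bad(paste0(name, ": probability outside [0,1]"))
  }
  sums1 <- function(x, name) {
    if (abs(sum(x) - 1) > 1e-9)
      bad(paste0(name, ": must sum to 1 (got ", format(sum(x)), ")"))
  }

  if (params$start_age >= params$end_age) bad("start_age: must be < end_age")
  if (params$screening_stop_age < params$start_age)
    bad("screening_stop_age: must be >= start_age")

  prob01(params$incidence_base, "incidence_base")
  prob01(params$dcis_incidence, "dcis_incidence")
  prob01(params$dcis_to_invasive, "dcis_to_invasive")
  prob01(params$background_mortality, "background_mortality")
  prob01(params$stage_survival, "stage_survival")

  sd <- params$stage_distribution
  if (!is.array(sd) || length(dim(sd)) != 4L) {
    bad("stage_distribution: must be a 4-d array (context, density, age band, stage)")
  } else {
    prob01(sd, "stage_distribution")
    s <- apply(sd, c(1, 2, 3), sum)
    off <- which(abs(s - 1) > 1e-9, arr.ind = TRUE)
    if (nrow(off)) {
      for (i in seq_len(nrow(off))) {
        bad(paste0("stage_distribution[",
                   paste(dimnames(sd)[[1]][off[i, 1]], dimnames(sd)[[2]][off[i, 2]],
                         dimnames(sd)[[3]][off[i, 3]], sep = ", "),
                   "]: stages must sum to 1"))
      }
    }
  }

  dp <- params$density_prevalence_by_age
  prob01(dp, "density_prevalence_by_age")
  for (b in rownames(dp)) sums1(dp[b, ], paste0("density_prevalence_by_age[", b, "]"))

  dt <- params$density_transition
  prob01(dt, "density_transition")
  for (i in seq_len(nrow(dt)))
    sums1(dt[i, ], paste0("density_transition[", rownames(dt)[i] %||% i, "]"))

  prob01(params$prevalence_family_history, "prevalence_family_history")
  prob01(params$prevalence_biopsy, "prevalence_biopsy")

  rr <- params$rr_table
  if (!all(c("density", "family_history", "biopsy") %in% names(rr))) {
    bad("rr_table: must have components density, family_history, biopsy")
  } else if (any(c(rr$density, rr$family_history, rr$biopsy) <= 0)) {
    bad("rr_table: multipliers must be positive")
  }

  prob01(params$adherence_rate, "adherence_rate")
  prob01(params$specificity, "specificity")
  prob01(params$p_followup_given_fp, "p_followup_given_fp")
  prob01(params$p_core_needle, "p_core_needle")
  prob01(params$p_vacuum, "p_vacuum")
  if (params$p_core_needle + params$p_vacuum > 1 + 1e-9)
    bad("p_core_needle + p_vacuum: must not exceed 1")
  prob01(params$overdiagnosis_per_screen, "overdiagnosis_per_screen")

  for (f in c("cost_mammo", "cost_followup", "cost_core_needle", "cost_vacuum")) {
    if (params[[f]] < 0) bad(paste0(f, ": cost must be >= 0"))
  }
  if (any(params$treatment_cost < 0)) bad("treatment_cost: costs must be >= 0")
  sums1(params$subtype_mix, "subtype_mix")
  prob01(params$subtype_mix, "subtype_mix")

  prob01(params$utility_healthy, "utility_healthy")
  prob01(params$utility_cancer, "utility_cancer")
  prob01(params$disutility_screen, "disutility_screen")
  prob01(params$disutility_biopsy, "disutility_biopsy")
  if (params$discount_rate < 0) bad("discount_rate: must be >= 0")

  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.screen_params <- function(x, ...) {
  cat("<screen_params>\n")
  cat("  ages", x$start_age, "to", x$end_age,
      "| screening stops at", x$screening_stop_age, "\n")
  cat("  adherence", x$adherence_rate, "| specificity", x$specificity,
      "| discount", x$discount_rate, "\n")
  cat("  fees (EUR): mammo", x$cost_mammo, "followup", x$cost_followup,
      "core-needle", x$cost_core_needle, "vacuum", x$cost_vacuum, "\n")
  rr <- combined_rr_grid(x)
  cat("  combined RR span:", format(min(rr$combined_rr), digits = 3), "-",
      format(max(rr$combined_rr), digits = 3), "\n")
  viol <- validate_parameters(x)
  cat("  validation:", if (length(viol)) paste(length(viol), "violations") else "ok", "\n")
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

.encode_field <- function(x) {
  if (is.array(x) || is.matrix(x)) {
    list(.array = TRUE, dim = dim(x), dimnames = dimnames(x), values = as.vector(x))
  } else if (is.list(x)) {
    lapply(x, .encode_field)
  } else if (is.numeric(x) && !is.null(names(x))) {
    list(.named = TRUE, names = names(x), values = unname(x))
  } else x
}

.decode_field <- function(x) {
  if (is.list(x) && isTRUE(x$.array)) {
    a <- array(unlist(x$values), dim = unlist(x$dim))
    if (!is.null(x$dimnames)) dimnames(a) <- lapply(x$dimnames, unlist)
    a
  } else if (is.list(x) && isTRUE(x$.named)) {
    v <- unlist(x$values)
    names(v) <- unlist(x$names)
    v
  } else if (is.list(x)) {
    lapply(x, .decode_field)
  } else x
}

#' Write a parameter set to a JSON file
#'
#' The on-disk schema is strict: exactly the documented fields, no extras.
#' \code{write_parameters} followed by \code{\link{read_parameters}} is the
#' identity up to numeric round-trip.
#'
#' @param params a valid \code{screen_params} object.
#' @param path file path to write.
#' @return \code{path}, invisibly.
#' @export
write_parameters <- function(params, path) {
  enc <- lapply(unclass(params)[.PARAM_FIELDS], .encode_field)
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a parameter set from a JSON file
#'
#' @param path file written by \code{\link{write_parameters}} (or authored by
#'   hand following the same schema). Missing or unknown keys are an error
#'   naming the key.
#' @return a \code{screen_params} object.
#' @export
read_parameters <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  unknown <- setdiff(names(raw), .PARAM_FIELDS)
  if (length(unknown))
    stop("unknown parameter key: ", paste(unknown, collapse = ", "))
  missing <- setdiff(.PARAM_FIELDS, names(raw))
  if (length(missing))
    stop("missing parameter key: ", paste(missing, collapse = ", "))
  dec <- lapply(raw, .decode_field)
  # integers that arrive as doubles
  for (f in c("start_age", "end_age", "screening_stop_age"))
    dec[[f]] <- as.integer(dec[[f]])
  params <- dec[.PARAM_FIELDS]
  class(params) <- "screen_params"
  viol <- validate_parameters(params)
  if (length(viol))
    stop("invalid parameter file: ", paste(viol, collapse = "; "))
  params
}

#' Export all parameter tables as CSV files for inspection
#'
#' Writes one CSV per tabular field (age curves, stage distributions,
#' survival, utilities, cost bundles) into \code{dir}.
#'
#' @param params a \code{screen_params} object.
#' @param dir output directory; created if absent.
#' @return character vector of files written, invisibly.
#' @export
export_parameter_tables <- function(params, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    f <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  ages <- as.integer(names(params$incidence_base))
  wr(data.frame(age = ages,
                incidence_invasive = unname(params$incidence_base),
                incidence_dcis = unname(params$dcis_incidence),
                background_mortality = unname(params$background_mortality),
                utility_healthy = unname(params$utility_healthy)),
     "age_curves")
  sd <- params$stage_distribution
  grid <- expand.grid(context = dimnames(sd)[[1]], density = dimnames(sd)[[2]],
                      age_band = dimnames(sd)[[3]], stringsAsFactors = FALSE)
  for (s in STAGES) grid[[s]] <- apply(grid, 1, function(r) sd[r[1], r[2], r[3], s])
  wr(grid, "stage_distribution")
  wr(as.data.frame(as.table(params$stage_survival),
                   responseName = "annual_bc_death_probability"),
     "stage_survival")
  wr(as.data.frame(as.table(params$treatment_cost), responseName = "cost_eur"),
     "treatment_cost")
  wr(as.data.frame(as.table(params$density_transition), responseName = "probability"),
     "density_transition")
  wr(as.data.frame(as.table(params$utility_cancer), responseName = "utility"),
     "utility_cancer")
  invisible(files)
}
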