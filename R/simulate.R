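# Top-level entry point: run a strategy set against the matched
# no-screening comparator under one or both adherence scenarios.

#' Simulate and compare screening strategies
#'
#' Runs every requested strategy (and the no-screening comparator) on the
#' same cohort with common random numbers, under full and/or 54\%-type
#' actual adherence, and returns the incremental results table, the
#' per-cluster subgroup tables for stratified strategies, and adherence
#' loss summaries. The no-screening arm is simulated once: it is
#' unaffected by adherence.
#'
#' @param params a \code{screen_params}.
#' @param strategies named list of \code{\link{screening_strategy}} objects
#'   (default: the eight built-in strategies).
#' @param n cohort size per arm.
#' @param seed integer seed; the same seed matches every arm woman-by-woman.
#' @param adherence character vector, subset of \code{c("full", "actual")}.
#' @param keep_cohorts if \code{TRUE}, retain the per-woman records of every
#'   arm in the result (memory grows with \code{n}).
#' @param ... further options passed to \code{\link{run_cohort}}.
#' @return object of class \code{screening_sim} with elements
#'   \code{results} (one row per strategy and scenario, see
#'   \code{\link{increments_vs_no_screening}}), \code{subgroups} (named
#'   list of subgroup tables, present when both scenarios were run),
#'   \code{comparator} totals, \code{n}, \code{seed}.
#' @examples
#' \donttest{
#' sim <- simulate_screening(n = 2000, seed = 42)
#' summary(sim)
#' }
#' @export
simulate_screening <- function(params = reference_parameters(),
                               strategies = builtin_strategies(),
                               n = 10000L, seed = 1L,
                               adherence = c("full", "actual"),
                               keep_cohorts = FALSE, ...) {
  adherence <- match.arg(adherence, several.ok = TRUE)
  streams <- crn_streams(n, seed, params)
  profiles <- assign_risk_profiles(params, n, u = list(
    density = streams$profile_density,
    family_history = streams$profile_fh,
    biopsy = streams$profile_bx))

  none <- screening_strategy("No screening", "none")
  tally0 <- run_cohort(n, none, params, seed, "full",
                       streams = streams, profiles = profiles, ...)

  results <- list()
  tallies <- list()
  for (sc in adherence) {
    for (nm in names(strategies)) {
      tal <- run_cohort(n, strategies[[nm]], params, seed, sc,
                        streams = streams, profiles = profiles, ...)
      results[[paste(nm, sc)]] <- increments_vs_no_screening(tal, tally0)
      tallies[[paste(nm, sc)]] <- tal
    }
  }
  results <- do.call(rbind, results)
  rownames(results) <- NULL
  class(results) <- c("strategy_result", "data.frame")

  subgroups <- NULL
  if (all(c("full", "actual") %in% adherence)) {
    subgroups <- lapply(names(strategies), function(nm) {
      subgroup_table(tallies[[paste(nm, "full")]],
                     tallies[[paste(nm, "actual")]], tally0)
    })
    names(subgroups) <- names(strategies)
  }

  structure(list(results = results,
                 subgroups = subgroups,
                 comparator = tally0$totals,
                 cohorts = if (keep_cohorts) c(tallies, list(`No screening` = tally0)),
                 n = n, seed = seed, adherence = adherence,
                 params = params),
            class = "screening_sim")
}

#' @export
print.screening_sim <- function(x, ...) {
  cat("<screening_sim> n =", x$n, "per arm | seed", x$seed, "\n")
  cat("Comparator (no screening): ", x$comparator$deaths_bc,
      " breast-cancer deaths (",
      sprintf("%.2f%%", 100 * x$comparator$deaths_bc / max(x$n, 1)), ")\n", sep = "")
  r <- x$results
  show <- data.frame(strategy = r$strategy, adherence = r$adherence,
                     `mortality reduction %` = round(r$mortality_reduction, 2),
                     `incr. QALY` = round(r$incremental_qaly, 4),
                     `FP biopsies` = round(r$fp_biopsies, 4),
                     `incr. cost EUR` = round(r$incremental_cost, 2),
                     check.names = FALSE)
  print(show, row.names = FALSE)
  invisible(x)
}

#' @export
summary.screening_sim <- function(object, wtp = NULL, ...) {
  x <- object
  print(x)
  if (all(c("full", "actual") %in% x$adherence)) {
    r <- x$results
    f <- r[r$adherence == "full", ]
    a <- r[r$adherence == "actual", ]
    a <- a[match(f$strategy, a$strategy), ]
    cat("\nRelative loss at reduced adherence (% of full-adherence value):\n")
    loss <- data.frame(strategy = f$strategy,
                       mortality = round(100 * (f$mortality_reduction - a$mortality_reduction) /
                                           f$mortality_reduction),
                       qaly = round(100 * (f$incremental_qaly - a$incremental_qaly) /
                                      f$incremental_qaly),
                       cost = round(100 * (f$incremental_cost - a$incremental_cost) /
                                      f$incremental_cost))
    print(loss, row.names = FALSE)
  }
  cat("\nQALY efficiency frontier (full adherence):\n")
  f <- x$results[x$results$adherence == x$adherence[1], ]
  print(efficiency_frontier(f))
  invisible(x)
}

#' @export
plot.screening_sim <- function(x, adherence = x$adherence[1],
                               effect = "incremental_qaly", ...) {
  r <- x$results[x$results$adherence == adherence, ]
  fr <- efficiency_frontier(r, effect = effect)
  plot(fr, xlab = paste("Incremental", sub("incremental_", "", effect)),
       main = paste("Efficiency frontier,", adherence, "adherence"), ...)
  invisible(x)
}

#' Write simulation reports to CSV
#'
#' Writes the incremental results table (one row per strategy and
#' adherence scenario) and, when available, one subgroup CSV per
#' stratified strategy, plus a JSON run manifest (n, seed, scenarios).
#' Existing files are only replaced when \code{overwrite = TRUE}.
#'
#' @param sim a \code{screening_sim}.
#' @param dir output directory, created if absent.
#' @param overwrite allow replacing existing files.
#' @return character vector of files written, invisibly.
#' @export
export_results <- function(sim, dir, overwrite = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  put <- function(name) {
    f <- file.path(dir, name)
    if (file.exists(f) && !overwrite)
      stop("refusing to overwrite ", f, " (use overwrite = TRUE)")
    files <<- c(files, f)
    f
  }
  utils::write.csv(as.data.frame(sim$results), put("increments.csv"),
                   row.names = FALSE)
  if (!is.null(sim$subgroups)) {
    for (nm in names(sim$subgroups)) {
      safe <- gsub("[^A-Za-z0-9._-]", "_", nm)
      utils::write.csv(sim$subgroups[[nm]],
                       put(paste0("subgroups_", safe, ".csv")), row.names = FALSE)
    }
  }
  manifest <- list(n = sim$n, seed = sim$seed, adherence = sim$adherence,
                   strategies = unique(sim$results$strategy),
                   package_version = as.character(utils::packageVersion("stratscreen")))
  jsonlite::write_json(manifest, put("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(files)
}
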