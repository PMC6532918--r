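# Decision layer: increments, ICERs, frontier, adherence summaries, subgroups.

make_tally <- function(women, strategy = "s", adherence = "full", seed = 1) {
  structure(list(women = women, strategy = strategy, adherence = adherence,
                 n = nrow(women), seed = seed,
                 totals = list(deaths_bc = sum(women$died_bc))),
            class = "cohort_tally")
}

toy_women <- function(died_bc, qaly, cost, fpb = 0) {
  n <- length(died_bc)
  data.frame(id = seq_len(n), died_bc = died_bc, qaly = qaly, cost = cost,
             fp_biopsies = rep_len(fpb, n))
}

test_that("increments: identity gives zero, arithmetic matches, guards hold", {
  w <- toy_women(c(TRUE, FALSE, FALSE, TRUE), c(10, 12, 11, 9), c(5, 6, 7, 8))
  t0 <- make_tally(w); ts <- make_tally(w)
  inc <- increments_vs_no_screening(ts, t0)
  expect_equal(inc$mortality_reduction, 0)
  expect_equal(inc$incremental_qaly, 0)
  expect_equal(inc$incremental_cost, 0)

  # deaths 200 -> 120 is a 40% reduction
  d0 <- toy_women(rep(c(TRUE, FALSE), c(200, 800)), rep(1, 1000), rep(0, 1000))
  ds <- toy_women(rep(c(TRUE, FALSE), c(120, 880)), rep(1, 1000), rep(0, 1000))
  inc2 <- increments_vs_no_screening(make_tally(ds), make_tally(d0))
  expect_equal(inc2$mortality_reduction, 40)

  # comparator without deaths: not applicable
  z0 <- toy_women(rep(FALSE, 10), rep(1, 10), rep(0, 10))
  zs <- toy_women(rep(FALSE, 10), rep(1, 10), rep(0, 10))
  inc3 <- increments_vs_no_screening(make_tally(zs), make_tally(z0))
  expect_true(is.na(inc3$mortality_reduction))
})

test_that("increments are antisymmetric in the two tallies", {
  set.seed(3)
  a <- toy_women(stats::runif(500) < 0.1, stats::rnorm(500, 15), stats::rnorm(500, 100), 0)
  b <- toy_women(stats::runif(500) < 0.1, stats::rnorm(500, 15), stats::rnorm(500, 100), 0)
  ab <- increments_vs_no_screening(make_tally(a), make_tally(b))
  ba <- increments_vs_no_screening(make_tally(b), make_tally(a))
  expect_equal(ab$incremental_qaly, -ba$incremental_qaly)
  expect_equal(ab$incremental_cost, -ba$incremental_cost)
  expect_equal(ab$fp_biopsies, -ba$fp_biopsies)
})

test_that("ICER arithmetic and guards", {
  expect_equal(icer(505.66, 0.0116)$icer, 43591)
  expect_equal(icer(273.61, 0.0057)$icer, 48002)   # nearest-euro display
  expect_equal(icer(0, 0.01)$icer, 0)
  bad <- icer(100, 0)
  expect_false(bad$defined)
  expect_true(is.na(bad$icer))
  # display rounding never feeds back: exact ratio preserved
  expect_equal(icer(505.66, 0.0116)$icer_exact, 505.66 / 0.0116)
})

test_that("frontier handles the simple cases", {
  one <- data.frame(strategy = "A", effect = 0.01, cost = 100)
  fr <- efficiency_frontier(one)
  expect_equal(fr$status[fr$strategy == "A"], "on-frontier")

  two <- data.frame(strategy = c("good", "bad"),
                    effect = c(0.02, 0.01), cost = c(100, 200))
  fr2 <- efficiency_frontier(two)
  expect_equal(fr2$status[fr2$strategy == "bad"], "dominated")
  expect_equal(fr2$status[fr2$strategy == "good"], "on-frontier")

  # classic extended dominance: middle point above the chord
  three <- data.frame(strategy = c("lo", "mid", "hi"),
                      effect = c(0.01, 0.02, 0.03), cost = c(100, 900, 1100))
  fr3 <- efficiency_frontier(three)
  expect_equal(fr3$status[fr3$strategy == "mid"], "extendedly dominated")
  # frontier ICERs strictly increase along the frontier (by effect)
  onf <- fr3[fr3$status == "on-frontier", ]
  ic <- onf$icer[order(onf$effect)]
  ic <- ic[!is.na(ic)]
  expect_true(all(diff(ic) > 0))
})

test_that("frontier matches the brute-force oracle on random strategy sets", {
  set.seed(99)
  for (rep in 1:200) {
    m <- sample(2:8, 1)
    df <- data.frame(strategy = paste0("s", seq_len(m)),
                     effect = stats::runif(m, -0.01, 0.06),
                     cost = stats::runif(m, -100, 1200))
    fr <- efficiency_frontier(df)
    oracle <- frontier_oracle(fr[, c("strategy", "effect", "cost")])
    expect_identical(fr$status, oracle)
    onf <- fr[fr$status == "on-frontier", ]
    ic <- onf$icer[order(onf$effect)]
    ic <- ic[!is.na(ic)]
    if (length(ic) > 1) expect_true(all(diff(ic) > 0))
  }
})

test_that("adherence loss and elasticity reproduce the published arithmetic", {
  expect_equal(adherence_loss(14.46, 8.81)$loss_display, 39)
  expect_equal(adherence_loss(427.8, 224.12)$loss_display, 48)
  expect_equal(adherence_loss(5, 5)$loss_display, 0)
  expect_true(is.na(adherence_loss(0, 1)$loss_pct))
  expect_equal(round(adherence_elasticity(14.46, 8.81, 46), 2), 0.85)
  expect_equal(adherence_elasticity(10, 10, 46), 0)
  expect_equal(adherence_elasticity(10, 5.4, 46), (100 * 4.6 / 10) / 46)
})

test_that("subgroup table: routine covers 100%, losses recompute row-wise", {
  p <- reference_parameters()
  n <- 20000
  streams <- crn_streams(n, 31, p)
  profiles <- assign_risk_profiles(p, n, u = list(
    density = streams$profile_density, family_history = streams$profile_fh,
    biopsy = streams$profile_bx))
  t0 <- run_cohort(n, screening_strategy("No screening", "none"), p, 31,
                   streams = streams, profiles = profiles)
  s <- builtin_strategies()[["Routine 2-year"]]
  tf <- run_cohort(n, s, p, 31, "full", streams = streams, profiles = profiles)
  ta <- run_cohort(n, s, p, 31, "actual", streams = streams, profiles = profiles)
  tab <- subgroup_table(tf, ta, t0)
  expect_equal(tab$population_pct[tab$cluster == "biennial"], 100)
  expect_equal(sum(tab$population_pct), 100)

  sr <- builtin_strategies()[["RR 2-1"]]
  tfs <- run_cohort(n, sr, p, 31, "full", streams = streams, profiles = profiles)
  tas <- run_cohort(n, sr, p, 31, "actual", streams = streams, profiles = profiles)
  tab2 <- subgroup_table(tfs, tas, t0)
  expect_equal(sum(tab2$population_pct), 100)
  # cluster shares agree with the exact enumeration
  fr <- risk_cluster_fractions(p, sr)
  for (k in 1:3) {
    se <- sqrt(max(fr[k] * (1 - fr[k]), 1e-12) / n)
    expect_lt(abs(tab2$population_pct[k] / 100 - fr[k]), 3 * se + 1e-9)
  }
  # loss columns equal adherence_loss applied to the two scenario columns
  ok <- !is.na(tab2$mr_full)
  expect_equal(tab2$mr_loss_pct[ok],
               adherence_loss(tab2$mr_full[ok], tab2$mr_actual[ok])$loss_display)
  expect_equal(tab2$qaly_loss_pct[ok],
               adherence_loss(tab2$qaly_full[ok], tab2$qaly_actual[ok])$loss_display)
})
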