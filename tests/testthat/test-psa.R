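# PSA layer: CEAC enumeration, dominance classification, EVPI, tornado.

# helper: samples data.frame from explicit per-draw outcomes
psa_samples <- function(...) {
  do.call(rbind, lapply(list(...), as.data.frame))
}

test_that("CEAC equals exact enumeration on discrete toy distributions", {
  # two strategies, each with a two-point (cost, effect) distribution;
  # the four equiprobable outcome pairs enumerate the product distribution
  A <- list(effect = c(0.010, 0.020), cost = c(100, 300))
  B <- list(effect = c(0.015, 0.015), cost = c(200, 200))
  rows <- list()
  d <- 0
  for (i in 1:2) for (j in 1:2) {
    d <- d + 1
    rows[[length(rows) + 1]] <- data.frame(
      draw = d, strategy = "A", incremental_qaly = A$effect[i],
      incremental_cost = A$cost[i], mortality_reduction = 0, fp_biopsies = 0)
    rows[[length(rows) + 1]] <- data.frame(
      draw = d, strategy = "B", incremental_qaly = B$effect[j],
      incremental_cost = B$cost[j], mortality_reduction = 0, fp_biopsies = 0)
  }
  samples <- do.call(rbind, rows)
  wtp <- c(0, 10000, 20000, 40000, 100000)
  cc <- ceac(samples, "incremental_qaly", wtp)
  # exact enumeration over the 4 outcomes at each wtp
  for (wi in seq_along(wtp)) {
    pa <- 0
    for (i in 1:2) for (j in 1:2) {
      nba <- wtp[wi] * A$effect[i] - A$cost[i]
      nbb <- wtp[wi] * B$effect[j] - B$cost[j]
      if (nba > nbb || (nba == nbb && A$cost[i] < B$cost[j])) pa <- pa + 0.25
    }
    expect_equal(cc$A[wi], pa, label = paste("wtp", wtp[wi]))
    expect_equal(cc$A[wi] + cc$B[wi], 1)
  }
})

test_that("CEAC probabilities sum to one and favour the cheap option at wtp 0", {
  samples <- psa_samples(
    data.frame(draw = 1:3, strategy = "No screening", incremental_qaly = 0,
               incremental_cost = 0, mortality_reduction = 0, fp_biopsies = 0),
    data.frame(draw = 1:3, strategy = "S", incremental_qaly = c(0.01, 0.02, 0.03),
               incremental_cost = c(100, 120, 90), mortality_reduction = 0,
               fp_biopsies = 0))
  cc <- ceac(samples, "incremental_qaly", wtp = c(0, 5000, 50000))
  expect_equal(cc$`No screening`[cc$wtp == 0], 1)   # cheaper option wins at 0
  sums <- rowSums(cc[, setdiff(names(cc), "wtp")])
  expect_equal(sums, rep(1, nrow(cc)))
  expect_equal(cc$S[cc$wtp == 50000], 1)            # high wtp: effect wins
})

test_that("CEAC dominance classification", {
  a <- c(0.6, 0.7, 0.8); b <- c(0.4, 0.3, 0.2)
  expect_equal(ceac_dominance(a, b)$relation, "strictly-above")
  expect_equal(ceac_dominance(b, a)$relation, "strictly-below")
  expect_equal(ceac_dominance(a, a)$relation, "intersecting")
  expect_true(is.na(ceac_dominance(a, a)$crossing_wtp))

  # constructed crossing: order flips between grid points
  wtp <- seq(0, 10000, by = 1000)
  ca <- seq(0.8, 0.2, length.out = length(wtp))
  cb <- seq(0.2, 0.8, length.out = length(wtp))
  res <- ceac_dominance(ca, cb, wtp)
  expect_equal(res$relation, "intersecting")
  # analytic crossing at wtp 5000; report within one grid step
  expect_lte(abs(res$crossing_wtp - 5000), 1000)
})

test_that("EVPI: hand-enumerated toy, non-negativity, degenerate zero", {
  # two strategies over two equiprobable scenarios with net benefits
  # A {10, 0} and B {0, 8}: E[max] = 9, max E = 5, EVPI = 4
  samples <- psa_samples(
    data.frame(draw = 1:2, strategy = "A", incremental_qaly = c(10, 0),
               incremental_cost = 0, mortality_reduction = 0, fp_biopsies = 0),
    data.frame(draw = 1:2, strategy = "B", incremental_qaly = c(0, 8),
               incremental_cost = 0, mortality_reduction = 0, fp_biopsies = 0))
  expect_equal(evpi(samples, "incremental_qaly", wtp = 1), 4)

  set.seed(5)
  rnd <- psa_samples(
    data.frame(draw = rep(1:20, 2), strategy = rep(c("A", "B"), each = 20),
               incremental_qaly = stats::rnorm(40, 0.01, 0.01),
               incremental_cost = stats::rnorm(40, 100, 50),
               mortality_reduction = 0, fp_biopsies = 0))
  expect_gte(evpi(rnd, "incremental_qaly", wtp = 30000), 0)

  # no uncertainty: identical outcomes in every draw
  const <- psa_samples(
    data.frame(draw = 1:5, strategy = "A", incremental_qaly = 0.02,
               incremental_cost = 100, mortality_reduction = 0, fp_biopsies = 0),
    data.frame(draw = 1:5, strategy = "B", incremental_qaly = 0.01,
               incremental_cost = 60, mortality_reduction = 0, fp_biopsies = 0))
  expect_equal(evpi(const, "incremental_qaly", wtp = 30000), 0)
})

test_that("run_psa is reproducible and degenerates to the point estimate", {
  p <- reference_parameters()
  strategies <- builtin_strategies()[c("Routine 2-year", "RR 2-1")]
  degen <- psa_spec(cost_mammo = list(dist = "uniform", base = p$cost_mammo,
                                      low = p$cost_mammo, high = p$cost_mammo))
  ps <- run_psa(p, degen, strategies, n_draws = 1, n_per_draw = 3000, seed = 77)
  # same cohort run directly: the PSA draw equals the base set, so the
  # only difference could come from seeding; recompute with the same sub-seed
  set.seed(77); sub <- sample.int(.Machine$integer.max - 1L, 2L)
  t0 <- run_cohort(3000, screening_strategy("No screening", "none"), p, sub[2])
  ts <- run_cohort(3000, strategies[["Routine 2-year"]], p, sub[2])
  inc <- increments_vs_no_screening(ts, t0)
  got <- ps$samples[ps$samples$strategy == "Routine 2-year", ]
  expect_equal(got$incremental_qaly, inc$incremental_qaly)
  expect_equal(got$incremental_cost, inc$incremental_cost)

  ps2 <- run_psa(p, degen, strategies, n_draws = 1, n_per_draw = 3000, seed = 77)
  expect_identical(ps$samples, ps2$samples)

  # non-degenerate spec produces between-draw variance
  sp <- psa_spec(cost_mammo = list(dist = "uniform", base = 73.5, low = 50, high = 100))
  ps3 <- run_psa(p, sp, strategies["Routine 2-year"], n_draws = 4,
                 n_per_draw = 1000, seed = 7)
  cc <- ps3$samples$incremental_cost[ps3$samples$strategy == "Routine 2-year"]
  expect_gt(stats::var(cc), 0)
})

test_that("tornado: zero-width range gives zero swing, output sorted, linear in fee", {
  p <- reference_parameters()
  # make incremental cost purely the mammography fee
  p$cost_followup <- 0; p$cost_core_needle <- 0; p$cost_vacuum <- 0
  p$treatment_cost[, ] <- 0; p$overdiagnosis_per_screen <- 0
  sp <- psa_spec(
    cost_mammo = list(dist = "uniform", base = 73.5, low = 60, high = 90),
    specificity = list(dist = "beta", base = 0.97, low = 0.97, high = 0.97))
  tor <- tornado(p, sp, builtin_strategies()[["Routine 2-year"]],
                 outcome = "incremental_cost", n = 3000, seed = 9)
  expect_equal(tor$swing[tor$parameter == "specificity"], 0)
  expect_true(all(diff(tor$swing) <= 0))
  # with common random numbers the cost outcome is exactly proportional
  row <- tor[tor$parameter == "cost_mammo", ]
  expect_equal(row$outcome_high / row$outcome_low, 90 / 60, tolerance = 1e-9)
})
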