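# Life-course engine: degenerate cases, schedule arithmetic, sampling
# checks, determinism, common random numbers, and oracle equivalence.

test_that("attendance draws follow the adherence rate", {
  p <- reference_parameters()
  p1 <- p; p1$adherence_rate <- 1
  expect_true(all(draw_attendance(p1, stats::runif(100))))
  p0 <- p; p0$adherence_rate <- 0
  expect_false(any(draw_attendance(p0, stats::runif(100))))
  set.seed(8)
  x <- draw_attendance(p, stats::runif(1e5))
  expect_lt(abs(mean(x) - 0.54), 3 * sqrt(0.54 * 0.46 / 1e5))
})

test_that("stage at diagnosis uses the right table and frequencies", {
  p <- reference_parameters()
  # degenerate distribution: always local
  p1 <- p
  p1$stage_distribution["interval-2", , , ] <- rep(c(1, 0, 0), each = 8)
  st <- stage_at_diagnosis(TRUE, 2L, rep(2L, 50), 60, p1, u = stats::runif(50))
  expect_true(all(st == 1L))

  # non-attenders draw from the no-screening table regardless of interval
  p2 <- p
  p2$stage_distribution["no-screening", , , ] <- rep(c(0, 0, 1), each = 8)
  st2 <- stage_at_diagnosis(FALSE, 1L, rep(1L, 50), 55, p2, u = stats::runif(50))
  expect_true(all(st2 == 3L))

  # multinomial frequencies within 3 SEs
  p3 <- p
  for (s in 1:3) p3$stage_distribution["no-screening", 1, 1, s] <- c(0.6, 0.3, 0.1)[s]
  set.seed(11)
  st3 <- stage_at_diagnosis(rep(FALSE, 1e5), 1L, rep(1L, 1e5), 55, p3)
  for (s in 1:3) {
    pr <- c(0.6, 0.3, 0.1)[s]
    expect_lt(abs(mean(st3 == s) - pr), 3 * sqrt(pr * (1 - pr) / 1e5))
  }
})

test_that("certain immediate death: one cycle, at most one invitation", {
  p <- reference_parameters()
  p$background_mortality[] <- 1
  tal <- run_cohort(200, builtin_strategies()[["Routine 2-year"]], p, seed = 1)
  w <- tal$women
  expect_true(all(w$life_years <= 1))
  expect_true(all(w$screens_invited <= 1))
  expect_true(all(w$died_other))
})

test_that("no disease, no deaths: schedule arithmetic and screening-only cost", {
  p <- eventless_params()
  p$specificity <- 1           # no false positives: pure fee-schedule cost
  s <- builtin_strategies()[["Routine 2-year"]]
  tal <- run_cohort(300, s, p, seed = 2, adherence = "full")
  w <- tal$women
  expect_true(all(!w$died_bc))
  expect_true(all(w$life_years == p$end_age - p$start_age))
  expect_true(all(w$screens_invited == 10))
  expect_true(all(w$screens_attended == 10))
  expect_true(all(w$false_positives == 0))
  # discounted cost = fee * annuity over invitation ages
  ages <- screening_ages(2, p)
  expected_cost <- sum(p$cost_mammo * discount_factor(p$discount_rate,
                                                      ages - p$start_age))
  expect_equal(w$cost, rep(expected_cost, 300), tolerance = 1e-10)
  # annual and triennial invitation counts
  t1 <- run_cohort(50, builtin_strategies()[["Routine 1-year"]], p, seed = 2)
  expect_true(all(t1$women$screens_invited == 20))
  t3 <- run_cohort(50, builtin_strategies()[["Routine 3-year"]], p, seed = 2)
  expect_true(all(t3$women$screens_invited == 7))
})

test_that("perfect specificity yields no false positives; zero adherence no screens", {
  p <- eventless_params()
  p$specificity <- 1
  tal <- run_cohort(500, builtin_strategies()[["Routine 1-year"]], p, seed = 3)
  expect_equal(sum(tal$women$false_positives), 0)

  p2 <- eventless_params()
  p2$adherence_rate <- 0
  tal2 <- run_cohort(500, builtin_strategies()[["Routine 1-year"]], p2, seed = 3,
                     adherence = "actual")
  expect_equal(sum(tal2$women$screens_attended), 0)
  expect_equal(sum(tal2$women$cost), 0)
  expect_equal(sum(tal2$women$false_positives), 0)
})

test_that("false positives scale with screens attended at rate 1 - specificity", {
  p <- eventless_params()      # no disease: every attended screen can be FP
  tal <- run_cohort(20000, builtin_strategies()[["Routine 1-year"]], p, seed = 4,
                    adherence = "actual")
  w <- tal$women
  fit <- stats::lm(false_positives ~ screens_attended, data = w)
  slope <- stats::coef(fit)[2]
  se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(slope - (1 - p$specificity)), 3 * se)
  # per-screen FP frequency directly
  rate <- sum(w$false_positives) / sum(w$screens_attended)
  expect_lt(abs(rate - 0.03), 3 * sqrt(0.03 * 0.97 / sum(w$screens_attended)))
})

test_that("run_cohort is deterministic and conserves the cohort", {
  p <- reference_parameters()
  s <- builtin_strategies()[["RR 2-1"]]
  a <- run_cohort(5000, s, p, seed = 10, adherence = "actual")
  b <- run_cohort(5000, s, p, seed = 10, adherence = "actual")
  expect_identical(a$women, b$women)
  t <- a$totals
  expect_equal(t$deaths_bc + t$deaths_other + t$alive_at_end, 5000)

  z <- run_cohort(0, s, p, seed = 1)
  expect_equal(z$totals$deaths_bc, 0)
  expect_equal(z$totals$cost, 0)
  expect_equal(nrow(z$women), 0)
})

test_that("common random numbers: undiagnosed women are identical across arms", {
  p <- reference_parameters()
  n <- 5000
  streams <- crn_streams(n, 21, p)
  profiles <- assign_risk_profiles(p, n, u = list(
    density = streams$profile_density, family_history = streams$profile_fh,
    biopsy = streams$profile_bx))
  t0 <- run_cohort(n, screening_strategy("No screening", "none"), p, 21,
                   streams = streams, profiles = profiles)
  t1 <- run_cohort(n, builtin_strategies()[["Routine 1-year"]], p, 21,
                   streams = streams, profiles = profiles)
  und <- is.na(t0$women$diagnosed_stage) & is.na(t1$women$diagnosed_stage) &
    !t1$women$overdiagnosed
  expect_gt(sum(und), 0)
  expect_identical(t0$women$died_other[und], t1$women$died_other[und])
  expect_equal(t0$women$life_years[und], t1$women$life_years[und])
})

test_that("micro-simulation matches the deterministic cohort recursion", {
  # stylized set: single stage, constant hazards, no screening
  p <- stylized_params()
  n <- 100000
  tal <- run_cohort(n, screening_strategy("No screening", "none"), p, seed = 5)
  oracle <- cohort_oracle(p)
  frac <- tal$totals$deaths_bc / n
  se <- sqrt(oracle$dead_bc * (1 - oracle$dead_bc) / n)
  expect_lt(abs(frac - oracle$dead_bc), 3 * se)

  # full reference set (heterogeneous risk, DCIS, banded survival)
  p2 <- reference_parameters()
  tal2 <- run_cohort(n, screening_strategy("No screening", "none"), p2, seed = 6)
  o2 <- cohort_oracle(p2)
  f2 <- tal2$totals$deaths_bc / n
  se2 <- sqrt(o2$dead_bc * (1 - o2$dead_bc) / n)
  expect_lt(abs(f2 - o2$dead_bc), 3 * se2)
  # other-cause deaths too
  fo <- tal2$totals$deaths_other / n
  seo <- sqrt(o2$dead_other * (1 - o2$dead_other) / n)
  expect_lt(abs(fo - o2$dead_other), 3 * seo)
})

test_that("life-course record is internally consistent", {
  p <- reference_parameters()
  s <- builtin_strategies()[["Routine 2-year"]]
  tal <- run_cohort(3000, s, p, seed = 12, adherence = "actual")
  w <- tal$women
  expect_true(all(w$screens_attended <= w$screens_invited))
  expect_true(all(w$fp_biopsies <= w$false_positives))
  expect_true(all(w$life_years >= 0 & w$cost >= 0))
  expect_true(all(w$life_years <= p$end_age - p$start_age))
  # breast-cancer deaths only among the diagnosed
  expect_true(all(!w$died_bc | !is.na(w$diagnosed_stage)))
})

test_that("overdiagnosis cannot kill and is bounded by screens attended", {
  p <- eventless_params()
  p$overdiagnosis_per_screen <- 0.05
  tal <- run_cohort(5000, builtin_strategies()[["Routine 1-year"]], p, seed = 13)
  w <- tal$women
  expect_equal(sum(w$died_bc), 0)
  expect_gt(sum(w$overdiagnosed), 0)
  # overdiagnosed women stop being invited
  expect_true(all(w$screens_invited[w$overdiagnosed] <= 20))
})
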