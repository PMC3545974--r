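test_that("degenerate inputs give full-accrual cycles and no events", {
  p <- flat_params(risks = c(hip = 0, vertebral = 0, wrist = 0), q6 = 0,
                   m6 = 0)
  out <- simulate_patient(bare_cohort(), "none", p, scripted_draws(3))
  expect_equal(nrow(out$ledger), 3)
  expect_equal(out$ledger$accrual_fraction, rep(1, 3))
  expect_equal(sum(out$fracture_counts), 0)
  expect_equal(out$cost, 0)
  expect_equal(out$life_years, 1.5)
})

test_that("a scripted trajectory matches a hand-computed ledger to 1e-12", {
  p <- flat_params(risks = c(hip = 0.1, vertebral = 0, wrist = 0),
                   q6 = 0.1, pfx = 0, m6 = 0.02,
                   excess_hip = c(3, 2, 1),
                   faf = c(hip = 2, vertebral = 2, wrist = 2),
                   base_utility = 0.8,
                   um_first = c(hip = 0.7, vertebral = 0.626, wrist = 0.94),
                   um_sub = c(hip = 0.9, vertebral = 0.909, wrist = 1),
                   acute = c(hip = 1000, vertebral = 500, wrist = 200),
                   continuing = c(hip = 100, vertebral = 50, wrist = 0))
  spec <- bare_cohort()
  # hip fracture in cycle 2, natural death in cycle 3
  draws <- scripted_draws(5, hip = c(0.99, 0.99, 1e-4, 0.99, 0.99),
                          natural = c(0.99, 0.99, 0.99, 1e-4, 0.99))
  out <- simulate_patient(spec, "none", p, draws)

  p6 <- 1 - 0.9^0.5           # six-month fracture probability from 0.1/yr
  dfc <- 1.03^(-0.5 * 0:3)
  # survival checks implicit in the draws: excess in cycle 3 is
  # m6*(mult-1) = 0.02*2 = 0.04 < 0.99; fracture prob in cycle 3 is
  # p6 * 2 (history RR) < 0.99
  expect_equal(out$ledger$cycle, 0:3)
  expect_equal(out$ledger$accrual_fraction, c(1, 1, 1, 0.5))
  expect_equal(out$ledger$cost_fracture_acute, c(0, 0, 1000, 0))
  expect_equal(out$ledger$cost_fracture_continuing, c(0, 0, 0, 0.5 * 100))
  expect_equal(out$ledger$utility,
               c(0.8, 0.8, 0.8 * 0.7, 0.8 * 0.7), tolerance = 1e-12)
  expect_equal(out$fracture_counts[["hip"]], 1)
  expect_equal(out$life_years, 1.75)
  expect_equal(out$cost, 1000 * dfc[3] + 50 * dfc[4], tolerance = 1e-12)
  expect_equal(out$qaly,
               0.5 * (0.8 * dfc[1] + 0.8 * dfc[2] + 0.56 * dfc[3] +
                        0.56 * 0.5 * dfc[4]),
               tolerance = 1e-12)

  # the ledger is self-consistent with the QALY accumulator
  acc <- accumulate_qalys(out$ledger, 0.03)
  expect_equal(acc[["qaly"]], out$qaly, tolerance = 1e-12)
  expect_equal(acc[["life_years"]], out$life_years, tolerance = 1e-12)
})

test_that("common random numbers make arms identical when treatment is inert", {
  p <- neutralized_params()
  spec <- default_cohorts()$pmo_2fx
  res <- run_cohort(spec, p, n_patients = 1500, n_replications = 2, seed = 9)
  s <- res$summary
  for (col in c("cost", "qaly", "life_years", "fx_hip", "fx_vertebral",
                "fx_wrist"))
    expect_equal(s[[col]], rep(s[[col]][1], nrow(s)), label = col)
})

test_that("with efficacy neutralized only, fracture streams still coincide", {
  p <- default_parameter_set()
  for (arm in c("teriparatide", "bisphosphonate"))
    for (t in fracture_types()) {
      p$efficacy[[arm]][[t]]$on_treatment_rr <- 1
      p$efficacy[[arm]][[t]]$sustained_rr <- 1
    }
  spec <- default_cohorts()$pmo_2fx
  res <- run_cohort(spec, p, n_patients = 1000, n_replications = 1, seed = 5)
  s <- res$summary
  for (col in c("fx_hip", "fx_vertebral", "fx_wrist", "life_years"))
    expect_equal(s[[col]], rep(s[[col]][1], nrow(s)), label = col)
  # but drug costs still differ across arms
  expect_gt(s$cost[s$arm == "teriparatide"], s$cost[s$arm == "none"])
})

test_that("runs are deterministic for a fixed seed and flag placeholders", {
  p <- default_parameter_set()
  spec <- default_cohorts()$giop_2fx
  a <- run_cohort(spec, p, n_patients = 400, n_replications = 2, seed = 33)
  b <- run_cohort(spec, p, n_patients = 400, n_replications = 2, seed = 33)
  expect_identical(a$summary, b$summary)
  expect_identical(a$rep_means, b$rep_means)
  c2 <- run_cohort(spec, p, n_patients = 400, n_replications = 2, seed = 34)
  expect_false(identical(a$summary, c2$summary))
  # any run on a bundle containing placeholder tables says so
  expect_true(length(a$placeholder_tables) > 0)
  expect_true("baseline_risks" %in% a$placeholder_tables)
})

test_that("stronger efficacy weakly reduces fractures under paired seeds", {
  spec <- default_cohorts()$pmo_2fx
  p_eff <- default_parameter_set()
  p_null <- p_eff
  for (t in fracture_types()) {
    p_null$efficacy$teriparatide[[t]]$on_treatment_rr <- 1
    p_null$efficacy$teriparatide[[t]]$sustained_rr <- 1
  }
  a <- run_cohort(spec, p_eff, 4000, 1, seed = 77, arms = "teriparatide")
  b <- run_cohort(spec, p_null, 4000, 1, seed = 77, arms = "teriparatide")
  tot <- function(r) sum(r$summary[c("fx_hip", "fx_vertebral", "fx_wrist")])
  expect_lte(tot(a), tot(b))
  # and QALYs never exceed life years times the maximum base utility
  expect_lte(a$summary$qaly, a$summary$life_years * 0.84)
})

test_that("mixed-gender cohorts assign gender per the female fraction", {
  p <- flat_params(risks = c(hip = 0, vertebral = 0, wrist = 0), q6 = 0,
                   m6 = 0)
  spec <- bare_cohort("GIOP", female_fraction = 0.8)
  set.seed(12)
  n <- 5000
  C <- 4
  draws <- make_draws(n, C)
  gender_idx <- ifelse(runif(n) < spec$female_fraction, 1L, 2L)
  expect_equal(mean(gender_idx == 1L), 0.8, tolerance = 0.03)
  res <- simulate_arm(spec, "none", p, draws, gender_idx)
  expect_equal(mean(res$life_years), C * 0.5)
})
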