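# minimal osteo_result for arithmetic checks
fake_result <- function(cost, qaly, ly = c(10, 10),
                        fx = rbind(c(0.3, 0.3, 0.3), c(0.25, 0.25, 0.25)),
                        arms = c("none", "teriparatide")) {
  summary <- data.frame(arm = arms, n_patients = 1000, cost = cost,
                        qaly = qaly, life_years = ly,
                        fx_hip = fx[, 1], fx_vertebral = fx[, 2],
                        fx_wrist = fx[, 3])
  rep_means <- cbind(replication = 1, summary)
  structure(list(arms = arms, summary = summary, rep_means = rep_means),
            class = "osteo_result")
}

test_that("ICER definition, dominance and degenerate labels", {
  r <- fake_result(cost = c(1000, 2000), qaly = c(1.00, 1.05))
  ce <- icer(r, "teriparatide", "none")
  expect_equal(ce$delta_cost, 1000)
  expect_equal(ce$delta_qaly, 0.05)
  expect_equal(ce$icer, 20000)
  expect_equal(ce$label, "icer")

  ce2 <- icer(fake_result(cost = c(1000, 990), qaly = c(1.00, 1.01)),
              "teriparatide", "none")
  expect_equal(ce2$label, "dominant")

  ce3 <- icer(fake_result(cost = c(1000, 1500), qaly = c(1.00, 1.00)),
              "teriparatide", "none")
  expect_equal(ce3$label, "undefined")
  expect_true(is.na(ce3$icer))

  ce4 <- icer(fake_result(cost = c(1000, 1500), qaly = c(1.00, 0.95)),
              "teriparatide", "none")
  expect_equal(ce4$label, "dominated")
})

test_that("quadrant classification matches a brute-force classifier", {
  set.seed(99)
  dc <- runif(10000, -1, 1)
  dq <- runif(10000, -1, 1)
  dq[sample(10000, 20)] <- 0
  for (i in seq_len(10000)) {
    got <- classify_ce(dc[i], dq[i])
    want <- if (dq[i] == 0) "undefined"
      else if (dq[i] > 0 && dc[i] <= 0) "dominant"
      else if (dq[i] > 0) "icer"
      else if (dc[i] >= 0) "dominated"
      else "sw"
    if (got != want) fail(sprintf("mismatch at dc=%g dq=%g", dc[i], dq[i]))
  }
  succeed()
})

test_that("fractures avoided per 1,000 is the scaled paired difference", {
  r <- fake_result(cost = c(0, 0), qaly = c(1, 1))
  av <- fractures_avoided_per_1000(r, "teriparatide", "none")
  expect_equal(unname(av[fracture_types()]), rep(50, 3))
  expect_equal(av[["total"]], 150)
  same <- fake_result(cost = c(0, 0), qaly = c(1, 1),
                      fx = rbind(c(0.3, 0.3, 0.3), c(0.3, 0.3, 0.3)))
  expect_equal(unname(fractures_avoided_per_1000(same, "teriparatide", "none")),
               rep(0, 4))
})

test_that("PSA sampling distributions keep their mean and support", {
  set.seed(2024)
  x <- psa_sample_values(10000, "lognormal", 1, 0.5, 2)
  expect_true(all(x >= 0.5 & x <= 2))
  expect_lt(abs(mean(x) - 1), 0.02)

  b <- psa_sample_values(10000, "beta", 0.17, 0.08, 0.36)
  expect_true(all(b >= 0.08 & b <= 0.36))
  expect_lt(abs(mean(b) - 0.17), 0.02 * 0.17 + 0.005)

  expect_equal(psa_sample_values(5, "beta", 0.4, 0.4, 0.4), rep(0.4, 5))
  expect_error(psa_sample_values(1, "beta", 0.9, 0.1, 0.5), "support")
})

test_that("sampled parameter sets stay within their stated supports", {
  p <- default_parameter_set()
  cfg <- default_psa_config(p)
  set.seed(7)
  for (i in 1:25) {
    ps <- sample_psa_draw(p, cfg)
    expect_true(validate_parameter_set(ps))
    rr <- ps$efficacy$teriparatide$vertebral$on_treatment_rr
    expect_true(rr >= 0.08 && rr <= 0.36)
    # pooled non-vertebral RR is shared by hip and wrist
    expect_equal(ps$efficacy$teriparatide$hip$on_treatment_rr,
                 ps$efficacy$teriparatide$wrist$on_treatment_rr)
    sc <- ps$costs$fracture_costs$acute / p$costs$fracture_costs$acute
    expect_true(all(sc >= 0.5 & sc <= 2))
  }
})

test_that("PSA quadrants partition the draws and reproduce base case when degenerate", {
  p <- flat_params(risks = c(hip = 0.05, vertebral = 0.08, wrist = 0.03),
                   q6 = 0.05)
  spec <- default_cohorts()$pmo_2fx
  psa <- run_psa(spec, p, degenerate_psa_config(p), n_sims = 3,
                 n_patients = 300, seed = 21)
  expect_equal(sum(psa$quadrant_counts), 3)

  # degenerate distributions: each draw equals a direct paired run with the
  # draw's engine seed
  for (i in seq_len(nrow(psa$draws))) {
    d <- psa$draws[i, ]
    res <- run_cohort(spec, p, 300, 1, d$run_seed,
                      arms = c("teriparatide", "bisphosphonate"))
    ce <- icer(res, "teriparatide", "bisphosphonate")
    expect_identical(d$delta_cost, ce$delta_cost)
    expect_identical(d$delta_qaly, ce$delta_qaly)
  }
})

test_that("acceptability curve counts dominance correctly and is monotone", {
  draws <- data.frame(delta_cost = c(10000 * 0.5, 30000 * 0.5, 70000 * 0.5),
                      delta_qaly = c(0.5, 0.5, 0.5))
  cur <- acceptability_curve(draws, wtp_grid = 50000)
  expect_equal(cur$prob, 2 / 3)

  dominant <- data.frame(delta_cost = c(-5, -10), delta_qaly = c(0.1, 0.2))
  cur2 <- acceptability_curve(dominant, wtp_grid = c(0, 25000, 50000))
  expect_equal(cur2$prob, rep(1, 3))

  mixed <- data.frame(delta_cost = c(-5, 100, 200),
                      delta_qaly = c(0.1, 0.01, -0.01))
  cur3 <- acceptability_curve(mixed, wtp_grid = 0)
  expect_equal(cur3$prob, 1 / 3)  # only the dominant draw at WTP 0

  set.seed(314)
  rand <- data.frame(delta_cost = rnorm(500, 100, 300),
                     delta_qaly = rnorm(500, 0.02, 0.05))
  cur4 <- acceptability_curve(rand, wtp_grid = seq(0, 2e5, by = 1e4))
  expect_true(all(diff(cur4$prob) >= 0))
  # NMB variant agrees when no draw has negative incremental QALYs
  pos <- rand[rand$delta_qaly > 0, ]
  g <- seq(0, 2e5, by = 1e4)
  expect_equal(acceptability_curve(pos, g, method = "share")$prob,
               acceptability_curve(pos, g, method = "nmb")$prob)
  expect_error(acceptability_curve(rand[0, ], g), "no PSA draws")
})

test_that("one-way sensitivity analysis reruns with same seeds and sorts", {
  p <- flat_params(risks = c(hip = 0.05, vertebral = 0.08, wrist = 0.03),
                   q6 = 0.05)
  spec <- default_cohorts()$pmo_2fx
  expect_equal(nrow(one_way_sa(spec, p, list())), 0)

  teri_fast_offset <- lapply(p$efficacy$teriparatide, function(pr) {
    pr$sustained_rr <- pr$on_treatment_rr
    pr$sustained_months <- 0
    pr$offset_months <- 18
    pr
  })
  vars <- list(
    # the exchange rate is not consumed by the engine: a pure no-op
    list(path = "sek_per_eur", low = 8, high = 10, name = "fx rate (inert)"),
    list(path = "efficacy.teriparatide", low = p$efficacy$teriparatide,
         high = teri_fast_offset, name = "teriparatide offset")
  )
  tt <- one_way_sa(spec, p, vars, n_patients = 2000, n_replications = 1,
                   seed = 13)
  inert <- tt[tt$name == "fx rate (inert)", ]
  expect_equal(inert$icer_low, inert$icer_high)
  expect_equal(inert$range, 0)
  off <- tt[tt$name == "teriparatide offset", ]
  # removing the sustained-efficacy period pushes the ICER up
  expect_gt(off$icer_high, off$icer_low)
  expect_equal(tt$name[1], "teriparatide offset")  # sorted by range width
})
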