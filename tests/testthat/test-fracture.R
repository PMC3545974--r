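risk_tab <- data.frame(gender = "female", ftype = "hip",
                       age = c(52, 57, 62), risk = c(0.01, 0.03, 0.05))

test_that("baseline risk interpolation hits midpoints, interpolates, clamps", {
  expect_equal(interpolate_baseline_risk(52, "female", "hip", risk_tab), 0.01)
  expect_equal(interpolate_baseline_risk(54.5, "female", "hip", risk_tab), 0.02)
  expect_equal(interpolate_baseline_risk(40, "female", "hip", risk_tab), 0.01)
  expect_equal(interpolate_baseline_risk(80, "female", "hip", risk_tab), 0.05)
  expect_error(interpolate_baseline_risk(60, "male", "hip", risk_tab),
               "no risk series")
})

test_that("male risks scale the female risk by the ratio, capped at 1", {
  expect_equal(male_risk_from_female(0.02, 0.5), 0.01)
  expect_equal(male_risk_from_female(0.02, 1.0), 0.02)
  expect_equal(male_risk_from_female(0.9, 1.5), 1.0)
  expect_error(male_risk_from_female(0.1, -1), "positive")
})

test_that("BMD multiplier is exponential in the T-score gap", {
  expect_equal(bmd_multiplier(-1.5, -1.5, 2.0), 1.0)
  expect_equal(bmd_multiplier(-2.0, -1.0, 2.0), 2.0)
  # half an SD below the mean, against a log-space recomputation
  expect_equal(bmd_multiplier(-1.5, -1.0, 2.0), exp(0.5 * log(2)),
               tolerance = 1e-12)
  expect_equal(round(bmd_multiplier(-1.5, -1.0, 2.0), 5), 1.41421)
  expect_error(bmd_multiplier(-1, 0, 0.9), ">= 1")
})

test_that("history multiplier follows the window, escalation and max rules", {
  p <- flat_params(faf = c(hip = 2.3, vertebral = 2.0, wrist = 1.5))
  h <- function(type, cycle) data.frame(type = type, cycle = cycle)

  expect_equal(history_multiplier(h(character(0), numeric(0)), 0, "PMO", p), 1)
  # a fracture six years ago is outside the five-year window
  expect_equal(history_multiplier(h("vertebral", -12), 0, "PMO", p), 1)
  # at exactly five years it still counts
  expect_equal(history_multiplier(h("vertebral", -10), 0, "PMO", p), 2.0)
  # two in-window vertebral fractures, PMO: 1 + 2 * (r - 1)
  expect_equal(history_multiplier(h(c("vertebral", "vertebral"), c(-10, -1)),
                                  0, "PMO", p), 3.0)
  # GIOP escalates by 50% instead: 1 + 1.5 * (r - 1)
  expect_equal(history_multiplier(h(c("vertebral", "vertebral"), c(-10, -1)),
                                  0, "GIOP", p), 2.5)
  # across types, the largest multiplier wins
  expect_equal(history_multiplier(h(c("hip", "wrist"), c(-2, -1)), 0, "PMO", p),
               2.3)
})

test_that("history multiplier matches a literal enumeration oracle", {
  p <- flat_params(faf = c(hip = 2.3, vertebral = 2.0, wrist = 1.5))
  oracle <- function(history, now, disease) {
    # direct transcription of the rule: per type, count events within the
    # 5-year window; 1 event -> r, 2+ events -> 1 + (1+s)(r-1); overall max
    s <- c(PMO = 1.0, GIOP = 0.5)[[disease]]
    best <- 1
    for (t in fracture_types()) {
      ys <- (now - history$cycle[history$type == t]) / 2
      k <- sum(ys >= 0 & ys <= 5)
      r <- p$fracture_after_fracture_rr[[t]]
      if (k == 1) best <- max(best, r)
      if (k >= 2) best <- max(best, 1 + (1 + s) * (r - 1))
    }
    best
  }
  set.seed(11)
  for (i in 1:200) {
    n <- sample(0:4, 1)
    hist <- data.frame(type = sample(fracture_types(), n, replace = TRUE),
                       cycle = sample(-14:0, n, replace = TRUE))
    now <- sample(0:6, 1)
    hist <- hist[hist$cycle <= now, , drop = FALSE]
    dis <- sample(c("PMO", "GIOP"), 1)
    expect_equal(history_multiplier(hist, now, dis, p),
                 oracle(hist, now, dis))
  }
})

test_that("treatment relative-risk timelines follow the published schedule", {
  p <- default_parameter_set()
  vert <- p$efficacy$teriparatide$vertebral
  hip <- p$efficacy$teriparatide$hip
  bis <- p$efficacy$bisphosphonate$vertebral

  # on treatment: trial RR held constant
  expect_equal(treatment_rr("teriparatide", "vertebral", 6, 18, vert), 0.17)
  expect_equal(treatment_rr("teriparatide", "hip", 0, 18, hip), 0.47)
  # sustained period after cessation
  expect_equal(treatment_rr("teriparatide", "vertebral", 18 + 12, 18, vert), 0.43)
  expect_equal(treatment_rr("teriparatide", "hip", 18 + 30, 18, hip), 0.73)
  # midpoint of the hip linear offset: 39 months post-cessation
  expect_equal(treatment_rr("teriparatide", "hip", 18 + 39, 18, hip), 0.865)
  # beyond the offset: no residual benefit
  expect_equal(treatment_rr("teriparatide", "hip", 18 + 48, 18, hip), 1)
  expect_equal(treatment_rr("teriparatide", "vertebral", 18 + 37, 18, vert), 1)
  # bisphosphonate ramp midpoint: (1 + on_treatment_rr) / 2
  expect_equal(treatment_rr("bisphosphonate", "vertebral", 18 + 9, 18, bis),
               (1 + bis$on_treatment_rr) / 2)
  # no-treatment arm is always 1
  expect_equal(treatment_rr("none", "hip", 40, 18), 1)
  # early cessation anchors the same timeline at the cessation month
  expect_equal(treatment_rr("teriparatide", "vertebral", 6 + 12, 6, vert), 0.43)
})

test_that("cycle fracture probability composes baseline and multipliers", {
  patient <- list(age = 69, gender = "female", t_score = 0, disease = "PMO",
                  arm = "none",
                  history = data.frame(type = character(0), cycle = numeric(0)))

  p0 <- flat_params(risks = c(hip = 0, vertebral = 0, wrist = 0))
  hb <- cycle_fracture_probability(patient, "hip", 0, p0)
  expect_equal(hb$final, 0)

  p1 <- flat_params(risks = c(hip = 0.04, vertebral = 0.04, wrist = 0.04))
  hb <- cycle_fracture_probability(patient, "hip", 0, p1)
  expect_equal(hb$final, 1 - 0.96^0.5, tolerance = 1e-12)
  expect_equal(round(hb$final, 4), 0.0202)

  gpatient <- modifyList(patient, list(disease = "GIOP"))
  p2 <- flat_params(risks = c(hip = 0.04, vertebral = 0.04, wrist = 0.04),
                    giop = c(hip = 2, vertebral = 2, wrist = 2))
  hb2 <- cycle_fracture_probability(gpatient, "hip", 0, p2)
  expect_equal(hb2$final, 2 * (1 - 0.96^0.5), tolerance = 1e-12)
  expect_equal(hb2$giop_multiplier, 2)
})

test_that("final probability is monotone in each multiplier", {
  patient <- list(age = 69, gender = "female", t_score = -2, disease = "PMO",
                  arm = "none",
                  history = data.frame(type = "hip", cycle = -1))
  base <- flat_params(risks = c(hip = 0.03, vertebral = 0.03, wrist = 0.03))
  f0 <- cycle_fracture_probability(patient, "hip", 0, base)$final
  # steeper BMD gradient raises risk for a below-mean patient
  steeper <- flat_params(risks = c(hip = 0.03, vertebral = 0.03, wrist = 0.03),
                         gradient = c(hip = 2, vertebral = 2, wrist = 2))
  f1 <- cycle_fracture_probability(patient, "hip", 0, steeper)$final
  expect_gt(f1, f0)
  # larger fracture-after-fracture RR raises risk
  stronger <- flat_params(risks = c(hip = 0.03, vertebral = 0.03, wrist = 0.03),
                          faf = c(hip = 3, vertebral = 3, wrist = 3))
  f2 <- cycle_fracture_probability(patient, "hip", 0, stronger)$final
  expect_gt(f2, f0)
  # rate-scale composition stays a probability under extreme multipliers
  extreme <- flat_params(risks = c(hip = 0.5, vertebral = 0.5, wrist = 0.5),
                         faf = c(hip = 10, vertebral = 10, wrist = 10))
  extreme$risk_composition <- "rate"
  f3 <- cycle_fracture_probability(patient, "hip", 0, extreme)$final
  expect_lt(f3, 1)
  expect_gt(f3, 0)
})
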