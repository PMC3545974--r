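#' Interpolate a baseline fracture risk from an age-banded table
#'
#' Risks are tabulated at age-band midpoints (the 50-54 band is carried at
#' age 52, and so on).  At a midpoint the table value is returned exactly;
#' between midpoints the value is linearly interpolated; below the first and
#' above the last midpoint the end value is used (clamping).
#'
#' @param age Age in years (vectorised).
#' @param gender `"female"` or `"male"`.
#' @param ftype One of [fracture_types()].
#' @param table A risk table with columns `gender`, `ftype`, `age`, `risk`.
#' @return Annual first-fracture probability at population-mean BMD.
#' @export
interpolate_baseline_risk <- function(age, gender, ftype, table) {
  sub <- table[table$gender == gender & table$ftype == ftype, ]
  if (!nrow(sub))
    stop("no risk series for gender=", gender, ", ftype=", ftype)
  .interp(age, sub$age, sub$risk)
}

#' Impute a male fracture risk from the female risk
#'
#' Male risks are obtained by scaling the female risk by the male:female
#' relative-risk ratio, capped at 1 so the result stays a probability.
#'
#' @param female_risk Female annual fracture probability.
#' @param ratio Male:female risk ratio (> 0).
#' @return Male annual fracture probability.
#' @export
male_risk_from_female <- function(female_risk, ratio) {
  if (any(ratio <= 0)) stop("male:female ratio must be positive")
  pmin(1, female_risk * ratio)
}

#' BMD relative-risk multiplier
#'
#' The fracture-risk gradient per standard deviation of bone mineral density
#' is applied exponentially to the gap between the age-specific population
#' mean T-score and the patient's measured T-score:
#' `gradient^(t_mean - t_measured)`.  A patient at the population mean has
#' multiplier 1; each SD below the mean multiplies risk by the gradient.
#'
#' @param t_measured Patient T-score (SD).
#' @param t_mean_at_age Population mean T-score at the patient's age (SD).
#' @param gradient Relative risk per SD of BMD (>= 1).
#' @return Risk multiplier.
#' @export
bmd_multiplier <- function(t_measured, t_mean_at_age, gradient) {
  if (any(gradient < 1)) stop("BMD gradient must be >= 1")
  gradient^(t_mean_at_age - t_measured)
}

#' Fracture-history relative-risk multiplier
#'
#' Prior fractures raise future fracture risk for a limited window (5 years
#' by default).  One in-window fracture of a type with relative risk `r`
#' contributes `r`; a second in-window fracture of the same type escalates
#' the risk increase by 50% (GIOP) or 100% (PMO):
#' `1 + (1 + s) * (r - 1)`.  Third and later same-type fractures reuse the
#' second-fracture multiplier.  Across types the largest multiplier applies.
#'
#' @param history Data frame of fracture events with columns `type` and
#'   `cycle` (6-month cycles; negative values are pre-baseline).
#' @param now Current cycle index.
#' @param disease `"PMO"` or `"GIOP"`.
#' @param params An `osteo_params` object.
#' @return Risk multiplier (>= 1).
#' @export
history_multiplier <- function(history, now, disease, params) {
  if (is.null(history) || !nrow(history)) return(1)
  window_cycles <- 2 * params$history_window_years
  s <- params$second_fracture_increase[[disease]]
  years_ok <- (now - history$cycle) >= 0 & (now - history$cycle) <= window_cycles
  inw <- history[years_ok, , drop = FALSE]
  if (!nrow(inw)) return(1)
  m <- 1
  for (t in unique(inw$type)) {
    r <- params$fracture_after_fracture_rr[[t]]
    n <- sum(inw$type == t)
    mt <- if (n >= 2) 1 + (1 + s) * (r - 1) else r
    m <- max(m, mt)
  }
  m
}

# relative risk after treatment cessation, t months after the last treated
# month: sustained_rr through the sustained period, then a linear return to
# 1 over the offset period
.offset_rr <- function(t_months, profile) {
  s <- profile$sustained_months
  off <- profile$offset_months
  rr <- rep(1, length(t_months))
  in_s <- t_months <= s
  rr[in_s] <- profile$sustained_rr
  if (off > 0) {
    in_o <- !in_s & t_months <= s + off
    rr[in_o] <- profile$sustained_rr +
      (1 - profile$sustained_rr) * (t_months[in_o] - s) / off
  }
  rr
}

#' Treatment-dependent relative fracture risk
#'
#' On treatment the trial relative risk applies; after completion or early
#' cessation the sustained relative risk holds for the sustained period,
#' then declines linearly to 1 (no residual benefit) over the offset period.
#' The no-treatment arm always has relative risk 1.
#'
#' @param arm One of [treatment_arms()].
#' @param ftype One of [fracture_types()] (used to pick the profile when
#'   `profile` is not given).
#' @param months_since_treatment_start Months since treatment began
#'   (vectorised).
#' @param months_treated Total months actually treated; times beyond this
#'   are post-cessation.
#' @param profile Efficacy profile (a list with `on_treatment_rr`,
#'   `sustained_rr`, `sustained_months`, `offset_months`); taken from
#'   `params` by the engine.
#' @return Relative risk in (0, 1].
#' @export
treatment_rr <- function(arm, ftype, months_since_treatment_start,
                         months_treated, profile = NULL) {
  if (arm == "none" || is.null(profile))
    return(rep(1, length(months_since_treatment_start)))
  on <- months_since_treatment_start < months_treated
  rr <- rep(profile$on_treatment_rr, length(months_since_treatment_start))
  t_off <- months_since_treatment_start[!on] - months_treated
  rr[!on] <- .offset_rr(t_off, profile)
  rr
}

# resolve mean T-score at an age
.mean_tscore_at <- function(age, params)
  .interp(age, params$mean_tscore$age, params$mean_tscore$tscore)

.giop_multiplier_at <- function(age, ftype, params) {
  sub <- params$giop_rr[params$giop_rr$ftype == ftype, ]
  .interp(age, sub$age, sub$rr)
}

# six-month probability from an annual one
.annual_to_cycle_prob <- function(p_annual) 1 - (1 - p_annual)^0.5

#' Per-cycle fracture probability for one patient
#'
#' Converts the age/gender baseline annual risk to a six-month probability
#' (`1 - (1 - p)^(1/2)`), then applies the BMD, fracture-history,
#' glucocorticoid and treatment relative-risk multipliers, capping the
#' result at 1.  With `params$risk_composition = "rate"`, the multipliers
#' compose on the hazard-rate scale instead.
#'
#' @param patient A list describing the patient state: `age`, `gender`,
#'   `t_score`, `disease`, `arm`, `history` (data frame with `type`,
#'   `cycle`), `months_treated`, and optionally `on_treatment`.
#' @param ftype One of [fracture_types()].
#' @param cycle Current cycle index (cycle 0 is the first simulated cycle).
#' @param params An `osteo_params` object.
#' @return A list of class `hazard_breakdown` with the baseline six-month
#'   probability, each multiplier, and the final probability.
#' @export
cycle_fracture_probability <- function(patient, ftype, cycle, params) {
  age <- patient$age
  p_f <- interpolate_baseline_risk(age, "female", ftype, params$baseline_risks)
  if (identical(patient$gender, "male")) {
    sub <- params$male_female_ratios[params$male_female_ratios$ftype == ftype, ]
    p_annual <- male_risk_from_female(p_f, .interp(age, sub$age, sub$ratio))
  } else p_annual <- p_f

  bmd_m <- bmd_multiplier(patient$t_score, .mean_tscore_at(age, params),
                          params$bmd_gradient[[ftype]])
  hist_m <- history_multiplier(patient$history, cycle, patient$disease, params)
  giop_m <- if (identical(patient$disease, "GIOP"))
    .giop_multiplier_at(age, ftype, params) else 1
  months_started <- 6 * cycle
  months_treated <- patient$months_treated %||% (months_started + 6)
  rr <- treatment_rr(patient$arm, ftype, months_started, months_treated,
                     params$efficacy[[patient$arm]][[ftype]])

  if (identical(params$risk_composition, "rate")) {
    h <- -log(1 - p_annual) / 2
    base6 <- 1 - exp(-h)
    final <- 1 - exp(-h * bmd_m * hist_m * giop_m * rr)
  } else {
    base6 <- .annual_to_cycle_prob(p_annual)
    final <- pmin(1, base6 * bmd_m * hist_m * giop_m * rr)
  }
  structure(list(baseline = base6, bmd_multiplier = bmd_m,
                 history_multiplier = hist_m, giop_multiplier = giop_m,
                 treatment_rr = rr, final = final),
            class = "hazard_breakdown")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
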