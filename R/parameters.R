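#' Fracture types modelled
#'
#' The three osteoporotic fracture sites carried by the model: hip, clinical
#' vertebral, and wrist.  Every table keyed by fracture type must cover all
#' three.
#'
#' @export
fracture_types <- function() c("hip", "vertebral", "wrist")

#' Treatment arms
#'
#' @return Character vector of the three strategies compared by the model.
#' @export
treatment_arms <- function() c("teriparatide", "bisphosphonate", "none")

# interpolation with constant extension beyond the table range (clamping);
# a length-1 series is treated as flat
.interp <- function(x, xs, ys) {
  if (length(xs) == 1L) return(rep(ys, length(x)))
  o <- order(xs)
  stats::approx(xs[o], ys[o], xout = x, rule = 2, ties = "ordered")$y
}

#' Convert Swedish kronor to euros
#'
#' Applies the fixed SEK-per-euro exchange rate used throughout the model
#' (12-month average ending December 2011).  The rounding policy mirrors the
#' precision at which the published unit costs are quoted: daily drug costs
#' to cents, visit prices to whole euros.
#'
#' @param amount_sek Amount in SEK (vectorised).
#' @param rate Exchange rate in SEK per euro; must be positive.
#' @param round_to One of `"none"` (default), `"cents"`, `"euros"`.
#' @return Amount in euros.
#' @examples
#' convert_sek_to_eur(3728.50 / 28, round_to = "cents")  # 14.74
#' convert_sek_to_eur(1125 + 695, round_to = "euros")    # 201
#' @export
convert_sek_to_eur <- function(amount_sek, rate = 9.0335,
                               round_to = c("none", "cents", "euros")) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("exchange rate must be a single positive number")
  round_to <- match.arg(round_to)
  eur <- amount_sek / rate
  switch(round_to, none = eur, cents = round(eur, 2), euros = round(eur))
}

# ---------------------------------------------------------------------------
# Placeholder tables
#
# Several age-indexed inputs of the model (baseline first-fracture risks,
# male:female risk ratios, glucocorticoid relative risks, age-banded fracture
# costs, life tables and attributable-death proportions, discontinuation
# curves, mean T-score by age) come from supplementary source tables that are
# not shipped with the package.  Stand-in tables are generated from coarse
# anchors: published anchor points are reproduced exactly and intermediate
# values are interpolated with a seeded, monotonicity-preserving jitter so
# that regenerating with the same seed is bit-identical.  Every such table is
# flagged with provenance "placeholder" and is swappable for user data.
# ---------------------------------------------------------------------------

# Interpolate a series through anchors; jitter perturbs the interpolation
# fraction inside each anchor interval (anchors stay exact, the direction of
# the anchor trend is preserved because perturbed fractions are re-sorted).
.anchored_series <- function(x, ax, ay, direction = c("none", "increasing",
                                                      "decreasing"),
                             jitter = 0) {
  direction <- match.arg(direction)
  if (direction == "increasing" && any(diff(ay) < 0))
    stop("anchors violate declared increasing monotonicity")
  if (direction == "decreasing" && any(diff(ay) > 0))
    stop("anchors violate declared decreasing monotonicity")
  y <- .interp(x, ax, ay)
  if (jitter > 0 && length(ax) > 1L) {
    for (i in seq_len(length(ax) - 1L)) {
      inside <- which(x > ax[i] & x < ax[i + 1L])
      if (!length(inside)) next
      f <- (x[inside] - ax[i]) / (ax[i + 1L] - ax[i])
      f <- sort(pmin(pmax(f + stats::runif(length(f), -jitter, jitter), 0), 1))
      y[inside] <- ay[i] + f * (ay[i + 1L] - ay[i])
    }
  }
  y
}

#' Default anchors for placeholder tables
#'
#' Coarse, field-plausible anchor points used by
#' [generate_placeholder_tables()].  Anchors that are quoted in the primary
#' source (the fracture-mortality endpoints 0.007 at age 65 for men and
#' 0.0375 at age 90+ for women) are reproduced exactly by the generator.
#'
#' @return A nested list of anchor specifications (ages, values, declared
#'   monotone direction) per table and series.
#' @export
placeholder_anchors <- function() {
  list(
    baseline_risks = list(   # annual first-fracture risk, Swedish females,
      direction = "increasing",  # population-mean BMD
      hip       = list(age = c(52, 67, 77, 92), value = c(0.0006, 0.004, 0.012, 0.045)),
      vertebral = list(age = c(52, 67, 77, 92), value = c(0.0025, 0.008, 0.015, 0.028)),
      wrist     = list(age = c(52, 67, 77, 92), value = c(0.006, 0.009, 0.011, 0.012))
    ),
    male_female_ratios = list(  # UK male:female fracture-risk ratios
      direction = "increasing",
      hip       = list(age = c(52, 92), value = c(0.55, 0.65)),
      vertebral = list(age = c(52, 92), value = c(0.60, 0.70)),
      wrist     = list(age = c(52, 92), value = c(0.20, 0.35))
    ),
    giop_rr = list(             # glucocorticoid relative risks by age
      direction = "decreasing",
      hip       = list(age = c(52, 92), value = c(2.3, 1.6)),
      vertebral = list(age = c(52, 92), value = c(2.6, 1.9)),
      wrist     = list(age = c(52, 92), value = c(1.6, 1.3))
    ),
    mean_tscore = list(         # population mean T-score by age (SD)
      direction = "decreasing",
      all = list(age = c(50, 69, 100), value = c(-0.7, -1.4, -2.5))
    ),
    fracture_costs = list(      # 6-month costs in EUR by age-band midpoint
      direction = "increasing",
      hip_acute        = list(age = c(52, 92), value = c(9000, 14000)),
      hip_continuing   = list(age = c(52, 72, 92), value = c(300, 1500, 6000)),
      vert_acute       = list(age = c(52, 92), value = c(3500, 5500)),
      vert_continuing  = list(age = c(52, 92), value = c(60, 120)),
      wrist_acute      = list(age = c(52, 92), value = c(1800, 2200))
    ),
    fx_mortality = list(        # base 6-month fracture-mortality probability
      direction = "increasing",
      male   = list(age = c(65, 90), value = c(0.007, 0.0350)),
      female = list(age = c(65, 90), value = c(0.0075, 0.0375))
    ),
    fx_attrib = list(           # proportion of deaths attributable to fracture
      direction = "increasing",
      female = list(age = c(50, 65, 90), value = c(0.005, 0.010, 0.060)),
      male   = list(age = c(50, 65, 90), value = c(0.008, 0.015, 0.070))
    )
  )
}

#' Generate placeholder tables for the parameter bundle
#'
#' Builds the age-indexed stand-in tables described in
#' [placeholder_anchors()].  Output is deterministic for a given seed;
#' anchor points are reproduced exactly and values between anchors follow
#' the anchor trend (seeded jitter cannot break monotonicity).  Life tables
#' are generated from a Gompertz hazard calibrated to Nordic-like adult
#' mortality and are not jittered.
#'
#' @param seed Integer seed controlling the jitter.
#' @param anchors Anchor specification, by default [placeholder_anchors()].
#' @param jitter Relative jitter applied to interpolation fractions between
#'   anchors (0 disables it).
#' @return Named list of data frames and discontinuation curves, all flagged
#'   `provenance = "placeholder"` when assembled by [default_parameter_set()].
#' @export
generate_placeholder_tables <- function(seed = 1L, anchors = placeholder_anchors(),
                                        jitter = 0.08) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  band_ages <- seq(52, 92, by = 5)
  fine_ages <- 50:110
  ft <- fracture_types()

  series <- function(tab, key, ages) {
    a <- anchors[[tab]][[key]]
    .anchored_series(ages, a$age, a$value, anchors[[tab]]$direction, jitter)
  }

  baseline_risks <- do.call(rbind, lapply(ft, function(t) {
    data.frame(gender = "female", ftype = t, age = band_ages,
               risk = series("baseline_risks", t, band_ages))
  }))
  male_female_ratios <- do.call(rbind, lapply(ft, function(t) {
    data.frame(ftype = t, age = band_ages,
               ratio = series("male_female_ratios", t, band_ages))
  }))
  giop_rr <- do.call(rbind, lapply(ft, function(t) {
    data.frame(ftype = t, age = band_ages,
               rr = series("giop_rr", t, band_ages))
  }))
  mean_tscore <- data.frame(age = 50:100,
                            tscore = series("mean_tscore", "all", 50:100))
  fracture_costs <- rbind(
    data.frame(ftype = "hip", age = band_ages,
               acute = series("fracture_costs", "hip_acute", band_ages),
               continuing = series("fracture_costs", "hip_continuing", band_ages)),
    data.frame(ftype = "vertebral", age = band_ages,
               acute = series("fracture_costs", "vert_acute", band_ages),
               continuing = series("fracture_costs", "vert_continuing", band_ages)),
    data.frame(ftype = "wrist", age = band_ages,
               acute = series("fracture_costs", "wrist_acute", band_ages),
               continuing = 0)
  )

  # Gompertz all-cause annual mortality, converted to 6-month probabilities
  q_annual <- function(age, a, b) pmin(0.75, exp(a + b * age))
  life_table <- rbind(
    data.frame(gender = "female", age = fine_ages,
               q6 = 1 - (1 - q_annual(fine_ages, -13.10, 0.1228))^0.5),
    data.frame(gender = "male", age = fine_ages,
               q6 = 1 - (1 - q_annual(fine_ages, -12.60, 0.1228))^0.5)
  )
  fx_attrib <- do.call(rbind, lapply(c("female", "male"), function(g) {
    data.frame(gender = g, age = fine_ages,
               p = series("fx_attrib", g, fine_ages))
  }))
  fx_mortality <- do.call(rbind, lapply(c("female", "male"), function(g) {
    data.frame(gender = g, age = fine_ages,
               m6 = series("fx_mortality", g, fine_ages))
  }))

  # persistence at the start of each treated 6-month cycle; observational
  # 3/9/15-month persistence interpolated to cycle boundaries
  teri_obs <- list(month = c(3, 9, 15), p = c(0.95, 0.87, 0.82))
  disc_teri <- c(1, .interp(c(6, 12), teri_obs$month, teri_obs$p))
  disc_bis <- c(1, 0.70, 0.56)

  list(baseline_risks = baseline_risks,
       male_female_ratios = male_female_ratios,
       giop_rr = giop_rr,
       mean_tscore = mean_tscore,
       fracture_costs = fracture_costs,
       life_table = life_table,
       fx_attrib = fx_attrib,
       fx_mortality = fx_mortality,
       discontinuation = list(teriparatide = disc_teri,
                              bisphosphonate = disc_bis,
                              none = numeric(0)))
}

.efficacy_profile <- function(on_treatment_rr, sustained_rr, sustained_months,
                              offset_months) {
  list(on_treatment_rr = on_treatment_rr, sustained_rr = sustained_rr,
       sustained_months = sustained_months, offset_months = offset_months)
}

#' Default parameter bundle
#'
#' Assembles the packaged parameter set: scalar model settings, drug and
#' visit prices derived from their published SEK amounts, efficacy timelines,
#' excess-mortality multiplier schedules, base utilities and fracture utility
#' multipliers, plus the generated placeholder tables for everything the
#' primary sources defer to supplementary data.  Each table carries a
#' provenance flag (`"packaged-default"` or `"placeholder"`).
#'
#' @param placeholder_seed Seed for [generate_placeholder_tables()].
#' @return A validated object of class `osteo_params`.
#' @export
default_parameter_set <- function(placeholder_seed = 20121030L) {
  ph <- generate_placeholder_tables(seed = placeholder_seed)
  sek <- 9.0335
  params <- structure(list(
    schema_version = 1L,
    discount_rate_costs = 0.03,
    discount_rate_effects = 0.03,
    sek_per_eur = sek,
    cycle_length_months = 6,
    days_per_cycle = 365.25 / 2,
    treatment_duration_months = 18,
    history_window_years = 5,
    second_fracture_increase = c(GIOP = 0.5, PMO = 1.0),
    age_cap = 100,
    risk_composition = "probability",

    baseline_risks = ph$baseline_risks,
    male_female_ratios = ph$male_female_ratios,
    bmd_gradient = c(hip = 2.6, vertebral = 1.8, wrist = 1.4),
    mean_tscore = ph$mean_tscore,
    giop_rr = ph$giop_rr,
    fracture_after_fracture_rr = c(hip = 2.3, vertebral = 2.0, wrist = 1.5),

    efficacy = list(
      teriparatide = list(
        hip       = .efficacy_profile(0.47, 0.73, 30, 18),
        vertebral = .efficacy_profile(0.17, 0.43, 18, 18),
        wrist     = .efficacy_profile(0.47, 0.73, 30, 18)
      ),
      bisphosphonate = list(  # combined oral-bisphosphonate efficacies;
        hip       = .efficacy_profile(0.77, 0.77, 0, 18),  # ramp to no
        vertebral = .efficacy_profile(0.56, 0.56, 0, 18),  # benefit over
        wrist     = .efficacy_profile(0.77, 0.77, 0, 18)   # 18 months
      ),
      none = NULL
    ),

    costs = list(
      fracture_costs = ph$fracture_costs,
      drug_daily_cost = c(
        teriparatide = convert_sek_to_eur(3728.50 / 28, sek, "cents"),
        bisphosphonate = convert_sek_to_eur(372.00 / 98, sek, "cents"),
        none = 0
      ),
      visit_cost = convert_sek_to_eur(1756, sek, "euros"),
      bmd_visit_cost = convert_sek_to_eur(1125 + 695, sek, "euros")
    ),

    mortality = list(
      life_table = ph$life_table,
      fx_attrib = ph$fx_attrib,
      fx_mortality = ph$fx_mortality,
      excess_multipliers = list(  # by years since fracture; reach 1 at the
        hip = c(2.5, 2.25, 2.0, 1.75, 1.5, 1.25, 1.0),  # phase-out horizon
        vertebral = c(2.5, 2.2, 1.9, 1.6, 1.3, 1.0)
      )
    ),

    utility = list(
      base = data.frame(age = c(50, 55, 60, 65, 70, 75, 80, 85),
                        utility = c(0.84, 0.82, 0.81, 0.78, 0.76, 0.73, 0.69, 0.65)),
      multipliers = data.frame(
        ftype = fracture_types(),
        first_year = c(0.726, 0.626, 0.940),
        subsequent = c(0.813, 0.909, 1.000)
      ),
      repeat_q = 0.25,
      repeat_rule = "multiplicative"
    ),

    discontinuation = ph$discontinuation,

    provenance = c(
      baseline_risks = "placeholder", male_female_ratios = "placeholder",
      bmd_gradient = "placeholder", mean_tscore = "placeholder",
      giop_rr = "placeholder", fracture_after_fracture_rr = "placeholder",
      fracture_costs = "placeholder", life_table = "placeholder",
      fx_attrib = "placeholder", fx_mortality = "placeholder",
      discontinuation = "placeholder",
      efficacy_teriparatide = "packaged-default",
      efficacy_bisphosphonate = "placeholder",
      drug_costs = "packaged-default", visit_costs = "packaged-default",
      utility_base = "packaged-default", utility_multipliers = "placeholder",
      excess_multipliers = "packaged-default"
    )
  ), class = "osteo_params")
  validate_parameter_set(params)
  params
}

#' Names of placeholder tables in a parameter set
#'
#' @param params An `osteo_params` object.
#' @return Character vector of table names whose provenance is
#'   `"placeholder"`.
#' @export
placeholder_tables <- function(params) {
  pv <- params$provenance
  names(pv)[pv == "placeholder"]
}

# ---------------------------------------------------------------------------
# Validation
# ---------------------------------------------------------------------------

#' Validate a parameter set
#'
#' Checks every invariant the simulation engine relies on: probability and
#' multiplier ranges, monotone discontinuation curves, excess-mortality
#' schedules that reach 1 at the phase-out horizon, complete fracture-type
#' coverage, non-negative costs.  Violations are reported together, naming
#' the offending field (and row, for tabular data).
#'
#' @param params An `osteo_params` object.
#' @return Invisibly `TRUE`; stops with a named-field report otherwise.
#' @export
validate_parameter_set <- function(params) {
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  ft <- fracture_types()

  num1 <- function(field, lo = -Inf, hi = Inf, strict_lo = FALSE) {
    v <- params[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        v < lo || v > hi || (strict_lo && v <= lo))
      add(sprintf("%s: must be a finite number in [%s, %s]", field, lo, hi))
  }
  num1("discount_rate_costs", 0)
  num1("discount_rate_effects", 0)
  num1("sek_per_eur", 0, strict_lo = TRUE)
  num1("days_per_cycle", 0, strict_lo = TRUE)
  num1("treatment_duration_months", 0)
  num1("history_window_years", 0)
  num1("age_cap", 50, 120)
  if (!identical(sort(names(params$second_fracture_increase)), c("GIOP", "PMO")))
    add("second_fracture_increase: must be named for GIOP and PMO")

  check_table <- function(df, field, cols, value_col, lo, hi,
                          lo_open = FALSE, hi_open = FALSE) {
    if (is.null(df)) { add(sprintf("%s: missing table", field)); return(invisible()) }
    if (!all(cols %in% names(df))) {
      add(sprintf("%s: missing columns %s", field,
                  paste(setdiff(cols, names(df)), collapse = ", ")))
      return(invisible())
    }
    v <- df[[value_col]]
    bad <- !is.finite(v) | v < lo | v > hi |
      (lo_open & v <= lo) | (hi_open & v >= hi)
    if (any(bad))
      add(sprintf("%s[row %s]: %s out of range", field,
                  paste(which(bad), collapse = ","), value_col))
  }

  check_table(params$baseline_risks, "baseline_risks",
              c("gender", "ftype", "age", "risk"), "risk", 0, 1)
  if (!is.null(params$baseline_risks)) {
    for (t in ft) {
      sub <- params$baseline_risks[params$baseline_risks$ftype == t, ]
      if (!nrow(sub)) add(sprintf("baseline_risks: no rows for ftype %s", t))
      else if (any(diff(sub$age) <= 0))
        add(sprintf("baseline_risks[ftype=%s]: age midpoints not strictly increasing", t))
    }
  }
  check_table(params$male_female_ratios, "male_female_ratios",
              c("ftype", "age", "ratio"), "ratio", 0, Inf, lo_open = TRUE)
  check_table(params$giop_rr, "giop_rr", c("ftype", "age", "rr"), "rr", 0,
              Inf, lo_open = TRUE)
  check_table(params$mean_tscore, "mean_tscore", c("age", "tscore"),
              "tscore", -Inf, 0)
  if (!all(ft %in% names(params$bmd_gradient)) ||
      any(params$bmd_gradient < 1))
    add("bmd_gradient: must cover all fracture types with values >= 1")
  if (!all(ft %in% names(params$fracture_after_fracture_rr)) ||
      any(params$fracture_after_fracture_rr <= 0))
    add("fracture_after_fracture_rr: must cover all fracture types with positive values")

  for (arm in c("teriparatide", "bisphosphonate")) {
    prof <- params$efficacy[[arm]]
    if (is.null(prof) || !all(ft %in% names(prof))) {
      add(sprintf("efficacy.%s: missing fracture-type profiles", arm)); next
    }
    for (t in ft) {
      p <- prof[[t]]
      for (f in c("on_treatment_rr", "sustained_rr"))
        if (!is.finite(p[[f]]) || p[[f]] <= 0 || p[[f]] > 1)
          add(sprintf("efficacy.%s.%s.%s: RR must be in (0, 1]", arm, t, f))
      for (f in c("sustained_months", "offset_months"))
        if (!is.finite(p[[f]]) || p[[f]] < 0)
          add(sprintf("efficacy.%s.%s.%s: must be >= 0", arm, t, f))
    }
  }

  fc <- params$costs$fracture_costs
  if (is.null(fc)) add("costs.fracture_costs: missing table")
  else {
    for (col in c("acute", "continuing")) {
      bad <- which(!is.finite(fc[[col]]) | fc[[col]] < 0)
      for (i in bad)
        add(sprintf("costs.fracture_costs[ftype=%s, age=%s]: negative or non-finite %s cost",
                    fc$ftype[i], fc$age[i], col))
    }
    wr <- fc[fc$ftype == "wrist", ]
    if (nrow(wr) && any(wr$continuing != 0))
      add("costs.fracture_costs[ftype=wrist]: continuing cost must be 0")
  }
  if (any(params$costs$drug_daily_cost < 0))
    add("costs.drug_daily_cost: negative cost")
  for (f in c("visit_cost", "bmd_visit_cost"))
    if (params$costs[[f]] < 0) add(sprintf("costs.%s: negative cost", f))

  check_table(params$mortality$life_table, "mortality.life_table",
              c("gender", "age", "q6"), "q6", 0, 1)
  check_table(params$mortality$fx_attrib, "mortality.fx_attrib",
              c("gender", "age", "p"), "p", 0, 1, hi_open = TRUE)
  check_table(params$mortality$fx_mortality, "mortality.fx_mortality",
              c("gender", "age", "m6"), "m6", 0, 1)
  for (t in c("hip", "vertebral")) {
    s <- params$mortality$excess_multipliers[[t]]
    if (is.null(s)) { add(sprintf("mortality.excess_multipliers.%s: missing", t)); next }
    if (any(s < 1)) add(sprintf("mortality.excess_multipliers.%s: values must be >= 1", t))
    if (any(diff(s) > 0)) add(sprintf("mortality.excess_multipliers.%s: must be non-increasing", t))
    if (s[length(s)] != 1) add(sprintf("mortality.excess_multipliers.%s: must reach 1 at phase-out", t))
  }

  ub <- params$utility$base
  check_table(ub, "utility.base", c("age", "utility"), "utility", 0, 1,
              lo_open = TRUE)
  um <- params$utility$multipliers
  if (is.null(um) || !all(ft %in% um$ftype))
    add("utility.multipliers: must cover all fracture types")
  else {
    for (col in c("first_year", "subsequent"))
      if (any(um[[col]] <= 0 | um[[col]] > 1))
        add(sprintf("utility.multipliers.%s: must be in (0, 1]", col))
    if (any(um$first_year > um$subsequent))
      add("utility.multipliers: first_year must be <= subsequent")
  }
  q <- params$utility$repeat_q
  if (!is.finite(q) || q < 0 || q > 1)
    add("utility.repeat_q: must be in [0, 1]")

  n_tx_cycles <- ceiling(params$treatment_duration_months / params$cycle_length_months)
  for (arm in c("teriparatide", "bisphosphonate")) {
    d <- params$discontinuation[[arm]]
    if (is.null(d) || length(d) < n_tx_cycles) {
      add(sprintf("discontinuation.%s: curve shorter than treatment duration", arm)); next
    }
    if (d[1] != 1) add(sprintf("discontinuation.%s: must start at 1.0", arm))
    if (any(d < 0 | d > 1)) add(sprintf("discontinuation.%s: values outside [0, 1]", arm))
    if (any(diff(d) > 0)) add(sprintf("discontinuation.%s: must be non-increasing", arm))
  }

  if (length(errs))
    stop("invalid parameter set:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Disk round trip: one YAML mapping for scalars and small structures, one CSV
# per age-indexed table.
# ---------------------------------------------------------------------------

.csv_tables <- c("baseline_risks", "male_female_ratios", "giop_rr",
                 "mean_tscore", "fracture_costs", "life_table", "fx_attrib",
                 "fx_mortality", "base_utilities")

#' Write a parameter set to a directory
#'
#' Serialises the bundle as one human-auditable `params.yaml` (scalars,
#' efficacy timelines, discontinuation curves, utility multipliers,
#' provenance) plus one CSV per age-indexed table.  [load_parameter_set()]
#' restores it field-by-field.
#'
#' @param params An `osteo_params` object.
#' @param dir Target directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_parameter_set <- function(params, dir) {
  validate_parameter_set(params)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
  wr(params$baseline_risks, "baseline_risks")
  wr(params$male_female_ratios, "male_female_ratios")
  wr(params$giop_rr, "giop_rr")
  wr(params$mean_tscore, "mean_tscore")
  wr(params$costs$fracture_costs, "fracture_costs")
  wr(params$mortality$life_table, "life_table")
  wr(params$mortality$fx_attrib, "fx_attrib")
  wr(params$mortality$fx_mortality, "fx_mortality")
  wr(params$utility$base, "base_utilities")

  um <- params$utility$multipliers
  scal <- list(
    schema_version = params$schema_version,
    discount_rate_costs = params$discount_rate_costs,
    discount_rate_effects = params$discount_rate_effects,
    sek_per_eur = params$sek_per_eur,
    cycle_length_months = params$cycle_length_months,
    days_per_cycle = params$days_per_cycle,
    treatment_duration_months = params$treatment_duration_months,
    history_window_years = params$history_window_years,
    second_fracture_increase = as.list(params$second_fracture_increase),
    age_cap = params$age_cap,
    risk_composition = params$risk_composition,
    bmd_gradient = as.list(params$bmd_gradient),
    fracture_after_fracture_rr = as.list(params$fracture_after_fracture_rr),
    efficacy = params$efficacy[c("teriparatide", "bisphosphonate")],
    drug_daily_cost = as.list(params$costs$drug_daily_cost),
    visit_cost = params$costs$visit_cost,
    bmd_visit_cost = params$costs$bmd_visit_cost,
    excess_multipliers = params$mortality$excess_multipliers,
    utility_multipliers = stats::setNames(
      lapply(seq_len(nrow(um)), function(i)
        list(first_year = um$first_year[i], subsequent = um$subsequent[i])),
      um$ftype),
    repeat_q = params$utility$repeat_q,
    repeat_rule = params$utility$repeat_rule,
    discontinuation = params$discontinuation[c("teriparatide", "bisphosphonate")],
    provenance = as.list(params$provenance)
  )
  yaml::write_yaml(scal, file.path(dir, "params.yaml"), precision = 15L)
  invisible(dir)
}

#' Load a parameter set from a directory
#'
#' Reads the structured config written by [write_parameter_set()] (or edited
#' by hand), reassembles the `osteo_params` object, and runs the full
#' validation pass.  A missing table file raises an error naming the table.
#'
#' @param dir Directory containing `params.yaml` and the table CSVs.
#' @return A validated `osteo_params` object.
#' @export
load_parameter_set <- function(dir) {
  if (!dir.exists(dir)) stop("parameter directory not found: ", dir)
  yml_path <- file.path(dir, "params.yaml")
  if (!file.exists(yml_path)) stop("missing config file: params.yaml")
  y <- yaml::read_yaml(yml_path)
  rd <- function(name) {
    p <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(p)) stop("missing table: ", name)
    utils::read.csv(p, stringsAsFactors = FALSE)
  }
  umy <- y$utility_multipliers
  um <- data.frame(
    ftype = names(umy),
    first_year = vapply(umy, function(x) x$first_year, numeric(1)),
    subsequent = vapply(umy, function(x) x$subsequent, numeric(1))
  )
  rownames(um) <- NULL
  params <- structure(list(
    schema_version = y$schema_version,
    discount_rate_costs = y$discount_rate_costs,
    discount_rate_effects = y$discount_rate_effects,
    sek_per_eur = y$sek_per_eur,
    cycle_length_months = y$cycle_length_months,
    days_per_cycle = y$days_per_cycle,
    treatment_duration_months = y$treatment_duration_months,
    history_window_years = y$history_window_years,
    second_fracture_increase = unlist(y$second_fracture_increase),
    age_cap = y$age_cap,
    risk_composition = y$risk_composition,
    baseline_risks = rd("baseline_risks"),
    male_female_ratios = rd("male_female_ratios"),
    bmd_gradient = unlist(y$bmd_gradient),
    mean_tscore = rd("mean_tscore"),
    giop_rr = rd("giop_rr"),
    fracture_after_fracture_rr = unlist(y$fracture_after_fracture_rr),
    efficacy = c(y$efficacy, list(none = NULL)),
    costs = list(
      fracture_costs = rd("fracture_costs"),
      drug_daily_cost = unlist(y$drug_daily_cost),
      visit_cost = y$visit_cost,
      bmd_visit_cost = y$bmd_visit_cost
    ),
    mortality = list(
      life_table = rd("life_table"),
      fx_attrib = rd("fx_attrib"),
      fx_mortality = rd("fx_mortality"),
      excess_multipliers = lapply(y$excess_multipliers, unlist)
    ),
    utility = list(
      base = rd("base_utilities"),
      multipliers = um,
      repeat_q = y$repeat_q,
      repeat_rule = y$repeat_rule
    ),
    discontinuation = c(lapply(y$discontinuation, unlist),
                        list(none = numeric(0))),
    provenance = unlist(y$provenance)
  ), class = "osteo_params")
  validate_parameter_set(params)
  params
}

#' @export
print.osteo_params <- function(x, ...) {
  cat("<osteo_params> schema v", x$schema_version, "\n", sep = "")
  cat("  cycle: ", x$cycle_length_months, " months; treatment: ",
      x$treatment_duration_months, " months; discounting: ",
      100 * x$discount_rate_costs, "%/yr\n", sep = "")
  cat("  drug daily cost (EUR): ",
      paste(sprintf("%s=%.2f", names(x$costs$drug_daily_cost),
                    x$costs$drug_daily_cost), collapse = ", "), "\n", sep = "")
  ph <- placeholder_tables(x)
  if (length(ph))
    cat("  placeholder tables: ", paste(ph, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Dotted-path access, used by the sensitivity analyses
# ---------------------------------------------------------------------------

#' Read a parameter by dotted path
#'
#' @param params An `osteo_params` object.
#' @param path Dotted path, e.g. `"efficacy.teriparatide.vertebral.on_treatment_rr"`.
#' @return The value at that path.
#' @export
get_param <- function(params, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  x <- params
  for (k in keys) {
    if (!(k %in% names(x))) stop("unresolvable parameter path: ", path)
    x <- x[[k]]
  }
  x
}

#' Replace a parameter by dotted path
#'
#' @inheritParams get_param
#' @param value Replacement value (any shape: scalar, vector, profile list).
#' @return The modified parameter set.
#' @export
set_param <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  rec <- function(x, keys) {
    if (!(keys[1] %in% names(x)))
      stop("unresolvable parameter path: ", path)
    if (length(keys) == 1L) x[[keys]] <- value
    else x[[keys[1]]] <- rec(x[[keys[1]]], keys[-1])
    x
  }
  rec(params, keys)
}
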