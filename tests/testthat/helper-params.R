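# Simplified, age-invariant parameter bundles for hand-verifiable oracles.
# All tables are flat in age so per-cycle quantities can be recomputed with
# plain arithmetic in the tests.
flat_params <- function(risks = c(hip = 0.1, vertebral = 0.1, wrist = 0.1),
                        ratios = 1,
                        giop = c(hip = 1, vertebral = 1, wrist = 1),
                        gradient = c(hip = 1, vertebral = 1, wrist = 1),
                        faf = c(hip = 2, vertebral = 2, wrist = 2),
                        q6 = 0.1, pfx = 0, m6 = 0.02,
                        excess_hip = c(3, 2, 1),
                        excess_vert = c(2.5, 1.75, 1),
                        base_utility = 0.8,
                        um_first = c(hip = 0.7, vertebral = 0.626, wrist = 0.94),
                        um_sub = c(hip = 0.9, vertebral = 0.909, wrist = 1),
                        acute = c(hip = 1000, vertebral = 500, wrist = 200),
                        continuing = c(hip = 100, vertebral = 50, wrist = 0),
                        daily = c(teriparatide = 10, bisphosphonate = 1, none = 0),
                        visit = 100, bmd_visit = 150,
                        days_per_cycle = 100,
                        disc_teri = c(1, 1, 1), disc_bis = c(1, 1, 1),
                        discount = 0.03) {
  p <- default_parameter_set()
  ft <- fracture_types()
  ages <- c(50, 100)
  flat_tab <- function(vals, col) {
    do.call(rbind, lapply(ft, function(t) {
      df <- data.frame(ftype = t, age = ages)
      df[[col]] <- vals[[t]]
      df
    }))
  }
  p$baseline_risks <- do.call(rbind, lapply(ft, function(t)
    data.frame(gender = "female", ftype = t, age = ages, risk = risks[[t]])))
  p$male_female_ratios <- flat_tab(setNames(rep(ratios, 3), ft), "ratio")
  p$giop_rr <- flat_tab(giop, "rr")
  p$bmd_gradient <- gradient
  p$mean_tscore <- data.frame(age = ages, tscore = 0)
  p$fracture_after_fracture_rr <- faf
  p$costs$fracture_costs <- do.call(rbind, lapply(ft, function(t)
    data.frame(ftype = t, age = ages, acute = acute[[t]],
               continuing = continuing[[t]])))
  p$costs$drug_daily_cost <- daily
  p$costs$visit_cost <- visit
  p$costs$bmd_visit_cost <- bmd_visit
  p$days_per_cycle <- days_per_cycle
  p$mortality$life_table <- do.call(rbind, lapply(c("female", "male"),
    function(g) data.frame(gender = g, age = ages, q6 = q6)))
  p$mortality$fx_attrib <- do.call(rbind, lapply(c("female", "male"),
    function(g) data.frame(gender = g, age = ages, p = pfx)))
  p$mortality$fx_mortality <- do.call(rbind, lapply(c("female", "male"),
    function(g) data.frame(gender = g, age = ages, m6 = m6)))
  p$mortality$excess_multipliers <- list(hip = excess_hip,
                                         vertebral = excess_vert)
  p$utility$base <- data.frame(age = ages, utility = base_utility)
  p$utility$multipliers <- data.frame(ftype = ft, first_year = unname(um_first[ft]),
                                      subsequent = unname(um_sub[ft]))
  p$discontinuation$teriparatide <- disc_teri
  p$discontinuation$bisphosphonate <- disc_bis
  p$discount_rate_costs <- discount
  p$discount_rate_effects <- discount
  validate_parameter_set(p)
  p
}

# a cohort with no prevalent fractures
bare_cohort <- function(disease = "PMO", start_age = 69, t_score = 0,
                        female_fraction = 1) {
  cohort_spec(disease, start_age, t_score,
              history = data.frame(type = character(0),
                                   months_before_start = numeric(0)),
              female_fraction = female_fraction)
}

# scripted uniform streams for simulate_patient (one value per cycle)
scripted_draws <- function(n_cycles, excess = 0.99, hip = 0.99,
                           vertebral = 0.99, wrist = 0.99, natural = 0.99,
                           disc = 0.99) {
  fill <- function(x) if (length(x) == 1) rep(x, n_cycles) else x
  list(excess = fill(excess), hip = fill(hip), vertebral = fill(vertebral),
       wrist = fill(wrist), natural = fill(natural), disc = fill(disc))
}

# parameter set in which treatment has no effect and no cost, so all arms
# must coincide under common random numbers
neutralized_params <- function(p = default_parameter_set()) {
  for (arm in c("teriparatide", "bisphosphonate"))
    for (t in fracture_types()) {
      p$efficacy[[arm]][[t]]$on_treatment_rr <- 1
      p$efficacy[[arm]][[t]]$sustained_rr <- 1
    }
  p$costs$drug_daily_cost[] <- 0
  p$costs$visit_cost <- 0
  p$costs$bmd_visit_cost <- 0
  p
}

# degenerate PSA configuration: every sampling support collapses to the
# baseline value
degenerate_psa_config <- function(params) {
  um <- params$utility$multipliers
  c(
    lapply(fracture_types(), function(t)
      list(kind = "cost_scale", ftype = t, min = 1, max = 1,
           dist = "lognormal")),
    unlist(lapply(fracture_types(), function(t) {
      i <- match(t, um$ftype)
      list(
        list(kind = "utility_multiplier", ftype = t, which = "first_year",
             min = um$first_year[i], max = um$first_year[i], dist = "beta"),
        list(kind = "utility_multiplier", ftype = t, which = "subsequent",
             min = um$subsequent[i], max = um$subsequent[i], dist = "beta")
      )
    }), recursive = FALSE),
    lapply(c("teriparatide", "bisphosphonate"), function(a) {
      rr <- params$efficacy[[a]]$vertebral$on_treatment_rr
      list(kind = "efficacy_rr", arm = a, ftypes = "vertebral",
           min = rr, max = rr, dist = "beta")
    })
  )
}
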