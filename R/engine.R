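#' Define a patient cohort
#'
#' @param disease `"PMO"` or `"GIOP"`.
#' @param start_age Starting age in years (>= 50).
#' @param t_score Measured BMD T-score (SD, <= 0).
#' @param history Data frame with columns `type` (fracture type) and
#'   `months_before_start` (>= 0) describing prevalent fractures.
#' @param female_fraction Proportion of women; defaults to 1.0 for PMO and
#'   0.80 for GIOP.
#' @param arms Treatment strategies to simulate.
#' @param label Optional cohort label.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(disease = c("PMO", "GIOP"), start_age = 69,
                        t_score = -3.0,
                        history = data.frame(type = character(0),
                                             months_before_start = numeric(0)),
                        female_fraction = NULL,
                        arms = treatment_arms(), label = NULL) {
  disease <- match.arg(disease)
  if (is.null(female_fraction))
    female_fraction <- if (disease == "GIOP") 0.80 else 1.00
  stopifnot(start_age >= 50, t_score <= 0,
            female_fraction >= 0, female_fraction <= 1,
            all(arms %in% treatment_arms()),
            all(history$type %in% fracture_types()),
            all(history$months_before_start >= 0))
  structure(list(disease = disease, start_age = start_age, t_score = t_score,
                 history = history, female_fraction = female_fraction,
                 arms = arms,
                 label = label %||% tolower(disease)),
            class = "cohort_spec")
}

#' The four base-case cohorts
#'
#' Severe PMO (T-score -3.0, 100% female) and GIOP (T-score -2.5, 80%
#' female) patients starting treatment at age 69, each with either an
#' incident clinical vertebral fracture 6 months before baseline alone
#' (`*_1fx`), or additionally a historical vertebral fracture 5 years
#' before baseline (`*_2fx`).
#'
#' @return Named list of four [cohort_spec()] objects.
#' @export
default_cohorts <- function() {
  inc <- data.frame(type = "vertebral", months_before_start = 6)
  two <- data.frame(type = c("vertebral", "vertebral"),
                    months_before_start = c(60, 6))
  list(
    pmo_2fx = cohort_spec("PMO", 69, -3.0, two, label = "pmo_2fx"),
    pmo_1fx = cohort_spec("PMO", 69, -3.0, inc, label = "pmo_1fx"),
    giop_2fx = cohort_spec("GIOP", 69, -2.5, two, label = "giop_2fx"),
    giop_1fx = cohort_spec("GIOP", 69, -2.5, inc, label = "giop_1fx")
  )
}

#' Generate the uniform draw streams for one replication
#'
#' Six independent uniform matrices (patients x cycles) feed, in fixed
#' order, the excess-mortality, hip/vertebral/wrist fracture, natural-
#' mortality and discontinuation draws.  Sharing one draw set across
#' treatment arms implements common random numbers: arms differ only
#' through treatment-dependent quantities.
#'
#' @param n_patients Number of patients.
#' @param n_cycles Number of six-month cycles.
#' @return Named list of six `n_patients x n_cycles` matrices.
#' @export
make_draws <- function(n_patients, n_cycles) {
  one <- function() matrix(stats::runif(n_patients * n_cycles),
                           n_patients, n_cycles)
  list(excess = one(), hip = one(), vertebral = one(), wrist = one(),
       natural = one(), disc = one())
}

# precompute per-cycle, per-gender scalars shared by all patients of a
# cohort (ages advance deterministically by 0.5 years per cycle; lookups
# use age at cycle start)
.engine_tables <- function(spec, params, n_cycles) {
  ages <- spec$start_age + 0.5 * (0:(n_cycles - 1))
  ft <- fracture_types()
  genders <- c("female", "male")
  p_annual <- array(0, c(2, 3, n_cycles))
  for (ti in 1:3) {
    pf <- interpolate_baseline_risk(ages, "female", ft[ti], params$baseline_risks)
    sub <- params$male_female_ratios[params$male_female_ratios$ftype == ft[ti], ]
    p_annual[1, ti, ] <- pf
    p_annual[2, ti, ] <- male_risk_from_female(pf, .interp(ages, sub$age, sub$ratio))
  }
  bmd <- matrix(0, 3, n_cycles)
  giop <- matrix(1, 3, n_cycles)
  tmean <- .mean_tscore_at(ages, params)
  for (ti in 1:3) {
    bmd[ti, ] <- bmd_multiplier(spec$t_score, tmean, params$bmd_gradient[[ft[ti]]])
    if (spec$disease == "GIOP")
      giop[ti, ] <- .giop_multiplier_at(ages, ft[ti], params)
  }
  qnat <- m6 <- matrix(0, 2, n_cycles)
  for (gi in 1:2) {
    qnat[gi, ] <- natural_death_probability(ages, genders[gi], params$mortality)
    fm <- params$mortality$fx_mortality[
      params$mortality$fx_mortality$gender == genders[gi], ]
    m6[gi, ] <- .interp(ages, fm$age, fm$m6)
  }
  acute <- contc <- matrix(0, 3, n_cycles)
  for (ti in 1:3) {
    acute[ti, ] <- .fracture_cost_at(ft[ti], ages, "acute", params$costs$fracture_costs)
    contc[ti, ] <- .fracture_cost_at(ft[ti], ages, "continuing", params$costs$fracture_costs)
  }
  list(ages = ages, p_annual = p_annual,
       p6 = .annual_to_cycle_prob(p_annual),
       h6 = -log(1 - p_annual) / 2,
       bmd = bmd, giop = giop, qnat = qnat, m6 = m6,
       acute = acute, contc = contc,
       baseu = .base_utility_at(ages, params),
       dfc = discount_factor(0:(n_cycles - 1), params$discount_rate_costs),
       dfe = discount_factor(0:(n_cycles - 1), params$discount_rate_effects))
}

# initial last/prev event-cycle matrices from the cohort's prevalent
# fracture history (cycle -k = k cycles before baseline)
.init_history <- function(spec, n_patients) {
  last <- prev <- matrix(-Inf, n_patients, 3)
  if (nrow(spec$history)) {
    h <- spec$history
    cyc <- -h$months_before_start / 6
    o <- order(cyc)
    for (i in o) {
      ti <- match(h$type[i], fracture_types())
      prev[, ti] <- last[, ti]
      last[, ti] <- cyc[i]
    }
  }
  list(last = last, prev = prev)
}

#' Simulate one treatment arm for a cohort of patients
#'
#' Cycle-synchronous patient-level simulation.  Within each six-month
#' cycle, in order: fracture-related excess-mortality draw (deaths at cycle
#' start accrue nothing); fracture draws per type; natural-mortality draw
#' (deaths at mid-cycle accrue half); cost and utility accrual with
#' discounting; treatment completion/discontinuation update at the cycle
#' boundary.  The loop ends at death or the age cap.
#'
#' @param spec A [cohort_spec()].
#' @param arm One of [treatment_arms()].
#' @param params An `osteo_params` object.
#' @param draws Draw streams from [make_draws()]; sharing them across arms
#'   gives common random numbers.
#' @param gender_idx Integer vector (1 = female, 2 = male) per patient.
#' @param keep_ledger Record per-cycle component matrices (for audit and
#'   small-n verification).
#' @param tables Precomputed engine tables (internal reuse).
#' @return List with per-patient discounted `cost`, discounted `qaly`,
#'   undiscounted `life_years`, a `counts` matrix of fractures by type, and
#'   optionally `ledger` matrices.
#' @export
simulate_arm <- function(spec, arm, params, draws, gender_idx,
                         keep_ledger = FALSE, tables = NULL) {
  n <- nrow(draws$excess)
  C <- ncol(draws$excess)
  if (is.null(tables)) tables <- .engine_tables(spec, params, C)
  ft <- fracture_types()
  rate_comp <- identical(params$risk_composition, "rate")
  window_cycles <- 2 * params$history_window_years
  s_inc <- params$second_fracture_increase[[spec$disease]]
  faf <- params$fracture_after_fracture_rr[ft]
  sched <- params$mortality$excess_multipliers
  dur_cycles <- ceiling(params$treatment_duration_months / params$cycle_length_months)
  curve <- params$discontinuation[[arm]]
  profile <- params$efficacy[[arm]]
  um <- params$utility$multipliers
  m_first <- um$first_year[match(ft, um$ftype)]
  m_sub <- um$subsequent[match(ft, um$ftype)]
  m_rep <- .repeat_first_year_multiplier(m_first, m_sub, params$utility$repeat_q,
                                         params$utility$repeat_rule)
  daily <- params$costs$drug_daily_cost[[arm]] * params$days_per_cycle
  vis <- params$costs$visit_cost
  bmdvis <- params$costs$bmd_visit_cost

  hist0 <- .init_history(spec, n)
  last <- hist0$last; prev <- hist0$prev
  cont <- matrix(0, n, 3)
  for (ti in 1:2)  # prevalent hip/vertebral fractures keep accruing
    cont[is.finite(last[, ti]), ti] <- tables$contc[ti, 1]  # continuing care
  counts <- matrix(0L, n, 3, dimnames = list(NULL, ft))
  cost <- qaly <- ly <- numeric(n)
  alive <- rep(TRUE, n)
  on_tx <- rep(arm != "none", n)
  ctreat <- integer(n)
  cess <- rep(NA_real_, n)
  ledger <- if (keep_ledger) {
    zeros <- function() matrix(0, n, C)
    list(cost_drug = zeros(), cost_monitoring = zeros(),
         cost_fracture_acute = zeros(), cost_fracture_continuing = zeros(),
         utility = zeros(), accrual_fraction = zeros(), alive_at_start = matrix(FALSE, n, C))
  } else NULL

  for (ci in seq_len(C)) {
    if (!any(alive)) break
    c0 <- ci - 1L
    al <- which(alive)

    # (1) fracture-related excess mortality at cycle start
    mult <- pmax(
      .excess_schedule_value(sched$hip, (c0 - last[al, 1]) / 2),
      .excess_schedule_value(sched$vertebral, (c0 - last[al, 2]) / 2))
    p_ex <- pmin(1, tables$m6[cbind(gender_idx[al], ci)] * (mult - 1))
    dex <- draws$excess[al, ci] < p_ex
    alive[al[dex]] <- FALSE
    amid <- al[!dex]
    if (keep_ledger) ledger$alive_at_start[al, ci] <- TRUE
    if (!length(amid)) next
    m <- length(amid)

    # history relative-risk multiplier (largest across types; second
    # in-window same-type fracture escalates by 50%/100%)
    histm <- rep(1, m)
    for (ti in 1:3) {
      dl <- c0 - last[amid, ti]
      dp <- c0 - prev[amid, ti]
      inl <- is.finite(dl) & dl >= 0 & dl <= window_cycles
      inp <- is.finite(dp) & dp >= 0 & dp <= window_cycles
      mt <- ifelse(inl & inp, 1 + (1 + s_inc) * (faf[ti] - 1),
                   ifelse(inl, faf[ti], 1))
      histm <- pmax(histm, mt)
    }

    # treatment relative risk per type
    rr <- matrix(1, m, 3)
    if (arm != "none") {
      on <- on_tx[amid]
      off <- !on & !is.na(cess[amid])
      t_off <- 6 * (c0 - cess[amid][off])
      for (ti in 1:3) {
        rr[on, ti] <- profile[[ft[ti]]]$on_treatment_rr
        if (any(off)) rr[off, ti] <- .offset_rr(t_off, profile[[ft[ti]]])
      }
    }

    # (2) fracture draws
    new_ev <- matrix(FALSE, m, 3)
    acute_c <- numeric(m)
    for (ti in 1:3) {
      mults <- tables$bmd[ti, ci] * tables$giop[ti, ci] * histm * rr[, ti]
      p <- if (rate_comp)
        1 - exp(-tables$h6[cbind(gender_idx[amid], rep(ti, m), rep(ci, m))] * mults)
      else
        pmin(1, tables$p6[cbind(gender_idx[amid], rep(ti, m), rep(ci, m))] * mults)
      ev <- draws[[ft[ti]]][amid, ci] < p
      new_ev[, ti] <- ev
      idx <- amid[ev]
      if (length(idx)) {
        prev[idx, ti] <- last[idx, ti]
        last[idx, ti] <- c0
        counts[idx, ti] <- counts[idx, ti] + 1L
        acute_c[ev] <- acute_c[ev] + tables$acute[ti, ci]
        if (ti != 3)
          cont[idx, ti] <- pmax(cont[idx, ti], tables$contc[ti, ci])
      }
    }
    cont_owed <- rowSums(cont[amid, , drop = FALSE] * !new_ev)

    # (3) natural mortality at mid-cycle
    dnat <- draws$natural[amid, ci] < tables$qnat[cbind(gender_idx[amid], ci)]
    af <- ifelse(dnat, 0.5, 1)

    # utility: product of per-type multipliers over the base utility
    umult <- rep(1, m)
    for (ti in 1:3) {
      lt <- last[amid, ti]
      has <- is.finite(lt)
      fy <- has & (c0 - lt) <= 1
      repf <- fy & is.finite(prev[amid, ti])
      mt <- rep(1, m)
      mt[has & !fy] <- m_sub[ti]
      mt[fy & !repf] <- m_first[ti]
      mt[repf] <- m_rep[ti]
      umult <- umult * mt
    }
    u <- tables$baseu[ci] * umult

    # (5) accrual: acute fracture costs in full (fracture precedes death in
    # the event order); everything else scaled by the accrual fraction
    on <- on_tx[amid]
    k <- ctreat[amid] + 1L
    drug <- ifelse(on, daily, 0)
    monit <- ifelse(on, ifelse(k %% 2 == 1L, bmdvis, vis), 0)
    cyc_cost <- af * (drug + monit + cont_owed) + acute_c
    cost[amid] <- cost[amid] + cyc_cost * tables$dfc[ci]
    qaly[amid] <- qaly[amid] + u * 0.5 * af * tables$dfe[ci]
    ly[amid] <- ly[amid] + 0.5 * af
    if (keep_ledger) {
      ledger$cost_drug[amid, ci] <- af * drug
      ledger$cost_monitoring[amid, ci] <- af * monit
      ledger$cost_fracture_acute[amid, ci] <- acute_c
      ledger$cost_fracture_continuing[amid, ci] <- af * cont_owed
      ledger$utility[amid, ci] <- u
      ledger$accrual_fraction[amid, ci] <- af
    }
    alive[amid[dnat]] <- FALSE

    # (4) treatment completion / discontinuation at the cycle boundary
    if (arm != "none") {
      surv <- amid[!dnat]
      o <- surv[on_tx[surv]]
      if (length(o)) {
        ctreat[o] <- ctreat[o] + 1L
        done <- o[ctreat[o] >= dur_cycles]
        on_tx[done] <- FALSE
        cess[done] <- c0 + 1
        rem <- setdiff(o, done)
        if (length(rem)) {
          k2 <- ctreat[rem]
          p_cont <- curve[k2 + 1L] / curve[k2]
          stopd <- rem[draws$disc[rem, ci] >= p_cont]
          on_tx[stopd] <- FALSE
          cess[stopd] <- c0 + 1
        }
      }
    }
  }

  list(cost = cost, qaly = qaly, life_years = ly, counts = counts,
       ledger = ledger)
}

#' Simulate a single patient against a scripted draw stream
#'
#' Convenience wrapper around [simulate_arm()] for one patient, returning a
#' per-cycle ledger for audit or hand verification.  Supplying the uniform
#' draws makes the trajectory fully scripted.
#'
#' @inheritParams simulate_arm
#' @param draws List of six numeric vectors (or 1-row matrices), one value
#'   per cycle, as in [make_draws()].
#' @param gender `"female"` or `"male"`.
#' @return List with `ledger` (data frame, one row per cycle survived into),
#'   `fracture_counts`, and the scalar totals `cost`, `qaly`, `life_years`.
#' @export
simulate_patient <- function(spec, arm, params, draws, gender = "female") {
  draws <- lapply(draws, function(d) matrix(d, nrow = 1))
  res <- simulate_arm(spec, arm, params, draws, match(gender, c("female", "male")),
                      keep_ledger = TRUE)
  C <- ncol(draws[[1]])
  lg <- res$ledger
  keep <- which(lg$alive_at_start[1, ])
  ledger <- data.frame(
    cycle = keep - 1L,
    cost_drug = lg$cost_drug[1, keep],
    cost_monitoring = lg$cost_monitoring[1, keep],
    cost_fracture_acute = lg$cost_fracture_acute[1, keep],
    cost_fracture_continuing = lg$cost_fracture_continuing[1, keep],
    utility = lg$utility[1, keep],
    accrual_fraction = lg$accrual_fraction[1, keep]
  )
  ledger$life_years <- 0.5 * ledger$accrual_fraction
  list(ledger = ledger, fracture_counts = res$counts[1, ],
       cost = res$cost, qaly = res$qaly, life_years = res$life_years)
}

#' Run a cohort through all arms with replications
#'
#' Simulates `n_replications` independent replications of `n_patients`
#' patients.  Within a replication every arm reuses the same gender
#' assignment and uniform draw streams (common random numbers), so arms
#' differ only through treatment-dependent quantities.  Results are
#' deterministic for a fixed seed.
#'
#' @param spec A [cohort_spec()].
#' @param params An `osteo_params` object.
#' @param n_patients Patients per replication.
#' @param n_replications Number of replications.
#' @param seed Integer seed.
#' @param arms Arms to simulate (default: the cohort's arms).
#' @param gender_assignment `"bernoulli"` draws each patient's gender from
#'   the cohort's female fraction; `"stratified"` fixes the split exactly.
#' @return An object of class `osteo_result`: per-arm summary table,
#'   replication-level means for CI construction, and run metadata
#'   including the names of any placeholder tables in the bundle.
#' @export
run_cohort <- function(spec, params, n_patients = 1000, n_replications = 1,
                       seed = 1L, arms = spec$arms,
                       gender_assignment = c("bernoulli", "stratified")) {
  stopifnot(n_patients >= 1, n_replications >= 1)
  gender_assignment <- match.arg(gender_assignment)
  validate_parameter_set(params)
  C <- max(1L, ceiling((params$age_cap - spec$start_age) * 2))
  tables <- .engine_tables(spec, params, C)
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replications)

  rep_rows <- vector("list", n_replications * length(arms))
  ri <- 0L
  for (r in seq_len(n_replications)) {
    set.seed(rep_seeds[r])
    if (gender_assignment == "bernoulli") {
      gender_idx <- ifelse(stats::runif(n_patients) < spec$female_fraction, 1L, 2L)
    } else {
      nf <- round(n_patients * spec$female_fraction)
      gender_idx <- c(rep(1L, nf), rep(2L, n_patients - nf))
    }
    draws <- make_draws(n_patients, C)
    for (arm in arms) {
      res <- simulate_arm(spec, arm, params, draws, gender_idx, tables = tables)
      ri <- ri + 1L
      rep_rows[[ri]] <- data.frame(
        replication = r, arm = arm,
        cost = mean(res$cost), qaly = mean(res$qaly),
        life_years = mean(res$life_years),
        fx_hip = mean(res$counts[, "hip"]),
        fx_vertebral = mean(res$counts[, "vertebral"]),
        fx_wrist = mean(res$counts[, "wrist"])
      )
    }
  }
  rep_means <- do.call(rbind, rep_rows)

  ciw <- function(x) if (length(x) > 1)
    stats::qnorm(0.975) * stats::sd(x) / sqrt(length(x)) else NA_real_
  agg <- lapply(split(rep_means, rep_means$arm), function(d) {
    data.frame(arm = d$arm[1], n_patients = n_patients,
               cost = mean(d$cost), qaly = mean(d$qaly),
               life_years = mean(d$life_years),
               fx_hip = mean(d$fx_hip), fx_vertebral = mean(d$fx_vertebral),
               fx_wrist = mean(d$fx_wrist),
               cost_ci = ciw(d$cost), qaly_ci = ciw(d$qaly))
  })
  summary <- do.call(rbind, agg[arms])
  rownames(summary) <- NULL

  structure(list(cohort = spec, arms = arms, summary = summary,
                 rep_means = rep_means, n_patients = n_patients,
                 n_replications = n_replications, seed = seed,
                 placeholder_tables = placeholder_tables(params)),
            class = "osteo_result")
}

#' @export
print.osteo_result <- function(x, ...) {
  cat("<osteo_result> cohort ", x$cohort$label, ": ",
      x$n_replications, " x ", x$n_patients, " patients (seed ", x$seed,
      ")\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 5)
  if (length(x$placeholder_tables))
    cat("note: bundle contains placeholder tables (",
        paste(x$placeholder_tables, collapse = ", "), ")\n", sep = "")
  invisible(x)
}
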