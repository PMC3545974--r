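#' Classify a point on the cost-effectiveness plane
#'
#' @param delta_cost Incremental cost (intervention minus comparator).
#' @param delta_qaly Incremental QALYs.
#' @return One of `"icer"` (north-east: more costly, more effective),
#'   `"dominant"` (cheaper and more effective), `"dominated"` (more costly,
#'   less effective), `"sw"` (cheaper and less effective; the ratio is
#'   reported but flagged), or `"undefined"` (zero QALY difference).
#' @export
classify_ce <- function(delta_cost, delta_qaly) {
  if (delta_qaly == 0) return("undefined")
  if (delta_qaly > 0 && delta_cost <= 0) return("dominant")
  if (delta_qaly < 0 && delta_cost >= 0) return("dominated")
  if (delta_qaly > 0) "icer" else "sw"
}

#' Incremental cost-effectiveness of one arm against another
#'
#' Computes incremental discounted cost, QALYs and undiscounted life years
#' from an [run_cohort()] result, with the ICER or a dominance label, and
#' 95% confidence intervals built from the paired replication-level means.
#'
#' @param result An `osteo_result`.
#' @param intervention Arm evaluated (default `"teriparatide"`).
#' @param comparator Reference arm.
#' @return A list of class `ce_result` with `delta_cost`, `delta_qaly`,
#'   `delta_life_years`, `icer`, `label`, and CI bounds where replications
#'   permit.
#' @export
icer <- function(result, intervention = "teriparatide", comparator = "none") {
  stopifnot(inherits(result, "osteo_result"),
            all(c(intervention, comparator) %in% result$arms))
  s <- result$summary
  si <- s[s$arm == intervention, ]
  sc <- s[s$arm == comparator, ]
  dc <- si$cost - sc$cost
  dq <- si$qaly - sc$qaly
  dly <- si$life_years - sc$life_years
  label <- classify_ce(dc, dq)
  ratio <- if (label %in% c("icer", "sw")) dc / dq else NA_real_

  rm <- result$rep_means
  ic <- rm[rm$arm == intervention, ]
  cc <- rm[rm$arm == comparator, ]
  ic <- ic[order(ic$replication), ]; cc <- cc[order(cc$replication), ]
  dci <- ic$cost - cc$cost
  dqi <- ic$qaly - cc$qaly
  ciq <- function(x) if (length(x) > 1)
    stats::quantile(x, c(0.025, 0.975), names = FALSE) else c(NA_real_, NA_real_)
  icer_ci <- if (length(dci) > 1 && all(dqi > 0)) ciq(dci / dqi)
             else c(NA_real_, NA_real_)

  structure(list(intervention = intervention, comparator = comparator,
                 delta_cost = dc, delta_qaly = dq, delta_life_years = dly,
                 icer = ratio, label = label,
                 delta_cost_ci = ciq(dci), delta_qaly_ci = ciq(dqi),
                 icer_ci = icer_ci),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(x$intervention, "vs.", x$comparator, "\n")
  cat(sprintf("  delta cost: %0.0f EUR; delta QALY: %0.4f; delta LY: %0.4f\n",
              x$delta_cost, x$delta_qaly, x$delta_life_years))
  if (x$label == "icer")
    cat(sprintf("  ICER: %0.0f EUR/QALY", x$icer))
  else cat("  ", x$label, sep = "")
  if (!any(is.na(x$icer_ci)))
    cat(sprintf("  (95%% CI %0.0f - %0.0f)", x$icer_ci[1], x$icer_ci[2]))
  cat("\n")
  invisible(x)
}

#' Fractures avoided per 1,000 patients
#'
#' Difference in mean fracture counts per patient between the comparator
#' and the intervention, per fracture type, scaled to 1,000 patients.
#'
#' @inheritParams icer
#' @param round Round to whole fractures (reporting precision).
#' @return Named numeric vector over [fracture_types()] plus `total`.
#' @export
fractures_avoided_per_1000 <- function(result, intervention = "teriparatide",
                                       comparator = "none", round = TRUE) {
  s <- result$summary
  si <- s[s$arm == intervention, ]
  sc <- s[s$arm == comparator, ]
  cols <- paste0("fx_", fracture_types())
  av <- 1000 * (unlist(sc[cols]) - unlist(si[cols]))
  names(av) <- fracture_types()
  av <- c(av, total = sum(av))
  if (round) round(av) else av
}

#' One-way sensitivity analysis (tornado table)
#'
#' Reruns a paired comparison with one parameter at a time set to its low
#' and high value (same seeds throughout, so differences are attributable
#' to the parameter), and reports the ICER at both ends, sorted by the
#' width of the ICER range.
#'
#' @param spec A [cohort_spec()].
#' @param params Base `osteo_params`.
#' @param variations List of variations, each a list with `path` (dotted
#'   parameter path, see [set_param()]), `low` and `high` values, and an
#'   optional `name`.
#' @param intervention,comparator Arms compared.
#' @param n_patients,n_replications,seed Simulation scale.
#' @return Data frame with one row per variation: ICER at the low and high
#'   settings, labels, and range width; sorted widest first.
#' @export
one_way_sa <- function(spec, params, variations,
                       intervention = "teriparatide",
                       comparator = "bisphosphonate",
                       n_patients = 1000, n_replications = 1, seed = 1L) {
  if (!length(variations))
    return(data.frame(name = character(0), icer_low = numeric(0),
                      icer_high = numeric(0), label_low = character(0),
                      label_high = character(0), range = numeric(0)))
  run_icer <- function(p) {
    res <- run_cohort(spec, p, n_patients, n_replications, seed,
                      arms = c(intervention, comparator))
    ce <- icer(res, intervention, comparator)
    list(icer = ce$icer, label = ce$label)
  }
  rows <- lapply(variations, function(v) {
    lo <- run_icer(set_param(params, v$path, v$low))
    hi <- run_icer(set_param(params, v$path, v$high))
    data.frame(name = v$name %||% v$path,
               icer_low = lo$icer, icer_high = hi$icer,
               label_low = lo$label, label_high = hi$label,
               range = abs(hi$icer - lo$icer))
  })
  out <- do.call(rbind, rows)
  out[order(-out$range), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Probabilistic sensitivity analysis
# ---------------------------------------------------------------------------

#' Sample values from a PSA uncertainty distribution
#'
#' Fracture costs use a lognormal distribution with mean fixed at the
#' baseline and log-scale spread chosen so `exp(mu +/- 1.96 sigma)` spans
#' the support (50% to 200% of baseline by default), truncated to the
#' support by rejection.  Disutility and relative-risk parameters use a
#' beta distribution rescaled to `[min, max]` with mean at the baseline and
#' a concentration such that two standard deviations span the range.
#' A degenerate support (`min == max == baseline`) returns the baseline.
#'
#' @param n Number of draws.
#' @param dist `"lognormal"` or `"beta"`.
#' @param baseline Mean of the distribution; must lie in `[min, max]`.
#' @param min,max Support bounds.
#' @return Numeric vector of `n` draws within `[min, max]`.
#' @export
psa_sample_values <- function(n, dist = c("lognormal", "beta"), baseline,
                              min, max) {
  dist <- match.arg(dist)
  if (baseline < min || baseline > max)
    stop("baseline outside sampling support")
  if (min == max) return(rep(baseline, n))
  if (dist == "lognormal") {
    sigma <- log(max / min) / (2 * stats::qnorm(0.975))
    mu <- log(baseline) - sigma^2 / 2
    out <- numeric(0)
    while (length(out) < n) {
      x <- stats::rlnorm(n, mu, sigma)
      out <- c(out, x[x >= min & x <= max])
    }
    out[seq_len(n)]
  } else {
    m <- (baseline - min) / (max - min)
    if (m < 1e-3 || m > 1 - 1e-3) return(rep(baseline, n))
    s <- base::min(0.25, 0.9 * sqrt(m * (1 - m)))
    nu <- m * (1 - m) / s^2 - 1
    min + (max - min) * stats::rbeta(n, m * nu, (1 - m) * nu)
  }
}

#' Default PSA distribution configuration
#'
#' The critical parameters sampled per simulation: per-type fracture-cost
#' scale factors (lognormal, 50% to 200% of baseline), per-type fracture
#' utility multipliers (beta within stated multiplier ranges), and
#' on-treatment relative risks (beta within trial confidence intervals;
#' the pooled non-vertebral RR is sampled once and applied to hip and
#' wrist together).
#'
#' @param params An `osteo_params` (supplies the baselines).
#' @return List of sampling-entry specifications for [sample_psa_draw()].
#' @export
default_psa_config <- function(params) {
  um <- params$utility$multipliers
  mrow <- function(t) um[um$ftype == t, ]
  util_entry <- function(t, which, lo, hi)
    list(kind = "utility_multiplier", ftype = t, which = which,
         min = lo, max = hi, dist = "beta")
  eff_entry <- function(arm, fts, lo, hi)
    list(kind = "efficacy_rr", arm = arm, ftypes = fts,
         min = lo, max = hi, dist = "beta")
  c(
    lapply(fracture_types(), function(t)
      list(kind = "cost_scale", ftype = t, min = 0.5, max = 2.0,
           dist = "lognormal")),
    list(
      util_entry("hip", "first_year", 0.55, 0.90),
      util_entry("hip", "subsequent", 0.70, 0.95),
      util_entry("vertebral", "first_year", 0.45, 0.80),
      util_entry("vertebral", "subsequent", 0.80, 0.98),
      util_entry("wrist", "first_year", 0.85, 0.99),
      util_entry("wrist", "subsequent", 0.95, 1.00),
      eff_entry("teriparatide", "vertebral", 0.08, 0.36),
      eff_entry("teriparatide", c("hip", "wrist"), 0.25, 0.88),
      eff_entry("bisphosphonate", "vertebral", 0.40, 0.78),
      eff_entry("bisphosphonate", c("hip", "wrist"), 0.60, 0.96)
    )
  )
}

#' Draw one perturbed parameter set for the PSA
#'
#' Applies one sample from each entry of the distribution configuration to
#' a copy of the parameter set; all other parameters are untouched.  Uses
#' the current RNG state.
#'
#' @param params Base `osteo_params`.
#' @param dist_config From [default_psa_config()] or user-supplied.
#' @return The perturbed parameter set, with the sampled values attached as
#'   attribute `"psa_sampled"`.
#' @export
sample_psa_draw <- function(params, dist_config = default_psa_config(params)) {
  sampled <- numeric(0)
  for (e in dist_config) {
    if (e$kind == "cost_scale") {
      sc <- psa_sample_values(1, e$dist %||% "lognormal", 1, e$min, e$max)
      fc <- params$costs$fracture_costs
      sel <- fc$ftype == e$ftype
      fc$acute[sel] <- fc$acute[sel] * sc
      fc$continuing[sel] <- fc$continuing[sel] * sc
      params$costs$fracture_costs <- fc
      sampled[paste0("cost_scale.", e$ftype)] <- sc
    } else if (e$kind == "utility_multiplier") {
      um <- params$utility$multipliers
      i <- match(e$ftype, um$ftype)
      v <- psa_sample_values(1, e$dist %||% "beta", um[[e$which]][i],
                             e$min, e$max)
      um[[e$which]][i] <- v
      # keep first_year <= subsequent after independent draws
      if (um$first_year[i] > um$subsequent[i])
        um$first_year[i] <- um$subsequent[i]
      params$utility$multipliers <- um
      sampled[paste0("utility.", e$ftype, ".", e$which)] <- v
    } else if (e$kind == "efficacy_rr") {
      base <- params$efficacy[[e$arm]][[e$ftypes[1]]]$on_treatment_rr
      v <- psa_sample_values(1, e$dist %||% "beta", base, e$min, e$max)
      for (t in e$ftypes) {
        prof <- params$efficacy[[e$arm]][[t]]
        if (prof$sustained_months == 0) prof$sustained_rr <- v
        prof$on_treatment_rr <- v
        params$efficacy[[e$arm]][[t]] <- prof
      }
      sampled[paste0("rr.", e$arm, ".", paste(e$ftypes, collapse = "+"))] <- v
    } else stop("unknown PSA entry kind: ", e$kind)
  }
  attr(params, "psa_sampled") <- sampled
  params
}

#' Probabilistic sensitivity analysis
#'
#' Repeats the paired comparison with parameters sampled from their
#' uncertainty distributions: per simulation, one perturbed parameter set
#' and one paired cohort run under common random numbers.  Returns the
#' incremental cost/QALY cloud, cost-effectiveness-plane quadrant counts
#' and dominance tallies.
#'
#' @param spec A [cohort_spec()].
#' @param params Base `osteo_params`.
#' @param dist_config Sampling configuration, see [default_psa_config()].
#' @param n_sims Number of simulations (parameter draws).
#' @param n_patients Patients per simulation.
#' @param seed Integer seed.
#' @param intervention,comparator Arms compared.
#' @return An object of class `osteo_psa` with the per-draw data frame
#'   (`draws`, including the per-draw engine seed for exact reproduction)
#'   and `quadrant_counts`.
#' @export
run_psa <- function(spec, params, dist_config = default_psa_config(params),
                    n_sims = 1000, n_patients = 1000, seed = 1L,
                    intervention = "teriparatide",
                    comparator = "bisphosphonate") {
  stopifnot(n_sims >= 1, n_patients >= 1)
  set.seed(as.integer(seed))
  sim_seeds <- sample.int(.Machine$integer.max - 1L, n_sims)
  rows <- vector("list", n_sims)
  for (s in seq_len(n_sims)) {
    set.seed(sim_seeds[s])
    p_s <- sample_psa_draw(params, dist_config)
    run_seed <- sample.int(.Machine$integer.max - 1L, 1)
    res <- run_cohort(spec, p_s, n_patients, 1, run_seed,
                      arms = c(intervention, comparator))
    ce <- icer(res, intervention, comparator)
    rows[[s]] <- data.frame(sim = s, run_seed = run_seed,
                            delta_cost = ce$delta_cost,
                            delta_qaly = ce$delta_qaly,
                            icer = ce$icer, label = ce$label)
  }
  draws <- do.call(rbind, rows)
  qc <- c(ne = sum(draws$label == "icer"),
          dominant = sum(draws$label == "dominant"),
          dominated = sum(draws$label == "dominated"),
          sw = sum(draws$label == "sw"),
          undefined = sum(draws$label == "undefined"))
  structure(list(draws = draws, quadrant_counts = qc, n_sims = n_sims,
                 n_patients = n_patients, seed = seed,
                 intervention = intervention, comparator = comparator),
            class = "osteo_psa")
}

#' @export
print.osteo_psa <- function(x, ...) {
  cat("<osteo_psa> ", x$n_sims, " simulations of ", x$n_patients,
      " patients: ", x$intervention, " vs. ", x$comparator, "\n", sep = "")
  print(x$quadrant_counts)
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws that are
#' acceptable: draws with positive incremental QALYs and either cost
#' savings (dominant) or a cost-per-QALY below the threshold.  Draws with
#' zero or negative incremental QALYs are never acceptable, which makes the
#' curve monotone non-decreasing.  The `"nmb"` method instead counts draws
#' with positive net monetary benefit `wtp * dQALY - dCost`.
#'
#' @param psa An `osteo_psa` object (or its `draws` data frame).
#' @param wtp_grid Willingness-to-pay values (euro per QALY).
#' @param method `"share"` (primary) or `"nmb"`.
#' @return Data frame with columns `wtp` and `prob`.
#' @export
acceptability_curve <- function(psa, wtp_grid = seq(0, 100000, by = 5000),
                                method = c("share", "nmb")) {
  method <- match.arg(method)
  draws <- if (inherits(psa, "osteo_psa")) psa$draws else psa
  if (is.null(draws) || !nrow(draws)) stop("no PSA draws")
  dc <- draws$delta_cost
  dq <- draws$delta_qaly
  prob <- vapply(wtp_grid, function(w) {
    if (method == "nmb") mean(w * dq - dc > 0)
    else mean(dq > 0 & (dc <= 0 | dc / dq < w))
  }, numeric(1))
  data.frame(wtp = wtp_grid, prob = prob)
}
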