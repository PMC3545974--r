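.base_utility_at <- function(age, params)
  .interp(age, params$utility$base$age, params$utility$base$utility)

# first-year multiplier for a repeat same-type fracture.  The default
# ("multiplicative") reading scales the first-year multiplier by a fraction
# q of the residual subsequent disutility of the previous fracture:
# m_first * (1 - q * (1 - m_sub)).  The "additive" reading adds q of the
# previous subsequent disutility to the first-year disutility:
# m_first - q * (1 - m_sub).
.repeat_first_year_multiplier <- function(m_first, m_sub, q, rule) {
  if (identical(rule, "additive")) pmax(.Machine$double.eps, m_first - q * (1 - m_sub))
  else m_first * (1 - q * (1 - m_sub))
}

#' Health utility for one cycle
#'
#' Utility is the age-specific base utility times the product, over fracture
#' types, of that type's current multiplier.  A type contributes its
#' first-year multiplier in the event cycle and the following cycle, and its
#' subsequent multiplier thereafter.  A repeat fracture of the same type
#' additionally carries a proportion `q` (25% by default) of the disutility
#' attributable to the previous fracture's subsequent multiplier during its
#' first year.
#'
#' @param age Age in years.
#' @param gender `"female"` or `"male"` (base utilities are age-specific).
#' @param new_events Character vector of fracture types occurring this
#'   cycle.
#' @param history Data frame of earlier fracture events (`type`, `cycle`).
#' @param params An `osteo_params` object.
#' @param now Current cycle index (events in `new_events` occur at `now`).
#' @return Utility in (0, 1].
#' @export
cycle_utility <- function(age, gender, new_events, history, params, now = 0) {
  um <- params$utility$multipliers
  q <- params$utility$repeat_q
  rule <- params$utility$repeat_rule
  u <- .base_utility_at(age, params)
  for (t in fracture_types()) {
    cyc <- history$cycle[history$type == t & history$cycle <= now]
    if (t %in% new_events) cyc <- c(cyc, now)
    if (!length(cyc)) next
    i <- match(t, um$ftype)
    last <- max(cyc)
    first_year <- (now - last) <= 1
    m <- if (!first_year) um$subsequent[i]
    else if (length(cyc) >= 2)
      .repeat_first_year_multiplier(um$first_year[i], um$subsequent[i], q, rule)
    else um$first_year[i]
    u <- u * m
  }
  u
}

#' Accumulate discounted QALYs and undiscounted life years from a ledger
#'
#' Each cycle contributes `utility * 0.5 years * accrual_fraction`,
#' discounted at the effects rate; life years accumulate undiscounted as
#' `0.5 * accrual_fraction`.
#'
#' @param ledger Data frame with columns `cycle`, `utility`,
#'   `accrual_fraction` (ordered by cycle).
#' @param rate Annual discount rate for effects.
#' @return Named numeric vector `c(qaly =, life_years =)`.
#' @export
accumulate_qalys <- function(ledger, rate) {
  if (is.null(ledger) || !nrow(ledger)) return(c(qaly = 0, life_years = 0))
  df <- discount_factor(ledger$cycle, rate)
  c(qaly = sum(ledger$utility * 0.5 * ledger$accrual_fraction * df),
    life_years = sum(0.5 * ledger$accrual_fraction))
}
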