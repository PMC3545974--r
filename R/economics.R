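#' Per-cycle discount factor
#'
#' Discounting is applied per six-month cycle at the annual rate:
#' `(1 + rate)^(-0.5 * cycle_index)`, with cycle 0 the start of follow-up.
#'
#' @param cycle_index Cycle index (vectorised).
#' @param annual_rate Annual discount rate (>= 0).
#' @return Discount factor.
#' @export
discount_factor <- function(cycle_index, annual_rate) {
  if (any(annual_rate < 0)) stop("discount rate must be >= 0")
  (1 + annual_rate)^(-0.5 * cycle_index)
}

#' Drug and monitoring costs for one treated cycle
#'
#' While on treatment, drug cost accrues as daily cost times days per cycle
#' and every treated cycle carries one physician visit: the BMD-inclusive
#' price in treated cycles 1, 3, 5, ... and the basic visit price otherwise.
#' Discontinued and untreated patients accrue neither.
#'
#' @param arm One of [treatment_arms()].
#' @param cycle_on_treatment 1-based index of the treated cycle.
#' @param on_treatment Logical; is the patient still on treatment this
#'   cycle?
#' @param params An `osteo_params` object.
#' @return Named numeric vector `c(drug =, monitoring =)` in euros.
#' @export
treatment_cycle_costs <- function(arm, cycle_on_treatment, on_treatment,
                                  params) {
  if (!on_treatment || arm == "none")
    return(c(drug = 0, monitoring = 0))
  stopifnot(cycle_on_treatment >= 1)
  drug <- params$costs$drug_daily_cost[[arm]] * params$days_per_cycle
  monitoring <- if (cycle_on_treatment %% 2 == 1)
    params$costs$bmd_visit_cost else params$costs$visit_cost
  c(drug = drug, monitoring = monitoring)
}

.fracture_cost_at <- function(ftype, age, col, table) {
  sub <- table[table$ftype == ftype, ]
  .interp(age, sub$age, sub[[col]])
}

#' Acute and continuing fracture costs for one cycle
#'
#' New fractures pay their acute six-month cost in the event cycle only.
#' Hip and vertebral fractures then enter the continuing-cost map, which
#' accrues every later cycle for the rest of life; a repeat fracture
#' supersedes the map entry only when its continuing cost is higher, so
#' long-term care is never double counted.  Wrist fractures carry no
#' continuing costs.
#'
#' @param new_events Character vector of fracture types occurring this
#'   cycle.
#' @param active_continuing Named numeric vector (one entry per fracture
#'   type) of currently accruing six-month continuing costs.
#' @param age Age in years (selects the age band of the cost table).
#' @param table The `fracture_costs` table (columns `ftype`, `age`,
#'   `acute`, `continuing`).
#' @return List with `acute` (euros), `continuing` (euros) and the updated
#'   `map`.
#' @export
fracture_cycle_costs <- function(new_events, active_continuing, age, table) {
  map <- active_continuing
  acute <- 0
  for (t in new_events) {
    acute <- acute + .fracture_cost_at(t, age, "acute", table)
    if (t != "wrist")
      map[[t]] <- max(map[[t]], .fracture_cost_at(t, age, "continuing", table))
  }
  pay <- setdiff(names(map)[map > 0], new_events)
  continuing <- sum(unlist(map[pay]))
  list(acute = acute, continuing = continuing, map = map)
}
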