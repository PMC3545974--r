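#' Natural (non-fracture) six-month death probability
#'
#' All-cause life-table mortality with the fracture-attributable proportion
#' removed, so that fracture-related excess mortality can be added without
#' double counting: `q_total * (1 - p_fx)`.
#'
#' @param age Age in years (clamped to the table range).
#' @param gender `"female"` or `"male"`.
#' @param tables The `mortality` component of an `osteo_params` object.
#' @return Six-month death probability.
#' @export
natural_death_probability <- function(age, gender, tables) {
  lt <- tables$life_table[tables$life_table$gender == gender, ]
  if (!nrow(lt)) stop("no life-table series for gender=", gender)
  at <- tables$fx_attrib[tables$fx_attrib$gender == gender, ]
  q <- .interp(age, lt$age, lt$q6)
  p_fx <- .interp(age, at$age, at$p)
  q * (1 - p_fx)
}

# schedule value for years-since-fracture; year 1 covers the first two
# cycles after the event; 1 beyond the phase-out horizon or with no event
.excess_schedule_value <- function(schedule, years_since) {
  idx <- floor(years_since) + 1
  ok <- is.finite(years_since) & years_since >= 0 & idx <= length(schedule)
  out <- rep(1, length(years_since))
  out[ok] <- schedule[idx[ok]]
  out
}

#' Fracture-related excess six-month death probability
#'
#' Hip and clinical vertebral fractures carry an excess-mortality multiplier
#' that is phased out with time since fracture (7 years for hip, 6 for
#' vertebral); when both are present the larger multiplier is used.  Wrist
#' fractures do not affect mortality.  The excess probability is the base
#' fracture-mortality probability for the patient's age and gender times
#' `(multiplier - 1)`.
#'
#' @param history Data frame of fracture events (`type`, `cycle`).
#' @param age Age in years.
#' @param gender `"female"` or `"male"`.
#' @param now Current cycle index.
#' @param tables The `mortality` component of an `osteo_params` object.
#' @return Six-month excess death probability.
#' @export
excess_death_probability <- function(history, age, gender, now, tables) {
  if (is.null(history) || !nrow(history)) return(0)
  mult <- 1
  for (t in c("hip", "vertebral")) {
    cyc <- history$cycle[history$type == t & history$cycle <= now]
    if (!length(cyc)) next
    ys <- (now - max(cyc)) / 2
    mult <- max(mult, .excess_schedule_value(tables$excess_multipliers[[t]], ys))
  }
  fm <- tables$fx_mortality[tables$fx_mortality$gender == gender, ]
  m6 <- .interp(age, fm$age, fm$m6)
  min(1, m6 * (mult - 1))
}

#' Within-cycle accrual fraction for a death kind
#'
#' Natural deaths are taken to occur at the mid-point of the six-month cycle
#' (half the cycle's costs and utilities accrue); fracture-related excess
#' deaths occur at the start of the cycle (nothing accrues); survivors
#' accrue the full cycle.
#'
#' @param kind `"natural"`, `"fracture_excess"`, or `"survivor"`.
#' @return Accrual fraction in \{0, 0.5, 1\}.
#' @export
death_timing <- function(kind = c("natural", "fracture_excess", "survivor")) {
  kind <- match.arg(kind)
  switch(kind, natural = 0.5, fracture_excess = 0.0, survivor = 1.0)
}
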