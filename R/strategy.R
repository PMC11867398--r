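#' Screening and chelation strategy
#'
#' Declarative description of one screening/chelation programme: who is
#' screened and treated, how many DMSA courses are given in the first and
#' second year, which safety measures accompany each course, and how
#' re-exposure to lead is screened for and retreated. The base case (label
#' "BC") screens all incident recipients at entry, treats every high-group
#' member with one course, monitors at the start of year 2 (60% receive a
#' repeated course), and rescreens the surviving initially-eligible members
#' every 5 years starting 5 years after treatment, retreating the 10% found
#' re-exposed.
#'
#' @param label Scenario identifier.
#' @param screening_bt Screen all incident recipients at entry?
#' @param eligibility_threshold Plasma lead (ug/L) above which a recipient is
#'   eligible for chelation (strict inequality).
#' @param course_fractions Fractions of eligible recipients receiving course
#'   1/2/3 within the first year.
#' @param monitoring_bt_year2 Monitoring blood test at the start of year 2?
#' @param repeated_fraction_year2 Fraction of surviving eligible recipients
#'   receiving a repeated course in year 2.
#' @param safety_iron_check Iron lab per administered course?
#' @param safety_iron_supplement_weeks Weeks of oral iron supplementation per
#'   course (0 = none; the unit cost covers an 8-week episode).
#' @param safety_liver_check AST/ALT lab per administered course?
#' @param reexposure_delay Years after treatment before the first follow-up
#'   screening (`Inf` = never, the no-re-exposure pattern).
#' @param reexposure_interval Years between subsequent follow-up screenings.
#' @param reexposure_fraction Fraction of surviving initially-eligible
#'   recipients found re-exposed (and retreated) at each follow-up screening.
#' @param reexposure_horizon Last model year in which follow-up screening can
#'   occur (`Inf` = lifetime).
#' @param effect_onset_cycle First cycle in which treated recipients use the
#'   medium-group graft-failure transition probabilities (default 2: chelation
#'   occupies year 1).
#' @return List of class `strategy_spec`.
#' @seealso [scenarios()], [scenario_strategy()]
#' @export
strategy_spec <- function(label = "BC",
                          screening_bt = TRUE,
                          eligibility_threshold = 0.38,
                          course_fractions = c(c1 = 1, c2 = 0, c3 = 0),
                          monitoring_bt_year2 = TRUE,
                          repeated_fraction_year2 = 0.60,
                          safety_iron_check = FALSE,
                          safety_iron_supplement_weeks = 0,
                          safety_liver_check = FALSE,
                          reexposure_delay = 5,
                          reexposure_interval = 5,
                          reexposure_fraction = 0.10,
                          reexposure_horizon = Inf,
                          effect_onset_cycle = 2) {
  assert_prob(course_fractions, "course_fractions")
  assert_prob(c(repeated_fraction_year2, reexposure_fraction), "fractions")
  if (is.finite(reexposure_interval) && reexposure_interval < 1) abort("`reexposure_interval` must be >= 1.")
  structure(
    list(label = label, screening_bt = screening_bt,
         eligibility_threshold = eligibility_threshold,
         course_fractions = course_fractions,
         monitoring_bt_year2 = monitoring_bt_year2,
         repeated_fraction_year2 = repeated_fraction_year2,
         safety_iron_check = safety_iron_check,
         safety_iron_supplement_weeks = safety_iron_supplement_weeks,
         safety_liver_check = safety_liver_check,
         reexposure_delay = reexposure_delay,
         reexposure_interval = reexposure_interval,
         reexposure_fraction = reexposure_fraction,
         reexposure_horizon = reexposure_horizon,
         effect_onset_cycle = effect_onset_cycle),
    class = "strategy_spec"
  )
}

#' Chelation eligibility
#'
#' A recipient is eligible when plasma lead strictly exceeds the intervention
#' threshold; under the default tertile boundaries this is exactly the high
#' group.
#'
#' @param lead Numeric lead values (ug/L), or a group factor/character with
#'   levels `low`/`medium`/`high`.
#' @param threshold Intervention threshold (default 0.38 ug/L).
#' @return Logical vector.
#' @export
eligibility <- function(lead, threshold = 0.38) {
  if (is.factor(lead) || is.character(lead)) return(as.character(lead) == "high")
  lead > threshold
}

# cycles (1-based model years) in which follow-up re-exposure screening
# occurs, for a programme whose initial screening happens at `start_cycle`
reexposure_cycles <- function(strategy, horizon, start_cycle = 1) {
  if (!is.finite(strategy$reexposure_delay)) return(integer(0))
  first <- start_cycle + strategy$reexposure_delay
  last <- min(horizon, start_cycle - 1 + strategy$reexposure_horizon)
  if (first > last) return(integer(0))
  as.integer(seq(first, last, by = max(1, strategy$reexposure_interval)))
}

# per-cycle lead-group schedule of the treated (initially high) subcohort:
# high until the effect-onset cycle, medium thereafter; re-exposed members are
# detected and retreated within the screening cycle so they never revert
treated_group_schedule <- function(strategy, horizon) {
  onset <- strategy$effect_onset_cycle
  ifelse(seq_len(horizon) < onset, "high", "medium")
}

#' Screening and treatment costs per cycle
#'
#' Computes the undiscounted screening/chelation programme cost stream for an
#' intervention-arm trace. Cycle 1 screens all entrants and treats the
#' eligible; cycle 2 adds the monitoring blood test and repeated courses;
#' follow-up screening cycles add a blood test for all surviving
#' initially-eligible members plus retreatment of the re-exposed fraction.
#' Safety labs/supplements are charged per administered course when enabled.
#' The standard-of-care arm accrues zero.
#'
#' @param trace A `markov_trace` from [run_cohort()].
#' @param strategy A `strategy_spec` (or `NULL` for standard of care).
#' @param costing An `intervention_costing` list.
#' @return Tibble with `cycle`, `screening_bt`, `courses`, `cost` (EUR,
#'   undiscounted).
#' @export
intervention_costs_per_cycle <- function(trace, strategy, costing = intervention_costing()) {
  horizon <- trace$horizon
  if (is.null(strategy)) {
    return(tibble::tibble(cycle = seq_len(horizon), screening_bt = 0,
                          courses = 0, cost = 0))
  }
  pc <- program_counts(trace$alive, trace$eligible_alive, strategy, horizon,
                       trace$start_cycle %||% 1, costing)
  tibble::tibble(cycle = seq_len(horizon), screening_bt = pc$bts,
                 courses = pc$courses, cost = pc$cost)
}

# numeric core shared with the fast sensitivity-analysis path: blood-test and
# course counts per cycle from boundary alive vectors (element b + 1 holds
# boundary b, so the start of cycle s is element s)
program_counts <- function(alive, elig, strategy, horizon, s, costing) {
  bt_cost <- costing$blood_draw + costing$lead_lab
  course_cost <- costing$dmsa_course +
    (if (strategy$safety_iron_check) costing$iron_lab else 0) +
    (if (strategy$safety_iron_supplement_weeks > 0) costing$iron_supplement else 0) +
    (if (strategy$safety_liver_check) costing$ast_alt_lab else 0)

  e0 <- elig[s]
  bts <- numeric(horizon); courses <- numeric(horizon)
  if (strategy$screening_bt) bts[s] <- alive[s]  # all alive at screening
  cf <- strategy$course_fractions
  courses[s] <- e0 * sum(cf)
  bts[s] <- bts[s] + e0 * (sum(cf) - cf[[1]])    # monitoring BT after courses 2/3
  if (strategy$monitoring_bt_year2 && s + 1 <= horizon) {
    bts[s + 1] <- bts[s + 1] + elig[s + 1]       # eligible survivors, year 2
    courses[s + 1] <- courses[s + 1] + strategy$repeated_fraction_year2 * elig[s + 1]
  }
  for (cyc in reexposure_cycles(strategy, horizon, s)) {
    surv <- elig[cyc]                            # survivors at start of that year
    bts[cyc] <- bts[cyc] + surv
    courses[cyc] <- courses[cyc] + strategy$reexposure_fraction * surv
  }
  list(bts = bts, courses = courses, cost = bts * bt_cost + courses * course_cost)
}

#' Shipped scenario table
#'
#' Loads the 26-row scenario file (base case plus 25 variations over time
#' horizon, discounting, course numbers, monitoring, safety measures and
#' re-exposure patterns) bundled with the package.
#'
#' @return Tibble with one row per scenario.
#' @export
scenarios <- function() {
  path <- system.file("extdata", "scenarios.yaml", package = "leadcea")
  raw <- yaml::read_yaml(path)
  purrr::map_dfr(raw$scenarios, function(s) {
    tibble::tibble(
      label = as.character(s$label),
      horizon = s$horizon %||% NA_integer_,
      disc_costs = s$disc_costs %||% 0.04,
      disc_effects = s$disc_effects %||% 0.015,
      c1 = s$c1 %||% 1, c2 = s$c2 %||% 0, c3 = s$c3 %||% 0,
      monitoring_bt_year2 = s$monitoring_bt_year2 %||% TRUE,
      repeated_fraction = s$repeated %||% 0.6,
      safety_iron = s$safety_iron %||% FALSE,
      iron_supplement_weeks = s$iron_supplement_weeks %||% 0,
      safety_liver = s$safety_liver %||% FALSE,
      reexposure_delay = if (identical(s$reexposure_delay, "lifetime")) Inf else s$reexposure_delay %||% 5,
      reexposure_fraction = s$reexposure_fraction %||% 0.1,
      reexposure_interval = s$reexposure_interval %||% 5
    )
  })
}

#' Build a strategy (and model overrides) from a scenario row
#'
#' @param label Scenario label (`"BC"`, `"1"` ... `"25"`).
#' @param table Scenario tibble, defaults to the shipped [scenarios()].
#' @return List with elements `strategy` (a `strategy_spec`), `horizon`
#'   (`NA` for the lifetime default) and `rates` (a `discount_rates`).
#' @export
scenario_strategy <- function(label, table = scenarios()) {
  row <- table[table$label == as.character(label), ]
  if (nrow(row) != 1) abort(sprintf("Unknown scenario label '%s'.", label))
  list(
    strategy = strategy_spec(
      label = row$label,
      course_fractions = c(c1 = row$c1, c2 = row$c2, c3 = row$c3),
      monitoring_bt_year2 = row$monitoring_bt_year2,
      repeated_fraction_year2 = row$repeated_fraction,
      safety_iron_check = row$safety_iron,
      safety_iron_supplement_weeks = row$iron_supplement_weeks,
      safety_liver_check = row$safety_liver,
      reexposure_delay = row$reexposure_delay,
      reexposure_interval = row$reexposure_interval,
      reexposure_fraction = row$reexposure_fraction
    ),
    horizon = if (is.na(row$horizon)) NA_integer_ else as.integer(row$horizon),
    rates = discount_rates(costs = row$disc_costs, effects = row$disc_effects)
  )
}
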