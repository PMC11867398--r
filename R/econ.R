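#' Health-state and event cost stream
#'
#' Undiscounted per-cycle health-state costs of a trace: half-cycle-corrected
#' functioning-graft occupancy times annual transplant upkeep, plus
#' half-cycle graft-failure occupancy times the modality-weighted annual
#' dialysis cost, plus one-off event costs counted at the cycle of the event
#' (graft-failure initial costs, retransplantation, death).
#'
#' @param trace A `markov_trace`.
#' @param costs A `cost_inputs` list.
#' @return Tibble with `cycle`, `fg_upkeep`, `dialysis`, `events`, `cost`.
#' @export
state_costs <- function(trace, costs = cost_inputs()) {
  hc <- trace$half_cycle
  fl <- trace$flows
  dial <- weighted_dialysis_cost(costs)
  fg_upkeep <- (hc$FG1 + hc$FG2) * costs$transplant_upkeep_annual
  dialysis <- (hc$GF1 + hc$GF2) * dial
  events <- fl$gf_events * costs$gf_initial +
    fl$retransplants * costs$transplantation +
    fl$deaths * costs$death_oneoff
  tibble::tibble(cycle = hc$cycle, fg_upkeep = fg_upkeep, dialysis = dialysis,
                 events = events, cost = fg_upkeep + dialysis + events)
}

#' QALY stream
#'
#' Undiscounted per-cycle quality-adjusted life years: half-cycle
#' functioning-graft occupancy weighted by the functioning-graft utility plus
#' half-cycle graft-failure occupancy weighted by the HD/PD-mixed utility;
#' death contributes zero.
#'
#' @param trace A `markov_trace`.
#' @param utilities A `utility_inputs` list.
#' @return Tibble with `cycle` and `qaly`.
#' @export
qalys <- function(trace, utilities = utility_inputs()) {
  hc <- trace$half_cycle
  u_gf <- weighted_gf_utility(utilities)
  tibble::tibble(
    cycle = hc$cycle,
    qaly = (hc$FG1 + hc$FG2) * utilities$u_fg + (hc$GF1 + hc$GF2) * u_gf
  )
}

# age band lookup; ages below 45 use the 45-54 values (documented fallback)
age_band_value <- function(age, bands) {
  ifelse(age >= 65, bands[["a65plus"]], ifelse(age >= 55, bands[["a55_64"]], bands[["a45_54"]]))
}

#' Friction-cost productivity-loss stream
#'
#' Undiscounted per-cycle productivity losses, all one-off at events: a drop
#' in employment share at graft failure costed over the friction period;
#' hospital days at retransplantation costed as work absence; and deaths
#' before the working-age cutoff costed as a friction-period job loss at the
#' dying state's employment share. Wages are mixed over sex.
#'
#' @param trace A `markov_trace`.
#' @param prod A `productivity_inputs` list.
#' @return Tibble with `cycle`, `gf_loss`, `retx_loss`, `death_loss`, `cost`.
#' @export
productivity_losses <- function(trace, prod = productivity_inputs()) {
  fl <- trace$flows
  age <- trace$baseline_age + fl$cycle
  wage <- prod$sex_mix_male * prod$wage_male + (1 - prod$sex_mix_male) * prod$wage_female
  hours <- prod$hours_per_day

  w_tx <- age_band_value(age, prod$work_posttx)
  w_dial <- age_band_value(age, prod$work_dialysis)
  hosp_days <- prod$donor_mix_living * prod$hospital_days[["living"]] +
    (1 - prod$donor_mix_living) * prod$hospital_days[["deceased"]]

  gf_loss <- fl$gf_events * pmax(w_tx - w_dial, 0) * prod$friction_days * hours * wage
  retx_loss <- fl$retransplants * w_dial * hosp_days * hours * wage
  working <- age < prod$death_working_age_max
  death_loss <- ifelse(working,
                       (fl$deaths_dwfg * w_tx + fl$deaths_dwgf * w_dial) *
                         prod$friction_days * hours * wage,
                       0)
  tibble::tibble(cycle = fl$cycle, gf_loss = gf_loss, retx_loss = retx_loss,
                 death_loss = death_loss, cost = gf_loss + retx_loss + death_loss)
}

#' Evaluate one arm of the model
#'
#' Assembles the discounted cost breakdown (health-state, screening and
#' treatment, productivity) and discounted QALYs for one trace.
#'
#' @param trace A `markov_trace`.
#' @param costs,utilities,prod,costing Input lists.
#' @param rates A `discount_rates` list.
#' @param perspective `"societal"` (default) includes productivity losses;
#'   `"payer"` excludes them.
#' @return One-row tibble: `health_state`, `screening_treatment`,
#'   `productivity`, `total_cost`, `qalys`.
#' @export
evaluate_arm <- function(trace,
                         costs = cost_inputs(),
                         utilities = utility_inputs(),
                         prod = productivity_inputs(),
                         costing = intervention_costing(),
                         rates = discount_rates(),
                         perspective = c("societal", "payer")) {
  perspective <- match.arg(perspective)
  cyc <- seq_len(trace$horizon)
  hs <- sum(discount(state_costs(trace, costs)$cost, rates$costs, cyc))
  st <- sum(discount(intervention_costs_per_cycle(trace, trace$strategy, costing)$cost,
                     rates$costs, cyc))
  pl <- if (perspective == "societal") {
    sum(discount(productivity_losses(trace, prod)$cost, rates$costs, cyc))
  } else 0
  ql <- sum(discount(qalys(trace, utilities)$qaly, rates$effects, cyc))
  tibble::tibble(health_state = hs, screening_treatment = st, productivity = pl,
                 total_cost = hs + st + pl, qalys = ql)
}

#' Incremental cost-effectiveness result
#'
#' @param intervention,soc One-row arm tibbles from [evaluate_arm()].
#' @return Object of class `cea_result` with the per-arm breakdown, `delta_c`,
#'   `delta_e`, `icer` (NA when undefined or dominant/dominated) and a
#'   `dominance` label (`"dominant"`, `"dominated"`, `"tradeoff"`,
#'   `"undefined"`).
#' @export
compute_icer <- function(intervention, soc) {
  dc <- intervention$total_cost - soc$total_cost
  de <- intervention$qalys - soc$qalys
  dominance <- if (dc < 0 && de > 0) "dominant"
  else if (dc > 0 && de < 0) "dominated"
  else if (de == 0) "undefined"
  else "tradeoff"
  icer <- if (de != 0 && dominance == "tradeoff") dc / de else NA_real_
  structure(
    list(
      arms = dplyr::bind_rows(
        dplyr::mutate(intervention, arm = "intervention", .before = 1),
        dplyr::mutate(soc, arm = "standard_of_care", .before = 1)
      ),
      delta_c = dc, delta_e = de, icer = icer, dominance = dominance
    ),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result> dC = %.2f EUR, dE = %.2f QALY, ICER: %s\n",
              x$delta_c, x$delta_e,
              if (x$dominance == "tradeoff") sprintf("%.0f EUR/QALY", x$icer) else x$dominance))
  invisible(x)
}

#' @export
tidy.cea_result <- function(x, ...) {
  tidyr::pivot_longer(x$arms, -dplyr::all_of("arm"),
                      names_to = "quantity", values_to = "value")
}

#' @export
glance.cea_result <- function(x, ...) {
  tibble::tibble(delta_c = x$delta_c, delta_e = x$delta_e,
                 icer = x$icer, dominance = x$dominance)
}

#' Broom-style generics
#'
#' `tidy()` and `glance()` methods are provided for fitted survival models,
#' cost-effectiveness results and probabilistic-sensitivity runs.
#'
#' @param x Object to summarise.
#' @param ... Unused.
#' @name tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")
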