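# Fast matrix-only cost-effectiveness evaluation used by the sensitivity
# analyses, which re-run the model tens of thousands of times. Produces the
# same numbers as run_cea() / evaluate_arm() (asserted in the test suite)
# but skips all tibble assembly. The low- and medium-group subcohorts are
# identical in both arms, so only four subcohort runs are needed per
# evaluation.

arm_value_fast <- function(occ, flows, alive, elig_alive, strategy, config,
                           perspective = "societal") {
  H <- nrow(flows)
  cyc <- seq_len(H)
  rates <- config$rates
  disc_c <- (1 + rates$costs)^-(cyc - 1)
  disc_e <- (1 + rates$effects)^-(cyc - 1)

  half <- (occ[-1, , drop = FALSE] + occ[-(H + 1), , drop = FALSE]) / 2
  fg_half <- half[, "FG1"] + half[, "FG2"]
  gf_half <- half[, "GF1"] + half[, "GF2"]

  costs <- config$costs
  hs <- fg_half * costs$transplant_upkeep_annual +
    gf_half * weighted_dialysis_cost(costs) +
    flows[, "gf_events"] * costs$gf_initial +
    flows[, "retransplants"] * costs$transplantation +
    flows[, "deaths"] * costs$death_oneoff

  st <- if (is.null(strategy)) 0 else {
    program_counts(alive, elig_alive, strategy, H, 1, config$costing)$cost
  }

  pl <- 0
  if (perspective == "societal") {
    prod <- config$prod
    age <- config$model$baseline_age + cyc
    wage <- prod$sex_mix_male * prod$wage_male + (1 - prod$sex_mix_male) * prod$wage_female
    w_tx <- age_band_value(age, prod$work_posttx)
    w_dial <- age_band_value(age, prod$work_dialysis)
    hosp <- prod$donor_mix_living * prod$hospital_days[["living"]] +
      (1 - prod$donor_mix_living) * prod$hospital_days[["deceased"]]
    pl <- flows[, "gf_events"] * pmax(w_tx - w_dial, 0) * prod$friction_days * prod$hours_per_day * wage +
      flows[, "retransplants"] * w_dial * hosp * prod$hours_per_day * wage +
      ifelse(age < prod$death_working_age_max,
             (flows[, "deaths_dwfg"] * w_tx + flows[, "deaths_dwgf"] * w_dial) *
               prod$friction_days * prod$hours_per_day * wage, 0)
  }

  u <- config$utilities
  q <- fg_half * u$u_fg + gf_half * weighted_gf_utility(u)

  c(cost = sum((hs + st + pl) * disc_c), qaly = sum(q * disc_e))
}

# incremental (delta_c, delta_e) of the configured strategy vs standard of
# care; numerically identical to glance(run_cea(config, perspective))
fast_cea_deltas <- function(config, perspective = "societal") {
  m <- config$model
  H <- m$horizon
  tp <- tp_from_parameters(config$survival, H)
  n <- m$cohort_size * m$group_mix

  low <- run_group_cohort(n[["low"]], rep("low", H), tp, m)
  med <- run_group_cohort(n[["medium"]], rep("medium", H), tp, m)
  high_soc <- run_group_cohort(n[["high"]], rep("high", H), tp, m)
  onset <- config$strategy$effect_onset_cycle
  high_trt <- run_group_cohort(
    n[["high"]], ifelse(seq_len(H) < onset, "high", "medium"), tp, m
  )

  assemble <- function(high) {
    occ <- low$occupancy + med$occupancy + high$occupancy
    flows <- low$flows + med$flows + high$flows
    alive <- rowSums(occ[, c("FG1", "GF1", "FG2", "GF2"), drop = FALSE])
    elig <- rowSums(high$occupancy[, c("FG1", "GF1", "FG2", "GF2"), drop = FALSE])
    list(occ = occ, flows = flows, alive = alive, elig = elig)
  }
  a_soc <- assemble(high_soc)
  a_trt <- assemble(high_trt)

  v_soc <- arm_value_fast(a_soc$occ, a_soc$flows, a_soc$alive, a_soc$elig,
                          NULL, config, perspective)
  v_trt <- arm_value_fast(a_trt$occ, a_trt$flows, a_trt$alive, a_trt$elig,
                          config$strategy, config, perspective)
  c(delta_c = unname(v_trt["cost"] - v_soc["cost"]),
    delta_e = unname(v_trt["qaly"] - v_soc["qaly"]))
}
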