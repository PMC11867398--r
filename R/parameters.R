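#' Synthetic default survival parameters
#'
#' Package-shipped, clearly synthetic stand-ins for fitted time-to-event
#' parameters: lognormal `(meanlog, sdlog)` for graft failure per lead group
#' and gamma `(shape, rate)` for the two death endpoints, with standard
#' errors of the kind a cohort of ~670 recipients (~220 per lead group)
#' would yield. They reproduce the qualitative epidemiology the model
#' assumes — ten-year death-censored graft-failure fractions of about
#' 8%/12%/25% in the low/medium/high lead groups, death with functioning
#' graft on a ~20-year scale, death on dialysis on a ~6-year mean time
#' scale — and are replaced by real
#' fitted parameters via [read_config()] / the `survival` block of the YAML
#' configuration whenever those are available.
#'
#' @return Nested list with elements `gf` (per-group `c(meanlog, sdlog)`),
#'   `dwfg`, `dwgf` (`c(shape, rate)`) and matching `*_se` standard errors.
#' @export
synthetic_survival_parameters <- function() {
  list(
    gf = list(
      low = c(meanlog = 4.27, sdlog = 1.40),
      medium = c(meanlog = 3.95, sdlog = 1.40),
      high = c(meanlog = 3.25, sdlog = 1.40)
    ),
    gf_se = list(
      low = c(meanlog = 0.45, sdlog = 0.30),
      medium = c(meanlog = 0.35, sdlog = 0.25),
      high = c(meanlog = 0.25, sdlog = 0.20)
    ),
    dwfg = c(shape = 1.60, rate = 0.080),
    dwfg_se = c(shape = 0.12, rate = 0.012),
    dwgf = c(shape = 1.30, rate = 0.200),
    dwgf_se = c(shape = 0.10, rate = 0.030)
  )
}

#' Markov model structural parameters
#'
#' @param horizon Number of one-year cycles (default 40, a lifetime horizon).
#' @param cohort_size Hypothetical cohort entering at FG1 (default 10,000).
#' @param baseline_age Cohort age at transplantation, years.
#' @param p_retransplant_base Annual retransplantation probability from GF1
#'   before the age-related decline (default 0.15).
#' @param age_decline_start Age after which the retransplant probability
#'   declines linearly (default 65).
#' @param age_decline_zero Age at which it reaches zero (default 80).
#' @param p_primary_nonfunction Probability that a retransplant immediately
#'   and persistently fails (default 0.007).
#' @param group_mix Cohort fractions in the low/medium/high lead groups.
#' @return List of class `model_parameters`.
#' @export
model_parameters <- function(horizon = 40,
                             cohort_size = 10000,
                             baseline_age = 53,
                             p_retransplant_base = 0.15,
                             age_decline_start = 65,
                             age_decline_zero = 80,
                             p_primary_nonfunction = 0.007,
                             group_mix = c(low = 1 / 3, medium = 1 / 3, high = 1 / 3)) {
  assert_prob(p_retransplant_base, "p_retransplant_base")
  assert_prob(p_primary_nonfunction, "p_primary_nonfunction")
  if (age_decline_zero <= age_decline_start) abort("`age_decline_zero` must exceed `age_decline_start`.")
  if (abs(sum(group_mix) - 1) > 1e-8) abort("`group_mix` must sum to 1.")
  structure(
    list(
      horizon = as.integer(horizon), cohort_size = cohort_size,
      baseline_age = baseline_age,
      p_retransplant_base = p_retransplant_base,
      age_decline_start = age_decline_start, age_decline_zero = age_decline_zero,
      p_primary_nonfunction = p_primary_nonfunction,
      group_mix = group_mix
    ),
    class = "model_parameters"
  )
}

#' Health-state and event costs (EUR 2022)
#'
#' Annual dialysis upkeep is a modality-weighted mean over centre
#' haemodialysis (CHD), home haemodialysis (HHD), automated and continuous
#' ambulatory peritoneal dialysis (APD/CAPD); the default mix 80/4/8/8 gives
#' a weighted cost of EUR 111,137.41 per dialysis-year.
#'
#' @param gf_initial One-off cost at graft failure.
#' @param dialysis_annual Named costs per modality-year (CHD/HHD/APD/CAPD).
#' @param modality_mix Modality fractions, must sum to 1.
#' @param transplantation One-off retransplantation cost.
#' @param transplant_upkeep_annual Annual cost of a functioning graft.
#' @param death_oneoff One-off cost at death.
#' @return List of class `cost_inputs`.
#' @export
cost_inputs <- function(gf_initial = 2818.80,
                        dialysis_annual = c(CHD = 113142.50, HHD = 106344.10,
                                            APD = 109863.60, CAPD = 94756.94),
                        modality_mix = c(CHD = 0.80, HHD = 0.04, APD = 0.08, CAPD = 0.08),
                        transplantation = 103993.68,
                        transplant_upkeep_annual = 14376.98,
                        death_oneoff = 1392.03) {
  if (abs(sum(modality_mix) - 1) > 1e-8) abort("`modality_mix` must sum to 1.")
  assert_positive(c(gf_initial, dialysis_annual, transplantation,
                    transplant_upkeep_annual, death_oneoff), "costs", strict = FALSE)
  structure(
    list(
      gf_initial = gf_initial, dialysis_annual = dialysis_annual,
      modality_mix = modality_mix, transplantation = transplantation,
      transplant_upkeep_annual = transplant_upkeep_annual,
      death_oneoff = death_oneoff
    ),
    class = "cost_inputs"
  )
}

#' Modality-weighted annual dialysis cost
#' @param costs A `cost_inputs` list.
#' @return Weighted mean dialysis cost per year (EUR).
#' @export
weighted_dialysis_cost <- function(costs = cost_inputs()) {
  sum(costs$dialysis_annual * costs$modality_mix)
}

#' Health-state utilities
#'
#' Graft-failure utility is the haemodialysis/peritoneal-dialysis weighted
#' mean (default 0.84 x 0.56 + 0.16 x 0.58 = 0.5632); death contributes zero.
#'
#' @param u_fg Utility with a functioning graft.
#' @param u_hd,u_pd Utilities on haemodialysis / peritoneal dialysis.
#' @param hd_share,pd_share Dialysis modality shares for the utility weight
#'   (kept separate from the cost-side modality mix).
#' @return List of class `utility_inputs`.
#' @export
utility_inputs <- function(u_fg = 0.81, u_hd = 0.56, u_pd = 0.58,
                           hd_share = 0.84, pd_share = 0.16) {
  assert_prob(c(u_fg, u_hd, u_pd, hd_share, pd_share), "utilities")
  if (abs(hd_share + pd_share - 1) > 1e-8) abort("`hd_share` + `pd_share` must equal 1.")
  structure(list(u_fg = u_fg, u_hd = u_hd, u_pd = u_pd,
                 hd_share = hd_share, pd_share = pd_share),
            class = "utility_inputs")
}

#' Weighted graft-failure utility
#' @param u A `utility_inputs` list.
#' @return HD/PD-weighted utility of the graft-failure states.
#' @export
weighted_gf_utility <- function(u = utility_inputs()) {
  u$hd_share * u$u_hd + u$pd_share * u$u_pd
}

#' Friction-cost productivity-loss inputs
#'
#' Productivity losses follow the friction-cost method: a job lost at graft
#' failure or death is costed only for the friction period (85 days) during
#' which the worker is replaced, at age-band-specific employment shares and a
#' sex-mixed hourly wage. Hospital days at retransplantation are costed as
#' absence from work. Ages below 45 use the 45-54 band.
#'
#' @param work_posttx Employment share with a functioning graft per age band
#'   (`a45_54`, `a55_64`, `a65plus`).
#' @param work_dialysis Employment share on dialysis per age band.
#' @param hospital_days Named days in hospital at retransplantation for
#'   living/deceased donors.
#' @param donor_mix_living Fraction of retransplants from living donors used
#'   to weight hospital days (50/50 default).
#' @param friction_days Friction period in days.
#' @param hours_per_day Working hours per day.
#' @param wage_male,wage_female Hourly wages (EUR).
#' @param sex_mix_male Cohort fraction male, used to mix wages.
#' @param death_working_age_max Deaths at or above this age carry no
#'   productivity loss (default 65).
#' @return List of class `productivity_inputs`.
#' @export
productivity_inputs <- function(work_posttx = c(a45_54 = 0.57, a55_64 = 0.41, a65plus = 0.061),
                                work_dialysis = c(a45_54 = 0.32, a55_64 = 0.19, a65plus = 0.028),
                                hospital_days = c(living = 13.30, deceased = 7.80),
                                donor_mix_living = 0.5,
                                friction_days = 85,
                                hours_per_day = 8,
                                wage_male = 28.45,
                                wage_female = 24.70,
                                sex_mix_male = 0.6,
                                death_working_age_max = 65) {
  assert_prob(c(work_posttx, work_dialysis, donor_mix_living, sex_mix_male), "work fractions")
  assert_positive(c(friction_days, hours_per_day, hospital_days), "days/hours", strict = FALSE)
  structure(
    list(work_posttx = work_posttx, work_dialysis = work_dialysis,
         hospital_days = hospital_days, donor_mix_living = donor_mix_living,
         friction_days = friction_days, hours_per_day = hours_per_day,
         wage_male = wage_male, wage_female = wage_female,
         sex_mix_male = sex_mix_male,
         death_working_age_max = death_working_age_max),
    class = "productivity_inputs"
  )
}

#' Discount rates
#' @param costs Annual discount rate for costs (default 4%).
#' @param effects Annual discount rate for effects (default 1.5%).
#' @return List of class `discount_rates`.
#' @export
discount_rates <- function(costs = 0.04, effects = 0.015) {
  assert_positive(c(costs, effects), "rates", strict = FALSE)
  structure(list(costs = costs, effects = effects), class = "discount_rates")
}

#' Unit costs of the screening and chelation programme (EUR 2022)
#'
#' @param blood_draw Cost of drawing blood.
#' @param lead_lab Plasma-lead laboratory determination.
#' @param iron_lab Iron-status laboratory panel (safety scenarios only).
#' @param ast_alt_lab AST/ALT liver panel (safety scenarios only).
#' @param dmsa_course One five-day course of oral DMSA capsules.
#' @param iron_supplement Oral iron supplementation episode (8 weeks).
#' @return List of class `intervention_costing`.
#' @export
intervention_costing <- function(blood_draw = 15.00,
                                 lead_lab = 50.63,
                                 iron_lab = 26.39,
                                 ast_alt_lab = 5.38,
                                 dmsa_course = 570.95,
                                 iron_supplement = 46.48) {
  assert_positive(c(blood_draw, lead_lab, iron_lab, ast_alt_lab,
                    dmsa_course, iron_supplement), "costing", strict = FALSE)
  structure(list(blood_draw = blood_draw, lead_lab = lead_lab,
                 iron_lab = iron_lab, ast_alt_lab = ast_alt_lab,
                 dmsa_course = dmsa_course, iron_supplement = iron_supplement),
            class = "intervention_costing")
}
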