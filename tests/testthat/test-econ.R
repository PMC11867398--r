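test_that("discounting convention: cycle one undiscounted, annuity closed form", {
  expect_equal(discount(104, 0.04, 2), 100)
  expect_equal(discount(123.45, 0.08, 1), 123.45)
  # 40-year annuity of 100 at 4%: closed form vs the cycle loop
  loop <- sum(discount(rep(100, 40), 0.04, 1:40))
  annuity <- 100 * (1 - 1.04^-40) / 0.04 * 1.04
  expect_equal(loop, annuity, tolerance = 1e-10)
  expect_error(discount(1, 0.04, 0), ">= 1")
})

test_that("modality-weighted dialysis cost and GF utility match hand computation", {
  expect_equal(weighted_dialysis_cost(),
               0.80 * 113142.50 + 0.04 * 106344.10 + 0.08 * 109863.60 + 0.08 * 94756.94)
  expect_equal(weighted_dialysis_cost(), 111137.41, tolerance = 1e-7)
  expect_equal(weighted_gf_utility(), 0.84 * 0.56 + 0.16 * 0.58)
  expect_equal(weighted_gf_utility(), 0.5632)
})

test_that("state costs decompose into upkeep, dialysis and one-off events", {
  half <- tibble::tibble(cycle = 1:2, FG1 = c(100, 0), GF1 = c(0, 50),
                         FG2 = 0, GF2 = 0, Death = 0)
  flows <- tibble::tibble(cycle = 1:2, gf_events = c(0, 10), retransplants = c(0, 1),
                          primary_nonfunction = 0, deaths = c(0, 2),
                          deaths_dwfg = c(0, 1), deaths_dwgf = c(0, 1))
  tr <- fake_trace(half, flows)
  sc <- state_costs(tr)
  expect_equal(sc$cost[1], 100 * 14376.98)
  expect_equal(sc$cost[2],
               50 * weighted_dialysis_cost() + 10 * 2818.80 + 1 * 103993.68 + 2 * 1392.03)
  # empty graft-failure states incur no dialysis cost
  expect_equal(sc$dialysis[1], 0)
})

test_that("QALYs weight half-cycle occupancy by state utility", {
  half <- tibble::tibble(cycle = 1, FG1 = 10000, GF1 = 0, FG2 = 0, GF2 = 0, Death = 0)
  flows <- tibble::tibble(cycle = 1, gf_events = 0, retransplants = 0,
                          primary_nonfunction = 0, deaths = 0,
                          deaths_dwfg = 0, deaths_dwgf = 0)
  expect_equal(qalys(fake_trace(half, flows))$qaly, 8100)
  # a dead cohort accrues nothing
  half0 <- dplyr::mutate(half, FG1 = 0, Death = 10000)
  expect_equal(qalys(fake_trace(half0, flows))$qaly, 0)
})

test_that("friction-cost productivity losses follow the event arithmetic", {
  mk <- function(baseline_age, flows1) {
    half <- tibble::tibble(cycle = 1, FG1 = 0, GF1 = 0, FG2 = 0, GF2 = 0, Death = 0)
    fake_trace(half, flows1, baseline_age = baseline_age)
  }
  flows <- tibble::tibble(cycle = 1, gf_events = 1, retransplants = 0,
                          primary_nonfunction = 0, deaths = 0,
                          deaths_dwfg = 0, deaths_dwgf = 0)

  # 65+ band: (6.1% - 2.8%) employment drop over the friction period
  pr <- productivity_inputs(sex_mix_male = 1)
  pl <- productivity_losses(mk(70, flows), pr)
  expect_equal(pl$cost, (0.061 - 0.028) * 85 * 8 * 28.45)

  # equal employment shares in both states produce no job-loss cost
  pr_eq <- productivity_inputs(work_posttx = c(a45_54 = 0.3, a55_64 = 0.3, a65plus = 0.3),
                               work_dialysis = c(a45_54 = 0.3, a55_64 = 0.3, a65plus = 0.3))
  expect_equal(productivity_losses(mk(50, flows), pr_eq)$gf_loss, 0)

  # one living-donor retransplant, male, 45-54 band
  flows_rtx <- dplyr::mutate(flows, gf_events = 0, retransplants = 1)
  pr_liv <- productivity_inputs(donor_mix_living = 1, sex_mix_male = 1)
  pl2 <- productivity_losses(mk(48, flows_rtx), pr_liv)
  expect_equal(pl2$cost, 0.32 * 13.30 * 8 * 28.45, tolerance = 1e-9)

  # deaths above the working-age cutoff carry no loss; below they do
  flows_d <- dplyr::mutate(flows, gf_events = 0, deaths = 1, deaths_dwfg = 1)
  expect_equal(productivity_losses(mk(70, flows_d), pr)$death_loss, 0)
  expect_gt(productivity_losses(mk(50, flows_d), pr)$death_loss, 0)

  # ages below 45 fall back to the 45-54 band
  expect_equal(productivity_losses(mk(30, flows), pr)$cost,
               productivity_losses(mk(48, flows), pr)$cost)
})

test_that("ICER classification covers dominance, tradeoff and undefined cases", {
  arm <- function(cost, q) tibble::tibble(health_state = cost, screening_treatment = 0,
                                          productivity = 0, total_cost = cost, qalys = q)
  dom <- compute_icer(arm(90, 11), arm(100, 10))
  expect_equal(dom$dominance, "dominant")
  expect_true(is.na(dom$icer))

  tr <- compute_icer(arm(150000, 11), arm(100000, 10))
  expect_equal(tr$dominance, "tradeoff")
  expect_equal(tr$icer, 50000)

  same <- compute_icer(arm(100, 10), arm(100, 10))
  expect_equal(same$dominance, "undefined")
  expect_true(is.na(same$icer))

  bad <- compute_icer(arm(120, 9), arm(100, 10))
  expect_equal(bad$dominance, "dominated")
})

test_that("arm totals are additive and the payer perspective is never dearer", {
  cfg <- default_config()
  tp <- tp_from_parameters(cfg$survival, cfg$model$horizon)
  tr <- run_cohort(cfg$model, tp, strategy = cfg$strategy)
  soc <- evaluate_arm(tr, perspective = "societal")
  pay <- evaluate_arm(tr, perspective = "payer")
  expect_equal(soc$total_cost,
               soc$health_state + soc$screening_treatment + soc$productivity)
  expect_lte(pay$total_cost, soc$total_cost)
  expect_equal(pay$qalys, soc$qalys)
})

test_that("zero discounting recovers utility-weighted half-cycle person-years", {
  cfg <- default_config()
  tp <- tp_from_parameters(cfg$survival, cfg$model$horizon)
  tr <- run_cohort(cfg$model, tp)
  ev <- evaluate_arm(tr, rates = discount_rates(costs = 0, effects = 0))
  hand <- sum((tr$half_cycle$FG1 + tr$half_cycle$FG2) * 0.81 +
                (tr$half_cycle$GF1 + tr$half_cycle$GF2) * weighted_gf_utility())
  expect_equal(ev$qalys, hand, tolerance = 1e-12)
})

test_that("worse graft survival never cheapens care nor adds QALYs under standard of care", {
  cfg <- default_config()
  H <- cfg$model$horizon
  base_tp <- tp_from_parameters(cfg$survival, H)
  ev_soc <- function(tp) {
    tr <- run_cohort(cfg$model, tp)
    evaluate_arm(tr)
  }
  base <- ev_soc(base_tp)
  for (mult in c(1.2, 1.5, 2)) {
    worse <- base_tp
    for (g in c("gf_low", "gf_medium", "gf_high")) worse[[g]] <- pmin(base_tp[[g]] * mult, 1)
    res <- ev_soc(worse)
    expect_gte(res$health_state, base$health_state)
    expect_lte(res$qalys, base$qalys)
  }
})
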