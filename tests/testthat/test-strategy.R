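test_that("eligibility is a strict threshold on lead, equivalently the high group", {
  expect_true(eligibility(0.39))
  expect_false(eligibility(0.38))   # exactly at threshold: not eligible
  expect_false(eligibility(0.20))
  expect_equal(eligibility(factor(c("low", "medium", "high"))),
               c(FALSE, FALSE, TRUE))
})

test_that("the shipped scenario table matches the base-case design row for row", {
  tab <- scenarios()
  expect_equal(nrow(tab), 26)
  expect_equal(tab$label, c("BC", as.character(1:25)))

  bc <- tab[tab$label == "BC", ]
  ref <- strategy_spec()
  expect_equal(bc$c1, unname(ref$course_fractions[["c1"]]))
  expect_equal(bc$c2, 0)
  expect_equal(bc$c3, 0)
  expect_equal(bc$repeated_fraction, ref$repeated_fraction_year2)
  expect_equal(bc$reexposure_delay, ref$reexposure_delay)
  expect_equal(bc$reexposure_interval, ref$reexposure_interval)
  expect_equal(bc$reexposure_fraction, ref$reexposure_fraction)
  expect_false(bc$safety_iron)
  expect_false(bc$safety_liver)
  expect_equal(bc$disc_costs, 0.04)
  expect_equal(bc$disc_effects, 0.015)

  # the year-2 repeated fraction stays 60% in the horizon/discounting rows
  expect_true(all(tab$repeated_fraction[tab$label %in% as.character(1:4)] == 0.6))
  # scenario 25: no re-exposure ever
  s25 <- scenario_strategy("25")$strategy
  expect_equal(leadcea:::reexposure_cycles(s25, 40), integer(0))
})

test_that("re-exposure screening cycles follow delay and interval", {
  s <- strategy_spec(reexposure_fraction = 1, reexposure_delay = 5, reexposure_interval = 5)
  expect_equal(leadcea:::reexposure_cycles(s, 40), as.integer(seq(6, 36, by = 5)))
  s10 <- strategy_spec(reexposure_delay = 10, reexposure_interval = 10)
  expect_equal(leadcea:::reexposure_cycles(s10, 40), c(11L, 21L, 31L))
  # shifted programme start
  expect_equal(leadcea:::reexposure_cycles(s, 40, start_cycle = 3),
               as.integer(seq(8, 38, by = 5)))
})

test_that("programme costs follow the screening/course arithmetic", {
  params <- model_parameters()
  tp <- tp_from_parameters(horizon = params$horizon)
  strat <- strategy_spec()
  trace <- run_cohort(params, tp, strategy = strat)
  costing <- intervention_costing()
  cc <- intervention_costs_per_cycle(trace, strat, costing)

  # cycle 1: screening blood test for everyone, one DMSA course per eligible
  n <- params$cohort_size
  e0 <- n / 3
  expect_equal(cc$cost[1], n * (15.00 + 50.63) + e0 * 570.95)
  expect_equal(15.00 + 50.63, 65.63)  # per-recipient screening cost

  # cycle 2: monitoring blood test + 60% repeated courses among survivors
  elig1 <- trace$eligible_alive[2]
  expect_equal(cc$cost[2], elig1 * (65.63 + 0.6 * 570.95), tolerance = 1e-9)

  # standard of care accrues nothing
  soc <- run_cohort(params, tp, strategy = NULL)
  cc0 <- intervention_costs_per_cycle(soc, NULL, costing)
  expect_true(all(cc0$cost == 0))

  # programme cost non-increasing after year 2 except at re-exposure screens
  rex <- leadcea:::reexposure_cycles(strat, params$horizon)
  flat <- setdiff(3:params$horizon, rex)
  expect_true(all(diff(cc$cost[flat]) <= 1e-9))
})

test_that("safety measures add per-course costs and are exactly additive", {
  params <- model_parameters()
  tp <- tp_from_parameters(horizon = params$horizon)
  costing <- intervention_costing()

  base <- strategy_spec()
  full <- strategy_spec(safety_iron_check = TRUE, safety_iron_supplement_weeks = 8,
                        safety_liver_check = TRUE)
  tr_b <- run_cohort(params, tp, strategy = base)
  tr_f <- run_cohort(params, tp, strategy = full)
  cb <- intervention_costs_per_cycle(tr_b, base, costing)
  cf <- intervention_costs_per_cycle(tr_f, full, costing)
  per_course_extra <- costing$iron_lab + costing$iron_supplement + costing$ast_alt_lab
  expect_equal(cf$cost, cb$cost + cb$courses * per_course_extra, tolerance = 1e-9)

  # switching every safety measure off reproduces base-case costs exactly
  off <- strategy_spec(safety_iron_check = FALSE, safety_iron_supplement_weeks = 0,
                       safety_liver_check = FALSE)
  tr_o <- run_cohort(params, tp, strategy = off)
  expect_equal(intervention_costs_per_cycle(tr_o, off, costing)$cost, cb$cost)
})

test_that("extra first-year courses add a course and a monitoring blood test each", {
  params <- model_parameters()
  tp <- tp_from_parameters(horizon = params$horizon)
  costing <- intervention_costing()
  multi <- strategy_spec(course_fractions = c(c1 = 1, c2 = 0.3, c3 = 0))
  tr <- run_cohort(params, tp, strategy = multi)
  cc <- intervention_costs_per_cycle(tr, multi, costing)
  e0 <- params$cohort_size / 3
  expect_equal(cc$cost[1],
               params$cohort_size * 65.63 + e0 * 1.3 * 570.95 + e0 * 0.3 * 65.63,
               tolerance = 1e-9)
})

test_that("scenario strategies apply horizon and discounting overrides", {
  sc1 <- scenario_strategy("1")
  expect_equal(sc1$horizon, 10L)
  sc3 <- scenario_strategy("3")
  expect_equal(sc3$rates$costs, 0)
  expect_equal(sc3$rates$effects, 0.015)
  expect_error(scenario_strategy("nope"), "Unknown scenario")
})
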