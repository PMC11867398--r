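#' Default model configuration
#'
#' Bundles every model input into one nested list: structural Markov
#' parameters, survival parameters (synthetic defaults unless real fitted
#' values are supplied), costs, utilities, productivity inputs, programme
#' unit costs, discount rates and the strategy.
#'
#' @param strategy A `strategy_spec` for the intervention arm.
#' @return Nested configuration list.
#' @export
default_config <- function(strategy = strategy_spec()) {
  list(
    model = model_parameters(),
    survival = synthetic_survival_parameters(),
    costs = cost_inputs(),
    utilities = utility_inputs(),
    prod = productivity_inputs(),
    costing = intervention_costing(),
    rates = discount_rates(),
    strategy = strategy
  )
}

#' Run the deterministic cost-effectiveness analysis
#'
#' Converts the configured survival parameters to transition probabilities,
#' runs the standard-of-care and intervention arms of the cohort model on
#' identical parameters, and returns the incremental result.
#'
#' @param config Configuration list from [default_config()] /
#'   [read_config()].
#' @param perspective `"societal"` or `"payer"`.
#' @return A `cea_result`.
#' @examples
#' res <- run_cea()
#' glance(res)
#' @export
run_cea <- function(config = default_config(), perspective = "societal") {
  tp <- tp_from_parameters(config$survival, config$model$horizon)
  soc <- run_cohort(config$model, tp, strategy = NULL)
  int <- run_cohort(config$model, tp, strategy = config$strategy)
  ev <- function(trace) {
    evaluate_arm(trace, config$costs, config$utilities, config$prod,
                 config$costing, config$rates, perspective)
  }
  compute_icer(ev(int), ev(soc))
}

#' Run a named scenario
#'
#' Applies one row of the shipped scenario table ([scenarios()]) — strategy
#' settings plus any horizon/discounting overrides — and runs the
#' deterministic analysis.
#'
#' @param label Scenario label (`"BC"`, `"1"` ... `"25"`).
#' @param config Base configuration.
#' @param perspective `"societal"` or `"payer"`.
#' @return A `cea_result`.
#' @export
run_scenario <- function(label, config = default_config(), perspective = "societal") {
  sc <- scenario_strategy(label)
  config$strategy <- sc$strategy
  config$rates <- sc$rates
  if (!is.na(sc$horizon)) {
    config$model$horizon <- sc$horizon
  }
  run_cea(config, perspective)
}

#' Run all scenarios
#'
#' @param config Base configuration.
#' @param labels Scenario labels to run (default: all shipped rows).
#' @return Tibble: one row per scenario with `delta_c`, `delta_e`, `icer`,
#'   `dominance`.
#' @export
run_all_scenarios <- function(config = default_config(), labels = scenarios()$label) {
  purrr::map_dfr(labels, function(lb) {
    dplyr::mutate(glance(run_scenario(lb, config)), label = lb, .before = 1)
  })
}
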