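# deep-merge user values over a default nested list, preserving names of
# numeric leaf vectors (so a YAML block {meanlog: 2.1} updates one element)
merge_config <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  if (!is.list(defaults)) {
    if (is.list(user)) {
      v <- defaults
      for (nm in names(user)) v[[nm]] <- user[[nm]]
      return(v)
    }
    return(user)
  }
  out <- defaults
  for (nm in names(user)) {
    out[[nm]] <- if (nm %in% names(defaults)) merge_config(defaults[[nm]], user[[nm]]) else user[[nm]]
  }
  out
}

#' Read a model configuration from YAML
#'
#' Reads a YAML file whose blocks mirror [default_config()] (`model`,
#' `survival`, `costs`, `utilities`, `prod`, `costing`, `rates`, `strategy`)
#' and merges it over the package defaults, so a file needs to state only
#' what differs. Supplying a `survival` block is how externally fitted
#' parameters (e.g. lognormal meanlog/sdlog per lead group with their 95%
#' CIs) enter the model without refitting.
#'
#' @param path YAML file path.
#' @return Configuration list as from [default_config()].
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  if (!is.null(user$strategy)) {
    cfg$strategy <- do.call(strategy_spec, user$strategy)
    user$strategy <- NULL
  }
  merge_config(cfg, user)
}

#' Run the full analysis pipeline
#'
#' Orchestrates cohort simulation, survival fitting, the deterministic
#' cost-effectiveness analysis, sensitivity analyses, budget impact and
#' value of information, with one master seed from which each stochastic
#' stage derives its own child seed. When `fit_from_cohort` is `TRUE` a
#' synthetic cohort is simulated (or taken from `cohort`), the survival
#' models are fitted and selected, and the fitted parameters replace the
#' configured ones; otherwise the configured survival parameters are passed
#' straight through.
#'
#' @param config Configuration list.
#' @param seed Master seed.
#' @param stages Character vector out of `"cea"`, `"scenarios"`, `"dsa"`,
#'   `"psa"`, `"bia"`, `"voi"`.
#' @param n_psa PSA iterations (also feeds the VOI stage).
#' @param wtp_grid Willingness-to-pay grid for CEAC/VOI.
#' @param fit_from_cohort Simulate + fit rather than using configured
#'   survival parameters.
#' @param cohort Optional patient-level tibble to fit on.
#' @param out_dir Optional directory; when given, every stage's table is
#'   written as CSV plus a JSON run manifest.
#' @return Named list of stage results.
#' @export
run_pipeline <- function(config = default_config(), seed = 1,
                         stages = c("cea", "psa", "bia", "voi"),
                         n_psa = 1000,
                         wtp_grid = seq(0, 100000, by = 5000),
                         fit_from_cohort = FALSE, cohort = NULL,
                         out_dir = NULL) {
  results <- list()
  seeds <- list()

  if (fit_from_cohort) {
    seeds$cohort <- child_seed(seed, "cohort")
    set.seed(seeds$cohort)
    if (is.null(cohort)) cohort <- simulate_cohort(cohort_spec())
    fits <- fit_all_endpoints(cohort, horizon = config$model$horizon)
    config$survival <- list(
      gf = list(low = fits$chosen$gf_low$params,
                medium = fits$chosen$gf_medium$params,
                high = fits$chosen$gf_high$params),
      gf_se = list(low = fits$chosen$gf_low$se,
                   medium = fits$chosen$gf_medium$se,
                   high = fits$chosen$gf_high$se),
      dwfg = fits$chosen$dwfg$params, dwfg_se = fits$chosen$dwfg$se,
      dwgf = fits$chosen$dwgf$params, dwgf_se = fits$chosen$dwgf$se
    )
    results$cohort <- cohort
    results$fits <- fits$fits
  }

  if ("cea" %in% stages) results$cea <- run_cea(config)
  if ("scenarios" %in% stages) results$scenarios <- run_all_scenarios(config)
  if ("dsa" %in% stages) results$dsa <- run_dsa(config)
  if ("psa" %in% stages || "voi" %in% stages) {
    seeds$psa <- child_seed(seed, "psa")
    results$psa <- run_psa(config, n_iter = n_psa, seed = seeds$psa)
    results$ceac <- ceac(results$psa, wtp_grid)
  }
  if ("bia" %in% stages) results$bia <- run_bia(config = config)
  if ("voi" %in% stages) {
    seeds$voi <- child_seed(seed, "voi")
    results$voi <- voi_summary(results$psa, wtp = wtp_grid)
    results$evsi <- evsi(results$psa, seed = seeds$voi)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, name) utils::write.csv(as.data.frame(x), file.path(out_dir, name), row.names = FALSE)
    if (!is.null(results$cohort)) wr(results$cohort, "cohort.csv")
    if (!is.null(results$fits)) wr(results$fits, "fits.csv")
    if (!is.null(results$cea)) wr(tidy(results$cea), "cea.csv")
    if (!is.null(results$scenarios)) wr(results$scenarios, "scenarios.csv")
    if (!is.null(results$dsa)) wr(results$dsa$results, "dsa.csv")
    if (!is.null(results$psa)) wr(results$psa$samples, "psa.csv")
    if (!is.null(results$ceac)) wr(results$ceac, "ceac.csv")
    if (!is.null(results$bia)) wr(results$bia$by_year, "bia.csv")
    if (!is.null(results$voi)) wr(results$voi, "voi.csv")
    if (!is.null(results$evsi)) wr(results$evsi, "evsi.csv")
    manifest <- list(
      package_version = as.character(utils::packageVersion("leadcea")),
      master_seed = seed, child_seeds = seeds,
      stages = stages, n_psa = n_psa,
      config_hash = rlang::hash(config),
      timestamp = format(Sys.time(), tz = "UTC")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  results
}
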