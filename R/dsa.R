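# --- parameter registry ----------------------------------------------------
#
# One table drives both the deterministic (DSA) and probabilistic (PSA)
# sensitivity analyses: each row names a scalar model input, where it lives
# in the configuration list, its base value, its 95% CI (printed ranges where
# the sources give them; otherwise a standard error of 25% of the value), and
# the distribution family used for probabilistic draws (beta for utilities
# and employment shares, gamma for costs, normal for counts, probabilities
# and survival parameters).

registry_row <- function(name, path, base, low = NA, high = NA,
                         dist = c("gamma", "beta", "normal"), group = "other") {
  dist <- match.arg(dist)
  if (is.na(low) || is.na(high)) {
    se <- 0.25 * abs(base)
    low <- base - 1.96 * se
    high <- base + 1.96 * se
    if (dist %in% c("beta")) { low <- max(low, 0); high <- min(high, 1) }
    if (dist == "gamma") low <- max(low, 0)
  }
  tibble::tibble(name = name, path = list(path), base = base,
                 low = low, high = high, dist = dist, group = group)
}

#' Sensitivity-analysis parameter registry
#'
#' @param config Configuration list; bases and survival CIs are read from it.
#' @return Tibble with one row per varied parameter: `name`, `path` (position
#'   in the configuration), `base`, `low`, `high` (95% CI), `dist` (PSA
#'   family) and `group` (used to define value-of-information subsets:
#'   `tp_gf`, `tp_death`, `cost`, `utility`, `productivity`, `programme`,
#'   `probability`, `other`).
#' @export
parameter_registry <- function(config = default_config()) {
  sv <- config$survival
  r <- list(
    # programme unit costs
    registry_row("cost_blood_draw", c("costing", "blood_draw"), config$costing$blood_draw, 7.65, 22.35, "gamma", "programme"),
    registry_row("cost_lead_lab", c("costing", "lead_lab"), config$costing$lead_lab, 25.82, 75.43, "gamma", "programme"),
    registry_row("cost_iron_lab", c("costing", "iron_lab"), config$costing$iron_lab, 13.46, 39.32, "gamma", "programme"),
    registry_row("cost_ast_alt_lab", c("costing", "ast_alt_lab"), config$costing$ast_alt_lab, 2.74, 8.02, "gamma", "programme"),
    registry_row("cost_dmsa_course", c("costing", "dmsa_course"), config$costing$dmsa_course, 291.18, 850.72, "gamma", "programme"),
    registry_row("cost_iron_supplement", c("costing", "iron_supplement"), config$costing$iron_supplement, 23.70, 69.26, "gamma", "programme"),
    # health-state costs
    registry_row("cost_gf_initial", c("costs", "gf_initial"), config$costs$gf_initial, 1437.59, 4200.01, "gamma", "cost"),
    registry_row("cost_chd", c("costs", "dialysis_annual", "CHD"), config$costs$dialysis_annual[["CHD"]], 61662.98, 164621.94, "gamma", "cost"),
    registry_row("cost_hhd", c("costs", "dialysis_annual", "HHD"), config$costs$dialysis_annual[["HHD"]], 76059.79, 136628.39, "gamma", "cost"),
    registry_row("cost_apd", c("costs", "dialysis_annual", "APD"), config$costs$dialysis_annual[["APD"]], 64633.50, 155093.72, "gamma", "cost"),
    registry_row("cost_capd", c("costs", "dialysis_annual", "CAPD"), config$costs$dialysis_annual[["CAPD"]], 29540.82, 159973.05, "gamma", "cost"),
    registry_row("cost_transplantation", c("costs", "transplantation"), config$costs$transplantation, 8986.50, 199000.85, "gamma", "cost"),
    registry_row("cost_transplant_upkeep", c("costs", "transplant_upkeep_annual"), config$costs$transplant_upkeep_annual, 7332.26, 21421.70, "gamma", "cost"),
    registry_row("cost_death", c("costs", "death_oneoff"), config$costs$death_oneoff, 709.93, 2074.12, "gamma", "cost"),
    # utilities
    registry_row("utility_fg", c("utilities", "u_fg"), config$utilities$u_fg, 0.72, 0.90, "beta", "utility"),
    registry_row("utility_hd", c("utilities", "u_hd"), config$utilities$u_hd, 0.49, 0.62, "beta", "utility"),
    registry_row("utility_pd", c("utilities", "u_pd"), config$utilities$u_pd, 0.50, 0.67, "beta", "utility"),
    # productivity
    registry_row("work_posttx_45_54", c("prod", "work_posttx", "a45_54"), config$prod$work_posttx[["a45_54"]], 0.291, 0.849, "beta", "productivity"),
    registry_row("work_posttx_55_64", c("prod", "work_posttx", "a55_64"), config$prod$work_posttx[["a55_64"]], 0.209, 0.611, "beta", "productivity"),
    registry_row("work_posttx_65plus", c("prod", "work_posttx", "a65plus"), config$prod$work_posttx[["a65plus"]], 0.031, 0.091, "beta", "productivity"),
    registry_row("work_dialysis_45_54", c("prod", "work_dialysis", "a45_54"), config$prod$work_dialysis[["a45_54"]], 0.163, 0.477, "beta", "productivity"),
    registry_row("work_dialysis_55_64", c("prod", "work_dialysis", "a55_64"), config$prod$work_dialysis[["a55_64"]], 0.097, 0.283, "beta", "productivity"),
    registry_row("work_dialysis_65plus", c("prod", "work_dialysis", "a65plus"), config$prod$work_dialysis[["a65plus"]], 0.014, 0.042, "beta", "productivity"),
    registry_row("hospital_days_living", c("prod", "hospital_days", "living"), config$prod$hospital_days[["living"]], 6.78, 19.82, "normal", "productivity"),
    registry_row("hospital_days_deceased", c("prod", "hospital_days", "deceased"), config$prod$hospital_days[["deceased"]], 3.98, 11.62, "normal", "productivity"),
    registry_row("friction_days", c("prod", "friction_days"), config$prod$friction_days, 43.35, 126.65, "normal", "productivity"),
    registry_row("hours_per_day", c("prod", "hours_per_day"), config$prod$hours_per_day, 4.08, 11.92, "normal", "productivity"),
    registry_row("wage_male", c("prod", "wage_male"), config$prod$wage_male, 23.47, 68.57, "gamma", "productivity"),
    registry_row("wage_female", c("prod", "wage_female"), config$prod$wage_female, 19.57, 57.17, "gamma", "productivity"),
    # probabilities and counts
    registry_row("p_retransplant", c("model", "p_retransplant_base"), config$model$p_retransplant_base, NA, NA, "normal", "probability"),
    registry_row("p_primary_nonfunction", c("model", "p_primary_nonfunction"), config$model$p_primary_nonfunction, 0.004, 0.010, "normal", "probability"),
    registry_row("repeated_fraction_year2", c("strategy", "repeated_fraction_year2"), config$strategy$repeated_fraction_year2, NA, NA, "normal", "programme"),
    # discount rates (deterministic ranges only; held fixed in PSA)
    registry_row("discount_costs", c("rates", "costs"), config$rates$costs, 0.0, 0.08, "normal", "discount"),
    registry_row("discount_effects", c("rates", "effects"), config$rates$effects, 0.0, 0.03, "normal", "discount"),
    # survival parameters: normal on the estimate with the reported SE
    registry_row("gf_meanlog_low", c("survival", "gf", "low", "meanlog"), sv$gf$low[["meanlog"]],
                 sv$gf$low[["meanlog"]] - 1.96 * sv$gf_se$low[["meanlog"]],
                 sv$gf$low[["meanlog"]] + 1.96 * sv$gf_se$low[["meanlog"]], "normal", "tp_gf"),
    registry_row("gf_sdlog_low", c("survival", "gf", "low", "sdlog"), sv$gf$low[["sdlog"]],
                 sv$gf$low[["sdlog"]] - 1.96 * sv$gf_se$low[["sdlog"]],
                 sv$gf$low[["sdlog"]] + 1.96 * sv$gf_se$low[["sdlog"]], "normal", "tp_gf"),
    registry_row("gf_meanlog_medium", c("survival", "gf", "medium", "meanlog"), sv$gf$medium[["meanlog"]],
                 sv$gf$medium[["meanlog"]] - 1.96 * sv$gf_se$medium[["meanlog"]],
                 sv$gf$medium[["meanlog"]] + 1.96 * sv$gf_se$medium[["meanlog"]], "normal", "tp_gf"),
    registry_row("gf_sdlog_medium", c("survival", "gf", "medium", "sdlog"), sv$gf$medium[["sdlog"]],
                 sv$gf$medium[["sdlog"]] - 1.96 * sv$gf_se$medium[["sdlog"]],
                 sv$gf$medium[["sdlog"]] + 1.96 * sv$gf_se$medium[["sdlog"]], "normal", "tp_gf"),
    registry_row("gf_meanlog_high", c("survival", "gf", "high", "meanlog"), sv$gf$high[["meanlog"]],
                 sv$gf$high[["meanlog"]] - 1.96 * sv$gf_se$high[["meanlog"]],
                 sv$gf$high[["meanlog"]] + 1.96 * sv$gf_se$high[["meanlog"]], "normal", "tp_gf"),
    registry_row("gf_sdlog_high", c("survival", "gf", "high", "sdlog"), sv$gf$high[["sdlog"]],
                 sv$gf$high[["sdlog"]] - 1.96 * sv$gf_se$high[["sdlog"]],
                 sv$gf$high[["sdlog"]] + 1.96 * sv$gf_se$high[["sdlog"]], "normal", "tp_gf"),
    registry_row("dwfg_shape", c("survival", "dwfg", "shape"), sv$dwfg[["shape"]],
                 sv$dwfg[["shape"]] - 1.96 * sv$dwfg_se[["shape"]],
                 sv$dwfg[["shape"]] + 1.96 * sv$dwfg_se[["shape"]], "normal", "tp_death"),
    registry_row("dwfg_rate", c("survival", "dwfg", "rate"), sv$dwfg[["rate"]],
                 sv$dwfg[["rate"]] - 1.96 * sv$dwfg_se[["rate"]],
                 sv$dwfg[["rate"]] + 1.96 * sv$dwfg_se[["rate"]], "normal", "tp_death"),
    registry_row("dwgf_shape", c("survival", "dwgf", "shape"), sv$dwgf[["shape"]],
                 sv$dwgf[["shape"]] - 1.96 * sv$dwgf_se[["shape"]],
                 sv$dwgf[["shape"]] + 1.96 * sv$dwgf_se[["shape"]], "normal", "tp_death"),
    registry_row("dwgf_rate", c("survival", "dwgf", "rate"), sv$dwgf[["rate"]],
                 sv$dwgf[["rate"]] - 1.96 * sv$dwgf_se[["rate"]],
                 sv$dwgf[["rate"]] + 1.96 * sv$dwgf_se[["rate"]], "normal", "tp_death")
  )
  dplyr::bind_rows(r)
}

# set one scalar leaf of the configuration list (base recursive indexing
# keeps this cheap inside the Monte Carlo loop)
set_config_value <- function(config, path, value) {
  config[[path]] <- value
  config
}

get_config_value <- function(config, path) {
  config[[path]]
}

#' Univariate deterministic sensitivity analysis
#'
#' Varies each registered parameter in turn to the bounds of its 95% CI
#' (unavailable CIs use a standard error of 25% of the value), re-runs the
#' deterministic model and records incremental costs and effects. The DMSA
#' capsule price is additionally varied to half and twice its base value.
#' Parameters are ranked by output swing for the tornado diagram.
#'
#' @param config Base configuration.
#' @param registry Parameter table, defaults to [parameter_registry()].
#' @param perspective `"societal"` or `"payer"`.
#' @return Object of class `dsa_result`: tibble with one row per parameter
#'   and bound (`name`, `bound`, `value`, `delta_c`, `delta_e`) plus the base
#'   result, with swing-ranked parameter ordering in `ranking`.
#' @export
run_dsa <- function(config = default_config(),
                    registry = parameter_registry(config),
                    perspective = "societal") {
  base_res <- glance(run_cea(config, perspective))
  extra <- registry[registry$name == "cost_dmsa_course", ]
  if (nrow(extra) == 1) {
    extra$name <- "cost_dmsa_course_price_shock"
    extra$low <- 0.5 * extra$base
    extra$high <- 2 * extra$base
    registry <- dplyr::bind_rows(registry, extra)
  }

  rows <- purrr::pmap_dfr(registry, function(name, path, base, low, high, dist, group) {
    purrr::map_dfr(c(low = low, high = high), function(v) {
      cfg <- set_config_value(config, path, v)
      d <- fast_cea_deltas(cfg, perspective)
      tibble::tibble(value = v, delta_c = d[["delta_c"]], delta_e = d[["delta_e"]])
    }, .id = "bound") |>
      dplyr::mutate(name = name, group = group, .before = 1)
  })

  ranking <- rows |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(
      swing_c = diff(range(.data$delta_c)),
      swing_e = diff(range(.data$delta_e)),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$swing_c))

  structure(list(results = rows, ranking = ranking, base = base_res,
                 perspective = perspective),
            class = "dsa_result")
}

#' @export
print.dsa_result <- function(x, ...) {
  cat(sprintf("<dsa_result> %d parameters; base dC = %.0f, dE = %.2f\n",
              nrow(x$ranking), x$base$delta_c, x$base$delta_e))
  print(utils::head(x$ranking, 5))
  invisible(x)
}
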