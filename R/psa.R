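# beta hyperparameters matched to a mean and a CI-implied variance
beta_moments <- function(mean, sd, name = "parameter") {
  v <- sd^2
  if (v <= 0) return(c(shape1 = Inf, shape2 = Inf))
  if (v >= mean * (1 - mean)) {
    abort(sprintf("Infeasible beta moment match for '%s' (variance too large).", name))
  }
  nu <- mean * (1 - mean) / v - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

# gamma hyperparameters matched to a mean and variance
gamma_moments <- function(mean, sd, name = "parameter") {
  v <- sd^2
  if (mean <= 0) abort(sprintf("Gamma moment match needs a positive mean for '%s'.", name))
  if (v <= 0) return(c(shape = Inf, rate = Inf))
  c(shape = mean^2 / v, rate = mean / v)
}

# one vector of n draws for a registry row; clips normal draws for
# probabilities/[0,1] fractions to feasibility and counts clips
draw_parameter <- function(n, name, base, low, high, dist, group, sd_scale = 1) {
  sd <- sd_scale * (high - low) / (2 * 1.96)
  if (sd == 0) return(list(draws = rep(base, n), clipped = 0L))
  clipped <- 0L
  draws <- switch(dist,
    beta = {
      hp <- beta_moments(base, sd, name)
      if (!is.finite(hp[1])) rep(base, n) else rbeta(n, hp[1], hp[2])
    },
    gamma = {
      hp <- gamma_moments(base, sd, name)
      if (!is.finite(hp[1])) rep(base, n) else rgamma(n, shape = hp[1], rate = hp[2])
    },
    normal = {
      x <- rnorm(n, base, sd)
      if (group %in% c("probability", "programme")) {
        clipped <- sum(x < 0 | x > 1)
        x <- pmin(pmax(x, 0), 1)
      } else if (grepl("sdlog|shape|rate|days|hours", name)) {
        clipped <- sum(x < 1e-6)
        x <- pmax(x, 1e-6)
      }
      x
    }
  )
  list(draws = draws, clipped = clipped)
}

#' Draw a probabilistic-sensitivity-analysis sample
#'
#' Samples every registered parameter from its assigned distribution (beta
#' for utilities and employment shares, gamma for costs, normal for counts,
#' probabilities and survival parameters, the latter parameterised by their
#' 95% CIs), by independent moment-matched draws. Discount rates are held at
#' base values. Normal draws of probabilities are clipped to [0, 1] and
#' positive-support quantities to a small positive floor; the clip count is
#' recorded.
#'
#' @param config Base configuration.
#' @param n_iter Number of iterations.
#' @param registry Parameter table from [parameter_registry()].
#' @param sd_scale Multiplier on every parameter's standard error (0 gives
#'   degenerate distributions reproducing the deterministic result).
#' @return Tibble of draws, one row per iteration, plus a `clipped`
#'   attribute naming clip counts.
#' @export
draw_psa <- function(config = default_config(), n_iter = 1000,
                     registry = parameter_registry(config), sd_scale = 1) {
  registry <- registry[registry$group != "discount", ]
  out <- vector("list", nrow(registry))
  clips <- integer(nrow(registry))
  for (i in seq_len(nrow(registry))) {
    row <- registry[i, ]
    d <- draw_parameter(n_iter, row$name, row$base, row$low, row$high,
                        row$dist, row$group, sd_scale)
    out[[i]] <- d$draws
    clips[i] <- d$clipped
  }
  names(out) <- registry$name
  draws <- tibble::as_tibble(out)
  attr(draws, "clipped") <- setNames(clips, registry$name)
  draws
}

#' Run the probabilistic sensitivity analysis
#'
#' Propagates each joint parameter draw through both model arms (the same
#' draw feeds both arms) and records incremental costs and effects per
#' iteration.
#'
#' @param config Base configuration.
#' @param n_iter Number of Monte Carlo iterations (the reference analysis
#'   uses 10,000).
#' @param seed Integer seed; the sample is reproducible bitwise.
#' @param registry Parameter table.
#' @param sd_scale Multiplier on parameter uncertainty (see [draw_psa()]).
#' @param perspective `"societal"` or `"payer"`.
#' @return Object of class `psa_result`: `samples` tibble (draws plus
#'   `delta_c`, `delta_e`), `registry`, `cohort_size`, base-case `base`.
#' @export
run_psa <- function(config = default_config(), n_iter = 1000, seed = 1,
                    registry = parameter_registry(config), sd_scale = 1,
                    perspective = "societal") {
  set.seed(seed)
  registry_used <- registry[registry$group != "discount", ]
  draws <- draw_psa(config, n_iter, registry, sd_scale)
  dc <- numeric(n_iter); de <- numeric(n_iter)
  for (j in seq_len(n_iter)) {
    cfg <- config
    for (i in seq_len(nrow(registry_used))) {
      cfg <- set_config_value(cfg, registry_used$path[[i]], draws[[registry_used$name[i]]][j])
    }
    d <- fast_cea_deltas(cfg, perspective)
    dc[j] <- d[["delta_c"]]
    de[j] <- d[["delta_e"]]
  }
  samples <- dplyr::mutate(draws, delta_c = dc, delta_e = de)
  structure(list(samples = samples, registry = registry_used,
                 cohort_size = config$model$cohort_size,
                 base = glance(run_cea(config, perspective)),
                 seed = seed, perspective = perspective),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations; mean dC = %.0f, mean dE = %.2f\n",
              nrow(x$samples), mean(x$samples$delta_c), mean(x$samples$delta_e)))
  invisible(x)
}

#' @export
tidy.psa_result <- function(x, ...) {
  dplyr::select(x$samples, dplyr::all_of(c("delta_c", "delta_e")))
}

#' @export
glance.psa_result <- function(x, wtp = 50000, ...) {
  tibble::tibble(
    n_iter = nrow(x$samples),
    mean_delta_c = mean(x$samples$delta_c),
    mean_delta_e = mean(x$samples$delta_e),
    p_ce_at_wtp = mean(wtp * x$samples$delta_e - x$samples$delta_c > 0),
    wtp = wtp
  )
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA iterations with positive net monetary benefit
#' `wtp * dE - dC` at each willingness-to-pay value.
#'
#' @param psa A `psa_result` (or a tibble with `delta_c`, `delta_e`).
#' @param wtp Numeric grid of willingness-to-pay thresholds (EUR/QALY).
#' @return Tibble of class `ceac_curve` with `wtp` and `probability`.
#' @export
ceac <- function(psa, wtp = seq(0, 100000, by = 5000)) {
  s <- if (inherits(psa, "psa_result")) psa$samples else psa
  if (!nrow(s)) abort("Empty PSA sample.")
  probability <- purrr::map_dbl(wtp, ~ mean(.x * s$delta_e - s$delta_c > 0))
  out <- tibble::tibble(wtp = wtp, probability = probability)
  class(out) <- c("ceac_curve", class(out))
  out
}
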