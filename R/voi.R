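# incremental net monetary benefit per iteration, full cohort scale
inb_samples <- function(psa, wtp) {
  wtp * psa$samples$delta_e - psa$samples$delta_c
}

# value of eliminating (part of) the uncertainty, from per-iteration values
# of the incremental net benefit (two decision options: adopt or not)
voi_from_inb <- function(inb) {
  mean(pmax(inb, 0)) - max(mean(inb), 0)
}

#' Expected value of perfect information
#'
#' Two-option EVPI from the PSA sample at one or more willingness-to-pay
#' values: the mean of the per-iteration best net benefit minus the best of
#' the mean net benefits, expressed per recipient by dividing by the cohort
#' size.
#'
#' @param psa A `psa_result`.
#' @param wtp Willingness-to-pay value(s), EUR/QALY.
#' @param per_ktr Divide by the modelled cohort size (default TRUE).
#' @return Tibble with `wtp` and `evpi`.
#' @export
evpi <- function(psa, wtp = 50000, per_ktr = TRUE) {
  scale <- if (per_ktr) psa$cohort_size else 1
  tibble::tibble(
    wtp = wtp,
    evpi = purrr::map_dbl(wtp, ~ voi_from_inb(inb_samples(psa, .x)) / scale)
  )
}

#' Resolve a value-of-information parameter subset
#'
#' Named subsets map onto the registry's parameter groups: `"tp_all"` (all
#' survival parameters), `"tp_gf_all"` (graft-failure parameters, all
#' groups), `"tp_gf_medium_high"` (graft-failure parameters of the medium and
#' high groups), `"gf_meanlogs_medium_high"` (the two meanlogs targeted by a
#' prospective study), `"all"` (every sampled parameter).
#'
#' @param psa A `psa_result`.
#' @param subset Subset name or an explicit character vector of parameter
#'   names.
#' @return Character vector of parameter (column) names.
#' @export
voi_subset <- function(psa, subset) {
  reg <- psa$registry
  if (length(subset) > 1 || !subset %in%
      c("tp_all", "tp_gf_all", "tp_gf_medium_high", "gf_meanlogs_medium_high", "all")) {
    missing <- setdiff(subset, reg$name)
    if (length(missing)) abort(sprintf("Unknown parameter(s): %s", paste(missing, collapse = ", ")))
    return(subset)
  }
  switch(subset,
    tp_all = reg$name[reg$group %in% c("tp_gf", "tp_death")],
    tp_gf_all = reg$name[reg$group == "tp_gf"],
    tp_gf_medium_high = grep("_(medium|high)$", reg$name[reg$group == "tp_gf"], value = TRUE),
    gf_meanlogs_medium_high = c("gf_meanlog_medium", "gf_meanlog_high"),
    all = reg$name
  )
}

# single-loop nonparametric-regression EVPPI/EVSI core: regress the
# incremental net benefit on conditioning variables with a GAM smoother and
# evaluate the value of knowing the fitted conditional mean
voi_regression <- function(inb, X, k = 4) {
  X <- as.data.frame(X)
  keep <- vapply(X, function(col) sd(col) > 1e-12, logical(1))
  if (!any(keep)) return(0)
  X <- X[, keep, drop = FALSE]
  names(X) <- paste0("x", seq_along(X))
  dat <- cbind(data.frame(.inb = inb), X)
  terms <- paste(sprintf("s(%s, k = %d)", names(X), k), collapse = " + ")
  fit <- mgcv::gam(stats::as.formula(paste(".inb ~", terms)), data = dat)
  g <- fitted(fit)
  max(mean(pmax(g, 0)) - max(mean(g), 0), 0)
}

#' Expected value of partial perfect information
#'
#' Single-loop regression estimator: the incremental net benefit is
#' regressed on the subset's parameter draws with a spline smoother
#' ([mgcv::gam()]); the EVPPI is the value of knowing the fitted conditional
#' mean. Non-negative by construction and bounded above by the EVPI up to
#' estimator error.
#'
#' @param psa A `psa_result` (draws stored per iteration).
#' @param subset Subset name or parameter names (see [voi_subset()]).
#' @param wtp Willingness-to-pay value(s).
#' @param per_ktr Express per recipient (default TRUE).
#' @param k Spline basis dimension per parameter.
#' @return Tibble with `wtp`, `subset`, `evppi`.
#' @export
evppi <- function(psa, subset = "tp_all", wtp = 50000, per_ktr = TRUE, k = 4) {
  nm <- voi_subset(psa, subset)
  scale <- if (per_ktr) psa$cohort_size else 1
  X <- psa$samples[, nm, drop = FALSE]
  tibble::tibble(
    wtp = wtp,
    subset = if (length(subset) == 1) subset else "custom",
    evppi = purrr::map_dbl(wtp, function(w) {
      voi_regression(inb_samples(psa, w), X, k) / scale
    })
  )
}

#' Expected value of sample information
#'
#' Regression-on-summary-statistics estimator: for each PSA iteration a
#' prospective follow-up study of `n` recipients is simulated from that
#' iteration's target parameters (lognormal graft-failure times in the
#' medium and high lead groups, administratively censored), reduced to
#' per-group summary statistics (mean log event time, event fraction), and
#' the incremental net benefit is regressed on those summaries. EVSI is the
#' value of knowing the fitted conditional mean; it is 0 at `n = 0` and, as
#' `n` grows, approaches the EVPPI of the parameter set the data inform —
#' censored event times carry information on both the meanlog and sdlog of
#' the sampled groups, so the bound is the EVPPI of all medium/high
#' graft-failure parameters.
#'
#' @param psa A `psa_result`.
#' @param sample_sizes Study sizes to evaluate (per group), e.g.
#'   `c(0, 100, 500, 1000)`.
#' @param wtp Willingness to pay (scalar).
#' @param target Parameter subset the study informs (default the medium- and
#'   high-group graft-failure meanlogs).
#' @param followup Study follow-up (years) for administrative censoring.
#' @param per_ktr Express per recipient.
#' @param seed Seed for the simulated study data.
#' @param k Spline basis dimension.
#' @return Tibble with `n`, `wtp`, `evsi`.
#' @export
evsi <- function(psa, sample_sizes = c(0, 100, 500, 1000), wtp = 50000,
                 target = "gf_meanlogs_medium_high", followup = 10,
                 per_ktr = TRUE, seed = 1, k = 4) {
  nm <- voi_subset(psa, target)
  scale <- if (per_ktr) psa$cohort_size else 1
  inb <- inb_samples(psa, wtp)
  n_iter <- nrow(psa$samples)
  set.seed(seed)

  sdlogs <- list(gf_meanlog_medium = "gf_sdlog_medium", gf_meanlog_high = "gf_sdlog_high")
  out <- purrr::map_dfr(sample_sizes, function(n) {
    if (n == 0) return(tibble::tibble(n = 0, wtp = wtp, evsi = 0))
    stats_mat <- matrix(0, n_iter, 2 * length(nm))
    col <- 1
    for (p in nm) {
      ml <- psa$samples[[p]]
      sl_name <- sdlogs[[p]]
      sl <- if (!is.null(sl_name) && sl_name %in% names(psa$samples)) {
        psa$samples[[sl_name]]
      } else rep(1, n_iter)
      for (j in seq_len(n_iter)) {
        t_lat <- rlnorm(n, ml[j], sl[j])
        ev <- t_lat <= followup
        t_obs <- pmin(t_lat, followup)
        stats_mat[j, col] <- mean(log(pmax(t_obs, 1e-8)))
        stats_mat[j, col + 1] <- mean(ev)
      }
      col <- col + 2
    }
    tibble::tibble(n = n, wtp = wtp,
                   evsi = voi_regression(inb, stats_mat, k) / scale)
  })
  out
}

#' Value-of-information summary across willingness to pay
#'
#' EVPI and EVPPI for the standard subsets over a WTP grid, in one tidy
#' table.
#'
#' @param psa A `psa_result`.
#' @param wtp WTP grid.
#' @param subsets Subset names to evaluate.
#' @return Tibble with `wtp`, `measure`, `subset`, `value` (EUR per
#'   recipient).
#' @export
voi_summary <- function(psa, wtp = seq(0, 100000, by = 10000),
                        subsets = c("tp_all", "tp_gf_all", "tp_gf_medium_high")) {
  ev <- evpi(psa, wtp) |>
    dplyr::transmute(wtp = .data$wtp, measure = "evpi", subset = "all", value = .data$evpi)
  pp <- purrr::map_dfr(subsets, function(s) {
    evppi(psa, s, wtp) |>
      dplyr::transmute(wtp = .data$wtp, measure = "evppi", subset = s, value = .data$evppi)
  })
  dplyr::bind_rows(ev, pp)
}
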