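#' Specify a synthetic kidney-transplant cohort
#'
#' Describes the statistical structure of the simulated transplant cohort:
#' the plasma-lead distribution (lognormal, moment-matched to a target median
#' and interquartile range), the tertile boundaries used to trichotomise lead,
#' and the generating time-to-event distributions for graft failure (GF,
#' lognormal per lead group), death with functioning graft (DWFG, gamma) and
#' death with graft failure (DwGF, gamma). Defaults emulate a single-centre
#' cohort of 670 recipients with a lead median of 0.31 ug/L (IQR 0.22-0.45)
#' and roughly ten years of administrative follow-up.
#'
#' @param n_patients Number of subjects to simulate.
#' @param lead_median Target median plasma lead, ug/L.
#' @param lead_iqr Length-2 numeric, target 25th and 75th lead percentiles.
#' @param tertile_boundaries Length-2 increasing numeric: leads at or below
#'   the first boundary are "low", above the second are "high". The upper
#'   default is the 0.38 ug/L intervention threshold; the lower default is the
#'   33.3rd percentile of the lead distribution so each group holds about a
#'   third of the cohort. Use `NULL` to recompute the lower boundary from the
#'   lead distribution.
#' @param gf_params Named list `low`/`medium`/`high`, each `c(meanlog, sdlog)`
#'   of the lognormal time (years) to graft failure.
#' @param dwfg_params `c(shape, rate)` of the gamma time to death with
#'   functioning graft, fitted on the whole cohort.
#' @param dwgf_params `c(shape, rate)` of the gamma time to death after graft
#'   failure.
#' @param max_followup Administrative censoring horizon in years.
#' @return A list of class `cohort_spec`.
#' @seealso [simulate_cohort()], [generate_leads()], [trichotomize()]
#' @export
cohort_spec <- function(n_patients = 670,
                        lead_median = 0.31,
                        lead_iqr = c(0.22, 0.45),
                        tertile_boundaries = NULL,
                        gf_params = synthetic_survival_parameters()$gf,
                        dwfg_params = synthetic_survival_parameters()$dwfg,
                        dwgf_params = synthetic_survival_parameters()$dwgf,
                        max_followup = 10) {
  if (!is_number(n_patients) || n_patients < 1) abort("`n_patients` must be a positive count.")
  assert_positive(lead_median, "lead_median")
  if (length(lead_iqr) != 2 || any(!is.finite(lead_iqr)) || any(lead_iqr <= 0)) {
    abort("`lead_iqr` must be two positive numbers.")
  }
  if (lead_iqr[1] > lead_iqr[2]) abort("`lead_iqr` must be non-decreasing.")
  assert_positive(max_followup, "max_followup", strict = FALSE)
  for (g in c("low", "medium", "high")) {
    p <- gf_params[[g]]
    if (is.null(p) || length(p) != 2 || p[2] < 0) abort("`gf_params` needs (meanlog, sdlog >= 0) per group.")
  }
  assert_positive(dwfg_params, "dwfg_params")
  assert_positive(dwgf_params, "dwgf_params")

  lead <- lead_lognormal_parameters(lead_median, lead_iqr)
  if (is.null(tertile_boundaries)) {
    b2 <- 0.38
    b1 <- if (lead[["sdlog"]] > 0) qlnorm(1 / 3, lead[["meanlog"]], lead[["sdlog"]]) else lead_median
    tertile_boundaries <- c(b1, b2)
  }
  if (length(tertile_boundaries) != 2 || diff(tertile_boundaries) <= 0) {
    abort("`tertile_boundaries` must be strictly increasing.")
  }

  structure(
    list(
      n_patients = as.integer(n_patients),
      lead_median = lead_median,
      lead_iqr = lead_iqr,
      lead_meanlog = lead[["meanlog"]],
      lead_sdlog = lead[["sdlog"]],
      tertile_boundaries = tertile_boundaries,
      gf_params = gf_params[c("low", "medium", "high")],
      dwfg_params = dwfg_params,
      dwgf_params = dwgf_params,
      max_followup = max_followup
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> n = %d, lead median %.2f ug/L (IQR %.2f-%.2f), tertile boundaries %.3f / %.3f, follow-up %g y\n",
    x$n_patients, x$lead_median, x$lead_iqr[1], x$lead_iqr[2],
    x$tertile_boundaries[1], x$tertile_boundaries[2], x$max_followup
  ))
  invisible(x)
}

#' Lognormal parameters matched to a median and IQR
#'
#' Solves the lognormal `(meanlog, sdlog)` so that the theoretical median
#' equals the target and the theoretical quartile ratio `q75/q25` equals the
#' target ratio: `meanlog = log(median)` and
#' `sdlog = log(q75/q25) / (2 * qnorm(0.75))`, from the probit relation
#' `log q_p = meanlog + sdlog * qnorm(p)`. A collapsed IQR gives `sdlog = 0`
#' (a point mass at the median).
#'
#' @param median Target median (> 0).
#' @param iqr Length-2 target quartiles, both > 0.
#' @return Named numeric `c(meanlog, sdlog)`.
#' @export
lead_lognormal_parameters <- function(median, iqr) {
  if (any(iqr <= 0)) abort("IQR bounds must be positive.")
  sdlog <- log(iqr[2] / iqr[1]) / (2 * qnorm(0.75))
  c(meanlog = log(median), sdlog = sdlog)
}

#' Draw plasma-lead concentrations
#'
#' Samples lead values from the moment-matched lognormal distribution of a
#' [cohort_spec()]. With a collapsed IQR the distribution degenerates to the
#' median.
#'
#' @param spec A `cohort_spec`.
#' @param n Number of draws; defaults to `spec$n_patients`.
#' @return Numeric vector of strictly positive lead concentrations (ug/L).
#' @export
generate_leads <- function(spec, n = spec$n_patients) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$lead_sdlog == 0) return(rep(spec$lead_median, n))
  rlnorm(n, spec$lead_meanlog, spec$lead_sdlog)
}

#' Assign lead tertile groups
#'
#' Closed-upper convention: `lead <= b1` is "low", `b1 < lead <= b2` is
#' "medium", `lead > b2` is "high". With the default boundaries a lead of
#' exactly 0.38 ug/L is medium and anything above is high (and eligible for
#' chelation).
#'
#' @param leads Numeric vector of lead concentrations, ug/L.
#' @param boundaries Length-2 strictly increasing numeric `(b1, b2)`.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
trichotomize <- function(leads, boundaries) {
  if (length(boundaries) != 2 || diff(boundaries) <= 0) {
    abort("`boundaries` must be strictly increasing.")
  }
  cut(leads,
    breaks = c(-Inf, boundaries, Inf),
    labels = c("low", "medium", "high"),
    right = TRUE
  )
}

#' Simulate patient-level event histories
#'
#' Draws, for each subject, independent latent times to graft failure (from
#' the lead group's lognormal), death with functioning graft and death with
#' graft failure (cohort-level gammas), each administratively censored at
#' `spec$max_followup` years. The three endpoints are generated independently
#' because the downstream survival models fit each endpoint separately.
#'
#' @param spec A `cohort_spec`.
#' @param leads Optional lead vector; drawn via [generate_leads()] if omitted.
#' @param groups Optional group factor; computed via [trichotomize()] if
#'   omitted.
#' @return A tibble with one row per patient: `lead`, `group`, and
#'   `time_*`/`event_*` pairs for `gf`, `dwfg`, `dwgf`.
#' @examples
#' spec <- cohort_spec(n_patients = 100)
#' set.seed(1)
#' cohort <- simulate_cohort(spec)
#' @export
simulate_cohort <- function(spec, leads = NULL, groups = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  leads <- leads %||% generate_leads(spec)
  groups <- groups %||% trichotomize(leads, spec$tertile_boundaries)
  n <- length(leads)

  gf_latent <- numeric(n)
  for (g in c("low", "medium", "high")) {
    idx <- which(groups == g)
    p <- spec$gf_params[[g]]
    if (length(idx)) gf_latent[idx] <- rlnorm(length(idx), p[1], p[2])
  }
  dwfg_latent <- rgamma(n, shape = spec$dwfg_params[1], rate = spec$dwfg_params[2])
  dwgf_latent <- rgamma(n, shape = spec$dwgf_params[1], rate = spec$dwgf_params[2])

  censor <- function(t) {
    event <- t <= spec$max_followup
    list(time = pmin(t, spec$max_followup), event = event)
  }
  gf <- censor(gf_latent)
  dwfg <- censor(dwfg_latent)
  dwgf <- censor(dwgf_latent)

  tibble::tibble(
    lead = leads,
    group = groups,
    time_gf = gf$time, event_gf = gf$event,
    time_dwfg = dwfg$time, event_dwfg = dwfg$event,
    time_dwgf = dwgf$time, event_dwgf = dwgf$event
  )
}

#' Write / read a simulated cohort as CSV
#'
#' Fixed eight-column layout: `lead, group, time_gf, event_gf, time_dwfg,
#' event_dwfg, time_dwgf, event_dwgf`.
#'
#' @param cohort Tibble from [simulate_cohort()].
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` a tibble.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$group <- factor(df$group, levels = c("low", "medium", "high"))
  for (ev in c("event_gf", "event_dwfg", "event_dwgf")) df[[ev]] <- as.logical(df[[ev]])
  tibble::as_tibble(df)
}
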