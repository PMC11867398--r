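STATES <- c("FG1", "GF1", "FG2", "GF2", "Death")

#' Age-dependent retransplantation probability
#'
#' Constant at the base probability up to the decline-start age, then linear
#' to zero at the decline-zero age, zero beyond.
#'
#' @param age Age(s) in years.
#' @param params A `model_parameters` list.
#' @return Probability vector.
#' @examples
#' p <- model_parameters()
#' retransplant_probability(60, p)    # 0.15
#' retransplant_probability(72.5, p)  # 0.075
#' retransplant_probability(80, p)    # 0
#' @export
retransplant_probability <- function(age, params = model_parameters()) {
  if (any(age < 0)) abort("`age` must be non-negative.")
  p0 <- params$p_retransplant_base
  a0 <- params$age_decline_start
  a1 <- params$age_decline_zero
  frac <- pmin(pmax((a1 - age) / (a1 - a0), 0), 1)
  p0 * frac
}

#' One-cycle transition matrix
#'
#' Builds the 5x5 row-stochastic matrix over states FG1, GF1, FG2, GF2,
#' Death for a given cycle and lead group. Death competes first: the
#' graft-failure and retransplantation probabilities are scaled by the
#' per-cycle survival probability so each row sums to one. A retransplant
#' succeeds with probability `1 - p_primary_nonfunction` (GF1 to FG2) and
#' immediately fails otherwise (GF1 to GF2). The second graft ages on its
#' own clock: `fg2_cycle` indexes the graft-failure series for FG2 occupants
#' (time since retransplantation; defaults to the calendar cycle).
#'
#' @param cycle Calendar cycle (1-based).
#' @param group Lead group of the subcohort (`"low"`, `"medium"`, `"high"`).
#' @param tp Named list of tp vectors as from [tp_from_parameters()].
#' @param params A `model_parameters` list.
#' @param fg2_cycle Graft-clock index for the FG2 row.
#' @return 5x5 matrix with rows/columns named by state.
#' @export
build_transition_matrix <- function(cycle, group, tp, params = model_parameters(),
                                    fg2_cycle = cycle) {
  if (cycle < 1 || cycle > params$horizon) abort("`cycle` outside the model horizon.")
  gf_series <- tp[[paste0("gf_", group)]]
  p_gf1 <- gf_series[cycle]
  p_gf2 <- gf_series[fg2_cycle]
  p_dwfg <- tp$dwfg[cycle]
  p_dwgf <- tp$dwgf[cycle]
  age <- params$baseline_age + cycle
  p_rtx <- retransplant_probability(age, params)
  pnf <- params$p_primary_nonfunction

  m <- matrix(0, 5, 5, dimnames = list(STATES, STATES))
  # FG1: death first, graft failure scaled by survival
  m["FG1", "Death"] <- p_dwfg
  m["FG1", "GF1"] <- (1 - p_dwfg) * p_gf1
  m["FG1", "FG1"] <- 1 - m["FG1", "Death"] - m["FG1", "GF1"]
  # GF1: death first, then retransplantation (success/primary non-function)
  m["GF1", "Death"] <- p_dwgf
  m["GF1", "FG2"] <- (1 - p_dwgf) * p_rtx * (1 - pnf)
  m["GF1", "GF2"] <- (1 - p_dwgf) * p_rtx * pnf
  m["GF1", "GF1"] <- 1 - sum(m["GF1", c("Death", "FG2", "GF2")])
  # FG2: second-graft failure on the reset clock
  m["FG2", "Death"] <- p_dwfg
  m["FG2", "GF2"] <- (1 - p_dwfg) * p_gf2
  m["FG2", "FG2"] <- 1 - m["FG2", "Death"] - m["FG2", "GF2"]
  # GF2: no further retransplantation
  m["GF2", "Death"] <- p_dwgf
  m["GF2", "GF2"] <- 1 - p_dwgf
  m["Death", "Death"] <- 1

  rs <- rowSums(m)
  if (any(abs(rs - 1) > 1e-9)) abort("Transition-matrix rows do not sum to 1.")
  m
}

# --- core engine -----------------------------------------------------------
#
# One lead-group subcohort, run as a deterministic cohort with an FG2 tunnel
# (occupancy stratified by retransplantation cycle so the second graft's
# failure probability runs on time since retransplant). `group_schedule` is a
# character vector of length `horizon` giving the group whose graft-failure
# series applies in each calendar cycle — this is how the chelation overlay
# switches treated recipients from high- to medium-group probabilities.
run_group_cohort <- function(n0, group_schedule, tp, params) {
  H <- params$horizon
  fg1 <- n0; gf1 <- 0; gf2 <- 0; dead <- 0
  fg2 <- numeric(H)  # occupancy by retransplant entry cycle

  occ <- matrix(0, H + 1, 5, dimnames = list(NULL, STATES))
  occ[1, ] <- c(fg1, 0, 0, 0, 0)
  flows <- matrix(0, H, 6, dimnames = list(NULL, c(
    "gf_events", "retransplants", "primary_nonfunction",
    "deaths", "deaths_dwfg", "deaths_dwgf"
  )))

  gf_low <- tp$gf_low; gf_med <- tp$gf_medium; gf_high <- tp$gf_high
  series_of <- function(g) switch(g, low = gf_low, medium = gf_med, high = gf_high)

  for (i in seq_len(H)) {
    p_dwfg <- tp$dwfg[i]; p_dwgf <- tp$dwgf[i]
    sgf <- series_of(group_schedule[i])
    age <- params$baseline_age + i
    p_rtx <- retransplant_probability(age, params)
    pnf <- params$p_primary_nonfunction

    # FG1
    d_fg1 <- fg1 * p_dwfg
    g_fg1 <- fg1 * (1 - p_dwfg) * sgf[i]
    # FG2 tunnel (entries at cycles e < i; graft clock s = i - e)
    ent <- seq_len(i - 1L)
    d_fg2 <- 0; g_fg2 <- 0
    if (i > 1L && any(fg2[ent] > 0)) {
      slice <- fg2[ent]
      dd <- slice * p_dwfg
      gg <- slice * (1 - p_dwfg) * sgf[i - ent]
      fg2[ent] <- slice - dd - gg
      d_fg2 <- sum(dd); g_fg2 <- sum(gg)
    }
    # GF1
    d_gf1 <- gf1 * p_dwgf
    rtx_all <- gf1 * (1 - p_dwgf) * p_rtx
    rtx_ok <- rtx_all * (1 - pnf)
    rtx_pnf <- rtx_all * pnf
    # GF2
    d_gf2 <- gf2 * p_dwgf

    fg1 <- fg1 - d_fg1 - g_fg1
    gf1 <- gf1 - d_gf1 - rtx_all + g_fg1
    fg2[i] <- rtx_ok
    gf2 <- gf2 - d_gf2 + rtx_pnf + g_fg2
    dead <- dead + d_fg1 + d_fg2 + d_gf1 + d_gf2

    occ[i + 1L, ] <- c(fg1, gf1, sum(fg2), gf2, dead)
    flows[i, ] <- c(
      g_fg1 + g_fg2, rtx_ok, rtx_pnf,
      d_fg1 + d_fg2 + d_gf1 + d_gf2,
      d_fg1 + d_fg2, d_gf1 + d_gf2
    )
  }
  list(occupancy = occ, flows = flows)
}

#' Run the five-state cohort model
#'
#' Propagates a cohort through the FG1/GF1/FG2/GF2/Death model over the full
#' horizon. The cohort is split over the three lead groups; under a
#' chelation strategy the initially-eligible (high-group) subcohort switches
#' to medium-group graft-failure probabilities from the strategy's
#' effect-onset cycle (optionally delayed to `start_cycle` for recipients
#' whose screening happens mid-model, as in the dynamic budget-impact
#' population). Trapezoidal half-cycle occupancies (arithmetic means of
#' consecutive cycle boundaries) are returned alongside raw boundary
#' occupancies and per-cycle event flows.
#'
#' @param params A `model_parameters` list.
#' @param tp Named list of transition-probability series
#'   ([tp_from_parameters()] or `fit_all_endpoints()$tp`).
#' @param strategy A `strategy_spec`, or `NULL` for standard of care.
#' @param start_cycle Calendar cycle at which the strategy's screening takes
#'   place (default 1; effect onset shifts with it).
#' @return Object of class `markov_trace`: `occupancy` (tibble, cycle 0..H by
#'   state), `half_cycle` (tibble, cycle 1..H), `flows` (tibble, cycle 1..H),
#'   `alive` and `eligible_alive` (boundary vectors), `horizon`, `strategy`.
#' @export
run_cohort <- function(params = model_parameters(),
                       tp = tp_from_parameters(horizon = params$horizon),
                       strategy = NULL,
                       start_cycle = 1) {
  H <- params$horizon
  mix <- params$group_mix
  n <- params$cohort_size * mix

  soc_schedule <- function(g) rep(g, H)
  schedules <- list(low = soc_schedule("low"), medium = soc_schedule("medium"),
                    high = soc_schedule("high"))
  if (!is.null(strategy)) {
    onset <- start_cycle - 1 + strategy$effect_onset_cycle
    schedules$high <- ifelse(seq_len(H) < onset, "high", "medium")
  }

  runs <- purrr::imap(schedules, function(sch, g) run_group_cohort(n[[g]], sch, tp, params))
  occ <- Reduce(`+`, purrr::map(runs, "occupancy"))
  flows <- Reduce(`+`, purrr::map(runs, "flows"))

  tot <- rowSums(occ)
  if (any(abs(tot - params$cohort_size) > 1e-6 * params$cohort_size)) {
    abort("Cohort conservation violated in the Markov trace.")
  }

  half <- (occ[-1, , drop = FALSE] + occ[-(H + 1), , drop = FALSE]) / 2
  alive <- tot - occ[, "Death"]
  elig_occ <- runs$high$occupancy
  eligible_alive <- rowSums(elig_occ[, c("FG1", "GF1", "FG2", "GF2"), drop = FALSE])

  structure(
    list(
      occupancy = tibble::as_tibble(cbind(cycle = 0:H, as.data.frame(occ))),
      half_cycle = tibble::as_tibble(cbind(cycle = 1:H, as.data.frame(half))),
      flows = tibble::as_tibble(cbind(cycle = 1:H, as.data.frame(flows))),
      alive = alive,
      eligible_alive = eligible_alive,
      horizon = H,
      cohort_size = params$cohort_size,
      baseline_age = params$baseline_age,
      strategy = strategy,
      start_cycle = start_cycle
    ),
    class = "markov_trace"
  )
}

#' @export
print.markov_trace <- function(x, ...) {
  final <- x$occupancy[nrow(x$occupancy), ]
  cat(sprintf("<markov_trace> %d cycles, cohort %g, %s arm; final: FG %.0f, GF %.0f, dead %.0f\n",
              x$horizon, x$cohort_size,
              if (is.null(x$strategy)) "standard-of-care" else paste0("strategy ", x$strategy$label),
              final$FG1 + final$FG2, final$GF1 + final$GF2, final$Death))
  invisible(x)
}

#' Stochastic microsimulation of the cohort model
#'
#' Individual-level counterpart of [run_cohort()] used as an independent
#' oracle: patients transition with binomially sampled counts through the
#' same tunnel structure, so its expectation is exactly the deterministic
#' cohort trace. Aggregating iid individual transitions to binomial counts
#' is what makes simulating 1e6 patients feasible.
#'
#' @inheritParams run_cohort
#' @param n_patients Number of simulated patients.
#' @return Tibble of boundary occupancies (cycle 0..H by state), scaled to
#'   `n_patients`.
#' @export
microsimulate_cohort <- function(params = model_parameters(),
                                 tp = tp_from_parameters(horizon = params$horizon),
                                 strategy = NULL, n_patients = 1e5) {
  H <- params$horizon
  mix <- params$group_mix
  n_g <- round(n_patients * mix)

  schedules <- list(low = rep("low", H), medium = rep("medium", H), high = rep("high", H))
  if (!is.null(strategy)) {
    schedules$high <- ifelse(seq_len(H) < strategy$effect_onset_cycle, "high", "medium")
  }

  occ_total <- matrix(0, H + 1, 5, dimnames = list(NULL, STATES))
  for (g in names(schedules)) {
    sch <- schedules[[g]]
    fg1 <- n_g[[g]]; gf1 <- 0L; gf2 <- 0L; dead <- 0L
    fg2 <- integer(H)
    occ_total[1, "FG1"] <- occ_total[1, "FG1"] + fg1
    for (i in seq_len(H)) {
      p_dwfg <- tp$dwfg[i]; p_dwgf <- tp$dwgf[i]
      sgf <- tp[[paste0("gf_", sch[i])]]
      p_rtx <- retransplant_probability(params$baseline_age + i, params)
      pnf <- params$p_primary_nonfunction

      d_fg1 <- rbinom(1, fg1, p_dwfg)
      g_fg1 <- rbinom(1, fg1 - d_fg1, sgf[i])
      ent <- seq_len(i - 1L)
      d_fg2_v <- rbinom(length(ent), fg2[ent], p_dwfg)
      g_fg2_v <- rbinom(length(ent), fg2[ent] - d_fg2_v, sgf[pmax(i - ent, 1L)])
      d_gf1 <- rbinom(1, gf1, p_dwgf)
      rtx_all <- rbinom(1, gf1 - d_gf1, p_rtx)
      rtx_pnf <- rbinom(1, rtx_all, pnf)
      d_gf2 <- rbinom(1, gf2, p_dwgf)

      fg1 <- fg1 - d_fg1 - g_fg1
      fg2[ent] <- fg2[ent] - d_fg2_v - g_fg2_v
      gf1 <- gf1 - d_gf1 - rtx_all + g_fg1
      fg2[i] <- rtx_all - rtx_pnf
      gf2 <- gf2 - d_gf2 + rtx_pnf + sum(g_fg2_v)
      dead <- dead + d_fg1 + sum(d_fg2_v) + d_gf1 + d_gf2
      occ_total[i + 1L, ] <- occ_total[i + 1L, ] + c(fg1, gf1, sum(fg2), gf2, dead)
    }
  }
  tibble::as_tibble(cbind(cycle = 0:H, as.data.frame(occ_total)))
}
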