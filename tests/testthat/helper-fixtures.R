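# shared fixtures: one moderately sized PSA sample reused across the PSA,
# CEAC, value-of-information and acceptance tests
.psa_cache <- new.env(parent = emptyenv())

shared_psa <- function(n_iter = 500, seed = 42) {
  key <- sprintf("psa_%d_%d", n_iter, seed)
  if (is.null(.psa_cache[[key]])) {
    .psa_cache[[key]] <- run_psa(default_config(), n_iter = n_iter, seed = seed)
  }
  .psa_cache[[key]]
}

# transition-probability set with hand-picked constant hazards, handy for
# closed-form checks
flat_tp <- function(horizon = 40, gf = c(low = 0.01, medium = 0.02, high = 0.05),
                    dwfg = 0.02, dwgf = 0.1) {
  list(
    gf_low = rep(gf[["low"]], horizon),
    gf_medium = rep(gf[["medium"]], horizon),
    gf_high = rep(gf[["high"]], horizon),
    dwfg = rep(dwfg, horizon),
    dwgf = rep(dwgf, horizon)
  )
}

# minimal markov_trace stand-in for cost/QALY unit checks
fake_trace <- function(half_cycle, flows, baseline_age = 53, horizon = nrow(flows),
                       alive = NULL, eligible_alive = NULL, strategy = NULL,
                       start_cycle = 1) {
  structure(
    list(half_cycle = half_cycle, flows = flows, baseline_age = baseline_age,
         horizon = horizon, alive = alive, eligible_alive = eligible_alive,
         strategy = strategy, start_cycle = start_cycle),
    class = "markov_trace"
  )
}
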