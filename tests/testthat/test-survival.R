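# build a records tibble for one endpoint from raw times/events
records_from <- function(time, event) {
  tibble::tibble(group = factor("all"), time_gf = time, event_gf = event)
}

test_that("exponential MLE equals events over total time at risk", {
  set.seed(21)
  time <- rexp(400, rate = 0.3)
  rec <- records_from(time, rep(TRUE, 400))
  fit <- fit_parametric(rec, "gf", "all", "exponential")
  expect_equal(unname(fit$params["rate"]), sum(rep(TRUE, 400)) / sum(time),
               tolerance = 1e-4)
})

test_that("a Weibull with shape one reproduces the exponential log-likelihood", {
  set.seed(22)
  time <- rexp(300, rate = 0.2)
  event <- time <= 6
  time <- pmin(time, 6)
  rec <- records_from(time, event)
  fit_exp <- fit_parametric(rec, "gf", "all", "exponential")
  rate <- unname(fit_exp$params["rate"])
  # evaluate the Weibull likelihood at (shape = 1, scale = 1/rate)
  ll_weib <- sum(ifelse(event,
                        dweibull(time, shape = 1, scale = 1 / rate, log = TRUE),
                        pweibull(time, shape = 1, scale = 1 / rate,
                                 lower.tail = FALSE, log.p = TRUE)))
  expect_equal(ll_weib, fit_exp$loglik, tolerance = 1e-8)
})

test_that("lognormal parameters are recovered from censored data", {
  set.seed(23)
  t_lat <- rlnorm(2000, meanlog = 2, sdlog = 0.8)
  cens <- quantile(t_lat, 0.8)  # ~20% censoring
  rec <- records_from(pmin(t_lat, cens), t_lat <= cens)
  fit <- fit_parametric(rec, "gf", "all", "lognormal")
  expect_lt(abs(fit$params[["meanlog"]] - 2), 0.05)
  expect_lt(abs(fit$params[["sdlog"]] - 0.8), 0.05)
})

test_that("all seven families recover their own parameters within three SE", {
  gens <- list(
    exponential = list(r = function(n) rexp(n, 0.25), true = c(rate = 0.25)),
    weibull = list(r = function(n) rweibull(n, 1.4, 8), true = c(shape = 1.4, scale = 8)),
    gompertz = list(r = function(n) flexsurv::rgompertz(n, 0.08, 0.05),
                    true = c(shape = 0.08, rate = 0.05)),
    gamma = list(r = function(n) rgamma(n, shape = 1.6, rate = 0.2),
                 true = c(shape = 1.6, rate = 0.2)),
    lognormal = list(r = function(n) rlnorm(n, 1.8, 0.7),
                     true = c(meanlog = 1.8, sdlog = 0.7)),
    loglogistic = list(r = function(n) flexsurv::rllogis(n, 2.2, 7),
                       true = c(shape = 2.2, scale = 7)),
    generalized_gamma = list(r = function(n) flexsurv::rgengamma(n, 1.9, 0.6, 0.5),
                             true = c(mu = 1.9, sigma = 0.6, Q = 0.5))
  )
  set.seed(24)
  for (fam in names(gens)) {
    t_lat <- gens[[fam]]$r(2000)
    cens <- quantile(t_lat, 0.85)
    rec <- records_from(pmin(t_lat, cens), t_lat <= cens)
    fit <- fit_parametric(rec, "gf", "all", fam)
    true <- gens[[fam]]$true
    for (p in names(true)) {
      expect_lt(abs(fit$params[[p]] - true[[p]]), 3 * fit$se[[p]] + 1e-9,
                label = sprintf("%s / %s recovery", fam, p))
    }
  }
})

test_that("fitting without events errors", {
  rec <- records_from(rep(5, 10), rep(FALSE, 10))
  expect_error(fit_parametric(rec, "gf", "all", "exponential"), "events")
})

test_that("model selection ranks by AIC and honours the expert override", {
  mkfit <- function(family, loglik, k) {
    structure(list(family = family, loglik = loglik, aic = 2 * k - 2 * loglik,
                   bic = k * log(100) - 2 * loglik),
              class = "parametric_fit")
  }
  fits <- list(mkfit("exponential", -100, 1), mkfit("gompertz", -90, 2))
  sel <- select_model(fits)
  expect_equal(sel$ranking$family[1], "gompertz")
  expect_equal(sel$chosen$family, "gompertz")
  sel2 <- select_model(fits, override = "exponential")
  expect_equal(sel2$chosen$family, "exponential")
  expect_error(select_model(fits, override = "weibull"), "not among")
})

test_that("lognormal data prefer the lognormal over the exponential by AIC", {
  set.seed(25)
  t_lat <- rlnorm(3000, 2, 0.6)
  rec <- records_from(t_lat, rep(TRUE, 3000))
  f_ln <- fit_parametric(rec, "gf", "all", "lognormal")
  f_ex <- fit_parametric(rec, "gf", "all", "exponential")
  expect_lt(f_ln$aic, f_ex$aic)
  # information-criterion identities
  expect_equal(f_ln$aic, 2 * 2 - 2 * f_ln$loglik)
  expect_equal(f_ln$bic, 2 * log(3000) - 2 * f_ln$loglik)
})

test_that("extrapolation evaluates the closed-form survival function", {
  s <- extrapolate_survival(list(family = "exponential", params = c(rate = 0.1)), 3)
  expect_equal(s$survival, exp(-0.1 * 0:3))

  for (fam_par in list(list("weibull", c(shape = 1.3, scale = 10)),
                       list("gamma", c(shape = 1.5, rate = 0.1)),
                       list("gompertz", c(shape = 0.05, rate = 0.04)))) {
    s <- extrapolate_survival(list(family = fam_par[[1]], params = fam_par[[2]]), 10)
    expect_equal(s$survival[1], 1)
    expect_true(all(diff(s$survival) <= 1e-12))
  }

  # lognormal against numerical integration of the density
  par <- c(meanlog = 2, sdlog = 1)
  s <- extrapolate_survival(list(family = "lognormal", params = par), 5)
  for (i in 2:6) {
    q <- integrate(dlnorm, lower = s$time[i], upper = Inf,
                   meanlog = 2, sdlog = 1, rel.tol = 1e-10)$value
    expect_equal(s$survival[i], q, tolerance = 1e-7)
  }
})

test_that("survival-to-transition-probability conversion and round trip", {
  tp <- survival_to_tp(tibble::tibble(time = 0:2, survival = c(1, 0.9, 0.81)))
  expect_equal(tp$tp, c(0.1, 0.1))

  # memorylessness: constant tp for the exponential
  s <- extrapolate_survival(list(family = "exponential", params = c(rate = 0.3)), 20)
  tp <- survival_to_tp(s)
  expect_equal(tp$tp, rep(1 - exp(-0.3), 20), tolerance = 1e-12)

  # round trip to machine precision for an arbitrary curve
  s <- extrapolate_survival(list(family = "lognormal", params = c(meanlog = 2, sdlog = 1)), 40)
  tp <- survival_to_tp(s)
  s_back <- cumprod(c(1, 1 - tp$tp))
  expect_equal(s_back, s$survival, tolerance = 1e-14)

  # lognormal(2, 1) first two cycles against a finely discretised curve
  fine <- tibble::tibble(time = 0:2,
                         survival = plnorm(c(0, 1, 2), 2, 1, lower.tail = FALSE))
  expect_equal(tp$tp[1:2], survival_to_tp(fine)$tp[1:2], tolerance = 1e-12)

  expect_error(survival_to_tp(tibble::tibble(time = 0:2, survival = c(1, 0.5, 0.6))),
               "non-increasing")
  expect_warning(
    survival_to_tp(tibble::tibble(time = 0:3, survival = c(1, 0.5, 0, 0))),
    "exhausted"
  )
})

test_that("transition probabilities of any valid curve lie in [0, 1]", {
  set.seed(26)
  for (rep in 1:20) {
    s <- sort(runif(10), decreasing = TRUE)
    curve <- tibble::tibble(time = 0:10, survival = c(1, s))
    tp <- suppressWarnings(survival_to_tp(curve))
    expect_true(all(tp$tp >= 0 & tp$tp <= 1))
  }
})

test_that("the full fitting stage selects the expert families and returns tp series", {
  spec <- cohort_spec(n_patients = 500)
  set.seed(27)
  cohort <- simulate_cohort(spec)
  out <- fit_all_endpoints(cohort, horizon = 15,
                           families = c("exponential", "gamma", "lognormal"))
  expect_named(out$tp, c("gf_low", "gf_medium", "gf_high", "dwfg", "dwgf"))
  expect_equal(out$chosen$gf_high$family, "lognormal")
  expect_equal(out$chosen$dwfg$family, "gamma")
  expect_true(all(purrr::map_int(out$tp, length) == 15))
  expect_true(all(unlist(out$tp) >= 0 & unlist(out$tp) <= 1))
})

test_that("tidy and glance summarise a fit", {
  set.seed(28)
  rec <- records_from(rlnorm(200, 2, 1), rep(TRUE, 200))
  fit <- fit_parametric(rec, "gf", "all", "lognormal")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "conf.low", "conf.high"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$nobs, 200)
})
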