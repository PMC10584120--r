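test_that("mortality curve is a valid CDF with the LT50 at its centre", {
  # forced values
  expect_equal(mortality_prob(10, 5, -3), 8 / 9)
  expect_equal(mortality_prob(0, 5, -3), 0)
  # Pm(t50) = 0.5 exactly for any parameters
  for (t50 in c(0.5, 4.02, 6.2, 9.27, 1000)) {
    for (s in c(-0.5, -3.06, -30)) {
      expect_identical(mortality_prob(t50, t50, s), 0.5)
    }
  }
  # bounds and monotonicity in t for s < 0
  t <- seq(0, 60, by = 0.25)
  p <- mortality_prob(t, 6.2, -3.06)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(diff(p) >= 0))
  expect_error(mortality_prob(5, -1, -3), "t50")
  expect_error(mortality_prob(-1, 5, -3), "t")
})

test_that("parameter-count bookkeeping matches the candidate set", {
  ks <- vapply(candidate_models(), count_params, integer(1))
  expect_identical(unname(ks), c(2L, 4L, 4L, 6L, 10L, 4L, 4L, 6L, 10L, 18L))
  expect_identical(count_params(survival_spec("E#L", "const")), 10L)
  expect_error(survival_spec("quadratic"), "arg")
})

test_that("interval likelihood matches the closed-form CDF differences", {
  # single larva dying on day d
  d <- 5L
  dat <- mortality_from_days(d, max_day = 49)
  spec <- survival_spec("const", "const")
  ll <- interval_loglik(c(log(6.2), -3.06), dat, spec)
  expect_equal(ll, log(llogis_cdf(5, 6.2, -3.06) - llogis_cdf(4, 6.2, -3.06)))

  # a censored larva contributes the survival mass at the horizon
  dat_c <- mortality_from_days(NA_integer_, max_day = 49)
  expect_equal(interval_loglik(c(log(6.2), -3.06), dat_c, spec),
               log(1 - llogis_cdf(49, 6.2, -3.06)))

  # additivity: duplicating every record doubles the log-likelihood
  days <- gen_death_days(6.2, -3, 40, seed = 4)
  d1 <- mortality_from_days(days, n_inserts = 2, id_prefix = "A")
  d2 <- mortality_from_days(rep(days, 2), n_inserts = 4, id_prefix = "B")
  expect_equal(2 * interval_loglik(c(log(6), -3), d1, spec),
               interval_loglik(c(log(6), -3), d2, spec))

  # near-step curve, all deaths in the modal interval: ~0 per larva
  dat_s <- mortality_from_days(rep(7L, 50))
  ll_s <- interval_loglik(c(log(6.5), -100), dat_s, spec)
  expect_gt(ll_s / 50, -0.01)

  expect_error(interval_loglik(c(NaN, -3), dat, spec), "non-finite")
  # zero-probability interval floors with a warning rather than -Inf
  expect_warning(
    ll0 <- interval_loglik(c(log(6.5), -60), mortality_from_days(40L), spec),
    "floored")
  expect_true(is.finite(ll0))
})

test_that("daily-binomial pseudo-likelihood is computed per insert-day", {
  days <- c(2L, 2L, 3L, NA)
  dat <- mortality_from_days(days, max_day = 4)
  spec <- survival_spec("const", "const")
  p <- mortality_prob(1:4, 6, -3)
  cum <- c(0, 2, 3, 3)
  expect_equal(
    interval_loglik(c(log(6), -3), dat, spec, mode = "daily-binomial"),
    sum(dbinom(cum, 4, p, log = TRUE)))
})

test_that("maximum likelihood recovers generating parameters", {
  # dense single-cell data: estimates within 1% of truth
  days <- gen_death_days(6.2, -3.06, 1e5, max_day = 49, seed = 10)
  dat <- mortality_from_days(days, n_inserts = 10)
  fit <- fit_survival_model(dat, survival_spec("const", "const"))
  expect_true(fit$converged)
  expect_lt(abs(fit$cells$t50[1] / 6.2 - 1), 0.01)
  expect_lt(abs(fit$cells$s[1] / (-3.06) - 1), 0.01)

  # independent oracle: interval-censored log-logistic fit in flexsurv
  skip_if_not_installed("flexsurv")
  sub <- gen_death_days(6.2, -3.06, 2000, max_day = 49, seed = 11)
  datf <- mortality_from_days(sub, n_inserts = 4, id_prefix = "F")
  fit2 <- fit_survival_model(datf, survival_spec("const", "const"))
  t1 <- ifelse(is.na(sub), 49, sub - 1)
  t2 <- ifelse(is.na(sub), Inf, sub)
  t1[t1 == 0] <- 1e-8
  fl <- flexsurv::flexsurvreg(
    survival::Surv(t1, t2, type = "interval2") ~ 1, dist = "llogis")
  expect_lt(abs(fit2$cells$t50[1] / fl$res["scale", "est"] - 1), 1e-3)
  expect_lt(abs(-fit2$cells$s[1] / fl$res["shape", "est"] - 1), 1e-3)
})

test_that("nested models never beat the models that contain them", {
  dat <- gen_survival_experiment(design_spec(seed = 21), survival_curve_params(1))
  fit_c <- fit_survival_model(dat, survival_spec("const", "const"))
  fit_el <- fit_survival_model(dat, survival_spec("E+L", "const"))
  fit_f <- fit_survival_model(dat, survival_spec("E#L", "E#L"))
  expect_gte(fit_el$logLik, fit_c$logLik - 1e-6)
  expect_gte(fit_f$logLik, fit_el$logLik - 1e-6)
})

test_that("degenerate mortality data are rejected informatively", {
  # all-censored cell named in the error
  dat <- mortality_from_days(rep(NA_integer_, 20), embryo = "pH 7.5",
                             larval = "Ambient")
  expect_error(fit_survival_model(dat, survival_spec("const", "const")),
               "pH 7.5/Ambient.*all-censored|all-censored")
  # full-interaction model needs every cell
  one_cell <- mortality_from_days(gen_death_days(6, -3, 20, seed = 1))
  expect_error(fit_survival_model(one_cell, survival_spec("E#L", "E#L")),
               "has no data")
  expect_error(fit_survival_model(one_cell[0, ], survival_spec("const", "const")),
               "empty|missing")
})

test_that("AICc implements the small-sample correction", {
  expect_equal(aicc(-100, 2, 1000), 204 + 12 / 997)
  expect_equal(aicc(-50, 0, 10), 100)
  expect_lt(abs(aicc(-100, 3, 1e9) - (206)), 1e-6)
  expect_error(aicc(-100, 5, 6), "n must exceed")
})

test_that("model comparison table has coherent weights", {
  dat <- gen_survival_experiment(design_spec(seed = 31), survival_curve_params(1))
  cmp <- compare_models(dat)
  expect_identical(nrow(cmp), 10L)
  expect_equal(min(cmp$dAICc), 0)
  expect_equal(sum(cmp$weight), 1)
  expect_true(all(diff(cmp$AICc) >= 0))
  expect_true(all(diff(cmp$weight) <= 1e-12))
  expect_equal(cmp$rel_lik, exp(-cmp$dAICc / 2))
  # two identical models share the weight equally
  sp <- survival_spec("const", "const")
  cmp2 <- compare_models(dat, specs = list(a = sp, b = sp))
  expect_equal(cmp2$weight, c(0.5, 0.5))
  expect_error(compare_models(dat[0, ]), "empty|missing")
})
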