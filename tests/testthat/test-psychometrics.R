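gen_afc <- function(n_per_offset, slope, pse, offsets = afc_probe_offsets()) {
  off <- rep(offsets, each = n_per_offset)
  data.frame(probe_offset_deg = off,
             response_left = runif(length(off)) < plogis(slope * (off - pse)))
}

test_that("a symmetric response pattern yields PSE near zero", {
  off <- rep(afc_probe_offsets(), each = 10)
  fit <- fit_psychometric(off, off > 0)   # perfectly symmetric, separated
  expect_lt(abs(fit$pse_deg), 0.5)
  expect_true(fit$separation_flag)
})

test_that("PSE and JND equal the bisection-found curve crossings", {
  set.seed(2)
  fit <- fit_psychometric(gen_afc(40, 0.25, 2)$probe_offset_deg,
                          gen_afc(40, 0.25, 2)$response_left)
  crossing <- function(p) {
    f <- function(x) predict(fit, x) - p
    stats::uniroot(f, c(-500, 500), tol = 1e-12)$root
  }
  expect_equal(fit$pse_deg, crossing(0.5), tolerance = 1e-9)
  expect_equal(fit$jnd_deg, crossing(0.75) - crossing(0.25), tolerance = 1e-9)
})

test_that("the ML fit is a local optimum of the likelihood", {
  set.seed(5)
  d <- gen_afc(30, 0.22, 1)
  fit <- fit_psychometric(d$probe_offset_deg, d$response_left)
  ll <- function(b) {
    p <- plogis(b[1] + b[2] * d$probe_offset_deg)
    sum(d$response_left * log(p) + (1 - d$response_left) * log1p(-p))
  }
  b <- coef(fit)
  ll0 <- ll(b)
  for (f1 in c(0.9, 1.1)) for (f2 in c(0.9, 1.1)) {
    expect_gte(ll0, ll(c(b[1] * f1, b[2] * f2)))
  }
})

test_that("fits are shift equivariant in the probe offsets", {
  set.seed(6)
  d <- gen_afc(50, 0.2, -1)
  f0 <- fit_psychometric(d$probe_offset_deg, d$response_left)
  f1 <- fit_psychometric(d$probe_offset_deg + 7, d$response_left)
  expect_equal(f1$pse_deg, f0$pse_deg + 7, tolerance = 1e-6)
  expect_equal(f1$jnd_deg, f0$jnd_deg, tolerance = 1e-6)
})

test_that("degenerate and underdetermined inputs are handled explicitly", {
  set.seed(7)
  off <- rep(afc_probe_offsets(), each = 20)
  flat <- fit_psychometric(off, runif(length(off)) < 0.5)
  expect_true(flat$degenerate_flag)

  expect_error(fit_psychometric(rep(10, 20), rep(c(TRUE, FALSE), 10)),
               "distinct probe offsets")

  sep <- fit_psychometric(off, off > 0)
  expect_true(sep$separation_flag)
  expect_true(all(is.finite(coef(sep))))
  expect_true(sep$jnd_deg > 0)
})

test_that("psychfit methods behave like a fitted model object", {
  set.seed(9)
  d <- gen_afc(40, 0.22, 3)
  fit <- fit_psychometric(d$probe_offset_deg, d$response_left)
  expect_s3_class(fit, "psychfit")
  expect_named(coef(fit), c("(Intercept)", "probe_offset_deg"))
  expect_equal(predict(fit, fit$pse_deg), 0.5, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_length(residuals(fit), nrow(d))
  expect_equal(dim(simulate(fit, nsim = 2, seed = 1)), c(nrow(d), 2L))
  expect_output(print(fit), "PSE")
  expect_output(print(summary(fit)), "JND")
  s <- summary(fit)
  expect_true(all(is.finite(s$coefficients[, "Std. Error"])))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  expect_s3_class(logLik(fit), "logLik")
})

test_that("PSE alignment pools two shifted curves without inflating the JND", {
  set.seed(11)
  slope <- 0.2197
  d1 <- gen_afc(210, slope, 3)
  d2 <- gen_afc(210, slope, -3)
  pool <- align_and_pool(d1, d2)
  expect_lt(abs(pool$joint$pse_deg), 0.5)
  jnd_true <- 2 * log(3) / slope
  expect_lt(abs(pool$joint$jnd_deg / jnd_true - 1), 0.05)
  # naive pooling without alignment inflates the measured JND
  naive <- fit_psychometric(c(d1$probe_offset_deg, d2$probe_offset_deg),
                            c(d1$response_left, d2$response_left))
  expect_gt(naive$jnd_deg, pool$joint$jnd_deg)

  # single-target designs pass through unchanged
  solo <- align_and_pool(d1)
  expect_equal(solo$joint$pse_deg,
               fit_psychometric(d1$probe_offset_deg,
                                d1$response_left)$pse_deg)
})

test_that("per-subject summaries recover generator PSE shifts and JND ratios", {
  cfg <- experiment_config("exp1", "afc2", n_blocks = 7)
  p <- sim_params("exp1", seed = 31,
                  loc_bias_deg = c(baseline = 0, adaptation = 1.7,
                                   washout = -0.7))
  ds <- simulate_experiment(cfg, p, n_subjects = 6)
  rep <- run_pipeline(ds)
  g <- attr(rep$psychometrics, "group")
  pse_a <- g$pse_mean[g$cycle_type == "adaptation"]
  pse_w <- g$pse_mean[g$cycle_type == "washout"]
  expect_lt(abs(pse_a - 1.7), 1.0)
  expect_lt(abs(pse_w - (-0.7)), 1.0)
  jnd_ratio <- g$jnd_mean[g$cycle_type == "adaptation"] /
    g$jnd_mean[g$cycle_type == "washout"]
  true_ratio <- (2 * log(3) / 0.211) / (2 * log(3) / 0.32)
  expect_lt(abs(jnd_ratio / true_ratio - 1), 0.15)
})
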