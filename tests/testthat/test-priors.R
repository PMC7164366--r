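# Birth-death node-age kernel, calibration densities, joint time prior,
# clock rate priors.

test_that("the BD kernel integrates to 1 over randomized parameter sets", {
  set.seed(41)
  for (i in 1:20) {
    bd <- bd_params(runif(1, 0.2, 3), runif(1, 0.2, 3), runif(1, 0.05, 1))
    t1 <- runif(1, 0.5, 3)
    f <- function(t) exp(bd_kernel_logdensity(t, t1, bd))
    expect_lt(abs(integrate(f, 0, t1, rel.tol = 1e-9)$value - 1), 1e-6)
  }
})

test_that("critical-case endpoint densities match the closed form", {
  bd <- bd_params(1, 1, 0.1)
  f <- function(t) exp(bd_kernel_logdensity(t, 1, bd))
  expect_equal(f(1e-12), 1.1, tolerance = 1e-9)
  expect_equal(f(1 - 1e-12), 1.1 / 1.21, tolerance = 1e-9)
  expect_equal(f(1e-12) / f(1 - 1e-12), (1 + 0.1 * 1 * 1)^2,
               tolerance = 1e-9)
  expect_identical(bd_kernel_logdensity(1.5, 1, bd), -Inf)
  expect_identical(bd_kernel_logdensity(0, 1, bd), -Inf)
})

test_that("full sampling with fast turnover concentrates ages near zero", {
  bd <- bd_params(10, 10, 1)
  g <- seq(0.05, 0.95, 0.1)
  dens <- bd_kernel_logdensity(g, 1, bd)
  expect_true(all(diff(dens) < 0))  # monotone decreasing
})

test_that("calibration densities have the stated shape and tail masses", {
  cal <- calibration_set(data.frame(
    tip_a = "a", tip_b = "b", t_min = 52.40, min_type = "hard",
    t_max = 164.6, max_type = "soft"))
  expect_identical(calibration_logdensity(40, cal[1, ]), -Inf)
  f <- function(t) exp(calibration_logdensity(t, cal[1, ]))
  upper <- integrate(f, 164.6, Inf, rel.tol = 1e-9)$value
  expect_lt(abs(upper - 0.025), 1e-6)
  total <- integrate(f, 0, Inf, rel.tol = 1e-9)$value
  expect_lt(abs(total - 1), 1e-6)
  # hard/hard narrow window: density 1/width inside, -Inf outside
  hard <- calibration_set(data.frame(
    tip_a = "a", tip_b = "b", t_min = 0.999, min_type = "hard",
    t_max = 1.001, max_type = "hard"))
  expect_equal(exp(calibration_logdensity(1, hard[1, ])), 500)
  expect_identical(calibration_logdensity(1.0011, hard[1, ]), -Inf)
  # soft lower tail carries its stated mass
  soft2 <- calibration_set(data.frame(
    tip_a = "a", tip_b = "b", t_min = 10, min_type = "soft",
    t_max = 20, max_type = "soft", p_lower = 0.025, p_upper = 0.025))
  lower <- integrate(function(t) exp(calibration_logdensity(t, soft2[1, ])),
                     0, 10, rel.tol = 1e-9)$value
  expect_lt(abs(lower - 0.025), 1e-6)
})

test_that("calibration sets validate their invariants", {
  expect_error(calibration_set(data.frame(
    tip_a = "a", tip_b = "b", t_min = 5, min_type = "hard", t_max = 5,
    max_type = "hard")), "t_min must be <")
  expect_error(calibration_set(data.frame(
    tip_a = "a", tip_b = "b", t_min = 1, min_type = "soft", t_max = 2,
    max_type = "soft", p_lower = 0.6, p_upper = 0)), "tail probabilities")
})

test_that("the joint time prior enforces ordering and hard bounds", {
  tt <- tt_in_ma(simulate_timetree(6, 0.4, seed = 42))
  cals <- make_calibrations(tt, rel_offsets = c(0.1, 0.1),
                            tails = c(0, 0.025))
  expect_true(is.finite(joint_time_logprior(tt, cals)))
  broken <- tt
  kid <- tt$phy$edge[tt$phy$edge[, 1] == 7, 2][1]
  broken$ages[kid] <- tt$ages[7] + 5  # child older than its parent
  expect_identical(joint_time_logprior(broken, cals), -Inf)
  below <- tt
  below$ages[7] <- cals$t_min[1] * 0.5  # root below its hard minimum
  expect_identical(joint_time_logprior(below, cals), -Inf)
})

test_that("uncalibrated nodes contribute exactly the BD kernel", {
  tt <- tt_in_ma(simulate_timetree(5, 0.4, seed = 43))
  root_only <- make_calibrations(tt, rel_offsets = c(0.1, 0.1),
                                 tails = c(0, 0.025))
  lp <- joint_time_logprior(tt, root_only, bd_params(1, 1, 0.1))
  n <- 5
  manual <- calibration_logdensity(tt$ages[n + 1], root_only[1, ])
  for (v in (n + 2):(2 * n - 1))
    manual <- manual + bd_kernel_logdensity(tt$ages[v], tt$ages[n + 1],
                                            bd_params(1, 1, 0.1))
  expect_equal(lp, manual, tolerance = 1e-12)
})

test_that("IR clock prior equals the term-by-term lognormal sum", {
  tt <- simulate_timetree(8, 0.4, seed = 44)
  spec <- clock_model_spec("IR", 0.1, 0.3)
  r <- simulate_branch_rates(tt, spec, seed = 45)
  lp <- clock_logprior(r, spec, tt)
  brute <- dgamma(0.1, 2, 20, log = TRUE) + dgamma(0.3, 2, 2, log = TRUE) +
    sum(dlnorm(r, log(0.1) - 0.15, sqrt(0.3), log = TRUE))
  expect_equal(lp, brute, tolerance = 1e-12)
  expect_error(clock_logprior(-r, spec, tt), "positive")
})

test_that("AR prior density peaks at rates = mu", {
  tt <- simulate_timetree(6, 0.4, seed = 46)
  spec <- clock_model_spec("AR", 0.1, 0.4)
  nedge <- nrow(tt$phy$edge)
  at_mu <- clock_logprior(rep(0.1, nedge), spec, tt)
  set.seed(47)
  for (i in 1:10) {
    pert <- rep(0.1, nedge) * exp(rnorm(nedge, 0, 0.5))
    expect_gt(at_mu, clock_logprior(pert, spec, tt))
  }
})

test_that("the Gamma(2, 20) rate hyperprior has mean 0.1 per time unit", {
  spec <- clock_model_spec("STR", 0.1)
  pr <- spec$priors$mu
  expect_equal(unname(pr["shape"] / pr["rate"]), 0.1)
  # and the density used matches dgamma at a few points
  expect_equal(clock_logprior(rep(0.2, 4), spec,
                              simulate_timetree(3, 1, seed = 1)),
               dgamma(0.1, 2, 20, log = TRUE))
})

test_that("prior log densities are finite on-support, -Inf off, never NaN", {
  set.seed(48)
  for (i in 1:50) {
    t1 <- runif(1, 0.5, 2)
    bd <- bd_params(runif(1, 0.1, 2), runif(1, 0.1, 2), runif(1, 0.1, 1))
    t <- runif(1, -0.5, 1.5 * t1)
    v <- bd_kernel_logdensity(t, t1, bd)
    expect_false(is.nan(v))
    if (t > 0 && t < t1) expect_true(is.finite(v)) else expect_identical(v, -Inf)
  }
})
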