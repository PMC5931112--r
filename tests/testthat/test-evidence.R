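test_that("power equals alpha at the null and is monotone in pve, N and |log OR|", {
  for (a in c(0.01, 0.05, 0.1)) {
    expect_equal(power_binary_mr(12488, 18169, 0.05, 1, alpha = a), a)
  }
  pve_grid <- c(0.01, 0.05, 0.1, 0.2)
  p1 <- power_binary_mr(12488, 18169, pve_grid, 1.3)
  expect_true(all(diff(p1) > 0))
  n_grid <- c(1000, 5000, 20000, 80000)
  p2 <- vapply(n_grid, function(n) power_binary_mr(n, n, 0.05, 1.3), 0)
  expect_true(all(diff(p2) > 0))
  or_grid <- c(1.05, 1.2, 1.5, 2)
  p3 <- power_binary_mr(12488, 18169, 0.05, or_grid)
  expect_true(all(diff(p3) > 0))
  # protective effects mirror harmful ones through |log OR|
  expect_equal(power_binary_mr(12488, 18169, 0.05, 1 / 1.3),
               power_binary_mr(12488, 18169, 0.05, 1.3))
  expect_error(power_binary_mr(12488, 18169, 0, 1.3),
               class = "mrgls_domain_error")
})

test_that("analytic power agrees with a Monte-Carlo Wald-test oracle", {
  # oracle: draw per-instrument ratio estimates around the true log OR with
  # the case-control sampling SE, pool by IVW, two-sided Wald test
  mc_power <- function(n_cases, n_controls, pve, or_alt, alpha, reps, k = 10) {
    n <- n_cases + n_controls
    phi <- n_cases / n
    se_k <- 1 / sqrt(n * (pve / k) * phi * (1 - phi))
    rej <- vapply(seq_len(reps), function(i) {
      est <- rnorm(k, log(or_alt), se_k)
      pooled <- mean(est)
      se_pooled <- se_k / sqrt(k)
      abs(pooled / se_pooled) > qnorm(1 - alpha / 2)
    }, logical(1))
    mean(rej)
  }
  withr::local_seed(2024)
  cases <- list(
    list(pve = 0.007, or = 1.2),  # weak instrument, mid power
    list(pve = 0.024, or = 1.15),
    list(pve = 0.15, or = 1.3)    # strong instrument, near-complete power
  )
  for (cs in cases) {
    sim <- mc_power(12488, 18169, cs$pve, cs$or, 0.05, reps = 10000)
    ana <- power_binary_mr(12488, 18169, cs$pve, cs$or)
    sim_se <- sqrt(max(sim * (1 - sim), 1e-6) / 10000)
    expect_lt(abs(ana - sim), 2 * sim_se + 1e-4)
  }
})

test_that("log OR and SE recovered from a reported CI round-trip", {
  r <- se_from_ci(0.91, 0.77, 1.07)
  expect_equal(round(r$theta_hat, 4), -0.0943)
  expect_equal(r$se, 0.0840, tolerance = 1e-3)
  # round trip on a log-symmetric interval
  theta <- 0.2; se <- 0.1
  r2 <- se_from_ci(exp(theta), exp(theta - 1.96 * se), exp(theta + 1.96 * se))
  expect_equal(r2$theta_hat, theta)
  expect_equal(r2$se, se)

  expect_warning(d <- se_from_ci(1, 1, 1), "degenerate")
  expect_equal(d$se, 0)
  expect_error(se_from_ci(0.9, 0.95, 1.1), class = "mrgls_domain_error")
})

test_that("the Wakefield Bayes factor matches closed forms and numeric integration", {
  # Z = 0 and W = V gives exactly sqrt(2)
  se <- 0.1
  or_w_eq_v <- exp(1.96 * se)
  expect_equal(wakefield_bf(0, se, or_w_eq_v), sqrt(2))
  # prior collapsing to the null sends the BF to 1
  expect_equal(wakefield_bf(0.05, 0.1, 1 + 1e-9), 1, tolerance = 1e-6)

  # numeric-integration oracle: marginal likelihood of theta_hat under the
  # null spike vs under the N(0, W) alternative
  bf_oracle <- function(theta_hat, se, or_max) {
    w <- (abs(log(or_max)) / 1.96)^2
    null_ml <- dnorm(theta_hat, 0, se)
    alt_ml <- stats::integrate(
      function(th) dnorm(theta_hat, th, se) * dnorm(th, 0, sqrt(w)),
      -Inf, Inf, rel.tol = 1e-10
    )$value
    null_ml / alt_ml
  }
  grid <- expand.grid(theta = c(-0.0943, 0, 0.27), se = c(0.084, 0.2),
                      or_max = c(0.6, 1.27, 2))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_equal(wakefield_bf(g$theta, g$se, g$or_max),
                 bf_oracle(g$theta, g$se, g$or_max), tolerance = 1e-8)
  }

  # published BMI example: bf around 1.15
  r <- se_from_ci(0.91, 0.77, 1.07)
  expect_equal(wakefield_bf(r$theta_hat, r$se, 1.27), 1.15, tolerance = 0.005)

  expect_error(wakefield_bf(0.1, 0.1, 1), class = "mrgls_domain_error")
})

test_that("BFNP and the minimum prior are exact inverses", {
  expect_equal(min_prior_for_bfnp(9, 0.1), 0.5)
  expect_equal(bfnp(1, 0.5), 0.5)
  for (bf in c(0.2, 1, 3.7, 42)) {
    for (tau in c(0.05, 0.1, 0.5)) {
      expect_equal(bfnp(bf, min_prior_for_bfnp(bf, tau)), tau,
                   tolerance = 1e-12)
    }
  }
  # limit: prior near 1 drives BFNP to 1
  expect_gt(bfnp(5, 1 - 1e-9), 0.999)
  # monotonicity on grids
  mp_bf <- min_prior_for_bfnp(c(0.5, 1, 2, 8, 32), 0.1)
  expect_true(all(diff(mp_bf) > 0))
  mp_tau <- min_prior_for_bfnp(2, c(0.01, 0.1, 0.5, 0.9))
  expect_true(all(diff(mp_tau) > 0))
})

test_that("the published minimum priors are reproduced from reported ORs and CIs", {
  rows <- published_glioma_rows()
  out <- bfnp_table(rows, tau = 0.1)
  reproducible <- !(out$trait %in% rounding_sensitive_traits)
  expect_equal(round(out$min_prior[reproducible], 2),
               rows$min_prior_printed[reproducible])
  # the two rounding-sensitive rows still land within 0.02 of print
  expect_true(all(abs(round(out$min_prior[!reproducible], 2) -
                        rows$min_prior_printed[!reproducible]) <= 0.0201))
})

test_that("power curves tabulate and plot over an OR grid", {
  pc <- power_curve(12488, 18169, 0.048, trait = "fasting_glucose",
                    or_grid = seq(1, 2, 0.1))
  expect_equal(nrow(pc), 11)
  expect_equal(pc$power[1], 0.05)
  # power rises with the OR until it saturates at 1
  expect_true(all(diff(pc$power) >= 0))
  expect_gt(pc$power[2], pc$power[1])
  expect_s3_class(plot_power_curves(pc), "ggplot")
})
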