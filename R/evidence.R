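#' A priori power for MR with a binary outcome
#'
#' Analytic power of a two-sided Wald test of the causal log odds ratio in a
#' case-control outcome study, following the non-centrality approximation
#' for summary-data MR: with `N = n_cases + n_controls`,
#' `phi = n_cases / N` and `b = ln(or_alt)`, the non-centrality is
#' `lambda = |b| * sqrt(N * pve * phi * (1 - phi))` and
#' `power = Phi(lambda - z) + Phi(-lambda - z)` with `z = z_(1 - alpha/2)`.
#' Both rejection tails are included, so at `or_alt = 1` the power equals
#' `alpha` exactly.
#'
#' @param n_cases,n_controls Outcome-study counts.
#' @param pve Fraction of exposure variance explained by the instruments,
#'   in (0, 1).
#' @param or_alt Odds ratio per exposure SD under the alternative.
#' @param alpha Two-sided significance level.
#' @return Power in (0, 1). Vectorised over `or_alt` and `pve`.
#' @export
power_binary_mr <- function(n_cases, n_controls, pve, or_alt, alpha = 0.05) {
  if (any(n_cases < 1) || any(n_controls < 1)) {
    stop_mrgls("need at least one case and one control", "mrgls_domain_error")
  }
  if (any(pve <= 0 | pve >= 1)) {
    stop_mrgls("pve must lie in (0, 1)", "mrgls_domain_error")
  }
  if (any(or_alt <= 0)) stop_mrgls("or_alt must be positive", "mrgls_domain_error")
  if (any(alpha <= 0 | alpha >= 1)) {
    stop_mrgls("alpha must lie in (0, 1)", "mrgls_domain_error")
  }
  n <- n_cases + n_controls
  phi <- n_cases / n
  lambda <- abs(log(or_alt)) * sqrt(n * pve * phi * (1 - phi))
  z <- qnorm(1 - alpha / 2)
  pnorm(lambda - z) + pnorm(-lambda - z)
}

#' Power across a grid of odds ratios
#'
#' @inheritParams power_binary_mr
#' @param trait Label carried into the output.
#' @param or_grid Odds ratios to evaluate.
#' @return A tibble with columns `trait`, `or`, `power`.
#' @export
power_curve <- function(n_cases, n_controls, pve, trait = "trait",
                        or_grid = seq(1, 2, by = 0.01), alpha = 0.05) {
  tibble::tibble(
    trait = trait, or = or_grid,
    power = power_binary_mr(n_cases, n_controls, pve, or_grid, alpha)
  )
}

#' Plot power curves
#'
#' @param curves Tibble from [power_curve()] (rows for several traits may be
#'   bound together).
#' @param target Horizontal reference line (default 0.8).
#' @return A ggplot object.
#' @export
plot_power_curves <- function(curves, target = 0.8) {
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$or, y = .data$power,
                               colour = .data$trait)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = target, linetype = "dashed") +
    ggplot2::labs(x = "Odds ratio per exposure SD", y = "Power",
                  colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Log odds ratio and its SE from a reported OR and 95% CI
#'
#' `theta = ln(OR)`, `se = (ln(ci_high) - ln(ci_low)) / (2 * 1.96)` —
#' inverting the normal-theory interval `exp(theta +/- 1.96 se)`. A
#' zero-width interval yields `se = 0` and is flagged degenerate with a
#' warning.
#'
#' @param or_ Odds ratio.
#' @param ci_low,ci_high 95% confidence limits, `0 < ci_low <= or_ <= ci_high`.
#' @return A tibble with columns `theta_hat`, `se`. Vectorised.
#' @export
se_from_ci <- function(or_, ci_low, ci_high) {
  if (any(ci_low <= 0) || any(ci_low > or_) || any(or_ > ci_high)) {
    stop_mrgls("need 0 < ci_low <= or_ <= ci_high", "mrgls_domain_error")
  }
  se <- (log(ci_high) - log(ci_low)) / (2 * 1.96)
  if (any(se == 0)) warn("degenerate interval: se = 0")
  tibble::tibble(theta_hat = log(or_), se = se)
}

#' Wakefield approximate Bayes factor (null vs alternative)
#'
#' Ratio of the marginal density of the estimate under the null,
#' `theta_hat ~ N(0, V)`, to that under a normal-prior alternative,
#' `theta_hat ~ N(0, V + W)`:
#' `BF = sqrt((V + W) / V) * exp(-Z^2 * W / (2 (V + W)))` with `V = se^2` and
#' `Z = theta_hat / se`. The prior variance is calibrated from a maximum
#' likely odds ratio interpreted as the 97.5th percentile of the prior on the
#' OR under the alternative: `W = (ln(or_max) / 1.96)^2` (protective
#' `or_max < 1` enters via `|ln|`). Values above 1 favour the null.
#'
#' @param theta_hat Estimated log OR.
#' @param se Its standard error, positive.
#' @param or_max Maximum likely OR calibrating the prior; must differ from 1.
#' @return The Bayes factor. Vectorised.
#' @export
wakefield_bf <- function(theta_hat, se, or_max) {
  if (any(se <= 0)) stop_mrgls("se must be positive", "mrgls_domain_error")
  if (any(or_max <= 0) || any(or_max == 1)) {
    stop_mrgls("or_max must be positive and differ from 1 (degenerate prior)",
               "mrgls_domain_error")
  }
  w <- (abs(log(or_max)) / 1.96)^2
  v <- se^2
  z <- theta_hat / se
  sqrt((v + w) / v) * exp(-z^2 * w / (2 * (v + w)))
}

#' Bayesian false null probability
#'
#' The posterior probability that the alternative is true given the Bayes
#' factor (null vs alternative) and a prior probability of association:
#' `BFNP = 1 / (1 + BF * (1 - prior) / prior)`. Equals `1 - BFDP`, the
#' complement of the Bayesian false discovery probability.
#'
#' @param bf Bayes factor from [wakefield_bf()], positive.
#' @param prior Prior probability of association, in (0, 1).
#' @return BFNP in (0, 1); strictly increasing in `prior`. Vectorised.
#' @export
bfnp <- function(bf, prior) {
  if (any(bf <= 0)) stop_mrgls("bf must be positive", "mrgls_domain_error")
  if (any(prior <= 0 | prior >= 1)) {
    stop_mrgls("prior must lie in (0, 1)", "mrgls_domain_error")
  }
  1 / (1 + bf * (1 - prior) / prior)
}

#' Minimum prior probability of association for BFNP above a threshold
#'
#' Solves `BFNP(bf, prior) = tau` for the prior:
#' `min_prior = tau * bf / (tau * bf + 1 - tau)`. A null result needing a
#' large minimum prior to retain even a `tau` chance of being a false null is
#' a reliable null.
#'
#' @param bf Bayes factor, positive.
#' @param tau BFNP threshold, in (0, 1); default 0.1.
#' @return The minimum prior in (0, 1). Vectorised.
#' @export
min_prior_for_bfnp <- function(bf, tau = 0.1) {
  if (any(bf <= 0)) stop_mrgls("bf must be positive", "mrgls_domain_error")
  if (any(tau <= 0 | tau >= 1)) {
    stop_mrgls("tau must lie in (0, 1)", "mrgls_domain_error")
  }
  tau * bf / (tau * bf + 1 - tau)
}

#' Bayesian null-evaluation table from reported ORs and CIs
#'
#' Chains [se_from_ci()], [wakefield_bf()] and [min_prior_for_bfnp()] over a
#' table of per-trait results, producing for each row the Bayes factor and
#' the minimum prior probability of association required for the Bayesian
#' false null probability to exceed `tau`.
#'
#' @param results Tibble with columns `trait`, `or`, `ci_low`, `ci_high`,
#'   `or_max` (rows with `NA` `or_max` get `or_max_default`).
#' @param tau BFNP threshold (default 0.1).
#' @param or_max_default Maximum likely OR used when no observational
#'   estimate is available (default 2).
#' @return The input with columns `or_max`, `theta_hat`, `se`, `bf`,
#'   `min_prior` appended.
#' @export
bfnp_table <- function(results, tau = 0.1, or_max_default = 2) {
  if (!("or_max" %in% names(results))) results$or_max <- NA_real_
  results |>
    dplyr::mutate(
      or_max = dplyr::coalesce(.data$or_max, or_max_default),
      se_from_ci(.data$or, .data$ci_low, .data$ci_high),
      bf = wakefield_bf(.data$theta_hat, .data$se, .data$or_max),
      min_prior = min_prior_for_bfnp(.data$bf, tau)
    )
}
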