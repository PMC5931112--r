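#' Per-SNP Wald ratio
#'
#' The causal effect implied by a single instrument: the outcome effect
#' divided by the exposure effect, `b_xy = b_zy / b_zx`, with first-order
#' delta-method standard error
#' `se_xy^2 = se_zy^2 / b_zx^2 + b_zy^2 * se_zx^2 / b_zx^4`.
#'
#' @param b_zx,se_zx Exposure effect and its SE (per effect allele).
#' @param b_zy,se_zy Outcome effect (log OR) and its SE.
#' @return A tibble with columns `b_xy`, `se_xy`. Vectorised.
#' @export
wald_ratio <- function(b_zx, se_zx, b_zy, se_zy) {
  if (any(b_zx == 0)) {
    stop_mrgls("b_zx = 0: instrument carries no exposure signal",
               "mrgls_domain_error")
  }
  tibble::tibble(
    b_xy = b_zy / b_zx,
    se_xy = sqrt(se_zy^2 / b_zx^2 + b_zy^2 * se_zx^2 / b_zx^4)
  )
}

# Internal: LD submatrix over the instruments, in instrument order.
ld_submatrix <- function(instruments, ld) {
  absent <- setdiff(instruments$snp, rownames(ld))
  if (length(absent) > 0) {
    stop_mrgls(paste0("LD matrix does not cover instrument(s): ",
                      paste(absent, collapse = ", ")),
               "mrgls_ld_error")
  }
  ld[instruments$snp, instruments$snp, drop = FALSE]
}

#' Pooled causal estimate by LD-aware generalised least squares
#'
#' Pools the per-SNP Wald ratios `b_xy,i` by generalised least squares under
#' the covariance `C_ij = r_ij * se_xy,i * se_xy,j`, where `r` is the LD
#' correlation between instruments:
#' `b_hat = (1' C^-1 b) / (1' C^-1 1)`, `se = (1' C^-1 1)^(-1/2)`.
#' With identity LD this reduces to the inverse-variance-weighted mean; with
#' a single instrument it equals the Wald ratio. The two-sided P value comes
#' from the standard normal, and the estimate is reported as an odds ratio
#' with a 1.96-SE (95%) confidence interval.
#'
#' @param instruments Harmonised instrument tibble (see [harmonise()]); needs
#'   columns `snp`, `b_xy`, `se_xy` (and `p_zx` for downstream HEIDI use).
#' @param ld Named LD correlation matrix covering all instruments.
#' @param trait,outcome Labels carried into the result.
#' @param alpha,bonferroni Evidence-tier thresholds passed to
#'   [classify_evidence()].
#' @param outliers_removed Character vector of SNPs removed upstream (for the
#'   record; see [mr_gsmr()]).
#' @return An object of class `mr_result`; see [tidy.mr_result()] and
#'   [glance.mr_result()].
#' @export
gsmr_estimate <- function(instruments, ld, trait = "exposure",
                          outcome = "outcome", alpha = 0.05,
                          bonferroni = 0.0017, outliers_removed = character()) {
  if (nrow(instruments) == 0) {
    stop_mrgls("no instruments supplied", "mrgls_domain_error")
  }
  r <- ld_submatrix(instruments, ld)
  se <- instruments$se_xy
  C <- r * outer(se, se)
  # Condition the correlation part: the scale matrix diag(se) is always
  # invertible, so near-singularity can only come from correlated instruments.
  if (nrow(r) > 1 && kappa(r, exact = FALSE) > 1e12) {
    stop_mrgls(paste0("ratio covariance matrix is numerically singular; ",
                      "instruments are too correlated - prune at a stricter r2"),
               "mrgls_singular_error")
  }
  ch <- tryCatch(chol(C), error = function(e) {
    stop_mrgls(paste0("ratio covariance matrix is not positive definite; ",
                      "instruments are too correlated - prune at a stricter r2"),
               "mrgls_singular_error")
  })
  ones <- rep(1, nrow(C))
  ci_b <- backsolve(ch, forwardsolve(t(ch), instruments$b_xy))
  ci_1 <- backsolve(ch, forwardsolve(t(ch), ones))
  denom <- sum(ones * ci_1)
  b_hat <- sum(ones * ci_b) / denom
  se_hat <- 1 / sqrt(denom)
  p <- 2 * pnorm(-abs(b_hat / se_hat))
  structure(
    list(
      trait = trait, outcome = outcome,
      b_xy_hat = b_hat, se_xy = se_hat,
      or_ = exp(b_hat),
      ci_low = exp(b_hat - 1.96 * se_hat),
      ci_high = exp(b_hat + 1.96 * se_hat),
      pvalue = p,
      n_snps_used = nrow(instruments),
      outliers_removed = outliers_removed,
      evidence_tier = classify_evidence(p, alpha, bonferroni),
      instruments = instruments
    ),
    class = "mr_result"
  )
}

#' HEIDI-style outlier test for horizontal pleiotropy
#'
#' Compares each instrument's Wald ratio with that of a reference SNP (the
#' instrument with the smallest exposure P value). Under the null of a single
#' shared causal effect, the deviation `d_i = b_xy,i - b_xy,ref` has variance
#' `se_xy,i^2 + se_xy,ref^2 - 2 * r_(i,ref) * se_xy,i * se_xy,ref`, and
#' `d_i^2 / var(d_i)` is chi-squared with 1 df. Instruments whose HEIDI P
#' value falls below the threshold are flagged as pleiotropic and removed in
#' a single pass; the reference SNP is never flagged.
#'
#' @param instruments Harmonised instrument tibble.
#' @param ld Named LD correlation matrix.
#' @param p_threshold Flagging threshold; default 0.01.
#' @return A list with `report` (per-SNP tibble: `snp`, `d`, `se_d`,
#'   `p_heidi`, `flagged`, `reference`) and `retained` (the surviving
#'   instruments). With fewer than two instruments the report carries no
#'   flags.
#' @export
heidi_outlier <- function(instruments, ld, p_threshold = 0.01) {
  if (nrow(instruments) < 2) {
    report <- tibble::tibble(
      snp = instruments$snp, d = 0, se_d = NA_real_, p_heidi = NA_real_,
      flagged = FALSE,
      reference = if (nrow(instruments) > 0) instruments$snp[1] else NA_character_
    )
    return(list(report = report, retained = instruments))
  }
  r <- ld_submatrix(instruments, ld)
  ref_idx <- strength_order_heidi(instruments)
  ref <- instruments$snp[ref_idx]
  d <- instruments$b_xy - instruments$b_xy[ref_idx]
  var_d <- instruments$se_xy^2 + instruments$se_xy[ref_idx]^2 -
    2 * unname(r[, ref_idx]) * instruments$se_xy * instruments$se_xy[ref_idx]
  var_d <- pmax(var_d, .Machine$double.eps)
  p_heidi <- pchisq(d^2 / var_d, df = 1, lower.tail = FALSE)
  flagged <- p_heidi < p_threshold
  flagged[ref_idx] <- FALSE
  p_heidi[ref_idx] <- NA_real_
  report <- tibble::tibble(
    snp = instruments$snp, d = d, se_d = sqrt(var_d), p_heidi = p_heidi,
    flagged = flagged, reference = ref
  )
  list(report = report, retained = instruments[!flagged, ])
}

# Internal: index of the HEIDI reference SNP — smallest exposure P, ties by
# largest |b_zx|, then snp id.
strength_order_heidi <- function(instruments) {
  order(instruments$p_zx, -abs(instruments$b_zx), instruments$snp)[1]
}

#' Classify the strength of MR evidence
#'
#' Three tiers: `none` above the global level, `potential` between the
#' Bonferroni-corrected and global levels, `significant` at or below the
#' corrected level.
#'
#' @param pvalue Two-sided P value(s) in (0, 1].
#' @param alpha Global significance level (default 0.05).
#' @param bonferroni Multiple-testing-corrected level (default 0.0017, i.e.
#'   0.05 corrected for 30 trait-outcome tests).
#' @return Character vector in `c("none", "potential", "significant")`.
#' @export
classify_evidence <- function(pvalue, alpha = 0.05, bonferroni = 0.0017) {
  if (any(pvalue <= 0 | pvalue > 1)) {
    stop_mrgls("pvalue must lie in (0, 1]", "mrgls_domain_error")
  }
  dplyr::case_when(
    pvalue <= bonferroni ~ "significant",
    pvalue <= alpha ~ "potential",
    TRUE ~ "none"
  )
}

#' GSMR analysis with HEIDI-outlier filtering
#'
#' The full estimator: optionally screen instruments with [heidi_outlier()]
#' (single pass by default; `iterate = TRUE` repeats until no instrument is
#' flagged), then pool the survivors with [gsmr_estimate()].
#'
#' @inheritParams gsmr_estimate
#' @param heidi Apply the HEIDI-outlier screen first.
#' @param p_heidi HEIDI flagging threshold.
#' @param iterate Repeat the screen to a fixed point instead of the default
#'   single pass.
#' @return An `mr_result` whose `outliers_removed` lists the flagged SNPs and
#'   whose `heidi_report` attribute holds the per-SNP report.
#' @export
mr_gsmr <- function(instruments, ld, trait = "exposure", outcome = "outcome",
                    heidi = TRUE, p_heidi = 0.01, iterate = FALSE,
                    alpha = 0.05, bonferroni = 0.0017) {
  removed <- character()
  report <- NULL
  if (heidi) {
    repeat {
      h <- heidi_outlier(instruments, ld, p_threshold = p_heidi)
      report <- if (is.null(report)) h$report else
        dplyr::bind_rows(report, dplyr::filter(h$report, .data$flagged))
      newly <- h$report$snp[h$report$flagged]
      removed <- c(removed, newly)
      instruments <- h$retained
      if (!iterate || length(newly) == 0) break
    }
  }
  res <- gsmr_estimate(instruments, ld, trait = trait, outcome = outcome,
                       alpha = alpha, bonferroni = bonferroni,
                       outliers_removed = removed)
  attr(res, "heidi_report") <- report
  res
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("GSMR estimate: %s -> %s\n", x$trait, x$outcome))
  cat(sprintf("  OR %.3f (95%% CI %.3f-%.3f), P = %.3g [%s]\n",
              x$or_, x$ci_low, x$ci_high, x$pvalue, x$evidence_tier))
  cat(sprintf("  %d instrument(s) used", x$n_snps_used))
  if (length(x$outliers_removed) > 0) {
    cat(sprintf("; removed as pleiotropic: %s",
                paste(x$outliers_removed, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Tidy a GSMR fit into per-instrument rows
#'
#' @param x An `mr_result`.
#' @param ... Unused.
#' @return A tibble with one row per instrument used (snp, exposure and
#'   outcome effects, Wald ratio and its SE).
#' @export
tidy.mr_result <- function(x, ...) {
  dplyr::mutate(x$instruments, trait = x$trait, outcome = x$outcome,
                .before = 1)
}

#' One-row summary of a GSMR fit
#'
#' @param x An `mr_result`.
#' @param ... Unused.
#' @return A one-row tibble: trait, outcome, b_xy_hat, se_xy, or, ci_low,
#'   ci_high, pvalue, n_snps_used, n_outliers_removed, evidence_tier.
#' @export
glance.mr_result <- function(x, ...) {
  tibble::tibble(
    trait = x$trait, outcome = x$outcome,
    b_xy_hat = x$b_xy_hat, se_xy = x$se_xy,
    or = x$or_, ci_low = x$ci_low, ci_high = x$ci_high,
    pvalue = x$pvalue, n_snps_used = x$n_snps_used,
    n_outliers_removed = length(x$outliers_removed),
    evidence_tier = x$evidence_tier
  )
}

#' Effect-scatter plot of a GSMR fit
#'
#' Per-instrument exposure effects against outcome effects with one-SE error
#' bars and the pooled GSMR slope as a dashed line.
#'
#' @param object An `mr_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_result <- function(object, ...) {
  d <- object$instruments
  ggplot2::ggplot(d, ggplot2::aes(x = .data$b_zx, y = .data$b_zy)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$b_zy - .data$se_zy,
                                        ymax = .data$b_zy + .data$se_zy),
                           width = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$b_zx - .data$se_zx,
                                         xmax = .data$b_zx + .data$se_zx),
                            height = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$b_xy_hat, intercept = 0,
                         linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("SNP effect on %s (SD)", object$trait),
      y = sprintf("SNP effect on %s (log OR)", object$outcome),
      title = sprintf("GSMR: %s vs %s", object$trait, object$outcome),
      subtitle = sprintf("OR %.2f (95%% CI %.2f-%.2f), P = %.3g",
                         object$or_, object$ci_low, object$ci_high,
                         object$pvalue)
    ) +
    ggplot2::theme_minimal()
}

#' Write a results table mirroring a per-trait OR/CI/P layout
#'
#' @param results A list of `mr_result` objects (or a single one).
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_mr_results <- function(results, path) {
  if (inherits(results, "mr_result")) results <- list(results)
  tab <- purrr::map_dfr(results, glance) |>
    dplyr::mutate(outliers = purrr::map_chr(
      results, ~ paste(.x$outliers_removed, collapse = ",")
    ))
  readr::write_tsv(tab, path)
  invisible(path)
}
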