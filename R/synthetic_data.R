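#' Simulate a two-sample GWAS summary-statistic study with known truth
#'
#' Generates exposure and outcome per-SNP summary statistics under a
#' configurable true causal effect, so every pipeline stage can be tested
#' against ground truth. Effect-allele frequencies are uniform on
#' `eaf_range`; true exposure effects are drawn standard-normal and rescaled
#' so the instruments jointly explain `pve_target` of a unit-variance
#' exposure (`sum(2 p (1-p) b^2) = pve_target`). Observed exposure effects
#' add noise with `se_zx = 1 / sqrt(2 p (1-p) n_exposure)`. True outcome
#' effects are `true_b_xy * b_zx`, plus a log-OR offset `pleiotropy_effect`
#' for `n_pleiotropic` randomly chosen SNPs (planted horizontal pleiotropy);
#' observed outcome effects add noise with the case-control approximation
#' `se_zy = 1 / sqrt(2 p (1-p) N phi (1-phi))`, `phi = n_cases / N`. Noise
#' in both studies is drawn with the same block-LD correlation used for
#' pruning (`ld_noise = FALSE` gives independent noise). P values are
#' two-sided Wald. All draws come from a single seeded generator, so the
#' same seed reproduces the study exactly.
#'
#' @param n_snps Number of SNPs.
#' @param true_b_xy True causal effect (log OR per exposure SD).
#' @param n_exposure Exposure-study sample size.
#' @param n_cases,n_controls Outcome case-control counts.
#' @param eaf_range Interval in (0, 1) for effect-allele frequencies.
#' @param pve_target Fraction of exposure variance jointly explained.
#' @param ld_blocks Data frame with columns `size` and `r` describing
#'   block-diagonal LD (constant within-block correlation); block sizes must
#'   sum to `n_snps`. `NULL` means all SNPs independent.
#' @param n_pleiotropic Number of SNPs given a direct outcome effect.
#' @param pleiotropy_effect Log-OR offset added to those SNPs; length 1 or
#'   `n_pleiotropic` (e.g. balanced `c(+d, -d)` offsets).
#' @param pleiotropic_snps Optional explicit ids (`"snp_0003"`-style) or
#'   indices of the pleiotropic SNPs, overriding the random choice. The
#'   noise draws do not depend on this choice, so regenerating with the same
#'   seed but different planted SNPs keeps every other quantity identical.
#' @param effect_dist Distribution of the true exposure-effect magnitudes
#'   before PVE rescaling. `"normal"` draws standard-normal effects, so some
#'   SNPs are near-null and would not survive instrument selection;
#'   `"selected"` emulates a post-selection panel of GWAS hits, with
#'   magnitudes uniform on \[0.5, 1.5\] and random signs, so every SNP is a
#'   usable instrument.
#' @param ld_noise Correlate the summary-statistic noise across each LD
#'   block (the realistic regime, and what gives the HEIDI covariance term
#'   meaning).
#' @param seed Integer seed.
#' @return A list of class `synthetic_study`: `exposure` and `outcome`
#'   summary tibbles in the standard columns, `ld` (named matrix), and
#'   `truth` (`true_b_xy`, `pleiotropic` ids, true `b_zx`/`b_zy`, the
#'   generating parameters).
#' @export
simulate_two_sample <- function(n_snps = 30, true_b_xy = 0,
                                n_exposure = 100000,
                                n_cases = 12488, n_controls = 18169,
                                eaf_range = c(0.1, 0.9), pve_target = 0.05,
                                ld_blocks = NULL, n_pleiotropic = 0,
                                pleiotropy_effect = 0, pleiotropic_snps = NULL,
                                effect_dist = c("normal", "selected"),
                                ld_noise = TRUE, seed = 1) {
  effect_dist <- match.arg(effect_dist)
  if (!is.null(pleiotropic_snps)) n_pleiotropic <- length(pleiotropic_snps)
  if (pve_target <= 0 || pve_target >= 1) {
    stop_mrgls("pve_target must lie in (0, 1)", "mrgls_domain_error")
  }
  if (n_pleiotropic > n_snps) {
    stop_mrgls("n_pleiotropic cannot exceed n_snps", "mrgls_domain_error")
  }
  ld <- build_block_ld(n_snps, ld_blocks)
  withr::with_seed(seed, {
    snp <- sprintf("snp_%04d", seq_len(n_snps))
    dimnames(ld) <- list(snp, snp)
    eaf <- stats::runif(n_snps, eaf_range[1], eaf_range[2])
    b_raw <- switch(effect_dist,
      normal = stats::rnorm(n_snps),
      selected = sample(c(-1, 1), n_snps, replace = TRUE) *
        stats::runif(n_snps, 0.5, 1.5)
    )
    het <- 2 * eaf * (1 - eaf)
    b_zx <- b_raw * sqrt(pve_target / sum(het * b_raw^2))
    n_out <- n_cases + n_controls
    phi <- n_cases / n_out
    se_zx <- 1 / sqrt(het * n_exposure)
    se_zy <- 1 / sqrt(het * n_out * phi * (1 - phi))
    noise_r <- if (ld_noise) ld else diag(n_snps)
    l <- t(chol(noise_r))
    eps <- unname(drop(l %*% stats::rnorm(n_snps))) * se_zx
    eta <- unname(drop(l %*% stats::rnorm(n_snps))) * se_zy
    # Pleiotropy placement comes after the noise draws so that the same seed
    # yields identical noise regardless of how the planted set is chosen.
    pleio <- if (is.null(pleiotropic_snps)) {
      sort(sample(snp, n_pleiotropic))
    } else if (is.numeric(pleiotropic_snps)) {
      sort(snp[pleiotropic_snps])
    } else {
      sort(as.character(pleiotropic_snps))
    }
    if (!all(pleio %in% snp)) {
      stop_mrgls("pleiotropic_snps must name simulated SNPs", "mrgls_domain_error")
    }
    offsets <- rep(0, n_snps)
    offsets[match(pleio, snp)] <- rep_len(pleiotropy_effect,
                                          max(n_pleiotropic, 1))[seq_len(n_pleiotropic)]
    b_zy <- true_b_xy * b_zx + offsets
    b_zx_obs <- b_zx + eps
    b_zy_obs <- b_zy + eta
    study <- list(
      exposure = tibble::tibble(
        snp = snp, effect_allele = "A", other_allele = "G", eaf = eaf,
        beta = b_zx_obs, se = se_zx,
        p = 2 * pnorm(-abs(b_zx_obs / se_zx)), n = n_exposure
      ),
      outcome = tibble::tibble(
        snp = snp, effect_allele = "A", other_allele = "G", eaf = eaf,
        beta = b_zy_obs, se = se_zy,
        p = 2 * pnorm(-abs(b_zy_obs / se_zy)), n = n_out
      ),
      ld = ld,
      truth = list(
        true_b_xy = true_b_xy, pleiotropic = pleio,
        b_zx = setNames(b_zx, snp), b_zy = setNames(b_zy, snp),
        eaf = setNames(eaf, snp), se_zy = setNames(se_zy, snp),
        n_exposure = n_exposure, n_cases = n_cases, n_controls = n_controls,
        pve_target = pve_target, pleiotropy_effect = pleiotropy_effect,
        ld_noise = ld_noise, seed = seed
      )
    )
  })
  structure(study, class = "synthetic_study")
}

# Internal: block-diagonal LD with constant within-block correlation.
build_block_ld <- function(n_snps, ld_blocks) {
  if (is.null(ld_blocks)) return(diag(n_snps))
  if (sum(ld_blocks$size) != n_snps) {
    stop_mrgls("ld_blocks sizes must sum to n_snps", "mrgls_domain_error")
  }
  blocks <- purrr::map2(ld_blocks$size, ld_blocks$r, function(k, r) {
    m <- matrix(r, k, k); diag(m) <- 1; m
  })
  n <- sum(ld_blocks$size)
  out <- matrix(0, n, n)
  at <- 0
  for (b in blocks) {
    k <- nrow(b)
    out[at + seq_len(k), at + seq_len(k)] <- b
    at <- at + k
  }
  out
}

#' Redraw the outcome study of a synthetic two-sample design
#'
#' Keeps the exposure study, LD and ground truth fixed and draws a fresh
#' outcome summary table from the same generating model — useful for
#' simulating several outcome phenotypes against one instrument set.
#'
#' @param study A `synthetic_study`.
#' @param seed Integer seed for the new outcome noise.
#' @return The study with a newly drawn `outcome` tibble.
#' @export
resample_outcome <- function(study, seed) {
  tr <- study$truth
  n_snps <- nrow(study$outcome)
  noise_r <- if (tr$ld_noise) study$ld else diag(n_snps)
  withr::with_seed(seed, {
    eta <- drop(t(chol(noise_r)) %*% stats::rnorm(n_snps)) * tr$se_zy
  })
  b_obs <- unname(tr$b_zy) + unname(eta)
  study$outcome$beta <- b_obs
  study$outcome$p <- 2 * pnorm(-abs(b_obs / study$outcome$se))
  study
}

#' Write a synthetic study to disk as pipeline-ready fixtures
#'
#' Writes the exposure and outcome summary tables and the LD matrix in the
#' text dialects that [read_gwas_summary()] and [read_ld_matrix()] read back
#' unchanged, plus the ground truth as JSON.
#'
#' @param study A `synthetic_study`.
#' @param out_dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the paths written (`exposure`,
#'   `outcome`, `ld`, `truth`).
#' @export
make_fixture_tables <- function(study, out_dir, prefix = "study") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop_mrgls(paste0("cannot create directory: ", out_dir), "mrgls_io_error")
  }
  paths <- c(
    exposure = file.path(out_dir, paste0(prefix, "_exposure.tsv")),
    outcome = file.path(out_dir, paste0(prefix, "_outcome.tsv")),
    ld = file.path(out_dir, paste0(prefix, "_ld.tsv")),
    truth = file.path(out_dir, paste0(prefix, "_truth.json"))
  )
  write_gwas_summary(study$exposure, paths["exposure"])
  write_gwas_summary(study$outcome, paths["outcome"])
  write_ld_matrix(study$ld, paths["ld"])
  jsonlite::write_json(
    list(true_b_xy = study$truth$true_b_xy,
         pleiotropic = study$truth$pleiotropic,
         b_zx = as.list(study$truth$b_zx),
         b_zy = as.list(study$truth$b_zy),
         seed = study$truth$seed),
    paths["truth"], auto_unbox = TRUE, digits = NA
  )
  paths
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic two-sample study: %d SNP(s), true b_xy = %g\n",
              nrow(x$exposure), x$truth$true_b_xy))
  if (length(x$truth$pleiotropic) > 0) {
    cat(sprintf("  pleiotropic: %s\n", paste(x$truth$pleiotropic, collapse = ", ")))
  }
  invisible(x)
}
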