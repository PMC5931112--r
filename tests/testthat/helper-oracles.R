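# Shared fixtures and independent oracles for the test suite.

# A small well-formed summary tibble.
toy_records <- function() {
  tibble::tibble(
    snp = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "C", "G"),
    other_allele = c("G", "T", "T"),
    eaf = c(0.3, 0.5, 0.12),
    beta = c(0.10, -0.05, 0.02),
    se = c(0.01, 0.012, 0.008),
    p = c(1e-23, 3.1e-5, 0.012),
    n = c(10000, 10000, 10000)
  )
}

write_toy_file <- function(df, dialect = mrgls::gwas_dialect()) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  out <- df
  names(out) <- dialect[names(df)]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Constant-correlation LD matrix over the given ids.
const_ld <- function(ids, r = 0) {
  m <- matrix(r, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 1
  m
}

# Definitional pruning oracle: walk the SNPs in strength order (smallest p,
# then largest |beta|, then id) and keep a SNP iff its squared correlation
# with every already-kept SNP is below the threshold. Plain double loop,
# independent of the package's matrix-based implementation.
prune_oracle <- function(records, ld, r2_max) {
  ord <- order(records$p, -abs(records$beta), records$snp)
  kept <- character()
  for (s in records$snp[ord]) {
    ok <- TRUE
    for (k in kept) if (ld[s, k]^2 >= r2_max) { ok <- FALSE; break }
    if (ok) kept <- c(kept, s)
  }
  kept
}

# IVW oracle: inverse-variance-weighted mean of per-SNP ratios.
ivw_oracle <- function(b_xy, se_xy) {
  w <- 1 / se_xy^2
  list(b = sum(w * b_xy) / sum(w), se = 1 / sqrt(sum(w)))
}

# Simulate one study, harmonise and fit, returning estimate and SE.
fit_once <- function(seed, true_b_xy, n_snps = 30, pve_target = 0.05,
                     heidi = FALSE, ...) {
  s <- mrgls::simulate_two_sample(n_snps = n_snps, true_b_xy = true_b_xy,
                                  pve_target = pve_target, seed = seed, ...)
  h <- mrgls::harmonise(s$exposure, s$outcome)
  f <- mrgls::mr_gsmr(h, s$ld, heidi = heidi)
  c(b = f$b_xy_hat, se = f$se_xy)
}

# Build a 20-instrument panel with one pleiotropic SNP planted on a
# mid-strength non-reference instrument, with a deviation of `n_se` HEIDI
# deviation-SEs, and return the planted id plus the flagged set.
plant_outlier <- function(seed, n_se = 10) {
  base <- function(off, ids = NULL, n = 0) {
    mrgls::simulate_two_sample(
      n_snps = 20, true_b_xy = 0.1, pve_target = 0.05,
      n_pleiotropic = n, pleiotropy_effect = off, pleiotropic_snps = ids,
      effect_dist = "selected", seed = seed
    )
  }
  s0 <- base(0)
  h0 <- mrgls::harmonise(s0$exposure, s0$outcome)
  ord <- order(h0$p_zx, -abs(h0$b_zx), h0$snp)
  ref <- h0$snp[ord[1]]
  pl <- h0$snp[ord[10]]
  i <- match(pl, h0$snp); r <- match(ref, h0$snp)
  se_d <- sqrt(h0$se_xy[i]^2 + h0$se_xy[r]^2 -
                 2 * s0$ld[pl, ref] * h0$se_xy[i] * h0$se_xy[r])
  s <- base(n_se * se_d * abs(s0$truth$b_zx[pl]), ids = pl)
  h <- mrgls::harmonise(s$exposure, s$outcome)
  hh <- mrgls::heidi_outlier(h, s$ld)
  list(planted = pl, flagged = hh$report$snp[hh$report$flagged],
       study = s, harmonised = h)
}

# Published all-glioma estimates and prior calibration: trait, OR, 95% CI
# and the maximum likely OR taken from observational studies (2 where none
# exists). The last column is the printed minimum prior for BFNP > 0.1.
published_glioma_rows <- function() {
  tibble::tribble(
    ~trait,              ~or,  ~ci_low, ~ci_high, ~or_max, ~min_prior_printed,
    "2h_glucose",        1.25, 0.93,    1.67,     2.00,    0.10,
    "bmi",               0.91, 0.77,    1.07,     1.27,    0.11,
    "fasting_glucose",   1.00, 0.78,    1.30,     1.57,    0.18,
    "fasting_insulin",   1.32, 0.71,    2.46,     2.00,    0.12,
    "hdl",               1.01, 0.98,    1.05,     2.00,    0.64,
    "ldl",               1.00, 0.95,    1.05,     2.00,    0.61,
    "t2d",               1.04, 0.97,    1.11,     0.60,    0.31,
    "total_cholesterol", 0.98, 0.88,    1.09,     2.00,    0.41,
    "triglycerides",     1.01, 0.97,    1.06,     2.00,    0.60,
    "whr",               1.11, 0.84,    1.46,     2.00,    0.19
  )
}

# Rows whose printed minimum prior is sensitive to the rounding of the
# published CI (recomputation from 2-dp CIs lands on a different 2-dp
# value); excluded from exact reproduction.
rounding_sensitive_traits <- c("hdl", "triglycerides")

# Per-trait instrument bookkeeping: SNPs before QC, ids missing from the
# outcome study, ids removed as pleiotropic, and the expected final count.
published_qc_ledger <- function() {
  tibble::tibble(
    trait = c("2h_glucose", "bmi", "fasting_glucose", "fasting_insulin",
              "hdl", "ldl", "t2d", "total_cholesterol", "triglycerides",
              "whr"),
    n_pre_qc = c(7L, 75L, 33L, 13L, 54L, 26L, 38L, 39L, 25L, 33L),
    missing = list(
      character(), character(), character(), "rs1530559",
      character(), character(),
      c("rs2972156", "rs34706136", "rs11257658", "rs144613775"),
      "rs7570971", character(), character()
    ),
    heidi_outliers = list(
      character(), character(), character(), character(),
      character(), character(), character(),
      "rs11603023", "rs5756931", character()
    ),
    n_final = c(7L, 75L, 33L, 12L, 54L, 26L, 34L, 37L, 24L, 33L)
  )
}

# Build exposure/outcome summary tables realising one row of the QC ledger:
# the named missing SNPs are absent from the outcome study, everything else
# is shared. Deterministic filler statistics.
qc_ledger_tables <- function(n_pre_qc, missing, heidi_outliers = character()) {
  n_fill <- n_pre_qc - length(missing) - length(heidi_outliers)
  ids <- c(missing, heidi_outliers, sprintf("rs9%05d", seq_len(n_fill)))
  exposure <- tibble::tibble(
    snp = ids, effect_allele = "A", other_allele = "G",
    eaf = 0.3, beta = 0.05, se = 0.005, p = 1e-10, n = 1e5
  )
  outcome <- exposure[!(exposure$snp %in% missing), ]
  outcome$beta <- 0.01
  outcome$se <- 0.02
  outcome$p <- 0.5
  list(exposure = exposure, outcome = outcome)
}
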