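test_that("reading a well-formed table preserves records and order", {
  df <- toy_records()
  path <- write_toy_file(df)
  x <- read_gwas_summary(path)
  expect_equal(nrow(x), 3)
  expect_equal(x$snp, df$snp)
  expect_equal(x$beta, df$beta)
  expect_equal(x$se, df$se)
  expect_equal(nrow(rejected_rows(x)), 0)
})

test_that("invalid rows are rejected with their row index, or raised when strict", {
  df <- toy_records()
  df$se[2] <- 0
  path <- write_toy_file(df)
  expect_warning(x <- read_gwas_summary(path), "se not positive")
  expect_equal(nrow(x), 2)
  rej <- rejected_rows(x)
  expect_equal(rej$row, 2L)
  expect_equal(rej$snp, "rs2")
  expect_error(read_gwas_summary(path, strict = TRUE),
               class = "mrgls_validation_error")

  df2 <- toy_records()
  df2$beta <- as.character(df2$beta)
  df2$beta[3] <- "not_a_number"
  path2 <- write_toy_file(df2)
  expect_warning(x2 <- read_gwas_summary(path2), "unparsable beta")
  expect_equal(rejected_rows(x2)$row, 3L)
})

test_that("lower-case alleles are normalised and missing columns reported", {
  df <- toy_records()
  df$effect_allele[1] <- "a"
  df$other_allele[1] <- "g"
  x <- read_gwas_summary(write_toy_file(df))
  expect_equal(x$effect_allele[1], "A")
  expect_equal(x$other_allele[1], "G")

  path <- write_toy_file(toy_records())
  bad <- gwas_dialect(beta = "BETA_MISSING")
  expect_error(read_gwas_summary(path, dialect = bad),
               class = "mrgls_config_error")
})

test_that("summary tables round-trip through write and read exactly", {
  df <- toy_records()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gwas_summary(df, path)
  back <- read_gwas_summary(path)
  expect_equal(as.data.frame(back), as.data.frame(df), ignore_attr = TRUE)

  # remapped dialect round-trips too
  dia <- gwas_dialect(snp = "rsid", beta = "BETA", p = "P")
  write_gwas_summary(df, path, dialect = dia)
  back2 <- read_gwas_summary(path, dialect = dia)
  expect_equal(as.data.frame(back2), as.data.frame(df), ignore_attr = TRUE)
})

test_that("LD matrix reading validates shape, symmetry and range", {
  ids <- c("s1", "s2")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ld_matrix(diag(2) |> `dimnames<-`(list(ids, ids)), path)
  r <- read_ld_matrix(path)
  expect_equal(r["s1", "s2"], 0)
  expect_equal(diag(r), c(s1 = 1, s2 = 1))

  m <- matrix(c(1, 0.7, 0.7, 1), 2, dimnames = list(ids, ids))
  write_ld_matrix(m, path)
  expect_equal(read_ld_matrix(path)["s2", "s1"], 0.7)

  asym <- matrix(c(1, 0.2, 0.7, 1), 2, dimnames = list(ids, ids))
  write_ld_matrix(asym, path)
  expect_error(read_ld_matrix(path), class = "mrgls_validation_error")

  big <- matrix(c(1, 1.5, 1.5, 1), 2, dimnames = list(ids, ids))
  write_ld_matrix(big, path)
  expect_error(read_ld_matrix(path), class = "mrgls_validation_error")

  nonsq <- data.frame(snp = ids, s1 = c(1, 0), s2 = c(0, 1), s3 = c(0, 0))
  utils::write.table(nonsq, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_ld_matrix(path), class = "mrgls_format_error")
})

test_that("harmonisation aligns outcome effects onto the exposure effect allele", {
  exposure <- toy_records()[1, ]
  same <- exposure
  same$beta <- 0.04
  h <- harmonise(exposure, same)
  expect_equal(h$b_zy, 0.04)

  swapped <- exposure
  swapped$effect_allele <- "G"
  swapped$other_allele <- "A"
  swapped$eaf <- 1 - exposure$eaf
  swapped$beta <- 0.05
  h2 <- harmonise(exposure, swapped)
  expect_equal(h2$b_zy, -0.05)
  expect_equal(h2$eaf_outcome, exposure$eaf)

  # opposite strand: A/G reported as T/C
  flipped <- exposure
  flipped$effect_allele <- "T"
  flipped$other_allele <- "C"
  flipped$beta <- 0.03
  h3 <- harmonise(exposure, flipped)
  expect_equal(h3$b_zy, 0.03)

  # irreconcilable alleles
  bad <- exposure
  bad$effect_allele <- "T"
  bad$other_allele <- "G"
  h4 <- harmonise(exposure, bad)
  expect_equal(nrow(h4), 0)
  expect_equal(exclusion_report(h4)$reason, "allele mismatch")
})

test_that("SNPs absent from the outcome are excluded and listed", {
  exposure <- toy_records()
  outcome <- toy_records()[-2, ]
  h <- harmonise(exposure, outcome)
  expect_equal(h$snp, c("rs1", "rs3"))
  rep <- exclusion_report(h)
  expect_equal(rep$snp, "rs2")
  expect_equal(rep$reason, "missing in outcome")
})

test_that("palindromic SNPs are oriented by frequency or dropped", {
  exposure <- toy_records()[1, ]
  exposure$effect_allele <- "A"
  exposure$other_allele <- "T"
  exposure$eaf <- 0.2

  # conclusive, same side of 0.5: keep as-is
  outcome <- exposure
  outcome$beta <- 0.04
  outcome$eaf <- 0.25
  expect_equal(harmonise(exposure, outcome)$b_zy, 0.04)

  # conclusive but frequency on the other side: strand flip, sign flips
  outcome$eaf <- 0.8
  h <- harmonise(exposure, outcome)
  expect_equal(h$b_zy, -0.04)
  expect_equal(h$eaf_outcome, 0.2)

  # inconclusive frequency: dropped
  outcome$eaf <- 0.5
  h2 <- harmonise(exposure, outcome)
  expect_equal(nrow(h2), 0)
  expect_equal(exclusion_report(h2)$reason, "palindromic ambiguous")

  # missing eaf: always dropped
  outcome$eaf <- 0.25
  exposure$eaf <- NA_real_
  h3 <- harmonise(exposure, outcome)
  expect_equal(exclusion_report(h3)$reason, "palindromic ambiguous")
})

test_that("harmonisation is idempotent and invariant to flipping the outcome", {
  s <- simulate_two_sample(n_snps = 12, true_b_xy = 0.1, seed = 11)
  h <- harmonise(s$exposure, s$outcome)

  # rebuild an outcome table from the harmonised records and re-harmonise
  outcome2 <- tibble::tibble(
    snp = h$snp, effect_allele = h$effect_allele, other_allele = h$other_allele,
    eaf = h$eaf_outcome, beta = h$b_zy, se = h$se_zy, p = h$p_zy,
    n = s$outcome$n[match(h$snp, s$outcome$snp)]
  )
  h2 <- harmonise(s$exposure, outcome2)
  expect_equal(h2$b_zy, h$b_zy)
  expect_equal(h2$b_xy, h$b_xy)

  # flipping both alleles and the beta sign of every outcome record leaves
  # all downstream ratios unchanged
  flipped <- s$outcome
  flipped$effect_allele <- s$outcome$other_allele
  flipped$other_allele <- s$outcome$effect_allele
  flipped$beta <- -s$outcome$beta
  flipped$eaf <- 1 - s$outcome$eaf
  h3 <- harmonise(s$exposure, flipped)
  expect_equal(h3$b_xy, h$b_xy)
  expect_equal(h3$se_xy, h$se_xy)
})
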