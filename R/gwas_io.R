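#' Column mapping for GWAS summary-statistic files
#'
#' Describes how the columns of a summary-statistic text file map onto the
#' standard internal names. The defaults follow the GCTA-COJO `.ma` dialect
#' (`SNP A1 A2 freq b se p N`), the de-facto interchange format for
#' summary-data Mendelian randomisation. `A1` is the effect allele.
#'
#' @param snp,effect_allele,other_allele,eaf,beta,se,p,n Column names in the
#'   file. `eaf` and `n` may be set to `NA` if the file lacks them.
#' @return A named character vector usable as the `dialect` argument of
#'   [read_gwas_summary()].
#' @export
#' @examples
#' gwas_dialect(beta = "BETA", p = "P_VALUE")
gwas_dialect <- function(snp = "SNP", effect_allele = "A1", other_allele = "A2",
                         eaf = "freq", beta = "b", se = "se", p = "p", n = "N") {
  c(snp = snp, effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf, beta = beta, se = se, p = p, n = n)
}

VALID_ALLELES <- c("A", "C", "G", "T")
ALLELE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# Internal: per-row invariant check on a standardised summary tibble.
# Returns a tibble (row, snp, reason) of offending rows; one reason each.
validate_gwas_rows <- function(x) {
  reason <- rep(NA_character_, nrow(x))
  flag <- function(bad, msg) ifelse(is.na(reason) & bad, msg, reason)
  reason <- flag(is.na(x$snp) | x$snp == "", "missing snp id")
  reason <- flag(!(x$effect_allele %in% VALID_ALLELES) |
                   !(x$other_allele %in% VALID_ALLELES), "invalid allele")
  reason <- flag(x$effect_allele == x$other_allele, "identical alleles")
  reason <- flag(is.na(x$beta), "unparsable beta")
  reason <- flag(is.na(x$se), "unparsable se")
  reason <- flag(is.na(x$p), "unparsable p")
  reason <- flag(!is.na(x$se) & x$se <= 0, "se not positive")
  reason <- flag(!is.na(x$p) & (x$p <= 0 | x$p > 1), "p outside (0, 1]")
  reason <- flag(!is.na(x$eaf) & (x$eaf <= 0 | x$eaf >= 1), "eaf outside (0, 1)")
  tibble::tibble(row = seq_len(nrow(x)), snp = x$snp, reason = reason) |>
    dplyr::filter(!is.na(.data$reason))
}

#' Read GWAS summary statistics
#'
#' Reads a whitespace- or tab-delimited summary-statistic table with a header
#' and returns one record per SNP with standardised column names: `snp`,
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `p`, `n`. Alleles are
#' upper-cased. Effect sizes are interpreted per copy of the effect allele, in
#' SD units of the trait (or log odds ratio for a binary trait).
#'
#' Rows violating the record invariants (non-ACGT or identical alleles,
#' `se <= 0`, `p` outside (0, 1], `eaf` outside (0, 1), unparsable numerics)
#' are collected into a per-row report. With `strict = FALSE` (default) the
#' offending rows are dropped with a warning and the report is attached as
#' attribute `"rejected"` (see [rejected_rows()]); with `strict = TRUE` the
#' collected report is raised as an error.
#'
#' @param path Path to the file.
#' @param dialect Column mapping from [gwas_dialect()].
#' @param strict Raise an error on invalid rows instead of dropping them.
#' @return A tibble of validated records, row order preserved.
#' @export
read_gwas_summary <- function(path, dialect = gwas_dialect(), strict = FALSE) {
  if (!file.exists(path)) {
    stop_mrgls(paste0("file not found: ", path), "mrgls_io_error")
  }
  raw <- utils::read.table(path, header = TRUE, colClasses = "character",
                           check.names = FALSE, comment.char = "")
  mandatory <- c("snp", "effect_allele", "other_allele", "beta", "se", "p")
  missing_cols <- dialect[mandatory][!(dialect[mandatory] %in% names(raw))]
  if (length(missing_cols) > 0) {
    stop_mrgls(paste0("mandatory column(s) missing from header: ",
                      paste(missing_cols, collapse = ", ")),
               "mrgls_config_error")
  }
  get_col <- function(field) {
    nm <- dialect[[field]]
    if (is.na(nm) || !(nm %in% names(raw))) rep(NA_character_, nrow(raw)) else raw[[nm]]
  }
  num <- function(v) suppressWarnings(as.numeric(v))
  x <- tibble::tibble(
    snp = get_col("snp"),
    effect_allele = toupper(get_col("effect_allele")),
    other_allele = toupper(get_col("other_allele")),
    eaf = num(get_col("eaf")),
    beta = num(get_col("beta")),
    se = num(get_col("se")),
    p = num(get_col("p")),
    n = num(get_col("n"))
  )
  report <- validate_gwas_rows(x)
  if (nrow(report) > 0) {
    msg <- paste0(nrow(report), " row(s) failed validation: ",
                  paste(sprintf("row %d (%s): %s", report$row, report$snp,
                                report$reason), collapse = "; "))
    if (strict) stop_mrgls(msg, "mrgls_validation_error")
    warn(msg)
    x <- x[-report$row, ]
  }
  attr(x, "rejected") <- report
  x
}

#' Per-row validation report of a summary-statistic read
#'
#' @param x A tibble returned by [read_gwas_summary()].
#' @return A tibble with columns `row`, `snp`, `reason` (empty if all rows
#'   were valid).
#' @export
rejected_rows <- function(x) {
  attr(x, "rejected") %||%
    tibble::tibble(row = integer(), snp = character(), reason = character())
}

#' Write GWAS summary statistics
#'
#' Writes a standardised summary tibble back to the tab-delimited dialect read
#' by [read_gwas_summary()]; a write-then-read round trip reproduces the
#' records exactly.
#'
#' @param x Tibble with the standard summary columns.
#' @param path Output path.
#' @param dialect Column mapping from [gwas_dialect()].
#' @return `path`, invisibly.
#' @export
write_gwas_summary <- function(x, path, dialect = gwas_dialect()) {
  out <- x[, c("snp", "effect_allele", "other_allele", "eaf", "beta", "se", "p", "n")]
  names(out) <- dialect[names(out)]
  readr::write_tsv(out, path)
  invisible(path)
}

# Internal: shared structural validation of an LD correlation matrix.
validate_ld <- function(r, ids = NULL) {
  if (!is.matrix(r) || nrow(r) != ncol(r)) {
    stop_mrgls("LD matrix must be square", "mrgls_format_error")
  }
  if (is.null(ids)) ids <- rownames(r)
  if (is.null(ids) || length(ids) != nrow(r)) {
    stop_mrgls("LD matrix must carry one SNP id per row/column",
               "mrgls_format_error")
  }
  dimnames(r) <- list(ids, ids)
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stop_mrgls("LD correlations must lie in [-1, 1]", "mrgls_validation_error")
  }
  r[r > 1] <- 1
  r[r < -1] <- -1
  if (max(abs(r - t(r))) > 1e-8) {
    stop_mrgls("LD matrix is asymmetric beyond tolerance 1e-8",
               "mrgls_validation_error")
  }
  r <- (r + t(r)) / 2
  if (max(abs(diag(r) - 1)) > 1e-8) {
    stop_mrgls("LD matrix diagonal must be 1", "mrgls_validation_error")
  }
  diag(r) <- 1
  ev_min <- min(eigen(r, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-6) {
    warn(sprintf("LD matrix is not positive semi-definite (min eigenvalue %.3g)",
                 ev_min))
  }
  r
}

#' Read an LD correlation matrix
#'
#' Reads a square matrix of pairwise allelic correlations (r, not r-squared)
#' from a TSV whose first row and first column carry the SNP ids. Asymmetry
#' beyond 1e-8 and entries outside \[-1, 1\] (beyond 1e-12) are errors; values
#' within 1e-12 of the boundary are clipped.
#'
#' @param path Path to the TSV.
#' @return A named symmetric numeric matrix with unit diagonal.
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) {
    stop_mrgls(paste0("file not found: ", path), "mrgls_io_error")
  }
  raw <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           row.names = 1, comment.char = "")
  r <- as.matrix(raw)
  if (nrow(r) != ncol(r)) {
    stop_mrgls("LD matrix file is not square", "mrgls_format_error")
  }
  if (!identical(rownames(r), colnames(r))) {
    stop_mrgls("LD matrix row and column ids disagree", "mrgls_format_error")
  }
  storage.mode(r) <- "double"
  validate_ld(r)
}

#' Write an LD correlation matrix
#'
#' @param r Named symmetric matrix as returned by [read_ld_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(r, path) {
  out <- tibble::as_tibble(r, rownames = "snp")
  readr::write_tsv(out, path)
  invisible(path)
}

# Internal: TRUE for strand-ambiguous (A/T or C/G) allele pairs.
is_palindromic <- function(a1, a2) ALLELE_COMPLEMENT[a1] == a2

#' Harmonise exposure and outcome summary statistics
#'
#' Aligns the outcome study's effects onto the exposure study's effect allele
#' for every SNP present in both studies, and computes each instrument's Wald
#' ratio. When the outcome's effect allele is the exposure's other allele the
#' outcome beta's sign is flipped and its frequency replaced by its
#' complement; alleles reported on the opposite strand are resolved by
#' complementing. Palindromic (A/T, C/G) SNPs are oriented by allele frequency
#' when both studies report an EAF conclusively away from 0.5
#' (`min(eaf, 1 - eaf) < eaf_conclusive` in both), and dropped otherwise.
#' SNPs absent from the outcome, with irreconcilable alleles, or with a zero
#' exposure effect are excluded and listed in the report attached as
#' attribute `"exclusions"` (see [exclusion_report()]).
#'
#' @param exposure,outcome Summary tibbles in the standard columns of
#'   [read_gwas_summary()]. Exposure betas are per trait SD (or log OR for a
#'   binary exposure); outcome betas are log OR.
#' @param eaf_conclusive Frequency margin below which `min(eaf, 1 - eaf)`
#'   must fall, in both studies, for a palindromic SNP to be oriented by
#'   frequency.
#' @return A tibble of harmonised instruments with columns `snp`,
#'   `effect_allele`, `other_allele`, `eaf_exposure`, `eaf_outcome`, `b_zx`,
#'   `se_zx`, `p_zx`, `b_zy`, `se_zy`, `p_zy`, `b_xy`, `se_xy`, ordered as in
#'   `exposure`.
#' @export
harmonise <- function(exposure, outcome, eaf_conclusive = 0.42) {
  if (anyDuplicated(exposure$snp) || anyDuplicated(outcome$snp)) {
    stop_mrgls("duplicate snp ids within a study", "mrgls_validation_error")
  }
  excl <- tibble::tibble(snp = character(), reason = character())
  drop <- function(ids, reason) {
    if (length(ids) > 0) {
      excl <<- dplyr::bind_rows(excl, tibble::tibble(snp = ids, reason = reason))
    }
  }

  missing <- setdiff(exposure$snp, outcome$snp)
  drop(missing, "missing in outcome")

  j <- dplyr::inner_join(
    exposure,
    dplyr::rename_with(outcome, ~ paste0(.x, "_out"), -"snp"),
    by = "snp"
  )
  if (nrow(j) == 0) {
    out <- empty_harmonised()
    attr(out, "exclusions") <- excl
    return(out)
  }

  e1 <- j$effect_allele; e2 <- j$other_allele
  o1 <- j$effect_allele_out; o2 <- j$other_allele_out
  b_zy <- j$beta_out
  eaf_out <- j$eaf_out
  pal <- is_palindromic(e1, e2)
  keep <- rep(TRUE, nrow(j))
  reason <- rep(NA_character_, nrow(j))

  same_pair <- (o1 == e1 & o2 == e2) | (o1 == e2 & o2 == e1)
  o1c <- unname(ALLELE_COMPLEMENT[o1]); o2c <- unname(ALLELE_COMPLEMENT[o2])
  comp_pair <- !same_pair & ((o1c == e1 & o2c == e2) | (o1c == e2 & o2c == e1))

  mismatch <- !same_pair & !comp_pair
  keep[mismatch] <- FALSE; reason[mismatch] <- "allele mismatch"

  # Strand-complement non-palindromic SNPs: allele identity (and hence
  # frequency and sign handling) is preserved by relabelling.
  relabel <- comp_pair & !pal
  o1[relabel] <- o1c[relabel]; o2[relabel] <- o2c[relabel]

  # Nominal orientation onto the exposure effect allele.
  swapped <- keep & (o1 == e2)
  b_zy[swapped] <- -b_zy[swapped]
  eaf_out[swapped] <- 1 - eaf_out[swapped]

  # Palindromic SNPs: the complement-swapped reading is indistinguishable by
  # alleles, so orientation must come from the allele frequencies.
  f_exp <- j$eaf
  conclusive <- !is.na(f_exp) & !is.na(eaf_out) &
    pmin(f_exp, 1 - f_exp) < eaf_conclusive &
    pmin(eaf_out, 1 - eaf_out) < eaf_conclusive
  amb <- keep & pal & !conclusive
  keep[amb] <- FALSE; reason[amb] <- "palindromic ambiguous"
  flip <- keep & pal & conclusive & ((f_exp < 0.5) != (eaf_out < 0.5))
  b_zy[flip] <- -b_zy[flip]
  eaf_out[flip] <- 1 - eaf_out[flip]

  null_iv <- keep & j$beta == 0
  keep[null_iv] <- FALSE; reason[null_iv] <- "null exposure effect"

  drop(j$snp[!keep], reason[!keep])
  k <- which(keep)
  wr <- wald_ratio(j$beta[k], j$se[k], b_zy[k], j$se_out[k])
  out <- tibble::tibble(
    snp = j$snp[k],
    effect_allele = e1[k], other_allele = e2[k],
    eaf_exposure = f_exp[k], eaf_outcome = eaf_out[k],
    b_zx = j$beta[k], se_zx = j$se[k], p_zx = j$p[k],
    b_zy = b_zy[k], se_zy = j$se_out[k], p_zy = j$p_out[k],
    b_xy = wr$b_xy, se_xy = wr$se_xy
  )
  attr(out, "exclusions") <- excl
  out
}

empty_harmonised <- function() {
  tibble::tibble(
    snp = character(), effect_allele = character(), other_allele = character(),
    eaf_exposure = double(), eaf_outcome = double(),
    b_zx = double(), se_zx = double(), p_zx = double(),
    b_zy = double(), se_zy = double(), p_zy = double(),
    b_xy = double(), se_xy = double()
  )
}

#' SNP exclusion report from harmonisation
#'
#' @param x A tibble returned by [harmonise()].
#' @return A tibble with columns `snp`, `reason`.
#' @export
exclusion_report <- function(x) {
  attr(x, "exclusions") %||%
    tibble::tibble(snp = character(), reason = character())
}

#' Write an exclusion report
#'
#' @param x A tibble with columns `snp`, `reason` (as from
#'   [exclusion_report()]).
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
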