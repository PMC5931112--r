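#' Filter to genome-wide significant SNPs
#'
#' Retains exactly the records whose association P value is at or below the
#' threshold (inclusive, so a SNP at exactly 5.0e-8 is kept), preserving row
#' order.
#'
#' @param records Summary tibble with a `p` column.
#' @param p_threshold Significance threshold; default 5.0e-8, genome-wide
#'   significance.
#' @return The filtered tibble.
#' @export
filter_significant <- function(records, p_threshold = 5.0e-8) {
  dplyr::filter(records, .data$p <= p_threshold)
}

# Internal: deterministic instrument-strength ranking. Smallest exposure P
# first, ties broken by largest |beta|, then lexicographic snp id.
strength_order <- function(records) {
  order(records$p, -abs(records$beta), records$snp)
}

#' Evaluate missing LD entries through proxy SNPs
#'
#' Augments an LD matrix so that SNPs without direct LD entries borrow the
#' row/column of a designated proxy SNP. Proxies inform LD evaluation only;
#' they never substitute association statistics. Each substitution is logged
#' (attribute `"proxy_log"`) with the proxy id and the proxy-target r-squared.
#'
#' @param ld Named symmetric LD matrix.
#' @param proxy_table Tibble/data frame with columns `snp`, `proxy`, `r2`
#'   (the LD between the target SNP and its proxy, recorded for the log).
#' @return The augmented LD matrix, with attribute `"proxy_log"`.
#' @export
apply_proxies <- function(ld, proxy_table) {
  log <- tibble::tibble(snp = character(), proxy = character(), r2 = double())
  if (is.null(proxy_table) || nrow(proxy_table) == 0) {
    attr(ld, "proxy_log") <- log
    return(ld)
  }
  for (i in seq_len(nrow(proxy_table))) {
    snp <- proxy_table$snp[i]
    proxy <- proxy_table$proxy[i]
    if (snp %in% rownames(ld)) next
    if (!(proxy %in% rownames(ld))) {
      stop_mrgls(paste0("proxy SNP absent from LD matrix: ", proxy,
                        " (proxy for ", snp, ")"),
                 "mrgls_ld_error")
    }
    row <- ld[proxy, ]
    ld <- rbind(cbind(ld, row), c(row, 1))
    n <- nrow(ld)
    rownames(ld)[n] <- colnames(ld)[n] <- snp
    log <- dplyr::bind_rows(log, tibble::tibble(
      snp = snp, proxy = proxy, r2 = proxy_table$r2[i]
    ))
  }
  attr(ld, "proxy_log") <- log
  ld
}

#' Greedy LD pruning of instrument candidates
#'
#' Selects an independent instrument set by strongest-first greedy pruning:
#' candidates are ranked by strength (smallest exposure P, ties by largest
#' absolute beta, then snp id), the strongest is accepted, every remaining
#' candidate with squared correlation `r2 >= r2_max` against an accepted SNP
#' is discarded, and the process repeats. The output is pairwise independent
#' at the threshold. A selection log recording every decision — including,
#' for each discard, the accepted SNP that triggered it and the offending
#' r-squared — is attached as attribute `"selection_log"` (see
#' [selection_log()]).
#'
#' @param records Summary tibble of candidate instruments.
#' @param ld Named symmetric LD matrix covering all candidates (possibly via
#'   proxies).
#' @param r2_max Squared-correlation threshold; pairs at or above it are
#'   considered correlated. Default 0.01.
#' @param proxy_table Optional proxy table passed to [apply_proxies()] for
#'   SNPs lacking direct LD entries.
#' @return The retained records, in input order.
#' @export
ld_prune <- function(records, ld, r2_max = 0.01, proxy_table = NULL) {
  ld <- apply_proxies(ld, proxy_table)
  proxy_log <- attr(ld, "proxy_log")
  absent <- setdiff(records$snp, rownames(ld))
  if (length(absent) > 0) {
    stop_mrgls(paste0("SNP(s) absent from LD matrix and no proxy supplied: ",
                      paste(absent, collapse = ", ")),
               "mrgls_ld_error")
  }
  ord <- strength_order(records)
  remaining <- records$snp[ord]
  accepted <- character()
  log <- list()
  while (length(remaining) > 0) {
    top <- remaining[1]
    accepted <- c(accepted, top)
    log[[length(log) + 1]] <- tibble::tibble(
      snp = top, action = "kept", trigger = NA_character_, r2 = NA_real_
    )
    remaining <- remaining[-1]
    if (length(remaining) > 0) {
      r2 <- ld[remaining, top]^2
      hit <- r2 >= r2_max
      if (any(hit)) {
        log[[length(log) + 1]] <- tibble::tibble(
          snp = remaining[hit], action = "dropped", trigger = top,
          r2 = unname(r2[hit])
        )
        remaining <- remaining[!hit]
      }
    }
  }
  out <- records[records$snp %in% accepted, ]
  attr(out, "selection_log") <- dplyr::bind_rows(log)
  attr(out, "proxy_log") <- proxy_log
  out
}

#' Selection log of an LD pruning run
#'
#' @param x A tibble returned by [ld_prune()].
#' @return A tibble with columns `snp`, `action` (`kept`/`dropped`),
#'   `trigger` (the accepted SNP that caused a discard) and `r2`.
#' @export
selection_log <- function(x) {
  attr(x, "selection_log") %||%
    tibble::tibble(snp = character(), action = character(),
                   trigger = character(), r2 = double())
}

#' Proportion of exposure variance explained by an instrument set
#'
#' For independent SNPs with effects in SD units of a standardised trait,
#' the variance explained is the sum over SNPs of
#' `2 * eaf * (1 - eaf) * beta^2`.
#'
#' @param records Summary tibble; every record must have `eaf` and `beta`.
#' @return The PVE as a fraction.
#' @export
compute_pve <- function(records) {
  if (nrow(records) == 0) return(0)
  no_eaf <- records$snp[is.na(records$eaf)]
  if (length(no_eaf) > 0) {
    stop_mrgls(paste0("eaf required for PVE but missing for: ",
                      paste(no_eaf, collapse = ", ")),
               "mrgls_validation_error")
  }
  sum(2 * records$eaf * (1 - records$eaf) * records$beta^2)
}

#' First-stage F-statistic for instrument strength
#'
#' `F = ((n - k - 1) / k) * (pve / (1 - pve))` for `k` instruments jointly
#' explaining a fraction `pve` of the exposure variance in a study of size
#' `n`. Values below 10 conventionally flag weak-instrument bias.
#'
#' @param pve Fraction of exposure variance explained, in \[0, 1).
#' @param n Exposure-study sample size; must exceed `k + 1`.
#' @param k Number of instruments, at least 1.
#' @return The F-statistic (non-negative).
#' @export
f_statistic <- function(pve, n, k) {
  if (any(pve < 0 | pve >= 1)) {
    stop_mrgls("pve must lie in [0, 1)", "mrgls_domain_error")
  }
  if (any(k < 1) || any(n <= k + 1)) {
    stop_mrgls("need n > k + 1 >= 2", "mrgls_domain_error")
  }
  ((n - k - 1) / k) * (pve / (1 - pve))
}

#' Select an instrument panel for one trait
#'
#' Convenience wrapper chaining the significance filter and greedy LD
#' pruning, then summarising instrument strength (PVE and first-stage
#' F-statistic when EAFs and a sample size are available).
#'
#' @param records Exposure summary tibble.
#' @param ld Named LD matrix.
#' @param trait Trait name carried into the summary.
#' @param p_threshold,r2_max,proxy_table Passed to [filter_significant()] and
#'   [ld_prune()].
#' @param n_exposure Exposure sample size for the F-statistic; defaults to
#'   the maximum `n` in `records` when present.
#' @param binary Binary exposure: effects are log ORs, so no PVE/F is
#'   computed.
#' @return A list of class `instrument_panel` with elements `trait`,
#'   `records`, `pve`, `f_statistic`, `n_exposure`, `selection_log`.
#' @export
select_instruments <- function(records, ld, trait = "trait",
                               p_threshold = 5.0e-8, r2_max = 0.01,
                               proxy_table = NULL, n_exposure = NULL,
                               binary = FALSE) {
  sig <- filter_significant(records, p_threshold)
  kept <- ld_prune(sig, ld, r2_max = r2_max, proxy_table = proxy_table)
  if (is.null(n_exposure)) {
    n_exposure <- if (all(is.na(kept$n))) NA_real_ else max(kept$n, na.rm = TRUE)
  }
  pve <- NA_real_
  f <- NA_real_
  if (!binary && nrow(kept) > 0 && !anyNA(kept$eaf)) {
    pve <- compute_pve(kept)
    if (!is.na(n_exposure) && n_exposure > nrow(kept) + 1) {
      f <- f_statistic(pve, n_exposure, nrow(kept))
    }
  }
  structure(
    list(trait = trait, records = kept, pve = pve, f_statistic = f,
         n_exposure = n_exposure, selection_log = selection_log(kept)),
    class = "instrument_panel"
  )
}

#' @export
print.instrument_panel <- function(x, ...) {
  cat(sprintf("Instrument panel: %s\n", x$trait))
  cat(sprintf("  %d SNP(s) after selection\n", nrow(x$records)))
  if (!is.na(x$pve)) cat(sprintf("  PVE %.3f%%\n", 100 * x$pve))
  if (!is.na(x$f_statistic)) cat(sprintf("  F-statistic %.2f\n", x$f_statistic))
  invisible(x)
}
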