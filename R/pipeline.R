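#' Read a pipeline run configuration
#'
#' Loads a declarative YAML configuration describing a full multi-trait,
#' multi-outcome MR run. Expected keys: `traits` (list of `name`,
#' `exposure` file, optional `ld`, `binary`, `or_max`, `n_exposure`),
#' `outcomes` (list of `name`, `file`, optional `n_cases`/`n_controls`),
#' optional global `ld_matrix` and `proxy_table` paths, `thresholds`
#' (`p_gws`, `r2_max`, `p_heidi`, `alpha`, `tau`, and optionally
#' `bonferroni` — otherwise computed as `alpha / (traits x outcomes)`),
#' `output_dir`, `seed`. Relative file paths are resolved against the
#' config file's directory.
#'
#' @param path Path to the YAML file.
#' @return The configuration as a named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || is.na(p)) return(p)
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  cfg$traits <- purrr::map(cfg$traits, function(tr) {
    tr$exposure <- resolve(tr$exposure)
    if (!is.null(tr$ld)) tr$ld <- resolve(tr$ld)
    tr$binary <- isTRUE(tr$binary)
    tr
  })
  cfg$outcomes <- purrr::map(cfg$outcomes, function(o) {
    o$file <- resolve(o$file)
    o
  })
  if (!is.null(cfg$ld_matrix)) cfg$ld_matrix <- resolve(cfg$ld_matrix)
  if (!is.null(cfg$proxy_table)) cfg$proxy_table <- resolve(cfg$proxy_table)
  cfg$thresholds <- fill_thresholds(cfg$thresholds,
                                    n_traits = length(cfg$traits),
                                    n_outcomes = length(cfg$outcomes))
  cfg$seed <- cfg$seed %||% 1L
  cfg
}

# Internal: default thresholds; the Bonferroni level divides alpha by the
# number of trait-outcome cells actually configured.
fill_thresholds <- function(th, n_traits, n_outcomes) {
  th <- th %||% list()
  th$p_gws <- th$p_gws %||% 5.0e-8
  th$r2_max <- th$r2_max %||% 0.01
  th$p_heidi <- th$p_heidi %||% 0.01
  th$alpha <- th$alpha %||% 0.05
  th$tau <- th$tau %||% 0.1
  th$bonferroni <- th$bonferroni %||% (th$alpha / max(1, n_traits * n_outcomes))
  bad <- purrr::keep(th, ~ !is.numeric(.x) || .x <= 0 || .x >= 1)
  if (length(bad) > 0) {
    stop_mrgls(paste0("thresholds must lie in (0, 1): ",
                      paste(names(bad), collapse = ", ")),
               "mrgls_config_error")
  }
  th
}

#' Run the full MR pipeline over every trait-outcome pair
#'
#' For each configured trait and outcome: read the summary statistics,
#' select instruments (genome-wide significance filter, greedy LD pruning
#' with optional proxies), harmonise against the outcome, screen with the
#' HEIDI-outlier test, pool by GSMR, classify the evidence tier, and — when
#' the inputs allow — compute a power curve and the Bayesian minimum prior
#' for a reliable null. A failure in one cell is logged and does not stop
#' the others. Every SNP of every exposure input is accounted for exactly
#' once per cell in the per-SNP log, either as `used` or as excluded with a
#' reason.
#'
#' @param config A configuration list from [read_run_config()], or a path to
#'   the YAML file.
#' @return A list of class `mr_pipeline` with elements `results` (one row
#'   per cell, Table-2-like), `instruments` (per-trait panel summary,
#'   Table-1-like), `bfnp` (Table-3-like), `power_curves`, `snp_log`
#'   (per-SNP accounting), `failures`, and `config`. If
#'   `config$output_dir` is set the tables are also written there as TSV
#'   plus a machine-readable JSON run log.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  th <- config$thresholds
  proxy_table <- if (!is.null(config$proxy_table)) {
    readr::read_tsv(config$proxy_table, show_col_types = FALSE)
  } else NULL
  global_ld <- if (!is.null(config$ld_matrix)) read_ld_matrix(config$ld_matrix) else NULL

  outcomes <- purrr::map(config$outcomes, function(o) {
    o$data <- tryCatch(read_gwas_summary(o$file), error = function(e) e)
    o
  })

  results <- list(); fits <- list(); instruments <- list(); bfnp_rows <- list()
  power_rows <- list(); snp_log <- list(); failures <- list()

  for (tr in config$traits) {
    exposure <- tryCatch(read_gwas_summary(tr$exposure), error = function(e) e)
    ld <- tryCatch(
      if (!is.null(tr$ld)) read_ld_matrix(tr$ld) else
        global_ld %||% stop_mrgls("no LD matrix configured", "mrgls_config_error"),
      error = function(e) e
    )
    panel <- NULL
    if (!inherits(exposure, "error") && !inherits(ld, "error")) {
      panel <- tryCatch(
        select_instruments(exposure, ld, trait = tr$name,
                           p_threshold = th$p_gws, r2_max = th$r2_max,
                           proxy_table = proxy_table,
                           n_exposure = tr$n_exposure,
                           binary = tr$binary),
        error = function(e) e
      )
    }
    if (inherits(exposure, "error") || inherits(ld, "error") ||
        inherits(panel, "error")) {
      err <- purrr::detect(list(exposure, ld, panel), ~ inherits(.x, "error"))
      for (o in outcomes) {
        failures[[length(failures) + 1]] <- tibble::tibble(
          trait = tr$name, outcome = o$name, stage = "load/select",
          reason = conditionMessage(err)
        )
      }
      next
    }
    instruments[[length(instruments) + 1]] <- tibble::tibble(
      trait = tr$name, n_snps = nrow(panel$records),
      pve = panel$pve, f_statistic = panel$f_statistic,
      n_exposure = panel$n_exposure %||% NA_real_
    )
    # Selection bookkeeping shared by every outcome cell of this trait.
    sel_excl <- dplyr::bind_rows(
      tibble::tibble(
        snp = setdiff(exposure$snp, filter_significant(exposure, th$p_gws)$snp),
        reason = "not genome-wide significant"
      ),
      selection_log(panel$records) |>
        dplyr::filter(.data$action == "dropped") |>
        dplyr::transmute(snp = .data$snp,
                         reason = paste0("correlated with ", .data$trigger))
    )

    for (o in outcomes) {
      if (inherits(o$data, "error")) {
        failures[[length(failures) + 1]] <- tibble::tibble(
          trait = tr$name, outcome = o$name, stage = "outcome load",
          reason = conditionMessage(o$data)
        )
        next
      }
      cell <- tryCatch({
        h <- harmonise(panel$records, o$data)
        fit <- mr_gsmr(h, ld, trait = tr$name, outcome = o$name,
                       p_heidi = th$p_heidi, alpha = th$alpha,
                       bonferroni = th$bonferroni)
        harm_excl <- exclusion_report(h)
        used <- setdiff(h$snp, fit$outliers_removed)
        log <- dplyr::bind_rows(
          sel_excl,
          harm_excl,
          tibble::tibble(snp = fit$outliers_removed,
                         reason = "pleiotropic (HEIDI)"),
          tibble::tibble(snp = used, reason = "used")
        ) |>
          dplyr::mutate(trait = tr$name, outcome = o$name,
                        status = ifelse(.data$reason == "used", "used",
                                        "excluded"),
                        .before = 1)
        list(fit = fit, log = log)
      }, error = function(e) e)
      if (inherits(cell, "error")) {
        failures[[length(failures) + 1]] <- tibble::tibble(
          trait = tr$name, outcome = o$name, stage = "estimate",
          reason = conditionMessage(cell)
        )
        next
      }
      fits[[length(fits) + 1]] <- cell$fit
      snp_log[[length(snp_log) + 1]] <- cell$log
      g <- glance(cell$fit) |>
        dplyr::mutate(outliers = paste(cell$fit$outliers_removed,
                                       collapse = ","))
      results[[length(results) + 1]] <- g
      bfnp_rows[[length(bfnp_rows) + 1]] <- tibble::tibble(
        trait = tr$name, outcome = o$name,
        or = g$or, ci_low = g$ci_low, ci_high = g$ci_high,
        or_max = tr$or_max %||% NA_real_
      )
      if (!is.na(panel$pve) && !is.null(o$n_cases) && !is.null(o$n_controls)) {
        power_rows[[length(power_rows) + 1]] <- power_curve(
          o$n_cases, o$n_controls, panel$pve,
          trait = tr$name, alpha = th$alpha
        ) |>
          dplyr::mutate(outcome = o$name, .after = "trait")
      }
    }
  }

  out <- structure(list(
    results = dplyr::bind_rows(results),
    instruments = dplyr::bind_rows(instruments),
    bfnp = if (length(bfnp_rows) > 0) {
      bfnp_table(dplyr::bind_rows(bfnp_rows), tau = th$tau)
    } else tibble::tibble(),
    power_curves = dplyr::bind_rows(power_rows),
    snp_log = dplyr::bind_rows(snp_log),
    failures = dplyr::bind_rows(failures),
    config = config
  ), class = "mr_pipeline")
  if (!is.null(config$output_dir)) write_pipeline_outputs(out, config$output_dir)
  out
}

# Internal: TSV tables plus a JSON run log in the output directory.
write_pipeline_outputs <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(x$results, file.path(dir, "results.tsv"))
  readr::write_tsv(x$instruments, file.path(dir, "instruments.tsv"))
  readr::write_tsv(x$bfnp, file.path(dir, "bfnp.tsv"))
  if (nrow(x$power_curves) > 0) {
    readr::write_tsv(x$power_curves, file.path(dir, "power_curves.tsv"))
  }
  readr::write_tsv(x$snp_log, file.path(dir, "snp_log.tsv"))
  jsonlite::write_json(
    list(
      n_cells = nrow(x$results), n_failures = nrow(x$failures),
      thresholds = x$config$thresholds,
      failures = x$failures, snp_log = x$snp_log
    ),
    file.path(dir, "run_log.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @export
print.mr_pipeline <- function(x, ...) {
  cat(sprintf("MR pipeline run: %d cell(s), %d failure(s)\n",
              nrow(x$results), nrow(x$failures)))
  print(x$results)
  invisible(x)
}

#' Write a simulated multi-trait, multi-outcome run to disk
#'
#' Generates one synthetic exposure study per trait, redraws its outcome
#' noise once per configured outcome, writes all tables plus a ready-to-run
#' YAML configuration, and returns the configuration path. Outcome files
#' contain the union of all traits' SNPs, as a real outcome GWAS would.
#'
#' @param dir Output directory.
#' @param n_traits Number of exposure traits.
#' @param outcome_names Names of the outcome phenotypes.
#' @param seed Integer seed; each trait and outcome derives its own stream.
#' @param true_b_xy True causal effect shared by all traits.
#' @param ... Further arguments to [simulate_two_sample()].
#' @return Path to the written `config.yaml`.
#' @export
simulate_run_inputs <- function(dir, n_traits = 10,
                                outcome_names = c("all_glioma", "gbm", "non_gbm"),
                                seed = 1, true_b_xy = 0, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  traits <- list()
  outcome_tables <- setNames(vector("list", length(outcome_names)), outcome_names)
  for (i in seq_len(n_traits)) {
    name <- sprintf("trait%02d", i)
    study <- simulate_two_sample(seed = seed + i, true_b_xy = true_b_xy, ...)
    # Per-trait snp ids must be unique across the union outcome file.
    rename <- function(ids) sub("^snp_", sprintf("%s_snp_", name), ids)
    study$exposure$snp <- rename(study$exposure$snp)
    dimnames(study$ld) <- list(rename(rownames(study$ld)),
                               rename(colnames(study$ld)))
    exposure_path <- file.path(dir, paste0(name, "_exposure.tsv"))
    ld_path <- file.path(dir, paste0(name, "_ld.tsv"))
    write_gwas_summary(study$exposure, exposure_path)
    write_ld_matrix(study$ld, ld_path)
    truth <- study$truth
    n_cc <- c(truth$n_cases, truth$n_controls)
    for (j in seq_along(outcome_names)) {
      redrawn <- resample_outcome(study, seed = seed + 7919L * j + i)
      redrawn$outcome$snp <- rename(redrawn$outcome$snp)
      outcome_tables[[j]] <- dplyr::bind_rows(outcome_tables[[j]],
                                              redrawn$outcome)
    }
    traits[[i]] <- list(name = name,
                        exposure = basename(exposure_path),
                        ld = basename(ld_path))
  }
  outcomes <- purrr::imap(outcome_tables, function(tab, nm) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    write_gwas_summary(tab, path)
    list(name = nm, file = basename(path),
         n_cases = n_cc[1], n_controls = n_cc[2])
  })
  config <- list(traits = traits, outcomes = unname(outcomes), seed = seed)
  config_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, config_path)
  config_path
}
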