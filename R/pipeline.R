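# End-to-end pipeline driver --------------------------------------------------

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a pipeline configuration in R
#'
#' Programmatic counterpart of [read_pipeline_config()]: same fields, same
#' defaults, no file needed.
#'
#' @param out_dir output directory (required).
#' @param cohort_csv optional path to an existing cohort CSV; when `NULL` a
#'   synthetic cohort of `n_pd` + `n_dp` patients is generated.
#' @param n_pd,n_dp synthetic group sizes.
#' @param sc_noise_sd logit-scale surgical-risk noise.
#' @param seed master seed for the whole run.
#' @param cutoff_grid strictly increasing cutoffs in percent.
#' @param mp_spec,sc_specs model specs ([logistic_model_spec()]).
#' @param rate_sets per-group [complication_rates()].
#' @param hl_bins Hosmer-Lemeshow bin counts to evaluate.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, cohort_csv = NULL, n_pd = 464, n_dp = 293,
                            sc_noise_sd = 0.4, seed = 1L, cutoff_grid = 1:99,
                            mp_spec = default_mp_spec(),
                            sc_specs = default_sc_specs(),
                            rate_sets = list(PD = default_rate_set("PD"),
                                             DP = default_rate_set("DP")),
                            hl_bins = c(10L, 5L)) {
  if (any(diff(cutoff_grid) <= 0)) {
    stop("configuration error: cutoff_grid must be strictly increasing",
         call. = FALSE)
  }
  structure(list(out_dir = out_dir, cohort_csv = cohort_csv, n_pd = n_pd,
                 n_dp = n_dp, sc_noise_sd = sc_noise_sd, seed = seed,
                 cutoff_grid = cutoff_grid, mp_spec = mp_spec,
                 sc_specs = sc_specs, rate_sets = rate_sets,
                 hl_bins = hl_bins),
            class = "pipeline_config")
}

#' Run the full risk-benefit analysis pipeline
#'
#' Drives both arms of the analysis: simulate (or load) a cohort, score it
#' with the malignancy and surgical-risk surrogates, build the balance
#' worksheet and the selected cutoffs per surgery group and severity,
#' compute confusion diagnostics at each selected cutoff plus cohort ROC/AUC
#' and Hosmer-Lemeshow calibration (10 % and 20 % quantile scales by
#' default), and summarise the direct per-patient `mp > sc` rule. All
#' randomness flows from the single config seed, so a rerun with the same
#' config is byte-identical. Every emitted table re-parses under the
#' package's own readers.
#'
#' @param config a `pipeline_config` from [read_pipeline_config()], or a
#'   plain list with the same fields.
#' @return invisibly, a list with the in-memory results (`cohort`,
#'   `balance` per group, `cutoffs`, `diagnostics`, `direct`,
#'   `calibration`); files are written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  log_lines <- c(
    paste0("ipmnbalance ", as.character(utils::packageVersion("ipmnbalance"))),
    paste0("run at seed ", cfg$seed)
  )
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort <- stage("cohort", {
    if (!is.null(cfg$cohort_csv)) {
      read_cohort(cfg$cohort_csv)
    } else {
      generate_cohort(cohort_config(n_pd = cfg$n_pd, n_dp = cfg$n_dp,
                                    rate_sets = cfg$rate_sets,
                                    sc_noise_sd = cfg$sc_noise_sd,
                                    seed = cfg$seed))
    }
  })
  cohort <- stage("score", {
    if (all(c("mp", "sc") %in% names(cohort))) cohort else {
      score_cohort(cohort, cfg$mp_spec, cfg$sc_specs,
                   sc_noise_sd = cfg$sc_noise_sd, seed = cfg$seed)
    }
  })
  write_cohort(cohort, file.path(cfg$out_dir, "scored_cohort.csv"))

  groups <- intersect(names(cfg$rate_sets), unique(cohort$surgery))
  balance <- list()
  cutoff_rows <- list()
  diag_rows <- list()
  for (g in groups) {
    sub <- cohort[cohort$surgery == g, ]
    tab <- stage(paste0("balance_", g), {
      build_balance_table(sub$malignant, sub$mp, cfg$cutoff_grid,
                          cfg$rate_sets[[g]])
    })
    balance[[g]] <- tab
    write_balance_table(tab, file.path(cfg$out_dir,
                                       paste0("balance_", g, ".tsv")))
    sel <- select_cutoffs(tab)
    for (s in names(sel)) {
      cutoff_rows[[paste(g, s)]] <- data.frame(
        group = g, severity = s, cutoff = sel[[s]],
        boundary = attr(sel, "boundary")[[s]])
      d <- diagnose_at_cutoff(sub$malignant, sub$mp, sel[[s]])
      diag_rows[[paste(g, s)]] <- data.frame(
        group = g, severity = s, cutoff = sel[[s]],
        n_under = d$n_under$count,
        pct_under = sprintf("%.1f", 100 * d$n_under$fraction),
        sensitivity = sprintf("%.4f", d$sensitivity),
        specificity = sprintf("%.4f", d$specificity),
        ppv = sprintf("%.4f", d$ppv),
        npv = sprintf("%.4f", d$npv),
        auc = sprintf("%.4f", d$auc))
    }
  }
  cutoffs <- do.call(rbind, cutoff_rows)
  diagnostics <- do.call(rbind, diag_rows)
  if (!is.null(cutoffs)) {
    write_tsv(cutoffs, file.path(cfg$out_dir, "selected_cutoffs.tsv"))
    write_tsv(diagnostics, file.path(cfg$out_dir, "diagnostics.tsv"))
  }

  direct <- stage("direct", summarize_direct(cohort$malignant, cohort$mp,
                                             cohort$sc))
  write_tsv(
    data.frame(rule = "mp_gt_sc",
               n_operate = direct$n_operate$count,
               pct_operate = sprintf("%.1f", 100 * direct$n_operate$fraction),
               surgery_reduction = sprintf("%.4f", direct$surgery_reduction),
               sensitivity = sprintf("%.4f", direct$diagnostics$sensitivity),
               specificity = sprintf("%.4f", direct$diagnostics$specificity),
               ppv = sprintf("%.4f", direct$diagnostics$ppv),
               npv = sprintf("%.4f", direct$diagnostics$npv),
               auc_point = sprintf("%.4f", direct$auc_point),
               auc_diff = sprintf("%.4f", direct$auc_diff)),
    file.path(cfg$out_dir, "direct_summary.tsv"))

  calibration <- stage("calibration", {
    lapply(stats::setNames(cfg$hl_bins, paste0("bins", cfg$hl_bins)),
           function(nb) hosmer_lemeshow(cohort$malignant, cohort$mp, nb))
  })
  for (nm in names(calibration)) {
    write_tsv(calibration[[nm]]$bin_table,
              file.path(cfg$out_dir, paste0("calibration_", nm, ".tsv")))
  }

  # echo the effective config so a run is self-describing
  echo <- list(n_pd = cfg$n_pd, n_dp = cfg$n_dp, seed = cfg$seed,
               sc_noise_sd = cfg$sc_noise_sd,
               cutoff_grid = range(cfg$cutoff_grid),
               hl_bins = cfg$hl_bins,
               cohort_csv = if (is.null(cfg$cohort_csv)) NA else cfg$cohort_csv,
               rate_sets = lapply(cfg$rate_sets, function(r) as.list(r$rate_ge)))
  yaml::write_yaml(echo, file.path(cfg$out_dir, "effective_config.yaml"))
  log_lines <- c(log_lines,
                 paste0("groups: ", paste(groups, collapse = ", ")),
                 paste0("cohort size: ", nrow(cohort)),
                 yaml::as.yaml(echo))
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))

  invisible(list(cohort = cohort, balance = balance, cutoffs = cutoffs,
                 diagnostics = diagnostics, direct = direct,
                 calibration = calibration))
}
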