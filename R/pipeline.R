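## End-to-end orchestration: simulate -> standardize -> label -> evaluate,
## with persisted stage outputs and a report mirroring the standard clinical
## table layout (variable, OR, 95% CI, P per analysis block).

#' Pipeline configuration
#'
#' @param simulation A [sim_config()] (or list of its arguments).
#' @param max_interval Affected-healthy pairing tolerance, seconds.
#' @param summary_method Phase representative, `"median"` or `"mean"`.
#' @param normal_reference Optional named vector of constant normal reference
#'   values per indicator for the diagnostic [standardized_values()] output.
#' @param stepwise_direction `"backward"` or `"forward"`.
#' @param alpha Significance level gating univariate candidates into the
#'   stepwise model and the stay/entry threshold (default 0.05).
#' @param out_dir Optional output directory; when set, every stage's output
#'   is persisted there.
#' @param verbose Log stage progress and per-patient pairing yield to stderr.
#' @return Object of class `baep_pipeline_config`.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            max_interval = 180,
                            summary_method = c("median", "mean"),
                            normal_reference = NULL,
                            stepwise_direction = c("backward", "forward"),
                            alpha = 0.05,
                            out_dir = NULL,
                            verbose = FALSE) {
  if (!inherits(simulation, "baep_sim_config"))
    simulation <- do.call(sim_config, simulation)
  summary_method <- match.arg(summary_method)
  stepwise_direction <- match.arg(stepwise_direction)
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1)
    stop_config("alpha must lie strictly between 0 and 1")
  if (!is_scalar_number(max_interval) || max_interval <= 0)
    stop_config("max_interval must be > 0")
  structure(list(simulation = simulation, max_interval = max_interval,
                 summary_method = summary_method,
                 normal_reference = normal_reference,
                 stepwise_direction = stepwise_direction, alpha = alpha,
                 out_dir = out_dir, verbose = isTRUE(verbose)),
            class = "baep_pipeline_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Every [pipeline_config()] and nested [sim_config()] default can be
#' overridden; unnamed fields keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A `baep_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  raw <- raw %||% list()
  sim_args <- raw$simulation %||% list()
  for (nm in c("reference_latencies", "reference_amplitudes",
               "common_mode_sd", "measurement_noise_sd", "patient_scale_sd"))
    if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
  top <- raw[setdiff(names(raw), "simulation")]
  do.call(pipeline_config, c(list(simulation = do.call(sim_config, sim_args)),
                             top))
}

safe_univariate <- function(x, y, variable) {
  tryCatch(univariate_logistic(x, y, variable),
           error = function(e)
             data.frame(variable = variable, n = sum(stats::complete.cases(x, y)),
                        odds_ratio = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_,
                        analysis = "univariate", status = "insufficient"))
}

analysis_block <- function(data, outcome, vars, alpha, direction) {
  uni <- do.call(rbind, lapply(vars, function(v)
    safe_univariate(data[[v]], outcome, v)))
  cand <- uni$variable[!is.na(uni$p_value) & uni$p_value <= alpha &
                         uni$status == "ok"]
  multi <- if (length(cand))
    multivariate_stepwise(data, outcome, cand, direction = direction,
                          alpha = alpha)
  else NULL
  list(univariate = uni, candidates = cand, multivariate = multi)
}

safe_roc <- function(x, y, variable) {
  tryCatch(roc_analysis(x, y, variable), error = function(e) NULL)
}

#' Evaluate standardized-index predictors of hearing preservation
#'
#' Runs the three analysis blocks of the evaluation battery on a per-patient
#' index table: (1) preoperative HP vs pre-resection raw and STI indicators;
#' (2) postoperative HP vs post-resection raw and STI indicators; (3) among
#' preoperatively hearing-preserved patients, postoperative HP vs the
#' intraoperative differences D and standardized differences STD. Each block
#' screens every indicator univariately, feeds the significant ones into the
#' stepwise multivariate model, and adds ROC analyses of the wave-V
#' predictors plus paired DeLong AUC comparisons of standardized vs raw
#' wave-V amplitude.
#'
#' @param indices Wide per-patient table from [standardize_cohort()].
#' @param labels Per-patient HP labels from [hp_labels()] (must include
#'   `hp_pre` and `hp_post`).
#' @param alpha Candidate/stay threshold.
#' @param direction Stepwise direction.
#' @return List with `pre`, `post`, `diff` analysis blocks, `roc` (list of
#'   `baep_roc`), and `auc_tests` (list of `baep_auc_test`).
#' @export
evaluate_predictors <- function(indices, labels, alpha = 0.05,
                                direction = "backward") {
  for (col in c("hp_pre", "hp_post"))
    if (is.null(labels[[col]]))
      stop_config("labels table lacks required column: %s", col)
  df <- merge(indices, labels, by = "patient_id")
  ind <- baep_indicators()

  pre_vars <- c(paste0("raw_pre_", ind), paste0("sti_pre_", ind))
  post_vars <- c(paste0("raw_post_", ind), paste0("sti_post_", ind))
  diff_vars <- c(paste0("d_", ind), paste0("std_", ind))

  pre <- analysis_block(df, df$hp_pre, pre_vars, alpha, direction)
  post <- analysis_block(df, df$hp_post, post_vars, alpha, direction)
  hp_sub <- df[df$hp_pre %in% TRUE, , drop = FALSE]
  diffb <- analysis_block(hp_sub, hp_sub$hp_post, diff_vars, alpha, direction)

  roc <- list()
  for (v in c("raw_pre_la_v", "raw_pre_am_v", "sti_pre_la_v", "sti_pre_am_v"))
    roc[[v]] <- safe_roc(df[[v]], df$hp_pre, v)
  for (v in c("raw_post_la_v", "raw_post_am_v", "sti_post_la_v", "sti_post_am_v"))
    roc[[v]] <- safe_roc(df[[v]], df$hp_post, v)
  for (v in c("d_am_v", "std_am_v"))
    roc[[v]] <- safe_roc(hp_sub[[v]], hp_sub$hp_post, v)

  safe_cmp <- function(a, b, y) tryCatch(compare_aucs(a, b, y),
                                         error = function(e) NULL)
  auc_tests <- list(
    pre_sti_am_v_vs_raw_la_v =
      safe_cmp(df$sti_pre_am_v, df$raw_pre_la_v, df$hp_pre),
    post_sti_am_v_vs_raw_am_v =
      safe_cmp(df$sti_post_am_v, df$raw_post_am_v, df$hp_post),
    diff_std_am_v_vs_d_am_v =
      safe_cmp(hp_sub$std_am_v, hp_sub$d_am_v, hp_sub$hp_post))
  auc_tests <- Filter(Negate(is.null), auc_tests)

  list(pre = pre, post = post, diff = diffb, roc = roc, auc_tests = auc_tests)
}

cohort_summary <- function(cohort, indices) {
  p <- cohort$patients
  num <- function(f) vapply(p, f, 0)
  yield <- (indices$n_pairs_pre + indices$n_pairs_post) / indices$n_epochs
  list(n_patients = length(p),
       age_mean = mean(num(function(x) x$age)),
       age_sd = stats::sd(num(function(x) x$age)),
       pct_female = round_half_up(100 * mean(vapply(p, function(x)
         x$sex == "female", TRUE)), 1),
       pct_left = round_half_up(100 * mean(vapply(p, function(x)
         x$affected_side == "left", TRUE)), 1),
       diameter_mean = mean(num(function(x) x$tumor_diameter_mm)),
       diameter_sd = stats::sd(num(function(x) x$tumor_diameter_mm)),
       koos = table(vapply(p, function(x) x$koos_grade, "")),
       pairing_yield_mean = mean(yield))
}

#' Run the full standardized-BAEP analysis pipeline
#'
#' Simulates a cohort, pairs and standardizes every patient's binaural
#' feature streams, labels hearing preservation from audiometry, and runs the
#' predictor-evaluation battery. Deterministic given the simulation seed.
#' When `config$out_dir` is set, all stage outputs are persisted:
#' `features.csv`, `hearing.csv`, `manifest.json`, `indices.csv` (wide) and
#' `indices_long.csv`, `outcomes.json`, the per-block regression tables as
#' CSV, ROC summaries and curves, `report.json` and `report.md`.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `baep_report`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "baep_pipeline_config"))
    stop_config("config must be a baep_pipeline_config")
  log_msg <- function(...) if (config$verbose) message(sprintf(...))

  log_msg("stage simulate: %d patients, seed %d",
          config$simulation$n_patients, config$simulation$seed)
  cohort <- simulate_cohort(config$simulation)

  log_msg("stage standardize: pairing (max interval %g s), %s summaries",
          config$max_interval, config$summary_method)
  indices <- standardize_cohort(cohort, max_interval = config$max_interval,
                                method = config$summary_method)
  if (config$verbose) {
    yield <- (indices$n_pairs_pre + indices$n_pairs_post) / indices$n_epochs
    for (i in seq_len(nrow(indices)))
      message(sprintf("  %s: %d+%d pairs from %d epochs (yield %.2f)",
                      indices$patient_id[i], indices$n_pairs_pre[i],
                      indices$n_pairs_post[i], indices$n_epochs[i], yield[i]))
  }

  log_msg("stage label: AAO-HNS classification")
  hearing <- cohort_hearing(cohort)
  labels <- hp_labels(hearing)
  outcomes <- outcome_table(hearing)

  log_msg("stage evaluate: logistic screen, stepwise %s, ROC",
          config$stepwise_direction)
  eval_res <- evaluate_predictors(indices, labels, alpha = config$alpha,
                                  direction = config$stepwise_direction)
  groups <- group_comparisons(hearing)

  report <- structure(
    list(summary = cohort_summary(cohort, indices),
         outcomes = outcomes,
         tables = eval_res[c("pre", "post", "diff")],
         roc = eval_res$roc, auc_tests = eval_res$auc_tests,
         group_tests = groups,
         indices = indices, labels = labels,
         provenance = list(seed = config$simulation$seed,
                           config_hash = config_hash(config),
                           timestamp = format(Sys.time(), tz = "UTC"),
                           package_version = as.character(
                             utils::packageVersion("baepstd")))),
    class = "baep_report")

  if (!is.null(config$out_dir)) {
    log_msg("stage report: writing to %s", config$out_dir)
    write_report(report, cohort, config)
  }
  report
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  cfg <- rapply(unclass(config), unclass, how = "replace")
  cfg$out_dir <- NULL
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

block_csv <- function(block, path) {
  uni <- block$univariate
  multi <- block$multivariate
  if (!is.null(multi) && nrow(multi)) uni <- rbind(uni, multi)
  utils::write.csv(uni, path, row.names = FALSE)
}

write_report <- function(report, cohort, config) {
  dir <- config$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(cohort, dir)
  utils::write.csv(report$indices, file.path(dir, "indices.csv"),
                   row.names = FALSE)
  utils::write.csv(indices_long(report$indices),
                   file.path(dir, "indices_long.csv"), row.names = FALSE)
  jsonlite::write_json(list(schema_version = "1", outcomes = report$outcomes),
                       file.path(dir, "outcomes.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  block_csv(report$tables$pre, file.path(dir, "table_pre_resection.csv"))
  block_csv(report$tables$post, file.path(dir, "table_post_resection.csv"))
  block_csv(report$tables$diff, file.path(dir, "table_intraop_difference.csv"))
  roc_df <- do.call(rbind, lapply(Filter(Negate(is.null), report$roc),
                                  function(r)
    data.frame(variable = r$variable, auc = r$auc, cutoff = r$cutoff,
               sensitivity = r$sensitivity, specificity = r$specificity,
               direction = r$direction, n_pos = r$n_pos, n_neg = r$n_neg)))
  utils::write.csv(roc_df, file.path(dir, "roc_summary.csv"),
                   row.names = FALSE)
  curves <- do.call(rbind, lapply(Filter(Negate(is.null), report$roc),
                                  function(r)
    cbind(variable = r$variable, r$curve)))
  utils::write.csv(curves, file.path(dir, "roc_curves.csv"),
                   row.names = FALSE)
  utils::write.csv(report$group_tests, file.path(dir, "group_tests.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(schema_version = "1", provenance = report$provenance,
         auc_tests = lapply(report$auc_tests, unclass)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  writeLines(report_markdown(report), file.path(dir, "report.md"))
  invisible(dir)
}

fmt_or <- function(row) {
  if (is.na(row$odds_ratio)) return(sprintf("- (%s)", row$status))
  sprintf("%.3f (%.3f-%.3f), P = %.3g%s", row$odds_ratio, row$ci_low,
          row$ci_high, row$p_value,
          if (row$status != "ok") paste0(" [", row$status, "]") else "")
}

report_markdown <- function(report) {
  out <- c("# Standardized BAEP analysis report", "",
           sprintf("Seed %d, config %s, generated %s (baepstd %s)",
                   report$provenance$seed, report$provenance$config_hash,
                   report$provenance$timestamp,
                   report$provenance$package_version), "",
           "## Cohort", "",
           sprintf("- %d patients; age %.1f +/- %.1f; %.1f%% female; %.1f%% left-sided",
                   report$summary$n_patients, report$summary$age_mean,
                   report$summary$age_sd, report$summary$pct_female,
                   report$summary$pct_left),
           sprintf("- mean pairing yield %.2f (pairs per epoch)",
                   report$summary$pairing_yield_mean), "",
           "## Hearing outcomes", "",
           sprintf("- preoperative HP: %d/%d (%.1f%%)",
                   report$outcomes$n_preop_hp, report$outcomes$n_patients,
                   report$outcomes$preop_hp_rate_pct),
           sprintf("- postoperative HP: %d/%d preop-HP patients (%.1f%%)",
                   report$outcomes$n_postop_hp, report$outcomes$n_preop_hp,
                   report$outcomes$postop_hp_rate_pct), "")
  for (nm in c("pre", "post", "diff")) {
    title <- c(pre = "Pre-resection predictors of preoperative HP",
               post = "Post-resection predictors of postoperative HP",
               diff = "Intraoperative-difference predictors of postoperative HP")[nm]
    block <- report$tables[[nm]]
    out <- c(out, paste("##", title), "",
             "| variable | analysis | OR (95% CI), P |", "|---|---|---|")
    tab <- block$univariate
    if (!is.null(block$multivariate) && nrow(block$multivariate))
      tab <- rbind(tab, block$multivariate)
    for (i in seq_len(nrow(tab)))
      out <- c(out, sprintf("| %s | %s | %s |", tab$variable[i],
                            tab$analysis[i], fmt_or(tab[i, ])))
    out <- c(out, "")
  }
  out <- c(out, "## ROC analyses", "",
           "| variable | AUC | cutoff | sens % | spec % |", "|---|---|---|---|---|")
  for (r in Filter(Negate(is.null), report$roc))
    out <- c(out, sprintf("| %s | %.3f | %s %.4g | %.1f | %.1f |",
                          r$variable, r$auc, r$direction, r$cutoff,
                          r$sensitivity, r$specificity))
  out <- c(out, "", "## Paired AUC comparisons", "")
  for (nm in names(report$auc_tests)) {
    tst <- report$auc_tests[[nm]]
    out <- c(out, sprintf("- %s: %.3f vs %.3f, p = %.4g", nm, tst$auc_a,
                          tst$auc_b, tst$p_value))
  }
  out
}

#' @export
print.baep_report <- function(x, ...) {
  cat(sprintf("BAEP analysis report: %d patients (seed %d)\n",
              x$summary$n_patients, x$provenance$seed))
  cat(sprintf("  preop HP %d/%d (%.1f%%); postop HP %d/%d (%.1f%%)\n",
              x$outcomes$n_preop_hp, x$outcomes$n_patients,
              x$outcomes$preop_hp_rate_pct, x$outcomes$n_postop_hp,
              x$outcomes$n_preop_hp, x$outcomes$postop_hp_rate_pct))
  for (v in c("raw_post_am_v", "sti_post_am_v"))
    if (!is.null(x$roc[[v]]))
      cat(sprintf("  AUC %s = %.3f\n", v, x$roc[[v]]$auc))
  invisible(x)
}
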