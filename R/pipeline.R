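#' Pipeline run configuration
#'
#' Bundles cohort generation parameters, extraction settings, and analysis
#' cutoffs (`dsc_good` = 0.7 marks good spatial overlap, `icc_cutoff` = 0.9
#' the robustness threshold, `nzv` = 0.95 the near-zero-variance modal
#' share) with a single global seed. A run's configuration is serialized
#' verbatim into its output directory, and identical configurations produce
#' identical outputs.
#'
#' @param n_easy,n_challenging,n_observers cohort composition.
#' @param seed global seed fanned out deterministically per stage and tumor.
#' @param cohort cohort parameters ([cohort_config()]).
#' @param extraction extraction settings ([extraction_config()]).
#' @param dsc_good,icc_cutoff,nzv analysis thresholds.
#' @return A `run_config` object.
#' @export
run_config <- function(n_easy = 30L, n_challenging = 10L, n_observers = 4L,
                       seed = 1L, cohort = cohort_config(),
                       extraction = extraction_config(),
                       dsc_good = 0.7, icc_cutoff = 0.9, nzv = 0.95) {
  structure(list(n_easy = as.integer(n_easy),
                 n_challenging = as.integer(n_challenging),
                 n_observers = as.integer(n_observers),
                 seed = as.integer(seed), cohort = cohort,
                 extraction = extraction, dsc_good = dsc_good,
                 icc_cutoff = icc_cutoff, nzv = nzv),
            class = "run_config")
}

#' Validate a run configuration
#'
#' @param cfg a [run_config()] (or plain list with the same fields).
#' @return character vector of human-readable violations (empty when valid).
#' @export
validate_config <- function(cfg) {
  issues <- character(0)
  add <- function(msg) issues <<- c(issues, msg)
  if (is.null(cfg$n_easy) || cfg$n_easy < 1) add("n_easy must be >= 1")
  if (is.null(cfg$n_challenging) || cfg$n_challenging < 1)
    add("n_challenging must be >= 1")
  if (is.null(cfg$n_observers) || cfg$n_observers < 2)
    add("n_observers must be >= 2")
  if (!is.null(cfg$icc_cutoff) &&
      (cfg$icc_cutoff <= -1 || cfg$icc_cutoff >= 1))
    add("icc_cutoff must lie in (-1, 1)")
  if (!is.null(cfg$dsc_good) && (cfg$dsc_good < 0 || cfg$dsc_good > 1))
    add("dsc_good must lie in [0, 1]")
  if (!is.null(cfg$nzv) && (cfg$nzv <= 0 || cfg$nzv > 1))
    add("nzv threshold must lie in (0, 1]")
  if (!is.null(cfg$extraction$bin_width) && cfg$extraction$bin_width <= 0)
    add("bin_width must be positive")
  if (!is.null(cfg$extraction$target_mm) && cfg$extraction$target_mm <= 0)
    add("target_mm must be positive")
  issues
}

#' Load a run configuration from YAML or JSON
#'
#' Keys mirror the arguments of [run_config()], [cohort_config()] and
#' [extraction_config()]; missing keys keep their defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  cfg <- run_config()
  for (nm in intersect(names(raw), c("n_easy", "n_challenging",
                                     "n_observers", "seed", "dsc_good",
                                     "icc_cutoff", "nzv")))
    cfg[[nm]] <- raw[[nm]]
  for (nm in intersect(names(raw$cohort %||% list()), names(cfg$cohort)))
    cfg$cohort[[nm]] <- raw$cohort[[nm]]
  for (nm in intersect(names(raw$extraction %||% list()),
                       names(cfg$extraction)))
    cfg$extraction[[nm]] <- raw$extraction[[nm]]
  issues <- validate_config(cfg)
  if (length(issues))
    stop("invalid configuration:\n  ", paste(issues, collapse = "\n  "),
         call. = FALSE)
  cfg
}

#' Run the full robustness pipeline
#'
#' simulate -> extract -> agree -> robustness: generates the synthetic
#' cohort, computes pairwise DSC, extracts all configured features per
#' (tumor, observer), applies the near-zero-variance filter, computes
#' per-feature ICC(2,1) overall and per difficulty stratum, and writes every
#' report table to `out_dir` (when given): dsc_pairs.csv, dsc_summary.csv,
#' feature_table.csv, icc_per_feature.csv, group_summary.csv,
#' stratified_summary.csv, removed_features.csv, comparison.json,
#' config.json and run.log.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param quiet suppress progress messages.
#' @return list: `cohort_summary`, `dsc` (pairwise table), `comparison`
#'   (Welch test), `features` (filtered table), `icc` (per-feature table),
#'   `report` (overall robustness), `report_by_stratum`, `removed`,
#'   `manifest`.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir = NULL, quiet = FALSE) {
  issues <- validate_config(cfg)
  if (length(issues))
    stop("invalid configuration:\n  ", paste(issues, collapse = "\n  "),
         call. = FALSE)
  log_lines <- character(0)
  say <- function(stage, msg) {
    line <- sprintf("[%s] %s", stage, msg)
    if (!quiet) message(line)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say(name, sprintf("done in %.1fs", as.numeric(Sys.time() - t0,
                                                  units = "secs")))
    out
  }

  cohort <- stage("simulate", make_cohort(
    cfg$n_easy, cfg$n_challenging, cfg$n_observers, cfg$seed, cfg$cohort))
  pd <- stage("agree", pairwise_dsc(cohort))
  ft <- stage("extract", cohort_feature_table(cohort, cfg$extraction))
  manifest <- feature_manifest(cfg$extraction)

  flt <- stage("filter", nzv_filter(ft, cfg$nzv))
  icc_all <- stage("icc", icc_table(flt$table, cfg$icc_cutoff, manifest))
  difficulty <- attr(ft, "difficulty")
  icc_strata <- stage("icc_strata", {
    lapply(split(names(difficulty), difficulty), function(ids) {
      sub <- flt$table[flt$table$tumor_id %in% ids, , drop = FALSE]
      icc_table(sub, cfg$icc_cutoff, manifest)
    })
  })
  report <- summarize_robustness(icc_all, manifest)
  report_strata <- lapply(icc_strata, summarize_robustness, manifest = manifest)
  comparison <- stage("compare", stratified_compare(pd))
  comparison$dsc_good_threshold <- cfg$dsc_good
  comparison$fraction_pairs_good_overlap <- mean(pd$dsc > cfg$dsc_good)

  result <- list(
    cohort_summary = list(
      n_easy = cfg$n_easy, n_challenging = cfg$n_challenging,
      n_observers = cfg$n_observers, seed = cfg$seed,
      mean_dsc = attr(pd, "overall_mean"),
      pair_means = attr(pd, "pair_means"),
      bin_width = attr(ft, "bin_width")),
    dsc = pd, comparison = comparison, features = flt$table,
    removed = flt$removed, icc = icc_all, icc_by_stratum = icc_strata,
    report = report, report_by_stratum = report_strata,
    manifest = manifest)

  if (!is.null(out_dir)) {
    stage("write", write_pipeline_outputs(result, cfg, out_dir, log_lines))
  }
  result
}

write_pipeline_outputs <- function(result, cfg, out_dir, log_lines) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(result$dsc, "dsc_pairs.csv")
  pm <- attr(result$dsc, "pair_means")
  wcsv(data.frame(pair = c(names(pm), "overall"),
                  mean_dsc = c(as.numeric(pm), attr(result$dsc,
                                                    "overall_mean"))),
       "dsc_summary.csv")
  wcsv(result$features, "feature_table.csv")
  wcsv(result$icc, "icc_per_feature.csv")
  group_summary <- result$report$by_group
  group_summary$stratum <- "all"
  for (s in names(result$report_by_stratum)) {
    g <- result$report_by_stratum[[s]]$by_group
    g$stratum <- s
    group_summary <- rbind(group_summary, g)
  }
  wcsv(group_summary, "group_summary.csv")
  strat <- do.call(rbind, lapply(names(result$report_by_stratum), function(s) {
    ov <- result$report_by_stratum[[s]]$overall
    data.frame(stratum = s, mean_icc = ov$mean_icc,
               robust_count = ov$robust_count, total_count = ov$total_count,
               robust_percentage = ov$robust_percentage)
  }))
  wcsv(strat, "stratified_summary.csv")
  wcsv(result$removed, "removed_features.csv")
  jsonlite::write_json(result$comparison,
                       file.path(out_dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass_recursive(cfg),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else x
}

#' Format a robust-feature percentage the way reports print it
#'
#' e.g. `format_robust_pct(552, 1328)` gives `"41.6% (552/1328)"`.
#'
#' @param robust,total robust and total feature counts.
#' @return character scalar.
#' @export
format_robust_pct <- function(robust, total) {
  sprintf("%.1f%% (%d/%d)", 100 * robust / total, robust, total)
}
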