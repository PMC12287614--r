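# End-to-end pipeline: orchestration, logging, and the validation report.
#
# Stage order mirrors a validation campaign: detection limits ->
# precision -> linearity -> interference -> stability -> threshold
# selection (or a fixed pair) -> clinical performance. The machine
# artifact is a single versioned JSON report; a Markdown rendering can be
# produced from it. All randomness flows from one seed; re-running with
# identical inputs and seed reproduces byte-identical reports.

REPORT_SCHEMA_VERSION <- "1.0"

#' Pipeline configuration
#'
#' Either point the config at CSV inputs (cohort, blanks, low-level
#' panel, LLoQ panel, replicate panel, admixture series, interference
#' pairs, stability pairs) or leave them `NULL` to have the synthetic
#' module generate the corresponding table from the study-world defaults.
#'
#' @param cohort,blanks,low_panel,lloq_panel,replicates,admixture,interference,stability
#'   CSV paths or `NULL` (synthetic)
#' @param thresholds either `"optimize"` (default) or a numeric
#'   `c(lower, upper)` pair in pg/mL
#' @param desirability a [desirability_spec()]
#' @param predilution_factor instrument pre-dilution carried into the
#'   functional LLoQ (default 2)
#' @param seed integer seed driving every synthetic table and the
#'   optimizer
#' @param out_dir output directory for the report files
#' @param format `"json"` or `"markdown"` (markdown implies json too)
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(cohort = NULL, blanks = NULL, low_panel = NULL,
                            lloq_panel = NULL, replicates = NULL,
                            admixture = NULL, interference = NULL,
                            stability = NULL,
                            thresholds = "optimize",
                            desirability = desirability_spec(),
                            predilution_factor = 2,
                            seed = 1L, out_dir = ".",
                            format = c("json", "markdown")) {
  format <- match.arg(format)
  if (!identical(thresholds, "optimize")) {
    if (!is.numeric(thresholds) || length(thresholds) != 2 ||
        thresholds[1] <= 0 || thresholds[1] > thresholds[2])
      abort_invalid("thresholds", "must be 'optimize' or c(lower, upper)")
  }
  if (length(seed) != 1 || seed != round(seed))
    abort_invalid("seed", "must be an integer")
  paths <- list(cohort = cohort, blanks = blanks, low_panel = low_panel,
                lloq_panel = lloq_panel, replicates = replicates,
                admixture = admixture, interference = interference,
                stability = stability)
  for (nm in names(paths))
    if (!is.null(paths[[nm]]) && !file.exists(paths[[nm]]))
      abort_invalid(nm, sprintf("file not found: %s", paths[[nm]]))
  structure(list(paths = paths, thresholds = thresholds,
                 desirability = desirability,
                 predilution_factor = predilution_factor,
                 seed = as.integer(seed), out_dir = out_dir,
                 format = format),
            class = "pipeline_config")
}

#' @noRd
pipeline_log <- function(stage, msg, log_file = NULL) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  stage, msg)
  message(line)
  if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE)
}

#' Run the full validation pipeline
#'
#' Executes every stage, writes `report.json` (and `report.md` when
#' requested) under the configured output directory, and returns the
#' report as a list. Stage failures abort with the failure recorded in a
#' `failure_manifest.json` next to any partial results.
#'
#' @param config a [pipeline_config()]
#' @return the report list, invisibly
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    abort_invalid("config", "must be a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(config$out_dir, "pipeline.log")
  seed <- config$seed
  report <- list(schema_version = REPORT_SCHEMA_VERSION, seed = seed,
                 units = "pg/mL")
  done <- character()

  load_or <- function(name, required_cols, generator) {
    path <- config$paths[[name]]
    if (is.null(path)) {
      pipeline_log(name, "no input file; generating synthetic table", log_file)
      generator()
    } else {
      pipeline_log(name, sprintf("reading %s (md5 %s)", path,
                                 unname(tools::md5sum(path))), log_file)
      read_table_csv(path, required_cols)
    }
  }

  run_stage <- function(stage, expr) {
    pipeline_log(stage, "start", log_file)
    out <- tryCatch(expr, error = function(e) {
      manifest <- list(failed_stage = stage, error = conditionMessage(e),
                       completed_stages = done)
      jsonlite::write_json(manifest,
                           file.path(config$out_dir, "failure_manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      partial <- file.path(config$out_dir, "report_partial.json")
      jsonlite::write_json(report, partial, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
    done <<- c(done, stage)
    pipeline_log(stage, "done", log_file)
    out
  }

  # -- detection limits ------------------------------------------------
  limits <- run_stage("limits", {
    blanks <- load_or("blanks", c("lot", "conc_pg_ml"),
                      function() generate_blank_panel(seed = seed))
    low <- load_or("low_panel", c("sample_id", "conc_pg_ml"),
                   function() generate_low_level_panel(seed = seed))
    lloq_tab <- load_or("lloq_panel", c("sample_id", "conc_pg_ml"),
                        function() {
                          a <- generate_lloq_panel(seed = seed)
                          a$lot <- 1L
                          b <- generate_lloq_panel(seed = seed + 1L)
                          b$lot <- 2L
                          rbind(a, b)
                        })
    lob <- suppressWarnings(estimate_lob(blanks))
    lod <- estimate_lod(lob$lob, low)
    if (!"lot" %in% names(lloq_tab)) lloq_tab$lot <- 1L
    profiles <- lapply(split(lloq_tab, lloq_tab$lot), fit_precision_profile)
    lq <- lloq_at_cv(profiles)
    func <- if (is.na(lq$lloq)) NA_real_
      else functional_lloq(lq$lloq, config$predilution_factor)
    list(lob = lob$lob, lob_per_lot = as.list(lob$per_lot),
         lod = lod$lod, sd_l = lod$sd_l, cp = lod$cp,
         lloq_analytical = lq$lloq,
         lloq_per_lot = if (!is.null(lq$per_lot)) as.list(lq$per_lot) else NULL,
         lloq_functional = func,
         predilution_factor = config$predilution_factor)
  })
  report$detection_limits <- limits

  # -- precision -------------------------------------------------------
  report$precision <- run_stage("precision", {
    panel <- load_or("replicates",
                     c("sample_id", "day", "run", "conc_pg_ml"),
                     function() generate_replicate_panel(
                       true_concs = c(0.010, 0.043, 0.052, 0.101, 0.396),
                       noise = assay_noise_spec(seed = seed)))
    vc <- variance_components(panel)
    lapply(split(vc, vc$sample_id), as.list)
  })

  # -- linearity -------------------------------------------------------
  report$linearity <- run_stage("linearity", {
    series <- load_or("admixture", c("ratio", "conc_pg_ml"),
                      function() generate_admixture_series(seed = seed))
    lin <- linearity_assess(series)
    list(avg_signed_bias_pct = lin$avg_signed_bias_pct,
         avg_abs_bias_pct = lin$avg_abs_bias_pct,
         slope = lin$regression$slope,
         intercept = lin$regression$intercept,
         r_squared = lin$regression$r_squared,
         poly_improves = lin$poly_improves)
  })

  # -- interference ----------------------------------------------------
  report$interference <- run_stage("interference", {
    pairs <- load_or("interference",
                     c("interferent", "sample_id", "control", "spiked"),
                     interference_reference)
    pd <- percent_difference(pairs)
    stats::setNames(as.list(pd$per_interferent$mean_pct_diff),
                    pd$per_interferent$interferent)
  })

  # -- stability -------------------------------------------------------
  report$stability <- run_stage("stability", {
    pairs <- load_or("stability",
                     c("condition", "specimen", "test", "control"),
                     function() generate_stability_pairs(seed = seed))
    se <- stability_effect(pairs)
    lapply(split(se, se$condition), function(s)
      list(avg_pct_diff = s$avg_pct_diff, lower_ci = s$lower_ci,
           upper_ci = s$upper_ci, n = s$n))
  })

  # -- cohort + thresholds --------------------------------------------
  cohort <- run_stage("cohort", {
    load_or("cohort", c("ptau217_pg_ml", "amyloid_status"),
            function() generate_cohort(study_cohort_spec(seed = seed)))
  })

  thr <- run_stage("thresholds", {
    if (identical(config$thresholds, "optimize")) {
      opt <- optimize_thresholds(cohort, spec = config$desirability,
                                 seed = seed)
      list(lower = opt$thresholds$lower, upper = opt$thresholds$upper,
           fn_rate = opt$rates$fn_rate, fp_rate = opt$rates$fp_rate,
           predicted = opt$predicted[c("sensitivity", "specificity",
                                       "intermediate_fraction", "accuracy")],
           source = "optimized")
    } else {
      list(lower = config$thresholds[1], upper = config$thresholds[2],
           source = "fixed")
    }
  })
  report$thresholds <- thr

  # -- clinical performance -------------------------------------------
  report$performance <- run_stage("performance", {
    summarize <- function(df) {
      ps <- suppressWarnings(performance_summary(
        df$ptau217_pg_ml, df$amyloid_status, thr$lower, thr$upper))
      list(n = ps$n, tp = ps$tp, fn = ps$fn, tn = ps$tn, fp = ps$fp,
           auc = ps$auc[c("estimate", "lower", "upper")],
           sensitivity = ps$sensitivity, specificity = ps$specificity,
           accuracy = ps$accuracy,
           intermediate_fraction = ps$intermediate_fraction)
    }
    strata <- if (all(c("cohort", "split") %in% names(cohort)))
      split(cohort, interaction(cohort$cohort, cohort$split, drop = TRUE,
                                sep = ":"))
    else list()
    pos <- cohort$ptau217_pg_ml[cohort$amyloid_status == 1]
    neg <- cohort$ptau217_pg_ml[cohort$amyloid_status == 0]
    overall <- summarize(cohort)
    pv <- predictive_values(overall$sensitivity$estimate,
                            overall$specificity$estimate, 0.5)
    sweep_tab <- prevalence_sweep(overall$sensitivity$estimate,
                                  overall$specificity$estimate)
    list(overall = overall,
         per_stratum = lapply(strata, summarize),
         median_fold_difference = median_fold_difference(pos, neg),
         positivity = positivity_rate(sum(cohort$amyloid_status), nrow(cohort)),
         ppv_at_50 = pv$ppv, npv_at_50 = pv$npv,
         prevalence_sweep = as.list(sweep_tab))
  })

  json_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  pipeline_log("report", sprintf("wrote %s", json_path), log_file)
  if (config$format == "markdown") {
    md_path <- file.path(config$out_dir, "report.md")
    writeLines(render_report_markdown(report), md_path)
    pipeline_log("report", sprintf("wrote %s", md_path), log_file)
  }
  invisible(report)
}

#' Render a pipeline report as Markdown
#'
#' @param report the list returned by [run_pipeline()]
#' @return character vector of Markdown lines
#' @export
render_report_markdown <- function(report) {
  pct <- function(ci)
    sprintf("%.1f%% (%.1f-%.1f%%)", 100 * ci$estimate, 100 * ci$lower,
            100 * ci$upper)
  dl <- report$detection_limits
  ov <- report$performance$overall
  c("# Assay validation report",
    sprintf("Schema %s, seed %d. All concentrations in %s.",
            report$schema_version, report$seed, report$units),
    "", "## Detection limits",
    sprintf("- LoB: %.4g", dl$lob),
    sprintf("- LoD: %.4g", dl$lod),
    sprintf("- LLoQ (analytical): %.4g", dl$lloq_analytical),
    sprintf("- LLoQ (functional, x%g pre-dilution): %.4g",
            dl$predilution_factor, dl$lloq_functional),
    "", "## Thresholds",
    sprintf("- lower %.4g / upper %.4g (%s)", report$thresholds$lower,
            report$thresholds$upper, report$thresholds$source),
    "", "## Clinical performance (overall)",
    sprintf("- n = %d, intermediate %s", ov$n, pct(ov$intermediate_fraction)),
    sprintf("- sensitivity %s, specificity %s, accuracy %s (excluding intermediates)",
            pct(ov$sensitivity), pct(ov$specificity), pct(ov$accuracy)),
    sprintf("- AUC %.2f (%.2f-%.2f)", ov$auc$estimate, ov$auc$lower,
            ov$auc$upper),
    sprintf("- PPV/NPV at 50%% prevalence: %.1f%% / %.1f%%",
            100 * report$performance$ppv_at_50,
            100 * report$performance$npv_at_50))
}
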