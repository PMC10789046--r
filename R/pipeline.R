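# End-to-end pipeline: screen -> adjudicate -> metrics -> reports.

fmt_pct <- function(x) {
  ifelse(is.na(x), "-", sprintf("%.2f%%", pct(x)))
}

#' Render the per-trigger performance report
#'
#' The per-trigger table in publication shape: trigger id, module, positive
#' count, ADE count, PPV rendered to two decimals (`"-"` for triggers that
#' never fired).
#'
#' @param performance Output of [trigger_performance()].
#' @return A data frame ready for CSV export.
#' @export
render_trigger_report <- function(performance) {
  data.frame(
    trigger_id = performance$trigger_id,
    module = performance$module,
    positive_triggers = performance$positive_count,
    ades = performance$ade_hit_count,
    ppv = fmt_pct(performance$ppv),
    stringsAsFactors = FALSE
  )
}

#' Run the full screening pipeline
#'
#' Stages, in order: read cohort, apply inclusion criteria, screen with the
#' obstetric registry and the GTT comparator, read assessments, consolidate
#' ADEs, compute metrics, apply the study revision rules, and write all
#' reports to the output directory: `hits.csv`, `gtt_hits.csv`, `ades.csv`,
#' `trigger_report.csv` (per-trigger PPV), `gtt_report.csv`,
#' `method_comparison.csv`, `summary.json` and `manifest.json`. Output is a
#' pure function of the inputs; the manifest records input digests so
#' identical runs can be verified byte-for-byte (timestamps excluded).
#'
#' @param cohort_path JSONL cohort file.
#' @param assessments_path Assessment CSV ([write_assessments_csv()] form);
#'   optional — without it only screening outputs are produced.
#' @param out_dir Output directory, created if needed.
#' @param registry Registry name or path (default `"obstetric_39"`).
#' @param comparator Comparator registry name or `NULL` to skip.
#' @param mode Screening mode.
#' @param ci_method `"wald"` or `"wilson"` for reported intervals.
#' @return Invisibly, a list with the in-memory stage outputs (`cohort`,
#'   `hits`, `gtt_hits`, `ades`, `performance`, `summary`, `comparison`).
#' @export
run_pipeline <- function(cohort_path, assessments_path = NULL,
                         out_dir = "obstrigger-run",
                         registry = "obstetric_39",
                         comparator = "gtt_medication",
                         mode = "screening", ci_method = "wald") {
  ci_method <- match.arg(ci_method, c("wald", "wilson"))
  t_start <- Sys.time()
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }

  cohort <- read_cohort(cohort_path)
  if (!length(cohort)) stop("empty cohort", call. = FALSE)
  log_stage("read", "%d records in", length(cohort))
  inc <- apply_inclusion_criteria(cohort)
  cohort <- inc$records
  if (!length(cohort)) stop("empty cohort after inclusion filter", call. = FALSE)
  log_stage("include", "%d records kept, %d excluded", length(cohort),
            nrow(inc$exclusions))

  reg <- load_registry(registry)
  hits <- screen_cohort(reg, cohort, mode = mode)
  log_stage("screen", "%s: %d hits on %d records", reg$name, nrow(hits),
            length(unique(hits$record_id)))
  gtt_reg <- NULL; gtt_hits <- NULL
  if (!is.null(comparator)) {
    gtt_reg <- load_registry(comparator)
    gtt_hits <- screen_cohort(gtt_reg, cohort, mode = mode)
    log_stage("screen", "%s: %d hits on %d records", gtt_reg$name,
              nrow(gtt_hits), length(unique(gtt_hits$record_id)))
  }

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(out_dir, recursive = TRUE), add = TRUE)

  write_hits_csv(hits, file.path(out_dir, "hits.csv"))
  if (!is.null(gtt_hits)) {
    write_hits_csv(gtt_hits, file.path(out_dir, "gtt_hits.csv"))
  }

  ades <- NULL; performance <- NULL; summary_row <- NULL; comparison <- NULL
  if (!is.null(assessments_path)) {
    assessments <- read_assessments_csv(assessments_path)
    ades <- consolidate_ades(cohort, assessments, hits, gtt_hits)
    log_stage("adjudicate", "%d assessments -> %d ADEs", nrow(assessments),
              nrow(ades))
    performance <- trigger_performance(hits, ades, reg)
    summary_row <- cohort_summary(cohort, hits, ades, reg)
    comparison <- method_comparison(ades, summary_row$n_records,
                                    summary_row$total_patient_days)
    write_ades_csv(ades, file.path(out_dir, "ades.csv"))
    utils::write.csv(render_trigger_report(performance),
                     file.path(out_dir, "trigger_report.csv"),
                     row.names = FALSE)
    if (!is.null(gtt_hits)) {
      gtt_perf <- trigger_performance(gtt_hits, ades, gtt_reg)
      utils::write.csv(render_trigger_report(gtt_perf),
                       file.path(out_dir, "gtt_report.csv"), row.names = FALSE)
    }
    comp_out <- as.data.frame(comparison)
    comp_out$detection_rate <- fmt_pct(comparison$detection_rate)
    utils::write.csv(comp_out, file.path(out_dir, "method_comparison.csv"),
                     row.names = FALSE)
    dist <- distribution_summary(ades)
    ppv_ci <- proportion_ci(summary_row$total_ade_flagged_hits,
                            summary_row$total_hits, method = ci_method)
    jsonlite::write_json(
      list(summary = summary_row,
           overall_ppv_ci = ppv_ci,
           severity = dist$severity, organ_class = dist$organ_class),
      file.path(out_dir, "summary.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
    log_stage("metrics", "overall PPV %s, %d ADEs",
              fmt_pct(summary_row$overall_ppv), summary_row$n_ades)
  } else {
    log_stage("adjudicate", "no assessments supplied; screening outputs only")
  }

  manifest <- list(
    registry = reg$name, registry_version = reg$version,
    comparator = if (!is.null(gtt_reg)) gtt_reg$name else NA,
    mode = mode, ci_method = ci_method,
    n_records = length(cohort),
    cohort_md5 = unname(tools::md5sum(cohort_path)),
    assessments_md5 = if (!is.null(assessments_path))
      unname(tools::md5sum(assessments_path)) else NA,
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  ok <- TRUE
  invisible(list(cohort = cohort, hits = hits, gtt_hits = gtt_hits,
                 ades = ades, performance = performance,
                 summary = summary_row, comparison = comparison,
                 exclusions = inc$exclusions))
}
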