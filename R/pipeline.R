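#' Run the full VGC analysis of a rating study
#'
#' End-to-end pipeline: read and validate the ratings, pool criteria into
#' classes, run the fixed-reader paired-case bootstrap for every
#' (test protocol, criterion class) combination against the reference
#' protocol, and optionally write a results table in the conventional
#' journal layout (one row per dose-reduced protocol; AUC, p-value and
#' effect size per class) plus a JSON sidecar carrying full precision
#' values, confidence intervals, per-observer AUCs, the seed and `n_boot`
#' for provenance.  Effect sizes in the table are rounded to 2 decimals;
#' the sidecar is unrounded.
#'
#' @param ratings a [rating_panel] or path to a ratings CSV.
#' @param class_map criterion-to-class map (data frame or CSV path); must
#'   cover exactly the panel's criteria.
#' @param reference label of the reference (full-dose) protocol.
#' @param config a [bootstrap_config()].
#' @param out_dir optional output directory; created if absent.  Writes
#'   `vgc_results.tsv` and `vgc_results.json`.
#' @param n_categories declared rating categories when `ratings` is a path.
#' @return List with `results` (list of `vgc_result`), `table` (wide
#'   one-row-per-protocol data frame) and `files` (paths written, if any).
#' @examples
#' panel <- generate_panel(synthetic_config(n_cases = 10, n_criteria = 4,
#'                                          seed = 3))
#' map <- data.frame(criterion = paste0("Q", 1:4),
#'                   class = rep(c("demarcation", "tumor"), each = 2))
#' res <- run_vgc_analysis(panel, map, reference = "ratio10",
#'                         config = bootstrap_config(n_boot = 200, seed = 9))
#' res$table
#' @export
run_vgc_analysis <- function(ratings, class_map, reference,
                             config = bootstrap_config(), out_dir = NULL,
                             n_categories = 5) {
  panel <- if (inherits(ratings, "rating_panel")) ratings
           else read_ratings(ratings, n_categories = n_categories)
  results <- compare_all(panel, reference, class_map, config)
  long <- vgc_result_table(results)
  classes <- unique(long$criterion_class)
  tests <- unique(long$test_protocol)

  wide <- data.frame(test_protocol = tests, stringsAsFactors = FALSE)
  for (cl in classes) {
    sub <- long[long$criterion_class == cl, , drop = FALSE]
    sub <- sub[match(tests, sub$test_protocol), , drop = FALSE]
    wide[[paste0(cl, "_auc")]] <- round(sub$auc, 2)
    wide[[paste0(cl, "_p")]] <- round(sub$p_value, 2)
    wide[[paste0(cl, "_effect")]] <- round(sub$effect_size, 2)
  }

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tsv <- file.path(out_dir, "vgc_results.tsv")
    utils::write.table(wide, tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    sidecar <- list(
      reference_protocol = reference,
      n_boot = config$n_boot, ci_level = config$ci_level,
      seed = config$seed,
      comparisons = lapply(results, function(r) {
        r$replicates <- NULL
        r[c("test_protocol", "reference_protocol", "criterion_class",
            "auc", "ci_low", "ci_high", "p_value", "effect_size",
            "per_observer_auc", "n_boot", "seed")]
      }))
    jsonf <- file.path(out_dir, "vgc_results.json")
    jsonlite::write_json(sidecar, jsonf, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(tsv, jsonf)
  }
  list(results = results, table = wide, files = files)
}

#' BMI-stratified dose summary table
#'
#' Reads a per-examination dose table, converts DAP to effective dose, and
#' writes/returns a summary in the conventional layout: one row per BMI
#' group, with mean and SD DAP at the reference ratio and, per ratio, the
#' mean and SD effective dose and the percentage of the reference-ratio
#' mean effective dose.
#'
#' @param dose a [dose_records()] data frame or path to a dose CSV with
#'   header `patient,dap_gycm2,dose_ratio,bmi`.
#' @param reference_ratio dose ratio treated as full dose (default 10).
#' @param coefficient DAP-to-effective-dose conversion when `dose` is a
#'   path or plain data frame.
#' @param out_dir optional output directory; writes `dose_summary.csv`.
#' @return List with `summary` (long per group-and-ratio data frame),
#'   `table` (wide one-row-per-group data frame) and `files`.
#' @export
run_dose_summary <- function(dose, reference_ratio = 10, coefficient = 0.26,
                             out_dir = NULL) {
  records <- if (inherits(dose, "dose_records")) dose
             else dose_records(dose, coefficient = coefficient)
  summ <- summarize_by_bmi(records, reference_ratio = reference_ratio)

  groups <- levels(droplevels(summ$bmi_group))
  ratios <- sort(unique(summ$dose_ratio), decreasing = TRUE)
  wide <- data.frame(bmi_group = groups, stringsAsFactors = FALSE)
  ref_rows <- summ[summ$dose_ratio == reference_ratio, , drop = FALSE]
  wide$mean_dap <- round(ref_rows$mean_dap[match(groups, ref_rows$bmi_group)], 2)
  wide$sd_dap <- round(ref_rows$sd_dap[match(groups, ref_rows$bmi_group)], 2)
  for (r in ratios) {
    sub <- summ[summ$dose_ratio == r, , drop = FALSE]
    sub <- sub[match(groups, sub$bmi_group), , drop = FALSE]
    wide[[sprintf("mean_e_ratio%d", r)]] <- round(sub$mean_effective_dose, 2)
    wide[[sprintf("sd_e_ratio%d", r)]] <- round(sub$sd_effective_dose, 2)
    if (r != reference_ratio)
      wide[[sprintf("percent_ratio%d", r)]] <- sub$percent_vs_reference
  }

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    csv <- file.path(out_dir, "dose_summary.csv")
    utils::write.csv(wide, csv, row.names = FALSE, quote = FALSE)
    files <- csv
  }
  list(summary = summ, table = wide, files = files)
}
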