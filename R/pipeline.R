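# Dataset-level orchestration binding the modules into the full workflow:
# simulate -> measure -> grade -> evaluate, with CSV/JSON artifacts at each
# boundary. A thin command-line wrapper over these functions ships in
# inst/cli/oiearr.R.

#' Simulate a cohort dataset to disk
#'
#' Generates a synthetic cohort and writes the complete dataset directory
#' (label files in both dialects, manifest, ground truth, config snapshot).
#' Deterministic: the same config yields a byte-identical tree.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory.
#' @return The `oiearr_cohort`, invisibly.
#' @export
run_simulate <- function(config = synthetic_config(), out_dir) {
  cohort <- generate_cohort(config, dir = out_dir)
  invisible(cohort)
}

#' Measure and grade a dataset
#'
#' Runs the measurement pipeline over a dataset directory (or in-memory
#' cohort), applies the grade thresholds, and optionally writes the combined
#' measurement/grade table as CSV. Teeth that could not be measured stay in
#' the table as skipped rows with reasons, so every manifest tooth is
#' accounted for.
#'
#' @param x Dataset directory or `oiearr_cohort`.
#' @param mode `"pose"` or `"detect"`.
#' @param thresholds A [grade_thresholds()].
#' @param formula Correction convention, see [corrected_final_root()].
#' @param out_csv Optional output CSV path.
#' @return The graded measurement data.frame.
#' @export
run_measure_grade <- function(x, mode = c("pose", "detect"),
                              thresholds = grade_thresholds(),
                              formula = c("scale_cancelling", "printed"),
                              out_csv = NULL) {
  mode <- match.arg(mode)
  formula <- match.arg(formula)
  graded <- grade_cohort(measure_cohort(x, mode, formula), thresholds)
  graded$t1 <- thresholds$t1
  graded$t2 <- thresholds$t2
  graded$t3 <- thresholds$t3
  if (!is.null(out_csv)) {
    utils::write.csv(graded, out_csv, row.names = FALSE)
  }
  graded
}

#' Evaluate predicted grades against ground truth
#'
#' Joins a prediction table to a ground-truth table on (patient_id, tooth)
#' and produces the full evaluation report; unmatched keys are an explicit
#' error. When the prediction table carries resorption percentages, the
#' Grade-0 reference error and ordinal AUCs are included.
#'
#' @param truth Data.frame (or CSV path) with `patient_id`, `tooth`,
#'   `true_grade` and optionally `true_resorption_percent`.
#' @param pred Data.frame (or CSV path) with `patient_id`, `tooth`, `grade`
#'   and optionally `resorption_percent`.
#' @param out_json Optional path for the JSON report.
#' @return The report list from [evaluate_grades()], extended with
#'   `grade0_error` when percentages are available.
#' @export
run_evaluate <- function(truth, pred, out_json = NULL) {
  if (is.character(truth)) truth <- utils::read.csv(truth)
  if (is.character(pred)) pred <- utils::read.csv(pred)
  keys <- c("patient_id", "tooth")
  merged <- merge(truth, pred, by = keys)
  only_truth <- setdiff(do.call(paste, truth[keys]),
                        do.call(paste, merged[keys]))
  only_pred <- setdiff(do.call(paste, pred[keys]),
                       do.call(paste, merged[keys]))
  if (length(only_truth) || length(only_pred)) {
    stop(sprintf(
      "join failure: unmatched keys [truth: %s] [pred: %s]",
      paste(only_truth, collapse = "; "),
      paste(only_pred, collapse = "; ")), call. = FALSE)
  }
  scored <- merged[!is.na(merged$grade), ]
  scores <- if ("resorption_percent" %in% names(scored)) {
    scored$resorption_percent
  } else NULL
  report <- evaluate_grades(scored$true_grade, scored$grade, scores)
  report$n_skipped <- sum(is.na(merged$grade))
  if (!is.null(scores)) {
    report$grade0_error <- grade0_error(
      scored[, c("patient_id", "tooth", "resorption_percent")],
      scored[, c("patient_id", "tooth", "true_grade")])
  }
  if (!is.null(out_json)) {
    jsonlite::write_json(report_to_json(report), out_json,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

report_to_json <- function(report) {
  out <- report
  out$confusion <- lapply(seq_len(nrow(report$confusion)),
                          function(i) as.integer(report$confusion[i, ]))
  out
}

#' Load a run configuration from YAML
#'
#' Reads a versioned YAML config with optional `mode`, `thresholds` and
#' `synthetic` blocks; unspecified values fall back to package defaults.
#'
#' @param path YAML file path.
#' @return List with `mode`, `thresholds` ([grade_thresholds()]) and
#'   `synthetic` ([synthetic_config()]).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  th <- do.call(grade_thresholds,
                raw$thresholds[intersect(names(raw$thresholds),
                                         c("t1", "t2", "t3"))])
  syn_args <- raw$synthetic
  if (!is.null(syn_args)) {
    syn_args <- syn_args[intersect(names(syn_args),
                                   names(formals(synthetic_config)))]
  }
  syn_args$thresholds <- th
  list(mode = if (is.null(raw$mode)) "pose" else match.arg(raw$mode,
                                                           c("pose", "detect")),
       thresholds = th,
       synthetic = do.call(synthetic_config, syn_args))
}
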