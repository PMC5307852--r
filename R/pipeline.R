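#' Run the full association-mining pipeline
#'
#' End-to-end orchestration over four annotation sources: 4-digit
#' calibration (weight grid search by ROC area, F-measure threshold
#' scan), an independent 3-digit calibration on the truncated hierarchy,
#' rescue of sub-threshold 4-digit candidates through accepted 3-digit
#' parents, per-source hypergeometric significance with Bonferroni
#' control, Gold/Silver/Bronze classification, and obligate-tuple mining
#' on the final accepted set.
#'
#' @param datasets Named list of `"assoc_dataset"` sources in canonical
#'   order (the order fixes the grid-search tie-break).
#' @param positives data.frame of curated positive pairs (4-digit `ec`,
#'   `pfam`).
#' @param seed Integer seed for negative sampling and reference splits
#'   (default 1515).
#' @param train_fraction,weight_step,threshold_step See [calibrate_level()].
#' @param max_arity Largest obligate tuple size (default 4).
#' @param pfam_names Optional accession -> name vector for tuple flags.
#' @param negative_source Dataset shuffled for negatives (default SIFTS).
#' @return List of class `"ecpfam_result"` with elements `cal4`, `cal3`
#'   (the two `"level_calibration"`s), `rescued`, `accepted` (classified
#'   final set), `tuples`, and `seed`.
#' @export
run_pipeline <- function(datasets, positives, seed = 1515L,
                         train_fraction = 0.5, weight_step = 0.1,
                         threshold_step = 0.01, max_arity = 4L,
                         pfam_names = NULL, negative_source = NULL) {
  cal4 <- calibrate_level(datasets, positives, ec_digits = 4L, seed = seed,
                          train_fraction = train_fraction,
                          weight_step = weight_step,
                          threshold_step = threshold_step,
                          negative_source = negative_source)
  cal3 <- calibrate_level(datasets, positives, ec_digits = 3L, seed = seed + 101L,
                          train_fraction = train_fraction,
                          weight_step = weight_step,
                          threshold_step = threshold_step,
                          negative_source = negative_source)
  accepted3 <- cal3$scored[cal3$scored$cs >= cal3$threshold, , drop = FALSE]
  rescued <- rescue_associations(cal4$scored, cal4$threshold, accepted3)
  final <- finalize_associations(cal4$scored, cal4$threshold, rescued)
  final <- attach_significance(final, datasets, cal4$tables)
  final <- classify_quality(final, cal4$threshold)
  tuples <- find_obligate_tuples(datasets, final, max_arity = max_arity,
                                 pfam_names = pfam_names)
  structure(list(cal4 = cal4, cal3 = cal3, rescued = rescued,
                 accepted = final, tuples = tuples, seed = seed),
            class = "ecpfam_result")
}

#' @export
print.ecpfam_result <- function(x, ...) {
  cat("== EC-Pfam association mining result ==\n")
  print(x$cal4)
  print(x$cal3)
  qc <- table(factor(x$accepted$quality, levels = c("Gold", "Silver", "Bronze")))
  cat(sprintf("final associations: %d (%d direct, %d rescued)\n",
              nrow(x$accepted), sum(x$accepted$provenance == "direct4"),
              sum(x$accepted$provenance == "rescued3")))
  cat(sprintf("quality classes: Gold %d / Silver %d / Bronze %d\n",
              qc[["Gold"]], qc[["Silver"]], qc[["Bronze"]]))
  cat(sprintf("obligate tuples: %d\n", nrow(x$tuples)))
  invisible(x)
}

#' Write the calibration report
#'
#' A flat key-value text block covering both EC levels: weights, AUC,
#' threshold, and train/test precision, recall and F-measure.
#'
#' @param result An `"ecpfam_result"`.
#' @param path Output path.
#' @export
write_calibration_report <- function(result, path) {
  fmt <- function(cal, tag) {
    c(sprintf("%s.weight.%s\t%.1f", tag, names(cal$weights), cal$weights),
      sprintf("%s.auc\t%.6f", tag, cal$auc),
      sprintf("%s.threshold\t%.2f", tag, cal$threshold),
      sprintf("%s.train.precision\t%.6f", tag, cal$train$precision),
      sprintf("%s.train.recall\t%.6f", tag, cal$train$recall),
      sprintf("%s.train.f_measure\t%.6f", tag, cal$train$f_measure),
      sprintf("%s.test.precision\t%.6f", tag, cal$test$precision),
      sprintf("%s.test.recall\t%.6f", tag, cal$test$recall),
      sprintf("%s.test.f_measure\t%.6f", tag, cal$test$f_measure))
  }
  writeLines(c(fmt(result$cal4, "ec4"), fmt(result$cal3, "ec3")), path)
  invisible(result)
}

#' Run the pipeline and write all result tables
#'
#' Convenience wrapper used by the command-line interface: runs
#' [run_pipeline()] and writes `associations.tsv`, `calibration.txt`,
#' `rescue.tsv` and `tuples.tsv` into a directory; when an entity-level
#' Pfam table is supplied, enzyme-unannotated entities are annotated into
#' `annotations.tsv`.
#'
#' @inheritParams run_pipeline
#' @param out_dir Output directory.
#' @param annotate_table Optional entity-level Pfam pair data.frame.
#' @param already_ec Entities with existing EC annotation, skipped during
#'   annotation.
#' @return The `"ecpfam_result"`, invisibly.
#' @export
run_all <- function(datasets, positives, out_dir, seed = 1515L,
                    annotate_table = NULL, already_ec = character(),
                    pfam_names = NULL, ...) {
  res <- run_pipeline(datasets, positives, seed = seed,
                      pfam_names = pfam_names, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_results_table(res$accepted, file.path(out_dir, "associations.tsv"))
  write_calibration_report(res, file.path(out_dir, "calibration.txt"))
  write_rescue_table(res$rescued, file.path(out_dir, "rescue.tsv"))
  write_tuples_table(res$tuples, file.path(out_dir, "tuples.tsv"))
  if (!is.null(annotate_table)) {
    ann <- annotate_entities(annotate_table, res$accepted, already_ec)
    write_annotation_table(ann, file.path(out_dir, "annotations.tsv"))
  }
  invisible(res)
}
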