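#' ROC area for a ranked association list
#'
#' AUC is computed via the Mann-Whitney identity: the probability that a
#' uniformly drawn positive pair outscores a uniformly drawn background
#' pair, with ties counted one half.  This equals the trapezoidal area
#' under the ROC curve with midrank tie handling.  Pairs absent from the
#' scored universe participate with a confidence score of zero.
#'
#' @param scored A `"scored_assoc"` data.frame (columns `ec`, `pfam`, `cs`),
#'   or any data.frame with those columns.
#' @param positives,background Disjoint data.frames of pairs (`ec`, `pfam`).
#' @return The AUC in `[0, 1]`.
#' @export
roc_auc <- function(scored, positives, background) {
  pos_key <- unique(pair_key(positives$ec, positives$pfam))
  bg_key <- unique(pair_key(background$ec, background$pfam))
  if (length(intersect(pos_key, bg_key)) > 0L)
    stop("positives and background must be disjoint")
  if (length(pos_key) == 0L || length(bg_key) == 0L)
    stop("both classes must be non-empty")
  lookup <- stats::setNames(scored$cs, pair_key(scored$ec, scored$pfam))
  score_of <- function(keys) {
    s <- unname(lookup[keys])
    s[is.na(s)] <- 0
    s
  }
  auc_mann_whitney(score_of(pos_key), score_of(bg_key))
}

# Mann-Whitney AUC from two score vectors (midrank ties).
auc_mann_whitney <- function(pos, bg) {
  r <- rank(c(pos, bg))
  np <- length(pos)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(bg))
}

#' Grid search over source weights by ROC area
#'
#' Every combination of per-source weights on the grid `{0, step, ..., 1}`
#' (excluding the all-zero point) is evaluated by the AUC of the combined
#' confidence scores, ranking the positive reference pairs against the
#' background.  The maximising combination is returned; exact AUC ties are
#' broken by the lexicographically smallest weight tuple in the order the
#' tables are given (so equivalent rescalings resolve deterministically).
#'
#' @param tables Named list of `"raw_scores"` tables, in the canonical
#'   source order used for tie-breaking (SIFTS, SwissProt, TrEMBL, UniRule
#'   in the full pipeline).
#' @param positives,background Pair data.frames as in [roc_auc()].
#' @param step Grid step (default 0.1).
#' @return List of class `"calibration_result"` with elements `weights`
#'   (named vector), `auc`, `ec_level`, and the evaluated `grid_size`.
#' @export
grid_search_weights <- function(tables, positives, background, step = 0.1) {
  nm <- names(tables)
  if (is.null(nm)) {
    nm <- vapply(tables, attr, character(1L), "dataset")
    names(tables) <- nm
  }
  k <- length(tables)
  stopifnot(k >= 1L)
  pos_key <- unique(pair_key(positives$ec, positives$pfam))
  bg_key <- unique(pair_key(background$ec, background$pfam))
  if (length(intersect(pos_key, bg_key)) > 0L)
    stop("positives and background must be disjoint")
  if (length(pos_key) == 0L || length(bg_key) == 0L)
    stop("both classes must be non-empty")

  keys <- unique(c(unlist(lapply(tables, function(t) pair_key(t$ec, t$pfam)),
                          use.names = FALSE), pos_key, bg_key))
  S <- matrix(0, nrow = length(keys), ncol = k)
  for (j in seq_len(k)) {
    t <- tables[[j]]
    S[match(pair_key(t$ec, t$pfam), keys), j] <- t$score
  }
  pos_idx <- match(pos_key, keys)
  bg_idx <- match(bg_key, keys)
  np <- length(pos_idx)
  nb <- length(bg_idx)
  eval_idx <- c(pos_idx, bg_idx)
  Se <- S[eval_idx, , drop = FALSE]

  vals <- seq(0, 1, by = step)
  grid <- as.matrix(do.call(expand.grid, rep(list(vals), k)))
  # lexicographic order with the first source most significant
  grid <- grid[do.call(order, as.data.frame(grid)), , drop = FALSE]
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]

  best_auc <- -Inf
  best_w <- NULL
  for (g in seq_len(nrow(grid))) {
    w <- grid[g, ]
    cs <- as.numeric(Se %*% w)  # AUC invariant to the 1/sum(w) factor
    r <- rank(cs)
    auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
    if (auc > best_auc) {
      best_auc <- auc
      best_w <- w
    }
  }
  structure(list(weights = stats::setNames(as.numeric(best_w), nm),
                 auc = best_auc, grid_size = nrow(grid)),
            class = "calibration_result")
}

#' Confusion counts and recall / precision / F-measure at a threshold
#'
#' A labelled pair is accepted when its confidence score satisfies
#' `cs >= threshold` (closed convention, so a score equal to the selected
#' grid value itself accepts); pairs missing from the scored universe have
#' score zero.  Then
#' \deqn{R = TP/(TP+FN), \quad P = TP/(TP+FP), \quad F = 2RP/(P+R),}
#' with `F = 0` when `P + R = 0`.
#'
#' @param scored Scored associations (columns `ec`, `pfam`, `cs`).
#' @param labeled data.frame with columns `ec`, `pfam`, `label`
#'   (`"pos"`/`"neg"`), e.g. one half of [split_reference()].
#' @param threshold Acceptance threshold on the confidence score.
#' @return List with `counts` (TP, FP, TN, FN), `recall`, `precision`,
#'   `f_measure`, `threshold`.
#' @export
evaluate_threshold <- function(scored, labeled, threshold) {
  if (!any(labeled$label == "pos") || !any(labeled$label == "neg"))
    stop("labelled set needs at least one positive and one negative")
  lookup <- stats::setNames(scored$cs, pair_key(scored$ec, scored$pfam))
  s <- unname(lookup[pair_key(labeled$ec, labeled$pfam)])
  s[is.na(s)] <- 0
  pos <- labeled$label == "pos"
  prf_from_scores(s[pos], s[!pos], threshold)
}

prf_from_scores <- function(pos_scores, neg_scores, threshold) {
  TP <- sum(pos_scores >= threshold)
  FN <- length(pos_scores) - TP
  FP <- sum(neg_scores >= threshold)
  TN <- length(neg_scores) - FP
  R <- if (TP + FN > 0) TP / (TP + FN) else 0
  P <- if (TP + FP > 0) TP / (TP + FP) else 0
  f <- if (P + R > 0) 2 * R * P / (P + R) else 0
  list(counts = c(TP = TP, FP = FP, TN = TN, FN = FN),
       recall = R, precision = P, f_measure = f, threshold = threshold)
}

#' Select the confidence-score threshold by F-measure scan
#'
#' The threshold is varied over the grid `{0, step, ..., 1}`; at each value
#' the labelled training pairs are classified by `cs >= t` and the
#' F-measure of [evaluate_threshold()] is computed.  The grid value with
#' the largest F wins; ties go to the smallest threshold.
#'
#' @inheritParams evaluate_threshold
#' @param step Grid step (default 0.01).
#' @return List of class `"calibration_result"` with `threshold`,
#'   `f_measure`, `precision`, `recall`, `counts`, and the full `grid`
#'   data.frame (`threshold`, `recall`, `precision`, `f_measure`).
#' @export
scan_threshold <- function(scored, labeled, step = 0.01) {
  if (!any(labeled$label == "pos") || !any(labeled$label == "neg"))
    stop("labelled set needs at least one positive and one negative")
  lookup <- stats::setNames(scored$cs, pair_key(scored$ec, scored$pfam))
  s <- unname(lookup[pair_key(labeled$ec, labeled$pfam)])
  s[is.na(s)] <- 0
  pos <- labeled$label == "pos"
  thresholds <- seq(0, 1, by = step)
  rows <- lapply(thresholds, function(t) prf_from_scores(s[pos], s[!pos], t))
  grid <- data.frame(threshold = thresholds,
                     recall = vapply(rows, `[[`, numeric(1L), "recall"),
                     precision = vapply(rows, `[[`, numeric(1L), "precision"),
                     f_measure = vapply(rows, `[[`, numeric(1L), "f_measure"))
  best <- which.max(grid$f_measure)  # first maximum = smallest threshold
  out <- rows[[best]]
  structure(list(threshold = out$threshold, f_measure = out$f_measure,
                 precision = out$precision, recall = out$recall,
                 counts = out$counts, grid = grid),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  if (!is.null(x$weights))
    cat("  weights: ",
        paste(sprintf("%s=%.1f", names(x$weights), x$weights), collapse = ", "),
        "\n", sep = "")
  if (!is.null(x$auc)) cat(sprintf("  AUC: %.4f\n", x$auc))
  if (!is.null(x$threshold))
    cat(sprintf("  threshold: %.2f (F=%.4f, P=%.4f, R=%.4f)\n",
                x$threshold, x$f_measure, x$precision, x$recall))
  invisible(x)
}

#' Calibrate one EC level end to end
#'
#' Runs, for one EC digit level, the full calibration recipe: per-source
#' raw scores, seeded negative sampling (size-matched to the positives),
#' a reproducible train/test split, the weight grid search of training
#' positives against the background of all remaining scored candidates,
#' combination at the winning weights, the threshold scan on the training
#' half, and evaluation on the held-out half.  At level 3 the positive
#' reference is truncated and deduplicated and negatives are regenerated
#' by shuffling at the 3-digit level.
#'
#' @param datasets Named list of `"assoc_dataset"` sources, in canonical
#'   order (used for the grid-search tie-break).
#' @param positives data.frame of curated positive pairs (`ec`, `pfam`)
#'   with 4-digit ECs.
#' @param ec_digits 4 or 3.
#' @param seed Integer seed driving negative sampling and the split.
#' @param train_fraction Fraction of the reference used for training.
#' @param weight_step,threshold_step Grid steps.
#' @param negative_source Dataset shuffled for negatives (default SIFTS).
#' @return List of class `"level_calibration"`: `tables`, `weights`, `auc`,
#'   `scored`, `threshold`, `train` / `test` evaluation lists, `reference`,
#'   `split`, `ec_digits`.
#' @export
calibrate_level <- function(datasets, positives, ec_digits = 4L, seed = 1515L,
                            train_fraction = 0.5, weight_step = 0.1,
                            threshold_step = 0.01, negative_source = NULL) {
  stopifnot(ec_digits %in% c(3L, 4L))
  if (nrow(positives) == 0L) stop("positive reference is empty")
  pos <- positives[, c("ec", "pfam")]
  if (ec_digits == 3L) {
    pos$ec <- ec_to_level3(pos$ec)
    pos <- pos[!duplicated(pair_key(pos$ec, pos$pfam)), , drop = FALSE]
  }
  tables <- lapply(datasets, raw_scores, ec_level = ec_digits)
  names(tables) <- names(datasets)
  negatives <- generate_negatives(datasets, n = nrow(pos), seed = seed + 11L,
                                  source = negative_source, positives = pos,
                                  ec_level = ec_digits)
  ref <- reference_set(pos, negatives, train_fraction = train_fraction,
                       seed = seed + 23L)
  halves <- split_reference(ref)
  train_pos <- halves$train[halves$train$label == "pos", , drop = FALSE]

  cand <- unique(unlist(lapply(tables, function(t) pair_key(t$ec, t$pfam)),
                        use.names = FALSE))
  bg_keys <- setdiff(cand, pair_key(train_pos$ec, train_pos$pfam))
  parts <- strsplit(bg_keys, "\t", fixed = TRUE)
  background <- data.frame(ec = vapply(parts, `[[`, character(1L), 1L),
                           pfam = vapply(parts, `[[`, character(1L), 2L),
                           stringsAsFactors = FALSE)

  gs <- grid_search_weights(tables, train_pos, background, step = weight_step)
  scored <- combine_scores(tables, gs$weights)
  sc <- scan_threshold(scored, halves$train, step = threshold_step)
  test_eval <- evaluate_threshold(scored, halves$test, sc$threshold)
  structure(list(tables = tables, weights = gs$weights, auc = gs$auc,
                 scored = scored, threshold = sc$threshold,
                 train = sc, test = test_eval,
                 reference = ref, split = halves, ec_digits = ec_digits),
            class = "level_calibration")
}

#' @export
print.level_calibration <- function(x, ...) {
  cat(sprintf("<level_calibration: %d-digit EC>\n", x$ec_digits))
  cat("  weights: ",
      paste(sprintf("%s=%.1f", names(x$weights), x$weights), collapse = ", "),
      sprintf("  (AUC %.4f)\n", x$auc), sep = "")
  cat(sprintf("  threshold %.2f: train F=%.4f, test F=%.4f (P=%.4f, R=%.4f)\n",
              x$threshold, x$train$f_measure, x$test$f_measure,
              x$test$precision, x$test$recall))
  invisible(x)
}
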