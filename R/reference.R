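# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb the
# user's RNG stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Assemble a labelled reference set
#'
#' Pairs curated positive EC-Pfam associations with sampled negatives and
#' records the train fraction and seed so the train/test split is a pure
#' function of (contents, fraction, seed).
#'
#' @param positives,negatives data.frames with columns `ec`, `pfam`.
#'   The two sets must be disjoint.
#' @param train_fraction Fraction of each class assigned to the training
#'   half (default 0.5, a random equal split).
#' @param seed Integer seed governing the split.
#' @return An object of class `"reference_set"`.
#' @export
reference_set <- function(positives, negatives, train_fraction = 0.5, seed = 1515L) {
  stopifnot(is.data.frame(positives), is.data.frame(negatives),
            train_fraction > 0, train_fraction < 1)
  pos_key <- pair_key(positives$ec, positives$pfam)
  neg_key <- pair_key(negatives$ec, negatives$pfam)
  if (anyDuplicated(pos_key) || anyDuplicated(neg_key))
    stop("reference pairs must be unique within each class")
  if (length(intersect(pos_key, neg_key)) > 0L)
    stop("positive and negative reference pairs must be disjoint")
  structure(list(positives = positives[order(pos_key), c("ec", "pfam"), drop = FALSE],
                 negatives = negatives[order(neg_key), c("ec", "pfam"), drop = FALSE],
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "reference_set")
}

#' Split a reference set into train and test halves
#'
#' Deterministic given the reference contents, fraction and seed: pairs
#' are put in canonical order before the seeded draw.
#'
#' @param ref A `"reference_set"`.
#' @return List with data.frames `train` and `test`, each with columns
#'   `ec`, `pfam`, `label` (`"pos"`/`"neg"`).
#' @export
split_reference <- function(ref) {
  stopifnot(inherits(ref, "reference_set"))
  take <- function(df, label, seed_offset) {
    n <- nrow(df)
    n_train <- round(n * ref$train_fraction)
    idx <- with_local_seed(ref$seed + seed_offset, sample.int(n, n_train))
    df$label <- label
    list(train = df[sort(idx), , drop = FALSE],
         test = df[setdiff(seq_len(n), idx), , drop = FALSE])
  }
  pos <- take(ref$positives, "pos", 0L)
  neg <- take(ref$negatives, "neg", 1L)
  train <- rbind(pos$train, neg$train)
  test <- rbind(pos$test, neg$test)
  rownames(train) <- rownames(test) <- NULL
  list(train = train, test = test)
}

#' Sample negative (shuffled) EC-Pfam reference pairs
#'
#' Emulates the construction of "false" associations: the CID columns of
#' one source's EC-CID and Pfam-CID pair lists are permuted independently,
#' the permuted lists are joined on CID, and the resulting pairs are
#' pooled; pairs that genuinely co-occur in any source (the candidate
#' universe) or that appear in the positive reference are rejected, and
#' `n` pairs are drawn uniformly from the survivors.
#'
#' @param datasets Named list of `"assoc_dataset"` objects (all sources;
#'   used to compute the candidate universe to reject).
#' @param n Number of negatives required.
#' @param seed Integer seed; same seed, same output.
#' @param source Name of the dataset whose pair lists are shuffled
#'   (default `"SIFTS"` when present, else the first).
#' @param positives Optional data.frame of positive pairs to reject.
#' @param ec_level 4 or 3; at level 3 shuffling happens on truncated EC
#'   labels and rejection uses the level-3 candidate universe.
#' @param max_rounds Shuffle rounds attempted before giving up.
#' @return data.frame with columns `ec`, `pfam`.
#' @export
generate_negatives <- function(datasets, n, seed = 1515L, source = NULL,
                               positives = NULL, ec_level = 4L, max_rounds = 50L) {
  stopifnot(n >= 0L)
  if (n == 0L)
    return(data.frame(ec = character(), pfam = character(), stringsAsFactors = FALSE))
  if (is.null(source))
    source <- if ("SIFTS" %in% names(datasets)) "SIFTS" else names(datasets)[1L]
  ds <- datasets[[source]]
  if (is.null(ds) || length(ds$ec_to_cids) == 0L || length(ds$pfam_to_cids) == 0L)
    stop(sprintf("shuffle source '%s' is empty or missing", source))

  forbidden <- unlist(lapply(datasets, function(d) {
    t <- raw_scores(d, ec_level = ec_level)
    pair_key(t$ec, t$pfam)
  }), use.names = FALSE)
  if (!is.null(positives))
    forbidden <- c(forbidden, pair_key(positives$ec, positives$pfam))
  forbidden <- unique(forbidden)

  ec_map <- ds$ec_to_cids
  if (ec_level == 3L) {
    key3 <- ec_to_level3(names(ec_map))
    ec_map <- lapply(split(ec_map, key3), function(s) unique(unlist(s)))
  }
  ec_lab <- rep(names(ec_map), lengths(ec_map))
  ec_cid <- unlist(ec_map, use.names = FALSE)
  pf_lab <- rep(names(ds$pfam_to_cids), lengths(ds$pfam_to_cids))
  pf_cid <- unlist(ds$pfam_to_cids, use.names = FALSE)

  pool <- character()
  with_local_seed(seed, {
    for (round in seq_len(max_rounds)) {
      ec_perm <- sample(ec_cid)
      pf_perm <- sample(pf_cid)
      joined <- merge(data.frame(ec = ec_lab, cid = ec_perm, stringsAsFactors = FALSE),
                      data.frame(pfam = pf_lab, cid = pf_perm, stringsAsFactors = FALSE),
                      by = "cid")
      cand <- unique(pair_key(joined$ec, joined$pfam))
      pool <- unique(c(pool, setdiff(cand, forbidden)))
      if (length(pool) >= n) break
    }
    if (length(pool) < n)
      stop(sprintf("could only generate %d of %d negative pairs after %d shuffle rounds",
                   length(pool), n, max_rounds))
    pool <- sample(pool, n)
  })
  parts <- strsplit(sort(pool), "\t", fixed = TRUE)
  data.frame(ec = vapply(parts, `[[`, character(1L), 1L),
             pfam = vapply(parts, `[[`, character(1L), 2L),
             stringsAsFactors = FALSE)
}
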