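#' Per-source raw cosine association scores
#'
#' Each EC number and each Pfam entry is represented as a binary vector
#' over the dataset's CIDs.  The EC-by-CID matrix is row-normalised to
#' unit vectors, the CID-by-Pfam matrix is column-normalised, and their
#' product yields the matrix of cosine similarities: for a pair (ec, d)
#' with CID sets A and B,
#' \deqn{S(ec, d) = |A \cap B| / (\sqrt{|A|}\,\sqrt{|B|}).}
#' Only pairs with a non-empty intersection are materialised; absent pairs
#' are implicitly zero.  Labels with no CID support produce no candidates
#' (a zero vector cannot be normalised).
#'
#' @param dataset An `"assoc_dataset"`.
#' @param ec_level 4 (default) scores fully specified EC numbers; 3 first
#'   truncates every EC key to its 3-digit parent, pooling the CID sets of
#'   sibling enzymes.
#' @return A data.frame of class `"raw_scores"` with columns `ec`, `pfam`,
#'   `score`, sorted by (`ec`, `pfam`); attributes `dataset` (name),
#'   `n_cids` (CID universe size) and `n_ec_cids` / `n_pfam_cids`
#'   (per-label support, used later by the significance module).
#' @export
raw_scores <- function(dataset, ec_level = 4L) {
  stopifnot(inherits(dataset, "assoc_dataset"), ec_level %in% c(3L, 4L))
  ec_map <- dataset$ec_to_cids
  if (ec_level == 3L && length(ec_map) > 0L) {
    key3 <- ec_to_level3(names(ec_map))
    ec_map <- lapply(split(ec_map, key3), function(sets) sort(unique(unlist(sets))))
  }
  pf_map <- dataset$pfam_to_cids
  empty <- data.frame(ec = character(), pfam = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  out <- if (length(ec_map) == 0L || length(pf_map) == 0L) {
    empty
  } else {
    cids <- sort(unique(c(unlist(ec_map, use.names = FALSE),
                          unlist(pf_map, use.names = FALSE))))
    ecs <- names(ec_map)
    pfs <- names(pf_map)
    E <- Matrix::sparseMatrix(
      i = rep(seq_along(ecs), lengths(ec_map)),
      j = match(unlist(ec_map, use.names = FALSE), cids),
      x = 1, dims = c(length(ecs), length(cids)))
    P <- Matrix::sparseMatrix(
      i = match(unlist(pf_map, use.names = FALSE), cids),
      j = rep(seq_along(pfs), lengths(pf_map)),
      x = 1, dims = c(length(cids), length(pfs)))
    En <- Matrix::Diagonal(x = 1 / sqrt(Matrix::rowSums(E))) %*% E
    Pn <- P %*% Matrix::Diagonal(x = 1 / sqrt(Matrix::colSums(P)))
    S <- methods::as(En %*% Pn, "TsparseMatrix")
    data.frame(ec = ecs[S@i + 1L], pfam = pfs[S@j + 1L], score = S@x,
               stringsAsFactors = FALSE)
  }
  out <- out[order(out$ec, out$pfam), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            dataset = dataset$name,
            ec_digits = ec_level,
            n_cids = length(dataset$cid_universe),
            n_ec_cids = lengths(ec_map),
            n_pfam_cids = lengths(pf_map),
            class = c("raw_scores", "data.frame"))
}

#' Set-arithmetic cosine score for one pair
#'
#' Independent of the matrix route in [raw_scores()]: computes the cosine
#' of two binary support vectors directly from the CID sets.
#'
#' @param ec_cids,pfam_cids Non-empty character vectors of CIDs.
#' @return The cosine similarity in `[0, 1]`.
#' @examples
#' cosine_oracle(c("c1", "c2"), "c1")  # 1 / sqrt(2)
#' @export
cosine_oracle <- function(ec_cids, pfam_cids) {
  ec_cids <- unique(ec_cids)
  pfam_cids <- unique(pfam_cids)
  if (length(ec_cids) == 0L || length(pfam_cids) == 0L)
    stop("cosine_oracle() requires non-empty CID sets")
  length(intersect(ec_cids, pfam_cids)) /
    (sqrt(length(ec_cids)) * sqrt(length(pfam_cids)))
}

#' Combine per-source raw scores into confidence scores
#'
#' The candidate universe is the union of scored pairs over all sources;
#' a source with no data for a pair contributes a score of zero.  The
#' combined confidence score is the weighted average
#' \deqn{CS_{ec,d} = \sum_i w_i S_i(ec,d) / \sum_i w_i,}
#' so it lives in `[0, 1]` and is monotone in every per-source score.
#'
#' @param tables Named list of `"raw_scores"` tables (names are the source
#'   labels; unnamed lists take each table's `dataset` attribute).
#' @param weights Named numeric vector of weights in `[0, 1]` covering
#'   every table name; their sum must be positive.
#' @return A data.frame of class `"scored_assoc"` with columns `ec`,
#'   `pfam`, one `S_<source>` column per table, and `cs`; rows sorted by
#'   decreasing `cs`, ties broken by (`ec`, `pfam`).
#' @export
combine_scores <- function(tables, weights) {
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- vapply(tables, attr, character(1L), "dataset")
  nm <- names(tables)
  if (anyDuplicated(nm)) stop("duplicate source names in 'tables'")
  if (!all(nm %in% names(weights)))
    stop(sprintf("no weight supplied for source(s): %s",
                 paste(setdiff(nm, names(weights)), collapse = ", ")))
  w <- as.numeric(weights[nm])
  if (any(w < 0) || any(w > 1)) stop("weights must lie in [0, 1]")
  if (sum(w) <= 0) stop("total weight must be positive")

  keys <- unique(unlist(lapply(tables, function(t) paste(t$ec, t$pfam, sep = "\t")),
                        use.names = FALSE))
  S <- matrix(0, nrow = length(keys), ncol = length(nm),
              dimnames = list(NULL, paste0("S_", nm)))
  for (k in seq_along(tables)) {
    t <- tables[[k]]
    S[match(paste(t$ec, t$pfam, sep = "\t"), keys), k] <- t$score
  }
  cs <- as.numeric(S %*% w) / sum(w)
  parts <- strsplit(keys, "\t", fixed = TRUE)
  out <- data.frame(ec = vapply(parts, `[[`, character(1L), 1L),
                    pfam = vapply(parts, `[[`, character(1L), 2L),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(S))
  out$cs <- cs
  ord <- order(-out$cs, out$ec, out$pfam)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, weights = stats::setNames(w, nm),
            class = c("scored_assoc", "data.frame"))
}

#' Write a combined score table
#'
#' TSV dialect: `ec`, `pfam`, one raw-score column per source, then the
#' combined `cs`, all scores with six decimal places (absent scores as 0).
#'
#' @param scored A `"scored_assoc"` data.frame.
#' @param path Output path.
#' @export
write_score_table <- function(scored, path) {
  num <- vapply(scored, is.numeric, logical(1L))
  out <- scored
  out[num] <- lapply(out[num], function(x) sprintf("%.6f", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(scored)
}

# fast key helper used across modules
pair_key <- function(ec, pfam) paste(ec, pfam, sep = "\t")

`%||%` <- function(x, y) if (is.null(x)) y else x
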