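#' Rescue sub-threshold 4-digit associations through the 3-digit hierarchy
#'
#' Fully specified enzymes with few annotated clusters can fail the
#' 4-digit threshold even when the association is real.  Scoring is
#' therefore repeated at the 3-digit level (pooling sibling enzymes), and
#' any scored 4-digit candidate below the 4-digit threshold whose parent
#' class carries an accepted 3-digit association with the same domain is
#' rescued into the final list.  Rescue never mints new pairs: only
#' candidates with an observed 4-digit co-occurrence are eligible.
#'
#' @param candidates4 Scored 4-digit associations (`"scored_assoc"`).
#' @param threshold4 The calibrated 4-digit acceptance threshold.
#' @param accepted3 data.frame of accepted 3-digit associations with
#'   columns `ec`, `pfam`, `cs` (e.g. the rows of a level-3 `scored`
#'   table with `cs >= threshold3`).
#' @return data.frame of rescue records: `ec`, `pfam`, `parent_ec3`,
#'   `cs4`, `cs3`.
#' @export
rescue_associations <- function(candidates4, threshold4, accepted3) {
  low <- candidates4[candidates4$cs < threshold4, , drop = FALSE]
  parent <- ec_to_level3(low$ec)
  key3 <- pair_key(accepted3$ec, accepted3$pfam)
  hit <- match(pair_key(parent, low$pfam), key3)
  keep <- !is.na(hit)
  out <- data.frame(ec = low$ec[keep], pfam = low$pfam[keep],
                    parent_ec3 = parent[keep], cs4 = low$cs[keep],
                    cs3 = accepted3$cs[hit[keep]],
                    stringsAsFactors = FALSE)
  out <- out[order(out$ec, out$pfam), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the final accepted association set
#'
#' Direct acceptances (`cs >= threshold4`, provenance `direct4`) are
#' united with hierarchy rescues (provenance `rescued3`).  The two parts
#' are disjoint by construction, so every association appears once and
#' direct provenance takes precedence.
#'
#' @param scored4 Scored 4-digit associations.
#' @param threshold4 4-digit acceptance threshold.
#' @param rescued data.frame from [rescue_associations()] (or `NULL`).
#' @return data.frame with the columns of `scored4` plus `provenance`,
#'   sorted by decreasing `cs`, ties by (`ec`, `pfam`).
#' @export
finalize_associations <- function(scored4, threshold4, rescued = NULL) {
  direct <- scored4[scored4$cs >= threshold4, , drop = FALSE]
  direct$provenance <- if (nrow(direct)) "direct4" else character()
  if (!is.null(rescued) && nrow(rescued) > 0L) {
    res <- scored4[match(pair_key(rescued$ec, rescued$pfam),
                         pair_key(scored4$ec, scored4$pfam)), , drop = FALSE]
    res$provenance <- "rescued3"
    out <- rbind(direct, res)
  } else {
    out <- direct
  }
  out <- out[order(-out$cs, out$ec, out$pfam), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the rescue audit table
#'
#' TSV dialect `ec4 pfam parent_ec3 cs4 cs3 status` with status
#' `rescued3`.
#'
#' @param rescued data.frame from [rescue_associations()].
#' @param path Output path.
#' @export
write_rescue_table <- function(rescued, path) {
  out <- data.frame(ec4 = rescued$ec, pfam = rescued$pfam,
                    parent_ec3 = rescued$parent_ec3,
                    cs4 = sprintf("%.6f", rescued$cs4),
                    cs3 = sprintf("%.6f", rescued$cs3),
                    status = rep("rescued3", nrow(rescued)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rescued)
}
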