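#' Query accepted associations by EC number or Pfam accession
#'
#' The key type is recognised from its syntax: `PF` plus five digits is a
#' Pfam accession, anything else must parse as an EC number.  Matching
#' associations are returned ordered by decreasing confidence; an unknown
#' key yields an empty result, not an error.
#'
#' @param accepted Final classified associations.
#' @param key A single EC string or Pfam accession.
#' @return The matching rows of `accepted`.
#' @export
query_associations <- function(accepted, key) {
  stopifnot(is.character(key), length(key) == 1L)
  hit <- if (is_pfam_acc(key)) {
    accepted$pfam == key
  } else {
    accepted$ec == format(parse_ec(key))
  }
  out <- accepted[hit, , drop = FALSE]
  out <- out[order(-out$cs, out$ec, out$pfam), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate enzyme-unannotated entities from their domain content
#'
#' Every entity that lacks a prior EC annotation but carries at least one
#' domain present in the accepted association store receives the EC
#' numbers those domains are associated with.  When several of an
#' entity's domains imply the same EC number, the best quality class
#' (Gold > Silver > Bronze) and the largest confidence score are
#' reported, and all witnessing domains are listed.
#'
#' @param entity_pfam data.frame of entity-level Pfam annotation pairs
#'   (columns `entity_id`, `label`), e.g. from
#'   [read_association_table()] with `kind = "pfam"`.
#' @param accepted Final classified associations (columns `ec`, `pfam`,
#'   `cs`, `quality`).
#' @param already_ec Character vector of entity ids that already have an
#'   EC annotation; these are skipped.
#' @return data.frame with columns `entity_id`, `ec`, `confidence`,
#'   `quality`, `via_pfam` (`;`-joined witnessing accessions), sorted by
#'   entity then decreasing confidence.  Entities with no inferable EC
#'   are omitted.
#' @export
annotate_entities <- function(entity_pfam, accepted, already_ec = character()) {
  df <- entity_pfam[!(entity_pfam$entity_id %in% already_ec), , drop = FALSE]
  if (nrow(df) == 0L || nrow(accepted) == 0L)
    return(data.frame(entity_id = character(), ec = character(),
                      confidence = numeric(), quality = character(),
                      via_pfam = character(), stringsAsFactors = FALSE))
  store <- accepted[, c("ec", "pfam", "cs", "quality")]
  joined <- merge(df, store, by.x = "label", by.y = "pfam")
  if (nrow(joined) == 0L)
    return(data.frame(entity_id = character(), ec = character(),
                      confidence = numeric(), quality = character(),
                      via_pfam = character(), stringsAsFactors = FALSE))
  qual_rank <- c(Gold = 1L, Silver = 2L, Bronze = 3L)
  grp <- split(joined, paste(joined$entity_id, joined$ec, sep = "\t"))
  rows <- lapply(grp, function(g) {
    data.frame(entity_id = g$entity_id[1L], ec = g$ec[1L],
               confidence = max(g$cs),
               quality = names(qual_rank)[min(qual_rank[g$quality])],
               via_pfam = paste(sort(unique(g$label)), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$entity_id, -out$confidence, out$ec), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the entity annotation table
#'
#' @param annotations data.frame from [annotate_entities()].
#' @param path Output path.
#' @export
write_annotation_table <- function(annotations, path) {
  out <- annotations
  out$confidence <- sprintf("%.6f", out$confidence)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(annotations)
}
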