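#' Read a two-column annotation association table
#'
#' The pipeline starts from pre-extracted plain TSV lists of
#' (entity, label) annotation pairs: one file per source per label kind.
#' Lines starting with `#` and blank lines are ignored; both LF and CRLF
#' endings are accepted.  Duplicate pairs collapse to their first
#' occurrence, preserving file order.
#'
#' @param path Path to a TSV file with columns `entity_id` and `label`.
#' @param kind `"ec"` or `"pfam"`; controls label validation
#'   ([normalize_ec()] vs the `PFxxxxx` accession rule).
#' @return A data.frame with character columns `entity_id` and `label`.
#' @export
read_association_table <- function(path, kind = c("ec", "pfam")) {
  kind <- match.arg(kind)
  fields <- read_tsv_fields(path, n_cols = 2L)
  df <- data.frame(entity_id = fields[[1L]], label = fields[[2L]],
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0L) {
    df$label <- if (kind == "ec") normalize_ec(df$label) else check_pfam(df$label)
    df <- df[!duplicated(paste(df$entity_id, df$label, sep = "\r")), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Read an entity-to-cluster (CID) mapping
#'
#' Clusters group entities (structure chains or sequences) at 100%
#' sequence identity so that redundant copies of the same molecule do not
#' inflate association support.  The mapping must be many-to-one; an
#' entity listed with two different CIDs is an error.
#'
#' @param path TSV file with columns `entity_id` and `cid`.
#' @param space Optional tag, `"structure"` or `"sequence"`.
#' @return A named character vector mapping entity id to CID, with a
#'   `space` attribute.
#' @export
read_cluster_map <- function(path, space = c("sequence", "structure")) {
  space <- match.arg(space)
  fields <- read_tsv_fields(path, n_cols = 2L)
  map <- fields[[2L]]
  names(map) <- fields[[1L]]
  dup <- duplicated(names(map))
  if (any(dup)) {
    clash <- map[names(map) %in% names(map)[dup]]
    bad <- tapply(clash, names(clash), function(v) length(unique(v)) > 1L)
    if (any(bad))
      stop(sprintf("entity '%s' mapped to more than one CID", names(bad)[bad][1L]))
    map <- map[!dup]
  }
  attr(map, "space") <- space
  map
}

#' Read a curated reference table of EC-Pfam pairs
#'
#' @param path TSV file `ec<TAB>pfam[<TAB>pos|neg]`; rows without a third
#'   column are positives.
#' @param ec_digits 4 (default) or 3; reference ECs must be at this level.
#' @return data.frame with columns `ec`, `pfam`, `label`.
#' @export
read_reference_table <- function(path, ec_digits = 4L) {
  lines <- read_tsv_lines(path)
  if (length(lines) == 0L)
    return(data.frame(ec = character(), pfam = character(), label = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L | nf > 3L))
    stop(sprintf("line %d of '%s': expected 2 or 3 tab-separated fields, got %d",
                 attr(lines, "line_no")[which(nf < 2L | nf > 3L)[1L]], path,
                 nf[which(nf < 2L | nf > 3L)[1L]]))
  ec <- normalize_ec(vapply(parts, `[[`, character(1L), 1L))
  if (any(ec_level(ec) != ec_digits))
    stop(sprintf("reference EC numbers must have %d digits", ec_digits))
  pfam <- check_pfam(vapply(parts, `[[`, character(1L), 2L))
  label <- vapply(parts, function(p) if (length(p) == 3L) p[[3L]] else "pos",
                  character(1L))
  if (!all(label %in% c("pos", "neg")))
    stop("reference labels must be 'pos' or 'neg'")
  df <- data.frame(ec = ec, pfam = pfam, label = label, stringsAsFactors = FALSE)
  df[!duplicated(paste(df$ec, df$pfam)), , drop = FALSE]
}

# Shared low-level TSV reading: returns non-comment, non-blank lines with
# original line numbers attached; CRLF tolerated.
read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  raw <- sub("\r$", "", raw)
  keep <- !grepl("^\\s*(#|$)", raw)
  out <- raw[keep]
  attr(out, "line_no") <- which(keep)
  out
}

read_tsv_fields <- function(path, n_cols) {
  lines <- read_tsv_lines(path)
  if (length(lines) == 0L)
    return(rep(list(character()), n_cols))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != n_cols)) {
    i <- which(nf != n_cols)[1L]
    stop(sprintf("line %d of '%s': expected %d tab-separated fields, got %d",
                 attr(lines, "line_no")[i], path, n_cols, nf[i]))
  }
  lapply(seq_len(n_cols), function(j) vapply(parts, `[[`, character(1L), j))
}

#' Write an entity-level annotation pair table
#'
#' Inverse of [read_association_table()]: emits `entity_id<TAB>label`
#' lines in the row order given.
#'
#' @param pairs data.frame with columns `entity_id`, `label`.
#' @param path Output path.
#' @export
write_pair_table <- function(pairs, path) {
  writeLines(if (nrow(pairs)) paste(pairs$entity_id, pairs$label, sep = "\t")
             else character(), path)
  invisible(pairs)
}

#' Build a CID-level association dataset
#'
#' Maps entity-level EC and Pfam annotation pairs onto their clusters,
#' collapsing duplicates, to give one source's `ec -> CIDs` and
#' `pfam -> CIDs` maps.  With `cluster_map = NULL` each entity is its own
#' cluster (identity map).
#'
#' @param ec_pairs,pfam_pairs data.frames as returned by
#'   [read_association_table()].
#' @param cluster_map Named character vector (entity -> CID) or `NULL`.
#' @param name Dataset label, e.g. `"SIFTS"` or `"SwissProt"`.
#' @return An object of class `"assoc_dataset"`: a list with `name`,
#'   `ec_to_cids` and `pfam_to_cids` (named lists of character vectors)
#'   and `cid_universe`.
#' @export
build_dataset <- function(ec_pairs, pfam_pairs, cluster_map = NULL, name = "dataset") {
  map_cids <- function(pairs) {
    if (nrow(pairs) == 0L)
      return(list(sets = list(), cids = character()))
    ent <- pairs$entity_id
    if (is.null(cluster_map)) {
      cid <- ent
    } else {
      cid <- unname(cluster_map[ent])
      if (anyNA(cid)) {
        missing <- sort(unique(ent[is.na(cid)]))
        stop(sprintf("entities absent from cluster map: %s",
                     paste(missing, collapse = ", ")))
      }
    }
    sets <- lapply(split(cid, pairs$label), function(v) sort(unique(v)))
    list(sets = sets, cids = unique(cid))
  }
  ec <- map_cids(ec_pairs)
  pf <- map_cids(pfam_pairs)
  structure(list(name = name,
                 ec_to_cids = ec$sets,
                 pfam_to_cids = pf$sets,
                 cid_universe = sort(unique(c(ec$cids, pf$cids)))),
            class = "assoc_dataset")
}

#' @export
print.assoc_dataset <- function(x, ...) {
  cat(sprintf("<assoc_dataset '%s': %d ECs, %d Pfam entries, %d CIDs>\n",
              x$name, length(x$ec_to_cids), length(x$pfam_to_cids),
              length(x$cid_universe)))
  invisible(x)
}

#' Write a dataset back to its TSV dialect
#'
#' Emits the CID-level pair lists (`cid<TAB>label`) for the EC and Pfam
#' maps of a dataset; re-reading with [read_association_table()] and
#' [build_dataset()] under the identity cluster map reproduces the maps.
#'
#' @param dataset An `"assoc_dataset"`.
#' @param ec_path,pfam_path Output file paths.
#' @return Invisibly, the dataset.
#' @export
write_dataset_tables <- function(dataset, ec_path, pfam_path) {
  dump_map <- function(m, path) {
    labs <- rep(names(m), lengths(m))
    cids <- unlist(m, use.names = FALSE)
    if (is.null(cids)) cids <- character()
    ord <- order(labs, cids)
    writeLines(if (length(labs)) paste(cids[ord], labs[ord], sep = "\t") else character(),
               path)
  }
  dump_map(dataset$ec_to_cids, ec_path)
  dump_map(dataset$pfam_to_cids, pfam_path)
  invisible(dataset)
}
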