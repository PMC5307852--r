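#' Parse an Enzyme Commission number
#'
#' EC numbers are hierarchical dot-separated codes with a top-level branch
#' (1--6: oxidoreductases, transferases, hydrolases, lyases, isomerases,
#' ligases) followed by class, subclass and, for fully specified enzymes, a
#' serial (substrate) component.  `parse_ec()` accepts 3- and 4-component
#' codes; trailing unspecified components written as `-` (e.g. `"3.4.22.-"`)
#' are dropped, so that code parses as the 3-digit class `3.4.22`.  Codes
#' with fewer than three specified components are rejected: both the
#' 4-digit scoring scheme and the 3-digit hierarchy relaxation need at
#' least the class level.
#'
#' @param text A single character string, e.g. `"2.7.8.28"` or `"3.4.22"`.
#' @return An object of class `"ec_number"`: a list with integer components
#'   `d1`, `d2`, `d3`, `d4` (`NA` when absent) and `level` (3 or 4).
#' @examples
#' parse_ec("2.7.8.28")
#' parse_ec("3.4.22")$level
#' @export
parse_ec <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("EC number must be a single non-empty string")
  comps <- strsplit(text, ".", fixed = TRUE)[[1L]]
  # drop trailing unspecified components written as "-"
  while (length(comps) > 0L && comps[length(comps)] == "-")
    comps <- comps[-length(comps)]
  if (length(comps) < 3L || length(comps) > 4L)
    stop(sprintf("malformed EC number '%s': expected 3 or 4 components, got %d",
                 text, length(comps)))
  bad <- !grepl("^[0-9]+$", comps)
  if (any(bad))
    stop(sprintf("malformed EC number '%s': non-numeric component '%s'",
                 text, comps[which(bad)[1L]]))
  num <- as.integer(comps)
  if (num[1L] < 1L || num[1L] > 6L)
    stop(sprintf("malformed EC number '%s': branch %d outside 1..6",
                 text, num[1L]))
  structure(list(d1 = num[1L], d2 = num[2L], d3 = num[3L],
                 d4 = if (length(num) == 4L) num[4L] else NA_integer_,
                 level = length(num)),
            class = "ec_number")
}

#' @export
format.ec_number <- function(x, ...) {
  comps <- c(x$d1, x$d2, x$d3, if (x$level == 4L) x$d4)
  paste(comps, collapse = ".")
}

#' @export
as.character.ec_number <- function(x, ...) format(x)

#' @export
print.ec_number <- function(x, ...) {
  cat(sprintf("<EC %s (level %d)>\n", format(x), x$level))
  invisible(x)
}

#' Validate and canonicalise a vector of EC codes
#'
#' Vectorised wrapper around the [parse_ec()] grammar, used by the TSV
#' readers.  Every element must parse; the canonical dot-joined rendering
#' is returned (so `"1.1.1.1."`-style irregularities never survive ingest).
#'
#' @param x Character vector of EC codes.
#' @return Character vector of canonical EC strings.
#' @export
normalize_ec <- function(x) {
  vapply(x, function(s) format(parse_ec(s)), character(1L), USE.NAMES = FALSE)
}

#' Number of specified EC components
#'
#' @param x Character vector of (already canonical) EC strings.
#' @return Integer vector of levels, 3 or 4.
#' @export
ec_level <- function(x) {
  lengths(strsplit(x, ".", fixed = TRUE))
}

#' Truncate a 4-digit EC number to its 3-digit parent
#'
#' `truncate_ec()` is strict: its input must be a fully specified 4-digit
#' code.  [ec_to_level3()] is the normalising companion that leaves 3-digit
#' codes unchanged, so repeated application is idempotent.
#'
#' @param x Character vector of EC strings (or a single `"ec_number"`).
#' @return Character vector of 3-digit EC strings (an `"ec_number"` in, an
#'   `"ec_number"` out).
#' @examples
#' truncate_ec("2.7.8.28")   # "2.7.8"
#' ec_to_level3(c("1.1.1.1", "3.4.22"))
#' @export
truncate_ec <- function(x) {
  if (inherits(x, "ec_number")) {
    if (x$level != 4L) stop("truncate_ec() requires a 4-digit EC number")
    return(parse_ec(paste(x$d1, x$d2, x$d3, sep = ".")))
  }
  lv <- ec_level(x)
  if (any(lv != 4L))
    stop("truncate_ec() requires 4-digit EC numbers; use ec_to_level3() to normalise mixed input")
  ec_to_level3(x)
}

#' @rdname truncate_ec
#' @export
ec_to_level3 <- function(x) {
  sub("^([0-9]+\\.[0-9]+\\.[0-9]+)\\.[0-9]+$", "\\1", x)
}

#' Validate Pfam accessions
#'
#' A Pfam entry (domain or family) is identified by an accession matching
#' `PF` followed by five digits; names are free text carried separately.
#' Comparisons throughout the package are by accession only.
#'
#' @param x Character vector of candidate accessions.
#' @return `x` invisibly for `check_pfam()`; logical vector for `is_pfam_acc()`.
#' @export
is_pfam_acc <- function(x) {
  grepl("^PF[0-9]{5}$", x)
}

#' @rdname is_pfam_acc
#' @export
check_pfam <- function(x) {
  bad <- !is_pfam_acc(x)
  if (any(bad))
    stop(sprintf("invalid Pfam accession '%s' (expected PF followed by five digits)",
                 x[which(bad)[1L]]))
  invisible(x)
}
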