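#' Support ratio of a domain tuple for an EC number in one source
#'
#' The fraction of the source's EC-annotated clusters that carry every
#' domain of the tuple.  A ratio of 1 means all clusters annotated with
#' the EC number also carry the full tuple.  When the EC number has no
#' annotated cluster in the source the ratio is non-evaluable (`NA`).
#'
#' @param dataset An `"assoc_dataset"`.
#' @param ec EC number string.
#' @param domains Character vector of Pfam accessions (the tuple).
#' @return Ratio in `[0, 1]`, or `NA` if non-evaluable.
#' @export
support_ratio <- function(dataset, ec, domains) {
  ec_cids <- dataset$ec_to_cids[[ec]]
  if (is.null(ec_cids) || length(ec_cids) == 0L) return(NA_real_)
  carry_all <- rep(TRUE, length(ec_cids))
  for (d in domains)
    carry_all <- carry_all & ec_cids %in% dataset$pfam_to_cids[[d]]
  mean(carry_all)
}

#' Mine obligate Pfam tuples for accepted EC associations
#'
#' For every EC number, size-2 to size-`max_arity` subsets of its accepted
#' partner domains are examined.  A tuple is rejected when, in any source,
#' some EC-annotated cluster carries a proper non-empty subset of the
#' tuple (some domains but not all): the domains then occur separably and
#' cannot form an obligate unit such as an interface or co-factor pair.
#' Surviving tuples are reported when their per-source support ratio
#' ([support_ratio()]) equals 1 in at least one evaluable source.
#'
#' Tuples whose domain names contain both an "N-terminal" and a
#' "C-terminal" token are flagged — these typically mark enzymes whose
#' catalytic site sits at the interface of two consecutive domains.
#'
#' @param datasets Named list of `"assoc_dataset"` sources.
#' @param accepted Final accepted associations (columns `ec`, `pfam`).
#' @param max_arity Largest tuple size considered (2--4; default 4).
#' @param pfam_names Optional named character vector of Pfam names
#'   (accession -> name) used only for the terminal-interface flag.
#' @param maximal_only If `TRUE`, drop tuples contained in a larger
#'   reported tuple for the same EC (default `FALSE`: pairs, triplets and
#'   quadruplets are all reported).
#' @param max_domains Safety cap on the number of accepted domains per EC
#'   enumerated (default 25).
#' @return data.frame with one row per reported tuple: `ec`, `arity`,
#'   `domains` (`;`-joined accessions), one `support_<source>` column per
#'   source, `nc_terminal_flag`.
#' @export
find_obligate_tuples <- function(datasets, accepted, max_arity = 4L,
                                 pfam_names = NULL, maximal_only = FALSE,
                                 max_domains = 25L) {
  stopifnot(max_arity >= 2L, max_arity <= 4L)
  nm <- names(datasets)
  # per-source membership: for each dataset, cid -> set of pfams (via lookup)
  by_ec <- split(accepted$pfam, accepted$ec)
  rows <- list()
  for (ec in names(by_ec)) {
    domains <- sort(unique(by_ec[[ec]]))
    if (length(domains) < 2L) next
    if (length(domains) > max_domains) {
      warning(sprintf("EC %s has %d accepted domains; enumerating the first %d",
                      ec, length(domains), max_domains))
      domains <- domains[seq_len(max_domains)]
    }
    # presence matrix per dataset: ec-annotated CIDs x candidate domains
    pres <- lapply(nm, function(d) {
      ds <- datasets[[d]]
      ec_cids <- ds$ec_to_cids[[ec]]
      if (is.null(ec_cids) || length(ec_cids) == 0L) return(NULL)
      m <- vapply(domains, function(p) ec_cids %in% ds$pfam_to_cids[[p]],
                  logical(length(ec_cids)))
      matrix(m, nrow = length(ec_cids), ncol = length(domains),
             dimnames = list(NULL, domains))
    })
    names(pres) <- nm
    for (arity in 2L:min(max_arity, length(domains))) {
      combos <- utils::combn(domains, arity, simplify = FALSE)
      for (tuple in combos) {
        hit_counts <- lapply(pres, function(m) {
          if (is.null(m)) NULL else rowSums(m[, tuple, drop = FALSE])
        })
        # rule (i): a proper non-empty subset on any ec-annotated CID
        # in any source disqualifies the tuple
        separable <- any(vapply(hit_counts, function(h) {
          !is.null(h) && any(h > 0L & h < arity)
        }, logical(1L)))
        if (separable) next
        support <- vapply(hit_counts, function(h) {
          if (is.null(h)) NA_real_ else mean(h == arity)
        }, numeric(1L))
        if (!any(!is.na(support) & support == 1)) next
        flag <- NA
        if (!is.null(pfam_names)) {
          nms <- pfam_names[tuple]
          flag <- any(grepl("N-terminal", nms, ignore.case = TRUE)) &&
            any(grepl("C-terminal", nms, ignore.case = TRUE))
        }
        rows[[length(rows) + 1L]] <- c(
          list(ec = ec, arity = arity, domains = paste(tuple, collapse = ";")),
          as.list(stats::setNames(support, paste0("support_", nm))),
          list(nc_terminal_flag = flag))
      }
    }
  }
  out <- if (length(rows) == 0L) {
    empty <- data.frame(ec = character(), arity = integer(), domains = character(),
                        stringsAsFactors = FALSE)
    for (d in nm) empty[[paste0("support_", d)]] <- numeric()
    empty$nc_terminal_flag <- logical()
    empty
  } else {
    do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  }
  if (maximal_only && nrow(out) > 1L) {
    keep <- rep(TRUE, nrow(out))
    doms <- strsplit(out$domains, ";", fixed = TRUE)
    for (i in seq_len(nrow(out))) {
      for (j in seq_len(nrow(out))) {
        if (i != j && out$ec[i] == out$ec[j] && out$arity[i] < out$arity[j] &&
            all(doms[[i]] %in% doms[[j]])) {
          keep[i] <- FALSE
          break
        }
      }
    }
    out <- out[keep, , drop = FALSE]
  }
  out <- out[order(out$ec, out$arity, out$domains), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the obligate-tuple table
#'
#' TSV dialect: `ec`, `arity`, `domains` (`;`-joined), per-source support
#' ratios, `nc_terminal_flag`.
#'
#' @param tuples data.frame from [find_obligate_tuples()].
#' @param path Output path.
#' @export
write_tuples_table <- function(tuples, path) {
  out <- tuples
  sup <- grep("^support_", names(out), value = TRUE)
  out[sup] <- lapply(out[sup], function(x) ifelse(is.na(x), "NA", sprintf("%.4f", x)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tuples)
}
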