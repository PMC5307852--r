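#' Upper-tail hypergeometric p-value for a co-occurrence
#'
#' With `N` clusters in a source, of which `N_ec` carry the EC number and
#' `N_d` carry the domain, the probability of observing at least the `K`
#' jointly annotated clusters under random assignment is the upper tail
#' \deqn{p = \sum_{i=K}^{\min(N_d, N_{ec})}
#'   \binom{N_{ec}}{i} \binom{N - N_{ec}}{N_d - i} / \binom{N}{N_d},}
#' evaluated through the stable log-space machinery of
#' [stats::phyper()].  `K = 0` gives exactly 1.
#'
#' @param N,N_ec,N_d,K Integer vectors (recycled): total clusters, EC
#'   support, domain support and joint support.  Must satisfy
#'   `0 <= K <= min(N_ec, N_d) <= N` and `K >= N_ec + N_d - N`.
#' @return Numeric vector of p-values in `(0, 1]`.
#' @examples
#' hypergeom_pvalue(10, 3, 3, 3)  # 1 / choose(10, 3)
#' @export
hypergeom_pvalue <- function(N, N_ec, N_d, K) {
  n <- max(length(N), length(N_ec), length(N_d), length(K))
  N <- rep_len(N, n); N_ec <- rep_len(N_ec, n)
  N_d <- rep_len(N_d, n); K <- rep_len(K, n)
  bad <- K < 0 | N_ec < 0 | N_d < 0 | N_ec > N | N_d > N |
    K > pmin(N_ec, N_d) | K < N_ec + N_d - N
  if (any(bad))
    stop(sprintf("invalid co-occurrence counts: N=%d, N_ec=%d, N_d=%d, K=%d",
                 N[bad][1L], N_ec[bad][1L], N_d[bad][1L], K[bad][1L]))
  stats::phyper(K - 1, m = N_ec, n = N - N_ec, k = N_d, lower.tail = FALSE)
}

#' Bonferroni family-wise significance level
#'
#' Each source tests as many associations as it has scored candidate
#' pairs; controlling the family-wise error rate at 0.05 divides the
#' per-test level accordingly.
#'
#' @param T Number of tested associations in a source (>= 1).
#' @return `0.05 / T`.
#' @export
bonferroni_alpha <- function(T) {
  if (any(T < 1)) stop("T must be >= 1")
  0.05 / T
}

#' Attach per-source hypergeometric significance to accepted associations
#'
#' For every accepted association and every source in which both the EC
#' number and the domain have cluster support, the upper-tail
#' hypergeometric p-value of the observed joint support is computed and
#' compared against that source's Bonferroni level `0.05 / T` (strict
#' inequality), where `T` is the number of candidate pairs the source
#' contributed.  Sources where either label is absent are non-evaluable
#' (`NA`) and are excluded from the all-significant conjunction; an
#' association with no evaluable source is never all-significant.
#'
#' @param accepted data.frame from [finalize_associations()].
#' @param datasets Named list of `"assoc_dataset"` sources.
#' @param tables Named list of level-4 `"raw_scores"` tables for the same
#'   sources (their row counts fix each source's `T`).
#' @return `accepted` with added columns `p_<source>` for each source,
#'   `all_significant`, plus an `alpha` attribute (named vector of
#'   per-source levels).
#' @export
attach_significance <- function(accepted, datasets, tables) {
  nm <- names(datasets)
  stopifnot(!is.null(nm), all(nm %in% names(tables)))
  alpha <- stats::setNames(vapply(nm, function(d) bonferroni_alpha(max(1L, nrow(tables[[d]]))),
                                  numeric(1L)), nm)
  n <- nrow(accepted)
  sig_any <- rep(FALSE, n)
  nonsig <- rep(FALSE, n)
  for (d in nm) {
    ds <- datasets[[d]]
    N <- length(ds$cid_universe)
    n_ec <- lengths(ds$ec_to_cids)[accepted$ec]
    n_pf <- lengths(ds$pfam_to_cids)[accepted$pfam]
    p <- rep(NA_real_, n)
    ok <- !is.na(n_ec) & !is.na(n_pf) & n_ec >= 1L & n_pf >= 1L
    if (any(ok)) {
      K <- mapply(function(e, f) length(intersect(ds$ec_to_cids[[e]],
                                                  ds$pfam_to_cids[[f]])),
                  accepted$ec[ok], accepted$pfam[ok], USE.NAMES = FALSE)
      p[ok] <- hypergeom_pvalue(N, n_ec[ok], n_pf[ok], K)
      sig_any <- sig_any | (ok & !is.na(p) & p < alpha[[d]])
      nonsig <- nonsig | (ok & !is.na(p) & p >= alpha[[d]])
    }
    accepted[[paste0("p_", d)]] <- p
  }
  accepted$all_significant <- sig_any & !nonsig
  attr(accepted, "alpha") <- alpha
  accepted
}

#' Assign Gold / Silver / Bronze quality classes
#'
#' Gold: confidence score at or above the 4-digit threshold and all
#' evaluable p-values significant.  Silver: above the threshold with at
#' least one non-significant p-value, or rescued through the 3-digit
#' hierarchy with all p-values significant.  Bronze: everything else
#' (rescued associations lacking full significance).  The three classes
#' partition the accepted set.
#'
#' @param accepted data.frame from [attach_significance()] (needs columns
#'   `cs`, `provenance`, `all_significant`).
#' @param threshold4 The 4-digit acceptance threshold.
#' @return `accepted` with an added `quality` column.
#' @export
classify_quality <- function(accepted, threshold4) {
  if (!all(c("provenance", "all_significant") %in% names(accepted)))
    stop("accepted associations must carry 'provenance' and 'all_significant'")
  above <- accepted$cs >= threshold4
  if (any(!above & accepted$provenance == "direct4"))
    stop("direct4 association below threshold: inconsistent input")
  quality <- ifelse(above & accepted$all_significant, "Gold",
             ifelse(above | accepted$all_significant, "Silver", "Bronze"))
  accepted$quality <- quality
  accepted
}

#' Write the final classified association table
#'
#' TSV dialect: `ec`, `pfam`, `CS`, `provenance`, one p-value column per
#' source (scientific notation, 3 significant digits, `NA` when
#' non-evaluable), `quality`.
#'
#' @param accepted Classified associations ([classify_quality()]).
#' @param path Output path.
#' @export
write_results_table <- function(accepted, path) {
  pcols <- grep("^p_", names(accepted), value = TRUE)
  out <- data.frame(ec = accepted$ec, pfam = accepted$pfam,
                    CS = sprintf("%.6f", accepted$cs),
                    provenance = accepted$provenance,
                    stringsAsFactors = FALSE)
  for (pc in pcols)
    out[[pc]] <- ifelse(is.na(accepted[[pc]]), "NA",
                        sprintf("%.3g", accepted[[pc]]))
  out$quality <- accepted$quality
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(accepted)
}
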