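# Shared fixtures and independent oracles for the test suite.

# Build an assoc_dataset straight from label -> CID set lists, using the
# identity cluster map (every CID its own entity).
toy_dataset <- function(ec_map, pfam_map, name = "toy") {
  to_pairs <- function(m) {
    data.frame(entity_id = unlist(m, use.names = FALSE) %||% character(),
               label = rep(names(m), lengths(m)) %||% character(),
               stringsAsFactors = FALSE)
  }
  `%||%` <- function(x, y) if (is.null(x)) y else x
  build_dataset(to_pairs(ec_map), to_pairs(pfam_map), cluster_map = NULL,
                name = name)
}

# Random small annotation dataset: each label gets a random CID subset.
random_dataset <- function(n_ec, n_pfam, n_cid, name = "rnd") {
  cids <- sprintf("c%03d", seq_len(n_cid))
  ecs <- sprintf("%d.%d.%d.%d", sample(1:6, n_ec, TRUE),
                 sample(1:20, n_ec, TRUE), sample(1:20, n_ec, TRUE),
                 seq_len(n_ec))
  pfs <- sprintf("PF%05d", sample.int(99999L, n_pfam))
  ec_map <- stats::setNames(
    lapply(seq_len(n_ec), function(i) sample(cids, sample.int(max(1L, n_cid %/% 4), 1L))),
    ecs)
  pf_map <- stats::setNames(
    lapply(seq_len(n_pfam), function(i) sample(cids, sample.int(max(1L, n_cid %/% 4), 1L))),
    pfs)
  toy_dataset(ec_map, pf_map, name = name)
}

# Trapezoidal ROC area with midrank tie handling, via pROC (independent
# of the package's Mann-Whitney implementation).
trapezoid_auc <- function(pos_scores, bg_scores) {
  r <- pROC::roc(response = c(rep(1, length(pos_scores)), rep(0, length(bg_scores))),
                 predictor = c(pos_scores, bg_scores),
                 direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

# Exhaustive-enumeration oracle for the hypergeometric upper tail:
# enumerate every N_d-subset of 1..N and count those whose overlap with
# the first N_ec elements is >= K.
enum_hyper_tail <- function(N, N_ec, N_d, K) {
  if (N_d == 0L) return(as.numeric(K <= 0))
  subsets <- utils::combn(N, N_d)
  hits <- colSums(subsets <= N_ec)
  mean(hits >= K)
}

# Brute-force obligate-tuple oracle: enumerate all 2..max_arity subsets
# of each EC's accepted domains and apply the rejection and support rules
# literally.
brute_obligate <- function(datasets, accepted, max_arity = 4L) {
  out <- list()
  by_ec <- split(accepted$pfam, accepted$ec)
  for (ec in names(by_ec)) {
    domains <- sort(unique(by_ec[[ec]]))
    if (length(domains) < 2L) next
    for (arity in 2L:min(max_arity, length(domains))) {
      for (tuple in utils::combn(domains, arity, simplify = FALSE)) {
        rejected <- FALSE
        supports <- c()
        for (d in names(datasets)) {
          ds <- datasets[[d]]
          ec_cids <- ds$ec_to_cids[[ec]]
          if (is.null(ec_cids) || length(ec_cids) == 0L) {
            supports[d] <- NA_real_
            next
          }
          n_all <- 0L
          for (cid in ec_cids) {
            n_in <- sum(vapply(tuple, function(p) cid %in% ds$pfam_to_cids[[p]],
                               logical(1L)))
            if (n_in > 0L && n_in < arity) rejected <- TRUE
            if (n_in == arity) n_all <- n_all + 1L
          }
          supports[d] <- n_all / length(ec_cids)
        }
        if (!rejected && any(!is.na(supports) & supports == 1))
          out[[length(out) + 1L]] <- list(ec = ec, domains = paste(tuple, collapse = ";"))
      }
    }
  }
  if (length(out) == 0L) return(character())
  sort(vapply(out, function(r) paste(r$ec, r$domains), character(1L)))
}

# The default synthetic world and its calibrated pipeline are shared by
# several test files; compute them once per test run.
.world_cache <- new.env(parent = emptyenv())

default_world <- function() {
  if (is.null(.world_cache$world))
    .world_cache$world <- generate_world(world_spec())
  .world_cache$world
}

default_result <- function() {
  if (is.null(.world_cache$result)) {
    w <- default_world()
    .world_cache$result <- run_pipeline(w$datasets, w$positives, seed = 1515L,
                                        pfam_names = w$pfam_names)
  }
  .world_cache$result
}
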