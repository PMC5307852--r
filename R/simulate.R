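#' Specification of a synthetic annotation world
#'
#' Describes a four-source world of protein chain/sequence clusters with
#' planted EC-Pfam ground truth, used to validate the whole pipeline
#' without external downloads.  Enzyme families are drawn from five
#' architectural archetypes: `one_to_one` (one domain, one function),
#' `two_domain` (two domains on one chain, each with its own function,
#' also observed as single-domain chains), `multi_ec` (one domain
#' carrying two functions), `cofactor` (a base domain with one function
#' plus an interface/co-factor partner jointly providing a second
#' function, yielding obligate domain pairs by construction) and
#' `hierarchy` (several sibling enzymes, same domain, differing only in
#' the serial digit; some families additionally carry a sparsely
#' annotated sibling that only the 3-digit rescue can recover).
#' Accessory domains ride on many chains without providing any function,
#' and a pool of enzyme-free chains carries decoy domains.
#'
#' Per-source annotation noise (spurious and dropped annotations) is the
#' base `noise` rate scaled by `noise_mult`, emulating sources of very
#' different reliability: a curated sequence source with no noise, a
#' structure source and a rule-annotated source with the base rate, and
#' an uncurated bulk source with three times the base rate.
#'
#' @param n_ec Number of 4-digit EC numbers (default 200).
#' @param n_pfam Number of Pfam accessions (default 300).
#' @param n_cid Named vector of cluster counts per source (default sums
#'   to 5000).
#' @param archetypes Named fractions of EC numbers allocated to each
#'   archetype; leftovers go to `one_to_one`.
#' @param branching Children per 3-digit parent in `hierarchy` families.
#' @param n_rescue Number of hierarchy families given a sparsely
#'   annotated ("rare") sibling.
#' @param n_accessory Number of accessory domains.
#' @param noise Base annotation noise probability (default 0.05).
#' @param noise_mult Per-source noise multipliers.
#' @param nonenzymatic_fraction Fraction of each source's clusters that
#'   carry domains but no enzyme annotation.
#' @param rule_coverage Fraction of families annotated by the rule-based
#'   source (a curated rule must exist before that source can annotate a
#'   family).
#' @param ref_fraction Fraction of the (non-rare) ground truth sampled as
#'   the curated positive reference.
#' @param redundancy Mean number of entities per cluster (>= 1).
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return A list of class `"world_spec"`.
#' @export
world_spec <- function(n_ec = 200L, n_pfam = 300L,
                       n_cid = c(SIFTS = 500L, SwissProt = 1000L,
                                 TrEMBL = 2250L, UniRule = 1250L),
                       archetypes = c(one_to_one = 0.45, two_domain = 0.14,
                                      multi_ec = 0.12, cofactor = 0.12,
                                      hierarchy = 0.17),
                       branching = 3L, n_rescue = 4L, n_accessory = 6L,
                       noise = 0.05,
                       noise_mult = c(SIFTS = 1, SwissProt = 0,
                                      TrEMBL = 3, UniRule = 1),
                       nonenzymatic_fraction = 0.25, rule_coverage = 0.6,
                       ref_fraction = 0.7, redundancy = 1.3, seed = 7L) {
  stopifnot(n_ec >= 1L, n_pfam >= 1L, all(n_cid >= 1L),
            all(archetypes >= 0), sum(archetypes) <= 1 + 1e-9,
            branching >= 2L, n_accessory >= 0L,
            noise >= 0, noise <= 1, all(noise_mult >= 0),
            nonenzymatic_fraction >= 0, nonenzymatic_fraction < 1,
            rule_coverage > 0, rule_coverage <= 1,
            ref_fraction > 0, ref_fraction <= 1, redundancy >= 1)
  if (is.null(names(n_cid)) || !setequal(names(n_cid), names(noise_mult)))
    stop("n_cid and noise_mult must be named consistently")
  need <- c("one_to_one", "two_domain", "multi_ec", "cofactor", "hierarchy")
  arch <- stats::setNames(rep(0, length(need)), need)
  arch[names(archetypes)] <- archetypes
  structure(list(n_ec = as.integer(n_ec), n_pfam = as.integer(n_pfam),
                 n_cid = n_cid, archetypes = arch,
                 branching = as.integer(branching),
                 n_rescue = as.integer(n_rescue),
                 n_accessory = as.integer(n_accessory),
                 noise = noise, noise_mult = noise_mult,
                 nonenzymatic_fraction = nonenzymatic_fraction,
                 rule_coverage = rule_coverage,
                 ref_fraction = ref_fraction, redundancy = redundancy,
                 seed = as.integer(seed)),
            class = "world_spec")
}

#' Generate a synthetic four-source annotation world
#'
#' Deterministically expands a [world_spec()] into entity-level EC and
#' Pfam annotation tables, entity-to-cluster maps, CID-level
#' `"assoc_dataset"` objects, a curated positive reference (a seeded
#' subsample of the planted ground truth, excluding the rare hierarchy
#' siblings that emulate under-curated enzymes), and bookkeeping of the
#' planted structures (ground truth with archetype labels, accessory
#' domains, planted obligate pairs, rare rescue children, Pfam names).
#'
#' @param spec A `"world_spec"`.
#' @return A list of class `"synthetic_world"`; see Details in the
#'   package vignette.
#' @export
generate_world <- function(spec) {
  stopifnot(inherits(spec, "world_spec"))
  sources <- names(spec$n_cid)

  # --- allocate EC numbers and domains to families -------------------------
  n_h_fam <- round(spec$archetypes[["hierarchy"]] * spec$n_ec / spec$branching)
  n_cf_fam <- round(spec$archetypes[["cofactor"]] * spec$n_ec / 2)
  n_td_fam <- round(spec$archetypes[["two_domain"]] * spec$n_ec / 2)
  n_me_fam <- round(spec$archetypes[["multi_ec"]] * spec$n_ec / 2)
  used <- n_h_fam * spec$branching + 2L * (n_cf_fam + n_td_fam + n_me_fam)
  n_11 <- spec$n_ec - used
  if (n_11 < 0L)
    stop("infeasible spec: archetype fractions allocate more EC numbers than n_ec")
  n_rescue <- min(spec$n_rescue, n_h_fam)

  needed_domains <- n_11 + 2L * n_td_fam + n_me_fam + 2L * n_cf_fam + n_h_fam
  n_decoy <- spec$n_pfam - needed_domains - spec$n_accessory
  if (n_decoy < 0L)
    stop(sprintf("infeasible spec: %d domains needed but only %d available",
                 needed_domains + spec$n_accessory, spec$n_pfam))

  parent_code <- function(idx) {
    paste((idx - 1L) %% 6L + 1L, ((idx - 1L) %/% 6L) %% 50L + 1L,
          (idx - 1L) %/% 300L + 1L, sep = ".")
  }
  pfam_acc <- sprintf("PF%05d", seq_len(spec$n_pfam))

  fam <- list()
  parent_i <- 0L
  pf_i <- 0L
  take_pf <- function(k) {
    out <- pfam_acc[pf_i + seq_len(k)]
    pf_i <<- pf_i + k
    out
  }
  add_fam <- function(type, ecs, domains, extra = list()) {
    fam[[length(fam) + 1L]] <<- c(list(id = length(fam) + 1L, type = type,
                                       ecs = ecs, domains = domains), extra)
  }
  # a share of single-domain families exists only in the curated sequence
  # source (newly curated enzymes not yet propagated to the bulk sources);
  # they give the weight calibration a reason to value the clean source
  n_sp_only <- min(n_11, round(0.12 * spec$n_ec))
  for (i in seq_len(n_11)) {
    parent_i <- parent_i + 1L
    add_fam("one_to_one", paste0(parent_code(parent_i), ".1"), take_pf(1L),
            extra = list(sp_only = i <= n_sp_only))
  }
  for (i in seq_len(n_td_fam)) {
    parent_i <- parent_i + 1L
    p1 <- parent_code(parent_i)
    parent_i <- parent_i + 1L
    p2 <- parent_code(parent_i)
    add_fam("two_domain", c(paste0(p1, ".1"), paste0(p2, ".1")), take_pf(2L))
  }
  for (i in seq_len(n_me_fam)) {
    parent_i <- parent_i + 1L
    p1 <- parent_code(parent_i)
    parent_i <- parent_i + 1L
    p2 <- parent_code(parent_i)
    add_fam("multi_ec", c(paste0(p1, ".1"), paste0(p2, ".1")), take_pf(1L))
  }
  for (i in seq_len(n_cf_fam)) {
    parent_i <- parent_i + 1L
    p1 <- parent_code(parent_i)
    parent_i <- parent_i + 1L
    p2 <- parent_code(parent_i)
    add_fam("cofactor", c(paste0(p1, ".1"), paste0(p2, ".1")), take_pf(2L))
  }
  for (i in seq_len(n_h_fam)) {
    parent_i <- parent_i + 1L
    p <- parent_code(parent_i)
    add_fam("hierarchy", paste0(p, ".", seq_len(spec$branching)), take_pf(1L),
            extra = list(rescue = i <= n_rescue))
  }
  accessory <- take_pf(spec$n_accessory)
  decoys <- take_pf(n_decoy)
  n_fam <- length(fam)

  pfam_names <- stats::setNames(sprintf("Domain family %d", seq_len(spec$n_pfam)),
                                pfam_acc)
  for (f in fam) {
    if (f$type == "cofactor") {
      pfam_names[f$domains[1L]] <- sprintf("Enzyme family %d, N-terminal domain", f$id)
      pfam_names[f$domains[2L]] <- sprintf("Enzyme family %d, C-terminal domain", f$id)
    }
  }
  if (spec$n_accessory > 0L)
    pfam_names[accessory] <- sprintf("Accessory (non-catalytic) domain %d",
                                     seq_len(spec$n_accessory))

  # --- planted ground truth ------------------------------------------------
  gt <- list()
  for (f in fam) {
    rows <- switch(f$type,
      one_to_one = data.frame(ec = f$ecs, pfam = f$domains, archetype = "one_to_one"),
      two_domain = data.frame(ec = f$ecs, pfam = f$domains, archetype = "two_domain"),
      multi_ec = data.frame(ec = f$ecs, pfam = rep(f$domains, 2L), archetype = "multi_ec"),
      cofactor = data.frame(ec = c(f$ecs[1L], f$ecs[2L], f$ecs[2L]),
                            pfam = c(f$domains[1L], f$domains[1L], f$domains[2L]),
                            archetype = "cofactor"),
      hierarchy = data.frame(ec = f$ecs, pfam = rep(f$domains, length(f$ecs)),
                             archetype = ifelse(isTRUE(f$rescue) &
                                                  seq_along(f$ecs) == length(f$ecs),
                                                "hierarchy_rare", "hierarchy")))
    gt[[length(gt) + 1L]] <- rows
  }
  ground_truth <- do.call(rbind, gt)
  ground_truth <- ground_truth[order(ground_truth$ec, ground_truth$pfam), ]
  rownames(ground_truth) <- NULL

  ec_pool <- sort(unique(ground_truth$ec))
  catalytic_pool <- sort(unique(ground_truth$pfam))

  with_local_seed(spec$seed, {
    abundance <- stats::rgamma(n_fam, shape = 2, rate = 1) + 0.3
    # the rule-based source only annotates families for which a curated
    # rule exists; the other sources cover everything
    rule_covered <- sort(sample.int(n_fam, round(spec$rule_coverage * n_fam)))

    entity_tables <- list()
    cluster_maps <- list()
    datasets <- list()
    obligate_planted <- list()
    rescue_children <- list()

    for (src in sources) {
      n_total <- spec$n_cid[[src]]
      p_noise <- spec$noise * spec$noise_mult[[src]]
      n_nonenz <- round(n_total * spec$nonenzymatic_fraction)
      # TrEMBL-style dilution chains for rescue-family domains come out of
      # the enzyme-free budget
      n_dilution <- if (src == "TrEMBL") min(n_nonenz, 60L * n_rescue) else 0L
      n_enz <- n_total - n_nonenz

      chain_ecs <- list()
      chain_pfs <- list()
      chain_fam <- integer()
      add_chain <- function(ecs, pfs, fam_id = NA_integer_) {
        chain_ecs[[length(chain_ecs) + 1L]] <<- ecs
        chain_pfs[[length(chain_pfs) + 1L]] <<- pfs
        chain_fam[length(chain_fam) + 1L] <<- fam_id
      }

      # enzymatic chains: every covered family is guaranteed one chain in
      # the sequence sources; the structure source samples freely
      # (structures are sparse)
      ab <- abundance
      covered <- seq_len(n_fam)
      if (src == "UniRule") {
        covered <- rule_covered
        ab[-covered] <- 0
      }
      if (src != "SwissProt") {
        sp_only_idx <- which(vapply(fam, function(f) isTRUE(f$sp_only), logical(1L)))
        covered <- setdiff(covered, sp_only_idx)
        ab[sp_only_idx] <- 0
      }
      if (length(covered) == 0L) {
        counts <- integer(n_fam)
      } else if (src == "SIFTS" || n_enz < length(covered)) {
        counts <- as.vector(stats::rmultinom(1L, n_enz, ab))
      } else {
        counts <- as.vector(stats::rmultinom(1L, n_enz - length(covered), ab))
        counts[covered] <- counts[covered] + 1L
      }
      for (fi in seq_len(n_fam)) {
        f <- fam[[fi]]
        m <- counts[fi]
        if (m == 0L) next
        if (f$type == "one_to_one") {
          for (j in seq_len(m)) add_chain(f$ecs, f$domains, fi)
        } else if (f$type == "two_domain") {
          kind <- sample(c("both", "a", "b"), m, replace = TRUE,
                         prob = c(0.5, 0.25, 0.25))
          for (j in seq_len(m)) add_chain(
            switch(kind[j], both = f$ecs, a = f$ecs[1L], b = f$ecs[2L]),
            switch(kind[j], both = f$domains, a = f$domains[1L], b = f$domains[2L]),
            fi)
        } else if (f$type == "multi_ec") {
          kind <- sample(c("both", "a", "b"), m, replace = TRUE,
                         prob = c(0.6, 0.2, 0.2))
          for (j in seq_len(m)) add_chain(
            switch(kind[j], both = f$ecs, a = f$ecs[1L], b = f$ecs[2L]),
            f$domains, fi)
        } else if (f$type == "cofactor") {
          kind <- sample(c("full", "base"), m, replace = TRUE, prob = c(0.5, 0.5))
          for (j in seq_len(m)) {
            if (kind[j] == "full") add_chain(f$ecs, f$domains, fi)
            else add_chain(f$ecs[1L], f$domains[1L], fi)
          }
        } else { # hierarchy
          kids <- if (isTRUE(f$rescue)) f$ecs[-length(f$ecs)] else f$ecs
          pick <- sample(kids, m, replace = TRUE)
          for (j in seq_len(m)) add_chain(pick[j], f$domains, fi)
        }
      }
      # the rare hierarchy sibling: a single bulk-source chain
      if (src == "TrEMBL" && n_rescue > 0L) {
        for (fi in seq_len(n_fam)) {
          f <- fam[[fi]]
          if (f$type == "hierarchy" && isTRUE(f$rescue))
            add_chain(f$ecs[length(f$ecs)], f$domains, fi)
        }
      }
      n_enz_real <- length(chain_ecs)

      # dilution chains: rescue-family domains on enzyme-free bulk chains
      if (n_dilution > 0L) {
        rescue_doms <- vapply(fam[vapply(fam, function(f)
          f$type == "hierarchy" && isTRUE(f$rescue), logical(1L))],
          function(f) f$domains, character(1L))
        for (j in seq_len(n_dilution))
          add_chain(character(), rescue_doms[(j - 1L) %% length(rescue_doms) + 1L])
      }
      # remaining enzyme-free chains: 1-2 decoy domains
      for (j in seq_len(n_nonenz - n_dilution)) {
        k <- sample(1:2, 1L)
        add_chain(character(), sample(decoys, min(k, length(decoys))))
      }

      # accessory domains: common on enzyme-free chains everywhere; in the
      # uncurated bulk source they additionally ride on widespread enzyme
      # families, but never on every chain of a family (an accessory
      # domain is precisely one the catalytic activity does not require,
      # so witness chains without it always exist)
      if (spec$n_accessory > 0L) {
        for (ci in seq_along(chain_pfs)) {
          if (length(chain_ecs[[ci]]) > 0L) next
          att <- accessory[stats::runif(spec$n_accessory) < 0.5]
          if (length(att)) chain_pfs[[ci]] <- c(chain_pfs[[ci]], att)
        }
        if (src == "TrEMBL") {
          big_fams <- which(counts >= 10L)
          for (a in accessory) {
            host <- big_fams[stats::runif(length(big_fams)) < 0.5]
            for (fi in host) {
              idx <- which(chain_fam == fi)
              ci <- idx[sample.int(length(idx), 1L)]
              chain_pfs[[ci]] <- unique(c(chain_pfs[[ci]], a))
            }
          }
        }
      }

      # noise draws copy annotations already established in the source,
      # weighted by how common they are there: mis-transfer propagates
      # familiar annotations, it does not invent unseen ones
      ec_freq <- table(unlist(chain_ecs[seq_len(n_enz_real)], use.names = FALSE))
      pf_freq <- table(unlist(chain_pfs[seq_len(n_enz_real)], use.names = FALSE))
      pf_freq <- pf_freq[names(pf_freq) %in% catalytic_pool]
      draw_common <- function(freq, n) {
        if (length(freq) == 0L || n == 0L) return(character())
        sample(names(freq), min(n, length(freq)), prob = as.numeric(freq))
      }

      # systematic annotation-transfer errors: with probability p_noise a
      # family acquires one wrong EC number propagated to all its chains
      # (the dominant error mode of uncurated and rule-based sources)
      if (p_noise > 0 && n_enz_real > 0L) {
        for (fi in seq_len(n_fam)) {
          if (stats::runif(1L) >= p_noise) next
          idx <- which(chain_fam == fi)
          if (length(idx) == 0L) next
          wrong <- draw_common(ec_freq, 1L)
          for (ci in idx)
            chain_ecs[[ci]] <- unique(c(chain_ecs[[ci]], wrong))
        }
      }

      # annotation noise on enzymatic chains: drops and spurious transfers
      if (p_noise > 0 && n_enz_real > 0L) {
        for (ci in seq_len(n_enz_real)) {
          ecs <- chain_ecs[[ci]]
          pfs <- chain_pfs[[ci]]
          ecs <- ecs[stats::runif(length(ecs)) >= p_noise]
          pfs <- pfs[stats::runif(length(pfs)) >= p_noise]
          ecs <- unique(c(ecs, draw_common(ec_freq, stats::rpois(1L, 3 * p_noise))))
          pfs <- unique(c(pfs, draw_common(pf_freq, stats::rpois(1L, 3 * p_noise))))
          chain_ecs[[ci]] <- ecs
          chain_pfs[[ci]] <- pfs
        }
      }

      # entities per chain (100%-identity cluster members)
      n_chain <- length(chain_ecs)
      cid <- sprintf("%s_c%05d", tolower(src), seq_len(n_chain))
      n_ent <- 1L + stats::rpois(n_chain, spec$redundancy - 1)
      ent_cid <- rep(cid, n_ent)
      ent_id <- sprintf("%s_%d", ent_cid, unlist(lapply(n_ent, seq_len)))
      cmap <- stats::setNames(ent_cid, ent_id)

      ents_by_chain <- split(ent_id, factor(ent_cid, levels = cid))
      rep_ann <- function(ann) {
        # each entity of a cluster carries the cluster's annotations
        per_chain <- lengths(ann)
        ids <- vector("list", n_chain)
        labs <- vector("list", n_chain)
        for (ci in seq_len(n_chain)) {
          if (per_chain[ci] == 0L) next
          ents <- ents_by_chain[[ci]]
          ids[[ci]] <- rep(ents, each = per_chain[ci])
          labs[[ci]] <- rep(ann[[ci]], length(ents))
        }
        data.frame(entity_id = unlist(ids, use.names = FALSE) %||% character(),
                   label = unlist(labs, use.names = FALSE) %||% character(),
                   stringsAsFactors = FALSE)
      }
      ec_tab <- rep_ann(chain_ecs)
      pf_tab <- rep_ann(chain_pfs)

      entity_tables[[src]] <- list(ec = ec_tab, pfam = pf_tab)
      cluster_maps[[src]] <- cmap
      datasets[[src]] <- build_dataset(ec_tab, pf_tab, cmap, name = src)
    }

    for (f in fam) {
      if (f$type == "cofactor")
        obligate_planted[[length(obligate_planted) + 1L]] <-
          data.frame(ec = f$ecs[2L], d1 = f$domains[1L], d2 = f$domains[2L],
                     stringsAsFactors = FALSE)
      if (f$type == "hierarchy" && isTRUE(f$rescue))
        rescue_children[[length(rescue_children) + 1L]] <-
          data.frame(ec = f$ecs[length(f$ecs)], pfam = f$domains,
                     stringsAsFactors = FALSE)
    }

    eligible <- ground_truth[ground_truth$archetype != "hierarchy_rare", ]
    n_ref <- max(1L, round(nrow(eligible) * spec$ref_fraction))
    positives <- eligible[sort(sample.int(nrow(eligible), n_ref)),
                          c("ec", "pfam"), drop = FALSE]
    rownames(positives) <- NULL

    structure(list(spec = spec, datasets = datasets,
                   entity_tables = entity_tables, cluster_maps = cluster_maps,
                   positives = positives, ground_truth = ground_truth,
                   pfam_names = pfam_names, accessory = accessory,
                   decoys = decoys,
                   obligate_planted = if (length(obligate_planted))
                     do.call(rbind, obligate_planted) else NULL,
                   rescue_children = if (length(rescue_children))
                     do.call(rbind, rescue_children) else NULL),
              class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world: %d ECs, %d Pfams, %d planted pairs, seed %d>\n",
              x$spec$n_ec, x$spec$n_pfam, nrow(x$ground_truth), x$spec$seed))
  for (d in x$datasets) print(d)
  invisible(x)
}

#' Write a synthetic world as its TSV input files
#'
#' Produces, per source, the entity-level EC and Pfam annotation tables
#' and the entity-to-cluster map, plus `reference_positives.tsv`,
#' `ground_truth.tsv` and `pfam_names.tsv`.  Output is deterministic:
#' identical specs give byte-identical files.
#'
#' @param world A `"synthetic_world"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    files <<- c(files, path)
  }
  for (src in names(world$entity_tables)) {
    emit(world$entity_tables[[src]]$ec, sprintf("%s_ec.tsv", src))
    emit(world$entity_tables[[src]]$pfam, sprintf("%s_pfam.tsv", src))
    cm <- world$cluster_maps[[src]]
    emit(data.frame(entity_id = names(cm), cid = unname(cm)),
         sprintf("%s_clusters.tsv", src))
  }
  emit(world$positives, "reference_positives.tsv")
  emit(world$ground_truth, "ground_truth.tsv")
  emit(data.frame(accession = names(world$pfam_names),
                  name = unname(world$pfam_names)), "pfam_names.tsv")
  invisible(files)
}
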