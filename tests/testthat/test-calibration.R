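pairs_df <- function(ec, pfam) data.frame(ec = ec, pfam = pfam,
                                          stringsAsFactors = FALSE)
scored_df <- function(ec, pfam, cs) data.frame(ec = ec, pfam = pfam, cs = cs,
                                               stringsAsFactors = FALSE)

test_that("ROC area follows the Mann-Whitney identity", {
  sc <- scored_df(sprintf("1.1.1.%d", 1:4), rep("PF00001", 4),
                  c(0.9, 0.4, 0.6, 0.1))
  pos <- pairs_df(c("1.1.1.1", "1.1.1.2"), rep("PF00001", 2))
  bg <- pairs_df(c("1.1.1.3", "1.1.1.4"), rep("PF00001", 2))
  # concordant pairs: 3 of 4
  expect_equal(roc_auc(sc, pos, bg), 0.75)

  # perfect separation and pure ties
  sc2 <- scored_df(sprintf("2.1.1.%d", 1:4), rep("PF00001", 4), c(1, 1, 0, 0))
  expect_equal(roc_auc(sc2, pairs_df(sprintf("2.1.1.%d", 1:2), rep("PF00001", 2)),
                       pairs_df(sprintf("2.1.1.%d", 3:4), rep("PF00001", 2))), 1)
  sc3 <- scored_df(sprintf("2.1.1.%d", 1:4), rep("PF00001", 4), rep(0.5, 4))
  expect_equal(roc_auc(sc3, pairs_df(sprintf("2.1.1.%d", 1:2), rep("PF00001", 2)),
                       pairs_df(sprintf("2.1.1.%d", 3:4), rep("PF00001", 2))), 0.5)

  # positives missing from the scored universe score zero
  expect_equal(roc_auc(sc2, pairs_df("6.1.1.1", "PF09999"),
                       pairs_df(sprintf("2.1.1.%d", 1:2), rep("PF00001", 2))), 0)
  expect_error(roc_auc(sc2, pairs_df("2.1.1.1", "PF00001"),
                       pairs_df("2.1.1.1", "PF00001")), "disjoint")
})

test_that("Mann-Whitney AUC equals trapezoidal ROC area on random scores", {
  skip_if_not_installed("pROC")
  set.seed(271)
  for (rep in 1:200) {
    np <- sample(2:20, 1L); nb <- sample(2:30, 1L)
    # mix of continuous and heavily tied score sets
    pool <- if (rep %% 2) runif(np + nb) else sample(seq(0, 1, 0.1), np + nb, TRUE)
    ours <- ecpfam:::auc_mann_whitney(pool[1:np], pool[-(1:np)])
    expect_equal(ours, trapezoid_auc(pool[1:np], pool[-(1:np)]), tolerance = 1e-12)
  }
})

test_that("threshold scan maximises F over the grid with smallest-t ties", {
  # separable case: any t in (0, 0.9] gives F = 1; smallest grid value wins
  lab <- data.frame(ec = sprintf("1.1.1.%d", 1:4), pfam = rep("PF00001", 4),
                    label = c("pos", "pos", "neg", "neg"))
  sc <- scored_df(sprintf("1.1.1.%d", 1:2), rep("PF00001", 2), c(0.9, 0.9))
  res <- scan_threshold(sc, lab)
  expect_equal(res$threshold, 0.01)
  expect_equal(res$f_measure, 1)

  # worked six-pair fixture: best F first reached at t = 0.03
  lab6 <- data.frame(ec = sprintf("2.1.1.%d", 1:6), pfam = rep("PF00001", 6),
                     label = c(rep("pos", 3), rep("neg", 3)))
  sc6 <- scored_df(sprintf("2.1.1.%d", 1:6), rep("PF00001", 6),
                   c(0.5, 0.3, 0.05, 0.2, 0.02, 0.01))
  res6 <- scan_threshold(sc6, lab6)
  expect_equal(res6$threshold, 0.03)
  # brute force over every grid value confirms optimality
  briefs <- vapply(seq(0, 1, 0.01), function(t)
    evaluate_threshold(sc6, lab6, t)$f_measure, numeric(1))
  expect_equal(res6$f_measure, max(briefs))
  expect_true(all(res6$grid$f_measure == briefs))

  expect_error(scan_threshold(sc6, lab6[lab6$label == "pos", ]), "negative")
})

test_that("confusion statistics follow the recall/precision identities", {
  lab <- data.frame(ec = sprintf("3.1.1.%d", 1:20), pfam = rep("PF00001", 20),
                    label = rep(c("pos", "neg"), c(10, 10)))
  sc <- scored_df(lab$ec, lab$pfam, c(rep(0.8, 9), 0.0, 0.8, rep(0, 9)))
  ev <- evaluate_threshold(sc, lab, 0.5)
  expect_equal(unname(ev$counts), c(9, 1, 9, 1))  # TP FP TN FN
  expect_equal(ev$recall, 0.9)
  expect_equal(ev$precision, 0.9)
  expect_equal(ev$f_measure, 0.9)
  # threshold 0 accepts everything; precision is the class prior
  ev0 <- evaluate_threshold(sc, lab, 0)
  expect_equal(ev0$recall, 1)
  expect_equal(ev0$precision, 0.5)
  # a threshold above every score accepts nothing
  ev1 <- evaluate_threshold(sc, lab, 1 + 1e-9)
  expect_equal(ev1$recall, 0)
  expect_equal(unname(ev1$counts["TP"]), 0)
  # F-measure is consistent with P and R wherever both are defined
  expect_equal(ev$f_measure, 2 * ev$recall * ev$precision / (ev$recall + ev$precision),
               tolerance = 1e-12)
})

test_that("weight grid search recovers planted signal and breaks ties", {
  # one table only: all grid weights give the same ranking; smallest wins
  set.seed(5)
  ds <- random_dataset(10, 10, 60)
  t1 <- raw_scores(ds)
  pos <- t1[t1$score > stats::median(t1$score), c("ec", "pfam")][1:3, ]
  bg_keys <- setdiff(paste(t1$ec, t1$pfam, sep = "\t"),
                     paste(pos$ec, pos$pfam, sep = "\t"))
  bg <- do.call(rbind, lapply(strsplit(bg_keys, "\t"), function(p)
    pairs_df(p[1], p[2])))
  one <- grid_search_weights(list(only = t1), pos, bg)
  expect_equal(unname(one$weights), 0.1)

  # two identical tables: every ranking identical; lexicographic tie-break
  two <- grid_search_weights(list(A = t1, B = t1), pos, bg)
  expect_equal(unname(two$weights), c(0.0, 0.1))
  expect_equal(two$grid_size, 120L)

  # planted signal: table A scores truth at 1, B is seeded noise
  set.seed(99)
  ecs <- sprintf("1.1.1.%d", 1:12)
  pfs <- sprintf("PF%05d", 1:12)
  truth <- pairs_df(ecs, pfs)
  mk <- function(name, ec, pf, s)
    structure(data.frame(ec = ec, pfam = pf, score = s, stringsAsFactors = FALSE),
              dataset = name, class = c("raw_scores", "data.frame"))
  grid_pairs <- expand.grid(ec = ecs, pfam = pfs, stringsAsFactors = FALSE)
  tA <- mk("A", truth$ec, truth$pfam, rep(1, 12))
  tB <- mk("B", grid_pairs$ec, grid_pairs$pfam, runif(nrow(grid_pairs)))
  bgAB <- grid_pairs[!(paste(grid_pairs$ec, grid_pairs$pfam) %in%
                         paste(truth$ec, truth$pfam)), ]
  gs <- grid_search_weights(list(A = tA, B = tB), truth, bgAB)
  expect_gte(gs$weights[["A"]], gs$weights[["B"]])
  expect_gte(gs$auc, 0.99)
})

test_that("negative sampling rejects genuine candidates and is seed-stable", {
  ds <- toy_dataset(list(`1.1.1.1` = "c1", `2.2.2.2` = "c2", `3.3.3.3` = c("c1", "c3")),
                    list(PF00001 = "c1", PF00002 = "c2", PF00003 = "c3"),
                    name = "SIFTS")
  datasets <- list(SIFTS = ds)
  cand <- raw_scores(ds)
  cand_key <- paste(cand$ec, cand$pfam, sep = "\t")
  # 9-pair space, 4 genuine candidates -> 5 negatives reachable
  neg <- generate_negatives(datasets, 5L, seed = 3L)
  expect_equal(nrow(neg), 5L)
  expect_length(intersect(paste(neg$ec, neg$pfam, sep = "\t"), cand_key), 0L)

  expect_equal(generate_negatives(datasets, 3L, seed = 8L),
               generate_negatives(datasets, 3L, seed = 8L))
  expect_equal(nrow(generate_negatives(datasets, 0L, seed = 1L)), 0L)
  expect_error(generate_negatives(datasets, 6L, seed = 1L, max_rounds = 30L),
               "only generate")
  # positives are rejected too
  negp <- generate_negatives(datasets, 4L, seed = 2L,
                             positives = pairs_df("1.1.1.1", "PF00002"))
  expect_false("1.1.1.1\tPF00002" %in% paste(negp$ec, negp$pfam, sep = "\t"))
})

test_that("reference splits are pure functions of contents, fraction and seed", {
  pos <- pairs_df(sprintf("1.1.1.%d", 1:10), sprintf("PF%05d", 1:10))
  neg <- pairs_df(sprintf("2.1.1.%d", 1:10), sprintf("PF%05d", 11:20))
  r1 <- reference_set(pos, neg, 0.5, seed = 77L)
  r2 <- reference_set(pos[sample.int(10), ], neg, 0.5, seed = 77L)  # reordered
  expect_identical(split_reference(r1), split_reference(r2))
  s <- split_reference(r1)
  expect_equal(nrow(s$train), 10L)
  expect_equal(sum(s$train$label == "pos"), 5L)
  expect_false(identical(split_reference(r1),
                         split_reference(reference_set(pos, neg, 0.5, seed = 78L))))
  expect_error(reference_set(pos, pos, 0.5, 1L), "disjoint")
})
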