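test_that("cosine scores match hand-computed supports", {
  ds <- toy_dataset(
    list(`1.1.1.1` = "c1", `2.2.2.2` = c("c1", "c2"), `3.3.3.3` = c("c1", "c2", "c3")),
    list(PF00001 = "c1", PF00002 = "c4"))
  t <- raw_scores(ds)
  key <- paste(t$ec, t$pfam)
  # identical singleton support
  expect_equal(t$score[key == "1.1.1.1 PF00001"], 1.0)
  # |A|=2, |B|=1, K=1 -> 1/sqrt(2)
  expect_equal(t$score[key == "2.2.2.2 PF00001"], 1 / sqrt(2))
  # empty intersection pairs are absent
  expect_false("3.3.3.3 PF00002" %in% key)
  expect_true(all(t$score > 0 & t$score <= 1))
})

test_that("the set-arithmetic oracle computes plain cosines", {
  expect_equal(cosine_oracle(letters[1:5], letters[1:5]), 1.0)
  expect_equal(cosine_oracle(letters[1:4], letters[c(1:3, 10:15)]), 3 / 6)
  expect_equal(cosine_oracle("a", "b"), 0.0)
  expect_error(cosine_oracle(character(), "a"), "non-empty")
})

test_that("matrix scores agree with the set oracle on random datasets", {
  set.seed(101)
  for (rep in 1:20) {
    ds <- random_dataset(sample(2:30, 1L), sample(2:30, 1L), sample(10:200, 1L))
    t <- raw_scores(ds)
    key <- paste(t$ec, t$pfam, sep = "\t")
    for (i in seq_len(nrow(t))) {
      expect_equal(t$score[i],
                   cosine_oracle(ds$ec_to_cids[[t$ec[i]]],
                                 ds$pfam_to_cids[[t$pfam[i]]]),
                   tolerance = 1e-12)
    }
    # absent pairs have empty intersections
    for (ec in names(ds$ec_to_cids)) {
      for (pf in names(ds$pfam_to_cids)) {
        if (!(paste(ec, pf, sep = "\t") %in% key))
          expect_length(intersect(ds$ec_to_cids[[ec]], ds$pfam_to_cids[[pf]]), 0L)
      }
    }
  }
})

test_that("3-digit scoring pools sibling enzymes before normalisation", {
  ds <- toy_dataset(list(`2.7.1.1` = c("c1", "c2"), `2.7.1.2` = c("c2", "c3"),
                         `3.1.1.1` = "c4"),
                    list(PF00001 = c("c1", "c2", "c3"), PF00002 = "c4"))
  t3 <- raw_scores(ds, ec_level = 3L)
  expect_setequal(t3$ec, c("2.7.1", "3.1.1"))
  # pooled support: CIDs(2.7.1) = {c1,c2,c3}
  expect_equal(t3$score[t3$ec == "2.7.1" & t3$pfam == "PF00001"], 1.0)
  # truncation merges keys: candidate universe no larger than at 4 digits
  expect_lte(nrow(t3), nrow(raw_scores(ds)))
})

test_that("weighted combination follows the confidence-score formula", {
  mk <- function(name, ec, pf, s) {
    structure(data.frame(ec = ec, pfam = pf, score = s, stringsAsFactors = FALSE),
              dataset = name, class = c("raw_scores", "data.frame"))
  }
  tables <- list(SIFTS = mk("SIFTS", character(), character(), numeric()),
                 SwissProt = mk("SwissProt", "1.1.1.1", "PF00001", 0.9),
                 TrEMBL = mk("TrEMBL", character(), character(), numeric()),
                 UniRule = mk("UniRule", character(), character(), numeric()))
  w <- c(SIFTS = 0.1, SwissProt = 1.0, TrEMBL = 0.1, UniRule = 0.6)
  sc <- combine_scores(tables, w)
  # (0.1*0 + 1.0*0.9 + 0.1*0 + 0.6*0) / 1.8
  expect_equal(sc$cs, 0.9 / 1.8)
  expect_equal(sc$S_SwissProt, 0.9)
  expect_equal(sc$S_TrEMBL, 0)

  # single-source degeneracy: CS equals the raw score at any weight
  ds <- random_dataset(10, 10, 50)
  t1 <- raw_scores(ds)
  for (wt in c(0.2, 1)) {
    sc1 <- combine_scores(list(only = t1), c(only = wt))
    expect_equal(sc1$cs[order(sc1$ec, sc1$pfam)], t1$score, tolerance = 1e-12)
  }

  # constant scores: CS = s under any valid weighting
  tt <- list(A = mk("A", "1.1.1.1", "PF00001", 0.37),
             B = mk("B", "1.1.1.1", "PF00001", 0.37))
  expect_equal(combine_scores(tt, c(A = 0.3, B = 0.9))$cs, 0.37)

  expect_error(combine_scores(tt, c(A = 0, B = 0)), "positive")
  expect_error(combine_scores(tt, c(A = 1)), "no weight")
})

test_that("combined scores are bounded and monotone in each raw score", {
  set.seed(7)
  mk <- function(name, s) {
    structure(data.frame(ec = "1.1.1.1", pfam = "PF00001", score = s,
                         stringsAsFactors = FALSE),
              dataset = name, class = c("raw_scores", "data.frame"))
  }
  w <- c(A = 0.4, B = 0.8)
  for (rep in 1:25) {
    s <- runif(2)
    cs <- combine_scores(list(A = mk("A", s[1]), B = mk("B", s[2])), w)$cs
    expect_gte(cs, 0); expect_lte(cs, 1)
    bump <- combine_scores(list(A = mk("A", min(1, s[1] + 0.1)), B = mk("B", s[2])), w)$cs
    expect_gte(bump, cs)
  }
})

test_that("duplicating every CID leaves all scores unchanged", {
  set.seed(13)
  ds <- random_dataset(8, 8, 40)
  dup <- toy_dataset(lapply(ds$ec_to_cids, function(v) c(v, paste0(v, "_dup"))),
                     lapply(ds$pfam_to_cids, function(v) c(v, paste0(v, "_dup"))))
  a <- raw_scores(ds)
  b <- raw_scores(dup)
  expect_equal(a$score, b$score, tolerance = 1e-12)
  expect_equal(paste(a$ec, a$pfam), paste(b$ec, b$pfam))
})

test_that("score tables write with six decimals and read back", {
  ds <- random_dataset(5, 5, 30)
  sc <- combine_scores(list(only = raw_scores(ds)), c(only = 1))
  path <- withr::local_tempfile()
  write_score_table(sc, path)
  back <- utils::read.delim(path)
  expect_equal(back$cs, round(sc$cs, 6), tolerance = 1e-9)
})
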