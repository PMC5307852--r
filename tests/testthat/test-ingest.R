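write_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("association tables read with dedup, comments and CRLF tolerance", {
  expect_equal(nrow(read_association_table(write_tmp(character()), "ec")), 0L)

  p <- write_tmp(c("# comment", "chainA\tPF01933", "chainA\tPF01933", ""))
  df <- read_association_table(p, "pfam")
  expect_equal(nrow(df), 1L)
  expect_equal(df$label, "PF01933")

  p <- write_tmp(c("chainA\t2.7.8.28\r", "chainB\t2.7.8.28"))
  df <- read_association_table(p, "ec")
  expect_equal(df$entity_id, c("chainA", "chainB"))
  expect_equal(df$label, rep("2.7.8.28", 2L))

  expect_error(read_association_table(write_tmp("a\tb\tc"), "ec"), "line 1")
  expect_error(read_association_table(write_tmp("chainA\t9.1.1.1"), "ec"), "branch")
  expect_error(read_association_table(write_tmp("chainA\tPF19"), "pfam"), "PF19")
  expect_error(read_association_table(file.path(tempdir(), "nope.tsv"), "ec"),
               "not found")
})

test_that("cluster maps are many-to-one and reject conflicts", {
  m <- read_cluster_map(write_tmp(c("e1\tc1", "e2\tc1", "e3\tc2", "e1\tc1")))
  expect_equal(unname(m[c("e1", "e2", "e3")]), c("c1", "c1", "c2"))
  expect_error(read_cluster_map(write_tmp(c("e1\tc1", "e1\tc2"))),
               "more than one CID")
})

test_that("build_dataset collapses duplicates through the cluster map", {
  ec <- data.frame(entity_id = c("e1", "e2"), label = c("1.1.1.1", "1.1.1.1"))
  pf <- data.frame(entity_id = c("e1", "e2"), label = c("PF00001", "PF00002"))
  cm <- c(e1 = "c1", e2 = "c1")
  ds <- build_dataset(ec, pf, cm, "x")
  # two entities in one cluster: a single CID of support
  expect_equal(ds$ec_to_cids[["1.1.1.1"]], "c1")
  expect_equal(ds$cid_universe, "c1")

  # identity map: maps equal the pairs re-keyed by label
  ec2 <- data.frame(entity_id = c("a", "b", "c"),
                    label = c("1.1.1.1", "1.1.1.1", "2.2.1.1"))
  pf2 <- data.frame(entity_id = c("a", "c"), label = c("PF00001", "PF00001"))
  ds2 <- build_dataset(ec2, pf2, NULL, "y")
  expect_equal(ds2$ec_to_cids, list(`1.1.1.1` = c("a", "b"), `2.2.1.1` = "c"))
  expect_equal(ds2$pfam_to_cids, list(PF00001 = c("a", "c")))

  # empty inputs give an empty dataset
  e <- build_dataset(ec2[0, ], pf2[0, ], NULL, "empty")
  expect_length(e$ec_to_cids, 0L)
  expect_length(e$cid_universe, 0L)

  expect_error(build_dataset(ec, pf, c(e1 = "c1"), "x"), "e2")
})

test_that("cluster collapse bounds CID set sizes by entity pair counts", {
  set.seed(41)
  for (rep in 1:10) {
    n_ent <- sample(5:40, 1L)
    ents <- sprintf("e%02d", seq_len(n_ent))
    cm <- stats::setNames(sprintf("c%02d", sample.int(max(2L, n_ent %/% 3), n_ent,
                                                      replace = TRUE)), ents)
    ec <- data.frame(entity_id = sample(ents, 30, TRUE),
                     label = sprintf("1.1.1.%d", sample(1:5, 30, TRUE)))
    pf <- data.frame(entity_id = sample(ents, 30, TRUE),
                     label = sprintf("PF%05d", sample(1:5, 30, TRUE)))
    ds <- build_dataset(ec, pf, cm, "p")
    for (lab in names(ds$ec_to_cids))
      expect_lte(length(ds$ec_to_cids[[lab]]), sum(ec$label == lab))
    for (lab in names(ds$pfam_to_cids))
      expect_lte(length(ds$pfam_to_cids[[lab]]), sum(pf$label == lab))
  }
})

test_that("dataset TSV round-trip reproduces identical maps", {
  ds <- toy_dataset(list(`1.1.1.1` = c("c1", "c2"), `2.7.1.1` = "c3"),
                    list(PF00001 = c("c1", "c3"), PF00002 = "c2"))
  ec_path <- withr::local_tempfile()
  pf_path <- withr::local_tempfile()
  write_dataset_tables(ds, ec_path, pf_path)
  back <- build_dataset(read_association_table(ec_path, "ec"),
                        read_association_table(pf_path, "pfam"),
                        NULL, ds$name)
  expect_equal(back$ec_to_cids, ds$ec_to_cids)
  expect_equal(back$pfam_to_cids, ds$pfam_to_cids)
  expect_equal(back$cid_universe, ds$cid_universe)
})

test_that("reference tables parse labels and default to positives", {
  p <- write_tmp(c("2.7.8.28\tPF01933", "1.1.1.1\tPF00001\tneg"))
  ref <- read_reference_table(p)
  expect_equal(ref$label, c("pos", "neg"))
  expect_error(read_reference_table(write_tmp("2.7.8\tPF01933")), "4 digits")
  expect_error(read_reference_table(write_tmp("2.7.8.28\tPF01933\tmaybe")),
               "pos.*neg")
})
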