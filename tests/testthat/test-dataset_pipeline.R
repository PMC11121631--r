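test_that("length filtering is inclusive at the threshold and counts reasons", {
  recs <- protein_records(
    c("a", "b", "c", "d"),
    c(strrep("M", 29), strrep("M", 30), strrep("M", 31), strrep("M", 40)),
    c("Nucleus", "Nucleus", "Nucleus", NA))
  kept <- filter_valid(recs, min_len = 30)
  expect_equal(kept$id, c("b", "c"))
  rep <- attr(kept, "report")
  expect_equal(unname(rep["no_location"]), 1L)
  expect_equal(unname(rep["too_short"]), 1L)
  expect_equal(nrow(filter_valid(recs[0, , drop = FALSE])), 0L)
})

test_that("greedy redundancy reduction keeps the earlier of similar pairs", {
  # identical duplicates: earlier survivor wins even if the backend is blind
  recs <- protein_records(c("a", "b"), rep(strrep("MKVLW", 8), 2),
                          c("Nucleus", "Nucleus"))
  out <- redundancy_reduce(recs, prefix_backend(dis_evalue = 10,
                                                sim_evalue = 10))
  expect_equal(out$id, "a")
  expect_equal(attr(out, "removed")$id, "b")

  # A ~ B similar, C dissimilar -> survivors {A, C}
  recs2 <- protein_records(
    c("A", "B", "C"),
    c(paste0(strrep("W", 10), strrep("A", 25)),
      paste0(strrep("W", 10), strrep("C", 25)),
      paste0(strrep("K", 10), strrep("D", 25))),
    "Secreted")
  out2 <- redundancy_reduce(recs2, prefix_backend())
  expect_equal(out2$id, c("A", "C"))

  # all-dissimilar set unchanged
  recs3 <- random_records(8, seed = 12)
  out3 <- redundancy_reduce(recs3, prefix_backend())
  expect_equal(out3$id, recs3$id)
})

test_that("reduction output survives an exhaustive all-pairs audit", {
  spec <- generator_spec(n_classes = 4, n_per_class = 10, seed = 21)
  recs <- generate_redundant_pairs(spec, n_dups = 10)
  backend <- similarity_backend_builtin()
  out <- redundancy_reduce(recs, backend, threshold = 0.001)
  expect_lt(nrow(out), nrow(recs))
  # brute-force oracle: every retained pair must be above threshold, under
  # the same database-size term the reduction used (set during its prepare)
  worst <- Inf
  for (i in seq_len(nrow(out) - 1)) {
    for (j in (i + 1):nrow(out)) {
      worst <- min(worst, backend$evaluate(out[i, ], out[j, ]))
    }
  }
  expect_gt(worst, 0.001)
})

test_that("interleaved split follows the 3:1:1 cycle exactly", {
  n <- 11825L
  recs <- protein_records(sprintf("p%05d", 1:n), rep("M", n) ,
                          rep("Nucleus", n))
  # length-1 sequences are fine here: the split only looks at positions
  sp <- interleaved_split(recs)
  expect_equal(nrow(sp$train), 7095L)
  expect_equal(nrow(sp$test), 2365L)
  expect_equal(nrow(sp$validation), 2365L)
  # position arithmetic: record i goes by i mod 5
  expect_equal(sp$train$id[1:3], c("p00001", "p00002", "p00003"))
  expect_equal(sp$test$id[1], "p00004")
  expect_equal(sp$validation$id[1], "p00005")

  small <- interleaved_split(recs[1:7, , drop = FALSE])
  expect_equal(vapply(small, nrow, integer(1)),
               c(train = 5L, test = 1L, validation = 1L))
  five <- interleaved_split(recs[1:5, , drop = FALSE])
  expect_equal(vapply(five, nrow, integer(1)),
               c(train = 3L, test = 1L, validation = 1L))
})

test_that("the split is deterministic, disjoint and conserving", {
  recs <- random_records(57, seed = 8)
  s1 <- interleaved_split(recs)
  s2 <- interleaved_split(recs)
  expect_identical(s1, s2)
  ids <- c(s1$train$id, s1$test$id, s1$validation$id)
  expect_equal(sort(ids), sort(recs$id))
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("class summaries match a brute-force tally", {
  recs <- random_records(60, seed = 14)
  sp <- interleaved_split(recs)
  tab <- class_summary(sp)
  expect_equal(tab$class, c(localization_classes(), "Total"))
  for (part in c("train", "test", "validation")) {
    manual <- vapply(localization_classes(), function(cl) {
      sum(sp[[part]]$label == cl)
    }, integer(1))
    expect_equal(tab[[part]][1:8], unname(manual))
    expect_equal(tab[[part]][9], nrow(sp[[part]]))
  }
  single <- protein_records(sprintf("s%02d", 1:10),
                            rep(strrep("M", 30), 10), "Plastid")
  tab1 <- class_summary(interleaved_split(single))
  expect_equal(unlist(tab1[tab1$class == "Plastid", c("train", "test",
                                                      "validation")],
                      use.names = FALSE), c(6L, 2L, 2L))
})

test_that("prepare_dataset chains the stages and reports counts", {
  spec <- generator_spec(n_classes = 2, n_per_class = 10, seed = 31)
  recs <- generate_redundant_pairs(spec, n_dups = 3)
  res <- prepare_dataset(recs, backend = similarity_backend_builtin())
  rep <- res$report
  expect_equal(unname(rep["input"]), nrow(recs))
  expect_equal(unname(rep["after_reduction"]), nrow(res$records))
  expect_equal(unname(rep["train"] + rep["test"] + rep["validation"]),
               nrow(res$records))
})
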