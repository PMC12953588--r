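test_that("temporal split assigns pairs by first supporting year", {
  recs <- make_records(
    make_record("N1", c("A", "B"), year = 2019),
    make_record("N2", c("A", "B"), year = 2022), # already known: train only
    make_record("N3", c("C", "D"), year = 2022), # first appears in test year
    make_record("N4", c("E", "F"), year = 2024) # beyond test year: ignored
  )
  sp <- temporal_split(recs, 2021)
  expect_equal(pair_rows(sp$train_pos), list(c("A", "B")))
  expect_equal(pair_rows(sp$test_pos), list(c("C", "D")))

  # counting example: years 2015, 2021 train; 2022, 2022 test
  recs2 <- make_records(
    make_record("M1", c("A", "B"), year = 2015),
    make_record("M2", c("C", "D"), year = 2021),
    make_record("M3", c("E", "F"), year = 2022),
    make_record("M4", c("G", "H"), year = 2022)
  )
  sp2 <- temporal_split(recs2, 2021)
  expect_equal(nrow(sp2$train_pos), 2)
  expect_equal(nrow(sp2$test_pos), 2)

  undated <- make_records(make_record("X", c("A", "B")))
  expect_error(temporal_split(undated, 2021), "random_split")
})

test_that("random split keeps every node covered in training", {
  triangle <- build_graph(make_records(
    make_record("N1", c("A", "B")),
    make_record("N2", c("B", "C")),
    make_record("N3", c("A", "C"))
  ))
  sp <- random_split_with_isolated(triangle, 1 / 3, seed = 1)
  expect_equal(nrow(sp$test_pos), 1)
  covered <- unique(c(sp$train_pos$u, sp$train_pos$v))
  expect_setequal(covered, c("A", "B", "C"))

  # star with two leaves: testing any edge would isolate a leaf
  star <- build_graph(make_records(
    make_record("N1", c("Hub", "L1")),
    make_record("N2", c("Hub", "L2"))
  ))
  sp2 <- random_split_with_isolated(star, 0.5, seed = 3)
  expect_lte(nrow(sp2$test_pos), 1)
  deg <- table(c(sp2$train_pos$u, sp2$train_pos$v))
  expect_true(all(c("L1", "L2", "Hub") %in% names(deg)))

  # determinism per seed
  g <- build_graph(random_records(40, 10, 5))
  a <- random_split_with_isolated(g, 0.2, seed = 9)
  b <- random_split_with_isolated(g, 0.2, seed = 9)
  expect_identical(a, b)

  empty <- build_graph(make_records(make_record("N1", "A")))
  expect_error(random_split_with_isolated(empty, 0.2, 1), "no edges")
})

test_that("every node keeps a training edge across many random splits", {
  g <- build_graph(random_records(60, 12, 8))
  active <- unique(c(g$edges$u, g$edges$v))
  for (seed in 1:10) {
    sp <- random_split_with_isolated(g, 0.25, seed = seed)
    covered <- unique(c(sp$train_pos$u, sp$train_pos$v))
    expect_setequal(covered, active)
    # partition: train + test == all edges
    expect_equal(
      sort(c(ctcollab:::pair_keys(sp$train_pos), ctcollab:::pair_keys(sp$test_pos))),
      sort(ctcollab:::pair_keys(g$edges))
    )
  }
})

test_that("negative sampling draws only non-adjacent unforbidden pairs", {
  # complete graph: no non-edges at all
  k4 <- build_graph(make_records(make_record("N1", c("A", "B", "C", "D"))))
  expect_error(sample_negatives(k4, 1, seed = 1), "only 0")

  # 4-node path: exactly the 3 non-edges come back when all are needed
  path_g <- build_graph(make_records(
    make_record("N1", c("A", "B")),
    make_record("N2", c("B", "C")),
    make_record("N3", c("C", "D"))
  ))
  negs <- sample_negatives(path_g, 3, seed = 2)
  expect_setequal(
    ctcollab:::pair_keys(negs),
    c("A\x1fC", "A\x1fD", "B\x1fD")
  )

  expect_equal(nrow(sample_negatives(path_g, 0, seed = 1)), 0)

  # forbidden pairs shrink the pool
  forb <- tibble::tibble(u = "A", v = "C")
  negs2 <- sample_negatives(path_g, 2, forbidden = forb, seed = 3)
  expect_false("A\x1fC" %in% ctcollab:::pair_keys(negs2))

  # determinism
  expect_identical(
    sample_negatives(path_g, 2, seed = 7),
    sample_negatives(path_g, 2, seed = 7)
  )
})

test_that("edge split validation catches role overlaps and imbalance", {
  ok <- edge_split(
    train_pos = tibble::tibble(u = "A", v = "B"),
    train_neg = tibble::tibble(u = "C", v = "D")
  )
  expect_silent(validate_edge_split(ok))

  dup <- edge_split(
    train_pos = tibble::tibble(u = "A", v = "B"),
    train_neg = tibble::tibble(u = "A", v = "B")
  )
  expect_error(validate_edge_split(dup), "both train_pos and train_neg")

  unbalanced <- edge_split(
    train_pos = tibble::tibble(u = c("A", "C"), v = c("B", "D")),
    train_neg = tibble::tibble(u = "E", v = "F")
  )
  expect_error(validate_edge_split(unbalanced), "1:1")
  expect_silent(validate_edge_split(unbalanced, require_negatives = FALSE))

  # pairs are stored canonically regardless of input orientation
  flipped <- edge_split(train_pos = tibble::tibble(u = "B", v = "A"))
  expect_equal(flipped$train_pos$u, "A")
})
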