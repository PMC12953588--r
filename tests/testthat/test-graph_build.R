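test_that("graph accumulation follows the per-trial clique rule", {
  # single-affiliation trial: isolated node, no edges
  g1 <- build_graph(make_records(make_record("N1", "A")))
  expect_equal(g1$nodes$name, "A")
  expect_equal(g1$nodes$trial_count, 1L)
  expect_equal(nrow(g1$edges), 0)

  # repeated pair accumulates edge and node weights
  g2 <- build_graph(make_records(
    make_record("N1", c("A", "B")),
    make_record("N2", c("A", "B"))
  ))
  expect_equal(g2$edges$u, "A")
  expect_equal(g2$edges$v, "B")
  expect_equal(g2$edges$collab_count, 2L)
  expect_equal(g2$nodes$trial_count, c(2L, 2L))

  # a 3-affiliation trial yields the pairwise clique
  g3 <- build_graph(make_records(make_record("N1", c("A", "B", "C"))))
  expect_equal(nrow(g3$edges), 3)
  expect_true(all(g3$edges$collab_count == 1))

  # duplicated affiliation within a trial: counted once, no self-loop
  g4 <- build_graph(make_records(make_record("N1", c("A", "A", "B"))))
  expect_equal(g4$nodes$trial_count[g4$nodes$name == "A"], 1L)
  expect_equal(nrow(g4$edges), 1)
  expect_true(all(g4$edges$u != g4$edges$v))
})

test_that("node attribute counts accumulate per trial", {
  recs <- make_records(
    make_record("N1", c("A", "B"),
      countries = c("France", "Japan"),
      interventions = iv(c("DRUG", "DRUG"), c("x", "y"))
    ),
    make_record("N2", "A",
      countries = "France",
      interventions = iv("DEVICE", "z")
    )
  )
  g <- build_graph(recs)
  a <- g$nodes[g$nodes$name == "A", ]
  expect_equal(a$country_counts[[1]], c(France = 2L, Japan = 1L))
  expect_equal(a$intervention_counts[[1]], c(DEVICE = 1L, DRUG = 2L))
  expect_equal(g$edges$intervention_raw, 1L)
})

test_that("weight conservation holds on random record sets", {
  for (seed in 1:5) {
    recs <- random_records(30, 8, seed)
    g <- build_graph(recs)
    n_affs <- vapply(recs$affiliations, function(a) length(unique(a)), integer(1))
    expect_identical(sum(g$nodes$trial_count), sum(n_affs))
    expect_identical(
      as.integer(sum(g$edges$collab_count)),
      as.integer(sum(choose(n_affs, 2)))
    )
  }
})

test_that("graph construction is invariant to record order", {
  recs <- random_records(25, 7, 42)
  g1 <- build_graph(recs)
  g2 <- build_graph(recs[rev(seq_len(nrow(recs))), ])
  expect_equal(g1$nodes, g2$nodes)
  expect_equal(g1$edges, g2$edges)
})

test_that("condition subgraphs equal filter-then-build", {
  recs <- mixed_fixture()
  full <- build_graph(recs)

  all_g <- condition_subgraph(recs, c("diabetes", "stroke", "diet", "obes", "hyper"))
  expect_equal(all_g$nodes, full$nodes)
  expect_equal(all_g$edges, full$edges)

  none <- condition_subgraph(recs, "oncology")
  expect_equal(nrow(none$nodes), 0)
  expect_equal(nrow(none$edges), 0)

  # A-B co-occur only in the diabetes trial, A-C only in the stroke trial
  dia <- condition_subgraph(recs, "diabetes")
  expect_true("B" %in% c(dia$edges$u, dia$edges$v))
  expect_false(any(dia$edges$u == "A" & dia$edges$v == "C"))
  expect_equal(dia$edges, build_graph(filter_by_condition(recs, "diabetes"))$edges)
})

test_that("intervention min-max normalization follows the 0-1 convention", {
  g <- build_graph(make_records(
    make_record("N1", c("A", "B")),
    make_record("N2", c("B", "C")),
    make_record("N3", c("A", "C"))
  ))
  g$edges$intervention_raw <- c(0L, 5L, 10L)
  g <- normalize_edge_interventions(g)
  expect_equal(sort(g$edges$intervention_norm), c(0, 0.5, 1))

  # constant raws -> all 1.0
  g$edges$intervention_raw <- c(3L, 3L, 3L)
  g <- normalize_edge_interventions(g)
  expect_equal(g$edges$intervention_norm, rep(1, 3))

  # single edge -> 1.0
  g1 <- build_graph(make_records(
    make_record("N1", c("A", "B"), interventions = iv("DRUG", "x"))
  ))
  expect_equal(g1$edges$intervention_norm, 1)

  # edgeless graph -> warning, no-op
  g0 <- build_graph(make_records(make_record("N1", "A")))
  expect_warning(normalize_edge_interventions(g0), "no edges")
})

test_that("adjacency matrices are symmetric with zero diagonal", {
  g <- build_graph(make_records(
    make_record("N1", c("A", "B")),
    make_record("N2", c("A", "B")),
    make_record("N3", c("A", "B"))
  ))
  expect_equal(unname(adjacency(g, weighted = TRUE)), rbind(c(0, 3), c(3, 0)))
  expect_equal(unname(adjacency(g, weighted = FALSE)), rbind(c(0, 1), c(1, 0)))

  empty <- build_graph(mixed_fixture()[0, ])
  expect_equal(dim(adjacency(empty)), c(0L, 0L))

  rnd <- build_graph(random_records(40, 10, 9))
  A <- adjacency(rnd)
  expect_identical(A, t(A))
  expect_true(all(diag(A) == 0))
})
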