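test_that("adjacency normalization matches hand-computed cases", {
  # single isolated node: self-loop only
  expect_equal(normalize_adjacency(matrix(0, 1, 1)), matrix(1, 1, 1))

  # one unweighted edge: both degrees 2, all entries 1/2
  A <- rbind(c(0, 1), c(1, 0))
  expect_equal(normalize_adjacency(A), matrix(0.5, 2, 2))

  # binarization makes the result scale-invariant
  W <- rbind(c(0, 7), c(7, 0))
  expect_equal(
    normalize_adjacency(W, use_edge_weights = FALSE),
    normalize_adjacency(A, use_edge_weights = FALSE)
  )

  expect_error(normalize_adjacency(rbind(c(0, 1), c(0, 0))), "symmetric")
  expect_error(normalize_adjacency(rbind(c(1, 1), c(1, 0))), "diagonal")
})

test_that("encode reduces to identity and zero in degenerate cases", {
  cfg <- model_config(encoder = "gcn", n_layers = 1, hidden_dim = 3)
  st <- init_model_state(3, cfg, seed = 1)
  st$layers[[1]]$W <- diag(3)
  X <- matrix(c(1, -2, 0.5), 1, 3)
  P <- matrix(1, 1, 1) # isolated node after self-loop normalization
  expect_equal(encode(X, P, st), X, ignore_attr = TRUE)

  # zero features propagate to zero output (no biases anywhere)
  cfg2 <- model_config(encoder = "gcn", n_layers = 2, hidden_dim = 4)
  st2 <- init_model_state(5, cfg2, seed = 2)
  X0 <- matrix(0, 6, 5)
  A <- random_adjacency(6, 3)
  P <- normalize_adjacency(A)
  expect_equal(encode(X0, P, st2), matrix(0, 6, 4), ignore_attr = TRUE)
})

test_that("one-layer linear GCN equals the closed form", {
  cfg <- model_config(encoder = "gcn", n_layers = 1, hidden_dim = 4)
  st <- init_model_state(3, cfg, seed = 5)
  A <- random_adjacency(7, 8)
  P <- normalize_adjacency(A)
  X <- withr::with_seed(9, matrix(rnorm(21), 7, 3))
  expect_equal(encode(X, P, st), P %*% X %*% st$layers[[1]]$W, ignore_attr = TRUE)
})

test_that("both encoders match the dense per-node oracle", {
  for (enc in c("gcn", "sage")) {
    for (seed in 1:4) {
      n <- 5 + seed
      A <- random_adjacency(n, seed)
      cfg <- model_config(encoder = enc, n_layers = 2, hidden_dim = 6)
      P <- ctcollab:::propagation_matrix(A, cfg)
      st <- init_model_state(4, cfg, seed = seed + 10)
      X <- withr::with_seed(seed, matrix(rnorm(n * 4), n, 4))
      expect_equal(
        encode(X, P, st), oracle_encode(X, P, st),
        tolerance = 1e-12, ignore_attr = TRUE
      )
    }
  }
})

test_that("encode is permutation-equivariant", {
  n <- 8
  A <- random_adjacency(n, 21)
  X <- withr::with_seed(22, matrix(rnorm(n * 3), n, 3))
  cfg <- model_config(encoder = "gcn", hidden_dim = 5)
  st <- init_model_state(3, cfg, seed = 1)
  perm <- withr::with_seed(23, sample(n))
  H <- encode(X, normalize_adjacency(A), st)
  Hp <- encode(X[perm, ], normalize_adjacency(A[perm, perm]), st)
  expect_equal(Hp, H[perm, ], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("dot scoring is an inner product with validation", {
  expect_equal(dot_score(c(0, 0), c(5, -3)), 0)
  expect_equal(dot_score(c(1, 0), c(0, 1)), 0)
  expect_equal(dot_score(c(1, 2), c(3, 4)), 11)
  expect_equal(dot_score(c(1, 2), c(3, 4)), dot_score(c(3, 4), c(1, 2)))
  expect_error(dot_score(1:2, 1:3), "lengths differ")

  # non-negativity of self-scores, zero iff zero vector
  expect_true(dot_score(c(0.3, -2), c(0.3, -2)) > 0)
  expect_equal(dot_score(numeric(2) * 0, numeric(2) * 0), 0)
})

test_that("score_edges vectorizes dot_score in order", {
  H <- withr::with_seed(4, matrix(rnorm(12), 4, 3))
  rownames(H) <- c("a", "b", "c", "d")

  expect_equal(score_edges(H, cbind(integer(), integer())), numeric())

  idx <- rbind(c(1, 2), c(3, 4), c(1, 2))
  got <- score_edges(H, idx)
  expect_equal(got[1], got[3])
  manual <- vapply(seq_len(nrow(idx)), function(k) {
    dot_score(H[idx[k, 1], ], H[idx[k, 2], ])
  }, numeric(1))
  expect_equal(got, manual)

  # name-based pairs resolve through rownames
  pairs <- tibble::tibble(u = c("a", "c"), v = c("b", "d"))
  expect_equal(score_edges(H, pairs), manual[1:2])

  expect_error(score_edges(H, rbind(c(1, 9))), "out of range")
  expect_error(
    score_edges(H, tibble::tibble(u = "a", v = "zz")),
    "not present"
  )
})

test_that("model state survives a save/load round trip bit-exactly", {
  for (enc in c("gcn", "sage")) {
    st <- init_model_state(7, model_config(encoder = enc, hidden_dim = 5), seed = 13)
    path <- withr::local_tempfile(fileext = ".json")
    save_model_state(st, path)
    back <- load_model_state(path)
    expect_identical(back$layers, st$layers)
    expect_equal(back$config, st$config)
    expect_identical(back$input_dim, st$input_dim)
  }
})
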