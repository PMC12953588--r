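# Fixture builders and independent oracles used across the suite.

iv <- function(category, name) tibble::tibble(category = category, name = name)

no_iv <- function() tibble::tibble(category = character(), name = character())

make_record <- function(nct, affiliations,
                        title = paste("Study", nct),
                        conditions = character(),
                        interventions = no_iv(),
                        countries = character(),
                        year = NA_integer_) {
  tibble::tibble(
    nct_id = nct,
    title = title,
    conditions = list(conditions),
    interventions = list(interventions),
    affiliations = list(affiliations),
    countries = list(countries),
    year = as.integer(year)
  )
}

make_records <- function(...) dplyr::bind_rows(...)

# A small mixed-disease fixture used by filtering / subgraph tests.
mixed_fixture <- function() {
  make_records(
    make_record("NCT01", c("A", "B"),
      title = "Insulin pump study",
      conditions = "Type 2 Diabetes", year = 2019,
      interventions = iv("DRUG", "Insulin")
    ),
    make_record("NCT02", c("A", "C"),
      title = "Rehab after cerebrovascular accident",
      conditions = "Stroke", year = 2020,
      interventions = iv("BEHAVIORAL", "Rehab")
    ),
    make_record("NCT03", c("D"),
      title = "Diet trial",
      conditions = "Obesity", year = 2021
    ),
    make_record("NCT04", c("B", "C", "D"),
      title = "Metformin extension",
      conditions = "Diabetes Mellitus", year = 2021,
      interventions = iv("DRUG", "Metformin")
    ),
    make_record("NCT05", c("E"),
      title = "Observational stroke registry",
      conditions = "Hypertension", year = 2022
    )
  )
}

# Random trial records (no years) for conservation / permutation checks.
random_records <- function(n_trials, n_affs, seed) {
  withr::with_seed(seed, {
    affs <- sprintf("Inst%02d", seq_len(n_affs))
    dplyr::bind_rows(lapply(seq_len(n_trials), function(t) {
      team <- sample(affs, sample(1:min(4, n_affs), 1))
      has_iv <- runif(1) < 0.7
      make_record(
        sprintf("NCT%04d", t), team,
        interventions = if (has_iv) iv("DRUG", "X") else no_iv(),
        countries = sample(c("France", "Japan"), 1)
      )
    }))
  })
}

pair_rows <- function(pairs) {
  lapply(seq_len(nrow(pairs)), function(i) c(pairs$u[[i]], pairs$v[[i]]))
}

# --- Independent oracles -------------------------------------------------

# All-pairs comparison form of the ROC AUC (ties count 1/2).
brute_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) {
    for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  }
  s / (length(pos) * length(neg))
}

# Dense per-node recomputation of the encoder forward pass.
oracle_encode <- function(X, P, state, config = state$config) {
  H <- X
  for (l in seq_len(config$n_layers)) {
    n <- nrow(H)
    agg <- matrix(0, n, ncol(H))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) agg[i, ] <- agg[i, ] + P[i, j] * H[j, ]
    }
    lay <- state$layers[[l]]
    Z <- if (config$encoder == "gcn") {
      agg %*% lay$W
    } else {
      H %*% lay$W_self + agg %*% lay$W_nbr
    }
    H <- if (l < config$n_layers) pmax(Z, 0) else Z
  }
  H
}

# Random small symmetric weighted adjacency (zero diagonal, connected-ish).
random_adjacency <- function(n, seed) {
  withr::with_seed(seed, {
    A <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (runif(1) < 0.4) A[i, j] <- A[j, i] <- sample(1:3, 1)
      }
    }
    A
  })
}

# Two-clique planted fixture: every block forms a clique via one big trial
# per block repeated over the years.
two_clique_records <- function(block_size = 8) {
  a <- sprintf("Ablock%02d", seq_len(block_size))
  b <- sprintf("Bblock%02d", seq_len(block_size))
  make_records(
    make_record("NCTA", a, year = 2020, interventions = iv("DRUG", "X")),
    make_record("NCTB", b, year = 2020, interventions = iv("DEVICE", "Y"))
  )
}
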