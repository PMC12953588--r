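# Synthetic registry generator: planted collaboration blocks with
# attribute homophily, emitted in the registry CSV dialect.

#' Synthetic registry configuration
#'
#' The generator plants a partition of affiliations into blocks. Each block
#' has a signature country and intervention category; each affiliation
#' adopts its block's signatures with probability `attribute_coupling`
#' (else a uniform draw), so attributes correlate with — but do not
#' duplicate — the block structure. Each trial draws a lead uniformly, a
#' team of collaborators of mean size `mean_team_size` (shifted Poisson,
#' minimum one collaborator, so every trial yields at least a pair), each
#' teammate from the lead's block with probability `p_within`, and a
#' registration year: the final year of `year_range` with probability
#' `test_year_fraction`, else uniform over the earlier years. Defaults give
#' a two-block registry of 120 affiliations and 600 trials with strong
#' structural (`p_within = 0.85`) and attribute (`attribute_coupling =
#' 0.9`) homophily spanning 2011-2022, the regime used throughout the
#' package's validation experiments.
#'
#' @param n_affiliations,n_trials,n_blocks Sizes.
#' @param p_within Probability a collaborator comes from the lead's block.
#' @param mean_team_size Mean number of collaborators beyond the lead
#'   (>= 1).
#' @param attribute_coupling Probability a node adopts its block's
#'   signature country/category.
#' @param year_range Integer vector `c(first, last)` of registration years.
#' @param test_year_fraction Probability a trial is registered in the last
#'   (test) year.
#' @param categories,countries Attribute vocabularies; block signatures
#'   cycle through them.
#' @param seed Integer seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_affiliations = 120L, n_trials = 600L,
                         n_blocks = 2L, p_within = 0.85,
                         mean_team_size = 2, attribute_coupling = 0.9,
                         year_range = c(2011L, 2022L),
                         test_year_fraction = 0.15,
                         categories = c("DRUG", "BEHAVIORAL", "DEVICE", "OTHER"),
                         countries = c("United States", "Korea", "Germany", "Brazil"),
                         seed = 1L) {
  cfg <- list(
    n_affiliations = as.integer(n_affiliations),
    n_trials = as.integer(n_trials),
    n_blocks = as.integer(n_blocks),
    p_within = p_within,
    mean_team_size = mean_team_size,
    attribute_coupling = attribute_coupling,
    year_range = as.integer(year_range),
    test_year_fraction = test_year_fraction,
    categories = categories,
    countries = countries,
    seed = as.integer(seed)
  )
  if (cfg$p_within < 0 || cfg$p_within > 1 ||
    cfg$attribute_coupling < 0 || cfg$attribute_coupling > 1 ||
    cfg$test_year_fraction < 0 || cfg$test_year_fraction > 1) {
    stop("Probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_affiliations < 2) {
    stop("Need at least 2 affiliations", call. = FALSE)
  }
  if (cfg$n_blocks > cfg$n_affiliations) {
    stop("More blocks than affiliations", call. = FALSE)
  }
  if (cfg$mean_team_size < 1) {
    stop("'mean_team_size' must be >= 1 collaborator", call. = FALSE)
  }
  if (1 + ceiling(cfg$mean_team_size) > cfg$n_affiliations) {
    stop("Infeasible config: teams larger than the affiliation pool", call. = FALSE)
  }
  if (length(cfg$year_range) != 2 || cfg$year_range[1] > cfg$year_range[2]) {
    stop("'year_range' must be c(first, last) with first <= last", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic clinical-trial registry
#'
#' Draws a registry under a [synth_config()] (see there for the generative
#' model). Output records use the same dialect as [read_registry()]: each
#' trial's interventions carry the lead's planted category, and its
#' locations are the countries of the participating affiliations, so node
#' attributes in the built graph inherit the planted homophily.
#' Deterministic per seed.
#'
#' @param config A [synth_config()].
#' @return A list with `records` (trial-record tibble) and `truth` (tibble
#'   `name`, `block` of the planted block assignment).
#' @export
generate_registry <- function(config = synth_config()) {
  withr::with_seed(config$seed, {
    n <- config$n_affiliations
    affs <- sprintf("Affiliation %03d", seq_len(n))
    block <- rep_len(seq_len(config$n_blocks), n) # round-robin
    sig_country <- rep_len(config$countries, config$n_blocks)
    sig_cat <- rep_len(config$categories, config$n_blocks)

    adopt_c <- runif(n) < config$attribute_coupling
    node_country <- ifelse(
      adopt_c, sig_country[block],
      sample(config$countries, n, replace = TRUE)
    )
    adopt_i <- runif(n) < config$attribute_coupling
    node_cat <- ifelse(
      adopt_i, sig_cat[block],
      sample(config$categories, n, replace = TRUE)
    )

    y0 <- config$year_range[1]
    y1 <- config$year_range[2]

    rec_list <- lapply(seq_len(config$n_trials), function(t) {
      lead <- sample.int(n, 1)
      k <- min(1L + rpois(1, config$mean_team_size - 1), n - 1L)
      team <- lead
      for (j in seq_len(k)) {
        same <- which(block == block[lead])
        othr <- which(block != block[lead])
        pool <- if (runif(1) < config$p_within) same else othr
        pool <- setdiff(pool, team)
        if (length(pool) == 0) pool <- setdiff(seq_len(n), team)
        if (length(pool) == 0) break
        team <- c(team, pool[sample.int(length(pool), 1)])
      }
      year <- if (y1 > y0 && runif(1) < config$test_year_fraction) {
        y1
      } else if (y1 > y0) {
        sample(seq(y0, y1 - 1L), 1)
      } else {
        y0
      }
      tibble::tibble(
        nct_id = sprintf("NCT%08d", t),
        title = sprintf(
          "Trial %04d of agent %d in chronic disease", t, sample.int(50, 1)
        ),
        conditions = list("Type 2 Diabetes"),
        interventions = list(tibble::tibble(
          category = node_cat[lead],
          name = sprintf("Agent %d", sample.int(50, 1))
        )),
        affiliations = list(affs[team]),
        countries = list(unique(node_country[team])),
        year = as.integer(year)
      )
    })

    list(
      records = dplyr::bind_rows(rec_list),
      truth = tibble::tibble(name = affs, block = block)
    )
  })
}

#' Within-block edge fraction of a built graph
#'
#' The fraction of graph edges whose two endpoints share a planted block —
#' a direct measure of how much of the planted structure survived into the
#' realized collaboration network. An edgeless graph returns 0 with a
#' warning.
#'
#' @param graph A `collab_graph` built from generated records.
#' @param truth The `truth` tibble from [generate_registry()].
#' @return A value in `[0, 1]`.
#' @export
planted_quality <- function(graph, truth) {
  if (!all(graph$nodes$name %in% truth$name)) {
    stop("'truth' must cover every node of the graph", call. = FALSE)
  }
  if (nrow(graph$edges) == 0) {
    warning("Graph has no edges; planted quality defined as 0", call. = FALSE)
    return(0)
  }
  bu <- truth$block[match(graph$edges$u, truth$name)]
  bv <- truth$block[match(graph$edges$v, truth$name)]
  mean(bu == bv)
}

#' Write a generated registry to disk
#'
#' Emits `registry.csv` (registry dialect with a date column),
#' `truth.tsv` and `config.json` under `dir`.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
simulate_registry_files <- function(config = synth_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_registry(config)
  write_registry(gen$records, file.path(dir, "registry.csv"))
  readr::write_tsv(gen$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  jsonlite::write_json(
    unclass(config), file.path(dir, "config.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
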