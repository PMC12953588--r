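# Reading, validating and canonicalizing clinical-trial registry exports.

#' Required column names of a registry export
#'
#' The registry dialect is a CSV with seven named fields; multi-valued cells
#' (conditions, interventions, collaborators, locations) use `|` as the
#' intra-cell delimiter. An extended dialect may add a registration-date
#' column, which is required only for the temporal edge split.
#'
#' @return Character vector of the seven required column names.
#' @export
registry_fields <- function() {
  c(
    "NCT Number", "Study Title", "Conditions", "Interventions",
    "Sponsor", "Collaborators", "Locations"
  )
}

#' Describe a registry CSV dialect
#'
#' @param date_col Name of the optional registration-date column (matched
#'   case-insensitively). Records read from files lacking this column carry
#'   `NA` years and can only be used with the random split.
#' @return A dialect description list.
#' @export
registry_dialect <- function(date_col = "Registration Date") {
  list(date_col = date_col)
}

split_multi <- function(cell) {
  if (length(cell) == 0) {
    return(list())
  }
  cell <- ifelse(is.na(cell), "", cell)
  lapply(strsplit(cell, "|", fixed = TRUE), function(x) {
    x <- trimws(x)
    x[nzchar(x)]
  })
}

parse_interventions <- function(tokens) {
  if (length(tokens) == 0) {
    return(tibble::tibble(category = character(), name = character()))
  }
  m <- regmatches(tokens, regexec("^([A-Z][A-Z_]*)\\s*:\\s*(.*)$", tokens))
  category <- vapply(m, function(g) if (length(g) == 3) g[[2]] else "OTHER", "")
  name <- vapply(
    seq_along(m),
    function(i) if (length(m[[i]]) == 3) m[[i]][[3]] else tokens[[i]], ""
  )
  tibble::tibble(category = category, name = trimws(name))
}

#' Read a clinical-trial registry CSV into trial records
#'
#' Each row of the export becomes one trial record. Multi-valued cells are
#' split on `|`, trimmed, and empty tokens dropped. Intervention tokens of
#' the form `"CATEGORY: name"` are parsed into (category, name) pairs; bare
#' tokens get category `OTHER`. Sponsor and collaborators are merged into a
#' single ordered affiliation list (sponsor first) because the collaboration
#' graph is undirected. Country names are the final comma-separated token of
#' each location entry. Rows listing no affiliation at all are dropped with
#' a warning.
#'
#' @param path Path to the CSV file.
#' @param dialect A [registry_dialect()].
#' @return A tibble of trial records with columns `nct_id`, `title`,
#'   `conditions` (list of character), `interventions` (list of tibbles with
#'   `category`, `name`), `affiliations` (list of character), `countries`
#'   (list of character) and `year` (integer, `NA` when the file has no date
#'   column).
#' @seealso [write_registry()], [canonicalize()], [filter_by_condition()]
#' @export
read_registry <- function(path, dialect = registry_dialect()) {
  if (!file.exists(path)) {
    stop("Cannot read registry file: ", path, call. = FALSE)
  }
  raw <- tryCatch(
    suppressWarnings(readr::read_csv(
      path,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE, show_col_types = FALSE, name_repair = "minimal"
    )),
    error = function(e) {
      stop("Registry schema error: unreadable or empty file (", path, "): ",
        conditionMessage(e),
        call. = FALSE
      )
    }
  )
  if (ncol(raw) == 0) {
    stop("Registry schema error: file has no header: ", path, call. = FALSE)
  }

  lookup <- function(field) {
    hit <- which(tolower(names(raw)) == tolower(field))
    if (length(hit) == 0) NA_integer_ else hit[[1]]
  }
  idx <- vapply(registry_fields(), lookup, integer(1))
  missing <- registry_fields()[is.na(idx)]
  if (length(missing) > 0) {
    stop("Registry schema error: missing required column(s): ",
      paste0("'", missing, "'", collapse = ", "),
      call. = FALSE
    )
  }
  col <- function(field) raw[[idx[[field]]]]

  date_idx <- lookup(dialect$date_col)
  year <- if (is.na(date_idx) || nrow(raw) == 0) {
    rep(NA_integer_, nrow(raw))
  } else {
    yr <- stringi::stri_extract_first_regex(raw[[date_idx]], "\\d{4}")
    as.integer(yr)
  }

  sponsors <- split_multi(col("Sponsor"))
  collabs <- split_multi(col("Collaborators"))
  affiliations <- mapply(
    function(s, c) unique(c(s, c)),
    sponsors, collabs,
    SIMPLIFY = FALSE
  )

  records <- tibble::tibble(
    nct_id = ifelse(is.na(col("NCT Number")), "", col("NCT Number")),
    title = ifelse(is.na(col("Study Title")), "", col("Study Title")),
    conditions = split_multi(col("Conditions")),
    interventions = lapply(split_multi(col("Interventions")), parse_interventions),
    affiliations = affiliations,
    countries = lapply(col("Locations"), extract_countries),
    year = year
  )

  n_aff <- vapply(records$affiliations, length, integer(1))
  if (any(n_aff == 0)) {
    warning(
      sum(n_aff == 0), " record(s) with no affiliation dropped",
      call. = FALSE
    )
    records <- records[n_aff > 0, ]
  }
  if (anyDuplicated(records$nct_id)) {
    stop("Registry schema error: duplicated NCT Number(s): ",
      paste(unique(records$nct_id[duplicated(records$nct_id)]), collapse = ", "),
      call. = FALSE
    )
  }
  records
}

#' Write trial records back to the registry CSV dialect
#'
#' Inverse of [read_registry()]: the first affiliation is written as the
#' sponsor, the remainder as collaborators; list cells are joined with `|`;
#' countries are written as the Locations column. A date column is emitted
#' only when at least one record carries a year.
#'
#' @param records A trial-record tibble.
#' @param path Output file path.
#' @param dialect A [registry_dialect()].
#' @return `path`, invisibly.
#' @export
write_registry <- function(records, path, dialect = registry_dialect()) {
  join <- function(xs) vapply(xs, paste, "", collapse = "|")
  iv_cell <- function(iv) {
    if (nrow(iv) == 0) "" else paste(iv$category, iv$name, sep = ": ", collapse = "|")
  }
  out <- tibble::tibble(
    `NCT Number` = records$nct_id,
    `Study Title` = records$title,
    Conditions = join(records$conditions),
    Interventions = vapply(records$interventions, iv_cell, ""),
    Sponsor = vapply(records$affiliations, function(a) a[[1]], ""),
    Collaborators = vapply(
      records$affiliations,
      function(a) paste(a[-1], collapse = "|"), ""
    ),
    Locations = join(records$countries)
  )
  if (any(!is.na(records$year))) {
    out[[dialect$date_col]] <- ifelse(
      is.na(records$year), "", sprintf("%04d-01-01", records$year)
    )
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

clean_affiliation <- function(x) {
  x <- stringi::stri_trans_nfc(x)
  trimws(gsub("\\s+", " ", x))
}

#' Read an affiliation alias map
#'
#' Accepts either a two-column TSV with header `raw`, `canonical`, or a JSON
#' object mapping raw names to canonical names.
#'
#' @param path Path to the alias file.
#' @return Named character vector: `names()` are raw spellings, values are
#'   canonical names.
#' @export
read_alias_map <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    aliases <- unlist(obj)
  } else {
    tab <- readr::read_tsv(
      path,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE, show_col_types = FALSE
    )
    if (!all(c("raw", "canonical") %in% names(tab))) {
      stop("Alias map must have columns 'raw' and 'canonical'", call. = FALSE)
    }
    aliases <- stats::setNames(tab$canonical, tab$raw)
  }
  aliases
}

validate_alias_map <- function(aliases) {
  if (length(aliases) == 0) {
    return(invisible(aliases))
  }
  keys <- clean_affiliation(names(aliases))
  vals <- clean_affiliation(unname(aliases))
  # canonical names must be fixed points: mapping a canonical target again
  # must return itself (rules out chains and cycles)
  hit <- match(vals, keys)
  bad <- which(!is.na(hit) & vals[hit] != vals)
  if (length(bad) > 0) {
    stop(
      "Alias map is not canonical: target(s) ",
      paste0("'", unique(vals[bad]), "'", collapse = ", "),
      " map onward to a different name",
      call. = FALSE
    )
  }
  invisible(stats::setNames(vals, keys))
}

#' Canonicalize affiliation names
#'
#' Applies deterministic string cleaning (unicode NFC normalization,
#' whitespace collapse, trim) followed by an alias-map lookup to every
#' affiliation of every record. Duplicates created by merging distinct
#' spellings are collapsed, keeping first-occurrence order. The operation is
#' idempotent.
#'
#' @param records A trial-record tibble.
#' @param aliases Named character vector (raw -> canonical), e.g. from
#'   [read_alias_map()]. Canonical targets must be fixed points of the map.
#' @return The records with canonical affiliation lists.
#' @export
canonicalize <- function(records, aliases = character()) {
  map <- validate_alias_map(aliases)
  keys <- names(map)
  records$affiliations <- lapply(records$affiliations, function(affs) {
    cleaned <- clean_affiliation(affs)
    hit <- match(cleaned, keys)
    mapped <- ifelse(is.na(hit), cleaned, unname(map[hit]))
    unique(mapped[nzchar(mapped)])
  })
  records
}

#' Extract country names from a Locations cell
#'
#' Location entries are `|`-separated, each a comma-separated list whose
#' final token is the country. Duplicates are removed, keeping the order of
#' first occurrence.
#'
#' @param location_cell A single Locations string (may be empty or `NA`).
#' @return Character vector of country names.
#' @export
extract_countries <- function(location_cell) {
  entries <- split_multi(location_cell)[[1]]
  if (length(entries) == 0) {
    return(character())
  }
  countries <- vapply(strsplit(entries, ",", fixed = TRUE), function(parts) {
    trimws(parts[[length(parts)]])
  }, "")
  unique(countries[nzchar(countries)])
}

#' Filter records by condition keywords
#'
#' Keeps records where any keyword occurs (case-insensitive substring) in
#' the study title or in any listed condition. Used to carve disease-centric
#' subsets (e.g. diabetes, stroke) out of a mixed registry.
#'
#' @param records A trial-record tibble.
#' @param keywords Non-empty character vector of keywords.
#' @return The matching subset of `records`, in input order.
#' @export
filter_by_condition <- function(records, keywords) {
  if (length(keywords) == 0 || all(!nzchar(keywords))) {
    stop("'keywords' must be a non-empty character vector", call. = FALSE)
  }
  hit <- vapply(seq_len(nrow(records)), function(i) {
    hay <- c(records$title[[i]], records$conditions[[i]])
    any(vapply(keywords, function(k) {
      any(stringi::stri_detect_fixed(
        hay, k,
        opts_fixed = stringi::stri_opts_fixed(case_insensitive = TRUE)
      ))
    }, logical(1)))
  }, logical(1))
  records[hit, ]
}
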