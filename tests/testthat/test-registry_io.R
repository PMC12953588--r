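test_that("registry reader accepts the seven-field schema and parses rows", {
  path <- withr::local_tempfile(fileext = ".csv")

  # header-only export: schema accepted, zero records
  writeLines(paste(shQuote(registry_fields(), "cmd"), collapse = ","), path)
  recs <- read_registry(path)
  expect_equal(nrow(recs), 0)

  # crafted rows: delimiter split, sponsor-first affiliation order,
  # intervention categories, country extraction
  writeLines(c(
    paste(shQuote(registry_fields(), "cmd"), collapse = ","),
    paste0(
      '"NCT1","Pump study","Diabetes|Obesity",',
      '"DRUG: Insulin|Lifestyle counselling","C","A|B",',
      '"Boston, Massachusetts, United States|Seoul, Korea"'
    ),
    '"NCT2","Other","X","","S","",""',
    '"NCT3","Third","Y","DEVICE: Pump","S2","A","France"'
  ), path)
  recs <- read_registry(path)
  expect_equal(nrow(recs), 3)
  expect_equal(recs$affiliations[[1]], c("C", "A", "B"))
  expect_equal(recs$interventions[[1]]$category, c("DRUG", "OTHER"))
  expect_equal(recs$interventions[[1]]$name, c("Insulin", "Lifestyle counselling"))
  expect_equal(recs$countries[[1]], c("United States", "Korea"))
  expect_equal(recs$interventions[[2]], no_iv())
  expect_true(all(is.na(recs$year)))
})

test_that("registry reader rejects broken schemas", {
  path <- withr::local_tempfile(fileext = ".csv")

  file.create(path)
  expect_error(read_registry(path), "schema error")

  writeLines(c('"NCT Number","Study Title"', '"a","b"'), path)
  expect_error(read_registry(path), "Conditions")

  expect_error(read_registry(file.path(tempdir(), "nope.csv")), "Cannot read")
})

test_that("rows without affiliations are dropped with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    paste(shQuote(registry_fields(), "cmd"), collapse = ","),
    '"NCT1","t","c","","","",""',
    '"NCT2","t","c","","S","",""'
  ), path)
  expect_warning(recs <- read_registry(path), "no affiliation")
  expect_equal(recs$nct_id, "NCT2")
})

test_that("write_registry/read_registry round-trips records field by field", {
  gen <- generate_registry(synth_config(
    n_affiliations = 12, n_trials = 25, seed = 4
  ))
  path <- withr::local_tempfile(fileext = ".csv")
  write_registry(gen$records, path)
  back <- read_registry(path)
  expect_equal(back, gen$records)

  # and with no years: the date column is omitted and years stay NA
  recs <- mixed_fixture()
  recs$year <- NA_integer_
  write_registry(recs, path)
  back <- read_registry(path)
  expect_equal(back, recs)
})

test_that("canonicalize merges alias spellings and is idempotent", {
  recs <- make_records(
    make_record("N1", c("Harvard University Medical School", "B")),
    make_record("N2", c("Harvard  Medical   School", "C"))
  )
  aliases <- c("Harvard University Medical School" = "Harvard Medical School")
  out <- canonicalize(recs, aliases)
  expect_equal(out$affiliations[[1]][1], "Harvard Medical School")
  expect_equal(out$affiliations[[2]][1], "Harvard Medical School")

  # idempotent
  expect_equal(canonicalize(out, aliases), out)

  # empty map: only whitespace cleaning
  out2 <- canonicalize(recs)
  expect_equal(out2$affiliations[[2]][1], "Harvard Medical School")
  expect_equal(out2$affiliations[[1]][1], "Harvard University Medical School")

  # two raw names collapsing onto one canonical target deduplicate
  recs3 <- make_records(make_record("N1", c("X", "Y")))
  out3 <- canonicalize(recs3, c(X = "Z", Y = "Z"))
  expect_equal(out3$affiliations[[1]], "Z")
})

test_that("alias maps whose targets are not fixed points are rejected", {
  expect_error(
    canonicalize(mixed_fixture(), c(A = "B", B = "C")),
    "not canonical"
  )
  # a cycle is also a non-fixed-point target
  expect_error(
    canonicalize(mixed_fixture(), c(A = "B", B = "A")),
    "not canonical"
  )
})

test_that("alias maps load from TSV and JSON", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("raw\tcanonical", "Foo Hospital\tFoo University"), tsv)
  expect_equal(
    read_alias_map(tsv),
    c("Foo Hospital" = "Foo University")
  )
  js <- withr::local_tempfile(fileext = ".json")
  writeLines('{"Foo Hospital": "Foo University"}', js)
  expect_equal(read_alias_map(js), c("Foo Hospital" = "Foo University"))
})

test_that("extract_countries takes the final comma token per location", {
  expect_equal(
    extract_countries("Boston, Massachusetts, United States|Seoul, Korea"),
    c("United States", "Korea")
  )
  expect_equal(extract_countries(""), character())
  expect_equal(extract_countries("France"), "France")
  # duplicates keep first occurrence only
  expect_equal(
    extract_countries("Lyon, France|Paris, France|Seoul, Korea"),
    c("France", "Korea")
  )
})

test_that("condition filtering matches title or conditions, case-insensitive", {
  recs <- mixed_fixture()
  hits <- filter_by_condition(recs, "diabetes")
  expect_equal(hits$nct_id, c("NCT01", "NCT04"))

  expect_equal(nrow(filter_by_condition(recs, "oncology")), 0)

  # title-only match retained
  got <- filter_by_condition(recs, "stroke")
  expect_true("NCT05" %in% got$nct_id)

  # output is a subsequence of the input
  expect_true(all(diff(match(hits$nct_id, recs$nct_id)) > 0))

  expect_error(filter_by_condition(recs, character()), "non-empty")
})
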