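test_that("bulk TSV parsing yields one cell per row-year with values, missings and flags", {
  cells <- parse_eurostat_tsv(fixture_tsv(), "HLTH_CO_DISCH1T")

  itc4 <- cells[cells$geo == "ITC4" & cells$icd10 == "TOTAL", ]
  expect_equal(nrow(itc4), 2)
  expect_equal(itc4$value[itc4$year == 2017], 318)
  expect_equal(itc4$value[itc4$year == 2012], 342)
  expect_equal(unique(cells$dataset_code), "HLTH_CO_DISCH1T")

  # ":" keeps the cell with a missing value and empty flags
  es <- cells[cells$geo == "ES11" & cells$year == 2017, ]
  expect_equal(nrow(es), 1)
  expect_true(is.na(es$value))
  expect_identical(es$flags, "")

  # flag-suffixed token
  fl <- cells[cells$geo == "ITC4" & cells$icd10 == "CH01" & cells$year == 2017, ]
  expect_equal(fl$value, 580)
  expect_identical(fl$flags, "e")
})

test_that("malformed input raises errors naming the offending place", {
  expect_error(parse_eurostat_tsv("unit,geo\t2017\nNR,DE\t5", "X"), "line 1")
  expect_error(parse_eurostat_tsv("unit\\time\t2017\nNR\t5", "X"), "geo")
  expect_error(
    parse_eurostat_tsv("unit,geo\\time\t2017\nNR,DE11\tfoo", "X"),
    "row 1, column 2017"
  )
  expect_error(
    parse_eurostat_tsv("unit,geo\\time\t2017\nNR,DE11\t5 z", "X"),
    "flag"
  )
})

test_that("region filtering keeps the study frame and is idempotent", {
  cells <- tibble::tibble(
    dataset_code = "X",
    geo = c("ES63", "ES64", "ES11", "FRY40", "FRM0", "DE", "DE11", "IT", "ITC4", "PL11"),
    year = 2017L, value = 1, flags = ""
  )
  kept <- filter_regions(cells)
  expect_identical(kept$geo, c("ES11", "FRM0", "DE11", "ITC4"))
  # idempotent and order-preserving
  expect_identical(filter_regions(kept), kept)
  # empty result allowed
  expect_equal(nrow(filter_regions(cells[cells$geo == "PL11", ])), 0)
})

test_that("panel assembly builds complete records and reports skipped regions", {
  f <- tiny_cells()
  p <- tiny_panel()
  expect_s3_class(p, "bed_panel")
  expect_equal(nrow(p$regions), 2)
  expect_equal(nrow(p$specialties), 4)
  # totals equal the sum of specialty discharges in this complete fixture
  sums <- dplyr::summarise(p$specialties, s = sum(discharges), .by = "geo")
  expect_equal(sums$s[match(p$regions$geo, sums$geo)], p$regions$total_discharges)
  expect_equal(p$regions$coverage, c(1, 1))

  # a ":" AvLOS chapter: record retained, chapter absent, coverage < 1
  f2 <- f
  f2$avlos$value[f2$avlos$geo == "AA01" & f2$avlos$icd10 == "CH02"] <- NA
  p2 <- assemble_panel(f2$beds, f2$discharges, f2$avlos, f2$population)
  expect_equal(nrow(p2$regions), 2)
  expect_equal(sum(p2$specialties$geo == "AA01"), 1)
  expect_lt(p2$regions$coverage[p2$regions$geo == "AA01"], 1)

  # a region with missing beds is skipped and listed
  f3 <- f
  f3$beds$value[f3$beds$geo == "AA02"] <- NA
  p3 <- assemble_panel(f3$beds, f3$discharges, f3$avlos, f3$population)
  expect_equal(p3$regions$geo, "AA01")
  expect_equal(skipped_regions(p3)$geo, "AA02")
  expect_match(skipped_regions(p3)$reason, "beds")

  # no shared geo codes at all -> assembly error
  expect_error(
    assemble_panel(dplyr::mutate(f$beds, geo = c("ZZ01", "ZZ02")),
                   f$discharges, f$avlos, f$population),
    "no geo codes shared"
  )
})

test_that("multi-year assembly yields one record per region-year", {
  f <- tiny_cells()
  two <- function(d) dplyr::bind_rows(d, dplyr::mutate(d, year = 2012L))
  p <- assemble_panel(two(f$beds), two(f$discharges), two(f$avlos),
                      two(f$population))
  expect_equal(nrow(p$regions), 4)
  expect_setequal(p$regions$year, c(2012L, 2017L))
})

test_that("per-100k rate is a plain rescale with guarded domain", {
  expect_equal(per_100k(580, 1e5), 580)
  expect_equal(per_100k(0, 123), 0)
  expect_equal(per_100k(23200, 4e6), 580)
  expect_error(per_100k(1, 0), "population")
  expect_error(per_100k(-1, 10), "count")
})

test_that("write/parse round trip is the identity, including missings and flags", {
  cells <- parse_eurostat_tsv(fixture_tsv(), "X")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_eurostat_tsv(cells, path)
  again <- read_eurostat_tsv(path, "X")
  ord <- function(d) dplyr::arrange(d, geo, icd10, year)
  expect_equal(ord(again), ord(cells))
  # serialised missing uses the ":" sentinel, flags re-attached with a space
  txt <- readLines(path)
  expect_true(any(grepl("\t:", txt)))
  expect_true(any(grepl("580 e", txt, fixed = TRUE)))
})

test_that("round trip survives random full-precision values", {
  set.seed(11)
  cells <- tibble::tibble(
    dataset_code = "X", unit = "NR",
    geo = sprintf("AA%02d", 1:20), year = rep(c(2012L, 2017L), 10),
    value = runif(20, 1, 1e6), flags = ""
  )
  cells$value[3] <- NA
  cells$flags[5] <- "ep"
  path <- withr::local_tempfile(fileext = ".tsv")
  write_eurostat_tsv(cells, path)
  again <- read_eurostat_tsv(path, "X")
  ord <- function(d) dplyr::arrange(d, geo, year)
  expect_identical(ord(again)$value, ord(cells)$value)
  expect_identical(ord(again)$flags, ord(cells)$flags)
})

test_that("long CSV reader produces the same cell layout", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("geo,year,icd10,value\nDE11,2017,TOTAL,42\nDE12,2017,TOTAL,", path)
  cells <- read_eurostat_long_csv(path, "X")
  expect_equal(cells$value, c(42, NA))
  expect_identical(cells$flags, c("", ""))
})
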