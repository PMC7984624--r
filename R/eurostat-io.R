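# Reader/writer for the Eurostat bulk-download TSV dialect and panel assembly.
#
# Bulk files have a header whose first field is a comma-joined list of
# dimension names ending in "\time" (e.g. "unit,icd10,geo\time"); the
# remaining header fields are years.  Each data row starts with the
# comma-joined dimension codes and continues with one token per year:
# a number, optionally followed by single-letter flags ("580 e"), or the
# missing-value sentinel ":" (itself optionally flag-suffixed).

EUROSTAT_FLAGS <- c("b", "e", "p", "u", "d")

#' Parse an Eurostat bulk-download TSV extract
#'
#' Parses the tab-separated bulk dialect into a long tibble of cells, one row
#' per (dimension combination, year) with a non-empty token. Missing values
#' (`":"`) are retained as cells with `value = NA` so that downstream assembly
#' can distinguish "reported missing" from "absent row". Value flags
#' (b, e, p, u, d) are preserved in a `flags` column but never affect any
#' computation.
#'
#' @param text character: either a single string holding the whole file or a
#'   character vector of lines.
#' @param dataset_code identifier recorded in the `dataset_code` column
#'   (e.g. `"HLTH_RS_BDSRG"`).
#' @return A tibble with columns `dataset_code`, one column per dimension
#'   named in the header (always including `geo`), `year` (integer),
#'   `value` (double, `NA` when the token is `":"`) and `flags` (character,
#'   `""` when unflagged).
#' @seealso [read_eurostat_tsv()], [write_eurostat_tsv()]
#' @export
#' @examples
#' txt <- "unit,geo\\time\t2017\t2012\nNR,ITC4\t318\t342\nNR,ES11\t:\t120 e"
#' parse_eurostat_tsv(txt, "HLTH_RS_BDSRG")
parse_eurostat_tsv <- function(text, dataset_code) {
  stopifnot(is.character(text), length(text) >= 1)
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1) abort("empty input: no header line")

  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  dimfield <- trimws(header[[1]])
  if (!grepl("\\\\time$", dimfield)) {
    abort(sprintf("malformed header (line 1): first field %s does not end in '\\time'",
                  dQuote(dimfield)))
  }
  dims <- strsplit(sub("\\\\time$", "", dimfield), ",", fixed = TRUE)[[1]]
  dims <- trimws(dims)
  if (length(dims) == 0 || any(!nzchar(dims))) {
    abort("malformed header (line 1): empty dimension name")
  }
  if (!"geo" %in% dims) {
    abort("malformed header (line 1): no 'geo' dimension")
  }
  years <- suppressWarnings(as.integer(trimws(header[-1])))
  if (length(years) == 0 || anyNA(years)) {
    abort("malformed header (line 1): year columns must be integers")
  }

  body <- lines[-1]
  rows <- lapply(seq_along(body), function(i) {
    fields <- strsplit(body[[i]], "\t", fixed = TRUE)[[1]]
    codes <- trimws(strsplit(fields[[1]], ",", fixed = TRUE)[[1]])
    if (length(codes) != length(dims)) {
      abort(sprintf("row %d: expected %d dimension codes, got %d",
                    i, length(dims), length(codes)))
    }
    tokens <- trimws(fields[-1])
    length(tokens) <- length(years)  # pad short rows with NA (absent cells)
    keep <- !is.na(tokens) & nzchar(tokens)
    if (!any(keep)) return(NULL)
    parsed <- parse_value_tokens(tokens[keep], row = i, years = years[keep])
    out <- tibble::as_tibble(setNames(as.list(codes), dims))
    out <- out[rep(1, sum(keep)), , drop = FALSE]
    out$year <- years[keep]
    out$value <- parsed$value
    out$flags <- parsed$flags
    out
  })
  cells <- dplyr::bind_rows(rows)
  if (nrow(cells) == 0) {
    cells <- tibble::as_tibble(c(
      setNames(rep(list(character()), length(dims)), dims),
      list(year = integer(), value = double(), flags = character())
    ))
  }
  dplyr::bind_cols(tibble::tibble(dataset_code = rep(dataset_code, nrow(cells))), cells)
}

parse_value_tokens <- function(tokens, row, years) {
  m <- regmatches(tokens, regexec("^(:|[0-9]+\\.?[0-9]*(?:[eE][+-]?[0-9]+)?)(?: +([a-z]+))?$", tokens))
  bad <- vapply(m, length, 1L) == 0
  if (any(bad)) {
    j <- which(bad)[[1]]
    abort(sprintf("row %d, column %d: cannot parse value token %s",
                  row, years[[j]], dQuote(tokens[[j]])))
  }
  value <- vapply(m, function(g) if (g[[2]] == ":") NA_real_ else as.numeric(g[[2]]), 1)
  flags <- vapply(m, function(g) if (length(g) >= 3) g[[3]] else "", "")
  badflag <- vapply(strsplit(flags, ""), function(f) any(!f %in% EUROSTAT_FLAGS), TRUE)
  if (any(badflag)) {
    j <- which(badflag)[[1]]
    abort(sprintf("row %d, column %d: unknown flag in token %s",
                  row, years[[j]], dQuote(tokens[[j]])))
  }
  list(value = value, flags = flags)
}

#' Read an Eurostat bulk TSV file
#'
#' @param path file path.
#' @inheritParams parse_eurostat_tsv
#' @return A cell tibble; see [parse_eurostat_tsv()].
#' @export
read_eurostat_tsv <- function(path, dataset_code) {
  parse_eurostat_tsv(readLines(path, warn = FALSE), dataset_code)
}

#' Read a long-format CSV of cells
#'
#' Plain long export alternative to the bulk dialect: one row per cell with
#' columns `geo`, `year`, `value`, optional `flags` and any further dimension
#' columns.
#'
#' @inheritParams read_eurostat_tsv
#' @return A cell tibble; see [parse_eurostat_tsv()].
#' @export
read_eurostat_long_csv <- function(path, dataset_code) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(d, c("geo", "year", "value"), "long CSV")
  d$year <- as.integer(d$year)
  d$value <- as.numeric(d$value)
  if (!"flags" %in% names(d)) d$flags <- "" else d$flags[is.na(d$flags)] <- ""
  dplyr::bind_cols(tibble::tibble(dataset_code = rep(dataset_code, nrow(d))), d)
}

#' Write cells back to the Eurostat bulk TSV dialect
#'
#' Inverse of [parse_eurostat_tsv()]: writing then re-parsing reproduces the
#' cell list (missing values as `":"`, flags re-attached after the value with
#' a single space). Values are written with 15 significant digits so numeric
#' round trips are lossless at double precision.
#'
#' @param cells cell tibble from [parse_eurostat_tsv()] (one dataset: a single
#'   `dataset_code` and a common dimension set; no `NA` dimension codes).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_eurostat_tsv <- function(cells, path) {
  assert_cols(cells, c("dataset_code", "geo", "year", "value", "flags"), "cells")
  if (length(unique(cells$dataset_code)) > 1) {
    abort("cells span more than one dataset_code")
  }
  dims <- setdiff(names(cells), c("dataset_code", "year", "value", "flags"))
  if (anyNA(cells[dims])) abort("NA dimension code: heterogeneous dimension sets")

  key <- do.call(paste, c(cells[dims], sep = ","))
  years <- sort(unique(cells$year), decreasing = TRUE)
  rows <- unique(key)
  tok <- matrix("", nrow = length(rows), ncol = length(years),
                dimnames = list(rows, as.character(years)))
  val <- ifelse(is.na(cells$value), ":", formatC(cells$value, digits = 17, format = "g"))
  val <- ifelse(nzchar(cells$flags), paste(val, cells$flags), val)
  tok[cbind(match(key, rows), match(cells$year, years))] <- val

  header <- paste(c(paste0(paste(dims, collapse = ","), "\\time"), years), collapse = "\t")
  body <- vapply(seq_along(rows), function(i) {
    paste(c(rows[[i]], tok[i, ]), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Region inclusion rules
#'
#' Configuration object for [filter_regions()]. The defaults reproduce the
#' four-country study frame: all German and Italian NUTS-2 regions, Spanish
#' regions without the autonomous cities of Ceuta (ES63) and Melilla (ES64),
#' and French regions without the overseas territories (geo prefix `FRY`
#' under the NUTS-2016 classification), Corse retained. National aggregates
#' (2-letter geo codes) are always dropped.
#'
#' @param countries 2-letter country codes to retain.
#' @param exclude_geo exact geo codes to drop.
#' @param exclude_prefixes geo prefixes to drop (overseas region blocks).
#' @param nuts_vintage label of the NUTS classification the codes refer to;
#'   metadata only, recorded because NUTS revisions renumber regions.
#' @return A list of class `region_filter`.
#' @export
region_filter <- function(countries = c("DE", "ES", "FR", "IT"),
                          exclude_geo = c("ES63", "ES64"),
                          exclude_prefixes = "FRY",
                          nuts_vintage = "NUTS-2016") {
  stopifnot(is.character(countries), all(nchar(countries) == 2))
  structure(list(countries = countries, exclude_geo = exclude_geo,
                 exclude_prefixes = exclude_prefixes,
                 nuts_vintage = nuts_vintage),
            class = "region_filter")
}

#' Filter cells to the study's NUTS-2 regions
#'
#' Keeps only NUTS-2 geo codes (length 4) of the configured countries,
#' dropping excluded codes/prefixes and national aggregates. Idempotent and
#' order-preserving; an empty result is allowed.
#'
#' @param cells cell tibble (needs a `geo` column).
#' @param rules a [region_filter()] object.
#' @return The filtered cell tibble.
#' @export
filter_regions <- function(cells, rules = region_filter()) {
  assert_cols(cells, "geo", "cells")
  stopifnot(inherits(rules, "region_filter"))
  geo <- cells$geo
  keep <- nchar(geo) == 4 &
    substr(geo, 1, 2) %in% rules$countries &
    !geo %in% rules$exclude_geo
  for (p in rules$exclude_prefixes) keep <- keep & !startsWith(geo, p)
  cells[keep, , drop = FALSE]
}

#' Rate per 100,000 inhabitants
#'
#' @param count non-negative numeric vector.
#' @param population positive numeric vector (inhabitants).
#' @return `1e5 * count / population`.
#' @export
#' @examples
#' per_100k(23200, 4e6)
per_100k <- function(count, population) {
  stopifnot(is.numeric(count), is.numeric(population))
  if (any(population <= 0, na.rm = TRUE)) abort("population must be > 0")
  if (any(count < 0, na.rm = TRUE)) abort("count must be >= 0")
  1e5 * count / population
}

#' Assemble a region-year panel from Eurostat cells
#'
#' Joins bed stocks, per-diagnosis discharges and per-diagnosis average
#' lengths of stay into one record per (geo, year). The all-diagnoses totals
#' (diagnosis code `total_code`) populate `total_discharges`/`total_avlos`;
#' every other diagnosis code becomes a specialty row when *both* its
#' discharge count and AvLOS are present. Regions missing beds, population or
#' either total are skipped and reported, never silently invented.
#'
#' @param beds cell tibble of bed counts (`geo`, `year`, `value`).
#' @param discharges cell tibble of discharges with a diagnosis dimension
#'   column (default name `icd10`).
#' @param avlos cell tibble of average lengths of stay, same layout as
#'   `discharges`.
#' @param population data frame with `geo`, `year`, `population`.
#' @param years integer years to assemble; default all years seen in `beds`.
#' @param total_code diagnosis code of the all-diagnoses aggregate.
#' @param diag_col name of the diagnosis dimension column.
#' @return An object of class `bed_panel`: a list with
#'   * `regions` — tibble `geo`, `country`, `year`, `population`, `beds`,
#'     `total_discharges`, `total_avlos`, `coverage` (fraction of total
#'     discharges carried by the attached specialty rows);
#'   * `specialties` — tibble `geo`, `year`, `specialty`, `discharges`,
#'     `avlos`;
#'   and an attribute `skipped`, a tibble of dropped (geo, year) pairs with
#'   reasons.
#' @export
assemble_panel <- function(beds, discharges, avlos, population,
                           years = NULL, total_code = "TOTAL",
                           diag_col = "icd10") {
  assert_cols(beds, c("geo", "year", "value"), "beds")
  assert_cols(discharges, c("geo", "year", "value", diag_col), "discharges")
  assert_cols(avlos, c("geo", "year", "value", diag_col), "avlos")
  assert_cols(population, c("geo", "year", "population"), "population")
  years <- years %||% sort(unique(beds$year))

  common <- intersect(beds$geo, intersect(discharges$geo, avlos$geo))
  if (length(common) == 0) abort("assembly error: no geo codes shared by beds, discharges and avlos")

  grid <- tidyr::expand_grid(geo = sort(unique(common)), year = as.integer(years))

  pick <- function(cells, nm) {
    cells %>%
      dplyr::filter(!is.na(.data$value)) %>%
      dplyr::distinct(.data$geo, .data$year, .keep_all = TRUE) %>%
      dplyr::select("geo", "year", !!nm := "value")
  }
  tot_d <- pick(dplyr::filter(discharges, .data[[diag_col]] == total_code), "total_discharges")
  tot_a <- pick(dplyr::filter(avlos, .data[[diag_col]] == total_code), "total_avlos")

  regions <- grid %>%
    dplyr::left_join(pick(beds, "beds"), by = c("geo", "year")) %>%
    dplyr::left_join(dplyr::select(population, "geo", "year", "population"),
                     by = c("geo", "year")) %>%
    dplyr::left_join(tot_d, by = c("geo", "year")) %>%
    dplyr::left_join(tot_a, by = c("geo", "year"))

  reason <- dplyr::case_when(
    is.na(regions$beds) ~ "missing beds",
    is.na(regions$population) ~ "missing population",
    is.na(regions$total_discharges) ~ "missing total discharges",
    is.na(regions$total_avlos) ~ "missing total AvLOS",
    TRUE ~ NA_character_
  )
  skipped <- tibble::tibble(geo = regions$geo, year = regions$year,
                            reason = reason)[!is.na(reason), ]
  regions <- regions[is.na(reason), , drop = FALSE]

  spec <- dplyr::inner_join(
    dplyr::filter(discharges, .data[[diag_col]] != total_code, !is.na(.data$value)) %>%
      dplyr::select("geo", "year", specialty = !!diag_col, discharges = "value"),
    dplyr::filter(avlos, .data[[diag_col]] != total_code, !is.na(.data$value)) %>%
      dplyr::select("geo", "year", specialty = !!diag_col, avlos = "value"),
    by = c("geo", "year", "specialty")
  ) %>%
    dplyr::semi_join(regions, by = c("geo", "year")) %>%
    dplyr::arrange(.data$geo, .data$year, .data$specialty)

  cov <- spec %>%
    dplyr::summarise(spec_discharges = sum(.data$discharges), .by = c("geo", "year"))
  regions <- regions %>%
    dplyr::left_join(cov, by = c("geo", "year")) %>%
    dplyr::mutate(
      country = substr(.data$geo, 1, 2),
      coverage = dplyr::coalesce(.data$spec_discharges, 0) / .data$total_discharges
    ) %>%
    dplyr::select("geo", "country", "year", "population", "beds",
                  "total_discharges", "total_avlos", "coverage") %>%
    dplyr::arrange(.data$geo, .data$year)

  new_bed_panel(regions, spec, skipped)
}

new_bed_panel <- function(regions, specialties, skipped = NULL) {
  structure(
    list(regions = tibble::as_tibble(regions),
         specialties = tibble::as_tibble(specialties)),
    skipped = skipped %||% tibble::tibble(geo = character(), year = integer(),
                                          reason = character()),
    class = "bed_panel"
  )
}

#' @export
print.bed_panel <- function(x, ...) {
  cat(sprintf("<bed_panel> %d region-years, %d specialty rows, %d skipped\n",
              nrow(x$regions), nrow(x$specialties), nrow(attr(x, "skipped"))))
  print(x$regions, n = 5)
  invisible(x)
}

#' Skip report of a panel assembly
#'
#' @param panel a `bed_panel`.
#' @return Tibble of skipped (geo, year) pairs with reasons.
#' @export
skipped_regions <- function(panel) {
  stopifnot(inherits(panel, "bed_panel"))
  attr(panel, "skipped")
}
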