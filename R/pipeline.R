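# End-to-end pipeline: ingest -> indicators -> zone -> CMI/PI quadrant ->
# combined cell -> per-country summaries, plus report writing and the
# region-level reproduction comparison. Deterministic given inputs and
# configuration; every reported number traces to one operation of the other
# modules (the report layer only formats).

#' Run the full regional efficiency pipeline
#'
#' Takes a panel (or the file paths to build one), computes bed-management
#' indicators, Barber-Johnson zones with centroid distances, CMI/PI with
#' quadrants scored against the pooled per-year benchmark, the combined
#' 12-cell classification, per-country distributions, and (when two or more
#' years are present) per-region percent changes of the per-100k bed rate.
#'
#' @param panel a `bed_panel`, a `synthetic_panel`, or a directory written by
#'   [export_fixture()].
#' @param thresholds an [efficiency_thresholds()] object.
#' @param distance_mode `"raw"` or `"band"` (see [centroid_distance()]).
#' @param benchmark optional fixed [build_benchmark()] object; default pools
#'   one per year from the panel's specialty table.
#' @param mode occupied-day derivation, `"specialty"` or `"total"`
#'   (see [panel_indicators()]).
#' @param period_days days in the accounting period.
#' @param rules optional [region_filter()] applied when `panel` is a
#'   directory.
#' @param change_years length-2 years for the change analysis; default the
#'   earliest and latest year in the panel.
#' @return A list of class `bedbench_report`:
#'   `classification` (per region-year: indicators, zone, distance, cmi, pi,
#'   quadrant, ratio, coverage, cell), `zone_distribution`,
#'   `quadrant_distribution`, `cell_distribution`, `spans` (per-country
#'   min/max of per-100k beds, per year), `changes` and
#'   `increasing_regions` (when >= 2 years), `benchmarks` (per year),
#'   `skipped`, and the `panel`.
#' @export
run_pipeline <- function(panel,
                         thresholds = efficiency_thresholds(),
                         distance_mode = c("raw", "band"),
                         benchmark = NULL,
                         mode = c("specialty", "total"),
                         period_days = 365,
                         rules = NULL,
                         change_years = NULL) {
  distance_mode <- match.arg(distance_mode)
  mode <- match.arg(mode)
  if (is.character(panel)) panel <- read_fixture(panel, rules = rules)
  if (inherits(panel, "synthetic_panel")) panel <- panel$panel
  stopifnot(inherits(panel, "bed_panel"))
  if (nrow(panel$regions) == 0) abort("pipeline error (ingest): empty panel")

  ind <- panel_indicators(panel, mode = mode, period_days = period_days)
  bj <- classify_bj(ind, thresholds, distance_mode)
  cm <- casemix_indices(panel$specialties, benchmark = benchmark,
                        total_discharges = dplyr::select(
                          panel$regions, "geo", "year", "total_discharges"))
  cls <- bj %>%
    dplyr::left_join(cm, by = c("geo", "year")) %>%
    dplyr::mutate(beds_per_100k = per_100k(.data$beds, .data$population))
  if (anyNA(cls$cmi)) {
    abort("pipeline error (casemix): regions without specialty data; check the skip report")
  }
  cls <- classify_overall(cls)

  years <- sort(unique(cls$year))
  benchmarks <- if (is.null(benchmark)) {
    setNames(lapply(years, function(y) {
      build_benchmark(panel$specialties[panel$specialties$year == y, ])
    }), years)
  } else {
    list(fixed = benchmark)
  }

  spans <- cls %>%
    dplyr::group_by(.data$country, .data$year) %>%
    country_span(value = "beds_per_100k", region = "geo")

  changes <- NULL; increasing <- NULL
  if (length(years) >= 2) {
    cy <- change_years %||% range(years)
    wide <- cls %>%
      dplyr::filter(.data$year %in% cy) %>%
      dplyr::select("geo", "country", "year", "beds_per_100k") %>%
      tidyr::pivot_wider(names_from = "year", values_from = "beds_per_100k",
                         names_prefix = "y")
    old <- wide[[paste0("y", cy[1])]]; new <- wide[[paste0("y", cy[2])]]
    ok <- !is.na(old) & !is.na(new)
    changes <- tibble::tibble(
      geo = wide$geo[ok], country = wide$country[ok],
      old = old[ok], new = new[ok],
      change_pct = percent_change(old[ok], new[ok]),
      change_pct_reported = percent_change(old[ok], new[ok], rounded = TRUE)
    )
    increasing <- count_increasing(cls, value = "beds_per_100k", years = cy)
  }

  dist_by_year <- function(by) {
    purrr::map_dfr(years, function(y) {
      dplyr::mutate(country_distribution(cls[cls$year == y, ], by),
                    year = y, .before = 1)
    })
  }

  structure(
    list(
      classification = cls,
      zone_distribution = dist_by_year("zone"),
      quadrant_distribution = dist_by_year("quadrant"),
      cell_distribution = dist_by_year("cell"),
      spans = spans,
      changes = changes,
      increasing_regions = increasing,
      benchmarks = benchmarks,
      skipped = skipped_regions(panel),
      panel = panel,
      settings = list(thresholds = thresholds, distance_mode = distance_mode,
                      mode = mode, period_days = period_days)
    ),
    class = "bedbench_report"
  )
}

#' @export
print.bedbench_report <- function(x, ...) {
  cat(sprintf("<bedbench_report> %d region-years, years: %s\n",
              nrow(x$classification),
              paste(sort(unique(x$classification$year)), collapse = ", ")))
  print(table(zone = x$classification$zone,
              quadrant = x$classification$quadrant))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits the per-region classification, the three per-country distribution
#' tables, spans, changes and benchmarks as CSV, the skip report and a run
#' summary as JSON, and optionally the two diagrams as PNG.
#'
#' @param report a `bedbench_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @param figures also render `bj_diagram.png` and `quadrant_diagram.png`?
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir, figures = FALSE) {
  stopifnot(inherits(report, "bedbench_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  put <- function(d, name) {
    p <- file.path(dir, name)
    readr::write_csv(d, p)
    files <<- c(files, p)
  }
  put(report$classification, "classification.csv")
  put(report$zone_distribution, "country_zone.csv")
  put(report$quadrant_distribution, "country_quadrant.csv")
  put(report$cell_distribution, "country_cell.csv")
  put(report$spans, "country_spans.csv")
  if (!is.null(report$changes)) put(report$changes, "changes.csv")
  if (!is.null(report$increasing_regions)) {
    put(report$increasing_regions, "increasing_regions.csv")
  }
  for (y in names(report$benchmarks)) {
    put(tidy(report$benchmarks[[y]]), sprintf("benchmark_%s.csv", y))
  }
  p <- file.path(dir, "skip_report.json")
  jsonlite::write_json(report$skipped, p, dataframe = "rows")
  files <- c(files, p)
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(list(
    n_region_years = nrow(report$classification),
    years = sort(unique(report$classification$year)),
    zone_counts = as.list(table(report$classification$zone)),
    quadrant_counts = as.list(table(report$classification$quadrant))
  ), p, auto_unbox = TRUE)
  files <- c(files, p)
  if (figures) {
    fig <- function(plot, name) {
      p <- file.path(dir, name)
      ok <- tryCatch({
        grDevices::png(p, width = 1400, height = 1000, res = 150)
        print(plot)
        grDevices::dev.off()
        TRUE
      }, error = function(e) {
        warn(sprintf("could not render %s: %s", name, conditionMessage(e)))
        FALSE
      })
      if (ok) files <<- c(files, p)
    }
    fig(plot_bj(report$classification, report$settings$thresholds,
                report$settings$period_days), "bj_diagram.png")
    fig(plot_quadrants(report$classification), "quadrant_diagram.png")
  }
  invisible(files)
}

#' Read a pipeline configuration file
#'
#' YAML (if the yaml package is available) or JSON. Recognised fields:
#' `thresholds` (any of the [efficiency_thresholds()] arguments),
#' `distance_mode`, `mode`, `period_days`, `filter` (any of the
#' [region_filter()] arguments) and `change_years`.
#'
#' @param path configuration file.
#' @return A named list ready to splice into [run_pipeline()]:
#'   `thresholds`, `distance_mode`, `mode`, `period_days`, `rules`,
#'   `change_years`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading YAML configuration requires the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  out <- list(
    thresholds = do.call(efficiency_thresholds, raw$thresholds %||% list()),
    distance_mode = raw$distance_mode %||% "raw",
    mode = raw$mode %||% "specialty",
    period_days = raw$period_days %||% 365,
    rules = if (is.null(raw$filter)) NULL else {
      do.call(region_filter, lapply(raw$filter, unlist))
    },
    change_years = raw$change_years
  )
  out
}

#' Compare computed classifications against reference labels
#'
#' Reproduction helper for checking a pipeline run against externally
#' published per-region labels or per-country counts. Reports match and
#' mismatch per region (and a per-country count comparison) without ever
#' hard-failing on disagreement — reference extracts get revised, so the
#' comparison is a report, not an assertion.
#'
#' @param observed data frame with `geo` (or `country`) and the compared
#'   column.
#' @param expected data frame with the same identifier and column; `NA`
#'   expected values are reported as `"unverified"`.
#' @param column name of the compared classification column (e.g. `"zone"`).
#' @return A list with `regions` (identifier, observed, expected, status:
#'   match / mismatch / unverified / missing) and `summary` (counts of each
#'   status).
#' @export
compare_region_classifications <- function(observed, expected, column = "zone") {
  id <- if ("geo" %in% names(observed) && "geo" %in% names(expected)) "geo" else "country"
  assert_cols(observed, c(id, column), "observed")
  assert_cols(expected, c(id, column), "expected")
  m <- dplyr::full_join(
    dplyr::select(tibble::as_tibble(observed), dplyr::all_of(id),
                  observed = dplyr::all_of(column)),
    dplyr::select(tibble::as_tibble(expected), dplyr::all_of(id),
                  expected = dplyr::all_of(column)),
    by = id
  ) %>%
    dplyr::mutate(
      observed = as.character(.data$observed),
      expected = as.character(.data$expected),
      status = dplyr::case_when(
        is.na(.data$observed) ~ "missing",
        is.na(.data$expected) ~ "unverified",
        .data$observed == .data$expected ~ "match",
        TRUE ~ "mismatch"
      )
    )
  list(
    regions = m,
    summary = dplyr::count(m, .data$status, name = "n")
  )
}
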