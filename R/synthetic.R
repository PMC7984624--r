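# Seeded generator of multi-country regional panels with known ground truth.
#
# Placement works backwards through the pipeline's own algebra:
#   * a (BOR, TOI) pair sampled inside the open box of the intended zone is
#     inverted exactly into discharges and AvLOS (invert_indicators);
#   * a (CMI, PI) pair sampled on the intended side of 1 is inverted into a
#     specialty profile against a fixed reference benchmark -- PI by uniform
#     AvLOS scaling (exact, PI is linear in the structure AvLOS), CMI by an
#     exponential tilt of the discharge shares solved by bisection.
# The two placements are coupled: a profile hitting (cmi, pi) has overall
# AvLOS = cmi * pi * overall_ref_avlos, which must equal the AvLOS implied
# by (bor, toi, beds). The sampler therefore draws (cmi, pi) first and
# rejects (bor, toi) candidates until the implied TOI lands in the intended
# band. A margin keeps every coordinate off the strict-inequality
# boundaries, so labels cannot flip on re-ingestion.

#' Configuration of the synthetic panel generator
#'
#' Defaults emulate the four-country study frame: region counts per country
#' as in the study (Germany 16, Spain 19, France 22, Italy 21), two
#' reference years, a zone mix close to the published distribution (about
#' 45% of regions in the efficient zone, 35% with both indicators outside
#' their bands) and a uniform quadrant mix. Bed rates and populations span
#' the ranges reported for European NUTS-2 regions.
#'
#' @param countries named integer vector: regions per 2-letter country code.
#' @param years integer vector of panel years.
#' @param zone_mix named proportions over GREEN/YELLOW/RED zones (sum 1).
#' @param quadrant_mix named proportions over GREEN/YELLOW/ORANGE/RED
#'   quadrants (sum 1).
#' @param beds_per_100k_range interval for the per-100k bed rate.
#' @param population_range interval for region population (inhabitants).
#' @param n_specialties number of specialty (ICD-chapter-like) groups, >= 2.
#' @param noise_sd sdlog of multiplicative lognormal noise applied to
#'   specialty discharges and AvLOS after placement (0 = exact placement).
#' @param seed integer seed driving all sampling.
#' @param margin half-width kept between sampled coordinates and the strict
#'   zone boundaries (days for TOI, occupancy fraction for BOR).
#' @param index_margin distance kept between sampled CMI/PI targets and the
#'   quadrant threshold at 1.
#' @param period_days days in the accounting period.
#' @param thresholds an [efficiency_thresholds()] object.
#' @param ref_avlos reference AvLOS per specialty (default evenly spaced
#'   from 3 to 12 days, the range of typical ICD-chapter mean stays).
#' @param ref_shares reference discharge shares (default uniform).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(countries = c(DE = 16, ES = 19, FR = 22, IT = 21),
                             years = c(2012, 2017),
                             zone_mix = c(GREEN = 0.45, YELLOW = 0.20, RED = 0.35),
                             quadrant_mix = c(GREEN = 0.25, YELLOW = 0.25,
                                              ORANGE = 0.25, RED = 0.25),
                             beds_per_100k_range = c(250, 900),
                             population_range = c(5e5, 8e6),
                             n_specialties = 10,
                             noise_sd = 0,
                             seed = 1,
                             margin = 1e-3,
                             index_margin = 0.04,
                             period_days = 365,
                             thresholds = efficiency_thresholds(),
                             ref_avlos = NULL,
                             ref_shares = NULL) {
  stopifnot(length(countries) >= 1, all(countries >= 1),
            !is.null(names(countries)), all(nchar(names(countries)) == 2))
  if (abs(sum(zone_mix) - 1) > 1e-8 || abs(sum(quadrant_mix) - 1) > 1e-8) {
    abort("zone_mix and quadrant_mix must each sum to 1")
  }
  if (!identical(sort(names(zone_mix)), sort(bj_zone_levels)) ||
      !identical(sort(names(quadrant_mix)), sort(quadrant_levels))) {
    abort("zone_mix must be named GREEN/YELLOW/RED and quadrant_mix GREEN/YELLOW/ORANGE/RED")
  }
  stopifnot(n_specialties >= 2, noise_sd >= 0, margin > 0, index_margin > 0,
            all(beds_per_100k_range > 0), all(population_range > 0),
            diff(beds_per_100k_range) >= 0, diff(population_range) >= 0)
  ref_avlos <- ref_avlos %||% seq(3, 12, length.out = n_specialties)
  ref_shares <- ref_shares %||% rep(1 / n_specialties, n_specialties)
  stopifnot(length(ref_avlos) == n_specialties,
            length(ref_shares) == n_specialties,
            all(ref_avlos > 0), all(ref_shares > 0))
  ref_shares <- ref_shares / sum(ref_shares)
  structure(
    list(countries = countries, years = as.integer(years),
         zone_mix = zone_mix[bj_zone_levels],
         quadrant_mix = quadrant_mix[quadrant_levels],
         beds_per_100k_range = beds_per_100k_range,
         population_range = population_range,
         n_specialties = as.integer(n_specialties),
         noise_sd = noise_sd, seed = as.integer(seed),
         margin = margin, index_margin = index_margin,
         period_days = period_days, thresholds = thresholds,
         ref_avlos = ref_avlos, ref_shares = ref_shares),
    class = "synthetic_config"
  )
}

# The generator's fixed reference benchmark (not the pooled panel benchmark).
reference_benchmark <- function(cfg) {
  build_benchmark(tibble::tibble(
    specialty = sprintf("CH%02d", seq_len(cfg$n_specialties)),
    discharges = cfg$ref_shares * 1e6,
    avlos = cfg$ref_avlos
  ))
}

#' Place a region at exact diagram coordinates
#'
#' Thin wrapper over [invert_indicators()] returning the activity fragment
#' that reproduces the requested occupancy and turnover interval exactly.
#'
#' @inheritParams invert_indicators
#' @return One-row tibble: `bor`, `toi`, `beds`, `discharges`, `avlos`,
#'   `occupied_days`.
#' @export
#' @examples
#' gen_region_at(0.80, 2, beds = 100)
gen_region_at <- function(bor, toi, beds, period_days = 365) {
  inv <- invert_indicators(bor, toi, beds, period_days)
  dplyr::bind_cols(tibble::tibble(bor = bor, toi = toi, beds = beds), inv)
}

#' Specialty profile hitting CMI and PI targets
#'
#' Inverts the two indices against a benchmark. The PI target is hit exactly
#' by uniform scaling (`avlos_j = pi_target * ref_avlos_j`; PI is linear in
#' the structure AvLOS). The CMI target is hit by exponentially tilting the
#' benchmark shares, `w_j(theta) ~ ref_share_j * exp(theta * ref_avlos_j)`;
#' the tilted CMI is continuous and strictly increasing in `theta`, so plain
#' bisection converges.
#'
#' @param benchmark a [build_benchmark()] object.
#' @param cmi_target target Case-Mix Index; must lie strictly inside the
#'   attainable interval `range(ref_avlos) / overall_ref_avlos`.
#' @param pi_target target Performance Index, > 0 (hit exactly).
#' @param tol absolute tolerance on the achieved CMI (default 1e-6).
#' @param max_steps bisection step budget (default 60).
#' @return Tibble `specialty`, `share` (sums to 1), `avlos`, with attributes
#'   `theta`, `steps` and `cmi_achieved`.
#' @export
#' @examples
#' b <- build_benchmark(tibble::tibble(specialty = c("A", "B"),
#'                                     discharges = c(500, 500),
#'                                     avlos = c(4, 10)))
#' gen_specialty_profile(b, cmi_target = 8.8 / 7, pi_target = 1)
gen_specialty_profile <- function(benchmark, cmi_target, pi_target,
                                  tol = 1e-6, max_steps = 60) {
  stopifnot(inherits(benchmark, "bed_benchmark"),
            is.numeric(cmi_target), length(cmi_target) == 1,
            is.numeric(pi_target), length(pi_target) == 1, pi_target > 0,
            tol > 0)
  b <- tidy(benchmark)
  a <- b$ref_avlos; s <- b$ref_share
  overall <- overall_ref_avlos(benchmark)
  lo_b <- min(a) / overall; hi_b <- max(a) / overall
  if (cmi_target <= lo_b || cmi_target >= hi_b) {
    abort(sprintf("cmi_target %.6g outside the attainable open interval (%.6g, %.6g)",
                  cmi_target, lo_b, hi_b))
  }

  tilt_shares <- function(theta) {
    w <- s * exp(theta * (a - max(a)))
    w / sum(w)
  }
  cmi_at <- function(theta) sum(tilt_shares(theta) * a) / overall

  steps <- 0L
  if (abs(cmi_at(0) - cmi_target) <= tol) {
    theta <- 0
  } else {
    lo <- -1; hi <- 1
    while (cmi_at(hi) < cmi_target && hi < 2^40) hi <- hi * 2
    while (cmi_at(lo) > cmi_target && lo > -2^40) lo <- lo * 2
    theta <- NA_real_
    for (k in seq_len(max_steps)) {
      mid <- (lo + hi) / 2
      steps <- k
      fm <- cmi_at(mid)
      if (abs(fm - cmi_target) <= tol) { theta <- mid; break }
      if (fm < cmi_target) lo <- mid else hi <- mid
    }
    if (is.na(theta)) {
      abort(sprintf("bisection did not reach |CMI - target| <= %g in %d steps",
                    tol, max_steps))
    }
  }
  out <- tibble::tibble(specialty = b$specialty,
                        share = tilt_shares(theta),
                        avlos = pi_target * a)
  attr(out, "theta") <- theta
  attr(out, "steps") <- steps
  attr(out, "cmi_achieved") <- cmi_at(theta)
  out
}

# Sample one region's (cmi, pi, bor, toi) for an intended (zone, quadrant).
# Rejection over the coupling constraint toi = cmi*pi*overall*(1-bor)/bor.
sample_placement <- function(zone, quadrant, cfg, overall, max_tries = 10000) {
  t <- cfg$thresholds; m <- cfg$margin; im <- cfg$index_margin
  box <- function(lohi) runif(1, lohi[1], lohi[2])
  cmi_box <- function(high) if (high) c(1 + im, 1.25) else c(0.80, 1 - im)
  pi_box <- cmi_box
  bor_in_box <- c(t$bor_low + m, t$bor_high - m)
  bor_out <- function() {
    if (runif(1) < 0.5) c(max(0.45, t$bor_low - 0.20), t$bor_low - m)
    else c(t$bor_high + m, min(0.97, t$bor_high + 0.12))
  }
  toi_in <- function(x) x > t$toi_low + m && x < t$toi_high - m
  toi_out <- function(x) (x >= 0.15 && x <= t$toi_low - m) ||
    (x >= t$toi_high + m && x <= 12)

  for (i in seq_len(max_tries)) {
    cmi <- box(cmi_box(quadrant %in% c("GREEN", "ORANGE")))
    pi <- box(pi_box(quadrant %in% c("ORANGE", "RED")))
    A <- cmi * pi * overall
    want_bor_in <- switch(zone, GREEN = TRUE, RED = FALSE,
                          YELLOW = runif(1) < 0.5)
    want_toi_in <- if (zone == "YELLOW") !want_bor_in else zone == "GREEN"
    bor <- if (want_bor_in) box(bor_in_box) else box(bor_out())
    toi <- A * (1 - bor) / bor
    ok <- if (want_toi_in) toi_in(toi) else toi_out(toi)
    if (ok) return(list(cmi = cmi, pi = pi, bor = bor, toi = toi))
  }
  abort(sprintf("could not place a region in zone %s / quadrant %s after %d tries",
                zone, quadrant, max_tries))
}

#' Generate a synthetic multi-country panel with ground truth
#'
#' Draws one region set per [synthetic_config()] and places every
#' region-year at exact, known coordinates. Zone labels are stratified to
#' the configured mix by largest-remainder apportionment (exact per zone);
#' quadrant labels are apportioned within each zone, so every zone x
#' quadrant cell is populated once counts allow. The ground-truth table
#' records both the intended labels and the labels implied by the finished
#' panel itself (indicators recomputed from the data; CMI/PI scored against
#' the panel's own pooled per-year benchmark, exactly as the pipeline will) —
#' with `noise_sd = 0` the two coincide, with noise the re-derived labels
#' are authoritative.
#'
#' @param cfg a [synthetic_config()].
#' @return A list of class `synthetic_panel`: `panel` (a `bed_panel`),
#'   `truth` (tibble with intended and achieved coordinates and labels per
#'   region-year) and `config`.
#' @export
#' @examples
#' sp <- gen_panel(synthetic_config(countries = c(AA = 6, BB = 6),
#'                                  years = 2017, seed = 42))
#' table(sp$truth$zone)
gen_panel <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  refb <- reference_benchmark(cfg)
  overall <- overall_ref_avlos(refb)
  geo <- unlist(lapply(names(cfg$countries), function(cc) {
    sprintf("%s%02d", cc, seq_len(cfg$countries[[cc]]))
  }), use.names = FALSE)
  n <- length(geo)

  zone_counts <- largest_remainder(cfg$zone_mix, n)
  labels <- purrr::map2_dfr(bj_zone_levels, zone_counts, function(z, nz) {
    qc <- largest_remainder(cfg$quadrant_mix, nz)
    tibble::tibble(zone = z, quadrant = rep(quadrant_levels, qc))
  })

  regions <- list(); specs <- list(); truth <- list()
  for (y in cfg$years) {
    lab <- labels[sample.int(n), , drop = FALSE]
    for (i in seq_len(n)) {
      pl <- sample_placement(lab$zone[i], lab$quadrant[i], cfg, overall)
      population <- runif(1, cfg$population_range[1], cfg$population_range[2])
      per100k <- runif(1, cfg$beds_per_100k_range[1], cfg$beds_per_100k_range[2])
      beds <- population * per100k / 1e5
      inv <- invert_indicators(pl$bor, pl$toi, beds, cfg$period_days)
      prof <- gen_specialty_profile(refb, pl$cmi, pl$pi)
      d_j <- inv$discharges * prof$share
      # rescale stays so the share-weighted total equals the placed AvLOS
      # exactly (the bisection residual on CMI would otherwise leak into TOI)
      a_j <- prof$avlos * pl$cmi / attr(prof, "cmi_achieved")
      if (cfg$noise_sd > 0) {
        # truncated noise: occupied days may not exceed bed capacity
        cap <- beds * cfg$period_days
        for (try in 1:100) {
          nd <- d_j * rlnorm(length(d_j), 0, cfg$noise_sd)
          na <- a_j * rlnorm(length(a_j), 0, cfg$noise_sd)
          if (sum(nd * na) <= cap) break
        }
        if (sum(nd * na) > cap) na <- na * 0.999 * cap / sum(nd * na)
        d_j <- nd; a_j <- na
      }
      tot_d <- sum(d_j)
      tot_a <- sum(d_j * a_j) / tot_d
      g <- geo[i]; cc <- substr(g, 1, 2)
      regions[[length(regions) + 1]] <- tibble::tibble(
        geo = g, country = cc, year = y,
        population = population, beds = beds,
        total_discharges = tot_d, total_avlos = tot_a, coverage = 1
      )
      specs[[length(specs) + 1]] <- tibble::tibble(
        geo = g, year = y, specialty = prof$specialty,
        discharges = d_j, avlos = a_j
      )
      truth[[length(truth) + 1]] <- tibble::tibble(
        geo = g, country = cc, year = y,
        intended_zone = lab$zone[i], intended_quadrant = lab$quadrant[i],
        intended_bor = pl$bor, intended_toi = pl$toi,
        intended_cmi = pl$cmi, intended_pi = pl$pi
      )
    }
  }
  panel <- new_bed_panel(dplyr::bind_rows(regions), dplyr::bind_rows(specs))
  truth <- dplyr::bind_rows(truth)

  # labels implied by the finished panel, derived with the pipeline's own ops
  ind <- panel_indicators(panel, mode = "specialty",
                          period_days = cfg$period_days)
  bj <- classify_bj(ind, cfg$thresholds)
  cm <- casemix_indices(panel$specialties,
                        total_discharges = dplyr::select(
                          panel$regions, "geo", "year", "total_discharges"))
  derived <- dplyr::inner_join(
    dplyr::select(bj, "geo", "year", "bor", "toi", "zone"),
    dplyr::select(cm, "geo", "year", "cmi", "pi", "quadrant"),
    by = c("geo", "year")
  )
  derived <- dplyr::bind_cols(
    derived, combine_classification(derived$zone, derived$quadrant))
  truth <- dplyr::left_join(truth, derived, by = c("geo", "year"))

  structure(list(panel = panel, truth = truth, config = cfg),
            class = "synthetic_panel")
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat(sprintf("<synthetic_panel> %d region-years (%d regions x %d years), seed %d\n",
              nrow(x$truth), length(unique(x$truth$geo)),
              length(unique(x$truth$year)), x$config$seed))
  print(table(zone = x$truth$zone, quadrant = x$truth$quadrant))
  invisible(x)
}

#' Export a panel as Eurostat-dialect fixture files
#'
#' Writes the bulk-TSV bed, discharge and AvLOS extracts plus a population
#' CSV (and, for synthetic panels, the ground-truth CSV) such that
#' re-ingesting them through [read_eurostat_tsv()] and [assemble_panel()]
#' reproduces the panel. Values are written with 17 significant digits, so
#' the round trip is lossless at double precision.
#'
#' @param x a `bed_panel` or `synthetic_panel`.
#' @param dir output directory (created if needed).
#' @param missing_rate fraction of specialty AvLOS cells replaced by the
#'   `":"` missing sentinel (uses the current RNG stream; seed beforehand
#'   for reproducibility).
#' @return Named character vector of the files written, invisibly.
#' @export
export_fixture <- function(x, dir, missing_rate = 0) {
  truth <- NULL
  if (inherits(x, "synthetic_panel")) {
    truth <- x$truth
    x <- x$panel
  }
  stopifnot(inherits(x, "bed_panel"), missing_rate >= 0, missing_rate < 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reg <- x$regions; spec <- x$specialties

  beds_cells <- tibble::tibble(dataset_code = "SYN_BDS", unit = "NR",
                               geo = reg$geo, year = reg$year,
                               value = reg$beds, flags = "")
  tot <- function(value) tibble::tibble(unit = NA_character_, icd10 = "TOTAL",
                                        geo = reg$geo, year = reg$year,
                                        value = value, flags = "")
  sp <- function(value) tibble::tibble(unit = NA_character_,
                                       icd10 = spec$specialty, geo = spec$geo,
                                       year = spec$year, value = value,
                                       flags = "")
  disch_cells <- dplyr::bind_rows(tot(reg$total_discharges), sp(spec$discharges))
  disch_cells$unit <- "NR"
  disch_cells <- dplyr::bind_cols(tibble::tibble(dataset_code = "SYN_DISCH"),
                                  disch_cells)
  avlos_cells <- dplyr::bind_rows(tot(reg$total_avlos), sp(spec$avlos))
  avlos_cells$unit <- "DAY"
  avlos_cells <- dplyr::bind_cols(tibble::tibble(dataset_code = "SYN_INPST"),
                                  avlos_cells)
  if (missing_rate > 0) {
    is_sp <- avlos_cells$icd10 != "TOTAL"
    hit <- is_sp & runif(nrow(avlos_cells)) < missing_rate
    avlos_cells$value[hit] <- NA_real_
  }

  paths <- c(
    beds = file.path(dir, "beds.tsv"),
    discharges = file.path(dir, "discharges.tsv"),
    avlos = file.path(dir, "avlos.tsv"),
    population = file.path(dir, "population.csv")
  )
  write_eurostat_tsv(beds_cells, paths[["beds"]])
  write_eurostat_tsv(disch_cells, paths[["discharges"]])
  write_eurostat_tsv(avlos_cells, paths[["avlos"]])
  readr::write_csv(dplyr::select(reg, "geo", "year", "population"),
                   paths[["population"]])
  if (!is.null(truth)) {
    paths <- c(paths, truth = file.path(dir, "ground_truth.csv"))
    readr::write_csv(truth, paths[["truth"]])
  }
  invisible(paths)
}

#' Read fixture files back into a panel
#'
#' Counterpart of [export_fixture()]: parses the three TSV extracts and the
#' population CSV and assembles the `bed_panel`.
#'
#' @param dir directory written by [export_fixture()].
#' @param rules optional [region_filter()] applied to all three cell tables.
#' @param years years to assemble (default: all years in the beds file).
#' @return A `bed_panel`.
#' @export
read_fixture <- function(dir, rules = NULL, years = NULL) {
  need <- c(beds = "beds.tsv", discharges = "discharges.tsv",
            avlos = "avlos.tsv", population = "population.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0) {
    abort(sprintf("pipeline error (ingest): missing %s file(s): %s",
                  paste(names(missing), collapse = ", "),
                  paste(file.path(dir, missing), collapse = ", ")))
  }
  beds <- read_eurostat_tsv(file.path(dir, "beds.tsv"), "SYN_BDS")
  disch <- read_eurostat_tsv(file.path(dir, "discharges.tsv"), "SYN_DISCH")
  avlos <- read_eurostat_tsv(file.path(dir, "avlos.tsv"), "SYN_INPST")
  pop <- readr::read_csv(file.path(dir, "population.csv"),
                         show_col_types = FALSE, progress = FALSE)
  if (!is.null(rules)) {
    beds <- filter_regions(beds, rules)
    disch <- filter_regions(disch, rules)
    avlos <- filter_regions(avlos, rules)
  }
  assemble_panel(beds, disch, avlos, pop, years = years)
}
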