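# Case-Mix and Performance indices against a pooled benchmark.
#
# For a structure with specialty discharge shares w_j and specialty AvLOS
# a_j, and a benchmark with reference AvLOS A_j, reference shares s_j and
# overall reference AvLOS A_ALL = sum_j s_j A_j:
#
#   CMI = sum_j A_j * w_j / A_ALL   -- is the mix tilted toward long-stay
#                                      specialties? (> 1: more complex)
#   PI  = sum_j a_j * s_j / A_ALL   -- are stays longer than the benchmark
#                                      expects at its own mix? (> 1: slower)
#
# Both sums run over the specialties shared between structure and benchmark,
# with the relevant share vector renormalised on that shared set; the
# denominator A_ALL always comes from the full benchmark.

quadrant_levels <- c("GREEN", "YELLOW", "ORANGE", "RED")

#' Build a pooled benchmark from specialty activity
#'
#' Pools specialty rows (typically all regions of all study countries) into
#' the reference profile: per-specialty reference discharges (sums),
#' reference AvLOS (discharge-weighted means) and discharge shares, plus the
#' overall reference AvLOS, defined as the share-weighted mean of the
#' specialty reference AvLOS — the definition under which a structure with
#' benchmark-equal stays scores PI = 1 exactly.
#'
#' @param specialties data frame with columns `specialty`, `discharges`,
#'   `avlos` (several rows per specialty are pooled).
#' @return A tibble of class `bed_benchmark` with columns `specialty`,
#'   `ref_discharges`, `ref_avlos`, `ref_share`, and attributes
#'   `total_ref_discharges` and `overall_ref_avlos`.
#' @export
#' @examples
#' build_benchmark(tibble::tibble(
#'   specialty = c("A", "A", "B"),
#'   discharges = c(100, 300, 400),
#'   avlos = c(4, 8, 10)))
build_benchmark <- function(specialties) {
  stopifnot(is.data.frame(specialties))
  assert_cols(specialties, c("specialty", "discharges", "avlos"), "specialties")
  if (nrow(specialties) == 0) abort("cannot build a benchmark from no specialty rows")
  if (any(specialties$discharges < 0) || any(specialties$avlos < 0)) {
    abort("discharges and avlos must be non-negative")
  }
  # rowsum keeps this cheap when called once per random instance or per year
  d <- rowsum(specialties$discharges, specialties$specialty)
  da <- rowsum(specialties$discharges * specialties$avlos, specialties$specialty)
  b <- tibble::tibble(
    specialty = rownames(d),
    ref_discharges = unname(d[, 1]),
    ref_avlos = unname(da[, 1] / d[, 1])  # discharge-weighted mean stay
  )
  total <- sum(b$ref_discharges)
  if (total <= 0) abort("zero total discharges: benchmark undefined")
  b$ref_share <- b$ref_discharges / total
  structure(b, total_ref_discharges = total,
            overall_ref_avlos = sum(b$ref_share * b$ref_avlos),
            class = c("bed_benchmark", class(b)))
}

#' Overall reference AvLOS of a benchmark
#' @param benchmark a `bed_benchmark`.
#' @return The share-weighted mean reference AvLOS (days).
#' @export
overall_ref_avlos <- function(benchmark) {
  stopifnot(inherits(benchmark, "bed_benchmark"))
  attr(benchmark, "overall_ref_avlos")
}

#' @method tidy bed_benchmark
#' @export
tidy.bed_benchmark <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("specialty", "ref_discharges", "ref_avlos", "ref_share")])
}

#' @method glance bed_benchmark
#' @export
glance.bed_benchmark <- function(x, ...) {
  tibble::tibble(
    n_specialties = nrow(x),
    total_ref_discharges = attr(x, "total_ref_discharges"),
    overall_ref_avlos = attr(x, "overall_ref_avlos")
  )
}

# match() rather than a join: these run once per region-year and dominate
# panel-sized workloads
shared_set <- function(specialties, benchmark) {
  i <- match(specialties$specialty, benchmark$specialty)
  keep <- which(!is.na(i))
  if (length(keep) == 0) abort("no specialties shared with the benchmark")
  col <- function(nm) if (nm %in% names(specialties)) specialties[[nm]][keep]
  list(
    discharges = col("discharges"),
    avlos = col("avlos"),
    ref_avlos = benchmark$ref_avlos[i[keep]],
    ref_share = benchmark$ref_share[i[keep]]
  )
}

#' Case-Mix Index of one structure
#'
#' Share-weighted mean of the *benchmark* AvLOS under the *structure's*
#' discharge mix, relative to the overall benchmark AvLOS. Values above 1
#' indicate a mix tilted toward specialties with long reference stays
#' (a more complex case load).
#'
#' @param specialties data frame with `specialty` and `discharges` for one
#'   structure (region-year).
#' @param benchmark a [build_benchmark()] object.
#' @return A single positive number.
#' @export
compute_cmi <- function(specialties, benchmark) {
  assert_cols(specialties, c("specialty", "discharges"), "specialties")
  shared <- shared_set(specialties, benchmark)
  tot <- sum(shared$discharges)
  if (tot <= 0) abort("structure has zero discharges on the shared specialties")
  sum(shared$ref_avlos * shared$discharges / tot) / overall_ref_avlos(benchmark)
}

#' Performance Index of one structure
#'
#' Share-weighted mean of the *structure's* AvLOS under the *benchmark's*
#' discharge mix, relative to the overall benchmark AvLOS. Values above 1
#' mean stays longer than the benchmark expects at equal complexity
#' (lower performance).
#'
#' @param specialties data frame with `specialty` and `avlos` for one
#'   structure (region-year).
#' @inheritParams compute_cmi
#' @return A single positive number.
#' @export
compute_pi <- function(specialties, benchmark) {
  assert_cols(specialties, c("specialty", "avlos"), "specialties")
  shared <- shared_set(specialties, benchmark)
  w <- shared$ref_share / sum(shared$ref_share)
  sum(shared$avlos * w) / overall_ref_avlos(benchmark)
}

#' Classify the CMI/PI quadrant
#'
#' Strict thresholds at 1 on both axes (equality counts as outside the
#' target): GREEN `cmi > 1 & pi < 1` (high complexity managed efficiently),
#' YELLOW `cmi <= 1 & pi < 1` (low complexity managed efficiently), ORANGE
#' `cmi > 1 & pi >= 1` (high complexity, low performance), RED otherwise
#' (low complexity, low performance).
#'
#' @param cmi,pi positive numeric vectors.
#' @return Factor with levels GREEN, YELLOW, ORANGE, RED.
#' @export
#' @examples
#' classify_quadrant(c(1.26, 1, 1.5), c(1.21, 1, 0.8))
classify_quadrant <- function(cmi, pi) {
  stopifnot(is.numeric(cmi), is.numeric(pi))
  if (any(!is.finite(cmi)) || any(!is.finite(pi))) abort("cmi and pi must be finite")
  factor(
    ifelse(pi < 1, ifelse(cmi > 1, "GREEN", "YELLOW"),
           ifelse(cmi > 1, "ORANGE", "RED")),
    levels = quadrant_levels
  )
}

#' Performance-to-complexity ratio
#'
#' `pi / cmi`, the colouring variable of the quadrant map: below 1 means the
#' structure performs better than its complexity alone would suggest.
#'
#' @param cmi positive numeric vector.
#' @param pi numeric vector.
#' @return Numeric vector `pi / cmi`.
#' @export
pi_cmi_ratio <- function(cmi, pi) {
  stopifnot(is.numeric(cmi), is.numeric(pi))
  if (any(cmi == 0)) abort("cmi must be non-zero")
  pi / cmi
}

#' Case-mix and performance indices per region-year
#'
#' Computes CMI, PI, the quadrant, the PI/CMI ratio and specialty coverage
#' for every region-year in a specialty table. With `benchmark = NULL` the
#' benchmark is pooled from the table itself (all regions of all countries,
#' separately per year), the study's definition of the reference.
#'
#' @param specialties data frame with `geo`, `year`, `specialty`,
#'   `discharges`, `avlos` (e.g. `panel$specialties`).
#' @param benchmark a [build_benchmark()] object, or `NULL` to pool one per
#'   year from `specialties`.
#' @param total_discharges optional data frame `geo`, `year`,
#'   `total_discharges` used as the coverage denominator; defaults to the sum
#'   of the region's specialty discharges (coverage 1 when every chapter
#'   is shared).
#' @return Tibble: `geo`, `year`, `cmi`, `pi`, `quadrant`, `pi_cmi_ratio`,
#'   `coverage`.
#' @export
casemix_indices <- function(specialties, benchmark = NULL,
                            total_discharges = NULL) {
  assert_cols(specialties, c("geo", "year", "specialty", "discharges", "avlos"),
              "specialties")
  spec <- tibble::as_tibble(specialties)
  years <- sort(unique(spec$year))
  res <- purrr::map_dfr(years, function(y) {
    sy <- spec[spec$year == y, , drop = FALSE]
    b <- benchmark %||% build_benchmark(sy)
    shared_codes <- tidy(b)$specialty
    sy %>%
      dplyr::group_by(.data$geo) %>%
      dplyr::group_modify(function(d, key) {
        tibble::tibble(
          cmi = compute_cmi(d, b),
          pi = compute_pi(d, b),
          shared_discharges = sum(d$discharges[d$specialty %in% shared_codes]),
          all_discharges = sum(d$discharges)
        )
      }) %>%
      dplyr::ungroup() %>%
      dplyr::mutate(year = y, .after = "geo")
  })
  denom <- res$all_discharges
  if (!is.null(total_discharges)) {
    assert_cols(total_discharges, c("geo", "year", "total_discharges"),
                "total_discharges")
    i <- match(paste(res$geo, res$year),
               paste(total_discharges$geo, total_discharges$year))
    denom <- ifelse(is.na(i), denom, total_discharges$total_discharges[i])
  }
  res %>%
    dplyr::mutate(
      quadrant = classify_quadrant(.data$cmi, .data$pi),
      pi_cmi_ratio = pi_cmi_ratio(.data$cmi, .data$pi),
      coverage = .data$shared_discharges / denom
    ) %>%
    dplyr::select("geo", "year", "cmi", "pi", "quadrant", "pi_cmi_ratio",
                  "coverage")
}

#' Four-quadrant CMI/PI diagram
#'
#' Scatter of regions in the (CMI, PI) plane with the four zones shaded and
#' the crosshair at (1, 1). CMI on the abscissa, PI on the ordinate.
#'
#' @param data data frame with columns `cmi` and `pi`.
#' @return A ggplot object; `NULL` (with a warning) for empty input.
#' @export
plot_quadrants <- function(data) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0) {
    warn("no regions to plot")
    return(invisible(NULL))
  }
  assert_cols(data, c("cmi", "pi"), "data")
  xr <- range(c(data$cmi, 1)) + c(-0.05, 0.05)
  yr <- range(c(data$pi, 1)) + c(-0.05, 0.05)
  quad_fill <- c(GREEN = "#4daf4a", YELLOW = "#ffd92f",
                 ORANGE = "#ff7f00", RED = "#e41a1c")
  rects <- tibble::tibble(
    quadrant = factor(quadrant_levels, levels = quadrant_levels),
    xmin = c(1, xr[1], 1, xr[1]), xmax = c(xr[2], 1, xr[2], 1),
    ymin = c(yr[1], yr[1], 1, 1), ymax = c(1, 1, yr[2], yr[2])
  )
  ggplot2::ggplot(tibble::as_tibble(data), ggplot2::aes(x = .data$cmi, y = .data$pi)) +
    ggplot2::geom_rect(
      data = rects, inherit.aes = FALSE, alpha = 0.25,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = .data$ymin,
                   ymax = .data$ymax, fill = .data$quadrant)
    ) +
    ggplot2::scale_fill_manual(values = quad_fill, name = "quadrant") +
    ggplot2::geom_hline(yintercept = 1, colour = "grey30") +
    ggplot2::geom_vline(xintercept = 1, colour = "grey30") +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(xlim = xr, ylim = yr, expand = FALSE) +
    ggplot2::labs(x = "Case-Mix Index", y = "Performance Index",
                  title = "Complexity and performance") +
    ggplot2::theme_minimal()
}
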