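# Cross-year and cross-region dispersion summaries: percent change,
# coefficient of variation, country spans, and the count of regions whose
# per-capita bed stock grew between two reference years.

#' Percent change between two values
#'
#' `100 * (new - old) / old`. Reported figures round to the nearest integer,
#' half away from zero (`rounded = TRUE`), the convention behind printed
#' values such as -4% for 834 -> 800.
#'
#' @param v_old positive numeric vector (baseline).
#' @param v_new numeric vector.
#' @param rounded round to whole percent for reporting?
#' @return Numeric vector of percent changes.
#' @export
#' @examples
#' percent_change(834, 800)                 # -4.0767...
#' percent_change(342, 318, rounded = TRUE) # -7
percent_change <- function(v_old, v_new, rounded = FALSE) {
  stopifnot(is.numeric(v_old), is.numeric(v_new))
  if (any(v_old <= 0)) abort("baseline value must be positive")
  pc <- 100 * (v_new - v_old) / v_old
  if (rounded) round_half_away(pc) else pc
}

#' Coefficient of variation of a regional series
#'
#' Standard deviation divided by the mean; dimensionless and invariant under
#' positive rescaling, which is what makes it comparable across series in
#' different units. Default is the sample (n-1) standard deviation;
#' `type = "population"` divides by n.
#'
#' @param values numeric vector, at least two values with positive mean.
#' @param type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return A single non-negative number.
#' @export
#' @examples
#' coefficient_of_variation(c(1, 2, 3))  # 0.5
coefficient_of_variation <- function(values, type = c("sample", "population")) {
  stopifnot(is.numeric(values))
  type <- match.arg(type)
  if (length(values) < 2) abort("need at least two values")
  if (any(!is.finite(values))) abort("values must be finite")
  m <- mean(values)
  if (m <= 0) abort("mean must be positive")
  s <- stats::sd(values)
  if (type == "population") s <- s * sqrt((length(values) - 1) / length(values))
  s / m
}

#' Minimum and maximum of a regional series
#'
#' Argmin/argmax scan with a deterministic tie-break: among tied values the
#' lexicographically smallest region code wins.
#'
#' @param data data frame; respects `dplyr` groups (e.g. grouped by country).
#' @param value name of the value column (default `"value"`).
#' @param region name of the region-code column (default `"geo"`).
#' @return Tibble (one row per group): `min_region`, `min_value`,
#'   `max_region`, `max_value`.
#' @export
#' @examples
#' d <- tibble::tibble(geo = c("A", "B", "C"), value = c(580, 1285, 900))
#' country_span(d)
country_span <- function(data, value = "value", region = "geo") {
  stopifnot(is.data.frame(data))
  assert_cols(data, c(value, region), "data")
  if (nrow(data) == 0) abort("empty series")
  span1 <- function(d, ...) {
    v <- d[[value]]; g <- d[[region]]
    mn <- min(v); mx <- max(v)
    tibble::tibble(
      min_region = min(g[v == mn]), min_value = mn,  # lexicographic ties
      max_region = min(g[v == mx]), max_value = mx
    )
  }
  if (dplyr::is_grouped_df(data)) {
    dplyr::ungroup(dplyr::group_modify(data, span1))
  } else {
    span1(data)
  }
}

#' Regions with a strict increase between two years
#'
#' Compares a per-region value (by default the per-100k bed rate) across two
#' years and returns the regions where it strictly increased; equal values do
#' not count. Regions lacking either year are reported in the `skipped`
#' attribute, not compared.
#'
#' @param data data frame with columns `geo`, `country`, `year` and the value
#'   column.
#' @param value name of the value column.
#' @param years length-2 integer vector `(old, new)`; default the two
#'   smallest/largest years present.
#' @return Tibble of increasing regions (`geo`, `country`, `old`, `new`,
#'   `change_pct`), with attributes `n` (the count) and `skipped` (geo codes
#'   missing a year).
#' @export
count_increasing <- function(data, value = "beds_per_100k", years = NULL) {
  stopifnot(is.data.frame(data))
  assert_cols(data, c("geo", "country", "year", value), "data")
  yrs <- years %||% range(data$year)
  stopifnot(length(yrs) == 2, yrs[1] != yrs[2])
  wide <- data %>%
    dplyr::filter(.data$year %in% yrs) %>%
    dplyr::distinct(.data$geo, .data$year, .keep_all = TRUE) %>%
    dplyr::select("geo", "country", "year", val = dplyr::all_of(value)) %>%
    tidyr::pivot_wider(names_from = "year", values_from = "val",
                       names_prefix = "y")
  old <- wide[[paste0("y", yrs[1])]] %||% rep(NA_real_, nrow(wide))
  new <- wide[[paste0("y", yrs[2])]] %||% rep(NA_real_, nrow(wide))
  skipped <- wide$geo[is.na(old) | is.na(new)]
  ok <- !is.na(old) & !is.na(new)
  up <- ok & new > old
  v_old <- old[up]; v_new <- new[up]
  out <- tibble::tibble(
    geo = wide$geo[up], country = wide$country[up],
    old = v_old, new = v_new,
    change_pct = percent_change(v_old, v_new)
  ) %>% dplyr::arrange(.data$geo)
  attr(out, "n") <- nrow(out)
  attr(out, "skipped") <- skipped
  out
}
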