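# Combined efficiency x complexity classification: the 3 Barber-Johnson
# zones crossed with the 4 CMI/PI quadrants give a 12-cell grid. The full
# grid is exposed; any coarser grouping is a user-supplied mapping from
# cell_id to group label.

bj_part_labels <- c(
  GREEN = "efficient bed management",
  YELLOW = "partially efficient bed management",
  RED = "inefficient bed management"
)
quadrant_part_labels <- c(
  GREEN = "high complexity, high performance",
  YELLOW = "low complexity, high performance",
  ORANGE = "high complexity, low performance",
  RED = "low complexity, low performance"
)

#' Combine zone and quadrant into the overall cluster cell
#'
#' Deterministic bijection from the (Barber-Johnson zone, CMI/PI quadrant)
#' pair onto 12 cell identifiers of the form `"BJ:GREEN|Q:GREEN"`, with a
#' human-readable label for each.
#'
#' @param bj_zone factor/character vector in GREEN/YELLOW/RED.
#' @param quadrant factor/character vector in GREEN/YELLOW/ORANGE/RED.
#' @return Tibble with columns `cell_id` and `label`, one row per input.
#' @export
#' @examples
#' combine_classification("GREEN", "GREEN")
combine_classification <- function(bj_zone, quadrant) {
  bj_zone <- as.character(bj_zone)
  quadrant <- as.character(quadrant)
  if (any(!bj_zone %in% bj_zone_levels)) abort("unknown Barber-Johnson zone")
  if (any(!quadrant %in% quadrant_levels)) abort("unknown quadrant")
  tibble::tibble(
    cell_id = paste0("BJ:", bj_zone, "|Q:", quadrant),
    label = paste(bj_part_labels[bj_zone], quadrant_part_labels[quadrant],
                  sep = " / ")
  )
}

#' Attach the combined cluster cell to a classification table
#'
#' @param data data frame with columns `zone` and `quadrant`.
#' @param cell_groups optional named character vector mapping `cell_id` to a
#'   coarser group label (added as a `cell_group` column).
#' @return `data` as a tibble with `cell_id`, `label` (and optionally
#'   `cell_group`) appended.
#' @export
classify_overall <- function(data, cell_groups = NULL) {
  stopifnot(is.data.frame(data))
  assert_cols(data, c("zone", "quadrant"), "data")
  out <- dplyr::bind_cols(tibble::as_tibble(data),
                          combine_classification(data$zone, data$quadrant))
  if (!is.null(cell_groups)) {
    out$cell_group <- unname(cell_groups[out$cell_id])
  }
  out
}

#' Per-country distribution of a classification
#'
#' Counts regions per (country, class) and expresses them as percentages of
#' the country's region total, rounded to the nearest integer (half away
#' from zero) for reporting.
#'
#' @param data data frame with a `country` column and the classification
#'   column selected by `by`.
#' @param by which classification to tabulate: `"zone"`, `"quadrant"` or
#'   `"cell"` (column `cell_id`).
#' @return Tibble: `country`, `class`, `n`, `pct` (integer percent),
#'   including zero rows for classes absent in a country so that counts
#'   always partition the country's regions.
#' @export
#' @examples
#' d <- tibble::tibble(country = rep("IT", 21),
#'                     zone = rep(c("GREEN", "YELLOW", "RED"), c(16, 2, 3)))
#' country_distribution(d, by = "zone")
country_distribution <- function(data, by = c("zone", "quadrant", "cell")) {
  stopifnot(is.data.frame(data))
  by <- match.arg(by)
  col <- switch(by, zone = "zone", quadrant = "quadrant", cell = "cell_id")
  assert_cols(data, c("country", col), "data")
  if (nrow(data) == 0) {
    return(tibble::tibble(country = character(), class = character(),
                          n = integer(), pct = double()))
  }
  lev <- switch(by, zone = bj_zone_levels, quadrant = quadrant_levels,
                cell = sort(unique(as.character(data[[col]]))))
  counts <- tibble::tibble(country = data$country,
                           class = factor(as.character(data[[col]]), levels = lev)) %>%
    dplyr::count(.data$country, .data$class, .drop = FALSE, name = "n") %>%
    dplyr::mutate(total = sum(.data$n), .by = "country") %>%
    dplyr::mutate(pct = round_half_away(100 * .data$n / .data$total),
                  class = as.character(.data$class)) %>%
    dplyr::select("country", "class", "n", "pct")
  counts
}
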