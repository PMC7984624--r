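# Barber-Johnson efficiency zones and diagram geometry.
#
# The diagram plots TOI (x) against AvLOS (y). Points of constant occupancy
# lie on rays through the origin with slope BOR/(1-BOR); points of constant
# turnover lie on the line AvLOS + TOI = period/BTO. The efficiency target
# is the open band 1 < TOI < 3 days and 75% < BOR < 85%; its centre
# (TOI = 2, BOR = 80%) is the centroid against which distances are measured.

#' Efficiency thresholds for zone classification
#'
#' The classical target bands: turnover interval strictly between
#' `toi_low` and `toi_high` days and occupancy strictly between `bor_low`
#' and `bor_high` (fractions). Band membership uses strict open intervals,
#' so values exactly on a threshold count as outside and ties cannot occur.
#'
#' @param toi_low,toi_high turnover-interval band in days (default 1 and 3).
#' @param bor_low,bor_high occupancy band as fractions (default 0.75, 0.85).
#' @param centroid_toi,centroid_bor target centre (default 2 days, 0.80).
#' @return A list of class `efficiency_thresholds`.
#' @export
efficiency_thresholds <- function(toi_low = 1, toi_high = 3,
                                  bor_low = 0.75, bor_high = 0.85,
                                  centroid_toi = 2, centroid_bor = 0.80) {
  if (!(toi_low < centroid_toi && centroid_toi < toi_high)) {
    abort("need toi_low < centroid_toi < toi_high")
  }
  if (!(bor_low < centroid_bor && centroid_bor < bor_high)) {
    abort("need bor_low < centroid_bor < bor_high")
  }
  if (bor_high > 1 || bor_low < 0) abort("bor thresholds must lie in [0, 1]")
  structure(list(toi_low = toi_low, toi_high = toi_high,
                 bor_low = bor_low, bor_high = bor_high,
                 centroid_toi = centroid_toi, centroid_bor = centroid_bor),
            class = "efficiency_thresholds")
}

bj_zone_levels <- c("GREEN", "YELLOW", "RED")

#' Classify regions into Barber-Johnson zones
#'
#' GREEN when both TOI and BOR fall strictly inside their bands, RED when
#' both fall outside, YELLOW otherwise. Also computes the Euclidean distance
#' of each region from the target centroid (see [centroid_distance()]).
#'
#' @param data data frame with columns `toi` (days) and `bor` (fraction).
#' @param thresholds an [efficiency_thresholds()] object.
#' @param distance_mode `"raw"` (TOI in days, BOR in percentage points) or
#'   `"band"` (each axis scaled by its half-band-width).
#' @return `data` as a tibble with `toi_in`, `bor_in`, `zone` (factor
#'   GREEN/YELLOW/RED) and `centroid_distance` appended.
#' @export
#' @examples
#' classify_bj(tibble::tibble(toi = c(2, 0.5, 2.5), bor = c(0.80, 0.70, 0.90)))
classify_bj <- function(data, thresholds = efficiency_thresholds(),
                        distance_mode = c("raw", "band")) {
  stopifnot(is.data.frame(data), inherits(thresholds, "efficiency_thresholds"))
  assert_cols(data, c("toi", "bor"), "data")
  distance_mode <- match.arg(distance_mode)
  t <- thresholds
  out <- tibble::as_tibble(data)
  out$toi_in <- out$toi > t$toi_low & out$toi < t$toi_high
  out$bor_in <- out$bor > t$bor_low & out$bor < t$bor_high
  out$zone <- factor(
    ifelse(out$toi_in & out$bor_in, "GREEN",
           ifelse(!out$toi_in & !out$bor_in, "RED", "YELLOW")),
    levels = bj_zone_levels
  )
  out$centroid_distance <- centroid_distance(out$toi, out$bor, t, distance_mode)
  out
}

#' Distance from the efficiency centroid
#'
#' Euclidean distance from (`centroid_toi`, `centroid_bor`). In `"raw"` mode
#' TOI is in days and BOR in percentage points, the literal reading of the
#' diagram's axes; in `"band"` mode each deviation is first divided by its
#' half-band-width (`(toi_high - toi_low)/2` days,
#' `(bor_high - bor_low)/2 * 100` percentage points), so one unit means "one
#' band" on either axis.
#'
#' @param toi numeric vector, days.
#' @param bor numeric vector, occupancy fraction.
#' @param thresholds an [efficiency_thresholds()] object.
#' @param mode `"raw"` or `"band"`.
#' @return Non-negative numeric vector; 0 exactly at the centroid.
#' @export
#' @examples
#' centroid_distance(3, 0.80)          # 1
#' centroid_distance(3, 0.85, mode = "band")  # sqrt(2)
centroid_distance <- function(toi, bor, thresholds = efficiency_thresholds(),
                              mode = c("raw", "band")) {
  stopifnot(inherits(thresholds, "efficiency_thresholds"))
  mode <- match.arg(mode)
  t <- thresholds
  dx <- toi - t$centroid_toi
  dy <- 100 * (bor - t$centroid_bor)
  if (mode == "band") {
    dx <- dx / ((t$toi_high - t$toi_low) / 2)
    dy <- dy / (100 * (t$bor_high - t$bor_low) / 2)
  }
  sqrt(dx^2 + dy^2)
}

#' Slope of a constant-occupancy ray
#'
#' In the (TOI, AvLOS) plane all points with occupancy `bor` lie on the ray
#' `AvLOS = bor/(1 - bor) * TOI` through the origin (a direct consequence of
#' the accounting identities). `bor = 1` returns `Inf`, the vertical ray.
#'
#' @param bor occupancy fraction in \[0, 1\].
#' @return Numeric slope vector.
#' @export
#' @examples
#' bor_ray(c(0, 0.5, 0.8))
bor_ray <- function(bor) {
  stopifnot(is.numeric(bor))
  if (any(bor < 0 | bor > 1)) abort("bor must lie in [0, 1]")
  ifelse(bor == 1, Inf, bor / (1 - bor))
}

#' Intercept of a constant-turnover isoline
#'
#' All indicator tuples with bed turnover `bto` satisfy
#' `AvLOS + TOI = period_days / bto`; the returned intercept is that common
#' sum, i.e. the isoline's intercept on both axes.
#'
#' @param bto positive bed turnover (patients per bed per period).
#' @param period_days days in the period (default 365).
#' @return Numeric intercept vector (days).
#' @export
#' @examples
#' bto_isoline(40)  # 9.125
bto_isoline <- function(bto, period_days = 365) {
  stopifnot(is.numeric(bto))
  if (any(bto <= 0)) abort("bto must be positive")
  period_days / bto
}

#' Barber-Johnson diagram
#'
#' Scatter of regions in the (TOI, AvLOS) plane with the three efficiency
#' zones shaded, the BOR threshold rays, a set of BTO isolines and the
#' centroid marked. Any point (toi, avlos) implies `bor = avlos/(avlos+toi)`,
#' which is what the shading classifies.
#'
#' @param data data frame with columns `toi` and `avlos` (and optionally a
#'   `zone` column used for point colour).
#' @param thresholds an [efficiency_thresholds()] object.
#' @param period_days days in the period, used for the BTO isoline labels.
#' @param bto_lines BTO values at which to draw isolines.
#' @param grid_n resolution of the zone shading raster.
#' @return A ggplot object; `NULL` (with a warning) for empty input.
#' @export
plot_bj <- function(data, thresholds = efficiency_thresholds(),
                    period_days = 365, bto_lines = c(20, 30, 40, 60),
                    grid_n = 200) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0) {
    warn("no regions to plot")
    return(invisible(NULL))
  }
  assert_cols(data, c("toi", "avlos"), "data")
  t <- thresholds
  xmax <- max(4, max(data$toi) * 1.15)
  ymax <- max(12, max(data$avlos) * 1.15)
  grid <- tidyr::expand_grid(
    toi = seq(xmax / grid_n / 2, xmax, length.out = grid_n),
    avlos = seq(ymax / grid_n / 2, ymax, length.out = grid_n)
  )
  grid$bor <- grid$avlos / (grid$avlos + grid$toi)
  grid <- classify_bj(grid, t)
  zone_fill <- c(GREEN = "#4daf4a", YELLOW = "#ffd92f", RED = "#e41a1c")

  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$toi, y = .data$avlos)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$zone), alpha = 0.25) +
    ggplot2::scale_fill_manual(values = zone_fill, name = "zone") +
    ggplot2::geom_abline(intercept = 0, slope = bor_ray(c(t$bor_low, t$bor_high)),
                         linetype = "dashed", colour = "grey30") +
    ggplot2::geom_vline(xintercept = c(t$toi_low, t$toi_high),
                        linetype = "dashed", colour = "grey30") +
    ggplot2::geom_abline(intercept = bto_isoline(bto_lines, period_days),
                         slope = -1, linetype = "dotted", colour = "grey50") +
    ggplot2::annotate("point", x = t$centroid_toi,
                      y = bor_ray(t$centroid_bor) * t$centroid_toi,
                      shape = 3, size = 3, stroke = 1.2) +
    ggplot2::geom_point(data = tibble::as_tibble(data)) +
    ggplot2::coord_cartesian(xlim = c(0, xmax), ylim = c(0, ymax), expand = FALSE) +
    ggplot2::labs(x = "Turnover interval (days)",
                  y = "Average length of stay (days)",
                  title = "Barber-Johnson diagram") +
    ggplot2::theme_minimal()
  p
}
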