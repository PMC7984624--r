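# The four classical bed-management indicators and their algebraic inverse.
#
# With B beds over a period of T days, D discharges and O occupied bed-days:
#   BOR   = O / (B T)        occupancy (fraction; reported as %)
#   AvLOS = O / D            mean stay (days)
#   BTO   = D / B            patients per bed per period
#   TOI   = (B T - O) / D    mean empty-bed interval between patients (days)
# which forces the two accounting identities
#   AvLOS + TOI = T / BTO    and    BOR = AvLOS * BTO / T.

#' Total occupied bed-days
#'
#' Occupied bed-days are derived from published activity as discharges times
#' average length of stay, either summed over specialties or from the
#' all-diagnoses totals; the two modes agree whenever the total AvLOS is the
#' discharge-weighted mean of the specialty values.
#'
#' @param discharges non-negative numeric vector of discharge counts.
#' @param avlos non-negative numeric vector of average lengths of stay (days),
#'   same length as `discharges` (or length 1).
#' @return `sum(discharges * avlos)`, a single number of bed-days; 0 for
#'   empty input.
#' @export
#' @examples
#' occupied_bed_days(c(100, 300), c(2, 10))  # 3200
#' occupied_bed_days(400, 8)                 # totals mode, also 3200
occupied_bed_days <- function(discharges, avlos) {
  stopifnot(is.numeric(discharges), is.numeric(avlos))
  if (any(discharges < 0) || any(avlos < 0)) {
    abort("discharges and avlos must be non-negative")
  }
  if (length(discharges) == 0) return(0)
  sum(discharges * avlos)
}

#' Compute bed-management indicators
#'
#' Adds the four indicators to a region-year table. `bor` is kept as a
#' fraction in \[0, 1\] throughout the package (multiply by 100 for display);
#' this avoids unit mistakes in centroid distances.
#'
#' @param data data frame with one row per region-year.
#' @param beds,discharges,occupied_days names of the columns of `data`
#'   holding bed stock, discharge count and occupied bed-days.
#' @param period_days days in the accounting period (default 365).
#' @return `data` as a tibble with columns `bor`, `avlos`, `toi`, `bto`
#'   appended.
#' @export
#' @examples
#' compute_indicators(tibble::tibble(
#'   beds = 100, discharges = 4000, occupied_days = 28000))
compute_indicators <- function(data, beds = "beds", discharges = "discharges",
                               occupied_days = "occupied_days",
                               period_days = 365) {
  stopifnot(is.data.frame(data), period_days > 0)
  B <- data[[beds]]; D <- data[[discharges]]; O <- data[[occupied_days]]
  if (is.null(B) || is.null(D) || is.null(O)) {
    abort("data must contain the beds, discharges and occupied_days columns")
  }
  if (any(B <= 0)) abort("beds must be positive")
  if (any(D <= 0)) abort("turnover undefined: discharges must be positive")
  if (any(O < 0)) abort("occupied_days must be non-negative")
  cap <- B * period_days
  if (any(O > cap * (1 + 1e-12))) {
    abort("occupied_days exceed capacity beds * period_days")
  }
  out <- tibble::as_tibble(data)
  out$bor <- O / cap
  out$avlos <- O / D
  out$bto <- D / B
  out$toi <- (cap - O) / D
  out
}

#' Invert bed occupancy and turnover interval
#'
#' Exact algebraic inverse of [compute_indicators()]: given a target
#' occupancy and turnover interval (and the bed stock), returns the
#' discharge count and average length of stay that produce them,
#' `avlos = toi * bor / (1 - bor)` and
#' `discharges = beds * period_days * (1 - bor) / toi`.
#' Used by the synthetic generator to place regions at exact diagram
#' coordinates. The boundary pair `bor == 1, toi == 0` is geometrically valid
#' (full occupancy, no idle time) but leaves discharges undetermined; it
#' returns `NA` with a warning.
#'
#' @param bor occupancy fraction, in (0, 1) (or exactly 1 with `toi == 0`).
#' @param toi turnover interval in days, > 0.
#' @param beds positive bed stock.
#' @param period_days days in the period (default 365).
#' @return Tibble with columns `discharges`, `avlos`, `occupied_days`
#'   (one row per input).
#' @export
#' @examples
#' invert_indicators(0.8, 2, beds = 100)  # discharges 3650, avlos 8
invert_indicators <- function(bor, toi, beds, period_days = 365) {
  stopifnot(is.numeric(bor), is.numeric(toi), is.numeric(beds))
  n <- max(length(bor), length(toi), length(beds))
  bor <- rep_len(bor, n); toi <- rep_len(toi, n); beds <- rep_len(beds, n)
  if (any(bor < 0 | bor > 1)) abort("bor must lie in [0, 1]")
  if (any(beds <= 0)) abort("beds must be positive")
  full <- bor == 1 & toi == 0
  if (any(bor == 1 & toi != 0)) abort("bor == 1 requires toi == 0")
  if (any(!full & (toi <= 0 | bor <= 0))) {
    abort("inconsistent target: need 0 < bor < 1 and toi > 0")
  }
  avlos <- ifelse(full, NA_real_, toi * bor / (1 - bor))
  discharges <- ifelse(full, NA_real_, beds * period_days * (1 - bor) / toi)
  if (any(full)) {
    warn("bor == 1 with toi == 0: discharges and avlos are undetermined (NA)")
  }
  tibble::tibble(discharges = discharges, avlos = avlos,
                 occupied_days = discharges * avlos)
}

#' Bed indicators for every region-year of a panel
#'
#' Derives occupied bed-days (specialty-sum mode where specialty rows exist
#' and `mode = "specialty"`, all-diagnoses totals otherwise) and computes the
#' four indicators for each region-year.
#'
#' @param panel a `bed_panel` from [assemble_panel()] or [gen_panel()].
#' @param mode `"specialty"` to sum discharges x AvLOS over ICD chapters when
#'   present (falling back to totals for regions without specialty rows), or
#'   `"total"` to always use the all-diagnoses totals.
#' @param period_days days in the period (default 365).
#' @return Tibble: `geo`, `country`, `year`, `population`, `beds`,
#'   `discharges`, `occupied_days`, `bor`, `avlos`, `toi`, `bto`.
#' @export
panel_indicators <- function(panel, mode = c("specialty", "total"),
                             period_days = 365) {
  stopifnot(inherits(panel, "bed_panel"))
  mode <- match.arg(mode)
  reg <- panel$regions
  occ_tot <- reg$total_discharges * reg$total_avlos
  occ <- occ_tot
  if (mode == "specialty" && nrow(panel$specialties) > 0) {
    s <- panel$specialties %>%
      dplyr::summarise(occ_spec = sum(.data$discharges * .data$avlos),
                       .by = c("geo", "year"))
    i <- match(paste(reg$geo, reg$year), paste(s$geo, s$year))
    occ <- ifelse(is.na(i), occ_tot, s$occ_spec[i])
  }
  out <- reg %>%
    dplyr::transmute(.data$geo, .data$country, .data$year, .data$population,
                     .data$beds, discharges = .data$total_discharges,
                     occupied_days = occ)
  compute_indicators(out, period_days = period_days)
}
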