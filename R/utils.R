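# shared numeric helpers

#' Round half away from zero
#'
#' Commercial rounding used for all reported percentages: ties go away from
#' zero (`round_half_away(0.5) == 1`, `round_half_away(-0.5) == -1`), unlike
#' base [round()] which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 0).
#' @return numeric vector, same length as `x`.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, -4.077))
round_half_away <- function(x, digits = 0) {
  stopifnot(is.numeric(x))
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Largest-remainder (Hamilton) apportionment of n items to proportions p.
# Returns integer counts summing to n; ties broken by position order.
largest_remainder <- function(p, n) {
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-8, n >= 0)
  quota <- p * n
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

assert_cols <- function(data, cols, what = "data") {
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
  invisible(data)
}
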