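# Small shared numeric helpers.

#' Round half away from zero
#'
#' Base R's [round()] rounds half to even; gene-family census tables in the
#' literature round half up, so censuses and percentage summaries in this
#' package use this helper.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded with ties going away from zero.
#' @examples
#' round_half_up(0.125, 2)  # 0.13, where round() gives 0.12
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage share of a count
#'
#' `100 * count / total`, rounded half-up.  This is the rounding convention
#' used by every census and proportion summary in the package.
#'
#' @param count,total numeric; `total` must be positive.
#' @param digits decimal places (default 2).
#' @return numeric percentage(s).
#' @examples
#' percent_share(108, 233)      # 46.35
#' percent_share(137, 233, 0)   # 59
#' @export
percent_share <- function(count, total, digits = 2) {
  stopifnot(is.numeric(count), is.numeric(total), all(total > 0))
  round_half_up(100 * count / total, digits)
}

# stop() with a consistent prefix-free message built by sprintf
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
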