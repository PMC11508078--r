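# Internal validation + table-rounding helpers.

stop_merisk <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, positive = FALSE, nonnegative = FALSE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop_merisk("'%s' must be numeric and non-missing", name)
  }
  if (positive && any(x <= 0)) {
    stop_merisk("'%s' must be > 0 (got %s)", name, paste(x[x <= 0], collapse = ", "))
  }
  if (nonnegative && any(x < 0)) {
    stop_merisk("'%s' must be >= 0 (got %s)", name, paste(x[x < 0], collapse = ", "))
  }
  invisible(x)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, the convention used by
#' common spreadsheet software and hence by most published summary tables.
#' Base R's [round()] rounds half to even, which differs at exact ties
#' (e.g. 2.645 at two decimals).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @seealso [signif_half_up()]
#' @export
#' @examples
#' round_half_up(2.645, 2) # 2.65
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  y <- abs(x) * p
  # nudge by a relative epsilon so decimal ties survive binary representation
  sign(x) * floor(y + 0.5 + y * 1e-10) / p
}

#' Round to significant figures, half away from zero
#'
#' @param x numeric vector.
#' @param digits number of significant figures (default 3, the precision used
#'   throughout the shipped exposure and risk tables).
#' @return `x` rounded to `digits` significant figures.
#' @export
signif_half_up <- function(x, digits = 3) {
  out <- x
  nz <- is.finite(x) & x != 0
  if (any(nz)) {
    e <- floor(log10(abs(x[nz])))
    out[nz] <- round_half_up(x[nz], digits - 1 - e)
  }
  out
}

# Paper-table reporting precisions: dose 3 s.f., HQ 3 decimals, HI 3 s.f.
paper_round_dose <- function(x) signif_half_up(x, 3L)
paper_round_hq <- function(x) round_half_up(x, 3L)
paper_round_hi <- function(x) signif_half_up(x, 3L)

# match a published cell's own precision (number of decimals it prints)
printed_decimals <- function(printed) {
  s <- sub("^-", "", format(printed, trim = TRUE, scientific = FALSE))
  ifelse(grepl("\\.", s), nchar(sub("^[^.]*\\.", "", s)), 0L)
}
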