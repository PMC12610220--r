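#' Parse a single nutrition-label value
#'
#' Nutrition declarations on European labels mix decimal commas and points,
#' may carry a unit suffix ("g", "mg", "kJ", "kcal"), and use upper-bound
#' notation such as \code{"<0.5 g"} for trace amounts. Following common survey
#' practice, an upper-bound declaration is recorded at its maximum value and
#' flagged so that sensitivity analyses can substitute e.g. half the bound.
#'
#' @param text a single non-empty label string, e.g. \code{"<0.5 g"},
#'   \code{"0,9"}, \code{"12.41"}.
#' @return a list with elements \code{value} (non-negative numeric) and
#'   \code{upper_bound} (logical; \code{TRUE} for \code{"<x"} declarations).
#' @examples
#' parse_label_value("<0.5 g")   # value 0.5, upper_bound TRUE
#' parse_label_value("0,9")      # value 0.9, upper_bound FALSE
#' @export
parse_label_value <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop_lp("parse_label_value() expects a single character string")
  }
  raw <- trimws(text)
  if (!nzchar(raw)) stop_lp("cannot parse empty label value")
  upper <- startsWith(raw, "<")
  body <- if (upper) trimws(substring(raw, 2L)) else raw
  m <- regmatches(
    body,
    regexec("^([0-9]+(?:[.,][0-9]+)?)[ ]*(g|mg|µg|ug|mcg|kj|kcal)?$",
            body, ignore.case = TRUE)
  )[[1]]
  if (length(m) == 0L) stop_lp("cannot parse label value token '%s'", text)
  value <- as.numeric(gsub(",", ".", m[2], fixed = TRUE))
  list(value = value, upper_bound = upper)
}

# Vectorised internal variant used by the CSV reader; empty strings map to NA.
parse_label_values <- function(x) {
  n <- length(x)
  value <- rep(NA_real_, n)
  upper <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (!is.na(x[i]) && nzchar(trimws(x[i]))) {
      p <- parse_label_value(x[i])
      value[i] <- p$value
      upper[i] <- p$upper_bound
    }
  }
  data.frame(value = value, upper_bound = upper)
}

#' Convert energy between kJ and kcal
#'
#' The canonical energy unit throughout the package is kJ (the primary unit of
#' EU Regulation 1169/2011 declarations); kcal values are derived with the
#' conversion factor 4.184 kJ/kcal. Rounding is left to the caller.
#'
#' @param e non-negative energy value(s).
#' @return numeric vector of the same length.
#' @examples
#' kcal_from_kj(1142)  # 272.97...
#' kj_from_kcal(273)
#' @export
kcal_from_kj <- function(e) {
  if (!is.numeric(e)) stop_lp("energy must be numeric")
  if (any(!is.na(e) & e < 0)) stop_lp("energy must be non-negative")
  e / 4.184
}

#' @rdname kcal_from_kj
#' @export
kj_from_kcal <- function(e) {
  if (!is.numeric(e)) stop_lp("energy must be numeric")
  if (any(!is.na(e) & e < 0)) stop_lp("energy must be non-negative")
  e * 4.184
}
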