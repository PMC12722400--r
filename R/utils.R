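#' Round half away from zero
#'
#' Published disproportionality tables conventionally round half away from
#' zero (so 1.005 renders as 1.01), unlike [base::round()], which rounds
#' half to even. Used wherever results are rendered at table precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(2.675, 2)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Normalise a free-text key: trim, case-fold, map empty to NA.
norm_key <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[!is.na(x) & x == ""] <- NA_character_
  x
}

# Numeric view of id/date strings for ordering; NA -> -Inf so that missing
# values always lose a "most recent / highest" comparison.
num_or_neginf <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  v[is.na(v)] <- -Inf
  v
}

# Placeholder used when missing values must compare equal to each other
# inside composite duplicate keys.
NA_TOKEN <- "·NA·"

na_token <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- NA_TOKEN
  x
}
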