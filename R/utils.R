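#' Round half up
#'
#' Rounds with ties going away from zero, the convention used for all
#' reported percentages (base `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(c(0.125, 0.135), 2)
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  # tiny guard against values sitting an ulp below the .5 boundary after
  # division (all inputs here are ratios of integer counts)
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# lowercase, punctuation -> space, squeeze whitespace
normalize_text <- function(x) {
  x <- stringr::str_to_lower(x)
  x <- stringr::str_replace_all(x, "[^\\p{L}\\p{N}]+", " ")
  stringr::str_squish(x)
}

period_levels <- function() {
  c("pre_announcement", "between", "post_implementation")
}

assert_counts <- function(x, n) {
  if (any(n <= 0)) {
    rlang::abort("`n` must be positive.")
  }
  if (any(x < 0) || any(x > n)) {
    rlang::abort("`x` must satisfy 0 <= x <= n.")
  }
  invisible(TRUE)
}
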