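#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble
NULL

#' Pipe operator
#'
#' Re-exported from \pkg{magrittr}.
#'
#' @name %>%
#' @rdname pipe
#' @keywords internal
#' @importFrom magrittr %>%
#' @export
#' @usage lhs \%>\% rhs
#' @param lhs A value.
#' @param rhs A function call using the pipe semantics.
#' @return Result of `rhs(lhs)`.
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero (the convention
#' used by most spreadsheet-era population-genetics tables), unlike base
#' [round()] which rounds ties to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector of the same length.
#' @examples
#' round_half_up(17.8875, 2) # 17.89
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# standard error of a vector (sd / sqrt(n)); NA-safe
se_of <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# derive a bounded child seed from a master seed and an operation label,
# so each generator consumes its own stream and added operations never
# perturb existing outputs
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) + 7919 * h) %% .Machine$integer.max)
}
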