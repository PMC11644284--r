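#' Kosambi map function
#'
#' Convert between recombination fraction and Kosambi map distance. The
#' Kosambi function accounts for crossover interference:
#' `d = 25 * log((1 + 2r) / (1 - 2r))` centimorgans, with inverse
#' `r = tanh(d / 50) / 2`. The two functions are exact algebraic inverses.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @param d Map distance(s) in centimorgans, `>= 0`.
#' @return `kosambi_r_to_cm`: distance in cM. `kosambi_cm_to_r`:
#'   recombination fraction.
#' @examples
#' kosambi_r_to_cm(0.25)              # 25 * log(3) = 27.465...
#' kosambi_cm_to_r(kosambi_r_to_cm(0.1))
#' @export
kosambi_r_to_cm <- function(r) {
  if (any(!is.finite(r)) || any(r < 0) || any(r >= 0.5)) {
    stop("recombination fraction must lie in [0, 0.5)", call. = FALSE)
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_r_to_cm
#' @export
kosambi_cm_to_r <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("map distance must be >= 0", call. = FALSE)
  }
  tanh(d / 50) / 2
}

#' Recombinant inbred line transition probability
#'
#' Observed recombination between fixed genotypes of selfed recombinant
#' inbred lines exceeds the meiotic fraction: `R = 2r / (1 + 2r)`
#' (the Haldane-Waddington expansion). `ril_recombination` maps a Kosambi
#' map distance in cM to this line-level recombination probability.
#'
#' @param d Map distance(s) in cM.
#' @return Line-level recombination probability in `[0, 0.5)`.
#' @export
ril_recombination <- function(d) {
  r <- kosambi_cm_to_r(d)
  2 * r / (1 + 2 * r)
}
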