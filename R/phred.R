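#' Phred-scale conversions
#'
#' The Phred scale expresses an error probability `p` as
#' `q = -10 * log10(p)`; a mapping quality of 60 corresponds to a 1e-6
#' chance that the reported locus is wrong, and a consensus quality of 50 to
#' a 1e-5 chance that the called genotype is incorrect.
#'
#' @param p error probability in `(0, 1]`. `p = 0` is mapped to `max_q`
#'   rather than `Inf`.
#' @param q Phred-scaled quality, `q >= 0`.
#' @param digits rounding applied to the returned quality; `NA` (default)
#'   leaves it unrounded.
#' @param max_q cap used when `p` underflows to zero (default 255, the
#'   consensus-quality cap).
#' @return `phred()` returns the quality; `unphred()` the probability.
#' @examples
#' phred(0.1)        # 10
#' unphred(50)       # 1e-5
#' @export
phred <- function(p, digits = NA, max_q = 255) {
  stopifnot(all(p >= 0), all(p <= 1))
  q <- ifelse(p == 0, max_q, -10 * log10(p))
  q <- pmin(q, max_q)
  if (!is.na(digits)) q <- round(q, digits)
  q
}

#' @rdname phred
#' @export
unphred <- function(q) {
  stopifnot(all(q >= 0))
  10^(-q / 10)
}
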