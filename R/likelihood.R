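#' Composite log-likelihood of an observed joint SFS
#'
#' Multinomial composite likelihood over unlinked SNPs:
#' `lnL = sum_c n_c log pi_c`, where `n_c` are the (possibly fractional,
#' after projection) observed counts and `pi` the model's expected SFS
#' normalized over polymorphic configurations. Cells observed but given
#' zero expected mass receive the configured probability floor, with a
#' warning.
#'
#' @param observed A `joint_sfs`.
#' @param expected An `expected_sfs` at the same projected sizes. If
#'   `observed` is folded and `expected` is not, the expectation is folded
#'   first.
#' @param prob_floor Probability assigned to observed cells with zero
#'   expected mass.
#' @return The composite log-likelihood (scalar).
#' @export
composite_loglik <- function(observed, expected, prob_floor = 1e-30) {
  stopifnot(inherits(observed, "joint_sfs"), inherits(expected, "expected_sfs"))
  if (!identical(unname(observed$m), unname(as.integer(expected$n)))) {
    stop("observed and expected spectra have different projected sizes")
  }
  if (observed$folded && !expected$folded) expected <- fold_sfs(expected)
  if (!observed$folded && expected$folded) {
    stop("cannot score unfolded observations against a folded expectation")
  }
  n <- as.vector(observed$counts)
  p <- as.vector(expected$prob)
  obs <- n > 0
  zero <- obs & p <= 0
  if (any(zero)) {
    warning(sum(zero), " observed cell(s) with zero expected mass; ",
            "floored at ", format(prob_floor))
    p[zero] <- prob_floor
  }
  sum(n[obs] * log(p[obs]))
}
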