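#' Binary decision entropy
#'
#' Shannon entropy (in bits) of a binary accept/reject decision with
#' acceptance probability `p`:
#' \deqn{DE = -[p \log_2 p + (1-p) \log_2 (1-p)]}
#' with the convention \eqn{0 \log_2 0 = 0}. Maximal (1 bit) at `p = 0.5`,
#' zero at `p = 0` or `p = 1`.
#'
#' @param p numeric vector of probabilities in `[0, 1]`.
#' @return numeric vector of entropies in bits, in `[0, 1]`.
#' @seealso [inverse_decision_entropy()], [prob_correct()]
#' @export
#' @examples
#' decision_entropy(c(0, 0.5, 1))
decision_entropy <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("'p' must be probabilities in [0, 1]")
  q <- 1 - p
  plogp <- function(x) ifelse(x > 0, x * log2(x), 0)
  -(plogp(p) + plogp(q))
}

#' Inverse decision entropy (iDE)
#'
#' The negative of [decision_entropy()]: a confidence-like quantity in
#' `[-1, 0]` bits that is high (near 0) when the decision is nearly
#' deterministic and low (near -1) when the acceptance probability is
#' close to 0.5.
#'
#' @inheritParams decision_entropy
#' @return numeric vector in `[-1, 0]`.
#' @export
inverse_decision_entropy <- function(p) -decision_entropy(p)

#' Subjective probability of being correct
#'
#' `max(p, 1 - p)`: the model's probability of the response it favours.
#' Like iDE it is a strictly increasing function of `|p - 0.5|`, which is
#' why the two are rank-equivalent on tie-free data.
#'
#' @inheritParams decision_entropy
#' @return numeric vector in `[0.5, 1]`.
#' @export
prob_correct <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("'p' must be probabilities in [0, 1]")
  pmax(p, 1 - p)
}
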