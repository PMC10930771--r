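# Objective: paradoxical loss between shallow and deep auxiliary
# classifiers, binary cross-entropy on auxiliary and head outputs, and
# their unweighted sum.

#' Paradoxical loss
#'
#' Mean over the batch of `max(P1 - P3, 0)`: a penalty whenever the
#' shallow layer's patches identify the true label better than the deep
#' layer's ("paradoxical" samples). Zero iff `P3 >= P1` elementwise;
#' bounded in `[0, 1]`. The subgradient at ties is taken as 0.
#'
#' @param P1,P3 equal-length vectors of true-class probabilities from the
#'   shallow and deep auxiliary classifiers.
#' @export
paradoxical_loss <- function(P1, P3) {
  if (length(P1) != length(P3)) stop("P1 and P3 must have equal length")
  mean(pmax(P1 - P3, 0))
}

#' Binary cross-entropy
#'
#' Standard negated log-likelihood mean; probabilities are clamped by
#' `eps = 1e-7` before the logs.
#'
#' @param y binary labels.
#' @param y_hat predicted class-1 probabilities.
#' @export
bce_loss <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("y and y_hat must have equal length")
  eps <- 1e-7
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Total loss
#'
#' The unweighted sum `L1 + L2 + L3` (paradoxical + auxiliary
#' cross-entropy + head cross-entropy).
#' @param L1,L2,L3 loss terms.
#' @export
total_loss <- function(L1, L2, L3) L1 + L2 + L3

# --- tape versions (per-slide scalars) ---------------------------------------

ad_bce_scalar <- function(tape, y, p) {
  pr <- if (y == 1) p else ad_sub(tape, 1, p)
  ad_scale(tape, ad_log(tape, ad_clamp_min(tape, pr, 1e-7)), -1)
}

ad_paradox_scalar <- function(tape, P1, P3) {
  ad_clamp_min(tape, ad_sub(tape, P1, P3), 0)
}
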