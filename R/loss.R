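#' Focal loss
#'
#' `FL = -alpha_t (1 - p_t)^gamma log(p_t)` with `p_t = p` for positive labels
#' and `1 - p` otherwise, `alpha_t = alpha` for positives and `1 - alpha`
#' otherwise. `gamma = 0`, `alpha = 0.5` reduces to 0.5 x binary
#' cross-entropy.
#'
#' @param p Predicted probabilities in (0, 1).
#' @param y Labels in \{0, 1\}.
#' @param alpha Positive-class weight.
#' @param gamma Focusing exponent.
#' @return Per-sample losses (non-negative).
#' @export
focal_loss <- function(p, y, alpha = 0.25, gamma = 2.0) {
  if (any(p <= 0 | p >= 1)) stop("probabilities must be in (0, 1)", call. = FALSE)
  stopifnot(all(y %in% c(0, 1)))
  pt <- ifelse(y == 1, p, 1 - p)
  at <- ifelse(y == 1, alpha, 1 - alpha)
  -at * (1 - pt)^gamma * log(pt)
}

# d(focal loss)/d(logit), derived in closed form from p = sigmoid(z)
focal_grad_logit <- function(p, y, alpha = 0.25, gamma = 2.0) {
  gpos <- alpha * gamma * p * (1 - p)^gamma * log(p) - alpha * (1 - p)^(gamma + 1)
  gneg <- (1 - alpha) * (p^(gamma + 1) - gamma * p^gamma * (1 - p) * log(1 - p))
  ifelse(y == 1, gpos, gneg)
}

#' Multi-task masked loss
#'
#' Weighted sum over receptors of the mean focal loss over samples with an
#' observed label; receptors with no observed labels in the batch contribute
#' zero.
#'
#' @param probs n x R probability matrix.
#' @param labels n x R label matrix (`NA` = missing).
#' @param weights Per-receptor loss weights.
#' @param alpha,gamma Focal-loss parameters.
#' @return List with `loss` (scalar) and `grad_logits` (n x R matrix of
#'   d loss / d logit, zero where masked).
#' @export
multitask_loss <- function(probs, labels, weights, alpha = 0.25, gamma = 2.0) {
  stopifnot(all(dim(probs) == dim(labels)), length(weights) == ncol(probs))
  # confident logits saturate the sigmoid to exactly 0/1 in double precision
  probs <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  grad <- matrix(0, nrow(probs), ncol(probs), dimnames = dimnames(probs))
  loss <- 0
  any_observed <- FALSE
  for (r in seq_len(ncol(probs))) {
    obs <- which(!is.na(labels[, r]))
    if (length(obs) == 0 || weights[r] == 0) next
    any_observed <- TRUE
    fl <- focal_loss(probs[obs, r], labels[obs, r], alpha, gamma)
    loss <- loss + weights[r] * mean(fl)
    grad[obs, r] <- weights[r] *
      focal_grad_logit(probs[obs, r], labels[obs, r], alpha, gamma) / length(obs)
  }
  if (!any_observed) {
    warning("all labels missing in batch; loss is 0", call. = FALSE)
  }
  list(loss = loss, grad_logits = grad)
}
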