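#' Smooth-L1 (Huber-like) loss
#'
#' The robust regression loss of the detection head: elementwise
#' \eqn{0.5 x^2} for \eqn{|x| < 1} and \eqn{|x| - 0.5} otherwise, summed
#' over components. Continuous and once-differentiable at the branch point
#' \eqn{|x| = 1}, where both branches equal 0.5.
#'
#' @param x Numeric vector of offset differences.
#' @return Scalar loss.
#' @examples
#' smoothL1(c(2, 0, 0, 0))   # 1.5
#' smoothL1(c(0.5, 0, 0, 0)) # 0.125
#' @export
smoothL1 <- function(x) {
  stopifnot(all(is.finite(x)))
  a <- abs(x)
  sum(ifelse(a < 1, 0.5 * x^2, a - 0.5))
}

#' Binary classification loss per anchor
#'
#' Negative log-probability of the true class:
#' \eqn{-\log(b^* b + (1 - b^*)(1 - b))} for predicted foreground
#' probability \eqn{b} and binary label \eqn{b^*}. Vectorized over anchors.
#'
#' @param b Predicted probabilities in \code{[0, 1]}.
#' @param bStar Binary ground-truth labels.
#' @param eps Probabilities of the true class are clamped below at
#'   \code{eps} to keep the loss finite; set \code{strict = TRUE} to error
#'   instead.
#' @param strict Error on a zero true-class probability.
#' @return Numeric vector of per-anchor losses.
#' @examples
#' classificationLoss(0.5, 1)  # log 2
#' @export
classificationLoss <- function(b, bStar, eps = 1e-12, strict = FALSE) {
  stopifnot(length(b) == length(bStar),
            all(b >= 0 & b <= 1), all(bStar %in% c(0, 1)))
  pTrue <- bStar * b + (1 - bStar) * (1 - b)
  if (strict && any(pTrue == 0))
    stop("infinite loss: predicted probability of the true class is 0")
  -log(pmax(pTrue, eps))
}

#' Box-regression loss per anchor
#'
#' Smooth-L1 of the difference between predicted and target box offsets,
#' one scalar per anchor.
#'
#' @param d,dStar Numeric matrices (anchors x 4) of predicted and target
#'   offsets, or vectors for a single anchor; must match in dimension.
#' @return Numeric vector of per-anchor losses.
#' @export
regressionLoss <- function(d, dStar) {
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  if (is.null(dim(dStar))) dStar <- matrix(dStar, nrow = 1)
  if (!all(dim(d) == dim(dStar)))
    stop("dimension mismatch between d and dStar")
  apply(d - dStar, 1, smoothL1)
}

#' Multi-task detection loss
#'
#' The two-term objective of the region-proposal detector: a normalized
#' classification term plus a balance-weighted regression term counted only
#' on positive anchors,
#' \deqn{L = \frac{1}{N_c} \sum_i L_c(b_i, b_i^*) +
#'       \alpha \frac{1}{N_r} \sum_i b_i^* L_r(d_i, d_i^*).}
#' Zero iff every classification is perfect and every positive anchor's
#' offsets match their targets.
#'
#' @param b,bStar Predicted probabilities and binary labels per anchor.
#' @param d,dStar Predicted and target box offsets (anchors x 4).
#' @param nC,nR Classification / regression normalizers (defaults: the
#'   number of anchors).
#' @param alpha Balance weight (default 1).
#' @param eps,strict Passed to [classificationLoss()].
#' @return Scalar total loss.
#' @examples
#' totalLoss(b = 0.5, bStar = 1, d = rep(0, 4), dStar = rep(0, 4))  # log 2
#' @export
totalLoss <- function(b, bStar, d, dStar, nC = length(b), nR = length(b),
                      alpha = 1, eps = 1e-12, strict = FALSE) {
  stopifnot(nC >= 1, nR >= 1, alpha >= 0)
  cls <- classificationLoss(b, bStar, eps = eps, strict = strict)
  reg <- regressionLoss(d, dStar)
  stopifnot(length(reg) == length(bStar))
  sum(cls) / nC + alpha * sum(bStar * reg) / nR
}
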