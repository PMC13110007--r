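# Classification head: 1024 -> 512 (LeakyReLU, batch norm) -> dropout ->
# 256 (LeakyReLU) -> single logit -> sigmoid. Batch norm uses batch
# statistics while training and running statistics at evaluation; dropout
# is active only while training.

.BN_MOMENTUM <- 0.1

# Batched head forward. Fmat: B x 1024. Returns probabilities, cache and
# (in training mode) updated running statistics.
.headFwd <- function(Fmat, P, training = FALSE, dropoutRate = 0.2) {
  Z1 <- sweep(Fmat %*% P$head.W1, 2, P$head.b1, `+`)
  A1 <- .leakyRelu(Z1)
  if (training) {
    mu <- colMeans(A1)
    v <- colMeans(sweep(A1, 2, mu)^2)
    rmean <- (1 - .BN_MOMENTUM) * P$head.bn_rmean + .BN_MOMENTUM * mu
    rvar <- (1 - .BN_MOMENTUM) * P$head.bn_rvar + .BN_MOMENTUM * v
  } else {
    mu <- P$head.bn_rmean
    v <- P$head.bn_rvar
    rmean <- P$head.bn_rmean
    rvar <- P$head.bn_rvar
  }
  inv <- 1 / sqrt(v + .NORM_EPS)
  Xhat <- sweep(sweep(A1, 2, mu), 2, inv, `*`)
  H1 <- sweep(sweep(Xhat, 2, P$head.bn_g, `*`), 2, P$head.bn_b, `+`)
  if (training && dropoutRate > 0) {
    mask <- matrix(
      stats::rbinom(length(H1), 1, 1 - dropoutRate) / (1 - dropoutRate),
      nrow(H1), ncol(H1)
    )
    D1 <- H1 * mask
  } else {
    mask <- NULL
    D1 <- H1
  }
  Z2 <- sweep(D1 %*% P$head.W2, 2, P$head.b2, `+`)
  A2 <- .leakyRelu(Z2)
  z3 <- as.numeric(A2 %*% P$head.W3) + P$head.b3
  list(
    prob = .sigmoid(z3), logits = z3,
    rmean = rmean, rvar = rvar,
    cache = list(Fmat = Fmat, Z1 = Z1, A1 = A1, Xhat = Xhat, inv = inv,
                 mu = mu, mask = mask, D1 = D1, Z2 = Z2, A2 = A2,
                 training = training)
  )
}

# Backward from dz3 (length B). Returns parameter gradients and dF.
.headBwd <- function(fwd, P, dz3) {
  ca <- fwd$cache
  B <- length(dz3)
  grads <- list()
  grads$head.W3 <- crossprod(ca$A2, matrix(dz3, B, 1))
  grads$head.b3 <- sum(dz3)
  dA2 <- matrix(dz3, B, 1) %*% t(P$head.W3)
  dZ2 <- dA2 * .leakyReluGrad(ca$Z2)
  grads$head.W2 <- crossprod(ca$D1, dZ2)
  grads$head.b2 <- colSums(dZ2)
  dD1 <- tcrossprod(dZ2, P$head.W2)
  dH1 <- if (!is.null(ca$mask)) dD1 * ca$mask else dD1
  dXhat <- sweep(dH1, 2, P$head.bn_g, `*`)
  grads$head.bn_g <- colSums(dH1 * ca$Xhat)
  grads$head.bn_b <- colSums(dH1)
  if (ca$training) {
    cs1 <- colMeans(dXhat)
    cs2 <- colMeans(dXhat * ca$Xhat)
    dA1 <- sweep(
      dXhat - matrix(cs1, B, length(cs1), byrow = TRUE) -
        sweep(ca$Xhat, 2, cs2, `*`),
      2, ca$inv, `*`
    )
  } else {
    dA1 <- sweep(dXhat, 2, ca$inv, `*`)
  }
  dZ1 <- dA1 * .leakyReluGrad(ca$Z1)
  grads$head.W1 <- crossprod(ca$Fmat, dZ1)
  grads$head.b1 <- colSums(dZ1)
  list(grads = grads, dF = tcrossprod(dZ1, P$head.W1))
}

#' Predict probability from a fused representation
#'
#' Runs the MLP head on one or more 1024-dimensional fused vectors. In
#' evaluation mode (the default) batch normalization uses the stored
#' running statistics and dropout is disabled, so repeated calls are
#' deterministic.
#'
#' @param fused numeric vector of length 1024 or matrix (batch x 1024).
#' @param model an [InhibitorClassifier-class] (or a bare parameter list).
#' @param training logical; enables batch statistics and dropout.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predictProbability <- function(fused, model, training = FALSE) {
  P <- if (is(model, "InhibitorClassifier")) model@params else model
  Fmat <- if (is.matrix(fused)) fused else matrix(fused, 1)
  .headFwd(Fmat, P, training = training)$prob
}

#' Binary cross-entropy loss
#'
#' Mean of -[y log p + (1 - y) log(1 - p)] with probabilities clipped to
#' [1e-7, 1 - 1e-7].
#'
#' @param probs predicted probabilities.
#' @param labels 0/1 ground-truth labels.
#' @return scalar loss.
#' @export
bceLoss <- function(probs, labels) {
  eps <- 1e-7
  p <- pmin(pmax(probs, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}
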