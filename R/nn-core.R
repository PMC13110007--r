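# Shared numerical primitives for the neural blocks. Every forward has a
# matching closed-form reverse-mode gradient; end-to-end correctness is
# checked against finite differences in the test suite.

.LRELU_SLOPE <- 0.01
.NORM_EPS <- 1e-5

.leakyRelu <- function(x, slope = .LRELU_SLOPE) {
  ifelse(x > 0, x, slope * x)
}

.leakyReluGrad <- function(x, slope = .LRELU_SLOPE) {
  ifelse(x > 0, 1, slope)
}

# Row-wise softmax with an optional logical mask of admissible entries.
# Masked-out entries get probability 0; every row must keep at least one
# admissible entry.
.softmaxRows <- function(E, mask = NULL) {
  if (!is.null(mask)) E[!mask] <- -Inf
  m <- apply(E, 1, max)
  Z <- exp(E - m)
  Z / rowSums(Z)
}

# Reverse of .softmaxRows: given probabilities A and upstream dA, returns
# dE (zero on masked entries because A is zero there).
.softmaxRowsBack <- function(A, dA) {
  A * (dA - rowSums(A * dA))
}

# Per-row layer normalization with learnable per-channel scale/shift.
.layerNormFwd <- function(X, gamma, beta, eps = .NORM_EPS) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc^2)
  inv <- 1 / sqrt(v + eps)
  Xhat <- Xc * inv
  list(out = sweep(sweep(Xhat, 2, gamma, `*`), 2, beta, `+`),
       Xhat = Xhat, inv = inv, Xc = Xc)
}

.layerNormBwd <- function(cache, gamma, dOut) {
  n <- ncol(cache$Xhat)
  dXhat <- sweep(dOut, 2, gamma, `*`)
  dgamma <- colSums(dOut * cache$Xhat)
  dbeta <- colSums(dOut)
  rs1 <- rowSums(dXhat)
  rs2 <- rowSums(dXhat * cache$Xhat)
  dX <- (dXhat - rs1 / n - cache$Xhat * rs2 / n) * cache$inv
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# Per-graph, per-channel standardization (GraphNorm-style) with learnable
# scale/shift: channels are normalized over the nodes of one graph.
.graphNormFwd <- function(X, gamma, beta, eps = .NORM_EPS) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  v <- colMeans(Xc^2)
  inv <- 1 / sqrt(v + eps)
  Xhat <- sweep(Xc, 2, inv, `*`)
  list(out = sweep(sweep(Xhat, 2, gamma, `*`), 2, beta, `+`),
       Xhat = Xhat, inv = inv)
}

.graphNormBwd <- function(cache, gamma, dOut) {
  n <- nrow(cache$Xhat)
  dXhat <- sweep(dOut, 2, gamma, `*`)
  dgamma <- colSums(dOut * cache$Xhat)
  dbeta <- colSums(dOut)
  cs1 <- colMeans(dXhat)
  cs2 <- colMeans(dXhat * cache$Xhat)
  dX <- sweep(
    dXhat - matrix(cs1, n, length(cs1), byrow = TRUE) -
      sweep(cache$Xhat, 2, cs2, `*`),
    2, cache$inv, `*`
  )
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Xavier/Glorot uniform initialization.
.xavier <- function(fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(stats::runif(fanIn * fanOut, -lim, lim), fanIn, fanOut)
}
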