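# Protein encoder: two scaled dot-product multi-head graph attention
# layers over the residue contact map, each with four 32-dimensional heads,
# an output projection with bias, a residual connection (through a
# learnable 24 -> 128 adapter at layer 1) and GraphNorm. A global average
# pool followed by a 128 -> 512 projection yields the protein-level vector.

# Attention neighborhoods: contact neighbors plus self (so no softmax is
# ever empty).
.attentionMask <- function(edges, n) {
  M <- diag(TRUE, n)
  if (nrow(edges)) {
    M[edges] <- TRUE
    M[edges[, c(2, 1), drop = FALSE]] <- TRUE
  }
  M
}

#' Scaled dot-product attention scores of one head
#'
#' Computes e_mn = (Wq h_m)' (Wk h_n) / sqrt(32) for every admissible pair
#' (contact neighbors plus self); inadmissible pairs are -Inf.
#'
#' @param states residue states (n x in_dim).
#' @param edges contact edge matrix (two columns).
#' @param Wq,Wk in_dim x 32 projection matrices of the head.
#' @return n x n score matrix.
#' @export
gatScores <- function(states, edges, Wq, Wk) {
  n <- nrow(states)
  Q <- states %*% Wq
  K <- states %*% Wk
  E <- tcrossprod(Q, K) / sqrt(32)
  E[!.attentionMask(edges, n)] <- -Inf
  E
}

# One GAT layer forward. P_l: list with Wq, Wk, Wv (in x 128 as four
# 32-column head blocks), Wproj, b, gn_g, gn_b, and optionally Wres.
.gatLayerFwd <- function(H, mask, P_l) {
  n <- nrow(H)
  Q <- H %*% P_l$Wq
  K <- H %*% P_l$Wk
  V <- H %*% P_l$Wv
  A <- vector("list", 4)
  O <- matrix(0, n, 128)
  for (d in 1:4) {
    idx <- ((d - 1) * 32 + 1):(d * 32)
    E <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(32)
    A[[d]] <- .softmaxRows(E, mask)
    O[, idx] <- A[[d]] %*% V[, idx, drop = FALSE]
  }
  Tm <- sweep(O %*% P_l$Wproj, 2, P_l$b, `+`)
  R <- if (!is.null(P_l$Wres)) H %*% P_l$Wres else H
  gn <- .graphNormFwd(Tm + R, P_l$gn_g, P_l$gn_b)
  list(out = gn$out,
       cache = list(H = H, Q = Q, K = K, V = V, A = A, O = O, gn = gn))
}

.gatLayerBwd <- function(cache, mask, P_l, dOut) {
  gb <- .graphNormBwd(cache$gn, P_l$gn_g, dOut)
  dZ <- gb$dX                       # gradient on Tm + R
  grads <- list(gn_g = gb$dgamma, gn_b = gb$dbeta)
  # residual branch
  if (!is.null(P_l$Wres)) {
    grads$Wres <- crossprod(cache$H, dZ)
    dH <- tcrossprod(dZ, P_l$Wres)
  } else {
    dH <- dZ
  }
  # projection branch
  grads$Wproj <- crossprod(cache$O, dZ)
  grads$b <- colSums(dZ)
  dO <- tcrossprod(dZ, P_l$Wproj)
  dQ <- matrix(0, nrow(dO), 128)
  dK <- matrix(0, nrow(dO), 128)
  dV <- matrix(0, nrow(dO), 128)
  for (d in 1:4) {
    idx <- ((d - 1) * 32 + 1):(d * 32)
    Ad <- cache$A[[d]]
    dOd <- dO[, idx, drop = FALSE]
    Vd <- cache$V[, idx, drop = FALSE]
    dA <- tcrossprod(dOd, Vd)
    dV[, idx] <- crossprod(Ad, dOd)
    dE <- .softmaxRowsBack(Ad, dA)
    dQ[, idx] <- dE %*% cache$K[, idx, drop = FALSE] / sqrt(32)
    dK[, idx] <- crossprod(dE, cache$Q[, idx, drop = FALSE]) / sqrt(32)
  }
  grads$Wq <- crossprod(cache$H, dQ)
  grads$Wk <- crossprod(cache$H, dK)
  grads$Wv <- crossprod(cache$H, dV)
  dH <- dH + tcrossprod(dQ, P_l$Wq) + tcrossprod(dK, P_l$Wk) +
    tcrossprod(dV, P_l$Wv)
  list(dH = dH, grads = grads)
}

#' One graph attention layer
#'
#' Four-head scaled dot-product attention over contact neighborhoods
#' (plus self), concatenation of the 32-dimensional head outputs into 128
#' dimensions, linear projection with bias, residual connection and
#' GraphNorm.
#'
#' @param states residue states (n x in_dim; 24 at layer 1, 128 at
#'   layer 2).
#' @param edges contact edge matrix.
#' @param layerParams named list with Wq, Wk, Wv (in_dim x 128 head
#'   blocks), Wproj (128 x 128), b (128), gn_g, gn_b (128) and, when
#'   in_dim differs from 128, the residual adapter Wres (in_dim x 128).
#' @return list with \code{states} (n x 128) and \code{attention} (list of
#'   four n x n coefficient matrices; every admissible row sums to 1).
#' @export
gatLayer <- function(states, edges, layerParams) {
  mask <- .attentionMask(edges, nrow(states))
  fw <- .gatLayerFwd(states, mask, layerParams)
  list(states = fw$out, attention = fw$cache$A)
}

.protLayerParams <- function(P, l) {
  pre <- paste0("prot.", l, ".")
  out <- list(
    Wq = P[[paste0(pre, "Wq")]], Wk = P[[paste0(pre, "Wk")]],
    Wv = P[[paste0(pre, "Wv")]], Wproj = P[[paste0(pre, "Wproj")]],
    b = P[[paste0(pre, "b")]], gn_g = P[[paste0(pre, "gn_g")]],
    gn_b = P[[paste0(pre, "gn_b")]]
  )
  if (l == "l1") out$Wres <- P$prot.l1.Wres
  out
}

.proteinFwd <- function(X, edges, P) {
  mask <- .attentionMask(edges, nrow(X))
  p1 <- .protLayerParams(P, "l1")
  p2 <- .protLayerParams(P, "l2")
  f1 <- .gatLayerFwd(X, mask, p1)
  f2 <- .gatLayerFwd(f1$out, mask, p2)
  gmean <- colMeans(f2$out)
  list(
    node_states = f2$out,
    global_vector = as.numeric(gmean %*% P$prot.Wfinal),
    attention = list(l1 = f1$cache$A, l2 = f2$cache$A),
    cache = list(mask = mask, f1 = f1, f2 = f2, p1 = p1, p2 = p2)
  )
}

# Backward from a gradient on the final node states. The pooled global
# path (Wfinal) is exposed for inspection but feeds no loss, so it carries
# no gradient here.
.proteinBwd <- function(fwd, P, dH2) {
  ca <- fwd$cache
  b2 <- .gatLayerBwd(ca$f2$cache, ca$mask, ca$p2, dH2)
  b1 <- .gatLayerBwd(ca$f1$cache, ca$mask, ca$p1, b2$dH)
  grads <- list()
  for (nm in names(b1$grads)) grads[[paste0("prot.l1.", nm)]] <- b1$grads[[nm]]
  for (nm in names(b2$grads)) grads[[paste0("prot.l2.", nm)]] <- b2$grads[[nm]]
  grads
}

#' Encode a protein
#'
#' Runs the two-layer multi-head graph attention encoder over the residue
#' contact map and pools the residue states into a 512-dimensional
#' protein-level vector (global mean followed by the 128 -> 512
#' projection).
#'
#' @param graph a [ProteinGraph-class].
#' @param model an [InhibitorClassifier-class] (or a bare parameter list).
#' @return list with \code{node_states} (residues x 128),
#'   \code{global_vector} (512) and \code{attention} (per-layer, per-head
#'   coefficient matrices).
#' @export
encodeProtein <- function(graph, model) {
  P <- if (is(model, "InhibitorClassifier")) model@params else model
  out <- .proteinFwd(nodeFeatures(graph), graph@edges, P)
  out$cache <- NULL
  out
}
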