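# Bidirectional cross-attention fusion. Both node-state sets are lifted
# from 128 to 512 dimensions, then each direction runs 4-head scaled
# dot-product attention (queries from one side, keys/values from the
# other, 128-dimensional head subspaces), an output projection, a residual
# connection and per-token layer normalization. Mean pooling over tokens
# and concatenation give the 1024-dimensional joint representation.

.crossDirFwd <- function(Pq, Pkv, W) {
  if (nrow(Pkv) == 0) stop("cross-attention requires a non-empty key sequence")
  Q <- Pq %*% W$Wq
  K <- Pkv %*% W$Wk
  V <- Pkv %*% W$Wv
  nq <- nrow(Pq)
  A <- vector("list", 4)
  Cc <- matrix(0, nq, 512)
  for (m in 1:4) {
    idx <- ((m - 1) * 128 + 1):(m * 128)
    E <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(128)
    A[[m]] <- .softmaxRows(E)
    Cc[, idx] <- A[[m]] %*% V[, idx, drop = FALSE]
  }
  list(context = Cc %*% W$Wo,
       cache = list(Pq = Pq, Pkv = Pkv, Q = Q, K = K, V = V, A = A, Cc = Cc))
}

# Backward through one cross-attention direction. Weight gradients are
# returned as (input, delta) stacks so a mini-batch can fuse them into a
# single crossprod per tensor (`defer = TRUE`), or assembled immediately.
.crossDirBwd <- function(cache, W, dCtx, defer = FALSE) {
  dCc <- tcrossprod(dCtx, W$Wo)
  dQ <- matrix(0, nrow(cache$Pq), 512)
  dK <- matrix(0, nrow(cache$Pkv), 512)
  dV <- matrix(0, nrow(cache$Pkv), 512)
  for (m in 1:4) {
    idx <- ((m - 1) * 128 + 1):(m * 128)
    Am <- cache$A[[m]]
    dCm <- dCc[, idx, drop = FALSE]
    dA <- tcrossprod(dCm, cache$V[, idx, drop = FALSE])
    dV[, idx] <- crossprod(Am, dCm)
    dE <- .softmaxRowsBack(Am, dA)
    dQ[, idx] <- dE %*% cache$K[, idx, drop = FALSE] / sqrt(128)
    dK[, idx] <- crossprod(dE, cache$Q[, idx, drop = FALSE]) / sqrt(128)
  }
  stacks <- list(
    Wq = list(X = cache$Pq, D = dQ),
    Wk = list(X = cache$Pkv, D = dK),
    Wv = list(X = cache$Pkv, D = dV),
    Wo = list(X = cache$Cc, D = dCtx)
  )
  out <- list(
    dPq = tcrossprod(dQ, W$Wq),
    dPkv = tcrossprod(dK, W$Wk) + tcrossprod(dV, W$Wv)
  )
  if (defer) {
    out$stacks <- stacks
  } else {
    out$grads <- lapply(stacks, function(s) crossprod(s$X, s$D))
  }
  out
}

#' Multi-head cross-attention between two token sequences
#'
#' Queries come from one modality, keys and values from the other. Each of
#' the four heads attends in a 128-dimensional subspace with 1/sqrt(128)
#' scaling; the softmax runs over the key sequence. Head outputs are
#' concatenated and passed through the output projection.
#'
#' @param queries numeric matrix of 512-dimensional query tokens.
#' @param keyvals numeric matrix of 512-dimensional key/value tokens
#'   (non-empty).
#' @param dirParams list with Wq, Wk, Wv, Wo (each 512 x 512).
#' @return list with \code{context} (queries x 512) and \code{attention}
#'   (four queries x keys matrices; rows sum to 1).
#' @export
crossAttend <- function(queries, keyvals, dirParams) {
  fw <- .crossDirFwd(queries, keyvals, dirParams)
  list(context = fw$context, attention = fw$cache$A)
}

.fusDirParams <- function(P, dir) {
  pre <- paste0("fus.", dir, ".")
  list(Wq = P[[paste0(pre, "Wq")]], Wk = P[[paste0(pre, "Wk")]],
       Wv = P[[paste0(pre, "Wv")]], Wo = P[[paste0(pre, "Wo")]])
}

# Full fusion forward for one protein/ligand pair of node-state matrices
# (each n x 128). Optionally reuses precomputed lifted protein tokens.
.fusionFwd <- function(Hp, Hl, P) {
  Pp <- Hp %*% P$fus.Up
  Pl <- Hl %*% P$fus.Ul
  wp <- .fusDirParams(P, "p2l")
  wl <- .fusDirParams(P, "l2p")
  d1 <- .crossDirFwd(Pp, Pl, wp)
  ln_p <- .layerNormFwd(Pp + d1$context, P$fus.p2l.ln_g, P$fus.p2l.ln_b)
  d2 <- .crossDirFwd(Pl, Pp, wl)
  ln_l <- .layerNormFwd(Pl + d2$context, P$fus.l2p.ln_g, P$fus.l2p.ln_b)
  hbar_p <- colMeans(ln_p$out)
  hbar_l <- colMeans(ln_l$out)
  list(
    fused = c(hbar_p, hbar_l),
    hbar_p = hbar_p, hbar_l = hbar_l,
    attention_p2l = d1$cache$A, attention_l2p = d2$cache$A,
    cache = list(Hp = Hp, Hl = Hl, Pp = Pp, Pl = Pl,
                 d1 = d1, d2 = d2, ln_p = ln_p, ln_l = ln_l,
                 wp = wp, wl = wl)
  )
}

# Backward from dF (length 1024). With `defer = TRUE`, matrix-valued
# weight gradients come back as (input, delta) stacks keyed by parameter
# name; vector-valued gradients are always assembled.
.fusionBwd <- function(fwd, P, dF, defer = FALSE) {
  ca <- fwd$cache
  np <- nrow(ca$Pp)
  nl <- nrow(ca$Pl)
  dOp <- matrix(dF[1:512] / np, np, 512, byrow = TRUE)
  dOl <- matrix(dF[513:1024] / nl, nl, 512, byrow = TRUE)
  lb_p <- .layerNormBwd(ca$ln_p, P$fus.p2l.ln_g, dOp)
  lb_l <- .layerNormBwd(ca$ln_l, P$fus.l2p.ln_g, dOl)
  dPp <- lb_p$dX
  dPl <- lb_l$dX
  cb1 <- .crossDirBwd(ca$d1$cache, ca$wp, lb_p$dX, defer = defer)
  dPp <- dPp + cb1$dPq
  dPl <- dPl + cb1$dPkv
  cb2 <- .crossDirBwd(ca$d2$cache, ca$wl, lb_l$dX, defer = defer)
  dPl <- dPl + cb2$dPq
  dPp <- dPp + cb2$dPkv
  vecGrads <- list(
    fus.p2l.ln_g = lb_p$dgamma, fus.p2l.ln_b = lb_p$dbeta,
    fus.l2p.ln_g = lb_l$dgamma, fus.l2p.ln_b = lb_l$dbeta
  )
  out <- list(vecGrads = vecGrads,
              dHp = tcrossprod(dPp, P$fus.Up),
              dHl = tcrossprod(dPl, P$fus.Ul))
  if (defer) {
    st <- list(fus.Up = list(X = ca$Hp, D = dPp),
               fus.Ul = list(X = ca$Hl, D = dPl))
    for (nm in names(cb1$stacks)) st[[paste0("fus.p2l.", nm)]] <- cb1$stacks[[nm]]
    for (nm in names(cb2$stacks)) st[[paste0("fus.l2p.", nm)]] <- cb2$stacks[[nm]]
    out$stacks <- st
  } else {
    grads <- vecGrads
    grads$fus.Up <- crossprod(ca$Hp, dPp)
    grads$fus.Ul <- crossprod(ca$Hl, dPl)
    for (nm in names(cb1$grads)) grads[[paste0("fus.p2l.", nm)]] <- cb1$grads[[nm]]
    for (nm in names(cb2$grads)) grads[[paste0("fus.l2p.", nm)]] <- cb2$grads[[nm]]
    out$grads <- grads
  }
  out
}

#' Fuse protein and ligand node representations
#'
#' Bidirectional cross-attention at node level: protein tokens attend over
#' ligand tokens and vice versa, each direction followed by residual +
#' layer normalization; mean pooling over residues and atoms and
#' concatenation produce the joint 1024-dimensional representation.
#'
#' @param proteinNodes residue states (residues x 128).
#' @param ligandNodes atom states (atoms x 128).
#' @param model an [InhibitorClassifier-class] (or a bare parameter list).
#' @return list with \code{fused} (1024), \code{hbar_p}, \code{hbar_l}
#'   (512 each), and per-direction attention maps.
#' @export
fuseRepresentations <- function(proteinNodes, ligandNodes, model) {
  P <- if (is(model, "InhibitorClassifier")) model@params else model
  out <- .fusionFwd(proteinNodes, ligandNodes, P)
  out$cache <- NULL
  out
}
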