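# Ligand encoder: dilated-neighborhood GraphSAGE over the molecular graph.
# Layer k (k = 0, 1, 2) aggregates, for every atom, the mean state of the
# atoms at shortest-path distance exactly 2^k, applies a learnable 128x128
# map and a LeakyReLU. A 4-head attention pooling then produces a
# 512-dimensional molecule-level vector.

#' Dilated neighborhood of a node
#'
#' Atoms at shortest-path (bond-count) distance exactly 2^k from the query
#' node: direct neighbors at k = 0, two-bond neighbors at k = 1, four-bond
#' neighbors at k = 2. May be empty (e.g. any node of a triangle at k = 2).
#'
#' @param graph a [MolecularGraph-class], or a list with an \code{edges}
#'   matrix and \code{n} nodes.
#' @param node query node index.
#' @param k dilation exponent, one of 0, 1, 2.
#' @return integer vector of node indices (possibly empty).
#' @export
dilatedNeighborhood <- function(graph, node, k) {
  stopifnot(k %in% 0:2)
  if (is(graph, "MolecularGraph")) {
    n <- atomCount(graph)
    edges <- graph@edges
  } else {
    n <- graph$n
    edges <- graph$edges
  }
  d <- .shortestPathMatrix(edges, n)
  which(d[node, ] == 2^k)
}

.shortestPathMatrix <- function(edges, n) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::distances(g)
}

# Mean-aggregation operators for dilations 1, 2, 4; rows with an empty
# neighborhood fall back to aggregating over the node itself.
.ligandAggregators <- function(edges, n) {
  d <- .shortestPathMatrix(edges, n)
  lapply(c(1, 2, 4), function(target) {
    A <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- which(d[i, ] == target)
      if (length(nb) == 0) nb <- i
      A[i, nb] <- 1 / length(nb)
    }
    A
  })
}

#' One dilated GraphSAGE layer
#'
#' For every node, the mean of the 128-dimensional states over its dilated
#' neighborhood (distance exactly 2^k; the node itself when the
#' neighborhood is empty) is mapped by \code{W} and passed through a
#' LeakyReLU.
#'
#' @param states numeric matrix, nodes x 128.
#' @param graph a [MolecularGraph-class] or list with \code{edges},
#'   \code{n}.
#' @param k dilation exponent (0, 1 or 2).
#' @param W 128 x 128 weight matrix.
#' @param slope LeakyReLU negative slope.
#' @return updated state matrix, nodes x 128.
#' @export
sageLayer <- function(states, graph, k, W, slope = 0.01) {
  stopifnot(k %in% 0:2)
  edges <- if (is(graph, "MolecularGraph")) graph@edges else graph$edges
  n <- nrow(states)
  A <- .ligandAggregators(edges, n)[[k + 1]]
  .leakyRelu((A %*% states) %*% W, slope)
}

#' Multi-head attention pooling over atom states
#'
#' Each of the four heads scores every atom by a learnable query vector
#' (scaled by 1/sqrt(128)), normalizes the scores with a softmax over
#' atoms, and pools the states with those weights. The concatenated head
#' outputs (4 x 128) are projected to a 512-dimensional global vector.
#'
#' @param states numeric matrix, atoms x 128 (at least one atom).
#' @param Q 4 x 128 matrix of head query vectors.
#' @param Wpool 512 x 512 projection.
#' @return list with \code{global_vector} (length 512) and
#'   \code{head_weights} (atoms x 4; every column sums to 1).
#' @export
attentionPool <- function(states, Q, Wpool) {
  if (nrow(states) == 0) stop("attention pooling requires at least one atom")
  L <- states %*% t(Q) / sqrt(128)            # atoms x 4
  B <- apply(L, 2, function(col) {
    e <- exp(col - max(col))
    e / sum(e)
  })
  B <- matrix(B, nrow = nrow(states), ncol = 4)
  pooled <- t(B) %*% states                   # 4 x 128
  concat <- as.numeric(t(pooled))             # head-major, length 512
  list(
    global_vector = as.numeric(concat %*% Wpool),
    head_weights = B
  )
}

# Full ligand-encoder forward pass with cache for the backward pass.
# Aggregation operators depend only on the topology and may be passed in
# precomputed (they are reused across epochs during training).
.ligandFwd <- function(X, edges, P, aggregators = NULL) {
  n <- nrow(X)
  A <- if (is.null(aggregators)) .ligandAggregators(edges, n) else aggregators
  H0 <- X %*% P$lig.proj
  Ws <- list(P$lig.W1, P$lig.W2, P$lig.W3)
  Hs <- list(H0)
  Ms <- vector("list", 3)
  Zs <- vector("list", 3)
  H <- H0
  for (k in 1:3) {
    M <- A[[k]] %*% H
    Z <- M %*% Ws[[k]]
    H <- .leakyRelu(Z)
    Ms[[k]] <- M; Zs[[k]] <- Z; Hs[[k + 1]] <- H
  }
  pool <- attentionPool(H, P$lig.Q, P$lig.Wpool)
  list(
    node_states = H, global_vector = pool$global_vector,
    head_weights = pool$head_weights,
    cache = list(X = X, A = A, Hs = Hs, Ms = Ms, Zs = Zs)
  )
}

# Backward through the three dilated layers given the gradient on the
# final node states (the pooled path carries no classification gradient:
# fusion consumes node states). Returns parameter gradients, or (input,
# delta) stacks when deferred for batched accumulation.
.ligandBwd <- function(fwd, P, dH, defer = FALSE) {
  cache <- fwd$cache
  Ws <- list(P$lig.W1, P$lig.W2, P$lig.W3)
  stacks <- list()
  for (k in 3:1) {
    dZ <- dH * .leakyReluGrad(cache$Zs[[k]])
    stacks[[paste0("lig.W", k)]] <- list(X = cache$Ms[[k]], D = dZ)
    dM <- tcrossprod(dZ, Ws[[k]])
    dH <- crossprod(cache$A[[k]], dM)
  }
  stacks[["lig.proj"]] <- list(X = cache$X, D = dH)
  if (defer) return(stacks)
  lapply(stacks, function(s) crossprod(s$X, s$D))
}

#' Encode a ligand
#'
#' Runs the full ligand encoder: input projection 105 -> 128, three dilated
#' GraphSAGE layers (dilations 1, 2, 4) and 4-head attention pooling.
#'
#' @param graph a [MolecularGraph-class].
#' @param model an [InhibitorClassifier-class] (or a bare parameter list).
#' @return list with \code{node_states} (atoms x 128),
#'   \code{global_vector} (512) and \code{head_weights} (atoms x 4).
#' @export
encodeLigand <- function(graph, model) {
  P <- if (is(model, "InhibitorClassifier")) model@params else model
  out <- .ligandFwd(nodeFeatures(graph), graph@edges, P)
  out$cache <- NULL
  out
}
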