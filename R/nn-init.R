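# Parameter initialization and checkpointing for the full model.

# Names of non-learnable buffers living alongside the parameters.
.BUFFER_NAMES <- c("head.bn_rmean", "head.bn_rvar")

#' Initialize model parameters
#'
#' Creates the full set of learnable tensors of the three neural blocks at
#' the architecture's fixed dimensions: ligand encoder (105 -> 128 input
#' projection, three 128 x 128 dilated-aggregation layers, 4-head attention
#' pooling to 512), protein encoder (two 4-head dot-product attention
#' layers with 32-dimensional heads, GraphNorm, residual adapter, 128 ->
#' 512 global projection), bidirectional cross-attention fusion (128 -> 512
#' node lifts, per-direction 512 x 512 query/key/value/output maps and
#' layer norms) and the MLP head (1024 -> 512 -> 256 -> 1 with batch norm
#' and dropout). Weights use Xavier-uniform initialization; scales start at
#' 1, shifts and biases at 0.
#'
#' @param seed integer seed controlling the initialization draw.
#' @return named list of parameter matrices/vectors (plus batch-norm
#'   running-statistic buffers).
#' @export
initModelParams <- function(seed = 1L) {
  set.seed(seed)
  P <- list()
  P$lig.proj <- .xavier(105, 128)
  P$lig.W1 <- .xavier(128, 128)
  P$lig.W2 <- .xavier(128, 128)
  P$lig.W3 <- .xavier(128, 128)
  P$lig.Q <- .xavier(4, 128)
  P$lig.Wpool <- .xavier(512, 512)

  for (l in c("l1", "l2")) {
    din <- if (l == "l1") 24 else 128
    P[[paste0("prot.", l, ".Wq")]] <- .xavier(din, 128)
    P[[paste0("prot.", l, ".Wk")]] <- .xavier(din, 128)
    P[[paste0("prot.", l, ".Wv")]] <- .xavier(din, 128)
    P[[paste0("prot.", l, ".Wproj")]] <- .xavier(128, 128)
    P[[paste0("prot.", l, ".b")]] <- numeric(128)
    P[[paste0("prot.", l, ".gn_g")]] <- rep(1, 128)
    P[[paste0("prot.", l, ".gn_b")]] <- numeric(128)
  }
  P$prot.l1.Wres <- .xavier(24, 128)
  P$prot.Wfinal <- .xavier(128, 512)

  P$fus.Up <- .xavier(128, 512)
  P$fus.Ul <- .xavier(128, 512)
  for (dir in c("p2l", "l2p")) {
    for (w in c("Wq", "Wk", "Wv", "Wo")) {
      P[[paste0("fus.", dir, ".", w)]] <- .xavier(512, 512)
    }
    P[[paste0("fus.", dir, ".ln_g")]] <- rep(1, 512)
    P[[paste0("fus.", dir, ".ln_b")]] <- numeric(512)
  }

  P$head.W1 <- .xavier(1024, 512)
  P$head.b1 <- numeric(512)
  P$head.bn_g <- rep(1, 512)
  P$head.bn_b <- numeric(512)
  P$head.W2 <- .xavier(512, 256)
  P$head.b2 <- numeric(256)
  P$head.W3 <- .xavier(256, 1)
  P$head.b3 <- numeric(1)
  P$head.bn_rmean <- numeric(512)
  P$head.bn_rvar <- rep(1, 512)
  P
}

.learnableNames <- function(params) {
  setdiff(names(params), .BUFFER_NAMES)
}

#' Save a classifier checkpoint
#'
#' Writes the named-tensor archive (parameters, buffers, normalization
#' statistics and training configuration) to disk.
#'
#' @param model an [InhibitorClassifier-class].
#' @param path output file.
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(
    params = model@params,
    normStats = model@normStats,
    config = model@config
  ), path)
  invisible(path)
}

#' Load a classifier checkpoint
#'
#' @param path file written by [saveCheckpoint()].
#' @return an [InhibitorClassifier-class].
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  new("InhibitorClassifier",
    params = obj$params, normStats = obj$normStats, config = obj$config
  )
}
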