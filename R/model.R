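# End-to-end pair model: ligand encoder + protein encoder + fusion + head,
# with the assembled reverse pass used by the trainer.

#' Score one protein-ligand pair
#'
#' Full forward pass: encode the ligand and the protein, fuse the node
#' representations with bidirectional cross-attention and run the MLP head
#' in evaluation mode.
#'
#' @param molGraph a [MolecularGraph-class].
#' @param protGraph a [ProteinGraph-class].
#' @param model an [InhibitorClassifier-class] (or bare parameter list).
#' @return list with \code{probability}, \code{fused} (1024),
#'   \code{attention_p2l}, \code{attention_l2p}.
#' @export
predictPair <- function(molGraph, protGraph, model) {
  P <- if (is(model, "InhibitorClassifier")) model@params else model
  lig <- .ligandFwd(nodeFeatures(molGraph), molGraph@edges, P)
  prot <- .proteinFwd(nodeFeatures(protGraph), protGraph@edges, P)
  fus <- .fusionFwd(prot$node_states, lig$node_states, P)
  prob <- as.numeric(.headFwd(matrix(fus$fused, 1), P, training = FALSE)$prob)
  list(
    probability = prob,
    fused = fus$fused,
    attention_p2l = fus$attention_p2l,
    attention_l2p = fus$attention_l2p
  )
}

# Batched evaluation of many ligands against one protein forward pass.
.scoreBatch <- function(ligGraphs, protFwd, P, aggregators = NULL) {
  if (!length(ligGraphs)) return(numeric(0))
  Fmat <- t(vapply(seq_along(ligGraphs), function(i) {
    g <- ligGraphs[[i]]
    lig <- .ligandFwd(nodeFeatures(g), g@edges, P,
                      aggregators = aggregators[[i]])
    .fusionFwd(protFwd$node_states, lig$node_states, P)$fused
  }, numeric(1024)))
  as.numeric(.headFwd(Fmat, P, training = FALSE)$prob)
}

# One training step over a mini-batch: returns loss, probabilities,
# gradients for every learnable tensor, and updated batch-norm buffers.
# Per-sample weight gradients of the fusion and ligand blocks are fused
# into one stacked crossprod per tensor.
.trainStep <- function(ligGraphs, labels, Xp, edgesP, P, dropoutRate,
                       aggregators = NULL) {
  B <- length(ligGraphs)
  protFwd <- .proteinFwd(Xp, edgesP, P)
  ligFwds <- vector("list", B)
  fusFwds <- vector("list", B)
  Fmat <- matrix(0, B, 1024)
  for (i in seq_len(B)) {
    g <- ligGraphs[[i]]
    ligFwds[[i]] <- .ligandFwd(nodeFeatures(g), g@edges, P,
                               aggregators = aggregators[[i]])
    fusFwds[[i]] <- .fusionFwd(protFwd$node_states, ligFwds[[i]]$node_states, P)
    Fmat[i, ] <- fusFwds[[i]]$fused
  }
  hf <- .headFwd(Fmat, P, training = TRUE, dropoutRate = dropoutRate)
  probs <- as.numeric(hf$prob)
  loss <- bceLoss(probs, labels)
  # combined sigmoid + BCE gradient on the logit
  dz3 <- (probs - labels) / B
  hb <- .headBwd(hf, P, dz3)
  grads <- hb$grads
  stacks <- list()  # name -> list of per-sample (X, D) pairs
  addVec <- function(acc, g) {
    for (nm in names(g)) {
      acc[[nm]] <- if (is.null(acc[[nm]])) g[[nm]] else acc[[nm]] + g[[nm]]
    }
    acc
  }
  pushStacks <- function(st) {
    for (nm in names(st)) {
      stacks[[nm]][[length(stacks[[nm]]) + 1L]] <<- st[[nm]]
    }
  }
  dHpTotal <- matrix(0, nrow(Xp), 128)
  for (i in seq_len(B)) {
    fb <- .fusionBwd(fusFwds[[i]], P, hb$dF[i, ], defer = TRUE)
    grads <- addVec(grads, fb$vecGrads)
    pushStacks(fb$stacks)
    dHpTotal <- dHpTotal + fb$dHp
    pushStacks(.ligandBwd(ligFwds[[i]], P, fb$dHl, defer = TRUE))
  }
  for (nm in names(stacks)) {
    Xall <- do.call(rbind, lapply(stacks[[nm]], `[[`, "X"))
    Dall <- do.call(rbind, lapply(stacks[[nm]], `[[`, "D"))
    grads[[nm]] <- crossprod(Xall, Dall)
  }
  grads <- addVec(grads, .proteinBwd(protFwd, P, dHpTotal))
  list(loss = loss, probs = probs, grads = grads,
       bn_rmean = hf$rmean, bn_rvar = hf$rvar)
}

# Full-model gradients of the mean BCE loss for a batch; used by the
# finite-difference gradient checks (dropout disabled for determinism).
.lossAndGrads <- function(ligGraphs, labels, protGraph, P) {
  .trainStep(ligGraphs, labels, nodeFeatures(protGraph), protGraph@edges,
             P, dropoutRate = 0)
}
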