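# Virtual screening: curate candidates, score them against a protein
# graph, apply the confidence threshold and emit a deterministic ranking.

#' Screen candidate molecules against a protein
#'
#' Optionally runs the full curation pipeline on the candidates, encodes
#' the survivors with the model's stored normalization statistics, scores
#' every (candidate, protein) pair and returns a ranked table. Ranking is
#' by descending probability with ties broken by canonical SMILES
#' lexicographic order, so re-running permutes nothing. Candidates that
#' cannot be featurized are skipped and logged.
#'
#' @param candidates character vector of SMILES strings.
#' @param protein a [ProteinGraph-class].
#' @param model a trained [InhibitorClassifier-class].
#' @param threshold confidence threshold; a candidate passes when its
#'   probability is >= threshold (default 0.97).
#' @param applyFilters run [runFilterPipeline()] first (default TRUE).
#' @return list with \code{results} (data.frame: rank, smiles_canonical,
#'   probability, passed_threshold) and \code{removed} (data.frame:
#'   smiles, reason).
#' @export
screenCandidates <- function(candidates, protein, model, threshold = 0.97,
                             applyFilters = TRUE) {
  removed <- data.frame(smiles = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  if (applyFilters) {
    fp <- runFilterPipeline(candidates)
    if (nrow(fp$audit)) {
      removed <- data.frame(
        smiles = fp$audit$input_smiles,
        reason = paste0("filter:", fp$audit$stage),
        stringsAsFactors = FALSE
      )
    }
    smis <- fp$survivors$smiles_canonical
  } else {
    smis <- normalizeSmiles(candidates)
    bad <- is.na(smis)
    if (any(bad)) {
      removed <- rbind(removed, data.frame(
        smiles = candidates[bad], reason = "unparseable"
      ))
      smis <- smis[!bad]
    }
    smis <- unique(smis)
  }
  st <- model@normStats
  graphs <- list()
  kept <- character(0)
  for (s in smis) {
    g <- tryCatch(featurizeMolecule(s, st), error = function(e) NULL)
    if (is.null(g)) {
      removed <- rbind(removed, data.frame(smiles = s, reason = "unfeaturizable"))
      next
    }
    graphs[[length(graphs) + 1L]] <- g
    kept <- c(kept, s)
  }
  if (!length(graphs)) {
    return(list(
      results = data.frame(
        rank = integer(0), smiles_canonical = character(0),
        probability = numeric(0), passed_threshold = logical(0)
      ),
      removed = removed
    ))
  }
  protFwd <- .proteinFwd(nodeFeatures(protein), protein@edges, model@params)
  probs <- .scoreBatch(graphs, protFwd, model@params)
  ord <- order(-probs, kept)
  results <- data.frame(
    rank = seq_along(ord),
    smiles_canonical = kept[ord],
    probability = probs[ord],
    passed_threshold = probs[ord] >= threshold,
    stringsAsFactors = FALSE
  )
  list(results = results, removed = removed)
}

#' Crop a protein graph to a residue index window
#'
#' Induced subgraph on the residues lying within \code{radius} positions
#' of any center index; node features are carried over unchanged and
#' contacts are re-indexed. Intended for focusing large structures on a
#' user-specified region (no automatic pocket detection).
#'
#' @param protein a [ProteinGraph-class].
#' @param centers integer vector of center residue indices.
#' @param radius window half-width in residue positions.
#' @return a [ProteinGraph-class] on the selected residues.
#' @export
cropResidueWindow <- function(protein, centers, radius) {
  n <- residueCount(protein)
  keep <- sort(unique(unlist(lapply(centers, function(c0) {
    seq(max(1, c0 - radius), min(n, c0 + radius))
  }))))
  idxMap <- integer(n)
  idxMap[keep] <- seq_along(keep)
  e <- protein@edges
  sel <- e[, 1] %in% keep & e[, 2] %in% keep
  newEdges <- cbind(idxMap[e[sel, 1]], idxMap[e[sel, 2]])
  storage.mode(newEdges) <- "integer"
  if (nrow(newEdges) == 0) newEdges <- matrix(integer(0), ncol = 2)
  new("ProteinGraph",
    nodeFeatures = protein@nodeFeatures[keep, , drop = FALSE],
    edges = newEdges,
    species = protein@species,
    residues = protein@residues[keep, , drop = FALSE]
  )
}
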