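#' @import methods
NULL

#' Molecular graph with atom-level features
#'
#' An undirected heavy-atom graph of a small molecule. Nodes carry a
#' 105-dimensional feature vector: a 100-slot one-hot over atomic numbers
#' 1--100, a z-scored formal charge, a min-max scaled van der Waals radius,
#' an aromaticity flag and a two-slot R/S chirality descriptor.
#'
#' @slot nodeFeatures numeric matrix, atoms x 105.
#' @slot edges integer matrix with two columns (atom indices, i < j), one
#'   row per bond; interpreted symmetrically.
#' @slot smiles canonical SMILES string of the molecule.
#' @slot atoms data.frame of atom descriptors (symbol, atomic_number,
#'   formal_charge, vdw_radius, is_aromatic, cip_code).
#'
#' @exportClass MolecularGraph
setClass("MolecularGraph",
  representation(
    nodeFeatures = "matrix",
    edges = "matrix",
    smiles = "character",
    atoms = "data.frame"
  )
)

setValidity("MolecularGraph", function(object) {
  msg <- character()
  n <- nrow(object@nodeFeatures)
  if (ncol(object@nodeFeatures) != 105) {
    msg <- c(msg, "nodeFeatures must have exactly 105 columns")
  }
  e <- object@edges
  if (nrow(e) > 0) {
    if (ncol(e) != 2) msg <- c(msg, "edges must have two columns")
    else {
      if (any(e < 1) || any(e > n)) msg <- c(msg, "edge endpoints out of range")
      if (any(e[, 1] == e[, 2])) msg <- c(msg, "self-edges are not allowed")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Protein residue contact-map graph
#'
#' Residues are nodes; an edge joins two residues whose alpha-carbons lie
#' closer than the contact cutoff (8 Angstrom by default). Each node carries
#' a 24-dimensional feature vector: a 20-slot amino-acid one-hot, a 3-class
#' secondary-structure assignment (helix, sheet, coil) and a binary solvent
#' exposure flag (relative accessible surface area >= 25%).
#'
#' @slot nodeFeatures numeric matrix, residues x 24.
#' @slot edges integer matrix with two columns (residue indices, i < j).
#' @slot species species tag carried through from the data source.
#' @slot residues data.frame of residue records (aa, resno, coordinates,
#'   ss3 columns, rsa).
#'
#' @exportClass ProteinGraph
setClass("ProteinGraph",
  representation(
    nodeFeatures = "matrix",
    edges = "matrix",
    species = "character",
    residues = "data.frame"
  )
)

setValidity("ProteinGraph", function(object) {
  msg <- character()
  n <- nrow(object@nodeFeatures)
  if (ncol(object@nodeFeatures) != 24) {
    msg <- c(msg, "nodeFeatures must have exactly 24 columns")
  }
  e <- object@edges
  if (nrow(e) > 0) {
    if (any(e < 1) || any(e > n)) msg <- c(msg, "edge endpoints out of range")
    if (any(e[, 1] == e[, 2])) msg <- c(msg, "self-edges are not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' Inhibitor classification model
#'
#' Bundles the learnable parameters of the three neural blocks (ligand
#' encoder, protein encoder, fusion + head), the atom-feature normalization
#' statistics of the training corpus, and the training configuration.
#'
#' @slot params named list of parameter matrices/vectors.
#' @slot normStats list with charge_mean, charge_std, vdw_min, vdw_max.
#' @slot config list of training settings (see [trainConfig()]).
#'
#' @exportClass InhibitorClassifier
setClass("InhibitorClassifier",
  representation(
    params = "list",
    normStats = "list",
    config = "list"
  )
)

#' @describeIn MolecularGraph number of atoms
#' @param object a \code{MolecularGraph} or \code{ProteinGraph}
#' @export
setGeneric("atomCount", function(object) standardGeneric("atomCount"))
setMethod("atomCount", "MolecularGraph", function(object) nrow(object@nodeFeatures))

#' @describeIn ProteinGraph number of residues
#' @export
setGeneric("residueCount", function(object) standardGeneric("residueCount"))
setMethod("residueCount", "ProteinGraph", function(object) nrow(object@nodeFeatures))

#' Node feature matrix of a graph object
#' @param object a \code{MolecularGraph} or \code{ProteinGraph}
#' @return numeric matrix (nodes x feature dimension)
#' @export
setGeneric("nodeFeatures", function(object) standardGeneric("nodeFeatures"))
setMethod("nodeFeatures", "MolecularGraph", function(object) object@nodeFeatures)
setMethod("nodeFeatures", "ProteinGraph", function(object) object@nodeFeatures)

#' Edge list of a graph object
#' @param object a \code{MolecularGraph} or \code{ProteinGraph}
#' @return two-column integer matrix, one row per undirected edge (i < j)
#' @export
setGeneric("edgeMatrix", function(object) standardGeneric("edgeMatrix"))
setMethod("edgeMatrix", "MolecularGraph", function(object) object@edges)
setMethod("edgeMatrix", "ProteinGraph", function(object) object@edges)

#' Canonical SMILES of a molecular graph
#' @param object a \code{MolecularGraph}
#' @export
setGeneric("canonicalSmiles", function(object) standardGeneric("canonicalSmiles"))
setMethod("canonicalSmiles", "MolecularGraph", function(object) object@smiles)

#' Species tag of a protein graph
#' @param object a \code{ProteinGraph}
#' @export
setGeneric("speciesTag", function(object) standardGeneric("speciesTag"))
setMethod("speciesTag", "ProteinGraph", function(object) object@species)

setMethod("show", "MolecularGraph", function(object) {
  cat(sprintf(
    "MolecularGraph: %d atoms, %d bonds\n  SMILES: %s\n",
    atomCount(object), nrow(object@edges), object@smiles
  ))
})

setMethod("show", "ProteinGraph", function(object) {
  cat(sprintf(
    "ProteinGraph: %d residues, %d contacts (species: %s)\n",
    residueCount(object), nrow(object@edges),
    if (length(object@species)) object@species else "unset"
  ))
})

setMethod("show", "InhibitorClassifier", function(object) {
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf(
    "InhibitorClassifier: %d tensors, %s parameters\n",
    length(object@params), format(np, big.mark = ",")
  ))
})

#' Model parameters of a classifier
#' @param object an \code{InhibitorClassifier}
#' @export
setGeneric("modelParams", function(object) standardGeneric("modelParams"))
setMethod("modelParams", "InhibitorClassifier", function(object) object@params)

#' Atom-feature normalization statistics of a classifier
#' @param object an \code{InhibitorClassifier}
#' @export
setGeneric("normStats", function(object) standardGeneric("normStats"))
setMethod("normStats", "InhibitorClassifier", function(object) object@normStats)
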