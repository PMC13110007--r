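# Atom featurization: the 105-dimensional encoding
# [one-hot(Z, 100) | z-scored formal charge | min-max scaled vdW radius |
#  aromatic flag | c_R | c_S].

#' Corpus normalization statistics for atom features
#'
#' Computes the mean and standard deviation of formal charges and the
#' minimum and maximum van der Waals radii over a corpus of atoms. These
#' statistics are fixed on the training corpus and reused verbatim when
#' featurizing new molecules.
#'
#' @param atoms a data.frame of atom descriptors as returned in the
#'   \code{atoms} component of [parseSmiles()], or a row-bound collection of
#'   such frames spanning the whole corpus.
#' @return list with \code{charge_mean}, \code{charge_std}, \code{vdw_min},
#'   \code{vdw_max}. A single-atom corpus yields \code{charge_std = 0}.
#' @export
computeNormStats <- function(atoms) {
  if (!is.data.frame(atoms) || nrow(atoms) == 0) {
    stop("normalization statistics require a non-empty atom corpus")
  }
  s <- stats::sd(atoms$formal_charge)
  list(
    charge_mean = mean(atoms$formal_charge),
    charge_std = if (is.na(s)) 0 else s,
    vdw_min = min(atoms$vdw_radius),
    vdw_max = max(atoms$vdw_radius)
  )
}

#' Featurize a single atom
#'
#' @param descriptor one-row data.frame (or list) with fields
#'   \code{atomic_number}, \code{formal_charge}, \code{vdw_radius},
#'   \code{is_aromatic}, \code{cip_code}.
#' @param stats normalization statistics from [computeNormStats()].
#' @return numeric vector of length 105.
#' @export
featurizeAtom <- function(descriptor, stats) {
  z <- descriptor$atomic_number
  if (is.na(z) || z < 1 || z > 100) {
    stop("atomic number must lie in 1..100, got ", z)
  }
  onehot <- numeric(100)
  onehot[z] <- 1
  q <- if (stats$charge_std > 0) {
    (descriptor$formal_charge - stats$charge_mean) / stats$charge_std
  } else 0
  span <- stats$vdw_max - stats$vdw_min
  r <- if (span > 0) (descriptor$vdw_radius - stats$vdw_min) / span else 0
  cR <- as.numeric(descriptor$cip_code == "R")
  cS <- as.numeric(descriptor$cip_code == "S")
  c(onehot, q, r, as.numeric(descriptor$is_aromatic), cR, cS)
}

#' Featurize a molecule into a MolecularGraph
#'
#' Parses the SMILES string and stacks per-atom feature vectors into the
#' node-feature matrix of a [MolecularGraph-class] object.
#'
#' @param smiles a single SMILES string.
#' @param stats normalization statistics from [computeNormStats()],
#'   computed over the training corpus.
#' @return a \code{MolecularGraph}.
#' @examples
#' top <- parseSmiles("CC")
#' st <- computeNormStats(top$atoms)
#' g <- featurizeMolecule("CC", st)
#' dim(nodeFeatures(g))  # 2 x 105
#' @export
featurizeMolecule <- function(smiles, stats) {
  top <- parseSmiles(smiles)
  feat <- t(vapply(
    seq_len(nrow(top$atoms)),
    function(i) featurizeAtom(top$atoms[i, ], stats),
    numeric(105)
  ))
  if (nrow(top$atoms) == 1) feat <- matrix(feat, nrow = 1)
  new("MolecularGraph",
    nodeFeatures = feat,
    edges = top$edges,
    smiles = top$smiles_canonical,
    atoms = top$atoms
  )
}

#' Write a graph object to a JSON container
#'
#' Serializes the node-feature matrix, edge list and metadata of a
#' [MolecularGraph-class] or [ProteinGraph-class] to a round-trippable JSON
#' file.
#'
#' @param graph the graph object.
#' @param path output file path.
#' @export
writeGraph <- function(graph, path) {
  if (is(graph, "MolecularGraph")) {
    obj <- list(
      type = "molecular",
      smiles = graph@smiles,
      node_features = graph@nodeFeatures,
      edges = graph@edges,
      atoms = graph@atoms
    )
  } else if (is(graph, "ProteinGraph")) {
    obj <- list(
      type = "protein",
      species = graph@species,
      node_features = graph@nodeFeatures,
      edges = graph@edges,
      residues = graph@residues
    )
  } else {
    stop("unsupported graph class: ", class(graph))
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a graph object from its JSON container
#'
#' @param path file written by [writeGraph()].
#' @return a \code{MolecularGraph} or \code{ProteinGraph}.
#' @export
readGraph <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nf <- matrix(as.numeric(obj$node_features),
               nrow = NROW(obj$node_features), ncol = NCOL(obj$node_features))
  ed <- obj$edges
  ed <- if (length(ed)) matrix(as.integer(as.matrix(ed)), ncol = 2)
        else matrix(integer(0), ncol = 2)
  if (identical(obj$type, "molecular")) {
    new("MolecularGraph",
      nodeFeatures = nf, edges = ed, smiles = obj$smiles,
      atoms = as.data.frame(obj$atoms)
    )
  } else if (identical(obj$type, "protein")) {
    new("ProteinGraph",
      nodeFeatures = nf, edges = ed,
      species = if (is.null(obj$species)) character(0) else obj$species,
      residues = as.data.frame(obj$residues)
    )
  } else {
    stop("unrecognized graph container type")
  }
}
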