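# SMILES -> molecular topology. Chemistry perception (valence, aromaticity,
# canonical order, stereo parity) is delegated to OpenBabel via ChemmineOB /
# ChemmineR; this file only assembles the results into atom descriptors.

# Legacy molfile charge codes (field 6 of the atom block).
.MOLFILE_CHARGE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L,
                     `4` = 0L, `5` = -1L, `6` = -2L, `7` = -3L)

.obConvert <- function(from, to, text, options = NULL) {
  out <- suppressWarnings(
    if (is.null(options)) ChemmineOB::convertFormat(from, to, text)
    else ChemmineOB::convertFormat(from, to, text, options = options)
  )
  out
}

.readSdfText <- function(sdfTxt) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(sdfTxt, tf)
  suppressWarnings(ChemmineR::read.SDFset(tf))
}

#' Canonicalize a SMILES string
#'
#' Returns the canonical SMILES form. Canonicalization is idempotent: the
#' canonical form of a canonical string is itself.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES; unparseable entries
#'   become \code{NA}.
#' @export
normalizeSmiles <- function(smiles) {
  vapply(smiles, function(s) {
    out <- .obConvert("SMI", "CAN", paste0(s, "\n"))
    out <- trimws(out)
    if (!length(out) || !nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

#' Parse a SMILES string into a molecular topology
#'
#' Builds the heavy-atom graph of a molecule: atoms become nodes, bonds
#' become undirected edges, hydrogens stay implicit. Each atom receives a
#' descriptor row with element, integer formal charge, van der Waals radius
#' (from the bundled element table), aromaticity flag and CIP chirality code
#' (R, S or none).
#'
#' @param smiles a single SMILES string.
#' @return a list with components \code{atoms} (descriptor data.frame),
#'   \code{edges} (two-column integer matrix, i < j, one row per bond) and
#'   \code{smiles_canonical}.
#' @examples
#' top <- parseSmiles("c1ccccc1")
#' nrow(top$atoms)   # 6
#' nrow(top$edges)   # 6
#' @export
parseSmiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  can <- normalizeSmiles(smiles)
  if (is.na(can)) {
    stop("SMILES could not be parsed: ", smiles)
  }
  sdfTxt <- .obConvert("SMI", "SDF", paste0(smiles, "\n"),
    options = data.frame(names = c("gen2D", "h"), args = c("", ""))
  )
  if (!length(sdfTxt) || !nzchar(trimws(sdfTxt))) {
    stop("SMILES could not be parsed: ", smiles)
  }
  sdf <- .readSdfText(sdfTxt)[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  sym <- sub("_.*$", "", rownames(ab))
  z <- atomicNumber(sym)
  if (anyNA(z)) {
    bad <- unique(sym[is.na(z)])
    stop("element outside the supported one-hot vocabulary (Z 1-100): ",
         paste(bad, collapse = ", "), " in ", smiles)
  }
  chargeCode <- as.character(ab[, "C6"])
  charge <- .MOLFILE_CHARGE[chargeCode]
  charge[is.na(charge)] <- 0L
  parity <- as.integer(ab[, "C7"])

  nAll <- nrow(ab)
  edgesAll <- if (is.null(dim(bb))) matrix(bb[1:3], ncol = 3) else
    cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3]))
  if (nrow(edgesAll) == 0) edgesAll <- matrix(integer(0), ncol = 3)

  arom <- .aromaticAtoms(sdf, nAll)
  cip <- .assignCip(z, edgesAll, parity)

  heavy <- which(sym != "H")
  nH <- integer(nAll)
  if (nrow(edgesAll)) {
    for (r in seq_len(nrow(edgesAll))) {
      i <- edgesAll[r, 1]; j <- edgesAll[r, 2]
      if (sym[j] == "H") nH[i] <- nH[i] + 1L
      if (sym[i] == "H") nH[j] <- nH[j] + 1L
    }
  }
  idxMap <- integer(nAll)
  idxMap[heavy] <- seq_along(heavy)
  keep <- edgesAll[, 1] %in% heavy & edgesAll[, 2] %in% heavy
  e <- edgesAll[keep, , drop = FALSE]
  edges <- cbind(
    pmin(idxMap[e[, 1]], idxMap[e[, 2]]),
    pmax(idxMap[e[, 1]], idxMap[e[, 2]])
  )
  storage.mode(edges) <- "integer"
  if (nrow(edges) > 1) edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]

  atoms <- data.frame(
    symbol = sym[heavy],
    atomic_number = z[heavy],
    formal_charge = as.integer(charge[heavy]),
    vdw_radius = unname(VDW_RADII[sym[heavy]]),
    is_aromatic = arom[heavy],
    cip_code = cip[heavy],
    n_h = nH[heavy],
    stringsAsFactors = FALSE
  )
  list(atoms = atoms, edges = edges, smiles_canonical = can)
}

# Atoms belonging to at least one aromatic ring, per ChemmineR ring
# perception on the (kekulized) connection table.
.aromaticAtoms <- function(sdf, nAll) {
  arom <- rep(FALSE, nAll)
  rng <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf, type = "all", arom = TRUE)),
    error = function(e) NULL
  )
  if (is.null(rng) || is.null(rng$AROMATIC) || !length(rng$RINGS)) return(arom)
  for (i in seq_along(rng$RINGS)) {
    if (isTRUE(rng$AROMATIC[[i]])) {
      idx <- as.integer(sub("^.*_", "", rng$RINGS[[i]]))
      arom[idx] <- TRUE
    }
  }
  arom
}
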