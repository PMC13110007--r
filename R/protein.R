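# Protein structure -> residue contact-map graph. Coordinate files are read
# with bio3d; secondary structure and solvent accessibility come from a DSSP
# output file when available, otherwise from a geometric fallback so that the
# pipeline runs without any external binary.

#' Read residues from a PDB or mmCIF coordinate file
#'
#' Extracts one record per standard amino-acid residue with an alpha-carbon
#' from a single chain. Residues lacking an alpha-carbon and non-standard
#' residues are skipped with a warning. Secondary structure (ss3) and
#' relative accessibility (rsa) are left unset; fill them with
#' [ingestDssp()] or [assignSsFallback()].
#'
#' @param path coordinate file; format chosen by extension (\code{.cif} /
#'   \code{.mmcif} for mmCIF, anything else is read as PDB).
#' @param chain chain identifier; by default the first chain in the file.
#' @return data.frame with columns \code{aa} (three-letter code),
#'   \code{resno}, \code{x}, \code{y}, \code{z}, plus unset \code{ss_helix},
#'   \code{ss_sheet}, \code{ss_coil}, \code{rsa}.
#' @export
readStructure <- function(path, chain = NULL) {
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) {
    suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
  } else {
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  }
  at <- pdb$atom
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain & at$type == "ATOM", , drop = FALSE]
  resKey <- paste(at$resno, at$insert %||% "", sep = "_")
  keys <- unique(resKey)
  rows <- lapply(keys, function(k) {
    sub <- at[resKey == k, , drop = FALSE]
    aa <- sub$resid[1]
    if (!(aa %in% AA_THREE)) {
      warning("skipping non-standard residue ", aa, " ", sub$resno[1])
      return(NULL)
    }
    ca <- sub[sub$elety == "CA", , drop = FALSE]
    if (nrow(ca) == 0) {
      warning("skipping residue ", aa, " ", sub$resno[1], ": no alpha-carbon")
      return(NULL)
    }
    data.frame(
      aa = aa, resno = ca$resno[1],
      x = ca$x[1], y = ca$y[1], z = ca$z[1],
      ss_helix = NA_real_, ss_sheet = NA_real_, ss_coil = NA_real_,
      rsa = NA_real_, stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(
      aa = character(0), resno = integer(0), x = numeric(0), y = numeric(0),
      z = numeric(0), ss_helix = numeric(0), ss_sheet = numeric(0),
      ss_coil = numeric(0), rsa = numeric(0)
    )
  }
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# DSSP 8-class -> 3-class mapping: {H,G,I} helix, {E,B} sheet, rest coil.
.SS3_FROM_DSSP <- c(
  H = "helix", G = "helix", I = "helix",
  E = "sheet", B = "sheet",
  T = "coil", S = "coil", P = "coil", ` ` = "coil", `-` = "coil"
)

#' Fill secondary structure and accessibility from a DSSP output file
#'
#' Parses a classic-format DSSP file, maps the 8-class assignment to a
#' 3-class one-hot (helix = \{H,G,I\}, sheet = \{E,B\}, coil otherwise) and
#' converts absolute accessible surface area to relative ASA using the
#' per-residue maxima of the bundled table, clipped to [0,1]. Residues with
#' no matching DSSP entry fall back to coil with rsa 0 (warning).
#'
#' @param path DSSP output file.
#' @param residues residue data.frame from [readStructure()].
#' @param chain chain identifier used to match DSSP rows; default matches
#'   any chain.
#' @return the residue data.frame with ss3 and rsa columns filled.
#' @export
ingestDssp <- function(path, residues, chain = NULL) {
  lines <- readLines(path)
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr)) stop("not a DSSP output file: ", path)
  body <- lines[(hdr[1] + 1):length(lines)]
  body <- body[nchar(body) >= 38]
  recResno <- suppressWarnings(as.integer(substr(body, 6, 10)))
  recChain <- trimws(substr(body, 12, 12))
  recAA <- substr(body, 14, 14)
  recSS <- substr(body, 17, 17)
  recACC <- suppressWarnings(as.numeric(substr(body, 35, 38)))
  ok <- !is.na(recResno) & recAA != "!"
  if (!is.null(chain)) ok <- ok & recChain == chain
  recResno <- recResno[ok]; recAA <- recAA[ok]
  recSS <- recSS[ok]; recACC <- recACC[ok]

  for (i in seq_len(nrow(residues))) {
    j <- which(recResno == residues$resno[i])
    if (length(j) == 0) {
      warning("no DSSP entry for residue ", residues$aa[i], " ",
              residues$resno[i], "; falling back to coil, rsa 0")
      residues[i, c("ss_helix", "ss_sheet", "ss_coil")] <- c(0, 0, 1)
      residues$rsa[i] <- 0
      next
    }
    j <- j[1]
    expected <- unname(AA_ONE[residues$aa[i]])
    if (recAA[j] != expected) {
      stop("DSSP/structure mismatch at residue ", residues$resno[i],
           ": structure ", residues$aa[i], ", DSSP '", recAA[j], "'")
    }
    cls <- .SS3_FROM_DSSP[recSS[j]]
    if (is.na(cls)) cls <- "coil"
    residues[i, c("ss_helix", "ss_sheet", "ss_coil")] <-
      as.numeric(cls == c("helix", "sheet", "coil"))
    maxA <- unname(MAX_ASA[residues$aa[i]])
    rsa <- recACC[j] / maxA
    residues$rsa[i] <- min(max(rsa, 0), 1)
  }
  residues
}

#' Geometric fallback for secondary structure and accessibility
#'
#' Assigns ss3 and rsa from alpha-carbon geometry alone, keeping the
#' pipeline runnable without DSSP. A residue is labeled helix when the
#' alpha-carbon distance over an i to i+4 window (forward or backward)
#' falls inside the ideal-helix band of 5.5--6.8 Angstrom; otherwise it is
#' labeled sheet when an i to i+2 window spans more than 6.4 Angstrom
#' (extended geometry); otherwise coil. Chains shorter than 5 residues are
#' all coil. Accessibility uses a contact-count proxy: rsa =
#' max(0, 1 - neighbors_within_10A / 12), clipped to [0,1].
#'
#' @param residues residue data.frame from [readStructure()].
#' @return the residue data.frame with ss3 and rsa columns filled.
#' @export
assignSsFallback <- function(residues) {
  n <- nrow(residues)
  xyz <- as.matrix(residues[, c("x", "y", "z")])
  dmat <- as.matrix(stats::dist(xyz))
  for (i in seq_len(n)) {
    helix <- FALSE
    sheet <- FALSE
    if (n >= 5) {
      d4 <- c(
        if (i + 4 <= n) dmat[i, i + 4] else NA,
        if (i - 4 >= 1) dmat[i - 4, i] else NA
      )
      helix <- any(!is.na(d4) & d4 >= 5.5 & d4 <= 6.8)
      if (!helix) {
        d2 <- c(
          if (i + 2 <= n) dmat[i, i + 2] else NA,
          if (i - 2 >= 1) dmat[i - 2, i] else NA
        )
        sheet <- any(!is.na(d2) & d2 > 6.4)
      }
    }
    residues[i, c("ss_helix", "ss_sheet", "ss_coil")] <-
      as.numeric(c(helix, !helix && sheet, !helix && !sheet))
    nb <- sum(dmat[i, ] < 10) - 1L
    residues$rsa[i] <- min(max(1 - nb / 12, 0), 1)
  }
  residues
}

#' Residue contact map from alpha-carbon distances
#'
#' An undirected edge joins residues i < j whenever their alpha-carbon
#' Euclidean distance is strictly below the cutoff.
#'
#' @param residues residue data.frame with x, y, z columns.
#' @param cutoff contact threshold in Angstrom (default 8.0; strict
#'   inequality).
#' @return two-column integer matrix of contacts (i < j).
#' @export
buildContactMap <- function(residues, cutoff = 8.0) {
  n <- nrow(residues)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  dmat <- as.matrix(stats::dist(as.matrix(residues[, c("x", "y", "z")])))
  idx <- which(upper.tri(dmat) & dmat < cutoff, arr.ind = TRUE)
  e <- cbind(idx[, 1], idx[, 2])
  storage.mode(e) <- "integer"
  dimnames(e) <- NULL
  if (nrow(e) > 1) e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  e
}

#' Featurize a residue record
#'
#' Produces the 24-dimensional residue encoding: 20-slot amino-acid one-hot
#' (alphabetical by three-letter code), the 3-class secondary-structure
#' assignment, and the binary exposure flag I_ASA = 1 iff rsa >= 0.25.
#'
#' @param residue one-row data.frame with \code{aa}, ss3 columns and
#'   \code{rsa}.
#' @return numeric vector of length 24.
#' @export
featurizeResidue <- function(residue) {
  pos <- match(residue$aa, AA_THREE)
  if (is.na(pos)) stop("not a canonical amino acid: ", residue$aa)
  onehot <- numeric(20)
  onehot[pos] <- 1
  ss3 <- as.numeric(residue[c("ss_helix", "ss_sheet", "ss_coil")])
  if (anyNA(ss3)) stop("ss3 unset; run ingestDssp() or assignSsFallback()")
  c(onehot, ss3, as.numeric(residue$rsa >= 0.25))
}

#' Build a ProteinGraph from a residue table
#'
#' Combines [buildContactMap()] and [featurizeResidue()] into the packaged
#' graph container.
#'
#' @param residues residue data.frame with coordinates, ss3 and rsa set.
#' @param species species tag stored on the graph.
#' @param cutoff contact cutoff in Angstrom.
#' @return a [ProteinGraph-class].
#' @export
buildProteinGraph <- function(residues, species = "unknown", cutoff = 8.0) {
  feat <- t(vapply(
    seq_len(nrow(residues)),
    function(i) featurizeResidue(residues[i, ]),
    numeric(24)
  ))
  if (nrow(residues) == 1) feat <- matrix(feat, nrow = 1)
  new("ProteinGraph",
    nodeFeatures = feat,
    edges = buildContactMap(residues, cutoff),
    species = species,
    residues = residues
  )
}

#' Protein graph straight from a coordinate file
#'
#' Convenience wrapper: [readStructure()], then [ingestDssp()] when a DSSP
#' file is supplied or [assignSsFallback()] otherwise, then
#' [buildProteinGraph()].
#'
#' @param path coordinate file (PDB or mmCIF).
#' @param dssp optional DSSP output file.
#' @param species species tag.
#' @param chain chain identifier (default: first chain).
#' @param cutoff contact cutoff in Angstrom.
#' @return a [ProteinGraph-class].
#' @export
proteinGraphFromFile <- function(path, dssp = NULL, species = "unknown",
                                 chain = NULL, cutoff = 8.0) {
  res <- readStructure(path, chain = chain)
  res <- if (is.null(dssp)) assignSsFallback(res) else ingestDssp(dssp, res, chain = chain)
  buildProteinGraph(res, species = species, cutoff = cutoff)
}
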