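# Deterministic synthetic fixtures: molecules spanning the filter rules,
# idealized polymer chains with known geometry and secondary structure,
# and labeled interaction datasets with a planted, separable signal. No
# downloads, no external binaries.

.SPECIES_TAGS <- c("human", "electric_eel", "mouse", "bovine",
                   "pacific_electric_ray", "rat")

# Designed filter violators; each fails exactly its designated stage (the
# others pass). Verified against the descriptor engine at design time.
.VIOLATORS <- data.frame(
  smiles = c(
    "[Na+].[Cl-]",
    "O=C(N1CCOCC1)c1ccc2c(c1)c1cc(C(=O)N3CCOCC3)ccc1c1ccc(C(=O)N3CCOCC3)cc21",
    "Clc1c(Cl)c(Cl)c(Cl)c(Cl)c1Cl",
    "CCOCCOCCOCCOCCOCC",
    "O=C1CSC(=S)N1"
  ),
  designed_violation = c("inorganic", "lipinski_mw", "lipinski_logp",
                         "veber_rotors", "pains"),
  stringsAsFactors = FALSE
)

# Random drug-like chain SMILES: short carbon chains with at least one
# interspersed heteroatom, kept small so that every filter rule passes by
# construction (low MW, logP well under 5, few rotatable bonds, small
# polar surface area, no alert substructure).
.randomChainSmiles <- function(allowN = TRUE) {
  units <- c("C", "CC", "CO", "CCO")
  if (allowN) units <- c(units, "CN", "CCN")
  parts <- sample(units, sample(2:4, 1), replace = TRUE)
  if (!any(grepl("[ON]", parts))) {
    parts[sample.int(length(parts), 1)] <- "CO"
  }
  paste(parts, collapse = "")
}

#' Generate fixture molecules spanning the filter rules
#'
#' Emits \code{n} molecules: five designed violators (one per curation
#' stage: an inorganic salt, an oversize-MW scaffold, a high-logP
#' scaffold, a rotatable-bond chain and a PAINS rhodanine core) plus
#' \code{n - 5} rule-passing molecules. Annotations state which stage each
#' violator fails by construction. Deterministic under the seed.
#'
#' @param n total number of molecules (>= 5).
#' @param seed integer seed.
#' @return data.frame with \code{smiles} and \code{designed_violation}
#'   ("none" for passers).
#' @export
genMolecules <- function(n, seed = 1L) {
  stopifnot(n >= 5)
  set.seed(seed)
  passers <- character(0)
  seen <- character(0)
  while (length(passers) < n - 5) {
    smi <- .randomChainSmiles()
    can <- normalizeSmiles(smi)
    if (is.na(can) || can %in% seen) next
    seen <- c(seen, can)
    passers <- c(passers, smi)
  }
  out <- rbind(
    .VIOLATORS,
    data.frame(smiles = passers,
               designed_violation = rep("none", length(passers)))
  )
  rownames(out) <- NULL
  out
}

#' Generate an idealized polymer chain with known geometry
#'
#' Alpha-carbon traces with exactly known secondary structure: "helix"
#' uses ideal helical parameters (rise 1.5 A, 100 degree twist, radius
#' 2.3 A; the i to i+4 distance is about 6.2 A), "extended" places
#' residues 3.8 A apart on a line, and "coil_mix" perturbs the helical
#' twist and rise at every step to produce an irregular compact coil.
#' Residue types are sampled uniformly from the 20 canonical amino acids.
#'
#' @param nResidues chain length.
#' @param geometry one of "helix", "extended", "coil_mix".
#' @param seed integer seed (residue identities; coil perturbations).
#' @return list with \code{residues} (data.frame: aa, resno, x, y, z and
#'   unset ss3/rsa columns) and \code{ss_true} (per-residue ground truth:
#'   "helix", "sheet" or "coil").
#' @export
genChain <- function(nResidues, geometry = c("helix", "extended", "coil_mix"),
                     seed = 1L) {
  geometry <- match.arg(geometry)
  set.seed(seed)
  aa <- sample(AA_THREE, nResidues, replace = TRUE)
  i <- seq_len(nResidues) - 1
  if (geometry == "helix") {
    theta <- i * 100 * pi / 180
    xyz <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
    ssTrue <- rep("helix", nResidues)
  } else if (geometry == "extended") {
    xyz <- cbind(3.8 * i, 0, 0)
    ssTrue <- rep("sheet", nResidues)
  } else {
    theta <- cumsum(c(0, stats::runif(nResidues - 1, 60, 150))) * pi / 180
    rise <- cumsum(c(0, stats::runif(nResidues - 1, 1.0, 2.6)))
    xyz <- cbind(2.3 * cos(theta), 2.3 * sin(theta), rise)
    ssTrue <- rep("coil", nResidues)
  }
  residues <- data.frame(
    aa = aa, resno = seq_len(nResidues),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    ss_helix = NA_real_, ss_sheet = NA_real_, ss_coil = NA_real_,
    rsa = NA_real_, stringsAsFactors = FALSE
  )
  list(residues = residues, ss_true = ssTrue)
}

#' Write a chain as a PDB file
#'
#' Alpha-carbon-only ATOM records in standard fixed-column PDB format.
#'
#' @param residues residue data.frame (aa, resno, x, y, z).
#' @param path output file.
#' @param chain chain identifier.
#' @export
writeChainPDB <- function(residues, path, chain = "A") {
  lines <- vapply(seq_len(nrow(residues)), function(i) {
    sprintf(
      "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      i, residues$aa[i], chain, residues$resno[i],
      residues$x[i], residues$y[i], residues$z[i]
    )
  }, character(1))
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Write a chain as a minimal mmCIF file
#'
#' Emits an atom_site loop equivalent to [writeChainPDB()]'s output, so
#' the same chain can be read back from either format.
#'
#' @param residues residue data.frame (aa, resno, x, y, z).
#' @param path output file.
#' @param chain chain identifier.
#' @export
writeChainCIF <- function(residues, path, chain = "A") {
  hdr <- c(
    "data_synthetic_chain",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"
  )
  rows <- vapply(seq_len(nrow(residues)), function(i) {
    sprintf(
      "ATOM %d C CA . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 %d %s %s CA 1",
      i, residues$aa[i], chain, residues$resno[i],
      residues$x[i], residues$y[i], residues$z[i],
      residues$resno[i], residues$aa[i], chain
    )
  }, character(1))
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}

#' Write a synthetic DSSP-format file for a chain
#'
#' Emits the classic DSSP fixed-column layout (header line plus one row
#' per residue) with the supplied 8-class codes and absolute accessible
#' surface areas, for exercising the DSSP reader without the external
#' binary.
#'
#' @param residues residue data.frame (aa, resno).
#' @param ss8 per-residue DSSP codes (H, G, I, E, B, T, S, or " ").
#' @param acc per-residue absolute ASA values.
#' @param path output file.
#' @param chain chain identifier.
#' @export
writeChainDssp <- function(residues, ss8, acc, path, chain = "A") {
  stopifnot(length(ss8) == nrow(residues), length(acc) == nrow(residues))
  hdr <- c(
    "==== Secondary Structure Definition, synthetic fixture ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA"
  )
  rows <- vapply(seq_len(nrow(residues)), function(i) {
    aa1 <- unname(AA_ONE[residues$aa[i]])
    paste0(
      sprintf("%5d", i),
      sprintf("%5d", residues$resno[i]),
      " ", chain,
      " ", aa1,
      "  ", substr(ss8[i], 1, 1),
      strrep(" ", 17),
      sprintf("%4d", as.integer(round(acc[i])))
    )
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# Random molecule for the planted-signal dataset. Positives contain at
# least one nitrogen atom; negatives contain none.
.motifMolecule <- function(positive) {
  units <- c("C", "CC", "CCC", "CO", "CCO")
  k <- sample(2:5, 1)
  parts <- sample(units, k, replace = TRUE)
  if (positive) {
    parts[sample.int(k, 1)] <- sample(c("CN", "CCN", "CNC"), 1)
  }
  body <- paste(parts, collapse = "")
  if (stats::runif(1) < 0.3) paste0("Cc1ccc(", body, ")cc1") else body
}

#' Generate a labeled interaction dataset with a planted signal
#'
#' Balanced binary dataset against one fixed protein: the positive class
#' is defined by the presence of a nitrogen-containing motif in the
#' molecule (a rule a trivial atom-count baseline separates perfectly, so
#' the graph encoders, not the filters, must carry it). IC50 values are
#' drawn consistently with the labeling rule: positives log-uniform on
#' [0.01, 1] micromolar, negatives on [1.5, 100]. Molecules are unique by
#' canonical SMILES. Deterministic under the seed.
#'
#' @param n total records (even; half positive).
#' @param seed integer seed.
#' @return list with \code{records} (data.frame: smiles,
#'   smiles_canonical, species, ic50_um, label) and \code{planted_rule}.
#' @export
genInteractionDataset <- function(n, seed = 1L) {
  stopifnot(n %% 2 == 0)
  set.seed(seed)
  half <- n / 2
  rows <- list()
  seen <- character(0)
  for (positive in c(TRUE, FALSE)) {
    made <- 0L
    while (made < half) {
      smi <- .motifMolecule(positive)
      can <- normalizeSmiles(smi)
      if (is.na(can) || can %in% seen) next
      # guard the motif rule on the canonical form
      hasN <- grepl("N", can, fixed = TRUE) | grepl("n", can, fixed = TRUE)
      if (hasN != positive) next
      seen <- c(seen, can)
      made <- made + 1L
      ic50 <- if (positive) 10^stats::runif(1, -2, 0) else
        10^stats::runif(1, log10(1.5), 2)
      rows[[length(rows) + 1L]] <- data.frame(
        smiles = smi, smiles_canonical = can,
        species = sample(.SPECIES_TAGS, 1),
        ic50_um = ic50,
        label = if (positive) "positive" else "negative",
        stringsAsFactors = FALSE
      )
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  list(records = records,
       planted_rule = "positive iff the molecule contains a nitrogen atom")
}
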