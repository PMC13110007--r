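# Medicinal-chemistry curation: normalization, inorganic removal, Lipinski,
# Veber and PAINS filters, applied in a fixed order with an audit trail.
# Descriptor engines: molecular weight, logP (OpenBabel atom-contribution
# model) and topological polar surface area from OpenBabel; H-bond donors
# and acceptors counted on the parsed structure per Lipinski's original
# definitions (HBA = N + O count, HBD = N-H + O-H count); rotatable bonds
# by SMARTS.

.painsCatalogEnv <- new.env(parent = emptyenv())

#' The bundled PAINS alert catalog
#'
#' A curated subset of well-known pan-assay interference substructure
#' alerts (rhodanines, quinones, catechols, azo dyes, hydroxyphenyl
#' hydrazones, alkylidene barbiturates, ...), shipped as a versioned TSV
#' with columns \code{rule}, \code{smarts}, \code{family}. All patterns are
#' compiled at first use; a pattern that fails to compile aborts loading.
#'
#' @return data.frame of alert rules.
#' @export
painsCatalog <- function() {
  if (!is.null(.painsCatalogEnv$catalog)) return(.painsCatalogEnv$catalog)
  path <- system.file("extdata", "pains_alerts.tsv", package = "GraphPLI")
  if (path == "") path <- file.path("inst", "extdata", "pains_alerts.tsv")
  cat0 <- utils::read.delim(path, stringsAsFactors = FALSE)
  probe <- .obConvert("SMI", "SDF", "CCO\n")
  for (i in seq_len(nrow(cat0))) {
    ok <- tryCatch({
      .smartsCount(probe, cat0$smarts[i])
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("PAINS pattern failed to compile: ", cat0$rule[i])
  }
  .painsCatalogEnv$catalog <- cat0
  cat0
}

# Count unique SMARTS matches of `pattern` in one molecule given as SDF text.
.smartsCount <- function(sdfTxt, pattern) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(sdfTxt, tf)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(tf))
  unname(ChemmineR::smartsSearchOB(sdfset, pattern, uniqueMatches = TRUE))
}

#' Physicochemical descriptors of a molecule
#'
#' @param smiles a single SMILES string.
#' @return one-row data.frame with \code{mw} (Da), \code{logp},
#'   \code{hbd}, \code{hba}, \code{rotatable_bonds}, \code{psa} (A^2).
#' @export
computeDescriptors <- function(smiles) {
  top <- parseSmiles(smiles)
  sdfTxt <- .obConvert("SMI", "SDF", paste0(smiles, "\n"),
    options = data.frame(names = "gen2D", args = "")
  )
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(sdfTxt, tf)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(tf))
  p <- ChemmineR::propOB(sdfset)
  isNO <- top$atoms$symbol %in% c("N", "O")
  data.frame(
    mw = p$MW[1],
    logp = p$logP[1],
    hbd = sum(top$atoms$n_h[isNO]),
    hba = sum(isNO),
    rotatable_bonds = as.integer(.smartsCount(sdfTxt, ROTOR_SMARTS)),
    psa = p$TPSA[1]
  )
}

#' Organic-subset check
#'
#' A molecule counts as organic when it contains at least one carbon atom
#' and all its elements belong to the organic subset
#' \{H, B, C, N, O, F, P, S, Cl, Br, I\}.
#'
#' @param smiles a single SMILES string.
#' @return logical.
#' @export
isOrganic <- function(smiles) {
  top <- tryCatch(parseSmiles(smiles), error = function(e) NULL)
  if (is.null(top)) return(FALSE)
  any(top$atoms$symbol == "C") && all(top$atoms$symbol %in% ORGANIC_ELEMENTS)
}

.verdict <- function(failed, stage) {
  list(passed = length(failed) == 0, failed_rules = failed, stage = stage)
}

#' Lipinski rule-of-five verdict
#'
#' Pass requires mw <= 500 Da, logP <= 5, H-bond donors <= 5 and H-bond
#' acceptors <= 10 (all four, boundaries inclusive).
#'
#' @param d descriptor record from [computeDescriptors()].
#' @return verdict list with \code{passed}, \code{failed_rules},
#'   \code{stage}.
#' @export
lipinskiPass <- function(d) {
  failed <- character(0)
  if (d$mw > 500) failed <- c(failed, "mw")
  if (d$logp > 5) failed <- c(failed, "logp")
  if (d$hbd > 5) failed <- c(failed, "hbd")
  if (d$hba > 10) failed <- c(failed, "hba")
  .verdict(failed, "lipinski")
}

#' Veber criteria verdict
#'
#' Pass requires rotatable bonds <= 10 and polar surface area <= 140 A^2
#' (boundaries inclusive).
#'
#' @param d descriptor record from [computeDescriptors()].
#' @return verdict list.
#' @export
veberPass <- function(d) {
  failed <- character(0)
  if (d$rotatable_bonds > 10) failed <- c(failed, "rotatable_bonds")
  if (d$psa > 140) failed <- c(failed, "psa")
  .verdict(failed, "veber")
}

#' PAINS alert verdict
#'
#' Fails when any substructure alert of the bundled catalog matches; all
#' matching rule names are reported.
#'
#' @param smiles a single (normalized) SMILES string.
#' @return verdict list.
#' @export
painsPass <- function(smiles) {
  cat0 <- painsCatalog()
  sdfTxt <- .obConvert("SMI", "SDF", paste0(smiles, "\n"),
    options = data.frame(names = "gen2D", args = "")
  )
  hits <- character(0)
  for (i in seq_len(nrow(cat0))) {
    if (.smartsCount(sdfTxt, cat0$smarts[i]) > 0) hits <- c(hits, cat0$rule[i])
  }
  .verdict(hits, "pains")
}

# Largest organic fragment of a (possibly multi-fragment) SMILES; used for
# salt stripping before filtering. Ties break lexicographically on the
# canonical fragment SMILES.
.largestOrganicFragment <- function(canSmiles) {
  frags <- strsplit(canSmiles, ".", fixed = TRUE)[[1]]
  if (length(frags) == 1) return(canSmiles)
  sizes <- vapply(frags, function(f) {
    top <- tryCatch(parseSmiles(f), error = function(e) NULL)
    if (is.null(top) || !any(top$atoms$symbol == "C")) -1L else nrow(top$atoms)
  }, integer(1))
  if (all(sizes < 0)) return(canSmiles)  # no organic fragment; later stages reject
  frags <- frags[sizes == max(sizes)]
  normalizeSmiles(sort(frags)[1])
}

#' Run the full curation pipeline
#'
#' Applies, in order: SMILES normalization (with salt stripping to the
#' largest organic fragment), inorganic removal, the Lipinski rule of five,
#' the Veber criteria and the PAINS alert filter; survivors are then
#' deduplicated on canonical SMILES. Every rejection is logged with its
#' stage and the rules that failed.
#'
#' @param smiles character vector of input SMILES.
#' @return list with \code{survivors} (data.frame: input_smiles,
#'   smiles_canonical and descriptor columns) and \code{audit} (data.frame:
#'   input_smiles, stage, failed_rules).
#' @export
runFilterPipeline <- function(smiles) {
  audit <- data.frame(
    input_smiles = character(0), stage = character(0),
    failed_rules = character(0), stringsAsFactors = FALSE
  )
  keepRows <- list()
  seen <- character(0)
  for (s in smiles) {
    can <- normalizeSmiles(s)
    if (is.na(can)) {
      audit <- rbind(audit, data.frame(
        input_smiles = s, stage = "normalize", failed_rules = "unparseable"
      ))
      next
    }
    can <- .largestOrganicFragment(can)
    if (!isOrganic(can)) {
      audit <- rbind(audit, data.frame(
        input_smiles = s, stage = "inorganic", failed_rules = "inorganic"
      ))
      next
    }
    d <- computeDescriptors(can)
    v <- lipinskiPass(d)
    if (!v$passed) {
      audit <- rbind(audit, data.frame(
        input_smiles = s, stage = "lipinski",
        failed_rules = paste(v$failed_rules, collapse = ",")
      ))
      next
    }
    v <- veberPass(d)
    if (!v$passed) {
      audit <- rbind(audit, data.frame(
        input_smiles = s, stage = "veber",
        failed_rules = paste(v$failed_rules, collapse = ",")
      ))
      next
    }
    v <- painsPass(can)
    if (!v$passed) {
      audit <- rbind(audit, data.frame(
        input_smiles = s, stage = "pains",
        failed_rules = paste(v$failed_rules, collapse = ",")
      ))
      next
    }
    if (can %in% seen) {
      audit <- rbind(audit, data.frame(
        input_smiles = s, stage = "dedup", failed_rules = "duplicate"
      ))
      next
    }
    seen <- c(seen, can)
    keepRows[[length(keepRows) + 1L]] <- cbind(
      data.frame(input_smiles = s, smiles_canonical = can,
                 stringsAsFactors = FALSE),
      d
    )
  }
  survivors <- if (length(keepRows)) do.call(rbind, keepRows) else
    data.frame(
      input_smiles = character(0), smiles_canonical = character(0),
      mw = numeric(0), logp = numeric(0), hbd = integer(0), hba = integer(0),
      rotatable_bonds = integer(0), psa = numeric(0)
    )
  rownames(survivors) <- NULL
  list(survivors = survivors, audit = audit)
}
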