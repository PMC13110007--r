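# Labeled-dataset curation: IC50 labeling, negative balancing, cross-set
# deduplication and stratified splitting.

#' Label an activity measurement
#'
#' Inhibitors with IC50 <= 1 micromolar are positives (boundary
#' inclusive); anything above enters the negative pool.
#'
#' @param ic50 IC50 values in micromolar.
#' @return character vector, "positive" or "negative".
#' @export
labelByIc50 <- function(ic50) {
  ifelse(ic50 <= 1.0, "positive", "negative")
}

#' Collapse replicate IC50 measurements
#'
#' Multiple measurements of one compound collapse to their geometric mean
#' before labeling.
#'
#' @param ic50 IC50 values in micromolar.
#' @return geometric mean.
#' @export
collapseIc50 <- function(ic50) {
  exp(mean(log(ic50)))
}

#' Balance negatives against positives
#'
#' Draws, without replacement, as many negatives from the pool as there
#' are positives; the draw is reproducible under the seed.
#'
#' @param positives data.frame of positive records.
#' @param negativePool data.frame of candidate negatives.
#' @param seed integer seed.
#' @return row-bound data.frame with equal class counts.
#' @export
balanceNegatives <- function(positives, negativePool, seed = 1L) {
  np <- nrow(positives)
  if (nrow(negativePool) < np) {
    stop("negative pool too small: need ", np, ", have ", nrow(negativePool),
         " (deficit ", np - nrow(negativePool), ")")
  }
  set.seed(seed)
  take <- sample.int(nrow(negativePool), np)
  out <- rbind(positives, negativePool[take, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Remove candidates already present in a reference set
#'
#' Drops every candidate whose canonical SMILES occurs in the reference
#' set (both sides canonicalized before comparison).
#'
#' @param candidates data.frame with a \code{smiles} column (or
#'   \code{smiles_canonical}).
#' @param reference data.frame with the same convention.
#' @return filtered candidates.
#' @export
dedupAgainst <- function(candidates, reference) {
  canOf <- function(df) {
    if ("smiles_canonical" %in% names(df)) df$smiles_canonical
    else normalizeSmiles(df$smiles)
  }
  keep <- !(canOf(candidates) %in% canOf(reference))
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Largest-remainder apportionment of n into parts proportional to ratios;
# ties break in ratio order (train before validation before test).
.largestRemainder <- function(n, ratios) {
  q <- n * ratios / sum(ratios)
  base <- floor(q)
  left <- n - sum(base)
  if (left > 0) {
    frac <- q - base
    ord <- order(-frac, seq_along(ratios))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Splits records in the given ratios (default 8:1:1), stratified by
#' species and label so each stratum's counts match the ratios to within
#' largest-remainder rounding. Reproducible under the seed.
#'
#' @param records data.frame with \code{species} and \code{label} columns.
#' @param ratios length-3 numeric ratios for train, validation, test.
#' @param seed integer seed.
#' @return character vector ("train"/"validation"/"test") aligned with the
#'   rows of \code{records}.
#' @export
splitDataset <- function(records, ratios = c(8, 1, 1), seed = 1L) {
  stopifnot(length(ratios) == 3)
  set.seed(seed)
  assignment <- character(nrow(records))
  strata <- interaction(records$species, records$label, drop = TRUE)
  for (s in levels(strata)) {
    idx <- which(strata == s)
    counts <- .largestRemainder(length(idx), ratios)
    shuffled <- idx[sample.int(length(idx))]
    assignment[shuffled] <- rep(
      c("train", "validation", "test"), times = counts
    )
  }
  assignment
}

#' Per-stratum split count table
#'
#' Tabulates split sizes by species and label, the layout used to report
#' dataset composition.
#'
#' @param records data.frame with \code{species} and \code{label}.
#' @param assignment split assignment from [splitDataset()].
#' @return data.frame of counts per species x label x split.
#' @export
splitCountTable <- function(records, assignment) {
  as.data.frame(table(
    species = records$species, label = records$label, split = assignment
  ))
}
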