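# SMILES parsing and the 105-dimensional atom encoding.

test_that("parseSmiles builds the expected heavy-atom topology", {
  m <- parseSmiles("C")
  expect_equal(nrow(m$atoms), 1)
  expect_equal(nrow(m$edges), 0)

  b <- parseSmiles("c1ccccc1")
  expect_equal(nrow(b$atoms), 6)
  expect_equal(nrow(b$edges), 6)
  expect_true(all(b$atoms$is_aromatic))

  e <- parseSmiles("CC")
  expect_equal(nrow(e$atoms), 2)
  expect_equal(nrow(e$edges), 1)
  expect_equal(e$atoms$formal_charge, c(0L, 0L))

  acet <- parseSmiles("CC(=O)[O-]")
  expect_equal(sum(acet$atoms$formal_charge), -1L)
})

test_that("parseSmiles rejects unusable input", {
  expect_error(parseSmiles("C1CC"), "could not be parsed")
  expect_error(parseSmiles("not a smiles )("), "could not be parsed")
  # mendelevium: atomic number 101, outside the 100-slot one-hot
  expect_error(parseSmiles("[Md]"), "vocabulary")
})

test_that("normalization statistics summarize the corpus", {
  corpus <- data.frame(
    formal_charge = c(0L, 1L),
    vdw_radius = c(1.20, 1.70)
  )
  st <- computeNormStats(corpus)
  expect_equal(st$charge_mean, 0.5)
  expect_equal(st$vdw_min, 1.20)
  expect_equal(st$vdw_max, 1.70)

  single <- computeNormStats(data.frame(formal_charge = 0L, vdw_radius = 1.7))
  expect_equal(single$charge_std, 0)

  expect_error(computeNormStats(data.frame()), "non-empty")
})

test_that("featurizeAtom lays out the 105-dimensional vector", {
  st <- list(charge_mean = 0, charge_std = 1, vdw_min = 1.2, vdw_max = 1.7)
  d <- data.frame(atomic_number = 6L, formal_charge = 0L, vdw_radius = 1.7,
                  is_aromatic = FALSE, cip_code = "none")
  v <- featurizeAtom(d, st)
  expect_length(v, 105)
  expect_equal(which(v[1:100] == 1), 6)
  expect_equal(v[104:105], c(0, 0))   # achiral
  expect_equal(v[102], 1)             # vdW at the corpus max

  # degenerate charge spread emits 0
  st0 <- st; st0$charge_std <- 0
  d$formal_charge <- 3L
  expect_equal(featurizeAtom(d, st0)[101], 0)
})

test_that("chirality slots follow the R/S one-hot convention", {
  st <- fixtureStats()
  # enantiomeric pair: R-alanine and S-alanine at the alpha carbon
  gR <- featurizeMolecule("C[C@@H](N)C(=O)O", st)
  gS <- featurizeMolecule("C[C@H](N)C(=O)O", st)
  expect_equal(gR@atoms$cip_code[gR@atoms$cip_code != "none"], "R")
  expect_equal(gS@atoms$cip_code[gS@atoms$cip_code != "none"], "S")
  iR <- which(gR@atoms$cip_code == "R")
  iS <- which(gS@atoms$cip_code == "S")
  expect_equal(unname(nodeFeatures(gR)[iR, 104:105]), c(1, 0))
  expect_equal(unname(nodeFeatures(gS)[iS, 104:105]), c(0, 1))
})

test_that("featurizeMolecule composes parsing and per-atom encoding", {
  st <- fixtureStats()
  g1 <- featurizeMolecule("C", st)
  expect_equal(dim(nodeFeatures(g1)), c(1, 105))

  g2 <- featurizeMolecule("CC", st)
  expect_equal(nodeFeatures(g2)[1, ], nodeFeatures(g2)[2, ])

  gb <- featurizeMolecule("c1ccccc1", st)
  expect_true(all(nodeFeatures(gb)[, 103] == 1))
})

test_that("feature invariants hold over a molecule collection", {
  smis <- c("CCO", "c1ccncc1", "CC(=O)NC", "ClCCBr", "C[C@H](N)C(=O)O",
            "O=C1CSC(=S)N1")
  # statistics computed over this corpus, as in training
  corpus <- do.call(rbind, lapply(smis, function(s) parseSmiles(s)$atoms))
  st <- computeNormStats(corpus)
  for (smi in smis) {
    g <- featurizeMolecule(smi, st)
    nf <- nodeFeatures(g)
    # exactly one 1 among the first 100 entries of every row
    expect_true(all(rowSums(nf[, 1:100, drop = FALSE] == 1) == 1))
    expect_true(all(rowSums(nf[, 1:100, drop = FALSE] != 0) == 1))
    # scaled vdW radius within [0, 1] for corpus-spanning stats
    expect_true(all(nf[, 102] >= 0 & nf[, 102] <= 1))
    # determinism
    expect_identical(nf, nodeFeatures(featurizeMolecule(smi, st)))
  }
})

test_that("canonicalization preserves the featurized graph", {
  st <- fixtureStats()
  for (smi in c("OCC", "c1ccccc1C", "N(C)C(=O)C")) {
    g1 <- featurizeMolecule(smi, st)
    g2 <- featurizeMolecule(canonicalSmiles(g1), st)
    # same multiset of feature rows and same degree sequence
    srt <- function(m) m[do.call(order, as.data.frame(m)), , drop = FALSE]
    expect_equal(srt(nodeFeatures(g1)), srt(nodeFeatures(g2)))
    degSeq <- function(g) sort(tabulate(edgeMatrix(g), nbins = atomCount(g)))
    expect_equal(degSeq(g1), degSeq(g2))
  }
})

test_that("molecular graphs survive a serialization round trip", {
  st <- fixtureStats()
  g <- featurizeMolecule("CC(=O)Nc1ccccc1", st)
  tf <- tempfile(fileext = ".json")
  writeGraph(g, tf)
  g2 <- readGraph(tf)
  expect_equal(nodeFeatures(g2), nodeFeatures(g))
  expect_equal(edgeMatrix(g2), edgeMatrix(g))
  expect_equal(canonicalSmiles(g2), canonicalSmiles(g))
})
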