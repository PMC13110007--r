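# Structure reading, secondary-structure assignment, contact maps and the
# 24-dimensional residue encoding.

test_that("readStructure recovers synthetic chains from PDB and mmCIF", {
  ch <- genChain(3, "extended", seed = 2)
  pdb <- tempfile(fileext = ".pdb")
  cif <- tempfile(fileext = ".cif")
  writeChainPDB(ch$residues, pdb)
  writeChainCIF(ch$residues, cif)
  rp <- readStructure(pdb)
  rc <- readStructure(cif)
  expect_equal(nrow(rp), 3)
  expect_equal(rp$aa, ch$residues$aa)
  expect_equal(rp$resno, 1:3)
  # both renderings of the same chain agree
  expect_equal(rc$aa, rp$aa)
  expect_equal(rc[, c("x", "y", "z")], rp[, c("x", "y", "z")],
               tolerance = 1e-6)
})

test_that("residues without alpha-carbons and non-standard residues are skipped", {
  ch <- genChain(4, "extended", seed = 3)
  pdb <- tempfile(fileext = ".pdb")
  writeChainPDB(ch$residues, pdb)
  lines <- readLines(pdb)
  # residue 2 keeps an atom but loses its alpha-carbon
  hit <- grep(sprintf("%3s A   2", ch$residues$aa[2]), lines)[1]
  lines[hit] <- sub(" CA ", " CB ", lines[hit])
  writeLines(lines, pdb)
  expect_warning(res <- readStructure(pdb), "alpha-carbon")
  expect_equal(nrow(res), 3)

  # a non-standard residue is skipped with a warning
  ch2 <- genChain(3, "extended", seed = 4)
  pdb2 <- tempfile(fileext = ".pdb")
  writeChainPDB(ch2$residues, pdb2)
  lines2 <- readLines(pdb2)
  lines2[2] <- sub(ch2$residues$aa[2], "LIG", lines2[2])
  writeLines(lines2, pdb2)
  expect_warning(res2 <- readStructure(pdb2), "non-standard")
  expect_equal(nrow(res2), 2)
})

test_that("DSSP ingestion maps 8-class codes onto the ss3 one-hot", {
  ch <- genChain(5, "helix", seed = 6)
  ss8 <- c("H", "E", "T", "G", "B")
  acc <- c(64.5, 39, 0, 200, 85)
  dsspFile <- tempfile(fileext = ".dssp")
  writeChainDssp(ch$residues, ss8, acc, dsspFile)
  res <- ingestDssp(dsspFile, ch$residues)
  expect_equal(unlist(res[1, c("ss_helix", "ss_sheet", "ss_coil")],
                      use.names = FALSE), c(1, 0, 0))
  expect_equal(unlist(res[2, c("ss_helix", "ss_sheet", "ss_coil")],
                      use.names = FALSE), c(0, 1, 0))
  expect_equal(unlist(res[3, c("ss_helix", "ss_sheet", "ss_coil")],
                      use.names = FALSE), c(0, 0, 1))
  expect_equal(unlist(res[4, c("ss_helix", "ss_sheet", "ss_coil")],
                      use.names = FALSE), c(1, 0, 0))  # G is helix
  # relative ASA normalized by the residue-type maximum, clipped to [0, 1]
  expect_true(all(res$rsa >= 0 & res$rsa <= 1))
  expect_equal(res$rsa[3], 0)
  expect_gt(res$rsa[4], 0.5)   # 200 A^2 is high exposure for any residue type
})

test_that("missing DSSP rows fall back to coil and mismatches abort", {
  ch <- genChain(4, "helix", seed = 8)
  dsspFile <- tempfile(fileext = ".dssp")
  # only residues 1-3 present
  writeChainDssp(ch$residues[1:3, ], c("H", "H", "H"), c(10, 10, 10), dsspFile)
  expect_warning(res <- ingestDssp(dsspFile, ch$residues), "no DSSP entry")
  expect_equal(unlist(res[4, c("ss_helix", "ss_sheet", "ss_coil")],
                      use.names = FALSE), c(0, 0, 1))
  expect_equal(res$rsa[4], 0)

  # amino-acid mismatch names the offending residue
  ch2 <- genChain(3, "helix", seed = 9)
  wrong <- ch2$residues
  wrong$aa <- ifelse(wrong$aa == "ALA", "GLY", "ALA")
  dssp2 <- tempfile(fileext = ".dssp")
  writeChainDssp(wrong, c("H", "H", "H"), c(5, 5, 5), dssp2)
  expect_error(ingestDssp(dssp2, ch2$residues), "mismatch")
})

test_that("the geometric fallback labels ideal chains correctly", {
  helix <- genChain(20, "helix", seed = 11)
  hres <- assignSsFallback(helix$residues)
  expect_gte(mean(hres$ss_helix == 1), 0.8)

  ext <- assignSsFallback(genChain(20, "extended", seed = 12)$residues)
  expect_equal(sum(ext$ss_helix), 0)

  short <- assignSsFallback(genChain(3, "helix", seed = 13)$residues)
  expect_true(all(short$ss_coil == 1))
})

test_that("contact map uses a strict 8 Angstrom alpha-carbon cutoff", {
  two <- data.frame(aa = c("ALA", "GLY"), resno = 1:2,
                    x = c(0, 5), y = 0, z = 0)
  expect_equal(nrow(buildContactMap(two)), 1)

  two$x <- c(0, 8)  # exactly at the cutoff: excluded
  expect_equal(nrow(buildContactMap(two)), 0)

  # collinear 3.8 A spacing: contacts exactly where |i - j| <= 2
  lin <- data.frame(aa = "ALA", resno = 1:5, x = 3.8 * (0:4), y = 0, z = 0)
  cm <- buildContactMap(lin)
  expect_setequal(
    paste(cm[, 1], cm[, 2]),
    c("1 2", "2 3", "3 4", "4 5", "1 3", "2 4", "3 5")
  )
})

test_that("contact map agrees with a brute-force distance check and is monotone", {
  set.seed(99)
  for (rep in 1:3) {
    n <- sample(10:50, 1)
    res <- data.frame(aa = "ALA", resno = 1:n,
                      x = runif(n, 0, 30), y = runif(n, 0, 30),
                      z = runif(n, 0, 30))
    cm <- buildContactMap(res)
    # brute force all pairs
    expected <- list()
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- sqrt(sum((res[i, c("x", "y", "z")] - res[j, c("x", "y", "z")])^2))
      if (d < 8) expected[[length(expected) + 1]] <- c(i, j)
    }
    expect_equal(nrow(cm), length(expected))
    if (length(expected)) {
      expect_setequal(paste(cm[, 1], cm[, 2]),
                      vapply(expected, paste, character(1), collapse = " "))
    }
    # shrinking the cutoff never adds edges
    e6 <- nrow(buildContactMap(res, 6))
    e8 <- nrow(buildContactMap(res, 8))
    e10 <- nrow(buildContactMap(res, 10))
    expect_true(e6 <= e8 && e8 <= e10)
  }
})

test_that("featurizeResidue lays out the 24-dimensional vector", {
  r <- data.frame(aa = "ALA", resno = 1, x = 0, y = 0, z = 0,
                  ss_helix = 1, ss_sheet = 0, ss_coil = 0, rsa = 0.10)
  v <- featurizeResidue(r)
  expect_length(v, 24)
  expect_equal(which(v[1:20] == 1), 1)       # alphabetical: ALA first
  expect_equal(v[21:23], c(1, 0, 0))
  expect_equal(v[24], 0)                     # rsa below the 25% threshold

  r$rsa <- 0.25                              # boundary inclusive
  expect_equal(featurizeResidue(r)[24], 1)
})

test_that("residue feature rows satisfy the simplex and one-hot invariants", {
  g <- fixtureProtein(15, seed = 21)
  nf <- nodeFeatures(g)
  expect_equal(ncol(nf), 24)
  expect_true(all(rowSums(nf[, 1:20] == 1) == 1))
  expect_true(all(abs(rowSums(nf[, 21:23]) - 1) < 1e-12))
  expect_true(all(nf[, 24] %in% c(0, 1)))
  # adjacency symmetric and without self-edges by construction
  e <- edgeMatrix(g)
  if (nrow(e)) expect_true(all(e[, 1] < e[, 2]))
})

test_that("protein graphs survive a serialization round trip", {
  g <- fixtureProtein(10, seed = 31)
  tf <- tempfile(fileext = ".json")
  writeGraph(g, tf)
  g2 <- readGraph(tf)
  expect_equal(nodeFeatures(g2), nodeFeatures(g))
  expect_equal(edgeMatrix(g2), edgeMatrix(g))
  expect_equal(speciesTag(g2), speciesTag(g))
})
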