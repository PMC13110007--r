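# Curation pipeline: normalization, organic subset, Lipinski, Veber,
# PAINS, dedup, audit trail.

test_that("normalization is canonical and idempotent", {
  expect_equal(normalizeSmiles("OCC"), normalizeSmiles("CCO"))
  can <- normalizeSmiles("c1ccccc1CC(=O)O")
  expect_equal(normalizeSmiles(can), can)
  expect_true(is.na(normalizeSmiles("C1CC")))
})

test_that("salts are stripped to the largest organic fragment", {
  fp <- runFilterPipeline("CCO.[Na+]")
  expect_equal(fp$survivors$smiles_canonical, normalizeSmiles("CCO"))
})

test_that("the organic-subset check requires carbon and allowed elements", {
  expect_true(isOrganic("CCO"))
  expect_false(isOrganic("[Na+].[Cl-]"))
  expect_false(isOrganic("O=[Si]=O"))
  # organometallic: iron is outside the organic subset
  expect_false(isOrganic("CC[Fe]CC"))
})

test_that("Lipinski verdicts use inclusive bounds on all four rules", {
  d <- function(mw, logp, hbd, hba) {
    data.frame(mw = mw, logp = logp, hbd = hbd, hba = hba,
               rotatable_bonds = 0L, psa = 0)
  }
  v <- lipinskiPass(d(600, 2, 1, 3))
  expect_false(v$passed)
  expect_equal(v$failed_rules, "mw")

  expect_true(lipinskiPass(d(500, 5, 5, 10))$passed)  # boundary inclusive

  v2 <- lipinskiPass(d(450, 6, 0, 0))
  expect_false(v2$passed)
  expect_equal(v2$failed_rules, "logp")

  v3 <- lipinskiPass(d(600, 6, 6, 11))
  expect_setequal(v3$failed_rules, c("mw", "logp", "hbd", "hba"))
})

test_that("Veber verdicts use inclusive bounds", {
  d <- function(rot, psa) {
    data.frame(mw = 100, logp = 1, hbd = 0, hba = 0,
               rotatable_bonds = rot, psa = psa)
  }
  expect_false(veberPass(d(11, 100))$passed)
  expect_true(veberPass(d(10, 140))$passed)   # boundaries inclusive
  v <- veberPass(d(0, 200))
  expect_false(v$passed)
  expect_equal(v$failed_rules, "psa")
})

test_that("PAINS alerts flag interference substructures", {
  expect_true(painsPass("CCO")$passed)
  v <- painsPass("O=C1CSC(=S)N1")           # rhodanine core
  expect_false(v$passed)
  expect_true("rhodanine" %in% v$failed_rules)
  # a catechol azo dye trips two alerts, both reported
  v2 <- painsPass("Oc1ccc(N=Nc2ccccc2)cc1O")
  expect_false(v2$passed)
  expect_gte(length(v2$failed_rules), 2)
})

test_that("verdicts are consistent: passed iff no failed rules", {
  ds <- list(
    data.frame(mw = 600, logp = 6, hbd = 0, hba = 0,
               rotatable_bonds = 12, psa = 150),
    data.frame(mw = 100, logp = 1, hbd = 1, hba = 2,
               rotatable_bonds = 2, psa = 40)
  )
  for (d in ds) {
    for (v in list(lipinskiPass(d), veberPass(d))) {
      expect_equal(v$passed, length(v$failed_rules) == 0)
    }
  }
})

test_that("the pipeline rejects designed violators and keeps passers", {
  mols <- genMolecules(10, seed = 42)
  res <- runFilterPipeline(mols$smiles)
  expect_equal(nrow(res$survivors), nrow(mols) - 5)
  expect_equal(nrow(res$audit), 5)
  # every rejection carries a stage and at least one named rule
  expect_true(all(nzchar(res$audit$stage)))
  expect_true(all(nzchar(res$audit$failed_rules)))
  # the audit stages match the violators' designed stages
  stageOf <- function(v) c(
    inorganic = "inorganic", lipinski_mw = "lipinski",
    lipinski_logp = "lipinski", veber_rotors = "veber", pains = "pains"
  )[[v]]
  designed <- mols[mols$designed_violation != "none", ]
  for (i in seq_len(nrow(designed))) {
    row <- res$audit[res$audit$input_smiles == designed$smiles[i], ]
    expect_equal(row$stage, stageOf(designed$designed_violation[i]))
  }
})

test_that("the pipeline deduplicates and is idempotent on its own output", {
  res <- runFilterPipeline(c("CCO", "OCC", "CCN"))
  expect_equal(nrow(res$survivors), 2)
  expect_equal(res$audit$stage, "dedup")

  # empty input
  empty <- runFilterPipeline(character(0))
  expect_equal(nrow(empty$survivors), 0)
  expect_equal(nrow(empty$audit), 0)

  # survivors pass unchanged through a second run
  res2 <- runFilterPipeline(res$survivors$smiles_canonical)
  expect_equal(res2$survivors$smiles_canonical,
               res$survivors$smiles_canonical)
  expect_equal(nrow(res2$audit), 0)
})

test_that("rule verdicts are monotone in the descriptors", {
  # if d1 is dominated by d2 in every descriptor, d2 passing implies d1
  # passes (relaxing any threshold can only grow the pass set)
  set.seed(7)
  for (rep in 1:20) {
    d2 <- data.frame(mw = runif(1, 100, 700), logp = runif(1, -2, 8),
                     hbd = sample(0:8, 1), hba = sample(0:14, 1),
                     rotatable_bonds = sample(0:15, 1),
                     psa = runif(1, 0, 200))
    shrink <- runif(6, 0.3, 1)
    d1 <- data.frame(mw = d2$mw * shrink[1], logp = d2$logp * shrink[2],
                     hbd = floor(d2$hbd * shrink[3]),
                     hba = floor(d2$hba * shrink[4]),
                     rotatable_bonds = floor(d2$rotatable_bonds * shrink[5]),
                     psa = d2$psa * shrink[6])
    if (lipinskiPass(d2)$passed) expect_true(lipinskiPass(d1)$passed)
    if (veberPass(d2)$passed) expect_true(veberPass(d1)$passed)
  }
})
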