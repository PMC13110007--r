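# Bidirectional cross-attention fusion, MLP head, loss, and the
# end-to-end gradient check.

test_that("cross-attention over a single key token is the identity pool", {
  P <- fixtureParams()
  dp <- GraphPLI:::.fusDirParams(P, "p2l")
  set.seed(23)
  q <- matrix(rnorm(3 * 512), 3, 512)
  kv <- matrix(rnorm(512), 1, 512)
  out <- crossAttend(q, kv, dp)
  for (m in 1:4) expect_equal(as.numeric(out$attention[[m]]), rep(1, 3))
  # context = value of that token through the output projection
  V <- kv %*% dp$Wv
  want <- matrix(V, 3, 512, byrow = TRUE) %*% dp$Wo
  expect_equal(out$context, want, tolerance = 1e-10)
})

test_that("cross-attention rows normalize over the key sequence", {
  P <- fixtureParams()
  dp <- GraphPLI:::.fusDirParams(P, "l2p")
  set.seed(29)
  q <- matrix(rnorm(4 * 512), 4, 512)
  kv <- matrix(rnorm(6 * 512), 6, 512)
  out <- crossAttend(q, kv, dp)
  for (m in 1:4) {
    expect_equal(unname(rowSums(out$attention[[m]])), rep(1, 4),
                 tolerance = 1e-12)
  }
  expect_error(crossAttend(q, matrix(0, 0, 512), dp), "non-empty")
})

test_that("cross-attention matches a loop-based oracle", {
  P <- fixtureParams()
  dp <- GraphPLI:::.fusDirParams(P, "p2l")
  set.seed(37)
  q <- matrix(rnorm(2 * 512), 2, 512)
  kv <- matrix(rnorm(3 * 512), 3, 512)
  got <- crossAttend(q, kv, dp)$context

  # explicit per-head, per-query loops
  Q <- q %*% dp$Wq; K <- kv %*% dp$Wk; V <- kv %*% dp$Wv
  Cc <- matrix(0, 2, 512)
  for (m in 1:4) {
    idx <- ((m - 1) * 128 + 1):(m * 128)
    for (i in 1:2) {
      e <- vapply(1:3, function(j) {
        sum(Q[i, idx] * K[j, idx]) / sqrt(128)
      }, numeric(1))
      a <- exp(e - max(e)); a <- a / sum(a)
      Cc[i, idx] <- colSums(V[, idx] * a)
    }
  }
  expect_equal(got, Cc %*% dp$Wo, tolerance = 1e-5)
})

test_that("fusion produces the 1024-dimensional joint representation", {
  P <- fixtureParams()
  set.seed(5)
  Hp <- matrix(rnorm(7 * 128), 7, 128)
  Hl <- matrix(rnorm(4 * 128), 4, 128)
  fu <- fuseRepresentations(Hp, Hl, P)
  expect_length(fu$fused, 1024)
  expect_equal(fu$fused, c(fu$hbar_p, fu$hbar_l))

  # swapping two atoms leaves the pooled ligand side unchanged
  Hl2 <- Hl[c(2, 1, 3, 4), ]
  fu2 <- fuseRepresentations(Hp, Hl2, P)
  expect_equal(fu2$hbar_l, fu$hbar_l, tolerance = 1e-10)
})

test_that("layer normalization centers each token before the affine map", {
  set.seed(11)
  X <- matrix(rnorm(5 * 512, 2, 3), 5, 512)
  ln <- GraphPLI:::.layerNormFwd(X, rep(1, 512), rep(0, 512))
  expect_equal(unname(rowMeans(ln$out)), rep(0, 5), tolerance = 1e-10)
})

test_that("the head emits calibrated probabilities deterministically", {
  P <- fixtureParams()
  set.seed(3)
  f <- rnorm(1024)
  p1 <- predictProbability(f, P)
  expect_true(p1 > 0 && p1 < 1)
  expect_identical(p1, predictProbability(f, P))  # eval mode: no dropout

  # all-zero parameters give the sigmoid of zero
  P0 <- lapply(P, function(x) x * 0)
  P0$head.bn_rvar <- rep(1, 512)
  expect_equal(predictProbability(f, P0), 0.5)
})

test_that("binary cross-entropy matches its closed forms", {
  expect_equal(bceLoss(1, 1), 0, tolerance = 1e-6)
  expect_equal(bceLoss(0.5, 1), log(2))
  expect_equal(bceLoss(0.5, 0), log(2))
  # mixed batch equals the hand-written per-sample mean
  p <- c(0.9, 0.2, 0.6, 0.4)
  y <- c(1, 0, 0, 1)
  want <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(bceLoss(p, y), want)
})

test_that("backpropagated gradients match finite differences end to end", {
  st <- fixtureStats()
  lig <- list(featurizeMolecule("CCO", st), featurizeMolecule("CCN", st))
  prot <- fixtureProtein(4, seed = 3)
  P <- fixtureParams()
  labels <- c(1, 0)
  out <- GraphPLI:::.lossAndGrads(lig, labels, prot, P)
  lossAt <- function(Pm) GraphPLI:::.lossAndGrads(lig, labels, prot, Pm)$loss
  eps <- 1e-6
  set.seed(55)
  checked <- 0L
  for (nm in names(out$grads)) {
    for (r in 1:2) {
      i <- sample.int(length(P[[nm]]), 1)
      P2 <- P; P2[[nm]][i] <- P2[[nm]][i] + eps
      P3 <- P; P3[[nm]][i] <- P3[[nm]][i] - eps
      fd <- (lossAt(P2) - lossAt(P3)) / (2 * eps)
      an <- out$grads[[nm]][i]
      # relative agreement to 1e-4, absolute for gradients near the
      # finite-difference noise floor
      expect_lt(abs(fd - an), 1e-4 * max(1, abs(fd), abs(an)))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 20)
})

test_that("both attention directions carry signal", {
  st <- fixtureStats()
  lig <- featurizeMolecule("CCO", st)
  prot <- fixtureProtein(5, seed = 9)
  P <- fixtureParams()
  base <- predictPair(lig, prot, P)$probability
  # zeroing the ligand-to-protein direction changes the output
  Pz <- P
  for (w in c("Wq", "Wk", "Wv", "Wo")) {
    Pz[[paste0("fus.l2p.", w)]] <- Pz[[paste0("fus.l2p.", w)]] * 0
  }
  expect_false(isTRUE(all.equal(predictPair(lig, prot, Pz)$probability, base)))
  # and likewise the protein-to-ligand direction
  Pz2 <- P
  for (w in c("Wq", "Wk", "Wv", "Wo")) {
    Pz2[[paste0("fus.p2l.", w)]] <- Pz2[[paste0("fus.p2l.", w)]] * 0
  }
  expect_false(isTRUE(all.equal(predictPair(lig, prot, Pz2)$probability, base)))
})

test_that("checkpoints round-trip the full model", {
  model <- new("InhibitorClassifier",
    params = fixtureParams(), normStats = fixtureStats(),
    config = trainConfig(epochs = 2)
  )
  tf <- tempfile(fileext = ".ckpt")
  saveCheckpoint(model, tf)
  m2 <- loadCheckpoint(tf)
  expect_identical(modelParams(m2), modelParams(model))
  expect_identical(normStats(m2), normStats(model))
})
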