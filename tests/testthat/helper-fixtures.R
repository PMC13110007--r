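# Shared test fixtures, built once per test run.

.fixtureEnv <- new.env(parent = emptyenv())

# Normalization statistics over a small, fixed descriptor corpus.
fixtureStats <- function() {
  list(charge_mean = 0, charge_std = 1, vdw_min = 1.2, vdw_max = 1.8)
}

# Small featurized protein graph from an irregular synthetic chain.
fixtureProtein <- function(n = 12, seed = 5) {
  key <- paste0("prot_", n, "_", seed)
  if (is.null(.fixtureEnv[[key]])) {
    ch <- genChain(n, "coil_mix", seed = seed)
    .fixtureEnv[[key]] <- buildProteinGraph(
      assignSsFallback(ch$residues), species = "human"
    )
  }
  .fixtureEnv[[key]]
}

# A handful of featurized ligand graphs.
fixtureLigands <- function() {
  if (is.null(.fixtureEnv$ligands)) {
    .fixtureEnv$ligands <- lapply(
      c("CCO", "CCN", "c1ccccc1", "CC(=O)O"),
      featurizeMolecule, stats = fixtureStats()
    )
  }
  .fixtureEnv$ligands
}

fixtureParams <- function(seed = 7) {
  key <- paste0("params_", seed)
  if (is.null(.fixtureEnv[[key]])) {
    .fixtureEnv[[key]] <- initModelParams(seed)
  }
  .fixtureEnv[[key]]
}

# Independent breadth-first-search distances (oracle for the dilated
# neighborhoods and shortest-path machinery; no igraph).
bfsDistances <- function(edges, n, start) {
  adj <- vector("list", n)
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1]; j <- edges[r, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  dist <- rep(Inf, n)
  dist[start] <- 0
  queue <- start
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# Random undirected simple graph as an edge matrix.
randomEdges <- function(n, p = 0.3) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p
  e <- pairs[keep, , drop = FALSE]
  storage.mode(e) <- "integer"
  e
}
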