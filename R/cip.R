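# CIP R/S assignment from MDL atom parity plus a substituent priority
# ranking. The ranking implements the dominant CIP ordering rule:
# sphere-by-sphere comparison of atomic numbers over the hierarchical
# digraph, with double/triple bonds contributing duplicated atoms and ring
# closures terminating in duplicate nodes. Exotic tie-break rules (isotopes,
# like/unlike descriptors) are out of scope; unresolved ties yield "none".

# Build the rooted comparison tree for neighbor `root` of stereocenter
# `center`. `adj` is a list of integer neighbor vectors on the full
# (explicit-hydrogen) graph, `bond` a matrix of bond orders.
.cipTree <- function(root, center, z, adj, bond, path) {
  node <- list(z = z[root], children = list())
  # duplicated atoms from multiple bonds at this atom (toward every bonded
  # partner, including the one we came from)
  for (nb in adj[[root]]) {
    o <- bond[root, nb]
    if (o > 1) {
      for (k in seq_len(o - 1)) {
        node$children[[length(node$children) + 1L]] <-
          list(z = z[nb], children = list())
      }
    }
  }
  for (nb in adj[[root]]) {
    if (nb == center && length(path) == 1L) next  # edge we came in on
    if (nb %in% path) {
      node$children[[length(node$children) + 1L]] <-
        list(z = z[nb], children = list())        # ring-closure duplicate
    } else {
      node$children[[length(node$children) + 1L]] <-
        .cipTree(nb, root, z, adj, bond, c(path, nb))
    }
  }
  node
}

# Lexicographic comparison of two trees: root atomic number first, then the
# children ordered by decreasing priority; missing branches rank as phantom
# atoms of atomic number 0. Returns -1, 0, 1.
.cipCompare <- function(a, b) {
  if (a$z != b$z) return(sign(a$z - b$z))
  ca <- .cipSortChildren(a$children)
  cb <- .cipSortChildren(b$children)
  n <- max(length(ca), length(cb))
  if (n == 0) return(0)
  for (i in seq_len(n)) {
    if (i > length(ca)) return(-1L)
    if (i > length(cb)) return(1L)
    cmp <- .cipCompare(ca[[i]], cb[[i]])
    if (cmp != 0) return(cmp)
  }
  0L
}

.cipSortChildren <- function(children) {
  n <- length(children)
  if (n < 2) return(children)
  # insertion sort by decreasing priority (branch counts are tiny)
  for (i in 2:n) {
    j <- i
    while (j > 1 && .cipCompare(children[[j - 1]], children[[j]]) < 0) {
      tmp <- children[[j - 1]]
      children[[j - 1]] <- children[[j]]
      children[[j]] <- tmp
      j <- j - 1
    }
  }
  children
}

# Parity of a permutation given as an integer vector.
.permSign <- function(p) {
  n <- length(p)
  visited <- rep(FALSE, n)
  sign <- 1L
  for (i in seq_len(n)) {
    if (!visited[i]) {
      j <- i
      len <- 0L
      while (!visited[j]) {
        visited[j] <- TRUE
        j <- p[j]
        len <- len + 1L
      }
      if (len %% 2 == 0) sign <- -sign
    }
  }
  sign
}

# Assign CIP codes for every atom of the explicit-hydrogen connection
# table. `edges` is a matrix (i, j, order); `parity` the MDL atom parity
# column (1 = even, 2 = odd, 0/3 = none).
.assignCip <- function(z, edges, parity) {
  n <- length(z)
  cip <- rep("none", n)
  stereo <- which(parity %in% c(1L, 2L))
  if (!length(stereo)) return(cip)
  adj <- vector("list", n)
  bond <- matrix(0L, n, n)
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1]; j <- edges[r, 2]; o <- edges[r, 3]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
      bond[i, j] <- o
      bond[j, i] <- o
    }
  }
  for (c0 in stereo) {
    nbrs <- sort(adj[[c0]])
    if (length(nbrs) != 4) next
    trees <- lapply(nbrs, function(nb) .cipTree(nb, c0, z, adj, bond, nb))
    # pairwise comparisons -> priority order (highest first)
    wins <- integer(4)
    tie <- FALSE
    for (i in 1:3) {
      for (j in (i + 1):4) {
        cmp <- .cipCompare(trees[[i]], trees[[j]])
        if (cmp == 0) tie <- TRUE
        if (cmp > 0) wins[i] <- wins[i] + 1L else if (cmp < 0) wins[j] <- wins[j] + 1L
      }
    }
    if (tie) next
    cipOrder <- nbrs[order(wins, decreasing = TRUE)]  # a > b > c > d
    # MDL parity 1: neighbors in atom-number order n1,n2,n3 appear clockwise
    # when viewed with n4 pointing away. Transpositions flip handedness.
    perm <- match(cipOrder, nbrs)
    clockwise <- (parity[c0] == 1L)
    if (.permSign(perm) < 0) clockwise <- !clockwise
    cip[c0] <- if (clockwise) "R" else "S"
  }
  cip
}
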