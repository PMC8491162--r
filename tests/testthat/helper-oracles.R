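# Independent oracles used across the suite. Each one recomputes a
# quantity from first principles, without touching the package internals
# it checks.

# breadth-first-search shortest-path oracle on an adjacency matrix
bfs_dist_oracle <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in which(A[v, ] == 1)) {
        if (is.infinite(dist[u])) {
          dist[u] <- dist[v] + 1
          queue <- c(queue, u)
        }
      }
    }
    D[s, ] <- dist
  }
  diag(D) <- 0
  D
}

# brute-force count of closed walks of length k by recursive enumeration
closed_walks_oracle <- function(A, k) {
  n <- nrow(A)
  walk <- function(v, target, steps) {
    if (steps == 0) return(as.integer(v == target))
    sum(vapply(which(A[v, ] == 1), walk, 0L, target = target,
               steps = steps - 1L))
  }
  sum(vapply(seq_len(n), function(s) walk(s, s, k), 0L))
}

# literal-formula Geary autocorrelation: explicit double loop
geary_oracle <- function(D, w, lag) {
  n <- length(w)
  num <- 0; npair <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (D[i, j] == lag) {
        num <- num + (w[i] - w[j])^2
        npair <- npair + 1
      }
    }
  }
  denom <- 2 * sum((w - mean(w))^2) / (n - 1)
  if (npair == 0 || denom < 1e-14) return(0)
  (num / npair) / denom
}

# literal-formula Moran autocorrelation over ordered pairs
moran_oracle <- function(D, w, lag) {
  n <- length(w)
  wc <- w - mean(w)
  num <- 0; npair <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && D[i, j] == lag) {
        num <- num + wc[i] * wc[j]
        npair <- npair + 1
      }
    }
  }
  denom <- sum(wc^2) / n
  if (npair == 0 || denom < 1e-14) return(0)
  (num / npair) / denom
}

# Wilks' lambda by literal scatter-matrix construction
wilks_oracle <- function(X, y) {
  X <- as.matrix(X)
  Tm <- t(scale(X, scale = FALSE)) %*% scale(X, scale = FALSE)
  W <- matrix(0, ncol(X), ncol(X))
  for (cls in unique(y)) {
    Xc <- X[y == cls, , drop = FALSE]
    Xc <- scale(Xc, scale = FALSE)
    W <- W + t(Xc) %*% Xc
  }
  det(W) / det(Tm)
}

# rebuild a molgraph with atoms relabeled by a permutation
permute_molgraph <- function(g, perm) {
  inv <- order(perm)  # inv[old] = new position
  atoms <- g$atoms[perm, ]
  bonds <- g$bonds
  bonds$i <- inv[bonds$i]
  bonds$j <- inv[bonds$j]
  new_molgraph(atoms, bonds, smiles = g$smiles)
}

# small diverse SMILES set used by oracle comparisons
oracle_smiles <- function() {
  c("C", "CC", "CCC", "CC(C)C", "C1CCCC1", "C1CCCCC1", "c1ccccc1",
    "c1ccncc1", "C=C", "C#N", "CC=O", "CCO", "CCN", "ClCCCl",
    "c1cc[nH]c1", "c1cnc[nH]1", "CC(=O)NC", "OC(=O)C", "FC(F)F",
    "c1ccc2[nH]ccc2c1", "CSC", "O=S(=O)(C)C", "BrCC", "ICCI",
    unname(unlist(fixture_registry()$smiles)))
}
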