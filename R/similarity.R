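# Fingerprint-based chemical diversity: Carhart atom-pair fingerprints,
# Tanimoto similarity, average-linkage hierarchical clustering with the
# Kelley-Gardner-Sutcliffe criterion choosing the number of clusters.

# Carhart atom type: element, number of heavy neighbors, pi indicator
.carhart_types <- function(g) {
  deg <- rowSums(g$adjacency)
  pi_at <- logical(g$n_heavy)
  if (nrow(g$bonds)) {
    multi <- g$bonds$order %in% c("2", "3", "ar")
    pi_at[unique(c(g$bonds$i[multi], g$bonds$j[multi]))] <- TRUE
  }
  sprintf("%s.%d.%d", g$atoms$element, deg, as.integer(pi_at))
}

# small deterministic string hash (FNV-style, 28-bit state); doubles stay
# exact because intermediates are kept below 2^53
.hash31 <- function(s) {
  vapply(s, function(x) {
    h <- 216613626
    for (cc in utf8ToInt(x)) h <- (h * 16777619 + cc) %% 268435399
    as.integer(h)
  }, 0L, USE.NAMES = FALSE)
}

#' Carhart atom-pair fingerprint
#'
#' Hashes every (atom type, atom type, topological distance) feature of
#' the heavy-atom graph — atom types are Carhart triplets (element, heavy
#' degree, pi flag) — and folds the features into an `n_bits` binary
#' string. A single-atom molecule gets its self-feature (type at distance
#' 0) so the fingerprint is never empty.
#'
#' @param g A `molgraph`.
#' @param n_bits Fingerprint length (default 1024; 32 reproduces the
#'   published tool's printed default but collides heavily and is kept
#'   only as a compatibility mode).
#' @return A `fingerprint`: logical vector of length `n_bits` with
#'   attributes `n_bits` and `scheme`.
#' @export
#' @examples
#' f <- atom_pair_fingerprint(parse_smiles("CCO"))
#' sum(f)
atom_pair_fingerprint <- function(g, n_bits = 1024L) {
  stopifnot(inherits(g, "molgraph"), n_bits >= 8L || n_bits == 32L ||
              n_bits > 0L)
  types <- .carhart_types(g)
  n <- g$n_heavy
  feats <- if (n == 1L) {
    paste0(types[1], ">0<", types[1])
  } else {
    idx <- which(upper.tri(g$topo_dist), arr.ind = TRUE)
    t1 <- pmin(types[idx[, 1]], types[idx[, 2]])
    t2 <- pmax(types[idx[, 1]], types[idx[, 2]])
    d <- g$topo_dist[idx]
    unique(paste0(t1, ">", d, "<", t2))
  }
  bits <- rep(FALSE, n_bits)
  bits[(.hash31(feats) %% n_bits) + 1L] <- TRUE
  structure(bits, n_bits = as.integer(n_bits), scheme = "carhart",
            class = "fingerprint")
}

#' Tanimoto similarity of two fingerprints
#'
#' `|A & B| / |A | B|` over set bits; two all-zero fingerprints are
#' defined as identical (similarity 1). The associated distance is
#' `1 - tanimoto(...)` (the Soergel distance on bit sets, a metric).
#'
#' @param f1,f2 Fingerprints of equal length.
#' @return Similarity in \[0, 1\].
#' @export
#' @examples
#' a <- c(TRUE, TRUE, FALSE, FALSE); b <- c(TRUE, FALSE, TRUE, FALSE)
#' tanimoto(a, b)  # 1/3
tanimoto <- function(f1, f2) {
  if (length(f1) != length(f2))
    stop("fingerprints must have equal length", call. = FALSE)
  u <- sum(f1 | f2)
  if (u == 0) return(1)
  sum(f1 & f2) / u
}

#' Pairwise Tanimoto distance matrix of a library
#'
#' @param library Data frame with `id` and `smiles` columns, or a named
#'   list of `fingerprint`s.
#' @param n_bits Fingerprint length (used when `library` holds SMILES).
#' @return Symmetric matrix of `1 - Tanimoto` distances with zero
#'   diagonal.
#' @export
tanimoto_distance_matrix <- function(library, n_bits = 1024L) {
  fps <- if (is.data.frame(library)) {
    fl <- lapply(library$smiles, function(s)
      atom_pair_fingerprint(parse_smiles(s), n_bits))
    names(fl) <- library$id
    fl
  } else library
  n <- length(fps)
  M <- matrix(0, n, n, dimnames = list(names(fps), names(fps)))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        M[i, j] <- M[j, i] <- 1 - tanimoto(fps[[i]], fps[[j]])
      }
    }
  }
  M
}

# Kelley-Gardner-Sutcliffe penalty over the cut levels of a dendrogram:
# average within-cluster spread (mean pairwise distance of non-singleton
# clusters), rescaled across levels to [1, n-1], plus the cluster count.
# Every level from one cluster to n-1 clusters is scored: the one-cluster
# level anchors the normalization, which is what lets the penalty reward
# a cut that splits well-separated families.
.kelley_penalty <- function(D, hc) {
  n <- nrow(D)
  ks <- 1:(n - 1)
  spread <- vapply(ks, function(k) {
    mem <- cutree(hc, k)
    per <- vapply(unique(mem), function(cl) {
      sel <- which(mem == cl)
      if (length(sel) < 2L) return(NA_real_)
      mean(D[sel, sel][upper.tri(D[sel, sel])])
    }, 0)
    if (all(is.na(per))) 0 else mean(per, na.rm = TRUE)
  }, 0)
  rng <- range(spread)
  scaled <- if (diff(rng) < .Machine$double.eps) rep(1, length(spread))
            else (n - 2) * (spread - rng[1]) / diff(rng) + 1
  tibble::tibble(k = ks, spread = spread, penalty = scaled + ks)
}

#' Cluster a distance matrix with the Kelley criterion
#'
#' Agglomerative hierarchical clustering (average linkage by default);
#' the flat cut is chosen by minimizing the Kelley-Gardner-Sutcliffe
#' penalty — normalized mean within-cluster spread plus the number of
#' clusters — over all cut levels.
#'
#' @param D Square symmetric distance matrix with zero diagonal (e.g.
#'   from [tanimoto_distance_matrix()]).
#' @param linkage `hclust` method (default `"average"`).
#' @return A `fingerprint_clustering`: list with `hclust`, `k` (chosen
#'   number of clusters), `membership` (named integer vector), and the
#'   `penalty` table.
#' @export
cluster_kelley <- function(D, linkage = "average") {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (max(abs(D - t(D))) > 1e-12 || any(abs(diag(D)) > 1e-12))
    stop("D must be symmetric with zero diagonal", call. = FALSE)
  n <- nrow(D)
  if (n < 2L) {
    return(structure(list(hclust = NULL, k = 1L,
                          membership = setNames(rep(1L, n), rownames(D)),
                          penalty = NULL),
                     class = "fingerprint_clustering"))
  }
  hc <- hclust(as.dist(D), method = linkage)
  if (n == 2L) {
    k <- if (D[1, 2] < .Machine$double.eps) 1L else 2L
    return(structure(list(hclust = hc, k = k,
                          membership = setNames(cutree(hc, k), rownames(D)),
                          penalty = NULL),
                     class = "fingerprint_clustering"))
  }
  if (max(D) < 1e-12) {
    return(structure(list(hclust = hc, k = 1L,
                          membership = setNames(rep(1L, n), rownames(D)),
                          penalty = NULL),
                     class = "fingerprint_clustering"))
  }
  pen <- .kelley_penalty(D, hc)
  k <- pen$k[which.min(pen$penalty)]
  structure(list(hclust = hc, k = k,
                 membership = setNames(cutree(hc, k), rownames(D)),
                 penalty = pen),
            class = "fingerprint_clustering")
}

#' @export
print.fingerprint_clustering <- function(x, ...) {
  cat(sprintf("<fingerprint_clustering> %d items, %d cluster(s)\n",
              length(x$membership), x$k))
  print(table(cluster = x$membership))
  invisible(x)
}

#' Cluster a compound library by fingerprint similarity
#'
#' Fingerprints the library, builds the Tanimoto distance matrix, and
#' clusters with [cluster_kelley()].
#'
#' @param library Data frame with `id` and `smiles`.
#' @param n_bits Fingerprint length.
#' @param linkage `hclust` method.
#' @return A tibble `id`, `cluster`, with the `fingerprint_clustering`
#'   object attached as attribute `"clustering"`.
#' @export
cluster_library <- function(library, n_bits = 1024L, linkage = "average") {
  D <- tanimoto_distance_matrix(library, n_bits)
  cl <- cluster_kelley(D, linkage)
  out <- tibble::tibble(id = names(cl$membership),
                        cluster = unname(cl$membership))
  attr(out, "clustering") <- cl
  out
}

#' Write a dendrogram as Newick
#'
#' Converts the hclust tree of a clustering to `ape`'s phylo and writes
#' Newick text.
#'
#' @param clustering A `fingerprint_clustering` with a non-null `hclust`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(clustering, path) {
  stopifnot(inherits(clustering, "fingerprint_clustering"),
            !is.null(clustering$hclust))
  if (!requireNamespace("ape", quietly = TRUE))
    stop("writing Newick dendrograms requires the ape package",
         call. = FALSE)
  phy <- ape::as.phylo(clustering$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
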