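# Topological descriptor engine.
#
# All descriptors are graph invariants of the hydrogen-suppressed chemical
# graph (the information-content family uses the hydrogen-filled graph, the
# convention of the descriptor software this engine mirrors). Conventions
# chosen for degenerate cases (empty autocorrelation lag, zero weight
# variance, fewer bonds than requested eigenvalue) all return 0 so that the
# descriptor table is total over any screening library.

#' Self-returning walk count of order 5
#'
#' Number of closed walks of length 5 in the heavy-atom graph: the trace of
#' the 5th power of the adjacency matrix. Sensitive to odd rings and in
#' practice to five-membered rings, a recurring motif of JAK inhibitor
#' scaffolds. Bipartite graphs (e.g. benzene alone) score 0.
#'
#' @param g A `molgraph`.
#' @param log_transform Return `log(1 + count)` instead of the raw count
#'   (some descriptor software log-transforms high-order walk counts).
#' @return Non-negative number.
#' @export
#' @examples
#' srw05(parse_smiles("C1CCCC1"))   # cyclopentane: 10
#' srw05(parse_smiles("c1ccccc1"))  # benzene: 0
srw05 <- function(g, log_transform = FALSE) {
  A <- g$adjacency
  storage.mode(A) <- "double"
  A5 <- A %*% A %*% A %*% A %*% A
  x <- sum(diag(A5))
  if (log_transform) log1p(x) else x
}

# Weisfeiler-Lehman style refinement of atom classes: after k rounds the
# class of an atom encodes its order-k neighborhood. Initial colors are
# (element, vertex degree); edges are labeled by bond order. This is the
# neighborhood-symmetry convention the information indices are defined
# on (the Tofacitinib CIC2 = 0.500 anchor pins it down).
.neighborhood_classes <- function(g, k) {
  n <- g$n_heavy
  if (n == 0L) return(integer(0))
  labels <- paste(g$atoms$element, rowSums(g$adjacency), sep = "/")
  if (k == 0L) labels <- g$atoms$element  # order 0: element partition only
  if (k == 0L || n == 1L) return(match(labels, unique(labels)))
  nbrs <- lapply(seq_len(n), function(i) integer(0))
  btype <- lapply(seq_len(n), function(i) character(0))
  for (r in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[r]; j <- g$bonds$j[r]; o <- g$bonds$order[r]
    nbrs[[i]] <- c(nbrs[[i]], j); btype[[i]] <- c(btype[[i]], o)
    nbrs[[j]] <- c(nbrs[[j]], i); btype[[j]] <- c(btype[[j]], o)
  }
  for (round in seq_len(k)) {
    new <- vapply(seq_len(n), function(i) {
      neigh <- sort(paste(btype[[i]], labels[nbrs[[i]]], sep = "~"))
      paste(labels[i], paste(neigh, collapse = "|"), sep = "::")
    }, "")
    labels <- new
  }
  match(labels, unique(labels))
}

#' Information content and complementary information content indices
#'
#' Partitions the atoms of the hydrogen-filled graph into equivalence
#' classes by iterated neighborhood refinement of order `k` (element,
#' degree and bond pattern up to the k-th coordination sphere), then
#' computes the Shannon entropy of the partition:
#' \deqn{IC_k = -\sum_c p_c \log_2 p_c, \quad p_c = |c| / n}
#' and its complement \eqn{CIC_k = \log_2(n) - IC_k}. High CIC means a
#' symmetric structure (few large classes); asymmetric molecules score low.
#'
#' @param g A `molgraph` (hydrogen-suppressed; the hydrogen-filled
#'   expansion is built internally).
#' @param k Neighborhood order (non-negative integer).
#' @return Named list with `ic` and `cic`, both in bits.
#' @export
#' @examples
#' information_content(parse_smiles("C"), k = 0)  # methane
information_content <- function(g, k = 2L) {
  stopifnot(inherits(g, "molgraph"), k >= 0L)
  gh <- hydrogen_filled(g)
  n <- gh$n_heavy
  if (n <= 1L) return(list(ic = 0, cic = 0))
  cls <- .neighborhood_classes(gh, as.integer(k))
  p <- as.numeric(table(cls)) / n
  ic <- -sum(p * log2(p))
  list(ic = ic, cic = log2(n) - ic)
}

# shared guts of the spatial autocorrelation descriptors
.autocorr_pairs <- function(g, lag) {
  D <- g$topo_dist
  idx <- which(upper.tri(D) & D == lag, arr.ind = TRUE)
  idx
}

#' Geary autocorrelation of a topological lag
#'
#' \deqn{GATS_k = \frac{\sum_{i<j,\,d_{ij}=k}(w_i-w_j)^2 / \Delta_k}
#'                    {2 \sum_i (w_i-\bar w)^2 / (n-1)}}
#' with carbon-scaled atomic property weights \eqn{w} and \eqn{\Delta_k}
#' the number of unordered atom pairs at topological distance `lag`.
#' Returns 0 when the lag is empty or the weights have zero variance
#' (homonuclear skeletons), so the descriptor is total.
#'
#' @param g A `molgraph`.
#' @param lag Topological distance (>= 1).
#' @param property Atomic property, see [atom_weights()].
#' @return Non-negative number.
#' @export
#' @examples
#' geary_autocorrelation(parse_smiles("CO"), 1, "mass")  # 1
geary_autocorrelation <- function(g, lag, property = "mass") {
  w <- atom_weights(g, property, scaled = TRUE)
  n <- length(w)
  if (n < 2L) return(0)
  denom <- 2 * sum((w - mean(w))^2) / (n - 1)
  if (denom <= .Machine$double.eps) return(0)
  idx <- .autocorr_pairs(g, lag)
  if (nrow(idx) == 0L) return(0)
  num <- sum((w[idx[, 1]] - w[idx[, 2]])^2) / nrow(idx)
  num / denom
}

#' Moran autocorrelation of a topological lag
#'
#' \deqn{MATS_k = \frac{\sum_{d_{ij}=k}(w_i-\bar w)(w_j-\bar w) / (2\Delta_k)}
#'                    {\sum_i (w_i-\bar w)^2 / n}}
#' (sum over ordered pairs). Same 0 conventions as
#' [geary_autocorrelation()].
#'
#' @inheritParams geary_autocorrelation
#' @return Number in roughly \[-1, 1\].
#' @export
moran_autocorrelation <- function(g, lag, property = "mass") {
  w <- atom_weights(g, property, scaled = TRUE)
  n <- length(w)
  if (n < 2L) return(0)
  denom <- sum((w - mean(w))^2) / n
  if (denom <= .Machine$double.eps) return(0)
  idx <- .autocorr_pairs(g, lag)
  if (nrow(idx) == 0L) return(0)
  wc <- w - mean(w)
  # ordered-pair sum = 2 x unordered sum
  num <- 2 * sum(wc[idx[, 1]] * wc[idx[, 2]]) / (2 * nrow(idx))
  num / denom
}

#' Galvez topological charge index of order k (JGIk)
#'
#' From the charge-transfer matrix \eqn{M = A Q} (adjacency times the
#' inverse-square-distance matrix), the charge terms
#' \eqn{CT_{ij} = m_{ij} - m_{ji}} are summed in absolute value over
#' unordered pairs at topological distance `k` and normalized by
#' \eqn{n - 1}.
#'
#' @param g A `molgraph`.
#' @param k Order (topological distance of the pairs).
#' @return Non-negative number; 0 for a single atom or empty order.
#' @export
charge_index <- function(g, k) {
  n <- g$n_heavy
  if (n < 2L) return(0)
  D <- g$topo_dist
  Q <- ifelse(D > 0, 1 / D^2, 0)
  A <- g$adjacency
  storage.mode(A) <- "double"
  M <- A %*% Q
  CT <- M - t(M)
  idx <- which(upper.tri(D) & D == k, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0)
  sum(abs(CT[idx])) / (n - 1)
}

# dipole weight for one bond: lookup by unordered element pair + order
# class, falling back to |Sanderson EN difference|
.bond_dipole <- function(e1, e2, order) {
  tab <- bond_dipole_table()
  a <- pmin(e1, e2); b <- pmax(e1, e2)
  hit <- tab$dipole[tab$a == a & tab$b == b & tab$order == order]
  if (length(hit)) return(hit[1])
  if (e1 == e2) return(0)
  ep <- element_properties()
  abs(ep$sanderson_en[match(e1, ep$symbol)] -
      ep$sanderson_en[match(e2, ep$symbol)])
}

#' Fifth eigenvalue of the dipole-augmented edge adjacency matrix
#'
#' Builds the edge adjacency matrix (bonds as vertices, entry 1 when two
#' bonds share an atom), puts per-bond dipole-moment weights (Debye, from
#' [bond_dipole_table()]) on the diagonal, and returns the 5th largest
#' eigenvalue. Molecules with fewer than 5 bonds score 0.
#'
#' @param g A `molgraph`.
#' @return Real eigenvalue (matrix is symmetric).
#' @export
eig05_aea_dm <- function(g) {
  nb <- nrow(g$bonds)
  if (nb < 5L) return(0)
  E <- matrix(0, nb, nb)
  ends <- cbind(g$bonds$i, g$bonds$j)
  for (r in seq_len(nb - 1L)) {
    for (s in (r + 1L):nb) {
      if (length(intersect(ends[r, ], ends[s, ]))) E[r, s] <- E[s, r] <- 1
    }
  }
  el <- g$atoms$element
  diag(E) <- vapply(seq_len(nb), function(r)
    .bond_dipole(el[ends[r, 1]], el[ends[r, 2]], g$bonds$order[r]), 0)
  ev <- sort(eigen(E, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[5]
}

#' P_VSA-like descriptor on atomic log P
#'
#' Sums the van der Waals surface-area increments of the heavy atoms whose
#' atomic log P contribution falls in bin `bin` of [pvsa_logp_bins()]
#' (bins are `(lo, hi]`). Summing over all bins returns the total
#' heavy-atom surface area.
#'
#' @param g A `molgraph`.
#' @param bin Bin index, 1 to 10.
#' @return Surface area in A^2.
#' @export
pvsa_logp <- function(g, bin) {
  edges <- pvsa_logp_bins()
  if (!is.numeric(bin) || bin < 1L || bin > length(edges) - 1L)
    stop(sprintf("bin must be between 1 and %d", length(edges) - 1L),
         call. = FALSE)
  lp <- atom_weights(g, "logp_atomic", scaled = FALSE)
  sa <- atom_weights(g, "vdw_surface", scaled = FALSE)
  sel <- lp > edges[bin] & lp <= edges[bin + 1L]
  sum(sa[sel])
}

# enumerate all simple paths up to max_len edges; returns total count and
# total bond-order-weighted count (each unordered path once)
.path_counts <- function(g, max_len = 10L) {
  n <- g$n_heavy
  if (n < 2L || nrow(g$bonds) == 0L) return(c(count = 0, weighted = 0))
  ordm <- matrix(0, n, n)
  ordm[cbind(g$bonds$i, g$bonds$j)] <- g$bonds$conv_order
  ordm[cbind(g$bonds$j, g$bonds$i)] <- g$bonds$conv_order
  nbrs <- lapply(seq_len(n), function(i) which(g$adjacency[i, ] == 1L))
  count <- 0; weighted <- 0
  visited <- logical(n)
  dfs <- function(v, start, depth, wprod) {
    for (u in nbrs[[v]]) {
      if (visited[u]) next
      w2 <- wprod * ordm[v, u]
      if (u > start) {  # count each unordered path once via endpoint order
        count <<- count + 1
        weighted <<- weighted + w2
      }
      if (depth < max_len) {
        visited[u] <<- TRUE
        dfs(u, start, depth + 1L, w2)
        visited[u] <<- FALSE
      }
    }
  }
  for (start in seq_len(n)) {
    visited[] <- FALSE
    visited[start] <- TRUE
    dfs(start, start, 1L, 1)
  }
  c(count = count, weighted = weighted)
}

#' Difference between multiple path count and path count (PCD)
#'
#' Simple paths are enumerated up to `max_len` edges; the multiple path
#' count weights each path by the product of conventional bond orders
#' along it (single 1, double 2, triple 3, aromatic 1.5), the plain count
#' weights each path by 1. Saturated acyclic hydrocarbons therefore score
#' exactly 0.
#'
#' @param g A `molgraph`.
#' @param max_len Maximum path length in edges (default 10).
#' @return Non-negative number.
#' @export
#' @examples
#' pcd(parse_smiles("C=C"))  # ethene: 2 - 1 = 1
pcd <- function(g, max_len = 10L) {
  pc <- .path_counts(g, max_len)
  unname(pc["weighted"] - pc["count"])
}

# registry of every descriptor the engine computes -------------------------

.descriptor_registry <- function() {
  props <- c(m = "mass", e = "sanderson_en", i = "ionization")
  reg <- list()
  for (k in 3:8) {
    reg[[sprintf("SRW%02d", k)]] <- local({
      kk <- k
      function(g) {
        A <- g$adjacency; storage.mode(A) <- "double"
        Ak <- A
        for (s in seq_len(kk - 1L)) Ak <- Ak %*% A
        sum(diag(Ak))
      }
    })
  }
  for (k in 0:3) {
    reg[[sprintf("CIC%d", k)]] <- local({
      kk <- k
      function(g) information_content(g, kk)$cic
    })
  }
  for (suf in names(props)) {
    for (k in 1:8) {
      reg[[sprintf("GATS%d%s", k, suf)]] <- local({
        kk <- k; pp <- props[[suf]]
        function(g) geary_autocorrelation(g, kk, pp)
      })
      reg[[sprintf("MATS%d%s", k, suf)]] <- local({
        kk <- k; pp <- props[[suf]]
        function(g) moran_autocorrelation(g, kk, pp)
      })
    }
  }
  for (k in 1:8) {
    reg[[sprintf("JGI%d", k)]] <- local({
      kk <- k
      function(g) charge_index(g, kk)
    })
  }
  reg[["PCD"]] <- function(g) pcd(g)
  reg[["Eig05_AEA_dm"]] <- function(g) eig05_aea_dm(g)
  for (b in 1:10) {
    reg[[sprintf("P_VSA_LogP_%d", b)]] <- local({
      bb <- b
      function(g) pvsa_logp(g, bb)
    })
  }
  reg
}

# canonical aliases used by the published models
.MODEL_DESCRIPTORS <- c("SRW05", "CIC2", "GATS6m", "PCD", "MATS5i",
                        "GATS4e", "GATS8m", "GATS5e", "Eig05_AEA_dm",
                        "P_VSA_LogP_5", "JGI8")

#' Descriptor pool for model retraining
#'
#' The candidate set used when refitting discriminant models: the eleven
#' descriptors of the published models plus the complete self-returning
#' walk, Geary/Moran autocorrelation (mass, electronegativity, ionization
#' weights) and Galvez charge-index families at orders/lags 1-8.
#'
#' @return Character vector of descriptor names.
#' @export
retraining_descriptors <- function() {
  unique(c(
    .MODEL_DESCRIPTORS,
    sprintf("SRW%02d", 3:8),
    sprintf("JGI%d", 1:8),
    as.vector(outer(1:8, c("m", "e", "i"),
                    function(k, s) sprintf("GATS%d%s", k, s))),
    as.vector(outer(1:8, c("m", "e", "i"),
                    function(k, s) sprintf("MATS%d%s", k, s)))
  ))
}

#' Compute the full descriptor vector of one molecule
#'
#' Evaluates every registered topological descriptor: self-returning walk
#' counts SRW03-SRW08, information indices CIC0-CIC3, Geary and Moran
#' autocorrelations at lags 1-8 weighted by mass (m), Sanderson
#' electronegativity (e) and ionization potential (i), Galvez charge
#' indices JGI1-JGI8, PCD, the dipole-augmented edge adjacency eigenvalue,
#' and the ten P_VSA log P bins. Deterministic and permutation-invariant.
#'
#' @param g A `molgraph`.
#' @return Named numeric vector.
#' @export
#' @examples
#' d <- descriptor_vector(parse_smiles("C1CCCC1"))
#' d[["SRW05"]]
descriptor_vector <- function(g) {
  reg <- .descriptor_registry()
  vapply(reg, function(f) f(g), 0)
}

#' Compute descriptors for a whole library
#'
#' @param library A data frame with columns `id` and `smiles`.
#' @param descriptors Optional character vector restricting the output
#'   columns (default: all registered descriptors).
#' @return A tibble: `id` column first, then one column per descriptor.
#' @export
#' @examples
#' calc_descriptors(tibble::tibble(id = "cp", smiles = "C1CCCC1"),
#'                  descriptors = c("SRW05", "CIC2"))
calc_descriptors <- function(library, descriptors = NULL) {
  stopifnot(all(c("id", "smiles") %in% names(library)))
  reg <- .descriptor_registry()
  if (!is.null(descriptors)) {
    unknown <- setdiff(descriptors, names(reg))
    if (length(unknown))
      stop("unknown descriptor(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    reg <- reg[descriptors]
  }
  rows <- purrr::map(seq_len(nrow(library)), function(r) {
    g <- parse_smiles(library$smiles[r])
    vapply(reg, function(f) f(g), 0)
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  dplyr::bind_cols(tibble::tibble(id = library$id), out)
}
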