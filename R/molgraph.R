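#' Construct a molgraph from atom and bond tables
#'
#' Low-level constructor; [parse_smiles()] is the usual entry point. Checks
#' connectivity, builds the adjacency and topological distance matrices.
#'
#' @param atoms Tibble with columns `element`, `aromatic`, `charge`, `n_h`.
#' @param bonds Tibble with columns `i`, `j`, `order` (`"1"`, `"2"`, `"3"`,
#'   `"ar"`) and `conv_order` (1, 2, 3, 1.5).
#' @param smiles Originating SMILES, if any.
#' @return A `molgraph` object.
#' @export
new_molgraph <- function(atoms, bonds, smiles = NA_character_) {
  n <- nrow(atoms)
  A <- matrix(0L, n, n)
  if (nrow(bonds)) {
    A[cbind(bonds$i, bonds$j)] <- 1L
    A[cbind(bonds$j, bonds$i)] <- 1L
  }
  if (n > 1L) {
    ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    if (igraph::components(ig)$no > 1L)
      stop("molgraph must be connected; reduce to the largest fragment first",
           call. = FALSE)
    D <- igraph::distances(ig)
  } else {
    D <- matrix(0, 1L, 1L)
  }
  structure(
    list(atoms = atoms, bonds = bonds, n_heavy = n,
         adjacency = A, topo_dist = D, smiles = smiles),
    class = "molgraph"
  )
}

#' @export
print.molgraph <- function(x, ...) {
  hs <- sum(x$atoms$n_h)
  cat(sprintf("<molgraph> %d heavy atoms, %d bonds, %d implicit H",
              x$n_heavy, nrow(x$bonds), hs))
  if (!is.na(x$smiles)) cat("  [", x$smiles, "]", sep = "")
  cat("\n")
  counts <- sort(table(x$atoms$element), decreasing = TRUE)
  cat("  elements:", paste0(names(counts), counts, collapse = " "), "\n")
  invisible(x)
}

#' Expand implicit hydrogens into explicit vertices
#'
#' Returns the hydrogen-filled graph: every implicit hydrogen becomes a
#' degree-1 `H` vertex single-bonded to its heavy atom. Needed by the
#' information-content indices, which are defined on the full molecular
#' graph.
#'
#' @param g A `molgraph`.
#' @return A `molgraph` including explicit hydrogens (their `n_h` is 0).
#' @export
#' @examples
#' hydrogen_filled(parse_smiles("C"))$n_heavy  # methane: 5 vertices
hydrogen_filled <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  nh <- g$atoms$n_h
  n0 <- g$n_heavy
  n_add <- sum(nh)
  if (n_add == 0L) return(g)
  owner <- rep(seq_len(n0), nh)
  atoms <- dplyr::bind_rows(
    dplyr::mutate(g$atoms, n_h = 0L),
    tibble::tibble(element = rep("H", n_add), aromatic = FALSE,
                   charge = 0L, n_h = 0L)
  )
  bonds <- dplyr::bind_rows(
    g$bonds,
    tibble::tibble(i = owner, j = n0 + seq_len(n_add),
                   order = "1", conv_order = 1)
  )
  new_molgraph(atoms, bonds, smiles = g$smiles)
}

#' Per-atom property weights
#'
#' Looks up one property value per heavy atom, in atom order, from the
#' shipped [element_properties()] table. With `scaled = TRUE` the values
#' are divided by the carbon value (the convention of the autocorrelation
#' descriptors, so carbon is exactly 1). The atomic log P contribution
#' uses aromatic-environment overrides for aromatic C/N/O/S.
#'
#' @param g A `molgraph`.
#' @param property One of `"mass"`, `"sanderson_en"`, `"ionization"`,
#'   `"vdw_surface"`, `"logp_atomic"`.
#' @param scaled Divide by the carbon value? Default `TRUE`.
#' @return Numeric vector, one value per heavy atom.
#' @export
#' @examples
#' atom_weights(parse_smiles("CO"), "mass", scaled = FALSE)
atom_weights <- function(g, property = c("mass", "sanderson_en", "ionization",
                                         "vdw_surface", "logp_atomic"),
                         scaled = TRUE) {
  stopifnot(inherits(g, "molgraph"))
  property <- match.arg(property)
  tab <- element_properties()
  idx <- match(g$atoms$element, tab$symbol)
  if (anyNA(idx)) {
    missing <- unique(g$atoms$element[is.na(idx)])
    stop(sprintf("no %s value for element(s): %s", property,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  w <- tab[[property]][idx]
  if (property == "logp_atomic") {
    ov <- .logp_aromatic[g$atoms$element]
    sel <- g$atoms$aromatic & !is.na(ov)
    w[sel] <- ov[sel]
  }
  if (scaled) w <- w / tab[[property]][tab$symbol == "C"]
  w
}

#' Molecular weight of a molgraph (heavy atoms + implicit/explicit H)
#' @param g A `molgraph`.
#' @return Molecular weight in u.
#' @export
molgraph_mw <- function(g) {
  tab <- element_properties()
  m <- tab$mass[match(g$atoms$element, tab$symbol)]
  sum(m) + sum(g$atoms$n_h) * tab$mass[tab$symbol == "H"]
}

#' Summarise a set of molecules as a table
#'
#' @param library A data frame with columns `id` and `smiles`.
#' @return A tibble with per-molecule heavy atom count, bond count,
#'   molecular weight, element counts (C/N/O/halogen) and ring information.
#' @export
graph_summary <- function(library) {
  purrr::map_dfr(seq_len(nrow(library)), function(k) {
    g <- parse_smiles(library$smiles[k])
    tibble::tibble(
      id = library$id[k],
      n_heavy = g$n_heavy,
      n_bonds = nrow(g$bonds),
      mw = molgraph_mw(g),
      n_C = sum(g$atoms$element == "C"),
      n_N = sum(g$atoms$element == "N"),
      n_O = sum(g$atoms$element == "O"),
      n_halogen = sum(g$atoms$element %in% c("F", "Cl", "Br", "I")),
      n_rings = nrow(g$bonds) - g$n_heavy + 1L,
      has_five_ring = has_five_membered_ring(g)
    )
  })
}

#' Does the graph contain a five-membered ring?
#'
#' Detected as a closed walk of length 5 returning to a vertex that is not
#' decomposable into shorter cycles — implemented via the cycle basis of
#' the graph.
#'
#' @param g A `molgraph`.
#' @return Logical scalar.
#' @export
has_five_membered_ring <- function(g) {
  if (g$n_heavy < 5L || nrow(g$bonds) < 5L) return(FALSE)
  ig <- igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
  girth_ok <- tryCatch({
    # minimum cycle through each edge; a 5-ring exists iff some edge lies
    # on a shortest cycle of length 5
    any(vapply(seq_len(nrow(g$bonds)), function(k) {
      i <- g$bonds$i[k]; j <- g$bonds$j[k]
      ig2 <- igraph::delete_edges(ig, igraph::get_edge_ids(ig, c(i, j)))
      d <- igraph::distances(ig2, v = i, to = j)
      is.finite(d) && d == 4
    }, TRUE))
  }, error = function(e) FALSE)
  girth_ok
}
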