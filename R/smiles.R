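# SMILES parsing into the annotated chemical graph.
#
# Daylight-style subset: organic subset atoms (B C N O P S F Cl Br I and
# aromatic b c n o p s), bracket atoms with isotope/charge/H-count,
# branches, ring closures (incl. %nn), bond symbols - = # : / \, and '.'
# separated fragments (largest kept). Stereo annotations are accepted and
# ignored: every descriptor here is a function of the connectivity only.

.ORGANIC <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.DEFAULT_VALENCE <- list(B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5),
                         S = c(2, 4, 6), F = 1, Cl = 1, Br = 1, I = 1,
                         H = 1, Si = 4)

smiles_error <- function(smiles, pos, what) {
  stop(sprintf("SMILES parse error at position %d ('%s'): %s",
               pos, substr(smiles, pos, min(nchar(smiles), pos + 4)), what),
       call. = FALSE)
}

# tokenize + build atom/bond lists in one pass
.parse_smiles_raw <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles))
    stop("`smiles` must be a single character string", call. = FALSE)
  if (!nzchar(trimws(smiles)))
    stop("empty SMILES input", call. = FALSE)
  s <- trimws(smiles)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)

  atoms <- list()   # list of lists: element, aromatic, charge, h_explicit
  bonds <- list()   # list of c(i, j, order)
  prev_stack <- integer(0)  # branch stack
  prev <- NA_integer_
  pending_bond <- NA_character_
  ring_open <- list()       # ring digit -> list(atom, bond)

  add_atom <- function(element, aromatic, charge = 0L, h = NA_integer_) {
    atoms[[length(atoms) + 1L]] <<- list(element = element, aromatic = aromatic,
                                         charge = charge, h_explicit = h)
    length(atoms)
  }
  add_bond <- function(i, j, order) {
    bonds[[length(bonds) + 1L]] <<- list(i = i, j = j, order = order)
  }
  connect <- function(idx, pos) {
    if (!is.na(prev)) {
      ord <- pending_bond
      if (is.na(ord)) {
        ord <- if (atoms[[prev]]$aromatic && atoms[[idx]]$aromatic) "ar" else "1"
      }
      add_bond(prev, idx, ord)
    }
    prev <<- idx
    pending_bond <<- NA_character_
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      close <- NA_integer_
      for (j in seq(i + 1L, n)) if (chars[j] == "]") { close <- j; break }
      if (is.na(close)) smiles_error(s, i, "unterminated bracket atom")
      body <- substr(s, i + 1L, close - 1L)
      m <- regmatches(body, regexec(
        "^([0-9]*)(se|as|[A-Z][a-z]?|[bcnops])(@{0,2}|@TH[12])?(H[0-9]*)?([+-]+[0-9]*|[+-][0-9]*)?(:[0-9]+)?$",
        body))[[1]]
      if (length(m) == 0L || !nzchar(m[3]))
        smiles_error(s, i, "cannot read bracket atom")
      sym <- m[3]
      aromatic <- sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
      element <- if (aromatic) {
        paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, nchar(sym)))
      } else sym
      hspec <- m[5]
      h <- if (is.na(hspec) || !nzchar(hspec)) 0L
           else if (hspec == "H") 1L
           else as.integer(substr(hspec, 2, nchar(hspec)))
      cspec <- m[6]
      charge <- 0L
      if (!is.na(cspec) && nzchar(cspec)) {
        sign <- if (substr(cspec, 1, 1) == "+") 1L else -1L
        digits <- gsub("[+-]", "", cspec)
        charge <- if (nzchar(digits)) sign * as.integer(digits)
                  else sign * nchar(gsub("[^+-]", "", cspec))
      }
      idx <- add_atom(element, aromatic, charge, h)
      connect(idx, i)
      i <- close + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      idx <- add_atom(paste0(ch, chars[i + 1L]), FALSE)
      connect(idx, i)
      i <- i + 2L
    } else if (ch %in% .ORGANIC) {
      idx <- add_atom(ch, FALSE)
      connect(idx, i)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      idx <- add_atom(toupper(ch), TRUE)
      connect(idx, i)
      i <- i + 1L
    } else if (ch %in% c("-", "/", "\\")) {
      pending_bond <- "1"; i <- i + 1L
    } else if (ch == "=") {
      pending_bond <- "2"; i <- i + 1L
    } else if (ch == "#") {
      pending_bond <- "3"; i <- i + 1L
    } else if (ch == ":") {
      pending_bond <- "ar"; i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) smiles_error(s, i, "branch before any atom")
      prev_stack <- c(prev_stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(prev_stack) == 0L) smiles_error(s, i, "unmatched ')'")
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_
      pending_bond <- NA_character_
      i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > n) smiles_error(s, i, "truncated %nn ring closure")
        key <- substr(s, i + 1L, i + 2L)
        i <- i + 3L
      } else {
        key <- ch
        i <- i + 1L
      }
      if (is.na(prev)) smiles_error(s, i, "ring closure before any atom")
      if (!is.null(ring_open[[key]])) {
        open <- ring_open[[key]]
        ring_open[[key]] <- NULL
        ord <- pending_bond
        if (is.na(ord)) ord <- open$bond
        if (is.na(ord)) {
          ord <- if (atoms[[open$atom]]$aromatic && atoms[[prev]]$aromatic) "ar" else "1"
        }
        add_bond(open$atom, prev, ord)
        pending_bond <- NA_character_
      } else {
        ring_open[[key]] <- list(atom = prev, bond = pending_bond)
        pending_bond <- NA_character_
      }
    } else if (ch == "@" || ch == "H") {
      # stereo marker outside bracket, or stray H: ignore / error
      if (ch == "H") smiles_error(s, i, "explicit H outside brackets")
      i <- i + 1L
    } else if (ch == " ") {
      break  # trailing title field
    } else {
      smiles_error(s, i, "unexpected character")
    }
  }
  if (length(prev_stack) > 0L) stop("SMILES parse error: unclosed branch '('", call. = FALSE)
  if (length(ring_open) > 0L)
    stop(sprintf("SMILES parse error: unclosed ring bond(s) %s",
                 paste(names(ring_open), collapse = ", ")), call. = FALSE)
  if (length(atoms) == 0L) stop("empty SMILES input", call. = FALSE)
  list(atoms = atoms, bonds = bonds)
}

# implicit hydrogen count per standard valence
.implicit_h <- function(element, aromatic, charge, h_explicit, bond_sum) {
  if (!is.na(h_explicit)) return(h_explicit)      # bracket atoms: explicit only
  val <- .DEFAULT_VALENCE[[element]]
  if (is.null(val)) return(0L)
  # lowercase aromatic atoms carry one delocalized double bond except the
  # two-connected lone-pair donors (o, s)
  eff <- bond_sum + if (aromatic && !element %in% c("O", "S")) 1L else 0L
  val <- val[val >= eff]
  if (length(val) == 0L) return(0L)
  max(0L, as.integer(val[1] - eff))
}

#' Parse a SMILES string into a molecular graph
#'
#' Builds the hydrogen-suppressed chemical graph of the largest connected
#' fragment: atom records (element, formal charge, implicit hydrogens,
#' aromatic flag), bond list with conventional bond orders (single 1,
#' double 2, triple 3, aromatic 1.5), the heavy-atom adjacency matrix and
#' the topological (shortest-path) distance matrix.
#'
#' @param smiles A single SMILES string. Stereochemistry annotations are
#'   ignored; multi-fragment inputs (salts) are reduced to the largest
#'   fragment.
#' @return A `molgraph` object: list with `atoms` (tibble), `bonds`
#'   (tibble), `n_heavy`, `adjacency`, `topo_dist`, and the input `smiles`.
#' @export
#' @examples
#' g <- parse_smiles("c1ccccc1")   # benzene
#' g$n_heavy
#' max(g$topo_dist)
parse_smiles <- function(smiles) {
  raw <- .parse_smiles_raw(smiles)
  n <- length(raw$atoms)
  el <- vapply(raw$atoms, `[[`, "", "element")
  ar <- vapply(raw$atoms, `[[`, TRUE, "aromatic")
  chg <- vapply(raw$atoms, `[[`, 0L, "charge")
  hx <- vapply(raw$atoms, function(a) as.integer(a$h_explicit), 0L)

  conv <- c("1" = 1, "2" = 2, "3" = 3, "ar" = 1.5)
  bi <- vapply(raw$bonds, `[[`, 0L, "i")
  bj <- vapply(raw$bonds, `[[`, 0L, "j")
  bo <- vapply(raw$bonds, `[[`, "", "order")

  bond_sum <- integer(n)
  if (length(bi)) {
    ordn <- rep(1L, length(bo))
    ordn[bo == "2"] <- 2L
    ordn[bo == "3"] <- 3L
    for (k in seq_along(bi)) {
      bond_sum[bi[k]] <- bond_sum[bi[k]] + ordn[k]
      bond_sum[bj[k]] <- bond_sum[bj[k]] + ordn[k]
    }
  }
  n_h <- vapply(seq_len(n), function(i)
    .implicit_h(el[i], ar[i], chg[i], hx[i], bond_sum[i]), 0L)

  # largest connected fragment
  if (length(bi)) {
    ig <- igraph::graph_from_edgelist(cbind(bi, bj), directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0L, n - igraph::vcount(ig)))
    comp <- igraph::components(ig)
    if (comp$no > 1L) {
      keep <- which(comp$membership == which.max(comp$csize))
      remap <- match(seq_len(n), keep)
      sel <- bi %in% keep & bj %in% keep
      bi <- remap[bi[sel]]; bj <- remap[bj[sel]]; bo <- bo[sel]
      el <- el[keep]; ar <- ar[keep]; chg <- chg[keep]; n_h <- n_h[keep]
      n <- length(keep)
    }
  } else if (n > 1L) {
    el <- el[1]; ar <- ar[1]; chg <- chg[1]; n_h <- n_h[1]; n <- 1L
  }

  new_molgraph(
    atoms = tibble::tibble(element = el, aromatic = ar,
                           charge = chg, n_h = n_h),
    bonds = tibble::tibble(i = bi, j = bj, order = bo,
                           conv_order = unname(conv[bo])),
    smiles = smiles
  )
}

#' Read a SMILES library file
#'
#' One record per line: SMILES, optionally followed by a tab- or
#' whitespace-separated identifier. Lines that fail to parse are reported
#' and dropped with a warning.
#'
#' @param path Path to a `.smi` file.
#' @return A tibble with columns `id`, `smiles`.
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  tibble::tibble(
    id = vapply(seq_along(parts), function(k)
      if (length(parts[[k]]) > 1L) parts[[k]][2] else sprintf("mol%04d", k), ""),
    smiles = vapply(parts, `[[`, "", 1L)
  )
}

#' Write a SMILES library file
#'
#' @param library A data frame with columns `smiles` and `id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_smi <- function(library, path) {
  writeLines(paste(library$smiles, library$id, sep = "\t"), path)
  invisible(path)
}

#' Read molecules from an SDF (V2000) file
#'
#' Delegates the format parsing to ChemmineR and converts each molecule's
#' atom and bond blocks into `molgraph` objects. Requires the ChemmineR
#' package.
#'
#' @param path Path to an SDF file.
#' @return A tibble with columns `id` and `graph` (list of `molgraph`).
#' @export
read_sdf_library <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("reading SDF files requires the ChemmineR package", call. = FALSE)
  sdfs <- ChemmineR::read.SDFset(path)
  graphs <- lapply(seq_along(sdfs), function(k) {
    sdf <- sdfs[[k]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    el <- gsub("_.*$", "", rownames(ab))
    heavy <- which(el != "H")
    remap <- match(seq_along(el), heavy)
    ords <- as.character(bb[, 3])
    keep <- el[bb[, 1]] != "H" & el[bb[, 2]] != "H"
    bi <- remap[bb[keep, 1]]; bj <- remap[bb[keep, 2]]; bo <- ords[keep]
    bo[bo == "4"] <- "ar"
    conv <- c("1" = 1, "2" = 2, "3" = 3, "ar" = 1.5)
    nh <- vapply(heavy, function(a) sum(el[bb[bb[, 1] == a, 2]] == "H") +
                                    sum(el[bb[bb[, 2] == a, 1]] == "H"), 0L)
    new_molgraph(
      atoms = tibble::tibble(element = el[heavy],
                             aromatic = rep(FALSE, length(heavy)),
                             charge = 0L, n_h = as.integer(nh)),
      bonds = tibble::tibble(i = bi, j = bj, order = bo,
                             conv_order = unname(conv[bo])),
      smiles = NA_character_
    )
  })
  tibble::tibble(id = ChemmineR::sdfid(sdfs), graph = graphs)
}
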