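# Synthetic labeled libraries with the statistical structure the QSAR
# stage assumes: actives enriched in five-membered (aza)rings with
# asymmetric, nitrogen-rich decoration; decoys MW- and heteroatom-matched
# but ring/symmetry-shifted. Built from a fragment grammar (vetted
# scaffold templates + substituent pools) so every SMILES is valid by
# construction.

.sub <- function(s) if (nzchar(s)) paste0("(", s, ")") else ""

# scaffold templates: functions of two substituent strings
.scaffolds_five <- list(
  pyrrole = function(s1, s2) {
    n <- if (nzchar(s2)) paste0("n(", s2, ")") else "[nH]"
    sprintf("c1cc%s%sc1", .sub(s1), n)
  },
  pyrazole = function(s1, s2) {
    n <- if (nzchar(s2)) paste0("n(", s2, ")") else "[nH]"
    sprintf("c1cc%s%sn1", .sub(s1), n)
  },
  imidazole = function(s1, s2) {
    if (nzchar(s2)) sprintf("c1nc%scn1%s", .sub(s1), s2)
    else sprintf("c1nc%sc[nH]1", .sub(s1))
  },
  cyclopentane = function(s1, s2) sprintf("C1CC%sC%sC1", .sub(s1), .sub(s2))
)

.scaffolds_six <- list(
  benzene = function(s1, s2) sprintf("c1cc%scc%sc1", .sub(s1), .sub(s2)),
  pyridine = function(s1, s2) sprintf("c1cc%snc%sc1", .sub(s1), .sub(s2)),
  pyrimidine = function(s1, s2) sprintf("c1nc%snc%sc1", .sub(s1), .sub(s2)),
  cyclohexane = function(s1, s2) sprintf("C1CC%sCC%sC1", .sub(s1), .sub(s2))
)

# decoration pools: actives carry polar/asymmetric, kinase-hinge-flavored
# groups; decoys carry simple lipophilic groups applied symmetrically
.active_subs <- c("CC#N", "C(N)=O", "NC(C)=O", "N(C)C", "CNC(C)=O",
                  "CC(N)=O", "c1ccncc1", "Nc1ncncc1", "CN", "CO")
.active_core <- "c1ncnc2[nH]ccc12"   # fused bicyclic aminopyrimidine motif
.decoy_subs <- c("C", "CC", "CCC", "C(C)C", "OC", "OCC", "O", "N",
                 "NC", "N(C)C", "C(=O)OC", "C#N", "CC#N", "C(N)=O",
                 "Cl", "F", "Br")

.compose <- function(five, s1, s2, rng_pick) {
  pool <- if (five) .scaffolds_five else .scaffolds_six
  pool[[rng_pick(length(pool))]](s1, s2)
}

#' Generate a seeded synthetic screening library
#'
#' Emulates the training design of the discriminant models: `n_per_class`
#' actives carry a five-membered ring scaffold with probability
#' `p_five_active` (default 0.75, echoing the reported 31/42 prevalence
#' among inhibitors) and asymmetric, nitrogen-rich decoration, optionally
#' fused to a bicyclic aminopyrimidine core; `n_per_class` decoys are
#' assembled with five-ring probability `p_five_decoy` (default 0.30,
#' echoing 18/59 among decoys), symmetric lipophilic decoration, and are
#' greedily matched to the actives on molecular weight and C/N/O/halogen
#' counts (best of `match_tries` candidates each).
#'
#' @param n_per_class Compounds per class (> 0).
#' @param seed Integer seed; same seed and settings give an identical
#'   library.
#' @param p_five_active,p_five_decoy Five-membered-ring probabilities.
#' @param match_tries Decoy candidates drawn per active for property
#'   matching.
#' @return A tibble `id`, `smiles`, `label` (`"active"`/`"inactive"`);
#'   all SMILES are parseable by construction (asserted).
#' @export
#' @examples
#' lib <- generate_library(10, seed = 42)
#' table(lib$label)
generate_library <- function(n_per_class = 100, seed = 42,
                             p_five_active = 0.75, p_five_decoy = 0.30,
                             match_tries = 25) {
  if (n_per_class < 1) stop("n_per_class must be >= 1", call. = FALSE)
  set.seed(seed)
  pick <- function(n) sample.int(n, 1L)

  make_active <- function() {
    five <- stats::runif(1) < p_five_active
    subs <- sample(.active_subs, 2L)
    # asymmetric decoration; half the five-ring actives carry the fused
    # core (the core holds a five-ring itself, so attaching it to six-ring
    # scaffolds would inflate the designed ring prevalence)
    if (five && stats::runif(1) < 0.5) subs[2] <- .active_core
    if (stats::runif(1) < 0.25) subs[1] <- ""
    .compose(five, subs[1], subs[2], pick)
  }
  # ring parity is decided per decoy (not per matching candidate) so the
  # property matching cannot bias the designed five-ring rate
  make_decoy <- function(five) {
    s <- sample(.decoy_subs, 1L)
    s2 <- if (stats::runif(1) < 0.8) s else sample(.decoy_subs, 1L)
    .compose(five, s, s2, pick)
  }

  props <- function(smiles) {
    g <- parse_smiles(smiles)
    c(mw = molgraph_mw(g),
      C = sum(g$atoms$element == "C"),
      N = sum(g$atoms$element == "N"),
      O = sum(g$atoms$element == "O"),
      X = sum(g$atoms$element %in% c("F", "Cl", "Br", "I")))
  }

  actives <- replicate(n_per_class, make_active())
  act_props <- t(vapply(actives, props, numeric(5)))

  decoys <- character(n_per_class)
  decoy_five <- stats::runif(n_per_class) < p_five_decoy
  for (k in seq_len(n_per_class)) {
    cands <- replicate(match_tries, make_decoy(decoy_five[k]))
    cp <- t(vapply(cands, props, numeric(5)))
    cost <- abs(cp[, "mw"] - act_props[k, "mw"]) / 5 +
      rowSums(abs(cp[, c("C", "N", "O", "X"), drop = FALSE] -
                  matrix(act_props[k, c("C", "N", "O", "X")],
                         match_tries, 4, byrow = TRUE)))
    decoys[k] <- cands[which.min(cost)]
  }

  lib <- tibble::tibble(
    id = c(sprintf("ACT%04d", seq_len(n_per_class)),
           sprintf("DEC%04d", seq_len(n_per_class))),
    smiles = c(actives, decoys),
    label = rep(c("active", "inactive"), each = n_per_class)
  )
  ok <- vapply(lib$smiles, function(s)
    !inherits(tryCatch(parse_smiles(s), error = identity), "error"), TRUE)
  if (!all(ok))
    stop("generator produced unparseable SMILES: ",
         paste(lib$smiles[!ok], collapse = "; "), call. = FALSE)
  lib
}

.FIXTURES <- c(
  Tofacitinib = "CC1CCN(CC1N(C)c1ncnc2[nH]ccc12)C(=O)CC#N",
  Ruxolitinib = "C1CCC(C1)C(CC#N)n1cc(cn1)c1ncnc2[nH]ccc12",
  Baricitinib = "CCS(=O)(=O)N1CC(CC#N)(C1)n1cc(cn1)c1ncnc2[nH]ccc12",
  Filgotinib = "O=C(Nc1nc2ccc(cc2n1C1CC1)-c1ccc(cc1)CN1CCS(=O)(=O)CC1)C1CC1",
  AG490 = "N#CC(=Cc1ccc(O)c(O)c1)C(=O)NCc1ccccc1"
)

#' Curated reference-inhibitor SMILES
#'
#' Versioned, immutable SMILES for reference JAK inhibitors used in tests
#' and calibration (Tofacitinib is the information-index anchor).
#'
#' @param name Optional compound name; omitted returns the whole registry.
#' @return A tibble `name`, `smiles`, or a single SMILES string when
#'   `name` is given. Unknown names raise an error.
#' @export
#' @examples
#' fixture_registry("Tofacitinib")
fixture_registry <- function(name = NULL) {
  if (is.null(name))
    return(tibble::tibble(name = names(.FIXTURES),
                          smiles = unname(.FIXTURES)))
  if (!name %in% names(.FIXTURES))
    stop(sprintf("unknown fixture compound '%s'; available: %s", name,
                 paste(names(.FIXTURES), collapse = ", ")), call. = FALSE)
  unname(.FIXTURES[[name]])
}
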