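#' Element property table
#'
#' Per-element physical properties used as atomic weights by the 2D
#' autocorrelation and surface-partition descriptors: standard atomic mass
#' (u), Sanderson electronegativity (dimensionless), first ionization
#' potential (eV), van der Waals surface area (A^2, sphere area from the
#' Bondi radius), and an atomic log P contribution (Crippen-style,
#' element-level approximation; aromatic carbon and nitrogen get their own
#' entries via [atom_weights()]).
#'
#' All values come from one fixed reference table so descriptor values are
#' reproducible; carbon-scaled weights (w / w_C) are the convention used by
#' the autocorrelation descriptors, so carbon is exactly 1 for every
#' property.
#'
#' @return A tibble with one row per element symbol.
#' @export
#' @examples
#' element_properties()
element_properties <- function() {
  r <- c(H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
         Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)
  tibble::tibble(
    symbol = names(r),
    mass = c(1.008, 10.811, 12.011, 14.007, 15.999, 18.998,
             28.086, 30.974, 32.065, 35.453, 79.904, 126.904),
    sanderson_en = c(2.592, 2.275, 2.746, 3.194, 3.654, 4.000,
                     2.138, 2.515, 2.957, 3.475, 3.219, 2.778),
    ionization = c(13.598, 8.298, 11.260, 14.534, 13.618, 17.423,
                   8.152, 10.487, 10.360, 12.968, 11.814, 10.451),
    vdw_surface = 4 * pi * unname(r)^2,
    logp_atomic = c(0.123, -0.032, 0.144, -0.600, -0.289, 0.426,
                    0.300, 0.861, 0.648, 0.648, 0.860, 0.887)
  )
}

# aromatic-environment overrides for the atomic log P contribution
.logp_aromatic <- c(C = 0.158, N = -0.324, O = -0.289, S = 0.648)

#' Bond dipole moment lookup
#'
#' Typical bond dipole moments (Debye) keyed by unordered element pair and
#' bond order class, used to weight the diagonal of the augmented edge
#' adjacency matrix. Homonuclear bonds have zero dipole; pairs absent from
#' the table fall back to the absolute Sanderson electronegativity
#' difference, a documented proxy that preserves the ordering of bond
#' polarities.
#'
#' @return A tibble with columns `a`, `b` (element symbols, `a <= b`
#'   lexicographically), `order` (`"1"`, `"2"`, `"3"`, `"ar"`), `dipole`.
#' @export
bond_dipole_table <- function() {
  tibble::tribble(
    ~a,  ~b,  ~order, ~dipole,
    "C", "H", "1", 0.40,
    "C", "N", "1", 0.22,
    "C", "N", "2", 1.40,
    "C", "N", "3", 3.50,
    "C", "N", "ar", 0.45,
    "C", "O", "1", 0.74,
    "C", "O", "2", 2.30,
    "C", "O", "ar", 0.90,
    "C", "F", "1", 1.41,
    "C", "S", "1", 0.90,
    "C", "S", "2", 1.80,
    "C", "S", "ar", 0.60,
    "C", "Cl", "1", 1.46,
    "C", "Br", "1", 1.38,
    "C", "I", "1", 1.19,
    "H", "N", "1", 1.31,
    "H", "O", "1", 1.51,
    "H", "S", "1", 0.68,
    "N", "N", "2", 0.00,
    "N", "O", "1", 0.30,
    "N", "O", "2", 2.00,
    "N", "N", "ar", 0.00,
    "N", "O", "ar", 0.80,
    "O", "S", "2", 2.80,
    "O", "P", "2", 2.70,
    "N", "S", "1", 0.80
  )
}

#' P_VSA log P bin edges
#'
#' Interval edges partitioning the atomic log P contribution axis into the
#' ten bins of the surface-partition descriptor family (SlogP_VSA-style
#' edge set). Bin k collects atoms with contribution in
#' `(edges[k], edges[k+1]]`; the descriptor value is the summed van der
#' Waals surface area of those atoms. The edge set lives in one place so it
#' can be recalibrated without touching descriptor code.
#'
#' @return Numeric vector of 11 edges (first `-Inf`, last `Inf`).
#' @export
pvsa_logp_bins <- function() {
  c(-Inf, -0.4, -0.2, 0, 0.1, 0.15, 0.2, 0.25, 0.3, 0.4, Inf)
}
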