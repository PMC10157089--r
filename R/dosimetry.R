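# Bead-level stoichiometry: emitters per bead, surface-group parking area,
# geometric protein capacity, coupling efficiency, molar detection limits,
# and the biotin-endpoint back-calculation.

# Avogadro constant, mol^-1
.N_A <- 6.02214e23

# IUPAC standard atomic weights, 5 significant figures. Covers the elements
# of the label complexes and common bioconjugation reagents.
.atomic_masses <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
  K = 39.098, Ca = 40.078, Fe = 55.845, Cu = 63.546, Zn = 65.38,
  Br = 79.904, I = 126.90, Eu = 151.96, Gd = 157.25, Tb = 158.93
)

#' Molar mass from an elemental composition
#'
#' Sums embedded IUPAC standard atomic masses (5 significant figures) over an
#' elemental composition given either as a named vector/list of counts or as
#' a condensed formula string such as `"EuC72H114F9O8P2S3"`.
#'
#' @param composition Named numeric vector or list (element -> count), or a
#'   single formula string.
#' @return Molar mass in g/mol.
#' @export
#' @examples
#' molar_mass(c(H = 2, O = 1))            # 18.015
#' molar_mass("EuC72H114F9O8P2S3")        # Eu(ttfa)3(TOPO)2, ~1588.8
molar_mass <- function(composition) {
  if (is.character(composition) && length(composition) == 1L) {
    composition <- parse_formula(composition)
  }
  composition <- unlist(composition)
  elems <- names(composition)
  if (is.null(elems) || any(!nzchar(elems))) {
    stop("composition must be named by element symbol", call. = FALSE)
  }
  unknown <- setdiff(elems, names(.atomic_masses))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown element(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (any(composition < 0)) stop("element counts must be >= 0", call. = FALSE)
  sum(.atomic_masses[elems] * composition)
}

#' Parse a condensed elemental formula
#'
#' @param formula String of element symbols with optional counts, e.g.
#'   `"C8H11NO2"`. No parentheses or hydration dots.
#' @return Named numeric vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  tokens <- regmatches(formula,
                       gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1L]]
  if (length(tokens) == 0L || nchar(paste(tokens, collapse = "")) !=
      nchar(formula)) {
    stop(sprintf("cannot parse formula '%s'", formula), call. = FALSE)
  }
  elems <- sub("[0-9]*$", "", tokens)
  counts <- as.numeric(sub("^[A-Z][a-z]?", "", tokens))
  counts[is.na(counts)] <- 1
  totals <- tapply(counts, elems, sum)
  stats::setNames(as.numeric(totals[unique(elems)]), unique(elems))
}

#' Number of emitter complexes in a single bead
#'
#' For a polymer sphere of diameter `d` loaded with a mass fraction `w` of a
#' complex of molar mass `M`:
#' `N = w * rho * (pi/6) * d^3 * N_A / M`.
#' With the default polystyrene density, a 100 nm bead at 1% wt of
#' Eu(ttfa)3(TOPO)2 holds about 2000 complexes -- the amplification factor
#' that makes loaded beads so much brighter than molecular labels.
#'
#' @param diameter_nm Bead diameter in nm.
#' @param mass_fraction Complex loading as a mass fraction in `[0, 1)`.
#' @param molar_mass_g_mol Molar mass of the complex in g/mol.
#' @param density_g_cm3 Polymer density in g/cm^3; default 1.05
#'   (polystyrene handbook value).
#' @return Complexes per bead (real-valued; round at report time).
#' @export
#' @examples
#' complexes_per_bead(100, 0.01, molar_mass("EuC72H114F9O8P2S3"))
complexes_per_bead <- function(diameter_nm, mass_fraction, molar_mass_g_mol,
                               density_g_cm3 = 1.05) {
  stopifnot(diameter_nm > 0, density_g_cm3 > 0, molar_mass_g_mol > 0,
            mass_fraction >= 0, mass_fraction < 1)
  volume_cm3 <- (pi / 6) * (diameter_nm * 1e-7)^3
  mass_fraction * density_g_cm3 * volume_cm3 * .N_A / molar_mass_g_mol
}

#' Mass of a single bead
#'
#' @inheritParams complexes_per_bead
#' @return Bead mass in grams.
#' @export
bead_mass <- function(diameter_nm, density_g_cm3 = 1.05) {
  stopifnot(diameter_nm > 0, density_g_cm3 > 0)
  density_g_cm3 * (pi / 6) * (diameter_nm * 1e-7)^3
}

#' Bead count corresponding to a sample mass
#'
#' Converts a total bead mass (e.g. from a weight-percent dispersion in a
#' known volume) into a bead count. Useful for cross-checking stated
#' beads-per-well figures against weight fractions.
#'
#' @param mass_g Total bead mass in grams.
#' @inheritParams complexes_per_bead
#' @return Number of beads (real-valued).
#' @export
beads_from_mass <- function(mass_g, diameter_nm, density_g_cm3 = 1.05) {
  stopifnot(mass_g >= 0)
  mass_g / bead_mass(diameter_nm, density_g_cm3)
}

#' Parking area of a surface functional group
#'
#' The bead surface area available to each surface group:
#' `pi * d^2 / n_groups`, in square Angstroms. Commercial carboxylated
#' beads typically run 22-32 A^2 per -COOH.
#'
#' @param diameter_nm Bead diameter in nm.
#' @param n_groups Number of functional groups per bead.
#' @return Parking area in A^2 per group.
#' @export
#' @examples
#' parking_area(200, 5e5)   # ~25 A^2
parking_area <- function(diameter_nm, n_groups) {
  stopifnot(diameter_nm > 0)
  if (length(n_groups) != 1L || !is.finite(n_groups) || n_groups <= 0) {
    stop("n_groups must be a positive count", call. = FALSE)
  }
  pi * (diameter_nm * 10)^2 / n_groups
}

#' Geometric maximum of surface-bound proteins per bead
#'
#' Divides the sphere surface by the circular footprint of a folded protein:
#' `pi * d_bead^2 / (pi * (d_protein/2)^2) = (2 * d_bead / d_protein)^2`.
#' No packing factor is applied; the plain footprint division is the
#' convention for these order-of-magnitude capacity estimates (a 100 nm bead
#' accommodates at most 1600 proteins of 5 nm diameter).
#'
#' @param bead_diameter_nm Bead diameter, nm.
#' @param protein_diameter_nm Folded (or hydrodynamic) protein diameter, nm.
#' @return Maximum protein count per bead (real-valued).
#' @export
max_surface_proteins <- function(bead_diameter_nm, protein_diameter_nm) {
  stopifnot(bead_diameter_nm > 0, protein_diameter_nm > 0)
  (2 * bead_diameter_nm / protein_diameter_nm)^2
}

#' Molar detection limit from a bead count
#'
#' Converts the smallest detectable number of beads into moles of surface
#' molecules: `n_beads * molecules_per_bead / N_A`. With ~1000 beads per
#' well and 1600 proteins per bead this is ~3e-18 mol.
#'
#' @param n_beads Number of beads at the detection limit.
#' @param molecules_per_bead Reporter or capture molecules per bead.
#' @return Detection limit in mol.
#' @export
detection_limit_mol <- function(n_beads, molecules_per_bead) {
  stopifnot(n_beads >= 0, molecules_per_bead >= 0)
  n_beads * molecules_per_bead / .N_A
}

#' Protein coupling efficiency
#'
#' Fraction of offered protein molecules that end up bead-bound.
#'
#' @param coupled_per_bead Molecules found on the bead surface.
#' @param offered_per_bead Molecules offered per bead in the coupling
#'   reaction; must be > 0.
#' @return Coupling efficiency as a fraction.
#' @export
coupling_efficiency <- function(coupled_per_bead, offered_per_bead) {
  stopifnot(coupled_per_bead >= 0)
  if (length(offered_per_bead) != 1L || !is.finite(offered_per_bead) ||
      offered_per_bead <= 0) {
    stop("offered_per_bead must be positive", call. = FALSE)
  }
  coupled_per_bead / offered_per_bead
}

#' Surface proteins from a biotin-blocking endpoint
#'
#' Avidin and Neutravidin carry 4 biotin binding sites; the biotin dose that
#' saturates all bead-surface protein (the titration endpoint) therefore
#' equals 4x the protein count.
#'
#' @param biotin_per_bead Biotin molecules per bead at the endpoint.
#' @param sites_per_protein Biotin binding sites per protein; default 4
#'   (tetrameric (Neutr)avidin).
#' @return Proteins per bead.
#' @export
#' @examples
#' proteins_from_biotin_endpoint(4000)  # 1000 Neutravidin
proteins_from_biotin_endpoint <- function(biotin_per_bead,
                                          sites_per_protein = 4L) {
  stopifnot(biotin_per_bead >= 0)
  if (length(sites_per_protein) != 1L || !is.finite(sites_per_protein) ||
      sites_per_protein < 1) {
    stop("sites_per_protein must be >= 1", call. = FALSE)
  }
  biotin_per_bead / sites_per_protein
}
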