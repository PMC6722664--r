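#' Default van der Waals radii (Angstrom), by element
#'
#' Bondi-style element radii used to build the hard-core distance
#' \eqn{\sigma = r_i + r_j} of every pair potential. User-overridable in
#' [energy_parameters()] or [assign_radii()].
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
default_vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
}

#' Default atomic solvation parameters (cal A^-2 mol^-1), by atom type
#'
#' Atomic solvation parameters s_t for the five hydropathy atom types:
#' aliphatic/aromatic carbon, neutral nitrogen/oxygen, positively charged
#' nitrogen, carboxylate oxygen and sulfur. Positive s_t marks a
#' hydrophobic type, negative a hydrophilic one.
#'
#' @return Named numeric vector keyed by type ("C", "N/O", "N+", "O-", "S").
#' @export
default_solvation_parameters <- function() {
  c("C" = 18, "N/O" = -7, "N+" = -34, "O-" = -20, "S" = 18)
}

#' Default per-type reference solvent-accessible surface areas (A^2)
#'
#' Reference exposed areas SASA_t entering the per-atom hydropathy value
#' HP_t = -s_t * SASA_t / n_t. The values are chosen at the scale of
#' side-chain atomic exposures in extended peptides and calibrated so that
#' every normalized |HP_t| lies in the 0.1-0.4 h-bond-unit band the model
#' requires; they are plain configuration and can be overridden.
#'
#' @return Named numeric vector keyed like [default_solvation_parameters()].
#' @export
default_sasa_table <- function() {
  c("C" = 36, "N/O" = 90, "N+" = 20, "O-" = 33, "S" = 40)
}

#' Energy-model parameter set
#'
#' Bundles every constant of the square-well triad cost function. Energies
#' are expressed in h-bond units: the depth of one hydrogen bond is 1 (set
#' by `e_hb = -1`) and is calibrated to `e_hb_kcal = 3` kcal/mol. The
#' electrostatic first-well magnitude is the median salt-bridge free-energy
#' gain (1.2 kcal/mol) divided by the h-bond calibration, and the outer
#' well is 0.3 times the first.
#'
#' @param e_hb H-bond well depth in h-bond units (default -1).
#' @param hb_cutoff H-bond donor-acceptor distance cutoff in Angstrom
#'   (default 3.2).
#' @param e_hb_kcal Physical h-bond strength, kcal/mol (default 3.0); the
#'   normalization constant of the h-bond unit.
#' @param salt_bridge_kcal Median free-energy gain of a surface salt
#'   bridge, kcal/mol (default 1.2).
#' @param e_el1 First electrostatic well magnitude, h-bond units; default
#'   `salt_bridge_kcal / e_hb_kcal` = 0.4.
#' @param e_el2 Second electrostatic well magnitude; default `0.3 * e_el1`.
#' @param el_well1_scale Outer edge of the first electrostatic well as a
#'   multiple of sigma (default 1.4).
#' @param el_cutoff_scale Electrostatic cutoff as a multiple of sigma
#'   (default 2.3).
#' @param hp_cutoff_scale Hydropathy cutoff as a multiple of the summed
#'   vdW radii (default 1.6, i.e. 160%).
#' @param solvation_table Named vector of atomic solvation parameters s_t
#'   in cal A^-2 mol^-1 (see [default_solvation_parameters()]).
#' @param sasa_table Named vector of reference SASA_t in A^2 (see
#'   [default_sasa_table()]); must share names with `solvation_table`.
#' @param n_t Neighbor-count estimate dividing HP_t (default 2).
#' @param clash_weight Penalty per intermolecular hard-core overlap added
#'   to the Monte Carlo objective, h-bond units (default 1.0).
#' @param radii_table Named vector of per-element vdW radii in Angstrom.
#' @param mixed_hydropathy If `TRUE`, hydrophobic-hydrophilic pairs also
#'   contribute their signed sum; default `FALSE` (like-class pairs only).
#'
#' @return An object of class `sw_params`: a validated list of the above.
#' @examples
#' p <- energy_parameters()
#' p$e_el1            # 0.4
#' hydropathy_parameter("C", p)
#' @export
energy_parameters <- function(e_hb = -1,
                              hb_cutoff = 3.2,
                              e_hb_kcal = 3.0,
                              salt_bridge_kcal = 1.2,
                              e_el1 = salt_bridge_kcal / e_hb_kcal,
                              e_el2 = 0.3 * e_el1,
                              el_well1_scale = 1.4,
                              el_cutoff_scale = 2.3,
                              hp_cutoff_scale = 1.6,
                              solvation_table = default_solvation_parameters(),
                              sasa_table = default_sasa_table(),
                              n_t = 2,
                              clash_weight = 1.0,
                              radii_table = default_vdw_radii(),
                              mixed_hydropathy = FALSE) {
  stopifnot(hb_cutoff > 0, e_hb_kcal > 0, n_t > 0,
            el_cutoff_scale > el_well1_scale, el_well1_scale > 1,
            clash_weight >= 0)
  if (!all(names(solvation_table) %in% names(sasa_table)))
    stop("sasa_table must cover every atom type in solvation_table")
  p <- list(e_hb = e_hb, hb_cutoff = hb_cutoff, e_hb_kcal = e_hb_kcal,
            salt_bridge_kcal = salt_bridge_kcal,
            e_el1 = e_el1, e_el2 = e_el2,
            el_well1_scale = el_well1_scale,
            el_cutoff_scale = el_cutoff_scale,
            hp_cutoff_scale = hp_cutoff_scale,
            solvation_table = solvation_table,
            sasa_table = sasa_table,
            n_t = n_t, clash_weight = clash_weight,
            radii_table = radii_table,
            mixed_hydropathy = isTRUE(mixed_hydropathy))
  class(p) <- "sw_params"
  p
}

#' @export
print.sw_params <- function(x, ...) {
  cat("Square-well energy parameters (h-bond units)\n")
  cat(sprintf("  h-bond:        depth %g, cutoff %g A (= %g kcal/mol)\n",
              x$e_hb, x$hb_cutoff, x$e_hb_kcal))
  cat(sprintf("  electrostatic: |E1| %g (sigma..%gs), |E2| %g (..%gs)\n",
              x$e_el1, x$el_well1_scale, x$e_el2, x$el_cutoff_scale))
  cat(sprintf("  hydropathy:    cutoff %g x (r_i + r_j), n_t = %g\n",
              x$hp_cutoff_scale, x$n_t))
  hp <- vapply(names(x$solvation_table), hydropathy_parameter,
               numeric(1), params = x)
  cat("  HP_t:          ",
      paste(sprintf("%s %+0.3f", names(hp), hp), collapse = ", "), "\n")
  cat(sprintf("  clash weight:  %g per overlapping pair\n", x$clash_weight))
  invisible(x)
}

#' Default pKa values of titratable groups
#'
#' Standard solution pKa values used when a residue-specific value is not
#' supplied. "NTR"/"CTR" are the chain termini.
#'
#' @return Named numeric vector.
#' @export
default_pka_table <- function() {
  c(ASP = 3.65, GLU = 4.25, HIS = 6.0, CYS = 8.3,
    LYS = 10.5, ARG = 12.5, NTR = 8.0, CTR = 3.6)
}

#' pH-dependent protonation model
#'
#' Couples a run pH with per-residue pKa values and acid/base rules. Bases
#' (His, Lys, Arg, N-terminus) are positively charged when pH < pKa; acids
#' (Asp, Glu, Cys, C-terminus) negatively when pH > pKa.
#'
#' @param pH Run pH, in `[0, 14]`.
#' @param pka Optional named numeric vector of residue-specific pKa values
#'   keyed by `"<chain>:<resno>"` (e.g. `"A:51"`); falls back to
#'   `defaults` per residue type.
#' @param defaults Named vector of per-type default pKa values.
#' @return An object of class `sw_protonation`.
#' @examples
#' protonation_model(5.2, pka = c("A:51" = 6.5))
#' @export
protonation_model <- function(pH, pka = NULL,
                              defaults = default_pka_table()) {
  stopifnot(is.numeric(pH), length(pH) == 1, pH >= 0, pH <= 14)
  if (!is.null(pka) && (is.null(names(pka)) || any(!nzchar(names(pka)))))
    stop("pka must be a named vector keyed by '<chain>:<resno>'")
  m <- list(pH = pH, pka = pka, defaults = defaults,
            rules = c(HIS = "base", LYS = "base", ARG = "base",
                      NTR = "base", ASP = "acid", GLU = "acid",
                      CYS = "acid", CTR = "acid"))
  class(m) <- "sw_protonation"
  m
}

#' @export
print.sw_protonation <- function(x, ...) {
  cat(sprintf("Protonation model at pH %g (%d residue-specific pKa value%s)\n",
              x$pH, length(x$pka), if (length(x$pka) == 1) "" else "s"))
  invisible(x)
}

# Atoms carrying the formal charge of each ionized group.  Restricting
# nonzero charge signs to these (rather than to every partial charge)
# keeps the double-well electrostatics between formally charged moieties.
charge_template <- list(
  ARG = c("NE", "NH1", "NH2"),
  LYS = c("NZ"),
  HIS = c("ND1", "NE2"),
  ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2"),
  CYS = c("SG"),
  NTR = c("N"),
  CTR = c("O", "OXT", "OT1", "OT2")
)

# Nitrogen atoms treated as h-bond acceptors (O and S always accept).
n_acceptor_template <- list(
  HIS = c("ND1", "NE2")
)

backbone_atom_names <- c("N", "CA", "C", "O", "OXT", "OT1", "OT2",
                         "H", "HN", "H1", "H2", "H3",
                         "HA", "HA1", "HA2", "HA3")

protein_residues <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                      "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                      "PRO", "SER", "THR", "TRP", "TYR", "VAL")
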