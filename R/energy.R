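#' Square-well hydrogen-bond potential
#'
#' Piecewise-constant donor-acceptor potential: the attractive well spans
#' the hard-core distance sigma up to the cutoff (default 3.2 Angstrom)
#' at depth `e_hb` (default -1 h-bond unit); zero beyond the cutoff. Below
#' sigma the pair is a hard-core clash (`NA` returned here; the pair
#' dispatcher counts it and applies the clash penalty to the objective).
#' If sigma exceeds the cutoff the attractive well is empty.
#'
#' @param r Donor-acceptor distance(s), Angstrom.
#' @param sigma Hard-core distance, the sum of the pair's vdW radii.
#' @param params [energy_parameters()].
#' @return Energy in h-bond units; `NA` marks the clash region.
#' @examples
#' p <- energy_parameters()
#' hbond_energy(3.0, 2.75, p)  # -1
#' hbond_energy(3.2, 2.75, p)  # 0
#' @export
hbond_energy <- function(r, sigma, params = energy_parameters()) {
  stopifnot(all(r >= 0))
  ifelse(r < sigma, NA_real_,
         ifelse(r < params$hb_cutoff, params$e_hb, 0))
}

#' Double square-well electrostatic potential
#'
#' Two flat wells between formally charged atoms: magnitude `e_el1` for
#' sigma < r < 1.4 sigma, `e_el2` for 1.4 sigma <= r < 2.3 sigma, zero
#' beyond. The sign follows the charge product: repulsive (positive) for
#' like charges, attractive for opposite charges. `r <= sigma` is the
#' hard-core region (`NA`; handled as a clash by the dispatcher).
#'
#' @param r Distance(s), Angstrom.
#' @param sigma Hard-core distance, Angstrom.
#' @param sign_i,sign_j Formal charge signs, each -1 or +1.
#' @param params [energy_parameters()].
#' @return Energy in h-bond units.
#' @examples
#' p <- energy_parameters()
#' electrostatic_energy(3.5, 3.0, +1, +1, p)  # +0.4
#' electrostatic_energy(5.0, 3.0, +1, -1, p)  # -0.12
#' @export
electrostatic_energy <- function(r, sigma, sign_i, sign_j,
                                 params = energy_parameters()) {
  if (any(sign_i == 0) || any(sign_j == 0))
    stop("electrostatic_energy requires nonzero charge signs")
  s <- sign(sign_i) * sign(sign_j)
  ifelse(r <= sigma, NA_real_,
         ifelse(r < params$el_well1_scale * sigma, s * params$e_el1,
                ifelse(r < params$el_cutoff_scale * sigma,
                       s * params$e_el2, 0)))
}

#' Normalized per-atom hydropathy value HP_t
#'
#' HP_t = -s_t * SASA_t / n_t with s_t in cal A^-2 mol^-1 and SASA_t in
#' A^2, converted to kcal/mol and normalized by the h-bond calibration
#' energy. Hydrophobic types (positive s_t) get negative HP_t, so summed
#' hydrophobic-hydrophobic contacts are attractive.
#'
#' @param atom_type One of the packaged types: "C", "N/O", "N+", "O-", "S".
#' @param params [energy_parameters()].
#' @return HP_t in h-bond units.
#' @examples
#' hydropathy_parameter("C", energy_parameters())  # -0.108
#' @export
hydropathy_parameter <- function(atom_type, params = energy_parameters()) {
  if (!atom_type %in% names(params$solvation_table))
    stop("unknown hydropathy atom type: ", atom_type)
  s <- params$solvation_table[[atom_type]]
  a <- params$sasa_table[[atom_type]]
  (-s * a / params$n_t) / 1000 / params$e_hb_kcal
}

#' Hydropathy pair potential
#'
#' When two side-chain heavy atoms of the same hydropathy class are closer
#' than `hp_cutoff_scale` (160%) times the sum of their vdW radii, the
#' pair contributes HP_i + HP_j; zero beyond the cutoff. By default
#' mixed hydrophobic-hydrophilic pairs do not contribute.
#'
#' @param atom_i,atom_j Single-row atom records (data frames or lists with
#'   `vdw_radius`, `hp_class`, `hp_value`).
#' @param r Distance, Angstrom.
#' @param params [energy_parameters()].
#' @return Energy in h-bond units.
#' @export
hydropathy_energy <- function(atom_i, atom_j, r,
                              params = energy_parameters()) {
  if (atom_i$hp_class == "none" || atom_j$hp_class == "none")
    stop("hydropathy_energy applies to classified side-chain atoms only")
  if (is.null(atom_i$hp_value) || is.null(atom_j$hp_value))
    stop("atoms lack hp_value")
  if (!params$mixed_hydropathy && atom_i$hp_class != atom_j$hp_class)
    return(0)
  cutoff <- params$hp_cutoff_scale * (atom_i$vdw_radius + atom_j$vdw_radius)
  if (r < cutoff) atom_i$hp_value + atom_j$hp_value else 0
}

# Pack the heavy atoms of a typed unit for the C++ evaluator.
pack_unit <- function(unit) {
  at <- unit$atoms[!unit$atoms$is_hydrogen, , drop = FALSE]
  cls <- match(at$hp_class, c("hydrophobic", "hydrophilic"))
  cls[is.na(cls)] <- 0L
  list(xyz = as.matrix(at[, c("x", "y", "z")]),
       vdw = as.numeric(at$vdw_radius),
       hp = as.numeric(at$hp_value),
       donor = as.integer(at$donor),
       acceptor = as.integer(at$acceptor),
       charge = as.integer(at$charge_sign),
       hpclass = as.integer(cls),
       labels = residue_ids(at),
       resid = at$resid, name = at$name)
}

check_typed <- function(unit, who = "unit") {
  if (any(is.na(unit$atoms$vdw_radius) & !unit$atoms$is_hydrogen))
    stop(who, " has unassigned vdW radii; run assign_radii()")
}

#' Total square-well interface energy between two rigid units
#'
#' Sums the hydrogen-bond, electrostatic and hydropathy square-well
#' potentials over every intermolecular heavy-atom pair; a pair
#' contributes through every potential for which both atoms qualify.
#' Counts contacts (pairs inside at least one attractive/repulsive well)
#' and clashes (pairs closer than their hard-core distance). Evaluation
#' uses a cell list over the fixed unit; `naive = TRUE` forces the
#' all-pairs double loop (same C++ kernel, no spatial acceleration).
#'
#' @param unit_a,unit_b Typed `sw_unit`s (radii, protonation and
#'   classification assigned with the same parameters).
#' @param params [energy_parameters()].
#' @param pairs If `TRUE`, return the per-pair interaction table.
#' @param naive Disable the cell-list acceleration.
#' @return List with `U` (h-bond units), `n_contacts`, `n_clashes`, and —
#'   when `pairs = TRUE` — a data frame of pair interactions with residue
#'   labels (`res_a`, `res_b`), kind, distance, sigma and energy.
#' @export
interface_energy <- function(unit_a, unit_b, params = energy_parameters(),
                             pairs = FALSE, naive = FALSE) {
  check_typed(unit_a, "unit_a"); check_typed(unit_b, "unit_b")
  pa <- pack_unit(unit_a); pb <- pack_unit(unit_b)
  res <- cpp_interface_energy(pa, pb, params, isTRUE(pairs), isTRUE(naive))
  if (isTRUE(pairs)) {
    pr <- res$pairs
    kinds <- c("hbond", "electrostatic", "hydropathy", "clash")
    res$pairs <- data.frame(
      res_a = pa$labels[pr$i + 1L], res_b = pb$labels[pr$j + 1L],
      atom_a = pa$name[pr$i + 1L], atom_b = pb$name[pr$j + 1L],
      kind = kinds[pr$kind], r = pr$r, sigma = pr$sigma,
      energy = pr$energy, stringsAsFactors = FALSE)
  }
  res
}
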