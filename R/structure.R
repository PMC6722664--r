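#' Build a structure unit from an atom table
#'
#' Low-level constructor for the rigid unit all other operations consume.
#' Most users obtain units from [read_structure()] or [make_toy_unit()];
#' this is exposed for tests and for programmatic fixtures.
#'
#' @param atoms Data frame with at least `serial`, `name`, `element`,
#'   `resid` (3-letter residue name), `resno`, `chain`, `x`, `y`, `z`.
#'   Typing columns (`vdw_radius`, `is_side_chain`, `is_hydrogen`,
#'   `donor`, `acceptor`, `charge_sign`, `hp_class`, `hp_value`) are
#'   added with neutral defaults when absent.
#' @param unit_id Identifier string.
#' @param source Provenance string (file + model number).
#' @return An object of class `sw_unit`.
#' @export
structure_unit <- function(atoms, unit_id = "unit", source = "in-memory") {
  need <- c("serial", "name", "element", "resid", "resno", "chain",
            "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms lacks columns: ", paste(miss, collapse = ", "))
  if (!nrow(atoms)) stop("unit must contain at least one atom")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  defaults <- list(vdw_radius = NA_real_,
                   is_hydrogen = atoms$element == "H",
                   is_side_chain = !(atoms$name %in% backbone_atom_names),
                   donor = FALSE, acceptor = FALSE,
                   charge_sign = 0L,
                   hp_class = "none", hp_value = 0)
  for (nm in names(defaults))
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  if (all(atoms$is_hydrogen)) stop("unit must contain a non-hydrogen atom")
  rownames(atoms) <- NULL
  u <- list(atoms = atoms, unit_id = unit_id, source = source,
            residue_count = nrow(unique(atoms[, c("chain", "resno")])))
  class(u) <- "sw_unit"
  u
}

#' @export
print.sw_unit <- function(x, ...) {
  cat(sprintf("<sw_unit '%s'> %d atoms, %d residues (%s)\n",
              x$unit_id, nrow(x$atoms), x$residue_count, x$source))
  invisible(x)
}

#' Coordinates of a unit as an n x 3 matrix
#' @param unit An `sw_unit`.
#' @return Numeric matrix with columns x, y, z.
#' @export
unit_coords <- function(unit) {
  as.matrix(unit$atoms[, c("x", "y", "z")])
}

# residue identifier convention: chain + author residue number
residue_ids <- function(atoms) paste0(atoms$chain, ":", atoms$resno)

infer_element <- function(name) {
  nm <- gsub("[0-9']", "", toupper(trimws(name)))
  ifelse(substr(nm, 1, 1) == "H" | grepl("^[0-9]*H", toupper(trimws(name))),
         "H", substr(nm, 1, 1))
}

#' Read one model of an all-atom PDB file as a structure unit
#'
#' Parses ATOM records of the selected model, resolving the element from
#' the element column (falling back to atom-name inference), dropping
#' waters and non-protein heteroatoms, and keeping the highest-occupancy
#' alternate location of each atom.
#'
#' @param path PDB file path.
#' @param model_index 1-based model number (for multi-model files).
#' @param unit_id Identifier; defaults to the file base name.
#' @return An `sw_unit` (untyped: radii/roles are assigned downstream by
#'   [assign_radii()], [assign_protonation()] and [classify_atoms()]).
#' @export
read_structure <- function(path, model_index = 1L,
                           unit_id = sub("\\.pdb$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("unreadable PDB file: ",
                                           conditionMessage(e)))
  n_models <- nrow(pdb$xyz)
  if (is.null(n_models)) n_models <- 1L
  if (model_index < 1 || model_index > n_models)
    stop(sprintf("model_index %d out of range (file has %d model%s)",
                 model_index, n_models, if (n_models == 1) "" else "s"))
  at <- pdb$atom
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  keep <- at$type == "ATOM" & at$resid %in% protein_residues
  at <- at[keep, , drop = FALSE]
  if (!nrow(at)) stop("no protein ATOM records in model ", model_index)
  # highest-occupancy altloc, first on ties
  if (any(!is.na(at$alt) & nzchar(at$alt))) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    occ <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(key, -occ, seq_len(nrow(at)))
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(key[ord]), , drop = FALSE]
    at <- at[order(at$eleno), , drop = FALSE]
  }
  elem <- toupper(trimws(as.character(at$elesy)))
  bad <- is.na(elem) | !nzchar(elem)
  elem[bad] <- infer_element(at$elety[bad])
  chain <- ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain)
  atoms <- data.frame(serial = at$eleno, name = trimws(at$elety),
                      element = elem, resid = at$resid, resno = at$resno,
                      chain = chain, x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  structure_unit(atoms, unit_id = unit_id,
                 source = sprintf("%s model %d", path, model_index))
}

#' Assign van der Waals radii by element
#'
#' @param unit An `sw_unit`.
#' @param radii_table Named vector, element -> radius in Angstrom.
#' @return The unit with `vdw_radius` filled in; otherwise unchanged.
#' @export
assign_radii <- function(unit, radii_table = default_vdw_radii()) {
  el <- unit$atoms$element
  missing_el <- setdiff(unique(el), names(radii_table))
  if (length(missing_el))
    stop("no vdW radius for element(s): ", paste(missing_el, collapse = ", "))
  unit$atoms$vdw_radius <- unname(radii_table[el])
  unit
}

# "<chain>:<resno>" lookup with per-type default fallback
lookup_pka <- function(model, chain, resno, type) {
  key <- paste0(chain, ":", resno)
  if (!is.null(model$pka) && key %in% names(model$pka))
    return(unname(model$pka[[key]]))
  if (type %in% names(model$defaults)) return(unname(model$defaults[[type]]))
  stop("no pKa value or default for titratable group ", type, " at ", key)
}

#' Assign pH-dependent formal charge signs
#'
#' Bases (His, Lys, Arg, N-terminus) receive `charge_sign = +1` on the
#' atoms of their ionizable moiety when pH < pKa; acids (Asp, Glu, Cys,
#' C-terminus) receive `-1` when pH > pKa. Charge placement follows the
#' packaged per-residue template (guanidinium nitrogens, Lys NZ, His
#' imidazole nitrogens, carboxylate oxygens, terminal N / O+OXT).
#'
#' @param unit An `sw_unit` with radii assigned.
#' @param model An [protonation_model()].
#' @return The unit with `charge_sign` set.
#' @export
assign_protonation <- function(unit, model) {
  stopifnot(inherits(model, "sw_protonation"))
  at <- unit$atoms
  at$charge_sign <- 0L
  res <- unique(at[, c("chain", "resno", "resid")])
  for (k in seq_len(nrow(res))) {
    r <- res[k, ]
    sel_res <- at$chain == r$chain & at$resno == r$resno
    if (r$resid %in% names(charge_template)) {
      pka <- lookup_pka(model, r$chain, r$resno, r$resid)
      rule <- model$rules[[r$resid]]
      ionized <- if (rule == "base") model$pH < pka else model$pH > pka
      if (ionized) {
        sel <- sel_res & at$name %in% charge_template[[r$resid]]
        at$charge_sign[sel] <- if (rule == "base") 1L else -1L
      }
    }
  }
  # chain termini
  for (ch in unique(at$chain)) {
    in_ch <- at$chain == ch
    nter <- min(at$resno[in_ch]); cter <- max(at$resno[in_ch])
    pka_n <- lookup_pka(model, ch, nter, "NTR")
    if (model$pH < pka_n) {
      sel <- in_ch & at$resno == nter & at$name %in% charge_template$NTR
      at$charge_sign[sel] <- 1L
    }
    pka_c <- lookup_pka(model, ch, cter, "CTR")
    if (model$pH > pka_c) {
      sel <- in_ch & at$resno == cter & at$name %in% charge_template$CTR
      at$charge_sign[sel] <- -1L
    }
  }
  unit$atoms <- at
  unit$pH <- model$pH
  unit
}

#' Assign interaction roles: donor, acceptor, hydropathy class
#'
#' Donors are N/O/S atoms with a covalently bonded hydrogen (nearest heavy
#' atom of each hydrogen within 1.25 Angstrom). Acceptors are all O and S
#' atoms plus template-listed nitrogens (His imidazole). Side-chain heavy
#' atoms are typed into \{C, N/O, N+, O-, S\} and given the per-type
#' hydropathy value HP_t via [hydropathy_parameter()]; positive solvation
#' parameter marks the type hydrophobic, negative hydrophilic.
#'
#' @param unit An `sw_unit` with protonation assigned.
#' @param params An [energy_parameters()] set.
#' @param require_hydrogens If `TRUE` (default) a structure without any
#'   hydrogen is rejected; with `FALSE` donor detection falls back to a
#'   template of donor-capable N/O/S atom names.
#' @return The unit with `donor`, `acceptor`, `hp_class`, `hp_value` set.
#' @export
classify_atoms <- function(unit, params = energy_parameters(),
                           require_hydrogens = TRUE) {
  at <- unit$atoms
  if (any(is.na(at$vdw_radius) & at$element != "H"))
    stop("assign radii before classifying")
  hyd <- which(at$is_hydrogen)
  heavy <- which(!at$is_hydrogen)
  at$donor <- FALSE
  if (length(hyd)) {
    hx <- as.matrix(at[hyd, c("x", "y", "z")])
    px <- as.matrix(at[heavy, c("x", "y", "z")])
    for (i in seq_along(hyd)) {
      d2 <- colSums((t(px) - hx[i, ])^2)
      j <- which.min(d2)
      if (sqrt(d2[j]) > 1.25)
        stop(sprintf("orphan hydrogen %s %s:%d (no heavy atom within 1.25 A)",
                     at$name[hyd[i]], at$chain[hyd[i]], at$resno[hyd[i]]))
      if (at$element[heavy[j]] %in% c("N", "O", "S"))
        at$donor[heavy[j]] <- TRUE
    }
  } else if (require_hydrogens) {
    stop("structure has no hydrogens; the all-atom model needs them for ",
         "donor detection (use require_hydrogens = FALSE to fall back ",
         "to a donor-capable template)")
  } else {
    donor_names <- c("N", "OG", "OG1", "OH", "NE", "NH1", "NH2", "NZ",
                     "ND1", "NE2", "ND2", "NE1", "SG", "OW")
    at$donor <- at$element %in% c("N", "O", "S") & at$name %in% donor_names
  }
  at$acceptor <- at$element %in% c("O", "S")
  for (resid in names(n_acceptor_template)) {
    sel <- at$resid == resid & at$name %in% n_acceptor_template[[resid]] &
      at$element == "N"
    at$acceptor[sel] <- TRUE
  }
  # hydropathy typing: side-chain heavy atoms only
  at$hp_class <- "none"; at$hp_value <- 0
  sc <- which(at$is_side_chain & !at$is_hydrogen &
                at$element %in% c("C", "N", "O", "S"))
  if (length(sc)) {
    type <- character(length(sc))
    el <- at$element[sc]; sign <- at$charge_sign[sc]
    type[el == "C"] <- "C"
    type[el == "S"] <- "S"
    type[el == "N" & sign > 0] <- "N+"
    type[el == "O" & sign < 0] <- "O-"
    type[(el == "N" & sign <= 0) | (el == "O" & sign >= 0)] <- "N/O"
    hp <- vapply(type, hydropathy_parameter, numeric(1), params = params)
    s <- unname(params$solvation_table[type])
    at$hp_class[sc] <- ifelse(s > 0, "hydrophobic",
                              ifelse(s < 0, "hydrophilic", "none"))
    at$hp_value[sc] <- ifelse(s == 0, 0, hp)
  }
  unit$atoms <- at
  unit$classified <- TRUE
  unit
}

#' Convenience: read + radii + protonation + classification
#'
#' @inheritParams read_structure
#' @param model A [protonation_model()].
#' @param params An [energy_parameters()] set.
#' @param ... Passed to [classify_atoms()].
#' @return A fully typed `sw_unit` ready for docking.
#' @export
prepare_structure <- function(path, model, params = energy_parameters(),
                              model_index = 1L, ...) {
  u <- read_structure(path, model_index)
  u <- assign_radii(u, params$radii_table)
  u <- assign_protonation(u, model)
  classify_atoms(u, params, ...)
}

format_pdb_atoms <- function(atoms) {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$serial %% 100000,
          ifelse(nchar(atoms$name) < 4, paste0(" ", atoms$name), atoms$name),
          atoms$resid, substr(atoms$chain, 1, 1), atoms$resno %% 10000,
          atoms$x, atoms$y, atoms$z, 1.0, 0.0, atoms$element)
}

#' Write a docked-complex ensemble as a multi-model PDB
#'
#' One MODEL block per member: the fixed unit followed by the posed mobile
#' unit (mobile chain relabelled if it collides with a fixed chain), with
#' the member's binding energy, contact and clash counts in REMARK lines.
#'
#' @param ensemble An `sw_ensemble` from [ensemble_dock()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "sw_ensemble"))
  if (!length(ensemble$members)) stop("empty ensemble")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("REMARK   3 SQUARE-WELL DOCKING ENSEMBLE",
               sprintf("REMARK   3 MEMBERS %d  PH %s  SEED %s",
                       length(ensemble$members),
                       format(ensemble$pH), format(ensemble$seed))), con)
  for (k in seq_along(ensemble$members)) {
    m <- ensemble$members[[k]]
    fa <- m$fixed$atoms
    mb <- m$mobile$atoms
    mb[, c("x", "y", "z")] <- apply_pose(unit_coords(m$mobile), m$pose,
                                         mobile_center(m$mobile))
    if (any(mb$chain %in% fa$chain)) {
      free <- setdiff(LETTERS, unique(fa$chain))
      map <- stats::setNames(free[seq_along(unique(mb$chain))],
                             unique(mb$chain))
      mb$chain <- unname(map[mb$chain])
    }
    mb$serial <- max(fa$serial) + seq_len(nrow(mb))
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(sprintf(
      "REMARK   3 BINDING ENERGY %.6f CONTACTS %d CLASHES %d FIXED %d",
      m$U, m$n_contacts, m$n_clashes, nrow(fa)), con)
    writeLines(format_pdb_atoms(fa), con)
    writeLines("TER", con)
    writeLines(format_pdb_atoms(mb), con)
    writeLines(c("TER", "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a docked ensemble back from a multi-model PDB
#'
#' Rebuilds an `sw_ensemble` from a file produced by [write_ensemble()]:
#' each MODEL is split into its fixed and mobile blocks (atom counts from
#' the REMARK header), both units are re-typed at the given pH, and the
#' interaction tables are re-evaluated with [interface_energy()]. Poses
#' are identities (coordinates as stored).
#'
#' @param path Multi-model PDB written by [write_ensemble()].
#' @param model A [protonation_model()] for re-typing.
#' @param params [energy_parameters()].
#' @return An `sw_ensemble` whose members carry re-evaluated energies,
#'   counts and interaction tables.
#' @export
read_ensemble <- function(path, model, params = energy_parameters()) {
  txt <- readLines(path)
  rem <- grep("REMARK   3 BINDING ENERGY", txt, value = TRUE)
  if (!length(rem)) stop("not an ensemble file: no binding-energy REMARKs")
  n_fixed <- as.integer(sub(".*FIXED ([0-9]+).*", "\\1", rem))
  # models may hold different conformers (unequal atom counts), so each
  # MODEL block is parsed on its own
  starts <- grep("^MODEL", txt)
  ends <- grep("^ENDMDL", txt)
  stopifnot(length(starts) == length(rem), length(ends) == length(rem))
  members <- vector("list", length(rem))
  for (k in seq_along(rem)) {
    tmp <- tempfile(fileext = ".pdb")
    writeLines(c(txt[(starts[k] + 1):(ends[k] - 1)], "END"), tmp)
    all_atoms <- read_structure(tmp, 1)
    unlink(tmp)
    fixed <- structure_unit(all_atoms$atoms[seq_len(n_fixed[k]), ],
                            unit_id = "fixed",
                            source = sprintf("%s model %d fixed", path, k))
    mobile <- structure_unit(
      all_atoms$atoms[-seq_len(n_fixed[k]), ], unit_id = "mobile",
      source = sprintf("%s model %d mobile", path, k))
    fixed <- classify_atoms(assign_protonation(
      assign_radii(fixed, params$radii_table), model), params)
    mobile <- classify_atoms(assign_protonation(
      assign_radii(mobile, params$radii_table), model), params)
    ev <- interface_energy(fixed, mobile, params, pairs = TRUE)
    members[[k]] <- list(
      fixed = fixed, mobile = mobile,
      pose = rigid_pose(c(1, 0, 0, 0), mobile_center(mobile)),
      U = ev$U, n_contacts = ev$n_contacts,
      n_clashes = ev$n_clashes, interactions = ev$pairs, seed = NA_integer_)
    class(members[[k]]) <- "sw_complex"
  }
  ens <- list(members = members,
              energies = vapply(members, `[[`, 0, "U"),
              converged = NA, pH = model$pH, seed = NA_integer_)
  class(ens) <- "sw_ensemble"
  ens
}

#' Write a single structure unit as a PDB file
#' @param unit An `sw_unit`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(unit, path) {
  writeLines(c(format_pdb_atoms(unit$atoms), "TER", "END"), path)
  invisible(path)
}
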