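# Idealized local residue templates (coordinates in Angstrom, CA at the
# origin, side chain extending towards -z). Bond lengths track standard
# values; stereochemistry is deliberately simplified — fixtures exercise
# the energy/search/analysis contracts, not rotamer libraries.
residue_templates <- local({
  bb <- function() list(
    N  = c("N", -1.460,  0.000,  0.000),
    H  = c("H", -1.963,  0.875,  0.000),
    CA = c("C",  0.000,  0.000,  0.000),
    HA = c("H",  0.550, -0.550,  0.750),
    C  = c("C",  1.000,  1.145,  0.000),
    O  = c("O",  1.370,  2.310,  0.000))
  sc <- function(...) c(bb(), list(...))
  a <- function(el, x, y, z) c(el, x, y, z)
  list(
    GLY = sc(HA2 = a("H", 0.00, -0.63, -0.88)),
    ALA = sc(CB = a("C", 0.00, -0.90, -1.20),
             HB1 = a("H", 0.95, -1.30, -1.45),
             HB2 = a("H", -0.75, -1.60, -1.10)),
    SER = sc(CB = a("C", 0.00, -0.90, -1.20),
             HB1 = a("H", 0.95, -1.35, -1.40),
             OG = a("O", 0.00, -0.35, -2.48),
             HG = a("H", 0.00, -0.95, -3.22)),
    LEU = sc(CB = a("C", 0.00, -0.90, -1.20),
             HB1 = a("H", 0.95, -1.35, -1.40),
             CG = a("C", 0.00, -0.25, -2.58),
             HG = a("H", -0.90, 0.35, -2.70),
             CD1 = a("C", 1.28, 0.58, -2.76),
             HD1 = a("H", 1.30, 1.05, -3.72),
             CD2 = a("C", -0.05, -1.30, -3.68),
             HD2 = a("H", 0.80, -1.95, -3.62)),
    PHE = sc(CB = a("C", 0.00, -0.90, -1.20),
             HB1 = a("H", 0.95, -1.35, -1.40),
             CG = a("C", 0.00, -0.25, -2.55),
             CD1 = a("C", 1.15, 0.05, -3.25),
             HD1 = a("H", 2.10, -0.20, -2.85),
             CD2 = a("C", -1.15, 0.05, -3.25),
             HD2 = a("H", -2.10, -0.20, -2.85),
             CE1 = a("C", 1.15, 0.70, -4.47),
             HE1 = a("H", 2.10, 0.95, -4.90),
             CE2 = a("C", -1.15, 0.70, -4.47),
             HE2 = a("H", -2.10, 0.95, -4.90),
             CZ = a("C", 0.00, 1.00, -5.15),
             HZ = a("H", 0.00, 1.50, -6.10)),
    ASP = sc(CB = a("C", 0.00, -0.90, -1.20),
             HB1 = a("H", 0.95, -1.35, -1.40),
             CG = a("C", 0.00, -0.25, -2.58),
             OD1 = a("O", 1.00, 0.40, -2.95),
             OD2 = a("O", -1.05, -0.40, -3.25)),
    GLU = sc(CB = a("C", 0.00, -0.90, -1.20),
             HB1 = a("H", 0.95, -1.35, -1.40),
             CG = a("C", 0.00, -0.25, -2.58),
             HG1 = a("H", -0.95, 0.30, -2.70),
             CD = a("C", 1.15, 0.65, -3.05),
             OE1 = a("O", 2.25, 0.45, -2.60),
             OE2 = a("O", 1.00, 1.55, -3.92)),
    LYS = sc(CB = a("C", 0.00, -0.90, -1.20),
             HB1 = a("H", 0.95, -1.35, -1.40),
             CG = a("C", 0.00, -0.25, -2.58),
             HG1 = a("H", -0.95, 0.30, -2.70),
             CD = a("C", 0.10, -1.25, -3.72),
             HD1 = a("H", 1.00, -1.85, -3.60),
             CE = a("C", 0.10, -0.60, -5.10),
             HE1 = a("H", -0.80, -0.02, -5.25),
             NZ = a("N", 0.15, -1.60, -6.18),
             HZ1 = a("H", 0.15, -1.15, -7.09),
             HZ2 = a("H", 1.00, -2.15, -6.10),
             HZ3 = a("H", -0.70, -2.15, -6.12)),
    ARG = sc(CB = a("C", 0.00, -0.90, -1.20),
             HB1 = a("H", 0.95, -1.35, -1.40),
             CG = a("C", 0.00, -0.25, -2.58),
             HG1 = a("H", -0.95, 0.30, -2.70),
             CD = a("C", 0.10, -1.25, -3.72),
             HD1 = a("H", 1.00, -1.85, -3.60),
             NE = a("N", 0.10, -0.55, -5.00),
             HE = a("H", -0.60, 0.15, -5.12),
             CZ = a("C", 0.95, -0.80, -6.00),
             NH1 = a("N", 1.85, -1.75, -5.90),
             HH11 = a("H", 1.90, -2.35, -5.08),
             NH2 = a("N", 0.90, -0.10, -7.14),
             HH21 = a("H", 1.55, -0.30, -7.88)),
    HIS = sc(CB = a("C", 0.00, -0.90, -1.20),
             HB1 = a("H", 0.95, -1.35, -1.40),
             CG = a("C", 0.00, -0.25, -2.55),
             ND1 = a("N", 1.05, 0.50, -3.02),
             HD1 = a("H", 1.90, 0.70, -2.53),
             CD2 = a("C", -0.95, -0.25, -3.52),
             HD2 = a("H", -1.85, -0.80, -3.60),
             CE1 = a("C", 0.80, 0.90, -4.28),
             HE1 = a("H", 1.50, 1.50, -4.85),
             NE2 = a("N", -0.40, 0.45, -4.65))
  )
})

#' Residue types available to the toy-structure generator
#' @return Character vector of 3-letter codes.
#' @export
fixture_residues <- function() names(residue_templates)

#' Specification of a deterministic toy structure
#'
#' @param n_residues Number of residues (>= 1).
#' @param composition Named non-negative weights over
#'   [fixture_residues()]; default uniform over ALA, SER, LEU, ASP, LYS.
#' @param planted_patch Optional list with `position` (residue index),
#'   `kind` (one of "donor", "charged", "hydrophobic", "acidic") marking a
#'   surface residue with a cluster of matching side-chain atoms.
#' @param geometry "rod" (extended, side chains radiating) or "blob"
#'   (residues on a compact spherical shell, side chains outward).
#' @param seed Integer; same spec + seed gives a bit-identical fixture.
#' @return A list of class `sw_fixture_spec`.
#' @export
fixture_spec <- function(n_residues,
                         composition = c(ALA = 1, SER = 1, LEU = 1,
                                         ASP = 1, LYS = 1),
                         planted_patch = NULL,
                         geometry = c("rod", "blob"),
                         seed = 1L) {
  geometry <- match.arg(geometry)
  stopifnot(n_residues >= 1, all(composition >= 0), sum(composition) > 0)
  bad <- setdiff(names(composition), fixture_residues())
  if (length(bad))
    stop("unsupported residue type(s): ", paste(bad, collapse = ", "))
  if (!is.null(planted_patch)) {
    stopifnot(planted_patch$position >= 1,
              planted_patch$position <= n_residues)
    planted_patch$kind <- match.arg(planted_patch$kind,
                                    c("donor", "charged", "hydrophobic",
                                      "acidic"))
  }
  s <- list(n_residues = as.integer(n_residues), composition = composition,
            planted_patch = planted_patch, geometry = geometry,
            seed = as.integer(seed))
  class(s) <- "sw_fixture_spec"
  s
}

# orthonormal frame whose third column is v
frame_from_axis <- function(v) {
  v <- v / sqrt(sum(v^2))
  h <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- h - sum(h * v) * v
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(v[2] * e1[3] - v[3] * e1[2],
          v[3] * e1[1] - v[1] * e1[3],
          v[1] * e1[2] - v[2] * e1[1])
  cbind(e1, e2, v)
}

#' Generate a deterministic toy all-atom structure
#'
#' Residue types are drawn from the spec's composition; each residue is an
#' idealized all-atom template (backbone N, H, CA, HA, C, O plus side
#' chain with hydrogens) placed either along an extended rod with side
#' chains radiating at the golden angle, or on a compact spherical shell
#' with side chains pointing outward. A planted patch substitutes a
#' residue rich in the requested interaction chemistry (donor: SER,
#' charged: LYS, acidic: ASP, hydrophobic: LEU).
#'
#' @param spec A [fixture_spec()].
#' @param unit_id Identifier for the unit.
#' @param chain Chain identifier (default "A").
#' @return An untyped `sw_unit` (run [assign_radii()],
#'   [assign_protonation()], [classify_atoms()] before docking).
#' @export
make_toy_unit <- function(spec, unit_id = "toy", chain = "A") {
  stopifnot(inherits(spec, "sw_fixture_spec"))
  types <- with_seed(spec$seed, {
    w <- spec$composition[spec$composition > 0]
    sample(names(w), spec$n_residues, replace = TRUE, prob = w)
  })
  if (!is.null(spec$planted_patch)) {
    types[spec$planted_patch$position] <- switch(spec$planted_patch$kind,
      donor = "SER", charged = "LYS", acidic = "ASP", hydrophobic = "LEU")
  }
  n <- spec$n_residues
  if (spec$geometry == "rod") {
    ca <- cbind(3.8 * (seq_len(n) - 1), 0, 0)
    axes <- t(vapply(seq_len(n), function(k) {
      phi <- (k - 1) * 2.399963  # golden angle
      c(0, -cos(phi), -sin(phi))
    }, numeric(3)))
  } else {
    # Fibonacci sphere sized for ~7 A nearest-neighbor spacing
    R <- max(5, 2.0 * sqrt(n))
    k <- seq_len(n)
    z <- 1 - (2 * k - 1) / n
    z <- pmin(pmax(z, -1), 1)
    th <- 2.399963 * (k - 1)
    axes <- cbind(sqrt(1 - z^2) * cos(th), sqrt(1 - z^2) * sin(th), z)
    ca <- R * axes
  }
  rows <- list()
  serial <- 0L
  for (k in seq_len(n)) {
    tmpl <- residue_templates[[types[k]]]
    # side chain (-z in the template) maps onto the outward axis
    Fm <- frame_from_axis(-axes[k, ])
    for (nm in names(tmpl)) {
      v <- tmpl[[nm]]
      loc <- as.numeric(v[2:4])
      pos <- ca[k, ] + as.numeric(Fm %*% loc)
      serial <- serial + 1L
      rows[[serial]] <- data.frame(
        serial = serial, name = nm, element = v[1], resid = types[k],
        resno = k, chain = chain, x = pos[1], y = pos[2], z = pos[3],
        stringsAsFactors = FALSE)
    }
  }
  structure_unit(do.call(rbind, rows), unit_id = unit_id,
                 source = sprintf("synthetic %s seed %d", spec$geometry,
                                  spec$seed))
}

#' Naive all-pairs interface energy (oracle)
#'
#' Pure-R double loop over every intermolecular heavy-atom pair, applying
#' the three square-well potentials and the clash rule directly. No
#' neighbor acceleration; defines ground truth for [interface_energy()].
#'
#' @inheritParams interface_energy
#' @return List with `U`, `n_contacts`, `n_clashes`.
#' @export
brute_force_interface_energy <- function(unit_a, unit_b,
                                         params = energy_parameters()) {
  check_typed(unit_a, "unit_a"); check_typed(unit_b, "unit_b")
  a <- unit_a$atoms[!unit_a$atoms$is_hydrogen, , drop = FALSE]
  b <- unit_b$atoms[!unit_b$atoms$is_hydrogen, , drop = FALSE]
  U <- 0; ncont <- 0L; nclash <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    r <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                (a$z[i] - b$z[j])^2)
    sigma <- a$vdw_radius[i] + b$vdw_radius[j]
    if (r < sigma) { nclash <- nclash + 1L; next }
    contact <- FALSE
    if (((a$donor[i] && b$acceptor[j]) || (b$donor[j] && a$acceptor[i])) &&
        r < params$hb_cutoff) {
      U <- U + params$e_hb; contact <- TRUE
    }
    if (a$charge_sign[i] != 0 && b$charge_sign[j] != 0) {
      s <- a$charge_sign[i] * b$charge_sign[j]
      e <- if (r > sigma && r < params$el_well1_scale * sigma)
        s * params$e_el1
      else if (r >= params$el_well1_scale * sigma &&
               r < params$el_cutoff_scale * sigma) s * params$e_el2
      else 0
      if (e != 0) { U <- U + e; contact <- TRUE }
    }
    if (a$hp_class[i] != "none" && b$hp_class[j] != "none" &&
        (params$mixed_hydropathy || a$hp_class[i] == b$hp_class[j]) &&
        r < params$hp_cutoff_scale * sigma) {
      U <- U + a$hp_value[i] + b$hp_value[j]; contact <- TRUE
    }
    if (contact) ncont <- ncont + 1L
  }
  list(U = U, n_contacts = ncont, n_clashes = nclash)
}

#' Exhaustive grid-search docking (oracle)
#'
#' Enumerates the mobile unit's pose over a Cartesian translation grid
#' (within a shell where contact is geometrically possible) crossed with a
#' z-y-z Euler-angle rotation grid, and returns the minimal-objective
#' pose. Intended as a test oracle on toy systems only.
#'
#' @param fixed,mobile Typed `sw_unit`s (small).
#' @param params [energy_parameters()].
#' @param resolution Length-2 vector: translation step (Angstrom) and
#'   rotation step (degrees).
#' @param max_poses Error out above this many poses (default 1e7).
#' @return List with `objective`, `U`, `n_contacts`, `n_clashes`, `pose`.
#' @export
grid_search_dock <- function(fixed, mobile, params = energy_parameters(),
                             resolution = c(0.5, 20), max_poses = 1e7) {
  cu <- center_units(fixed, mobile)
  fx <- pack_unit(cu$fixed)
  mb <- pack_unit(cu$mobile)
  c0 <- mobile_center(cu$mobile)
  rf <- bounding_radius(cu$fixed); rm_ <- bounding_radius(cu$mobile)
  L <- rf + rm_ + 3.2
  dstep <- resolution[1]
  astep <- resolution[2] * pi / 180
  tgrid <- seq(-L, L, by = dstep)
  tt <- as.matrix(expand.grid(x = tgrid, y = tgrid, z = tgrid))
  tt <- tt[rowSums(tt^2) > 1 & rowSums(tt^2) <= L^2, , drop = FALSE]
  alpha <- seq(0, 2 * pi - astep / 2, by = astep)
  beta <- seq(0, pi, by = astep)
  gamma <- seq(0, 2 * pi - astep / 2, by = astep)
  n_pose <- as.numeric(nrow(tt)) * length(alpha) * length(beta) *
    length(gamma)
  if (n_pose > max_poses)
    stop(sprintf("grid too large: %g poses (max %g)", n_pose, max_poses))
  best <- list(objective = Inf)
  m0 <- sweep(mb$xyz, 2, c0)
  for (al in alpha) for (be in beta) for (ga in gamma) {
    q <- quat_multiply(quat_from_axis_angle(c(0, 0, 1), al),
                       quat_multiply(quat_from_axis_angle(c(0, 1, 0), be),
                                     quat_from_axis_angle(c(0, 0, 1), ga)))
    rot <- m0 %*% t(quat_to_matrix(q))
    ob <- cpp_grid_objective(fx, mb, rot, tt, params)
    k <- which.min(ob[, 1])
    if (ob[k, 1] < best$objective)
      best <- list(objective = ob[k, 1], U = ob[k, 2],
                   n_contacts = as.integer(ob[k, 3]),
                   n_clashes = as.integer(ob[k, 4]),
                   pose = rigid_pose(q, tt[k, ]))
  }
  best
}

#' Synthetic ensemble with a planted sticky residue
#'
#' Builds an ensemble of stub members whose interaction tables contain a
#' planted residue-residue contact at a fixed per-member rate against
#' uniform background contacts, so the ground-truth hot-spot is known by
#' construction. Members carry interaction tables and binding energies
#' only (no structures).
#'
#' @param n_members Ensemble size (>= 10).
#' @param sticky_residue Planted fixed-unit residue id (default "A:5");
#'   its partner is the same position on the mobile unit ("B:<pos>").
#' @param planted_rate Per-member probability of the planted contact.
#' @param background_rate Per-member probability of each background
#'   contact; must be below `planted_rate`.
#' @param n_residues Residues per unit (default 20).
#' @param n_background Number of distinct background contact pairs
#'   (default 30).
#' @param seed Integer seed.
#' @return An `sw_ensemble` of stub members, with attribute
#'   `planted_residue`.
#' @export
make_planted_ensemble <- function(n_members, sticky_residue = "A:5",
                                  planted_rate = 0.8,
                                  background_rate = 0.1,
                                  n_residues = 20, n_background = 30,
                                  seed = 1L) {
  stopifnot(n_members >= 10, planted_rate >= 0, planted_rate <= 1,
            background_rate >= 0, background_rate <= 1,
            background_rate < planted_rate)
  pos <- as.integer(sub("^.*:", "", sticky_residue))
  planted_key <- c(sticky_residue, paste0("B:", pos))
  with_seed(seed, {
    pool <- expand.grid(a = seq_len(n_residues), b = seq_len(n_residues))
    pool <- pool[!(pool$a == pos & pool$b == pos), ]
    bg <- pool[sample.int(nrow(pool), n_background), ]
    members <- lapply(seq_len(n_members), function(m) {
      ra <- character(0); rb <- character(0)
      if (stats::runif(1) < planted_rate) {
        ra <- planted_key[1]; rb <- planted_key[2]
      }
      on_ <- stats::runif(n_background) < background_rate
      ra <- c(ra, paste0("A:", bg$a[on_]))
      rb <- c(rb, paste0("B:", bg$b[on_]))
      pr <- data.frame(res_a = ra, res_b = rb,
                       atom_a = "X", atom_b = "X", kind = "hbond",
                       r = 3.0, sigma = 2.9,
                       energy = rep(-1, length(ra)),
                       stringsAsFactors = FALSE)
      list(U = sum(pr$energy), n_contacts = nrow(pr), n_clashes = 0L,
           interactions = pr, seed = m)
    })
    ens <- list(members = members,
                energies = vapply(members, `[[`, 0, "U"),
                convergence = NULL, converged = TRUE, pH = NA_real_,
                seed = seed, target = c(n_members, n_members))
    class(ens) <- "sw_ensemble"
    attr(ens, "planted_residue") <- sticky_residue
    ens
  })
}
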