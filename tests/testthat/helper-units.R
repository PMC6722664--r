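# Hand-flagged minimal units for energy/docking tests: atoms carry their
# interaction roles directly, bypassing classification.

flag_atom <- function(serial, name, element, x, y, z, resno = 1L,
                      chain = "A", resid = "GLY", vdw = 1.7,
                      donor = FALSE, acceptor = FALSE, charge = 0L,
                      hp_class = "none", hp_value = 0) {
  data.frame(serial = serial, name = name, element = element,
             resid = resid, resno = resno, chain = chain,
             x = x, y = y, z = z, vdw_radius = vdw,
             is_side_chain = TRUE, is_hydrogen = element == "H",
             donor = donor, acceptor = acceptor,
             charge_sign = as.integer(charge),
             hp_class = hp_class, hp_value = hp_value,
             stringsAsFactors = FALSE)
}

# fixed: acceptor O + plain C; mobile: donor N + plain C (2 atoms each)
donor_acceptor_pair <- function() {
  fa <- rbind(
    flag_atom(1, "O", "O", 0, 0, 0, vdw = 1.52, acceptor = TRUE),
    flag_atom(2, "C", "C", 2, 0, 0))
  mb <- rbind(
    flag_atom(1, "N", "N", 10, 0, 0, vdw = 1.55, donor = TRUE,
              chain = "B", resno = 1L),
    flag_atom(2, "C", "C", 12, 0, 0, chain = "B", resno = 1L))
  list(fixed = structure_unit(fa, "acceptor-unit"),
       mobile = structure_unit(mb, "donor-unit"))
}

# both units carry a single +1 charge site
like_charge_pair <- function() {
  fa <- rbind(
    flag_atom(1, "NZ", "N", 0, 0, 0, vdw = 1.55, charge = 1L),
    flag_atom(2, "C", "C", 2, 0, 0))
  mb <- rbind(
    flag_atom(1, "NZ", "N", 10, 0, 0, vdw = 1.55, charge = 1L,
              chain = "B"),
    flag_atom(2, "C", "C", 12, 0, 0, chain = "B"))
  list(fixed = structure_unit(fa, "plus-unit"),
       mobile = structure_unit(mb, "plus-unit-2"))
}

# classified toy units built by the generator
typed_toy <- function(seed, n = 8, chain = "A", geometry = "blob",
                      pH = 7.2, params = energy_parameters(),
                      composition = c(ALA = 1, SER = 1, LEU = 1,
                                      ASP = 1, LYS = 1),
                      planted_patch = NULL) {
  u <- make_toy_unit(fixture_spec(n, composition = composition,
                                  planted_patch = planted_patch,
                                  geometry = geometry, seed = seed),
                     unit_id = paste0("toy", seed), chain = chain)
  u <- assign_radii(u, params$radii_table)
  u <- assign_protonation(u, protonation_model(pH))
  classify_atoms(u, params)
}

# small in-memory PDB text fixture (two models, two residues, hydrogens)
two_model_pdb <- function(path) {
  l <- c(
    "MODEL        1",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  H   ALA A   1      -0.500   0.870   0.000  1.00  0.00           H",
    "ATOM      3  CA  ALA A   1       1.460   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CB  ALA A   1       2.000   1.420   0.000  1.00  0.00           C",
    "ATOM      5  C   ALA A   1       2.000  -0.760   1.200  1.00  0.00           C",
    "ATOM      6  O   ALA A   1       1.300  -1.500   1.900  1.00  0.00           O",
    "ATOM      7  N   SER A   2       3.300  -0.600   1.400  1.00  0.00           N",
    "ATOM      8  H   SER A   2       3.850   0.050   0.900  1.00  0.00           H",
    "ATOM      9  CA  SER A   2       4.000  -1.300   2.500  1.00  0.00",
    "ATOM     10  OG  SER A   2       5.300  -0.800   2.600  1.00  0.00           O",
    "ATOM     11  HG  SER A   2       5.800  -1.300   3.250  1.00  0.00           H",
    "TER",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   ALA A   1      10.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  H   ALA A   1       9.500   0.870   0.000  1.00  0.00           H",
    "ATOM      3  CA  ALA A   1      11.460   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CB  ALA A   1      12.000   1.420   0.000  1.00  0.00           C",
    "ATOM      5  C   ALA A   1      12.000  -0.760   1.200  1.00  0.00           C",
    "ATOM      6  O   ALA A   1      11.300  -1.500   1.900  1.00  0.00           O",
    "ATOM      7  N   SER A   2      13.300  -0.600   1.400  1.00  0.00           N",
    "ATOM      8  H   SER A   2      13.850   0.050   0.900  1.00  0.00           H",
    "ATOM      9  CA  SER A   2      14.000  -1.300   2.500  1.00  0.00",
    "ATOM     10  OG  SER A   2      15.300  -0.800   2.600  1.00  0.00           O",
    "ATOM     11  HG  SER A   2      15.800  -1.300   3.250  1.00  0.00           H",
    "TER",
    "ENDMDL",
    "END")
  writeLines(l, path)
  path
}

random_rigid_motion <- function() {
  q <- swdock:::quat_normalize(stats::rnorm(4))
  list(R = quat_to_matrix(q), b = stats::runif(3, -20, 20))
}

move_unit <- function(unit, motion) {
  xyz <- unit_coords(unit) %*% t(motion$R)
  xyz <- sweep(xyz, 2, motion$b, "+")
  unit$atoms[, c("x", "y", "z")] <- xyz
  unit
}
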