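test_that("read_structure parses ATOM records, infers elements, selects models", {
  path <- withr::local_tempfile(fileext = ".pdb")
  two_model_pdb(path)
  u1 <- read_structure(path, 1)
  expect_s3_class(u1, "sw_unit")
  expect_equal(nrow(u1$atoms), 11)
  expect_equal(u1$residue_count, 2)
  # blank element column on atom 9 (" CA ") inferred as carbon
  expect_equal(u1$atoms$element[u1$atoms$name == "CA"], c("C", "C"))
  u2 <- read_structure(path, 2)
  expect_equal(u2$atoms$x, u1$atoms$x + 10)
  expect_equal(u2$atoms$y, u1$atoms$y)
  expect_error(read_structure(path, 3), "out of range")
  expect_error(read_structure(file.path(tempdir(), "nope.pdb")),
               "not found")
})

test_that("waters and heteroatoms are excluded", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.460   0.000   0.000  1.00  0.00           C",
    "HETATM    3  O   HOH A 101       5.000   5.000   5.000  1.00  0.00           O",
    "END"), path)
  u <- read_structure(path)
  expect_equal(nrow(u$atoms), 2)
  expect_false(any(u$atoms$resid == "HOH"))
})

test_that("assign_radii looks elements up and rejects unknown ones", {
  pr <- donor_acceptor_pair()
  u <- pr$fixed
  u$atoms$vdw_radius <- NA_real_
  u <- assign_radii(u, c(C = 1.70, N = 1.55, O = 1.52))
  expect_equal(u$atoms$vdw_radius, c(1.52, 1.70))
  # sigma for a C-N pair is the sum of the assigned radii
  expect_equal(1.70 + 1.55, 3.25)
  u$atoms$element[1] <- "X"
  expect_error(assign_radii(u, c(C = 1.70, N = 1.55, O = 1.52)), "X")
})

test_that("protonation follows the acid/base pKa rules", {
  p <- energy_parameters()
  u <- make_toy_unit(fixture_spec(3, composition = c(HIS = 1), seed = 1))
  u <- assign_radii(u, p$radii_table)
  # His with pKa 6.5 at pH 5.2: protonated, +1 on both imidazole nitrogens
  m <- protonation_model(5.2, pka = c("A:2" = 6.5))
  ua <- assign_protonation(u, m)
  his2 <- ua$atoms[ua$atoms$resno == 2 & ua$atoms$name %in%
                     c("ND1", "NE2"), ]
  expect_equal(his2$charge_sign, c(1L, 1L))
  # His with pKa 5.2 at pH 7.2: neutral imidazole
  m2 <- protonation_model(7.2, pka = c("A:2" = 5.2))
  ub <- assign_protonation(u, m2)
  his2b <- ub$atoms[ub$atoms$resno == 2 & ub$atoms$name %in%
                      c("ND1", "NE2"), ]
  expect_equal(his2b$charge_sign, c(0L, 0L))
  # Asp at pH 7.2 (pKa 3.65 default): -1 on both carboxylate oxygens
  ud <- make_toy_unit(fixture_spec(3, composition = c(ASP = 1), seed = 1))
  ud <- assign_protonation(assign_radii(ud, p$radii_table),
                           protonation_model(7.2))
  asp <- ud$atoms[ud$atoms$resno == 2 & ud$atoms$name %in%
                    c("OD1", "OD2"), ]
  expect_equal(asp$charge_sign, c(-1L, -1L))
  # termini: N-terminal N positive below its pKa, C-terminal O negative
  expect_equal(ud$atoms$charge_sign[ud$atoms$resno == 1 &
                                      ud$atoms$name == "N"], 1L)
  expect_equal(ud$atoms$charge_sign[ud$atoms$resno == 3 &
                                      ud$atoms$name == "O"], -1L)
})

test_that("protonation is monotone in pH", {
  p <- energy_parameters()
  u <- assign_radii(make_toy_unit(
    fixture_spec(6, composition = c(HIS = 1, ASP = 1, LYS = 1, GLU = 1),
                 seed = 4)), p$radii_table)
  phs <- c(1, 3, 5, 7, 9, 11, 13)
  pos_sets <- lapply(phs, function(ph) {
    at <- assign_protonation(u, protonation_model(ph))$atoms
    which(at$charge_sign > 0)
  })
  neg_sets <- lapply(phs, function(ph) {
    at <- assign_protonation(u, protonation_model(ph))$atoms
    which(at$charge_sign < 0)
  })
  for (k in seq_len(length(phs) - 1)) {
    # lowering pH never removes a positive sign
    expect_true(all(pos_sets[[k + 1]] %in% pos_sets[[k]]))
    # raising pH never removes a negative sign
    expect_true(all(neg_sets[[k]] %in% neg_sets[[k + 1]]))
  }
})

test_that("classification flags donors, acceptors and hydropathy types", {
  p <- energy_parameters()
  u <- typed_toy(2, n = 6, composition = c(SER = 1, LEU = 1))
  at <- u$atoms
  # Ser side-chain hydroxyl O: donor (bonded HG) and acceptor
  og <- at[at$name == "OG", ]
  expect_true(all(og$donor) && all(og$acceptor))
  # Leu side-chain carbons hydrophobic (s_C = 18 > 0)
  leu_c <- at[at$resid == "LEU" & at$is_side_chain & at$element == "C", ]
  expect_true(all(leu_c$hp_class == "hydrophobic"))
  expect_true(all(leu_c$hp_value < 0))
  # backbone carbonyl O: acceptor but no hydropathy class
  bb_o <- at[at$name == "O", ]
  expect_true(all(bb_o$acceptor))
  expect_true(all(bb_o$hp_class == "none"))
  # every side-chain heavy atom is classified with finite hp_value
  sc <- at[at$is_side_chain & !at$is_hydrogen, ]
  expect_true(all(sc$hp_class != "none"))
  expect_true(all(is.finite(sc$hp_value)))
})

test_that("classification is idempotent and rejects hydrogen-free input", {
  p <- energy_parameters()
  u <- typed_toy(5, n = 5)
  u2 <- classify_atoms(u, p)
  expect_identical(u$atoms, u2$atoms)
  bare <- u
  bare$atoms <- bare$atoms[!bare$atoms$is_hydrogen, ]
  expect_error(classify_atoms(bare, p), "no hydrogens")
  fallback <- classify_atoms(bare, p, require_hydrogens = FALSE)
  expect_true(any(fallback$atoms$donor))
})

test_that("orphan hydrogens are rejected", {
  p <- energy_parameters()
  u <- typed_toy(3, n = 4)
  far <- u
  k <- which(far$atoms$is_hydrogen)[1]
  far$atoms$x[k] <- far$atoms$x[k] + 50
  expect_error(classify_atoms(far, p), "orphan hydrogen")
})

test_that("ensemble round-trips through multi-model PDB", {
  p <- energy_parameters()
  a <- typed_toy(11, n = 5)
  b <- typed_toy(12, n = 5, chain = "B")
  ens <- ensemble_dock(list(a), list(b), p, dock_schedule(300),
                       target = c(3, 3), rng_seed = 7)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ens, path)
  txt <- readLines(path)
  expect_equal(sum(grepl("^MODEL", txt)), 3)
  expect_equal(sum(grepl("BINDING ENERGY", txt)), 3)
  for (k in 1:3) {
    m <- read_structure(path, k)
    expect_equal(nrow(m$atoms),
                 nrow(a$atoms) + nrow(b$atoms))
    # fixed block matches the stored member's fixed unit to PDB precision
    fixed_atoms <- m$atoms[seq_len(nrow(a$atoms)), ]
    expect_equal(fixed_atoms$x, ens$members[[k]]$fixed$atoms$x,
                 tolerance = 1e-3)
    expect_equal(fixed_atoms$name, ens$members[[k]]$fixed$atoms$name)
    expect_equal(fixed_atoms$resno, ens$members[[k]]$fixed$atoms$resno)
  }
  empty <- ens
  empty$members <- list()
  expect_error(write_ensemble(empty, path), "empty")
})

test_that("read_ensemble rebuilds members with re-evaluated energies", {
  p <- energy_parameters()
  pm <- protonation_model(7.2)
  # pools of different conformer sizes: models have unequal atom counts
  a1 <- typed_toy(61, n = 4)
  a2 <- typed_toy(62, n = 6)
  b <- typed_toy(63, n = 5, chain = "B")
  ens <- ensemble_dock(list(a1, a2), list(b), p, dock_schedule(500),
                       target = c(4, 4), tol = 0.02, rng_seed = 31,
                       pH = 7.2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ens, path)
  back <- read_ensemble(path, pm, p)
  expect_equal(length(back$members), 4)
  # energies survive the 0.001-A coordinate rounding
  expect_equal(back$energies, ens$energies, tolerance = 1e-6)
  expect_equal(vapply(back$members, `[[`, 0L, "n_contacts"),
               vapply(ens$members, `[[`, 0L, "n_contacts"))
})

test_that("single units round-trip write/read to PDB precision", {
  u <- typed_toy(21, n = 6)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(u, path)
  back <- read_structure(path)
  expect_equal(nrow(back$atoms), nrow(u$atoms))
  expect_equal(back$atoms$name, u$atoms$name)
  expect_equal(back$atoms$resno, u$atoms$resno)
  expect_equal(back$atoms$x, u$atoms$x, tolerance = 1e-3)
  expect_equal(back$atoms$y, u$atoms$y, tolerance = 1e-3)
  expect_equal(back$atoms$z, u$atoms$z, tolerance = 1e-3)
})
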