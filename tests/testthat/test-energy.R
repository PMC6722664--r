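p <- energy_parameters()

test_that("h-bond square well has the printed depth, cutoff and hard core", {
  expect_equal(hbond_energy(3.0, 2.75, p), -1)
  expect_equal(hbond_energy(3.2, 2.75, p), 0)   # half-open at the cutoff
  expect_equal(hbond_energy(2.75, 2.75, p), -1) # well includes sigma
  expect_true(is.na(hbond_energy(2.0, 2.75, p)))  # hard core
  expect_equal(hbond_energy(10, 2.75, p), 0)
  # empty well when sigma exceeds the cutoff
  expect_equal(hbond_energy(3.5, 3.4, p), 0)
  expect_error(hbond_energy(-1, 2.75, p))
})

test_that("electrostatic double well has printed geometry, magnitudes, signs", {
  expect_equal(electrostatic_energy(3.5, 3.0, +1, +1, p), +0.4)
  expect_equal(electrostatic_energy(5.0, 3.0, +1, -1, p), -0.12)
  expect_equal(electrostatic_energy(7.0, 3.0, +1, +1, p), 0)  # beyond 2.3s
  expect_equal(electrostatic_energy(4.2, 3.0, -1, -1, p), +0.12)
  expect_true(is.na(electrostatic_energy(2.9, 3.0, 1, 1, p)))
  expect_error(electrostatic_energy(3.5, 3.0, 0, 1, p), "nonzero")
  # derived magnitudes: salt-bridge / h-bond calibration, and the 0.3 ratio
  expect_equal(p$e_el1, 1.2 / 3.0)
  expect_equal(p$e_el2, 0.3 * p$e_el1)
})

test_that("hydropathy parameters follow HP_t = -s_t SASA_t / n_t, normalized", {
  expect_equal(hydropathy_parameter("C", p), -18 * 36 / 2 / 1000 / 3)
  expect_equal(hydropathy_parameter("C", p), -0.108)
  expect_equal(hydropathy_parameter("N+", p), 34 * 20 / 2 / 1000 / 3)
  expect_error(hydropathy_parameter("Zz", p), "unknown")
  # zero solvation parameter gives zero HP
  p0 <- energy_parameters(solvation_table = c(X = 0),
                          sasa_table = c(X = 50))
  expect_equal(hydropathy_parameter("X", p0), 0)
  # packaged magnitudes lie in the required band
  hp <- vapply(names(p$solvation_table), hydropathy_parameter,
               numeric(1), params = p)
  expect_true(all(abs(hp) >= 0.1 & abs(hp) <= 0.4))
})

test_that("hydropathy pair energy sums per-atom values inside 160% cutoff", {
  ai <- list(vdw_radius = 1.7, hp_class = "hydrophobic", hp_value = -0.15)
  aj <- list(vdw_radius = 1.7, hp_class = "hydrophobic", hp_value = -0.12)
  expect_equal(hydropathy_energy(ai, aj, 5.0, p), -0.27)   # < 1.6 * 3.4
  expect_equal(hydropathy_energy(ai, aj, 1.7 * 3.4, p), 0) # beyond cutoff
  hi <- list(vdw_radius = 1.52, hp_class = "hydrophilic", hp_value = 0.11)
  expect_equal(hydropathy_energy(hi, hi, 4.0, p), 0.22)
  # mixed pairs excluded by default, signed sum behind the flag
  expect_equal(hydropathy_energy(ai, hi, 4.0, p), 0)
  pmix <- energy_parameters(mixed_hydropathy = TRUE)
  expect_equal(hydropathy_energy(ai, hi, 4.0, pmix), -0.15 + 0.11)
  bare <- list(vdw_radius = 1.7, hp_class = "none", hp_value = 0)
  expect_error(hydropathy_energy(ai, bare, 3, p), "classified")
})

test_that("each pair potential is piecewise constant with at most 3 finite levels", {
  r <- seq(0.05, 12, by = 0.005)
  sig <- 3.0
  hb <- hbond_energy(r, sig, p)
  el <- electrostatic_energy(r + 1e-9, sig, 1, -1, p)
  expect_lte(length(unique(hb[!is.na(hb)])), 3)
  expect_lte(length(unique(el[!is.na(el)])), 3)
  ai <- list(vdw_radius = 1.5, hp_class = "hydrophobic", hp_value = -0.12)
  hp <- vapply(r, function(x) hydropathy_energy(ai, ai, x, p), numeric(1))
  expect_lte(length(unique(hp)), 3)
})

test_that("interface energy sums qualifying pairs additively", {
  pr <- donor_acceptor_pair()
  # place donor N at 3.1 A from acceptor O (sigma = 3.07): one h-bond
  pr$mobile$atoms$x <- c(-3.1, -5.1)
  ev <- interface_energy(pr$fixed, pr$mobile, p)
  expect_equal(ev$U, -1)
  expect_equal(ev$n_contacts, 1)
  expect_equal(ev$n_clashes, 0)
  # far apart: exact zero
  pr$mobile$atoms$x <- c(100, 102)
  far <- interface_energy(pr$fixed, pr$mobile, p)
  expect_equal(far$U, 0)
  expect_equal(far$n_contacts, 0)
  # h-bond (-1) plus a like-charge first-well pair (+0.4)
  fa <- rbind(
    flag_atom(1, "O", "O", 0, 0, 0, vdw = 1.52, acceptor = TRUE),
    flag_atom(2, "NZ", "N", 0, 6, 0, vdw = 1.55, charge = 1L))
  mb <- rbind(
    flag_atom(1, "N", "N", -3.1, 0, 0, vdw = 1.55, donor = TRUE,
              chain = "B"),
    flag_atom(2, "NZ", "N", 0, 9.5, 0, vdw = 1.55, charge = 1L,
              chain = "B"))
  ua <- structure_unit(fa, "a"); ub <- structure_unit(mb, "b")
  both <- interface_energy(ua, ub, p, pairs = TRUE)
  expect_equal(both$U, -1 + 0.4)
  expect_equal(both$n_contacts, 2)
  expect_setequal(both$pairs$kind, c("hbond", "electrostatic"))
  # a clash is counted and excluded from U
  mb2 <- mb; mb2$x[1] <- -2.0
  clashy <- interface_energy(ua, structure_unit(mb2, "b2"), p)
  expect_equal(clashy$n_clashes, 1)
  expect_equal(clashy$U, 0.4)
})

test_that("a dual-role pair contributes through both h-bond and electrostatics", {
  fa <- flag_atom(1, "OD1", "O", 0, 0, 0, vdw = 1.52, acceptor = TRUE,
                  charge = -1L)
  mb <- flag_atom(1, "NZ", "N", 3.1, 0, 0, vdw = 1.55, donor = TRUE,
                  charge = 1L, chain = "B")
  ev <- interface_energy(structure_unit(fa, "a"), structure_unit(mb, "b"),
                         p, pairs = TRUE)
  # r = 3.1: inside the h-bond well and the first electrostatic well
  expect_equal(ev$U, -1 - 0.4)
  expect_equal(nrow(ev$pairs), 2)
  expect_equal(ev$n_contacts, 1)
})

test_that("interface energy is symmetric and rigid-motion invariant", {
  set.seed(42)
  for (k in 1:5) {
    a <- typed_toy(100 + k, n = 6)
    b <- typed_toy(200 + k, n = 6, chain = "B")
    b$atoms$x <- b$atoms$x + 8   # partial overlap
    e_ab <- interface_energy(a, b, p)
    e_ba <- interface_energy(b, a, p)
    expect_equal(e_ab$U, e_ba$U, tolerance = 1e-12)
    expect_identical(e_ab$n_contacts, e_ba$n_contacts)
    expect_identical(e_ab$n_clashes, e_ba$n_clashes)
    mo <- random_rigid_motion()
    e_mv <- interface_energy(move_unit(a, mo), move_unit(b, mo), p)
    expect_equal(e_mv$U, e_ab$U, tolerance = 1e-9)
    expect_equal(e_mv$n_contacts, e_ab$n_contacts)
    expect_equal(e_mv$n_clashes, e_ab$n_clashes)
  }
})

test_that("cell-list evaluation equals the naive double loop and the R oracle", {
  set.seed(7)
  for (k in 1:20) {
    a <- typed_toy(300 + k, n = sample(3:10, 1))
    b <- typed_toy(400 + k, n = sample(3:10, 1), chain = "B")
    b$atoms$x <- b$atoms$x + runif(1, 0, 25)
    b$atoms$y <- b$atoms$y + runif(1, -5, 5)
    fast <- interface_energy(a, b, p)
    slow <- interface_energy(a, b, p, naive = TRUE)
    oracle <- brute_force_interface_energy(a, b, p)
    expect_equal(fast$U, slow$U, tolerance = 1e-12)
    expect_identical(fast$n_contacts, slow$n_contacts)
    expect_identical(fast$n_clashes, slow$n_clashes)
    expect_equal(fast$U, oracle$U, tolerance = 1e-9)
    expect_identical(fast$n_contacts, oracle$n_contacts)
    expect_identical(fast$n_clashes, oracle$n_clashes)
  }
})
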