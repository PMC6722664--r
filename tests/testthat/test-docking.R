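p <- energy_parameters()

test_that("poses apply and invert exactly", {
  set.seed(1)
  for (k in 1:10) {
    q <- swdock:::quat_normalize(rnorm(4))
    pose <- rigid_pose(q, runif(3, -10, 10))
    expect_equal(sum(pose$q^2), 1, tolerance = 1e-12)
    xyz <- matrix(rnorm(30), ncol = 3)
    ctr <- colMeans(xyz)
    fwd <- apply_pose(xyz, pose, ctr)
    back <- apply_pose(fwd, invert_pose(pose, ctr), pose$t)
    expect_equal(back, xyz, tolerance = 1e-9)
  }
})

test_that("initial placement is contact-free, deterministic, isotropic", {
  a <- typed_toy(31, n = 5)
  b <- typed_toy(32, n = 5, chain = "B")
  cu <- center_units(a, b)
  pose1 <- initial_placement(cu$fixed, cu$mobile, rng_seed = 5)
  pose2 <- initial_placement(cu$fixed, cu$mobile, rng_seed = 5)
  expect_identical(pose1, pose2)
  c0 <- mobile_center(cu$mobile)
  posed <- cu$mobile
  posed$atoms[, c("x", "y", "z")] <- apply_pose(unit_coords(cu$mobile),
                                               pose1, c0)
  ev <- interface_energy(cu$fixed, posed, p)
  expect_equal(ev$n_clashes, 0)
  expect_equal(ev$n_contacts, 0)
  # docking-axis directions cover all octants
  dirs <- t(vapply(1:1000, function(s)
    initial_placement(cu$fixed, cu$mobile, rng_seed = s)$t, numeric(3)))
  oct <- table(paste(dirs[, 1] > 0, dirs[, 2] > 0, dirs[, 3] > 0))
  expect_equal(length(oct), 8)
  expect_gt(stats::chisq.test(as.vector(oct))$p.value, 1e-4)
})

test_that("proposal moves respect their geometric contracts", {
  pose <- rigid_pose(c(1, 0, 0, 0), c(10, 0, 0))
  # translation-only proposals keep the center on the docking axis
  set.seed(2)
  tp <- pose
  for (k in 1:200) {
    tp <- propose_move(tp, c(rot_max = 0, trans_max = 1.5))
    cross <- c(tp$t[2] * 10 - 0, 0 - tp$t[3] * 10, 0)
    expect_lt(sqrt(sum(cross^2)) / sqrt(sum(tp$t^2)) / 10, 1e-6)
  }
  # rotation-only proposals keep the center fixed
  rp <- pose
  for (k in 1:200) {
    rp <- propose_move(rp, c(rot_max = 20, trans_max = 0))
  }
  expect_equal(rp$t, pose$t, tolerance = 1e-9)
  # quaternion stays unit after many proposals
  mp <- pose
  for (k in 1:2000) mp <- propose_move(mp, c(rot_max = 30, trans_max = 1))
  expect_equal(sum(mp$q^2), 1, tolerance = 1e-9)
})

test_that("mc_dock finds the single-h-bond optimum on 2-atom units", {
  pr <- donor_acceptor_pair()
  ok <- 0
  for (s in 1:20) {
    cx <- mc_dock(pr$fixed, pr$mobile, p, dock_schedule(20000),
                  rng_seed = s)
    if (cx$objective <= -1 + 1e-9) ok <- ok + 1
    # stored U always matches a fresh evaluation of the stored pose
    posed <- cx$mobile
    posed$atoms[, c("x", "y", "z")] <-
      apply_pose(unit_coords(cx$mobile), cx$pose, mobile_center(cx$mobile))
    re <- interface_energy(cx$fixed, posed, p)
    expect_equal(re$U, cx$U, tolerance = 1e-9)
    expect_identical(re$n_clashes, cx$n_clashes)
  }
  expect_gte(ok, 18)
})

test_that("mc_dock is deterministic and its best-so-far trace is monotone", {
  a <- typed_toy(33, n = 6)
  b <- typed_toy(34, n = 6, chain = "B")
  cx1 <- mc_dock(a, b, p, dock_schedule(3000), rng_seed = 9)
  cx2 <- mc_dock(a, b, p, dock_schedule(3000), rng_seed = 9)
  expect_identical(cx1$pose$q, cx2$pose$q)
  expect_identical(cx1$pose$t, cx2$pose$t)
  expect_identical(cx1$U, cx2$U)
  expect_true(all(diff(cx1$trace) <= 0))
  # acceptance rate strictly inside (0, 1) on an interacting system
  expect_gt(cx1$accepted, 0)
  expect_lt(cx1$accepted, 3000)
})

test_that("units without qualifying pairs end separated at zero energy", {
  fa <- flag_atom(1, "C", "C", 0, 0, 0)
  fb <- rbind(flag_atom(1, "C", "C", 8, 0, 0, chain = "B"),
              flag_atom(2, "C", "C", 10, 0, 0, chain = "B"))
  f <- structure_unit(fa, "inert-a")
  m <- structure_unit(fb, "inert-b")
  cx <- mc_dock(f, m, p, dock_schedule(2000), rng_seed = 3)
  expect_equal(cx$U, 0)
  expect_equal(cx$n_clashes, 0)
})

test_that("grid-search oracle agrees with mc_dock on toy systems", {
  pr <- donor_acceptor_pair()
  g <- grid_search_dock(pr$fixed, pr$mobile, p, resolution = c(0.5, 45))
  expect_equal(g$objective, -1)       # deepest attainable well
  ok <- 0
  for (s in 1:20) {
    cx <- mc_dock(pr$fixed, pr$mobile, p, dock_schedule(20000),
                  rng_seed = s)
    if (cx$objective <= g$objective + 0.05) ok <- ok + 1
  }
  expect_gte(ok, 18)
  # like charges only: repulsion-only landscape, optimum is zero
  lc <- like_charge_pair()
  g2 <- grid_search_dock(lc$fixed, lc$mobile, p, resolution = c(1.0, 60))
  expect_equal(g2$objective, 0)
  expect_error(grid_search_dock(pr$fixed, pr$mobile, p,
                                resolution = c(0.1, 5)), "grid too large")
})

test_that("the stopping rule triggers on stationary series and not before", {
  set.seed(11)
  u <- rnorm(400, mean = -18, sd = 1)
  rc <- running_convergence(u, tol = 0.02, window = 50)
  expect_true(any(rc$converged))
  first <- which(rc$converged)[1]
  expect_lt(first, 400)
  expect_gt(first, 51)
  # a strongly drifting series does not converge
  drift <- seq(0, -100, length.out = 200) + rnorm(200, 0, 0.1)
  rc2 <- running_convergence(drift, tol = 0.02, window = 50)
  expect_false(any(rc2$converged))
  expect_error(running_convergence(u, tol = 0), "tol")
})

test_that("ensemble docking converges, honors bounds and reproduces bit-identically", {
  a <- typed_toy(35, n = 5)
  b <- typed_toy(36, n = 5, chain = "B")
  ens <- ensemble_dock(list(a), list(b), p, dock_schedule(400),
                       target = c(10, 20), tol = 5, window = 5,
                       rng_seed = 21)
  expect_gte(length(ens$members), 10)
  expect_lte(length(ens$members), 20)
  expect_equal(nrow(ens$convergence), length(ens$members))
  ens2 <- ensemble_dock(list(a), list(b), p, dock_schedule(400),
                        target = c(10, 20), tol = 5, window = 5,
                        rng_seed = 21)
  expect_identical(ens$energies, ens2$energies)
  expect_identical(ens$members[[3]]$pose, ens2$members[[3]]$pose)
  expect_error(ensemble_dock(list(), list(b), p), "empty")
})

test_that("ensemble summary and energies table are consistent", {
  a <- typed_toy(37, n = 4)
  b <- typed_toy(38, n = 4, chain = "B")
  ens <- ensemble_dock(list(a), list(b), p, dock_schedule(200),
                       target = c(4, 4), tol = 0.02, rng_seed = 2)
  df <- as.data.frame(ens)
  expect_equal(nrow(df), 4)
  expect_equal(df$U, ens$energies)
  s <- summary(ens)
  expect_equal(s$n, 4)
  expect_equal(s$mean, mean(ens$energies))
})
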