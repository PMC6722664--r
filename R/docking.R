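# quaternion helpers (w, x, y, z)

quat_normalize <- function(q) q / sqrt(sum(q^2))

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Rotation matrix of a unit quaternion
#' @param q Unit quaternion `c(w, x, y, z)`.
#' @return 3x3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

random_quaternion <- function() {
  # uniform over SO(3) (Shoemake)
  u <- stats::runif(3)
  c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3]))
}

#' Construct a rigid pose
#'
#' A pose rotates the mobile unit about its own geometric center (unit
#' quaternion `q`) and places that center at the absolute position `t`.
#'
#' @param q Quaternion `c(w, x, y, z)`; normalized on construction.
#' @param t Center position, 3-vector in Angstrom.
#' @return Object of class `sw_pose`.
#' @export
rigid_pose <- function(q = c(1, 0, 0, 0), t = c(0, 0, 0)) {
  stopifnot(length(q) == 4, length(t) == 3, all(is.finite(c(q, t))))
  p <- list(q = quat_normalize(q), t = as.numeric(t))
  class(p) <- "sw_pose"
  p
}

#' @export
print.sw_pose <- function(x, ...) {
  cat(sprintf("<sw_pose> center (%.2f, %.2f, %.2f), |t| = %.2f A\n",
              x$t[1], x$t[2], x$t[3], sqrt(sum(x$t^2))))
  invisible(x)
}

#' Geometric center of a unit's heavy atoms
#' @param unit An `sw_unit`.
#' @return 3-vector.
#' @export
mobile_center <- function(unit) {
  at <- unit$atoms[!unit$atoms$is_hydrogen, , drop = FALSE]
  c(mean(at$x), mean(at$y), mean(at$z))
}

#' Apply a rigid pose to coordinates
#'
#' @param coords n x 3 matrix of original mobile coordinates.
#' @param pose An [rigid_pose()].
#' @param center Rotation center (the mobile unit's original geometric
#'   center).
#' @return Transformed n x 3 matrix.
#' @export
apply_pose <- function(coords, pose, center) {
  R <- quat_to_matrix(pose$q)
  sweep(sweep(coords, 2, center) %*% t(R), 2, pose$t, "+")
}

#' Invert a rigid pose
#'
#' If `pose` was applied with rotation center `center`, the returned pose,
#' applied to the transformed coordinates with rotation center `pose$t`
#' (where `center` maps to), recovers the original coordinates.
#'
#' @param pose An [rigid_pose()].
#' @param center Rotation center used with [apply_pose()].
#' @return The inverse `sw_pose`.
#' @export
invert_pose <- function(pose, center) {
  rigid_pose(c(pose$q[1], -pose$q[2:4]), center)
}

bounding_radius <- function(unit) {
  at <- unit$atoms[!unit$atoms$is_hydrogen, , drop = FALSE]
  ctr <- c(mean(at$x), mean(at$y), mean(at$z))
  sqrt(max((at$x - ctr[1])^2 + (at$y - ctr[2])^2 + (at$z - ctr[3])^2)) +
    max(at$vdw_radius, na.rm = TRUE)
}

#' Random contact-free initial placement along a docking axis
#'
#' The fixed unit is centered at the origin; the mobile unit receives a
#' uniformly random orientation and its center is placed along a uniformly
#' random direction (the docking axis) at a separation equal to the sum of
#' the two bounding radii plus 2 Angstrom, guaranteeing zero initial
#' contacts and clashes.
#'
#' @param fixed,mobile Typed `sw_unit`s.
#' @param rng_seed Optional integer; when given, `set.seed` is called so
#'   the placement is reproducible.
#' @return An `sw_pose` for the mobile unit (relative to units already
#'   centered with [center_units()]).
#' @export
initial_placement <- function(fixed, mobile, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  rf <- bounding_radius(fixed)
  rm_ <- bounding_radius(mobile)
  if (!is.finite(rf) || !is.finite(rm_))
    stop("degenerate unit: bounding radius undefined")
  axis <- random_unit_vector()
  q <- quat_normalize(stats::rnorm(4))
  rigid_pose(q, axis * (rf + rm_ + 2))
}

#' Propose a Monte Carlo rigid-body move
#'
#' With probability 1/2 a rotation of the mobile unit about its own center
#' by an angle uniform in (0, rot_max] about a random axis; otherwise a
#' translation along the current docking axis (the line from the fixed
#' center at the origin through the mobile center) of length uniform in
#' (0, trans_max], direction sign random. Translations that would bring
#' the mobile center closer than `min_separation` to the origin are
#' rejected (the input pose is returned).
#'
#' @param pose Current `sw_pose`.
#' @param step List or vector with `rot_max` (degrees) and `trans_max`
#'   (Angstrom).
#' @param min_separation Smallest allowed center-center distance.
#' @return A new `sw_pose`.
#' @export
propose_move <- function(pose, step = c(rot_max = 15, trans_max = 1.5),
                         min_separation = 0.5) {
  step <- as.list(step)
  stopifnot(step$rot_max >= 0, step$trans_max >= 0)
  if (stats::runif(1) < 0.5) {
    ang <- step$rot_max * pi / 180 * stats::runif(1)
    dq <- quat_from_axis_angle(random_unit_vector(), ang)
    rigid_pose(quat_multiply(dq, pose$q), pose$t)
  } else {
    s <- sqrt(sum(pose$t^2))
    d <- step$trans_max * stats::runif(1) * sign(stats::runif(1) - 0.5)
    s2 <- s + d
    if (s2 < min_separation) return(pose)
    rigid_pose(pose$q, pose$t * (s2 / s))
  }
}

#' Annealing schedule for the Monte Carlo search
#'
#' @param n_steps Number of MC steps.
#' @param t_start,t_end Start and end temperatures (h-bond units) of the
#'   geometric cooling schedule.
#' @param rot_max Maximum rotation per move, degrees.
#' @param trans_max Maximum translation per move, Angstrom.
#' @return A list of class `sw_schedule`.
#' @export
dock_schedule <- function(n_steps = 50000, t_start = 2.0, t_end = 0.05,
                          rot_max = 15, trans_max = 1.5) {
  stopifnot(n_steps >= 1, t_start > 0, t_end > 0)
  s <- list(n_steps = as.integer(n_steps), t_start = t_start, t_end = t_end,
            rot_max = rot_max, trans_max = trans_max)
  class(s) <- "sw_schedule"
  s
}

#' Translate both units so the fixed unit's center is at the origin
#' @param fixed,mobile `sw_unit`s.
#' @return List with shifted `fixed` and `mobile`.
#' @export
center_units <- function(fixed, mobile) {
  ctr <- mobile_center(fixed)
  shift <- function(u) {
    u$atoms$x <- u$atoms$x - ctr[1]
    u$atoms$y <- u$atoms$y - ctr[2]
    u$atoms$z <- u$atoms$z - ctr[3]
    u
  }
  list(fixed = shift(fixed), mobile = shift(mobile))
}

#' Monte Carlo rigid-body docking of one conformer pair
#'
#' Runs a Metropolis simulated-annealing search over the mobile unit's
#' pose (rotations about its center; translations along the docking axis)
#' minimizing the objective F = U + clash_weight * n_clashes, where U is
#' the square-well interface energy. The best pose visited is returned;
#' the recorded binding energy is the pure interface energy of that pose,
#' re-evaluated with [interface_energy()].
#'
#' @param fixed,mobile Typed `sw_unit`s.
#' @param params [energy_parameters()].
#' @param schedule [dock_schedule()].
#' @param rng_seed Integer seed; the run is bit-reproducible given
#'   (seed, inputs, parameters).
#' @return An object of class `sw_complex`: fixed/mobile units (centered),
#'   `pose`, `U`, `n_contacts`, `n_clashes`, `objective`, the per-pair
#'   interaction table, and the best-objective trace.
#' @export
mc_dock <- function(fixed, mobile, params = energy_parameters(),
                    schedule = dock_schedule(), rng_seed = 1L) {
  stopifnot(inherits(schedule, "sw_schedule"))
  check_typed(fixed, "fixed"); check_typed(mobile, "mobile")
  cu <- center_units(fixed, mobile)
  set.seed(rng_seed)
  pose0 <- initial_placement(cu$fixed, cu$mobile)
  pf <- pack_unit(cu$fixed)
  pm <- pack_unit(cu$mobile)
  c0 <- mobile_center(cu$mobile)
  # the walk is confined to the shell where interactions are possible:
  # beyond every pair cutoff the objective is identically zero
  s_max <- bounding_radius(cu$fixed) + bounding_radius(cu$mobile) +
    params$el_cutoff_scale * 2 * max(params$radii_table)
  run <- cpp_mc_dock(pf, pm, params, pose0$q, pose0$t, c0,
                     schedule$n_steps, schedule$t_start, schedule$t_end,
                     schedule$rot_max, schedule$trans_max, 0.5, s_max)
  pose <- rigid_pose(run$q, run$t)
  posed <- cu$mobile
  posed$atoms[, c("x", "y", "z")] <-
    apply_pose(unit_coords(cu$mobile), pose, c0)
  ev <- interface_energy(cu$fixed, posed, params, pairs = TRUE)
  cx <- list(fixed = cu$fixed, mobile = cu$mobile, pose = pose,
             fixed_source = cu$fixed$source, mobile_source = cu$mobile$source,
             U = ev$U, n_contacts = ev$n_contacts,
             n_clashes = ev$n_clashes,
             objective = ev$U + params$clash_weight * ev$n_clashes,
             interactions = ev$pairs, trace = run$trace,
             accepted = run$accepted, seed = rng_seed)
  class(cx) <- "sw_complex"
  cx
}

#' @export
print.sw_complex <- function(x, ...) {
  cat(sprintf(
    "<sw_complex> U = %.3f h-bond units, %d contacts, %d clashes (seed %d)\n",
    x$U, x$n_contacts, x$n_clashes, x$seed))
  invisible(x)
}

#' Running-convergence check on a binding-energy series
#'
#' The ensemble stops growing when, over the last `window` additions, the
#' running mean and running standard deviation have both moved by less
#' than `tol` times the current standard deviation.
#'
#' @param u Numeric vector of binding energies, in arrival order.
#' @param tol Relative tolerance (default 0.02).
#' @param window Number of trailing additions compared (default 50).
#' @return List with `mean`, `sd` (running traces) and `converged`
#'   (logical vector per index).
#' @export
running_convergence <- function(u, tol = 0.02, window = 50) {
  stopifnot(tol > 0, window >= 1)
  n <- length(u)
  cm <- cumsum(u) / seq_len(n)
  cs <- vapply(seq_len(n), function(k)
    if (k < 2) NA_real_ else stats::sd(u[seq_len(k)]), numeric(1))
  conv <- rep(FALSE, n)
  idx <- which(seq_len(n) > window + 1)
  for (k in idx) {
    s <- cs[k]
    if (!is.na(s) && s > 0 &&
        abs(cm[k] - cm[k - window]) < tol * s &&
        abs(cs[k] - cs[k - window]) < tol * s)
      conv[k] <- TRUE
  }
  list(mean = cm, sd = cs, converged = conv)
}

# evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# counter-based per-run seed stream: independent of execution order
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(2147483646L, n, replace = FALSE))
}

#' Monte Carlo ensemble docking over conformer pools
#'
#' Repeatedly draws a (fixed, mobile) conformer pair uniformly with
#' replacement, docks it with [mc_dock()] under a per-run seed derived
#' from the master seed by a counter-based stream, and appends the result
#' until the running mean and standard deviation of the binding energy
#' both converge (see [running_convergence()]) with at least `target[1]`
#' members, or until `target[2]` members. Tetramer (dimer-of-dimers) mode
#' is the same call with pools of dimers re-read as rigid units.
#'
#' @param pool_a,pool_b Lists of typed `sw_unit` conformers (the fixed and
#'   mobile pools).
#' @param params [energy_parameters()].
#' @param schedule [dock_schedule()].
#' @param target Length-2 integer vector: (min, max) ensemble size;
#'   defaults to the dimer production range `c(1000, 1500)`.
#' @param tol,window Convergence tolerance and window.
#' @param rng_seed Master seed.
#' @param pH Annotation only (recorded on the ensemble).
#' @param progress Print a line every `progress` members (0 = quiet).
#' @return Object of class `sw_ensemble`: `members` (list of
#'   `sw_complex`), `energies`, `convergence` data frame (n, running mean,
#'   running sd), `converged`, `pH`, `seed`, `target`.
#' @export
ensemble_dock <- function(pool_a, pool_b, params = energy_parameters(),
                          schedule = dock_schedule(),
                          target = c(1000L, 1500L), tol = 0.02,
                          window = 50L, rng_seed = 1L, pH = NA_real_,
                          progress = 0) {
  if (!length(pool_a) || !length(pool_b)) stop("empty conformer pool")
  stopifnot(tol > 0, length(target) == 2, target[2] >= target[1],
            target[1] >= 2)
  n_max <- as.integer(target[2])
  seeds <- derive_seeds(rng_seed, n_max)
  picks <- with_seed(rng_seed + 1,
    cbind(sample.int(length(pool_a), n_max, replace = TRUE),
          sample.int(length(pool_b), n_max, replace = TRUE)))
  members <- vector("list", n_max)
  u <- numeric(0)
  converged <- FALSE
  n <- 0L
  while (n < n_max) {
    n <- n + 1L
    cx <- mc_dock(pool_a[[picks[n, 1]]], pool_b[[picks[n, 2]]],
                  params, schedule, rng_seed = seeds[n])
    members[[n]] <- cx
    u[n] <- cx$U
    if (progress > 0 && n %% progress == 0)
      message(sprintf("  member %d: U = %.3f", n, cx$U))
    if (n >= max(target[1], window + 2L)) {
      rc <- running_convergence(u, tol, window)
      if (rc$converged[n]) { converged <- TRUE; break }
    }
  }
  members <- members[seq_len(n)]
  rc <- running_convergence(u, tol, window)
  ens <- list(members = members, energies = u,
              convergence = data.frame(n = seq_len(n), mean = rc$mean,
                                       sd = rc$sd),
              converged = converged, pH = pH, seed = rng_seed,
              target = as.integer(target), tol = tol, window = window)
  class(ens) <- "sw_ensemble"
  ens
}

#' @export
print.sw_ensemble <- function(x, ...) {
  cat(sprintf("<sw_ensemble> %d members%s, seed %s\n",
              length(x$members),
              if (x$converged) " (converged)" else "", format(x$seed)))
  if (length(x$energies) > 1)
    cat(sprintf("  binding energy: mean %.3f, sd %.3f h-bond units\n",
                mean(x$energies), stats::sd(x$energies)))
  invisible(x)
}

#' @export
summary.sw_ensemble <- function(object, ...) {
  u <- object$energies
  s <- list(n = length(u), mean = mean(u), sd = stats::sd(u),
            range = range(u),
            contacts = mean(vapply(object$members, `[[`, 0, "n_contacts")),
            clashes = mean(vapply(object$members, `[[`, 0, "n_clashes")),
            converged = object$converged)
  class(s) <- "summary.sw_ensemble"
  s
}

#' @export
print.summary.sw_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d docked complexes%s\n", x$n,
              if (x$converged) " (converged)" else " (max size reached)"))
  cat(sprintf("  U: mean %.3f, sd %.3f, range [%.3f, %.3f]\n",
              x$mean, x$sd, x$range[1], x$range[2]))
  cat(sprintf("  mean contacts %.1f, mean clashes %.1f\n",
              x$contacts, x$clashes))
  invisible(x)
}

#' @export
as.data.frame.sw_ensemble <- function(x, ...) {
  data.frame(member = seq_along(x$members),
             U = x$energies,
             n_contacts = vapply(x$members, `[[`, 0L, "n_contacts"),
             n_clashes = vapply(x$members, `[[`, 0L, "n_clashes"),
             seed = vapply(x$members, `[[`, 0L, "seed"))
}

#' Binding-energy density plot of an ensemble
#' @param x An `sw_ensemble`.
#' @param ... Passed to [binding_energy_density()].
#' @return Invisibly, the `sw_density`.
#' @export
plot.sw_ensemble <- function(x, ...) {
  d <- binding_energy_density(x, ...)
  plot(d)
  invisible(d)
}
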