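#' Simulation configuration
#'
#' Time is measured in units of \eqn{\tau}, the average time for a free
#' adhesin-sized particle to diffuse one unit length.  Interpreting this as
#' \eqn{\langle|\Delta r|^2\rangle = \sigma_P^2} at \eqn{t = \tau} in 3D gives
#' a free-particle diffusivity \eqn{D_P = \sigma_P^2/(6\tau)} and hence, via
#' \eqn{D = k_B T/(\gamma m)}, the friction rate `friction_gamma = 6` per unit
#' atom mass.  A cell of \eqn{n} atoms receives drag summed over its
#' constituent atoms, which works out to the same rate \eqn{\gamma = 6}
#' applied to both its translational and rotational Langevin updates.
#'
#' Two presets are provided.  `"paper"` pins the full published schedule
#' (512 cells in a 500^3 periodic box, 8e8 tau equilibration, 300 recorded
#' configurations, compression over 2e7 tau from plate separation 500 to 50);
#' it is far beyond interactive scale and exists as a record of those values.
#' `"desk"` is the working preset: 64 cells in a 160^3 box (number density
#' within 2x of the published system), 2e5 tau equilibration, 10 recorded
#' configurations over 1e4 tau, compression over 5e3 tau to a plate gap of 16
#' (the same 10:1 height reduction).
#'
#' @param preset `"desk"`, `"paper"` or `"custom"` (start from desk values).
#' @param ... named overrides of any field below.
#' @return An object of class `sim_config` with fields `n_cells`,
#'   `box_lengths`, `kBT`, `tau`, `dt`, `t_equilibrate`, `t_record_window`,
#'   `record_interval`, `t_compress`, `plate_final_gap`, `n_replicates`,
#'   `seed`, `friction_gamma`, `particle_mass`.
#' @export
sim_config <- function(preset = c("desk", "paper", "custom"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    n_cells = 64, box_lengths = c(160, 160, 160), kBT = 1, tau = 1,
    dt = 0.05, t_equilibrate = 2e5, t_record_window = 1e4,
    record_interval = 1e3, t_compress = 5e3, plate_final_gap = 16,
    n_replicates = 5, seed = 1, friction_gamma = 6, particle_mass = 1)
  if (preset == "paper") {
    cfg$n_cells <- 512
    cfg$box_lengths <- c(500, 500, 500)
    cfg$t_equilibrate <- 8e8
    cfg$t_record_window <- 1.5e8
    cfg$record_interval <- 0.5e6
    cfg$t_compress <- 2e7
    cfg$plate_final_gap <- 50
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown sim_config fields: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$dt > 0, cfg$n_cells >= 1, all(cfg$box_lengths > 0),
            cfg$kBT >= 0, cfg$friction_gamma >= 0, cfg$particle_mass > 0)
  nrec <- cfg$t_record_window / cfg$record_interval
  if (abs(nrec - round(nrec)) > 1e-9)
    stop("record_interval must divide t_record_window")
  structure(c(cfg, list(preset = preset)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config (", x$preset, "): ", x$n_cells, " cells in ",
      paste(x$box_lengths, collapse = " x "), " box\n", sep = "")
  cat("  dt =", x$dt, " equilibrate", x$t_equilibrate, "tau, record",
      x$t_record_window, "tau every", x$record_interval, "tau\n")
  cat("  compress over", x$t_compress, "tau to gap", x$plate_final_gap, "\n")
  invisible(x)
}

#' Minimum-image displacement
#'
#' Maps each displacement component into the half-open interval
#' \eqn{(-L/2, L/2]} of a periodic box.
#'
#' @param d displacement vector or n x 3 matrix.
#' @param box box lengths (length 3, or scalar recycled).
#' @return Same shape as `d`.
#' @export
minimum_image <- function(d, box) {
  if (is.matrix(d)) {
    for (k in seq_len(ncol(d)))
      d[, k] <- d[, k] - box[min(k, length(box))] *
        ceiling(d[, k] / box[min(k, length(box))] - 0.5)
    return(d)
  }
  box <- rep_len(box, length(d))
  d - box * ceiling(d / box - 0.5)
}

#' Place cells in the box
#'
#' Cell centers are drawn by rejection sampling with a minimum center-center
#' distance of `2 * sigma_B` (no body overlap, periodic metric), orientations
#' are uniform random unit quaternions, and velocities are Maxwell-Boltzmann
#' at `kBT` for the cell mass and isotropic inertia of the template.
#' Deterministic given `seed`; the caller's RNG state is untouched.
#'
#' @param config a [sim_config()].
#' @param template a [build_cell_template()] object.
#' @param params a [cell_params()] object.
#' @param seed integer seed (default `config$seed`).
#' @return An object of class `system_state`: matrices `pos` (n x 3, wrapped
#'   into the box), `quat` (n x 4, unit), `vel`, `angvel`, plus `box`, `time`,
#'   `body_radius`, and `plates` (NULL until compression).
#' @export
initialize_system <- function(config, template, params = cell_params(),
                              seed = config$seed) {
  n <- config$n_cells
  box <- config$box_lengths
  with_seed(seed, function() {
    pos <- matrix(NA_real_, n, 3)
    placed <- 0
    attempts <- 0
    max_attempts <- 1000 * n
    dmin2 <- (2 * params$sigma_B)^2
    while (placed < n) {
      attempts <- attempts + 1
      if (attempts > max_attempts)
        stop("infeasible density: failed to place ", n, " cells with minimum ",
             "separation ", 2 * params$sigma_B, " after ", max_attempts,
             " attempts")
      cand <- runif(3) * box
      if (placed > 0) {
        dd <- minimum_image(sweep(pos[seq_len(placed), , drop = FALSE], 2,
                                  cand), box)
        if (min(rowSums(dd^2)) < dmin2) next
      }
      placed <- placed + 1
      pos[placed, ] <- cand
    }
    quat <- matrix(rnorm(4 * n), n, 4)
    quat <- quat / sqrt(rowSums(quat^2))
    m <- template$mass * config$particle_mass
    inr <- template$inertia * config$particle_mass
    vel <- matrix(rnorm(3 * n, sd = sqrt(config$kBT / m)), n, 3)
    angvel <- matrix(rnorm(3 * n, sd = sqrt(config$kBT / inr)), n, 3)
    structure(list(pos = pos, quat = quat, vel = vel, angvel = angvel,
                   box = box, time = 0, body_radius = params$sigma_B,
                   plates = NULL),
              class = "system_state")
  })
}

#' @export
print.system_state <- function(x, ...) {
  cat("system_state:", nrow(x$pos), "cells, box",
      paste(x$box, collapse = " x "), " t =", x$time, "\n")
  if (!is.null(x$plates))
    cat("  plates at z =", signif(x$plates[1], 6), "/",
        signif(x$plates[2], 6), "\n")
  invisible(x)
}

#' Forces and torques on every cell
#'
#' Sums the B-B, B-P and P-P pair interactions between distinct cells under
#' the minimum-image convention; intra-cell pairs are excluded (the molecule
#' is rigid).  Torques are taken about each cell center from the forces on
#' its adhesins.
#'
#' @param state a `system_state`.
#' @param template the cell template.
#' @param params pair-potential parameters.
#' @param method `"neighbor"` (Verlet pair list, the production path) or
#'   `"brute"` (all cell pairs, all atom pairs; reference path).
#' @return List with `force` (n x 3), `torque` (n x 3) and total potential
#'   `energy`.
#' @export
compute_forces <- function(state, template, params = cell_params(),
                           method = c("neighbor", "brute")) {
  method <- match.arg(method)
  cpp_forces(state$pos, state$quat, template$local_coords, state$box,
             unclass(params), wrap_z = is.null(state$plates), method = method)
}

# shared driver for advance_state / run_phase
run_dynamics <- function(state, template, params, config, n_steps, seed,
                         record_every = 0L, plates = NULL, diag_every = 0L,
                         dt = config$dt, kBT = config$kBT,
                         gamma = config$friction_gamma) {
  m <- template$mass * config$particle_mass
  inr <- template$inertia * config$particle_mass
  out <- cpp_run_phase(state$pos, state$quat, state$vel, state$angvel,
                       template$local_coords, state$box, unclass(params),
                       as.integer(n_steps), dt, kBT, gamma, m, inr,
                       as.numeric(seed), as.integer(record_every),
                       plates, wrap_z = is.null(plates) && is.null(state$plates),
                       diag_every = as.integer(diag_every))
  new <- state
  new$pos <- out$pos
  new$quat <- out$quat
  new$vel <- out$vel
  new$angvel <- out$angvel
  new$time <- state$time + n_steps * dt
  if (!is.null(plates)) new$plates <- c(out$plate_lo, out$plate_hi)
  list(state = new, raw = out)
}

#' Advance the system by Langevin dynamics
#'
#' One or more BAOAB Langevin steps: half-kick, half-drift,
#' Ornstein-Uhlenbeck velocity refresh at `kBT`, half-drift, half-kick, with
#' quaternion orientations rotated by the angular velocity and renormalized,
#' so the rigid geometry is preserved exactly.  With `gamma = 0` the update
#' reduces to velocity Verlet (no noise, no drag).
#'
#' @inheritParams compute_forces
#' @param config a [sim_config()] (supplies `dt`, `kBT`, friction, mass).
#' @param n_steps number of steps.
#' @param seed seed for the thermostat noise stream.
#' @param kBT,gamma,dt optional overrides of the config values.
#' @param diag_every if positive, kinetic/potential energy recorded every
#'   that many steps (returned as attribute `"diagnostics"`).
#' @return The updated `system_state`.
#' @export
advance_state <- function(state, config, template, params = cell_params(),
                          n_steps = 1, seed = config$seed,
                          kBT = config$kBT, gamma = config$friction_gamma,
                          dt = config$dt, diag_every = 0) {
  r <- run_dynamics(state, template, params, config, n_steps, seed,
                    diag_every = diag_every, dt = dt, kBT = kBT,
                    gamma = gamma)
  st <- r$state
  if (diag_every > 0) attr(st, "diagnostics") <- r$raw$diagnostics
  st
}

#' Run one protocol phase
#'
#' * `"equilibrate"`: advance `t_equilibrate` with no snapshots.
#' * `"record"`: advance `t_record_window`, taking a snapshot every
#'   `record_interval` (exactly `t_record_window / record_interval`
#'   snapshots).
#' * `"compress"`: uniaxial plate compression.  Two repulsive walls
#'   (one-sided WCA per atom in the wall-normal coordinate) start one wall
#'   cutoff outside the z faces of the box and close at constant speed to a
#'   centered gap of `plate_final_gap` over `t_compress`.  The z direction
#'   stops being periodic for the rest of the state's life.
#'
#' @inheritParams advance_state
#' @param phase one of `"equilibrate"`, `"record"`, `"compress"`.
#' @return A list with `state` (final state) and, for the record phase,
#'   `trajectory` (class `trajectory`: snapshot list, times, box, seed).
#' @export
run_phase <- function(state, config, template, params = cell_params(),
                      phase = c("equilibrate", "record", "compress"),
                      seed = config$seed) {
  phase <- match.arg(phase)
  dt <- config$dt
  if (phase == "equilibrate") {
    n_steps <- round(config$t_equilibrate / dt)
    r <- run_dynamics(state, template, params, config, n_steps, seed)
    return(list(state = r$state, trajectory = NULL))
  }
  if (phase == "record") {
    n_steps <- round(config$t_record_window / dt)
    rec <- round(config$record_interval / dt)
    r <- run_dynamics(state, template, params, config, n_steps, seed,
                      record_every = rec)
    traj <- structure(list(snapshots = r$raw$snapshots,
                           times = state$time + r$raw$snapshot_times,
                           box = state$box, seed = seed,
                           pattern = template$pattern),
                      class = "trajectory")
    return(list(state = r$state, trajectory = traj))
  }
  # compress
  if (!is.null(state$plates)) stop("state is already compressed")
  lz <- state$box[3]
  margin <- 2^(1 / 6) * state$body_radius
  gap <- config$plate_final_gap
  plates <- c(-margin, lz + margin, lz / 2 - gap / 2, lz / 2 + gap / 2)
  n_steps <- round(config$t_compress / dt)
  r <- run_dynamics(state, template, params, config, n_steps, seed,
                    plates = plates)
  list(state = r$state, trajectory = NULL)
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", length(x$snapshots), "snapshots, t in [",
      min(x$times), ",", max(x$times), "], box",
      paste(x$box, collapse = " x "), "\n")
  invisible(x)
}

#' Rebuild a full system state from a recorded snapshot
#'
#' @param trajectory a `trajectory` from the record phase.
#' @param i snapshot index.
#' @param body_radius body-sphere radius carried into the new state.
#' @return A `system_state`.
#' @export
state_from_snapshot <- function(trajectory, i, body_radius = 5) {
  s <- trajectory$snapshots[[i]]
  structure(list(pos = s$pos, quat = s$quat, vel = s$vel, angvel = s$angvel,
                 box = trajectory$box, time = trajectory$times[i],
                 body_radius = body_radius, plates = NULL),
            class = "system_state")
}

# world-frame rotation of body-frame coordinates by unit quaternion q
quat_rotate <- function(q, coords) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  coords %*% t(R)
}

#' World coordinates of every adhesin
#'
#' Derived on demand from the cell centers and quaternions (adhesin positions
#' are never stored independently).
#'
#' @param state a `system_state`.
#' @param template the cell template.
#' @return Array `n_cells x n_adhesins x 3` of absolute (unwrapped relative
#'   to each center) adhesin positions.
#' @export
adhesin_positions <- function(state, template) {
  n <- nrow(state$pos)
  na <- template$n_adhesins
  out <- array(NA_real_, c(n, na, 3))
  for (c in seq_len(n)) {
    u <- quat_rotate(state$quat[c, ], template$local_coords)
    out[c, , ] <- sweep(u, 2, state$pos[c, ], "+")
  }
  out
}
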