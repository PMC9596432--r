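cfg_small <- sim_config("desk", n_cells = 8, box_lengths = c(120, 120, 120),
                        t_equilibrate = 50, t_record_window = 10,
                        record_interval = 2, t_compress = 500,
                        plate_final_gap = 24)

test_that("minimum image maps into (-L/2, L/2] with the fixed convention", {
  expect_equal(minimum_image(c(499, 0, 0), 500), c(-1, 0, 0))
  # boundary convention: both +L/2 and -L/2 map to +L/2
  expect_equal(minimum_image(c(250, -250, 0), 500), c(250, 250, 0))
  set.seed(4)
  d <- matrix(runif(300, -900, 900), 100, 3)
  m <- minimum_image(d, c(500, 300, 120))
  expect_true(all(abs(m) <= abs(d) + 1e-12))
  expect_true(all(m[, 1] > -250 & m[, 1] <= 250))
  expect_true(all(m[, 3] > -60 & m[, 3] <= 60))
})

test_that("initialization respects the minimum separation and the seed", {
  tmpl <- get_template("dispersed")
  cfg <- sim_config("desk", n_cells = 24, box_lengths = c(120, 120, 120))
  s1 <- initialize_system(cfg, tmpl, default_params, seed = 5)
  s2 <- initialize_system(cfg, tmpl, default_params, seed = 5)
  expect_identical(s1, s2)
  d <- as.matrix(dist(s1$pos))  # box is wide; also check periodic metric
  for (i in 1:23) for (j in (i + 1):24) {
    dd <- minimum_image(s1$pos[i, ] - s1$pos[j, ], s1$box)
    expect_gte(sqrt(sum(dd^2)), 10)
  }
  expect_equal(sqrt(rowSums(s1$quat^2)), rep(1, 24), tolerance = 1e-12)
})

test_that("overpacked boxes raise an infeasible-density error", {
  tmpl <- get_template("dispersed")
  cfg <- sim_config("desk", n_cells = 60, box_lengths = c(40, 40, 40))
  expect_error(initialize_system(cfg, tmpl, default_params, seed = 1),
               "infeasible density")
})

test_that("forces are zero beyond all cutoffs and obey Newton's third law", {
  tmpl <- get_template("dispersed")
  far <- two_cell_state(40)
  f <- compute_forces(far, tmpl, default_params)
  expect_equal(f$force, matrix(0, 2, 3))
  expect_equal(f$torque, matrix(0, 2, 3))
  expect_equal(f$energy, 0)
  # random dense configuration: total force is zero
  cfg <- sim_config("desk", n_cells = 24, box_lengths = c(60, 60, 60))
  st <- initialize_system(cfg, tmpl, default_params, seed = 8)
  f <- compute_forces(st, tmpl, default_params)
  expect_equal(colSums(f$force), c(0, 0, 0), tolerance = 1e-12)
})

test_that("neighbor-list forces equal all-pairs forces on random systems", {
  for (pat in c("dispersed", "localized")) {
    tmpl <- get_template(pat)
    cfg <- sim_config("desk", n_cells = 32, box_lengths = c(70, 70, 70))
    st <- initialize_system(cfg, tmpl, default_params, seed = 21)
    fn <- compute_forces(st, tmpl, default_params, method = "neighbor")
    fb <- compute_forces(st, tmpl, default_params, method = "brute")
    expect_lt(max(abs(fn$force - fb$force)), 1e-10)
    expect_lt(max(abs(fn$torque - fb$torque)), 1e-10)
    expect_lt(abs(fn$energy - fb$energy), 1e-10)
  }
})

test_that("aligned adhesin pairs produce the expected binding energy", {
  tmpl <- get_template("dispersed")
  # rotate adhesin 1 of cell 1 onto +x and of cell 2 onto -x; at center
  # distance 12.2 the two adhesin tips sit 0.2 apart
  st <- two_cell_state(12.2, face = FALSE)
  st$quat[1, ] <- quat_from_to(tmpl$local_coords[1, ], c(1, 0, 0))
  st$quat[2, ] <- quat_from_to(tmpl$local_coords[1, ], c(-1, 0, 0))
  f <- compute_forces(st, tmpl, default_params)
  # aligned tips contribute E_PP(0.2); each tip also feels the other body's
  # B-P repulsion at 6.2; everything else is beyond cutoff
  expected <- pair_energy_adhesin(0.2, -8, 1) +
    2 * pair_energy_repulsive(6.2, 5, 1)
  expect_equal(f$energy, expected, tolerance = 1e-6)
  expect_lt(f$energy, -10)
})

test_that("zero-temperature, zero-force dynamics is a fixed point", {
  tmpl <- get_template("dispersed")
  st <- two_cell_state(60)
  out <- advance_state(st, cfg_small, tmpl, default_params, n_steps = 100,
                       seed = 1, kBT = 0, gamma = 0)
  expect_equal(out$pos, st$pos)
  expect_equal(out$quat, st$quat)
  expect_equal(out$vel, st$vel)
})

test_that("velocity decays as exp(-gamma t) at zero temperature", {
  tmpl <- get_template("dispersed")
  st <- two_cell_state(100)
  st$vel[1, ] <- c(0.3, -0.2, 0.1)
  n <- 400
  out <- advance_state(st, cfg_small, tmpl, default_params, n_steps = n,
                       seed = 1, kBT = 0, gamma = 6)
  expected <- st$vel[1, ] * exp(-6 * n * cfg_small$dt)
  expect_equal(out$vel[1, ], expected, tolerance = 1e-10)
})

test_that("rigid geometry and unit quaternions survive 10^4 steps", {
  tmpl <- get_template("dispersed")
  cfg <- sim_config("desk", n_cells = 8, box_lengths = c(60, 60, 60))
  st <- initialize_system(cfg, tmpl, default_params, seed = 2)
  out <- advance_state(st, cfg, tmpl, default_params, n_steps = 1e4,
                       seed = 3)
  expect_equal(sqrt(rowSums(out$quat^2)), rep(1, 8), tolerance = 1e-9)
  ap <- adhesin_positions(out, tmpl)
  for (c in 1:8) {
    off <- sweep(matrix(ap[c, , ], ncol = 3), 2, out$pos[c, ])
    expect_equal(sqrt(rowSums(off^2)), rep(6, 19), tolerance = 1e-9)
  }
})

test_that("momentum is conserved with the thermostat off", {
  tmpl <- get_template("dispersed")
  cfg <- sim_config("desk", n_cells = 12, box_lengths = c(50, 50, 50))
  st <- initialize_system(cfg, tmpl, default_params, seed = 9)
  p0 <- colSums(st$vel) * tmpl$mass
  out <- advance_state(st, cfg, tmpl, default_params, n_steps = 2000,
                       seed = 1, kBT = 0, gamma = 0)
  expect_equal(colSums(out$vel) * tmpl$mass, p0, tolerance = 1e-9)
})

test_that("total energy is conserved with thermostat off at reduced dt", {
  tmpl <- get_template("dispersed")
  cfg <- sim_config("desk", n_cells = 8, box_lengths = c(42, 42, 42),
                    dt = 0.005)
  st <- initialize_system(cfg, tmpl, default_params, seed = 14)
  st$vel <- st$vel * 0.3   # mild speeds, several interacting pairs
  out <- advance_state(st, cfg, tmpl, default_params, n_steps = 1e4,
                       seed = 1, kBT = 0, gamma = 0, diag_every = 100)
  d <- attr(out, "diagnostics")
  etot <- d$kinetic + d$potential
  scale <- max(abs(etot[1]), max(d$kinetic))
  drift <- max(abs(etot - etot[1])) / scale
  expect_lt(drift, 1e-3)
})

test_that("single-cell kinetic energy satisfies equipartition", {
  tmpl <- get_template("dispersed")
  cfg <- sim_config("desk", n_cells = 4, box_lengths = c(1e4, 1e4, 1e4))
  st <- initialize_system(cfg, tmpl, default_params, seed = 3)
  r <- piliagg:::run_dynamics(st, tmpl, default_params, cfg,
                              n_steps = 1.2e5, seed = 11, record_every = 40)
  v <- do.call(rbind, lapply(r$raw$snapshots, function(s) s$vel))
  w <- do.call(rbind, lapply(r$raw$snapshots, function(s) s$angvel))
  expect_equal(0.5 * tmpl$mass * mean(v^2), 0.5, tolerance = 0.05)
  expect_equal(0.5 * tmpl$inertia * mean(w^2), 0.5, tolerance = 0.05)
})

test_that("free cell diffuses with D = kBT / (gamma * mass)", {
  tmpl <- get_template("dispersed")
  cfg <- sim_config("desk", n_cells = 12, box_lengths = c(1e5, 1e5, 1e5))
  st <- initialize_system(cfg, tmpl, default_params, seed = 5)
  r <- piliagg:::run_dynamics(st, tmpl, default_params, cfg,
                              n_steps = 2e5, seed = 13, record_every = 200)
  pos <- lapply(r$raw$snapshots, function(s) s$pos)
  nt <- length(pos)
  dt_snap <- 200 * cfg$dt
  # time-averaged MSD over all origins at a handful of lags (box huge:
  # trajectories never wrapped)
  lags <- c(20, 40, 80, 160)
  msd <- vapply(lags, function(L) {
    mean(vapply(seq_len(nt - L), function(i)
      mean(rowSums((pos[[i + L]] - pos[[i]])^2)), 1))
  }, 1)
  fit <- stats::lm(msd ~ I(lags * dt_snap))
  D_fit <- unname(stats::coef(fit)[2]) / 6
  D_expect <- 1 / (6 * tmpl$mass)   # kBT/(gamma m), gamma = 6, m = 20
  expect_equal(D_fit, D_expect, tolerance = 0.1)
})

test_that("dynamics is bit-reproducible from the seed", {
  tmpl <- get_template("localized")
  cfg <- sim_config("desk", n_cells = 10, box_lengths = c(60, 60, 60))
  st <- initialize_system(cfg, tmpl, default_params, seed = 4)
  a <- advance_state(st, cfg, tmpl, default_params, n_steps = 3000, seed = 8)
  b <- advance_state(st, cfg, tmpl, default_params, n_steps = 3000, seed = 8)
  expect_identical(a$pos, b$pos)
  expect_identical(a$quat, b$quat)
  expect_identical(a$vel, b$vel)
  c_ <- advance_state(st, cfg, tmpl, default_params, n_steps = 3000, seed = 9)
  expect_false(identical(a$pos, c_$pos))
})

test_that("record phase emits exactly window/interval snapshots", {
  tmpl <- get_template("dispersed")
  st <- initialize_system(cfg_small, tmpl, default_params, seed = 6)
  out <- run_phase(st, cfg_small, tmpl, default_params, "record", seed = 2)
  expect_equal(length(out$trajectory$snapshots),
               cfg_small$t_record_window / cfg_small$record_interval)
  expect_true(all(diff(out$trajectory$times) > 0))
})

test_that("plate compression confines every cell between the plates", {
  tmpl <- get_template("dispersed")
  st <- initialize_system(cfg_small, tmpl, default_params, seed = 7)
  out <- run_phase(st, cfg_small, tmpl, default_params, "compress", seed = 3)
  plates <- out$state$plates
  expect_equal(plates[2] - plates[1], cfg_small$plate_final_gap)
  sb <- default_params$sigma_B
  expect_true(all(out$state$pos[, 3] >= plates[1] + sb - 1.5))
  expect_true(all(out$state$pos[, 3] <= plates[2] - sb + 1.5))
  expect_error(run_phase(out$state, cfg_small, tmpl, default_params,
                         "compress"), "already compressed")
})

test_that("pathological overlaps raise an integration blow-up error", {
  tmpl <- get_template("dispersed")
  # uncapped forces and an absurd time step in a confined box: velocities
  # escalate at every re-encounter until they overflow
  cfg <- sim_config("desk", n_cells = 8, box_lengths = c(32, 32, 32), dt = 10)
  par_hot <- cell_params(force_cap = 1e308)
  st <- initialize_system(cfg, tmpl, par_hot, seed = 2)
  expect_error(
    advance_state(st, cfg, tmpl, par_hot, n_steps = 50000, seed = 1,
                  gamma = 0),
    "blow-up")
})
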