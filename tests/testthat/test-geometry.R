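test_that("repulsive energy has the truncated-shifted LJ values", {
  # contact: bracket vanishes, E = epsilon
  expect_equal(pair_energy_repulsive(10, 5, 5), 1)
  # cutoff and beyond: exactly zero
  expect_equal(pair_energy_repulsive(2^(1 / 6) * 10, 5, 5), 0)
  expect_equal(pair_energy_repulsive(20, 5, 5), 0)
  # strictly decreasing on (0, cutoff]
  r <- seq(3, 2^(1 / 6) * 10, length.out = 400)
  e <- pair_energy_repulsive(r, 5, 5)
  expect_true(all(diff(e) < 0))
  # continuity at the cutoff
  expect_lt(pair_energy_repulsive(2^(1 / 6) * 10 - 1e-9, 5, 5), 1e-7)
  expect_error(pair_energy_repulsive(0, 5, 5), "undefined")
})

test_that("adhesin binding energy follows the soft cosine form", {
  expect_equal(pair_energy_adhesin(0, A = -8, r_c = 1), -16)    # 2A
  expect_equal(pair_energy_adhesin(1, A = -8, r_c = 1), 0)      # cutoff
  expect_equal(pair_energy_adhesin(0.5, A = -8, r_c = 1), -8)   # cos(pi/2)=0
  expect_equal(pair_energy_adhesin(c(0, 0.3, 0.9, 2), A = 0, r_c = 1),
               c(0, 0, 0, 0))                                   # A=0 strain
  expect_lt(abs(pair_energy_adhesin(1 - 1e-9, A = -8, r_c = 1)), 1e-7)
})

test_that("pair forces are analytic gradients of the energies", {
  params <- default_params
  set.seed(11)
  for (kind in c("BB", "BP", "PP")) {
    rmax <- switch(kind, BB = 12, BP = 7.5, PP = 1.3)
    efun <- switch(kind,
      BB = function(r) pair_energy_repulsive(r, 5, 5, 1),
      BP = function(r) pair_energy_repulsive(r, 5, 1, 1),
      PP = function(r) pair_energy_adhesin(r, -8, 1))
    for (k in 1:100) {
      r <- runif(1, 0.4 * rmax, rmax)
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      f <- pair_force(r * dir, kind, params)
      h <- 1e-6 * r
      fmag_fd <- -(efun(r + h) - efun(r - h)) / (2 * h)
      expect_equal(sum(f * dir), fmag_fd, tolerance = 1e-6)
      # Newton's third law
      expect_equal(pair_force(-r * dir, kind, params), -f)
    }
  }
})

test_that("forces vanish at and beyond the cutoffs", {
  params <- default_params
  expect_equal(pair_force(c(2^(1 / 6) * 10, 0, 0), "BB", params), c(0, 0, 0))
  expect_equal(pair_force(c(0, 2^(1 / 6) * 6, 0), "BP", params), c(0, 0, 0))
  expect_equal(pair_force(c(0, 0, 1), "PP", params), c(0, 0, 0))
  # continuous approach to zero at the cutoff
  expect_lt(sqrt(sum(pair_force(c(2^(1 / 6) * 10 - 1e-9, 0, 0), "BB",
                                params)^2)), 1e-6)
  expect_lt(sqrt(sum(pair_force(c(1 - 1e-9, 0, 0), "PP", params)^2)), 1e-6)
  expect_error(pair_force(c(0, 0, 0), "BB", params), "zero separation")
})

test_that("localized template is a hexagonal one-sided patch", {
  tmpl <- get_template("localized")
  expect_equal(tmpl$n_adhesins, 19)
  expect_equal(nrow(tmpl$local_coords), 19)
  # all at the contact radius sigma_B + sigma_P = 6
  expect_equal(sqrt(rowSums(tmpl$local_coords^2)), rep(6, 19),
               tolerance = 1e-12)
  # one-sided: positive projection on the patch axis
  expect_true(all(tmpl$local_coords[, 3] > 0))
  # closely packed but non-overlapping
  expect_gte(min(dist(tmpl$local_coords)), 2 - 1e-9)
})

test_that("dispersed template is non-overlapping and near-uniform", {
  tmpl <- get_template("dispersed")
  expect_equal(sqrt(rowSums(tmpl$local_coords^2)), rep(6, 19),
               tolerance = 1e-12)
  # exhaustive check over all 171 pairs
  d <- as.matrix(dist(tmpl$local_coords))
  expect_gte(min(d[upper.tri(d)]), 2)
  # genuinely more uniform than the localized patch: smaller covering gap
  gap_disp <- covering_radius(tmpl$local_coords)
  gap_loc <- covering_radius(get_template("localized")$local_coords)
  expect_lt(gap_disp, gap_loc)
})

test_that("single-adhesin templates coincide up to rotation", {
  t1 <- build_cell_template("localized", default_params, 1)
  t2 <- build_cell_template("dispersed", default_params, 1)
  expect_equal(sqrt(sum(t1$local_coords^2)), sqrt(sum(t2$local_coords^2)))
  expect_equal(nrow(t1$local_coords), 1)
})

test_that("rigid geometry is rotation invariant", {
  tmpl <- get_template("dispersed")
  d0 <- dist(tmpl$local_coords)
  set.seed(3)
  for (k in 1:5) {
    rc <- piliagg:::quat_rotate(random_quat(), tmpl$local_coords)
    expect_equal(as.numeric(dist(rc)), as.numeric(d0), tolerance = 1e-12)
  }
})

test_that("infeasible adhesin counts raise a geometric error", {
  expect_error(build_cell_template("localized", default_params, 500),
               "infeasib")
  expect_error(build_cell_template("dispersed", default_params, 500),
               "infeasib")
})

test_that("parameter validation enforces the model invariants", {
  expect_error(cell_params(A = 2), "A must be")
  expect_error(cell_params(sigma_B = 0.5), "sigma_B > sigma_P")
  expect_error(cell_params(epsilon = -1))
})
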