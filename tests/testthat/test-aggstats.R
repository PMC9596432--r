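test_that("autocorrelation of trivial fields is exact", {
  ones <- binary_image(matrix(1L, 32, 32), periodic = TRUE)
  prof <- autocorrelation(ones)
  expect_equal(prof$C, rep(1, nrow(prof)), tolerance = 1e-12)

  expect_error(autocorrelation(binary_image(matrix(0L, 16, 16),
                                            periodic = TRUE)),
               "undefined normalization")
})

test_that("C(0) = 1 and C(r>0) ~ p for Bernoulli noise", {
  p <- 0.3
  b <- make_correlated_binary("bernoulli", size = 512, seed = 12,
                              fraction = p)
  prof <- autocorrelation(b$image, max_r = 60)
  expect_equal(prof$C[prof$r == 0], 1, tolerance = 1e-12)
  tail_C <- prof$C[prof$r > 2]
  # <phi(0)phi(r)> -> p^2 so C -> p; SE per bin is tiny at 512^2
  expect_lt(max(abs(tail_C - p)), 0.01)
})

test_that("FFT autocorrelation equals the pair-counting double loop", {
  set.seed(77)
  for (periodic in c(TRUE, FALSE)) {
    px <- matrix(rbinom(256, 1, 0.4), 16, 16)
    img <- binary_image(px, periodic = periodic)
    prof <- autocorrelation(img, max_r = 8)
    oracle <- autocorr_oracle(img, max_lag = 8)
    merged <- merge(as.data.frame(prof), oracle, by = "r",
                    suffixes = c("", "_o"))
    expect_equal(nrow(merged), nrow(prof))
    expect_lt(max(abs(merged$C - merged$C_o)), 1e-10)
    expect_equal(merged$pair_count, merged$pair_count_o)
  }
})

test_that("offset-exponential fit recovers exact parameters", {
  prof <- make_exponential_profile(C_inf = 0.2, a = 7, r_max = 100)
  expect_equal(prof$C[1], 1)   # model property at r = 0
  fit <- fit_correlation(prof)
  expect_true(fit$converged)
  expect_equal(fit$C_inf, 0.2, tolerance = 1e-6)
  expect_equal(fit$a, 7, tolerance = 1e-6)
})

test_that("fit recovery is robust to noise across seeds", {
  ok <- vapply(1:100, function(s) {
    prof <- make_exponential_profile(0.2, 7, 100, noise_sd = 0.01, seed = s)
    fit <- fit_correlation(prof)
    fit$converged && abs(fit$a - 7) / 7 < 0.05
  }, TRUE)
  expect_gte(sum(ok), 95)
})

test_that("degenerate profiles are flagged, not silently fitted", {
  ones <- binary_image(matrix(1L, 64, 64), periodic = TRUE)
  fit <- fit_correlation(autocorrelation(ones))
  expect_false(fit$converged)

  # too few points
  short <- make_exponential_profile(0.1, 3, 100)[1:3, ]
  attr(short, "pixel_size") <- 1
  expect_false(fit_correlation(short)$converged)
})

test_that("fitted C_inf approximates the foreground area fraction", {
  b <- make_correlated_binary("smoothed_noise", size = 512, seed = 5,
                              fraction = 0.35, kernel_scale = 6)
  res <- aggregate_size(b$image)
  expect_true(res$fit$converged)
  expect_equal(res$fit$C_inf, res$area_fraction, tolerance = 0.2)
})

test_that("aggregate size grows with disk radius and is translation
           invariant", {
  size_of_disk <- function(R, cx = 128, cy = 128) {
    px <- matrix(0L, 256, 256)
    xs <- (1:256) - 0.5
    dx <- pmin(abs(xs - cx), 256 - abs(xs - cx))   # periodic metric
    dy <- pmin(abs(xs - cy), 256 - abs(xs - cy))
    px[outer(dx^2, dy^2, "+") <= R^2] <- 1L
    aggregate_size(binary_image(px, periodic = TRUE))$size
  }
  sizes <- vapply(c(5, 10, 20, 40), size_of_disk, 1)
  expect_true(all(diff(sizes) > 0))

  # translation invariance under periodic wrap (integer-pixel shift so the
  # rasterized shape is identical)
  expect_equal(size_of_disk(10, 128, 128), size_of_disk(10, 12, 250),
               tolerance = 1e-9)

  # unstructured noise: size at the pixel scale
  b <- make_correlated_binary("bernoulli", size = 512, seed = 2,
                              fraction = 0.3)
  expect_lt(aggregate_size(b$image)$size, 2)
})

test_that("cluster labels match brute-force transitive closure", {
  tmpl <- get_template("dispersed", 7)
  # two cells with an adhesin pair at half the binding cutoff
  st <- two_cell_state(12.3, face = FALSE)
  st$quat[1, ] <- quat_from_to(tmpl$local_coords[1, ], c(1, 0, 0))
  st$quat[2, ] <- quat_from_to(tmpl$local_coords[1, ], c(-1, 0, 0))
  # tips 0.3 apart < r_c
  cl <- cluster_cells(st, tmpl, r_c = 1)
  expect_equal(cl$n_clusters, 1)
  expect_equal(cl$sizes, 2L)

  # isolated cells -> all singletons
  cfg <- sim_config("desk", n_cells = 12, box_lengths = c(400, 400, 400))
  far <- initialize_system(cfg, tmpl, default_params, seed = 3)
  far$pos <- matrix(runif(36) * 30, 12, 3) * 0  # grid placement below
  far$pos <- as.matrix(expand.grid(x = c(50, 150, 250),
                                   y = c(100, 300), z = c(100, 300)))
  cl2 <- cluster_cells(far, tmpl, r_c = 1)
  expect_equal(cl2$n_clusters, 12)

  # random dense configurations against the O(N^2) closure oracle
  tmpl5 <- get_template("dispersed", 5)
  for (seed in c(4, 5, 6)) {
    cfg <- sim_config("desk", n_cells = 14, box_lengths = c(46, 46, 46))
    st <- initialize_system(cfg, tmpl5, default_params, seed = seed)
    got <- cluster_cells(st, tmpl5, r_c = 2.5)$labels
    want <- cluster_oracle(st, tmpl5, r_c = 2.5)
    # same partition up to label permutation
    expect_equal(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(want, got, function(x) length(unique(x))) == 1))
  }
})
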