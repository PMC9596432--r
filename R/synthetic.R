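#' Synthetic correlated binary images
#'
#' Fixture generators with known structure, standing in for the study's
#' unreleased micrographs; every generator is deterministic given `seed`.
#'
#' * `"bernoulli"`: iid pixels at foreground probability `fraction` (no
#'   spatial structure beyond the pixel).
#' * `"smoothed_noise"`: periodic white noise convolved with an isotropic
#'   Gaussian kernel of scale `kernel_scale`, thresholded at the quantile
#'   that hits `fraction`.  The measured correlation length is monotone in
#'   the kernel scale (the thresholded field's correlation function is not
#'   exactly exponential, so only monotonicity is asserted, never an analytic
#'   identity).
#' * `"disks"`: `n_disks` filled disks of radius `disk_radius`, placed
#'   uniformly, or clustered around `n_parents` parent points with Gaussian
#'   spread `parent_spread` (emulating small vs large aggregates).
#'
#' @param kind one of `"bernoulli"`, `"smoothed_noise"`, `"disks"`.
#' @param size image side in pixels (square).
#' @param seed mandatory integer seed.
#' @param fraction target foreground fraction (bernoulli, smoothed_noise).
#' @param kernel_scale Gaussian kernel sigma in pixels.
#' @param n_disks,disk_radius,n_parents,parent_spread disk parameters;
#'   `n_parents = 0` places disks uniformly.
#' @param pixel_size physical length per pixel.
#' @return List with `image` (a periodic [binary_image()]) and `meta`
#'   (the generative parameters).
#' @export
make_correlated_binary <- function(kind = c("bernoulli", "smoothed_noise",
                                            "disks"),
                                   size = 512, seed, fraction = 0.3,
                                   kernel_scale = 8, n_disks = 30,
                                   disk_radius = 10, n_parents = 0,
                                   parent_spread = 30, pixel_size = 1) {
  kind <- match.arg(kind)
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(size >= 4)
  meta <- list(kind = kind, size = size, seed = seed)
  img <- with_seed(seed, function() {
    if (kind == "bernoulli") {
      stopifnot(fraction > 0, fraction < 1)
      meta$fraction <<- fraction
      return(matrix(rbinom(size^2, 1, fraction), size, size))
    }
    if (kind == "smoothed_noise") {
      stopifnot(fraction > 0, fraction < 1, kernel_scale > 0)
      meta$fraction <<- fraction
      meta$kernel_scale <<- kernel_scale
      g <- matrix(rnorm(size^2), size, size)
      dx <- c(0:(size - 1)); dx <- pmin(dx, size - dx)
      k <- exp(-outer(dx^2, dx^2, "+") / (2 * kernel_scale^2))
      sm <- Re(fft(fft(g) * fft(k), inverse = TRUE)) / size^2
      thr <- quantile(sm, 1 - fraction)
      return((sm > thr) * 1L)
    }
    # disks
    stopifnot(n_disks >= 1, disk_radius > 0)
    meta$n_disks <<- n_disks
    meta$disk_radius <<- disk_radius
    meta$n_parents <<- n_parents
    L <- size * pixel_size
    if (n_parents > 0) {
      par_xy <- matrix(runif(2 * n_parents) * L, n_parents, 2)
      assign_to <- rep_len(seq_len(n_parents), n_disks)
      centers <- par_xy[assign_to, , drop = FALSE] +
        matrix(rnorm(2 * n_disks, sd = parent_spread), n_disks, 2)
      centers <- centers %% L
    } else {
      centers <- matrix(runif(2 * n_disks) * L, n_disks, 2)
    }
    meta$centers <<- centers
    rasterize_disks(matrix(0L, size, size), centers, disk_radius, pixel_size,
                    c(L, L))
  })
  list(image = binary_image(img, pixel_size, periodic = TRUE), meta = meta)
}

#' Synthetic phase-contrast-like micrograph with ground truth
#'
#' Emulates the gross features of a phase-contrast acquisition of bacterial
#' aggregates: dark cell-body disks (default diameter 15 px, about 1 um at
#' 0.065 um/px) with bright halos on a brighter background, a multiplicative
#' illumination gradient, additive Gaussian sensor noise (default sd 0.01,
#' i.e. a signal-to-noise ratio of about 60 for the 0.6 intensity contrast,
#' typical of modern sCMOS phase contrast), and salt-and-pepper pixels.
#' Cells cluster tightly around parent points (default spread comparable to
#' the cell diameter) so aggregated cells touch, as they do under an agar
#' pad.  The ground-truth mask is the clean disk raster, so segmentation
#' accuracy can be scored exactly.  It does not attempt photorealistic
#' optics (no point-spread function, no depth effects).
#'
#' @param size image side in pixels.
#' @param n_cells number of cell disks.
#' @param cell_radius disk radius in pixels.
#' @param seed mandatory integer seed.
#' @param noise_sd additive Gaussian noise standard deviation (intensity
#'   units, image scale 0..1).
#' @param sp_fraction fraction of pixels replaced by salt or pepper.
#' @param gradient_strength relative amplitude of the illumination plane.
#' @param halo_strength brightness added in a 2 px halo ring around each
#'   cell.
#' @param n_parents,parent_spread spatial clustering of the cells (as in
#'   [make_correlated_binary()]).
#' @param min_separation if positive, cell centers are rejection-sampled to
#'   keep at least this distance apart (periodic metric).  Used by the
#'   geometric-fidelity calibration fixture: morphological closing merges
#'   structures within about twice its radius, so scoring pixel-exact
#'   recovery is only meaningful on separated cells.
#' @param pixel_size physical length per pixel.
#' @return List with `image` (numeric matrix in \[0, 1\]), `mask` (ground-truth
#'   [binary_image()]) and `spec` (all parameters).
#' @export
make_micrograph <- function(size = 512, n_cells = 60, cell_radius = 7.5,
                            seed, noise_sd = 0.01, sp_fraction = 0.01,
                            gradient_strength = 0.3, halo_strength = 0.15,
                            n_parents = 6, parent_spread = 12,
                            min_separation = 0, pixel_size = 1) {
  if (missing(seed)) stop("seed is mandatory")
  spec <- as.list(environment())
  with_seed(seed, function() {
    L <- size * pixel_size
    if (n_cells > 0) {
      if (min_separation > 0) {
        centers <- matrix(NA_real_, n_cells, 2)
        placed <- 0
        for (att in seq_len(5000 * n_cells)) {
          cand <- runif(2) * L
          if (placed > 0) {
            dd <- abs(sweep(centers[seq_len(placed), , drop = FALSE], 2,
                            cand))
            dd <- pmin(dd, L - dd)
            if (min(rowSums(dd^2)) < min_separation^2) next
          }
          placed <- placed + 1
          centers[placed, ] <- cand
          if (placed == n_cells) break
        }
        if (placed < n_cells)
          stop("cannot place ", n_cells, " cells at separation ",
               min_separation)
      } else if (n_parents > 0) {
        par_xy <- matrix(runif(2 * n_parents) * L, n_parents, 2)
        centers <- par_xy[rep_len(seq_len(n_parents), n_cells), ,
                          drop = FALSE] +
          matrix(rnorm(2 * n_cells, sd = parent_spread), n_cells, 2)
        centers <- centers %% L
      } else {
        centers <- matrix(runif(2 * n_cells) * L, n_cells, 2)
      }
      mask_px <- rasterize_disks(matrix(0L, size, size), centers,
                                 cell_radius, pixel_size, c(L, L))
      halo_px <- rasterize_disks(matrix(0L, size, size), centers,
                                 cell_radius + 2, pixel_size, c(L, L))
    } else {
      centers <- matrix(numeric(0), 0, 2)
      mask_px <- matrix(0L, size, size)
      halo_px <- mask_px
    }
    clean <- matrix(0.8, size, size)
    clean[halo_px == 1] <- 0.8 + halo_strength
    clean[mask_px == 1] <- 0.2
    gx <- seq(1 - gradient_strength / 2, 1 + gradient_strength / 2,
              length.out = size)
    grad <- outer(gx, rev(gx), function(a, b) (a + b) / 2)
    img <- clean * grad
    if (noise_sd > 0) img <- img + matrix(rnorm(size^2, sd = noise_sd),
                                          size, size)
    if (sp_fraction > 0) {
      nsp <- round(sp_fraction * size^2)
      idx <- sample.int(size^2, nsp)
      img[idx] <- rep_len(c(0, 1), nsp)
    }
    img <- pmin(pmax(img, 0), 1)
    list(image = img,
         mask = binary_image(mask_px, pixel_size, periodic = FALSE),
         spec = spec)
  })
}

#' Synthetic exponential-decay correlation profile
#'
#' Exact evaluation of the fit model
#' \eqn{C(r) = C_\infty + (1-C_\infty)\exp(-r/a)} on integer radii, with
#' optional additive Gaussian noise; used for fit-recovery calibration.
#'
#' @param C_inf offset, in [0, 1).
#' @param a correlation length (> 0).
#' @param r_max largest radius.
#' @param noise_sd Gaussian noise sd added at r > 0 (`C(0)` stays exactly 1).
#' @param seed seed; required if `noise_sd > 0`.
#' @param pair_count pair count attached to every bin.
#' @return A `correlation_profile`.
#' @export
make_exponential_profile <- function(C_inf, a, r_max, noise_sd = 0,
                                     seed = NULL, pair_count = 1e4) {
  stopifnot(C_inf >= 0, C_inf < 1, a > 0, r_max >= 4)
  r <- 0:r_max
  C <- C_inf + (1 - C_inf) * exp(-r / a)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed required when noise_sd > 0")
    C[-1] <- C[-1] + with_seed(seed, function() rnorm(r_max, sd = noise_sd))
  }
  structure(data.frame(r = r, C = C, pair_count = rep(pair_count,
                                                      length(r))),
            class = c("correlation_profile", "data.frame"),
            pixel_size = 1, periodic = TRUE, area_fraction = C_inf,
            n_pixels = NA_integer_, default_fit_max = r_max)
}
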