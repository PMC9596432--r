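#' Pair-potential parameters
#'
#' Parameters of the two interaction potentials: a purely repulsive
#' truncated-and-shifted Lennard-Jones (WCA) potential acting between body
#' spheres and between a body and an adhesin sphere, and a soft cosine
#' attraction acting between adhesin spheres of different cells.  The adhesin
#' radius `sigma_P` defines the unit length and energies are in units of
#' \eqn{k_B T}.
#'
#' @param sigma_B body-sphere radius (default 5).
#' @param sigma_P adhesin-sphere radius; the unit length (default 1).
#' @param epsilon repulsion energy scale (default 1).
#' @param A adhesin binding strength, must be \eqn{\le 0}; `-8` for adhesive
#'   cells, `0` for the non-adhesive control.
#' @param r_c adhesin-adhesin cutoff (default `sigma_P`).
#' @param force_cap magnitude bound applied to any single pair force during
#'   dynamics, a numerical safeguard against near-overlapping initial
#'   configurations.
#' @return An object of class `pair_params`.
#' @export
cell_params <- function(sigma_B = 5, sigma_P = 1, epsilon = 1, A = -8,
                        r_c = sigma_P, force_cap = 1e3) {
  stopifnot(sigma_P > 0, sigma_B > sigma_P, epsilon > 0, r_c > 0,
            force_cap > 0)
  if (A > 0) stop("binding strength A must be <= 0 (attractive or off)")
  structure(list(sigma_B = sigma_B, sigma_P = sigma_P, epsilon = epsilon,
                 A = A, r_c = r_c, force_cap = force_cap),
            class = "pair_params")
}

#' WCA repulsion energy
#'
#' Truncated and shifted Lennard-Jones repulsion between spheres of radii
#' `sigma_X` and `sigma_Y`:
#' \deqn{E(r) = \epsilon + 4\epsilon[((\sigma_X+\sigma_Y)/r)^{12} -
#'   ((\sigma_X+\sigma_Y)/r)^6]} for \eqn{r < 2^{1/6}(\sigma_X+\sigma_Y)},
#' and 0 beyond.  The shift makes the energy (and its derivative) continuous
#' and exactly zero at the cutoff.
#'
#' @param r center-center distance(s), must be positive.
#' @param sigma_X,sigma_Y sphere radii.
#' @param epsilon energy scale.
#' @return Energy, vectorized over `r`.
#' @export
pair_energy_repulsive <- function(r, sigma_X, sigma_Y, epsilon = 1) {
  if (any(r <= 0)) stop("repulsive pair energy undefined at r <= 0")
  s <- sigma_X + sigma_Y
  cutoff <- 2^(1 / 6) * s
  sr6 <- (s / r)^6
  e <- epsilon + 4 * epsilon * (sr6^2 - sr6)
  ifelse(r < cutoff, e, 0)
}

#' Soft adhesin binding energy
#'
#' \deqn{E(r) = A [1 + \cos(\pi r / r_c)]} for \eqn{r < r_c}, 0 beyond.
#' With \eqn{A < 0} the minimum \eqn{2A} sits at zero separation and the
#' potential rises smoothly to zero at the cutoff, so two adhesins bind
#' without a hard core.
#'
#' @param r adhesin center-center distance(s), non-negative.
#' @param A binding strength (\eqn{\le 0}).
#' @param r_c cutoff.
#' @return Energy, vectorized over `r`.
#' @export
pair_energy_adhesin <- function(r, A = -8, r_c = 1) {
  if (any(r < 0)) stop("distance must be non-negative")
  ifelse(r < r_c, A * (1 + cos(pi * r / r_c)), 0)
}

#' Pair force between two atoms
#'
#' Analytic gradient of the pair potentials: the force acting on the atom at
#' `r_vec` relative to its partner (so `pair_force(-r_vec, ...)` is its
#' negative).
#'
#' @param r_vec separation 3-vector (position of atom 1 minus atom 2).
#' @param kind `"BB"`, `"BP"` or `"PP"`.
#' @param params a [cell_params()] object.
#' @return Force 3-vector.
#' @export
pair_force <- function(r_vec, kind = c("BB", "BP", "PP"),
                       params = cell_params()) {
  kind <- match.arg(kind)
  r2 <- sum(r_vec^2)
  r <- sqrt(r2)
  if (kind %in% c("BB", "BP")) {
    if (r <= 0) stop("repulsive pair force undefined at zero separation")
    s <- if (kind == "BB") 2 * params$sigma_B else
      params$sigma_B + params$sigma_P
    if (r >= 2^(1 / 6) * s) return(c(0, 0, 0))
    sr6 <- (s / r)^6
    f_over_r <- 24 * params$epsilon * (2 * sr6^2 - sr6) / r2
    return(f_over_r * r_vec)
  }
  # PP soft cosine; force -> 0 smoothly at both r = 0 and r = r_c
  if (r >= params$r_c) return(c(0, 0, 0))
  if (r < 1e-12) return(c(0, 0, 0))
  f_over_r <- params$A * pi * sin(pi * r / params$r_c) / (params$r_c * r)
  f_over_r * r_vec
}

# planar hexagonal lattice points (spacing s), n closest to the origin,
# deterministic tie-break by angle
hex_lattice <- function(n, s) {
  m <- ceiling(sqrt(n)) + 3
  g <- expand.grid(i = -m:m, j = -m:m)
  x <- s * (g$i + g$j / 2)
  y <- s * g$j * sqrt(3) / 2
  d <- sqrt(x^2 + y^2)
  ang <- atan2(y, x)
  ord <- order(round(d, 9), round(ang, 9))
  cbind(x = x[ord[seq_len(n)]], y = y[ord[seq_len(n)]])
}

# n near-uniform unit vectors: Fibonacci sphere + deterministic pairwise
# repulsion relaxation on the sphere
fibonacci_sphere <- function(n, relax_iter = 300, step = 0.1) {
  if (n == 1) return(matrix(c(0, 0, 1), 1, 3))
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  rho <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (3 - sqrt(5)) * (i - 1)
  p <- cbind(rho * cos(th), rho * sin(th), z)
  for (it in seq_len(relax_iter)) {
    f <- matrix(0, n, 3)
    for (k in seq_len(n)) {
      dv <- sweep(-p, 2, -p[k, ])     # p[k,] - p[j,]
      d2 <- rowSums(dv^2)
      d2[k] <- Inf
      f[k, ] <- colSums(dv / d2^1.5)
    }
    p <- p + step / n * f
    p <- p / sqrt(rowSums(p^2))
  }
  p
}

#' Build a rigid cell template
#'
#' A cell is one body sphere at the origin plus `n_adhesins` adhesin spheres
#' whose centers all sit at `contact_radius` from the body center (so the
#' adhesin spheres are tangent to the body surface at the default radius
#' `sigma_B + sigma_P`).  Two placements are supported:
#'
#' * `"localized"`: a closely packed hexagonal patch (rings of 1, 6, 12 for
#'   the default 19 adhesins) on one side of the body.  A planar hexagonal
#'   lattice is projected radially onto the contact sphere; radial projection
#'   shrinks in-plane distances, so the lattice spacing is rescaled until the
#'   minimum projected center distance equals `2 * sigma_P` (tangent adhesin
#'   spheres).
#' * `"dispersed"`: a near-uniform spherical point set (Fibonacci sphere
#'   refined by a short deterministic repulsion relaxation).
#'
#' @param pattern `"localized"` or `"dispersed"`.
#' @param params a [cell_params()] object.
#' @param n_adhesins number of adhesin spheres (default 19).
#' @param contact_radius distance of adhesin centers from the body center;
#'   default `sigma_B + sigma_P`.
#' @return An object of class `cell_template` with fields `pattern`,
#'   `n_adhesins`, `local_coords` (n x 3 body-frame offsets),
#'   `contact_radius`, `mass` (one unit per atom) and `inertia` (isotropic
#'   scalar moment, two thirds of the summed squared offsets).
#' @export
build_cell_template <- function(pattern = c("localized", "dispersed"),
                                params = cell_params(), n_adhesins = 19,
                                contact_radius = NULL) {
  pattern <- match.arg(pattern)
  stopifnot(n_adhesins >= 1)
  cr <- if (is.null(contact_radius)) params$sigma_B + params$sigma_P else
    contact_radius
  sp <- params$sigma_P
  if (pattern == "localized") {
    if (n_adhesins == 1) {
      coords <- matrix(c(0, 0, cr), 1, 3)
    } else {
      s <- 2 * sp
      coords <- NULL
      for (it in 1:400) {
        xy <- hex_lattice(n_adhesins, s)
        v <- cbind(xy[, 1], xy[, 2], cr)   # plane tangent at the +z pole
        coords <- v * (cr / sqrt(rowSums(v^2)))
        dmin <- min(stats::dist(coords))
        if (abs(dmin - 2 * sp) < 1e-10) break
        s <- s * (2 * sp) / dmin
        if (s > 20 * cr) break  # patch cannot fit
      }
      if (min(stats::dist(coords)) < 2 * sp - 1e-8 ||
          any(coords[, 3] <= 0)) {
        stop("geometric infeasibility: cannot place ", n_adhesins,
             " non-overlapping adhesins as a one-sided patch at contact ",
             "radius ", cr)
      }
    }
  } else {
    u <- fibonacci_sphere(n_adhesins)
    coords <- u * cr
    if (n_adhesins > 1 && min(stats::dist(coords)) < 2 * sp - 1e-8) {
      stop("geometric infeasibility: ", n_adhesins, " adhesins overlap on a ",
           "sphere of radius ", cr)
    }
  }
  dimnames(coords) <- NULL
  structure(list(pattern = pattern, n_adhesins = n_adhesins,
                 local_coords = coords, contact_radius = cr,
                 mass = n_adhesins + 1,
                 inertia = (2 / 3) * sum(coords^2)),
            class = "cell_template")
}

#' @export
print.cell_template <- function(x, ...) {
  cat("cell_template:", x$pattern, "pattern,", x$n_adhesins,
      "adhesins at contact radius", x$contact_radius, "\n")
  cat("  mass", x$mass, " isotropic inertia", signif(x$inertia, 6), "\n")
  invisible(x)
}
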