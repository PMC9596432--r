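#' Radially averaged spatial autocorrelation of a binary image
#'
#' Computes \deqn{C_{\phi\phi}(r) = \langle\phi(0)\phi(r)\rangle /
#' \langle\phi^2\rangle,} the average running over all pixel pairs, by FFT:
#' circular correlation for periodic images (simulation projections), and
#' zero-padded correlation with per-lag valid-pair normalization for
#' non-periodic ones (micrographs).  2D lags are averaged into unit-pixel
#' radial bins; bins with no pairs are dropped.  For a binary field
#' \eqn{\phi^2 = \phi}, so \eqn{C(0) = 1} exactly and
#' \eqn{C(r \to \infty) \to \langle\phi\rangle}, the area fraction.
#'
#' @param image a [binary_image()].
#' @param max_r largest radius (in the image's physical units); default half
#'   the smaller image side.
#' @return Object of class `correlation_profile`: data frame with `r`, `C`,
#'   `pair_count`, plus attributes `pixel_size`, `periodic`, `area_fraction`
#'   and `default_fit_max`.
#' @export
autocorrelation <- function(image, max_r = NULL) {
  stopifnot(inherits(image, "binary_image"))
  phi <- image$pixels
  ps <- image$pixel_size
  m <- mean(phi)
  if (m == 0)
    stop("undefined normalization: image has no foreground (<phi^2> = 0)")
  nx <- nrow(phi); ny <- ncol(phi)
  max_lag <- floor(min(nx, ny) / 2)
  if (!is.null(max_r)) max_lag <- min(max_lag, floor(max_r / ps))
  max_lag <- max(max_lag, 1L)

  if (image$periodic) {
    S <- Re(fft(Mod(fft(phi))^2, inverse = TRUE)) / length(phi)
    di <- c(0:(nx - 1)); di[di > nx / 2] <- di[di > nx / 2] - nx
    dj <- c(0:(ny - 1)); dj[dj > ny / 2] <- dj[dj > ny / 2] - ny
    rad <- sqrt(outer(di^2, dj^2, "+"))
    bin <- floor(rad + 0.5)
    keep <- bin <= max_lag
    sums <- tapply(S[keep], bin[keep], sum)
    cnts <- tapply(S[keep], bin[keep], length)
    r_px <- as.numeric(names(sums))
    # each lag contributes N ordered pixel pairs
    Cb <- as.numeric(sums) / (as.numeric(cnts) * length(phi)) / m
    pc <- as.numeric(cnts) * length(phi)
  } else {
    px <- nextn(nx + max_lag, c(2, 3, 5))
    py <- nextn(ny + max_lag, c(2, 3, 5))
    pad <- matrix(0, px, py); pad[1:nx, 1:ny] <- phi
    one <- matrix(0, px, py); one[1:nx, 1:ny] <- 1
    S <- Re(fft(Mod(fft(pad))^2, inverse = TRUE)) / length(pad)
    W <- round(Re(fft(Mod(fft(one))^2, inverse = TRUE)) / length(pad))
    di <- c(0:(px - 1)); di[di > px / 2] <- di[di > px / 2] - px
    dj <- c(0:(py - 1)); dj[dj > py / 2] <- dj[dj > py / 2] - py
    ok <- outer(abs(di) <= min(max_lag, nx - 1),
                abs(dj) <= min(max_lag, ny - 1), "&") & W > 0
    rad <- sqrt(outer(di^2, dj^2, "+"))
    bin <- floor(rad + 0.5)
    ok <- ok & bin <= max_lag
    sums <- tapply(S[ok], bin[ok], sum)
    wsum <- tapply(W[ok], bin[ok], sum)
    r_px <- as.numeric(names(sums))
    Cb <- as.numeric(sums) / as.numeric(wsum) / m
    pc <- as.numeric(wsum)
  }
  ord <- order(r_px)
  out <- data.frame(r = r_px[ord] * ps, C = Cb[ord], pair_count = pc[ord])
  structure(out,
            class = c("correlation_profile", "data.frame"),
            pixel_size = ps, periodic = image$periodic, area_fraction = m,
            n_pixels = length(phi),
            default_fit_max = min(min(nx, ny) / 4, 150) * ps)
}

#' Fit an offset exponential to a correlation profile
#'
#' Weighted nonlinear least squares of
#' \deqn{C(r) = C_\infty + (1 - C_\infty)\exp(-r/a)} over the fit range,
#' with per-bin weights proportional to the square root of the pair count
#' (bin noise is roughly inverse to the pair count).  Starting values: the
#' large-r plateau mean for \eqn{C_\infty}, and the first radius where the
#' profile drops below \eqn{C_\infty + (1-C_\infty)/e} for \eqn{a}.
#' Parameters are bounded (\eqn{0 \le C_\infty \le 0.999},
#' \eqn{0.1 \mathrm{px} \le a \le} profile extent); non-convergence or `a`
#' pinned at a bound is flagged, never silently returned as success.
#'
#' @param profile a `correlation_profile`.
#' @param fit_range `c(lo, hi)` radii (profile units); default
#'   `[0, min(L/4, 150 px)]`.
#' @param min_pairs bins with fewer pairs are excluded (default 100).
#' @return Object of class `correlation_fit`: `C_inf`, `a`, `converged`,
#'   `boundary_hit`, `n_points`, `sigma` (residual scale), `cov` (parameter
#'   covariance or NULL), `fit_range`.
#' @export
fit_correlation <- function(profile, fit_range = NULL, min_pairs = 100) {
  ps <- attr(profile, "pixel_size")
  if (is.null(ps)) ps <- 1
  if (is.null(fit_range)) {
    hi <- attr(profile, "default_fit_max")
    if (is.null(hi)) hi <- max(profile$r)
    fit_range <- c(0, hi)
  }
  d <- profile[profile$r >= fit_range[1] & profile$r <= fit_range[2] &
                 profile$pair_count >= min_pairs, , drop = FALSE]
  fail <- function(reason) {
    structure(list(C_inf = NA_real_, a = NA_real_, converged = FALSE,
                   boundary_hit = FALSE, n_points = nrow(d), sigma = NA_real_,
                   cov = NULL, fit_range = fit_range, reason = reason),
              class = "correlation_fit")
  }
  if (nrow(d) < 4) return(fail("fewer than 4 usable radii in fit range"))
  if (!all(is.finite(d$C))) return(fail("non-finite correlation values"))
  if (stats::var(d$C) < 1e-14)
    return(fail("degenerate profile: correlation is constant"))

  plateau <- mean(d$C[d$r >= 0.75 * max(d$r)])
  C0 <- min(max(plateau, 0.01), 0.99)  # floored: a start at exactly 0 can
                                       # make the initial Jacobian singular
  target <- C0 + (1 - C0) / exp(1)
  below <- d$r[d$r > 0 & d$C < target]
  a0 <- if (length(below)) min(below) else max(d$r) / 5
  a0 <- max(a0, 0.5 * ps)
  lo <- c(C_inf = 0, a = 0.1 * ps)
  up <- c(C_inf = 0.999, a = max(profile$r))

  fit <- tryCatch(
    minpack.lm::nlsLM(C ~ C_inf + (1 - C_inf) * exp(-r / a), data = d,
                      start = list(C_inf = C0, a = a0),
                      weights = sqrt(d$pair_count),
                      lower = lo, upper = up,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("optimizer failure"))
  est <- stats::coef(fit)
  info <- fit$convInfo
  ok <- isTRUE(info$isConv) || (is.numeric(info$stopCode) &&
                                  info$stopCode %in% 1:3)
  tol <- 1e-6
  boundary <- (est["a"] <= lo["a"] * (1 + tol)) ||
    (est["a"] >= up["a"] * (1 - tol)) ||
    (est["C_inf"] >= up["C_inf"] - tol)
  cv <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  structure(list(C_inf = unname(est["C_inf"]), a = unname(est["a"]),
                 converged = ok && !boundary, boundary_hit = boundary,
                 n_points = nrow(d),
                 sigma = tryCatch(stats::sigma(fit), error = function(e) NA_real_),
                 cov = cv, fit_range = fit_range, reason = NULL),
            class = "correlation_fit")
}

#' @export
print.correlation_fit <- function(x, ...) {
  cat("correlation_fit: C_inf =", signif(x$C_inf, 5), " a =", signif(x$a, 5),
      if (x$converged) "(converged)" else "(FLAGGED)", "\n")
  if (!is.null(x$reason)) cat("  reason:", x$reason, "\n")
  invisible(x)
}

#' Aggregate size of a binary image
#'
#' The headline statistic: twice the correlation length of the offset
#' exponential fitted to the radially averaged spatial autocorrelation.
#'
#' @param image a [binary_image()].
#' @param fit_range passed to [fit_correlation()].
#' @param max_r passed to [autocorrelation()].
#' @param source optional identifier carried into the result.
#' @return Object of class `aggregate_size`: `size` (= `2 * fit$a`), `fit`,
#'   `area_fraction`, `n_pixels`, `source`.
#' @export
aggregate_size <- function(image, fit_range = NULL, max_r = NULL,
                           source = NA_character_) {
  prof <- autocorrelation(image, max_r = max_r)
  fit <- fit_correlation(prof, fit_range = fit_range)
  structure(list(size = 2 * fit$a, fit = fit,
                 area_fraction = attr(prof, "area_fraction"),
                 n_pixels = attr(prof, "n_pixels"), source = source),
            class = "aggregate_size")
}

#' @export
print.aggregate_size <- function(x, ...) {
  cat("aggregate_size: 2a =", signif(x$size, 5),
      if (x$fit$converged) "" else "(fit flagged)", "\n")
  invisible(x)
}

#' Particle-space contact clusters
#'
#' Union-find over inter-cell adhesin pairs closer than `r_c` (minimum
#' image): the particle-space cross-check of the image-based size statistic.
#'
#' @param state a `system_state`.
#' @param template the cell template.
#' @param r_c contact distance (defaults to the binding cutoff in `params`).
#' @param params a [cell_params()] used only for the default `r_c`.
#' @return List with `labels` (cluster id per cell, 1..n_clusters), `sizes`
#'   (cells per cluster) and `n_clusters`.
#' @export
cluster_cells <- function(state, template, r_c = params$r_c,
                          params = cell_params()) {
  n <- nrow(state$pos)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1) {
    ap <- adhesin_positions(state, template)
    reach <- 2 * template$contact_radius + r_c
    wrapz <- is.null(state$plates)
    for (i in seq_len(n - 1)) {
      d <- minimum_image(sweep(state$pos[(i + 1):n, , drop = FALSE], 2,
                               state$pos[i, ]), state$box)
      if (!wrapz) d[, 3] <- state$pos[(i + 1):n, 3] - state$pos[i, 3]
      cand <- which(rowSums(d^2) < reach^2) + i
      for (j in cand) {
        ri <- find(i); rj <- find(j)
        if (ri == rj) next
        # adhesin pairs, same image shift as the centers
        shift <- d[j - i, ] - (state$pos[j, ] - state$pos[i, ])
        pj <- ap[j, , , drop = FALSE]
        dim(pj) <- dim(ap)[2:3]
        pj <- sweep(pj, 2, shift, "+")   # move j into i's image
        pi_ <- ap[i, , , drop = FALSE]
        dim(pi_) <- dim(ap)[2:3]
        d2 <- outer(rowSums(pi_^2), rowSums(pj^2), "+") -
          2 * pi_ %*% t(pj)
        if (min(d2) < r_c^2) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- as.integer(factor(roots))
  sizes <- as.integer(table(labels))
  list(labels = labels, sizes = sizes, n_clusters = length(sizes))
}
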