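# shared fixtures and independent oracles

default_params <- cell_params()

template_cache <- new.env()
get_template <- function(pattern, n = 19) {
  key <- paste0(pattern, n)
  if (is.null(template_cache[[key]]))
    template_cache[[key]] <- build_cell_template(pattern, default_params, n)
  template_cache[[key]]
}

# state with two cells at a given center separation along x, facing each
# other (+z pole of cell 1 rotated to +x, cell 2 to -x when face = TRUE)
two_cell_state <- function(dist, box = c(200, 200, 200), face = TRUE) {
  mid <- box / 2
  pos <- rbind(mid - c(dist / 2, 0, 0), mid + c(dist / 2, 0, 0))
  # quaternion rotating +z to +x: rotate by 90 deg about y
  qy <- c(cos(pi / 4), 0, sin(pi / 4), 0)
  # +z to -x: rotate by -90 deg about y
  qym <- c(cos(pi / 4), 0, -sin(pi / 4), 0)
  quat <- if (face) rbind(qy, qym) else rbind(c(1, 0, 0, 0), c(1, 0, 0, 0))
  structure(list(pos = pos, quat = unname(quat),
                 vel = matrix(0, 2, 3), angvel = matrix(0, 2, 3),
                 box = box, time = 0, body_radius = default_params$sigma_B,
                 plates = NULL),
            class = "system_state")
}

# brute-force O(N^4) pair-counting autocorrelation oracle
autocorr_oracle <- function(image, max_lag) {
  phi <- image$pixels
  nx <- nrow(phi); ny <- ncol(phi)
  m <- mean(phi)
  sums <- list(); cnts <- list()
  add <- function(bin, v) {
    key <- as.character(bin)
    sums[[key]] <<- (if (is.null(sums[[key]])) 0 else sums[[key]]) + v
    cnts[[key]] <<- (if (is.null(cnts[[key]])) 0 else cnts[[key]]) + 1
  }
  for (i1 in 1:nx) for (j1 in 1:ny) for (i2 in 1:nx) for (j2 in 1:ny) {
    dx <- i2 - i1; dy <- j2 - j1
    if (image$periodic) {
      if (dx > nx / 2) dx <- dx - nx
      if (dx <= -nx / 2) dx <- dx + nx
      if (dy > ny / 2) dy <- dy - ny
      if (dy <= -ny / 2) dy <- dy + ny
    }
    bin <- floor(sqrt(dx^2 + dy^2) + 0.5)
    if (bin > max_lag) next
    add(bin, phi[i1, j1] * phi[i2, j2])
  }
  bins <- sort(as.integer(names(sums)))
  data.frame(r = bins,
             C = vapply(as.character(bins),
                        function(k) sums[[k]] / cnts[[k]], 1) / m,
             pair_count = vapply(as.character(bins),
                                 function(k) cnts[[k]], 1))
}

# brute-force transitive closure clustering oracle
cluster_oracle <- function(state, template, r_c) {
  n <- nrow(state$pos)
  ap <- adhesin_positions(state, template)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    # all adhesin pairs under minimum image
    mind <- Inf
    for (a in seq_len(template$n_adhesins))
      for (b in seq_len(template$n_adhesins)) {
        d <- minimum_image(ap[i, a, ] - ap[j, b, ], state$box)
        mind <- min(mind, sqrt(sum(d^2)))
      }
    adj[i, j] <- adj[j, i] <- mind < r_c
  }
  reach <- adj | diag(n) > 0
  for (k in seq_len(n)) reach <- reach | (reach[, k] %o% reach[k, ] > 0)
  labels <- integer(n)
  lab <- 0
  for (i in seq_len(n)) if (labels[i] == 0) {
    lab <- lab + 1
    labels[which(reach[i, ])] <- lab
  }
  labels
}

# covering radius of a point set on a sphere: largest angular distance from
# any direction (sampled) to its nearest point
covering_radius <- function(coords, n_dirs = 2000) {
  u <- coords / sqrt(rowSums(coords^2))
  set.seed(7)
  dirs <- matrix(rnorm(3 * n_dirs), n_dirs, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  cosang <- dirs %*% t(u)
  max(acos(pmin(1, apply(cosang, 1, max))))
}

random_quat <- function() {
  q <- rnorm(4)
  q / sqrt(sum(q^2))
}

# unit quaternion rotating direction `from` onto direction `to`
quat_from_to <- function(from, to) {
  f <- from / sqrt(sum(from^2))
  g <- to / sqrt(sum(to^2))
  cth <- sum(f * g)
  if (cth > 1 - 1e-12) return(c(1, 0, 0, 0))
  if (cth < -1 + 1e-12) {
    ax <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- ax - sum(ax * f) * f
    ax <- ax / sqrt(sum(ax^2))
    return(c(0, ax))
  }
  ax <- c(f[2] * g[3] - f[3] * g[2],
          f[3] * g[1] - f[1] * g[3],
          f[1] * g[2] - f[2] * g[1])
  ax <- ax / sqrt(sum(ax^2))
  half <- acos(max(-1, min(1, cth))) / 2
  c(cos(half), ax * sin(half))
}
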