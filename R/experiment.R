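#' Strain specification
#'
#' A simulated strain is an adhesin placement pattern plus a binding
#' strength: the parental strain maps to a localized patch with `A = -8`, the
#' regulator-mutant strain to dispersed adhesins with `A = -8`, and the
#' pilin-deletion control to `A = 0`.
#'
#' @param name unique label.
#' @param pattern `"localized"` or `"dispersed"`.
#' @param A binding strength (\eqn{\le 0}).
#' @param replicates number of replicate simulations (default 5).
#' @return Object of class `strain_spec`.
#' @export
strain_spec <- function(name, pattern = c("localized", "dispersed"), A = -8,
                        replicates = 5) {
  pattern <- match.arg(pattern)
  stopifnot(replicates >= 1, A <= 0)
  structure(list(name = name, pattern = pattern, A = A,
                 replicates = replicates), class = "strain_spec")
}

#' Default strain panel
#'
#' The three simulated strains compared throughout: localized adhesins with
#' binding, dispersed adhesins with binding, and the non-adhesive control.
#'
#' @param replicates replicates per strain.
#' @return List of [strain_spec()] objects.
#' @export
default_strains <- function(replicates = 5) {
  list(strain_spec("localized_A-8", "localized", -8, replicates),
       strain_spec("dispersed_A-8", "dispersed", -8, replicates),
       strain_spec("dispersed_A0", "dispersed", 0, replicates))
}

#' Run the end-to-end strain-comparison experiment
#'
#' For every strain and replicate: initialize, equilibrate, record snapshots,
#' compress the final `n_compress_frames` recorded configurations between
#' plates, project each compressed configuration to a binary image, and fit
#' the aggregate size 2a; the replicate's size is the mean over its
#' compressed frames.  Particle-space cluster statistics (cluster count and
#' mean cluster size via [cluster_cells()]) are taken as medians over all
#' recorded snapshots, which suppresses transient unbound contacts.
#'
#' Replicate `k` uses seed `base_seed + k - 1` for every strain, so
#' replicates form matched seed sets across strains.  The whole run is
#' deterministic given `base_seed`.
#'
#' @param strains list of [strain_spec()] (default [default_strains()]).
#' @param preset `"desk"` or `"paper"` (see [sim_config()]).
#' @param base_seed integer.
#' @param n_compress_frames how many of the final recorded frames are
#'   compressed and quantified per replicate (default 3).
#' @param pixel_size projection resolution.
#' @param config optional [sim_config()] overriding the preset.
#' @param verbose per-replicate progress via `message()`.
#' @return Object of class `experiment_result`: `results` (one row per
#'   strain x replicate), `summary` (per-strain mean and SD of size),
#'   `base_seed`, `preset`, `n_compress_frames`, `errors` (per-replicate
#'   failure messages, if any).
#' @export
run_experiment <- function(strains = default_strains(), preset = "desk",
                           base_seed = 1, n_compress_frames = 3,
                           pixel_size = 1, config = NULL, verbose = TRUE) {
  nm <- vapply(strains, function(s) s$name, "")
  if (anyDuplicated(nm)) stop("strain names must be unique")
  rows <- list()
  errors <- list()
  for (s in strains) {
    par <- cell_params(A = s$A)
    tmpl <- build_cell_template(s$pattern, par)
    for (rep_i in seq_len(s$replicates)) {
      seed <- base_seed + rep_i - 1
      cfg <- if (is.null(config)) sim_config(preset, seed = seed) else {
        config$seed <- seed
        config
      }
      if (verbose)
        message(sprintf("[%s] replicate %d (seed %d) ...", s$name, rep_i,
                        seed))
      row <- tryCatch({
        t0 <- Sys.time()
        state <- initialize_system(cfg, tmpl, par, seed = seed)
        eq <- run_phase(state, cfg, tmpl, par, "equilibrate",
                        seed = seed * 16 + 1)
        rec <- run_phase(eq$state, cfg, tmpl, par, "record",
                         seed = seed * 16 + 2)
        traj <- rec$trajectory
        nsnap <- length(traj$snapshots)
        cl <- lapply(seq_len(nsnap), function(i) {
          cluster_cells(state_from_snapshot(traj, i, par$sigma_B), tmpl,
                        r_c = par$r_c)
        })
        n_clusters <- median(vapply(cl, function(x) x$n_clusters, 1))
        mean_csize <- median(vapply(cl, function(x) mean(x$sizes), 1))
        k <- min(n_compress_frames, nsnap)
        frame_ids <- seq(nsnap - k + 1, nsnap)
        sizes <- C_infs <- numeric(0)
        conv <- logical(0)
        for (f in frame_ids) {
          st <- state_from_snapshot(traj, f, par$sigma_B)
          comp <- run_phase(st, cfg, tmpl, par, "compress",
                            seed = seed * 16 + 3 + f)
          img <- project_state_to_binary(comp$state, pixel_size)
          res <- aggregate_size(img, source = sprintf("%s_rep%d_frame%d",
                                                      s$name, rep_i, f))
          sizes <- c(sizes, res$size)
          C_infs <- c(C_infs, res$fit$C_inf)
          conv <- c(conv, res$fit$converged)
        }
        use <- if (any(conv)) conv else !logical(length(sizes))
        data.frame(strain = s$name, pattern = s$pattern, A = s$A,
                   replicate = rep_i, seed = seed,
                   size_2a = mean(sizes[use]),
                   C_inf = mean(C_infs[use]),
                   n_frames = length(sizes), n_converged = sum(conv),
                   n_clusters = n_clusters, mean_cluster_size = mean_csize,
                   elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs")))
      }, error = function(e) {
        errors[[sprintf("%s_rep%d", s$name, rep_i)]] <<- conditionMessage(e)
        NULL
      })
      if (!is.null(row)) rows[[length(rows) + 1]] <- row
      if (verbose && !is.null(row))
        message(sprintf("  size 2a = %.2f  clusters = %g  (%.0fs)",
                        row$size_2a, row$n_clusters, row$elapsed_s))
    }
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(results, results$strain), function(d)
    data.frame(strain = d$strain[1], pattern = d$pattern[1], A = d$A[1],
               n = nrow(d), mean_size = mean(d$size_2a),
               sd_size = sd(d$size_2a),
               mean_n_clusters = mean(d$n_clusters))))
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary,
                 base_seed = base_seed, preset = preset,
                 n_compress_frames = n_compress_frames,
                 complete = length(errors) == 0, errors = errors),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("experiment_result (", x$preset, " preset, base seed ", x$base_seed,
      ")\n", sep = "")
  print(x$summary, row.names = FALSE)
  if (!x$complete)
    cat("INCOMPLETE:", length(x$errors), "replicate(s) failed\n")
  invisible(x)
}

#' Quantify a folder of masks and/or micrographs
#'
#' Every readable PNG/TIFF in `path` is reduced to an aggregate size: images
#' whose values are already binary are treated as masks, anything else is
#' routed through [preprocess_micrograph()] first.  Unreadable or degenerate
#' (empty-foreground) images are skipped with a recorded reason.
#'
#' @param path folder of images.
#' @param pixel_size physical length per pixel.
#' @param fit_range passed to [fit_correlation()].
#' @param ... passed to [preprocess_micrograph()] for grayscale inputs.
#' @return List with `results` (one row per image: source, type, C_inf, a,
#'   size_2a, converged, n_pixels, area_fraction), `summary` (mean/SD of
#'   size), `skipped` (named reasons).
#' @export
quantify_folder <- function(path, pixel_size = 1, fit_range = NULL, ...) {
  files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                      full.names = TRUE)
  if (!length(files)) stop("no PNG/TIFF images found in ", path)
  rows <- list()
  skipped <- list()
  for (f in files) {
    r <- tryCatch({
      img <- read_grayscale(f)
      vals <- unique(as.vector(img))
      is_mask <- length(vals) <= 2 && all(vals %in% c(0, 1))
      bi <- if (is_mask) {
        binary_image(img, pixel_size, periodic = FALSE)
      } else {
        preprocess_micrograph(img, pixel_size = pixel_size, ...)
      }
      res <- aggregate_size(bi, fit_range = fit_range, source = basename(f))
      data.frame(source = basename(f),
                 type = if (is_mask) "mask" else "grayscale",
                 C_inf = res$fit$C_inf, a = res$fit$a, size_2a = res$size,
                 converged = res$fit$converged, n_pixels = res$n_pixels,
                 area_fraction = res$area_fraction)
    }, error = function(e) {
      skipped[[basename(f)]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(r)) rows[[length(rows) + 1]] <- r
  }
  if (!length(rows)) stop("no image in ", path, " could be quantified")
  results <- do.call(rbind, rows)
  list(results = results,
       summary = data.frame(n = nrow(results),
                            mean_size = mean(results$size_2a),
                            sd_size = sd(results$size_2a)),
       skipped = skipped)
}
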