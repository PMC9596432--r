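#' Write a trajectory or state as extended XYZ
#'
#' One frame per snapshot; per-atom columns are species (`B` body, `P`
#' adhesin), position, and owning cell id, declared in the extended-XYZ
#' `Properties` string.  The comment line also carries the box as a
#' `Lattice` and the frame time.
#'
#' @param x a `trajectory` or a single `system_state`.
#' @param file output path.
#' @param template the cell template (adhesin positions are regenerated from
#'   the quaternions).
#' @return `file`, invisibly.
#' @export
write_xyz <- function(x, file, template) {
  states <- if (inherits(x, "system_state")) {
    list(x)
  } else {
    lapply(seq_along(x$snapshots), function(i)
      state_from_snapshot(x, i))
  }
  con <- file(file, "w")
  on.exit(close(con))
  for (st in states) {
    n <- nrow(st$pos)
    na <- template$n_adhesins
    ap <- adhesin_positions(st, template)
    lat <- if (inherits(x, "system_state")) st$box else x$box
    writeLines(as.character(n * (na + 1)), con)
    writeLines(sprintf(
      'Lattice="%g 0 0 0 %g 0 0 0 %g" Properties=species:S:1:pos:R:3:cell:I:1 Time=%g',
      lat[1], lat[2], lat[3], st$time), con)
    for (c in seq_len(n)) {
      writeLines(sprintf("B %.10g %.10g %.10g %d", st$pos[c, 1],
                         st$pos[c, 2], st$pos[c, 3], c), con)
      writeLines(sprintf("P %.10g %.10g %.10g %d", ap[c, , 1], ap[c, , 2],
                         ap[c, , 3], rep(c, na)), con)
    }
  }
  invisible(file)
}

#' Read an extended-XYZ trajectory
#'
#' @param file path written by [write_xyz()] (or compatible).
#' @return List of frames; each frame is a list with `atoms` (data frame:
#'   species, x, y, z, cell), `box` and `time`.
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    header <- lines[i + 1]
    lat <- regmatches(header, regexpr('Lattice="[^"]*"', header))
    box <- if (length(lat)) {
      v <- as.numeric(strsplit(gsub('Lattice="|"', "", lat), " +")[[1]])
      v[c(1, 5, 9)]
    } else rep(NA_real_, 3)
    tm <- regmatches(header, regexpr("Time=[0-9eE.+-]+", header))
    tm <- if (length(tm)) as.numeric(sub("Time=", "", tm)) else NA_real_
    rows <- strsplit(lines[(i + 2):(i + 1 + n)], " +")
    atoms <- data.frame(
      species = vapply(rows, `[`, "", 1),
      x = as.numeric(vapply(rows, `[`, "", 2)),
      y = as.numeric(vapply(rows, `[`, "", 3)),
      z = as.numeric(vapply(rows, `[`, "", 4)),
      cell = as.integer(vapply(rows, `[`, "", 5)))
    frames[[length(frames) + 1]] <- list(atoms = atoms, box = box, time = tm)
    i <- i + 2 + n
  }
  frames
}

#' Project an XYZ frame's cell bodies to a binary image
#'
#' Companion to [read_xyz()] for quantifying trajectories from disk: the `B`
#' atoms are rendered as periodic disks exactly as in
#' [project_state_to_binary()].
#'
#' @param frame one element of [read_xyz()]'s result.
#' @param pixel_size pixel edge length.
#' @param body_radius disk radius.
#' @return A periodic [binary_image()].
#' @export
project_xyz_frame <- function(frame, pixel_size = 1, body_radius = 5) {
  b <- frame$atoms[frame$atoms$species == "B", , drop = FALSE]
  box <- frame$box
  nx <- round(box[1] / pixel_size)
  ny <- round(box[2] / pixel_size)
  img <- rasterize_disks(matrix(0L, nx, ny), cbind(b$x, b$y), body_radius,
                         pixel_size, box)
  binary_image(img, pixel_size, periodic = TRUE)
}
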