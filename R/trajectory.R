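#' Trajectory container
#'
#' An in-memory trajectory: an \code{n_frames x n_atoms x 3} coordinate array
#' (nm), per-frame box matrices (nm), frame times (ps) and the constant frame
#' spacing \code{dt} (ps). Times must be strictly increasing and equally
#' spaced within 1e-6 ps.
#'
#' @param coords \code{n_frames x n_atoms x 3} array (nm).
#' @param box A 3x3 matrix (or edge vector) used for all frames, or an
#'   \code{n_frames x 3 x 3} array.
#' @param times Frame times (ps); default \code{0, dt, 2 dt, ...}.
#' @param dt Frame spacing in ps (required if `times` absent).
#' @return A \code{nanosite_trajectory} object.
#' @export
trajectory <- function(coords, box, times = NULL, dt = NULL) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  nf <- dim(coords)[1]
  if (is.null(times)) {
    if (is.null(dt)) ns_abort("either times or dt must be given", "spacing_error")
    times <- (seq_len(nf) - 1) * dt
  }
  if (length(times) != nf)
    ns_abort("times length must equal the number of frames", "spacing_error")
  if (nf > 1) {
    steps <- diff(times)
    if (any(steps <= 0))
      ns_abort("frame times must be strictly increasing", "spacing_error")
    if (max(steps) - min(steps) > 1e-6) {
      bad <- which(abs(steps - stats::median(steps)) > 1e-6)
      ns_abort(paste0("non-uniform frame spacing at frame(s) ",
                      paste(bad + 1, collapse = ", ")), "spacing_error")
    }
    dt <- stats::median(steps)
  } else dt <- dt %||% 1
  if (length(dim(box)) != 3) {
    b <- .as_box(box)
    box <- array(NA_real_, c(nf, 3, 3))
    for (f in seq_len(nf)) box[f, , ] <- b
  }
  structure(list(coords = coords, box = box, times = as.numeric(times),
                 dt = as.numeric(dt)),
            class = "nanosite_trajectory")
}

#' @export
print.nanosite_trajectory <- function(x, ...) {
  cat(sprintf("<nanosite trajectory: %d frames x %d atoms, dt = %g ps, %g ps total>\n",
              n_frames(x), dim(x$coords)[2], x$dt,
              x$times[length(x$times)] - x$times[1]))
  invisible(x)
}

#' @rdname trajectory
#' @param traj A trajectory object.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

# frame f coordinates as an n_atoms x 3 matrix
.frame <- function(traj, f) {
  x <- traj$coords[f, , , drop = TRUE]
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  x
}

.frame_box <- function(traj, f) traj$box[f, , ]

#' Load a trajectory file
#'
#' Reads a DCD binary trajectory or a multi-frame GRO text trajectory and
#' checks it against a labelled topology. GRO frame times are taken from the
#' \code{t=} field of each title line; the DCD header carries the frame
#' spacing. The frame spacing is inferred from the times and must be uniform
#' within 1e-6 ps.
#'
#' @param file Path to a \code{.dcd} or (multi-frame) \code{.gro} file.
#' @param topology Topology the trajectory must match (atom count check).
#' @param dt Frame spacing in ps, required only if the file carries no time
#'   information.
#' @return A \code{nanosite_trajectory}.
#' @export
load_trajectory <- function(file, topology, dt = NULL) {
  if (!file.exists(file))
    ns_abort(paste0("cannot read trajectory file: ", file), "format_error")
  ext <- tolower(tools::file_ext(file))
  if (ext == "dcd") {
    raw <- .read_dcd(file)
    if (dim(raw$coords)[2] != nrow(topology))
      ns_abort(sprintf("trajectory has %d atoms but topology has %d",
                       dim(raw$coords)[2], nrow(topology)), "shape_error")
    dt <- dt %||% raw$dt
    tr <- trajectory(raw$coords, raw$box[1, , ], dt = dt)
    tr$box <- raw$box
    return(tr)
  }
  if (ext %in% c("gro", "trj")) {
    frames <- .read_gro_frames(file)
    na <- nrow(frames[[1]]$atoms)
    if (na != nrow(topology))
      ns_abort(sprintf("trajectory has %d atoms but topology has %d",
                       na, nrow(topology)), "shape_error")
    nf <- length(frames)
    coords <- array(NA_real_, c(nf, na, 3))
    box <- array(NA_real_, c(nf, 3, 3))
    times <- numeric(nf)
    for (f in seq_len(nf)) {
      coords[f, , ] <- frames[[f]]$coords
      box[f, , ] <- frames[[f]]$box
      times[f] <- frames[[f]]$time
    }
    if (anyNA(times)) {
      if (is.null(dt))
        ns_abort("GRO frames carry no t= times; supply dt", "spacing_error")
      times <- (seq_len(nf) - 1) * dt
    }
    tr <- trajectory(coords, box[1, , ], times = times, dt = dt)
    tr$box <- box
    return(tr)
  }
  if (ext %in% c("xtc", "trr"))
    ns_abort("XTC/TRR are not supported; convert to DCD or GRO", "format_error")
  ns_abort(paste0("unsupported trajectory format: .", ext), "format_error")
}
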