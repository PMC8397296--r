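# GRO text format: fixed-width coordinate frames, nm units.
# Frame = title line (optionally "... t= <ps>"), atom count, atom lines
# "%5d%-5s%5s%5d%8.3f%8.3f%8.3f", box line (3 floats orthorhombic, 9 triclinic).

.parse_gro_frame <- function(lines, start) {
  title <- lines[start]
  natom <- suppressWarnings(as.integer(trimws(lines[start + 1])))
  if (is.na(natom))
    ns_abort("malformed GRO: bad atom-count line", "format_error")
  at <- lines[(start + 2):(start + 1 + natom)]
  resid <- as.integer(substr(at, 1, 5))
  resname <- trimws(substr(at, 6, 10))
  name <- trimws(substr(at, 11, 15))
  x <- as.numeric(substr(at, 21, 28))
  y <- as.numeric(substr(at, 29, 36))
  z <- as.numeric(substr(at, 37, 44))
  boxv <- as.numeric(strsplit(trimws(lines[start + 2 + natom]), "\\s+")[[1]])
  box <- diag(boxv[1:3])
  if (length(boxv) >= 9) {
    # v1(x) v2(y) v3(z) v1(y) v1(z) v2(x) v2(z) v3(x) v3(y)
    box[1, 2] <- boxv[4]; box[1, 3] <- boxv[5]
    box[2, 1] <- boxv[6]; box[2, 3] <- boxv[7]
    box[3, 1] <- boxv[8]; box[3, 2] <- boxv[9]
  }
  tm <- NA_real_
  m <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1]]
  if (length(m) == 2) tm <- as.numeric(m[2])
  list(atoms = tibble(name = name, resid = resid, resname = resname),
       coords = unname(cbind(x, y, z)), box = box, time = tm,
       next_start = start + 3 + natom)
}

.read_gro_atoms <- function(file) {
  lines <- readLines(file)
  fr <- .parse_gro_frame(lines, 1)
  fr[c("atoms", "coords", "box")]
}

# all frames of a (possibly multi-frame) GRO file
.read_gro_frames <- function(file) {
  lines <- readLines(file)
  frames <- list(); i <- 1
  while (i + 2 <= length(lines) && nzchar(trimws(lines[i + 1]))) {
    fr <- .parse_gro_frame(lines, i)
    frames[[length(frames) + 1]] <- fr
    i <- fr$next_start
    if (i > length(lines)) break
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1
    if (i > length(lines)) break
  }
  frames
}

#' Write coordinates to a GRO file
#'
#' Writes one or more frames in GROMACS GRO format (nm). Frame times are
#' recorded in the title line as \code{t= <ps>} so trajectories written this
#' way round-trip through [load_trajectory()].
#'
#' @param topology Topology tibble.
#' @param coords A single n x 3 matrix or an n_frames x n_atoms x 3 array (nm).
#' @param box 3x3 box matrix or edge-length vector (nm).
#' @param file Output path.
#' @param times Frame times in ps (defaults to 0, 1, 2, ... for arrays).
#' @return Invisibly, `file`.
#' @export
write_gro <- function(topology, coords, box, file, times = NULL) {
  if (length(dim(coords)) == 2) {
    coords <- array(coords, dim = c(1, dim(coords)))
  }
  nf <- dim(coords)[1]
  times <- times %||% (seq_len(nf) - 1)
  box <- .as_box(box)
  if (!.is_orthorhombic(box))
    boxline <- paste(sprintf("%10.5f", c(diag(box), box[1, 2], box[1, 3],
                                         box[2, 1], box[2, 3],
                                         box[3, 1], box[3, 2])), collapse = "")
  else boxline <- paste(sprintf("%10.5f", diag(box)), collapse = "")
  con <- file(file, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    xyz <- coords[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    writeLines(sprintf("synthetic nanozyme frame t= %.4f", times[f]), con)
    writeLines(sprintf("%5d", nrow(topology)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       topology$resid %% 100000,
                       substr(topology$resname, 1, 5),
                       substr(topology$name, 1, 5),
                       topology$index %% 100000,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines(boxline, con)
  }
  invisible(file)
}
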