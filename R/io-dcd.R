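# Minimal CHARMM-style DCD binary trajectory I/O.
# Little-endian Fortran unformatted records; coordinates stored in Angstrom
# (converted from/to nm here), unit-cell record per frame, frame time step
# stored in the header in AKMA units as CHARMM does.

.AKMA_PS <- 0.0488882129

.write_record <- function(con, raw_bytes) {
  writeBin(as.integer(length(raw_bytes)), con, size = 4, endian = "little")
  writeBin(raw_bytes, con)
  writeBin(as.integer(length(raw_bytes)), con, size = 4, endian = "little")
}

.read_record <- function(con) {
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (length(n) == 0) return(NULL)
  bytes <- readBin(con, "raw", n)
  readBin(con, "integer", 1, size = 4, endian = "little")
  bytes
}

#' Write a trajectory to a DCD file
#'
#' Writes a CHARMM-format binary DCD (coordinates converted to Angstrom, one
#' unit-cell record per frame, frame spacing recorded in the header). Readable
#' by [load_trajectory()] and by standard MD tools.
#'
#' @param traj A trajectory object (see [trajectory()]).
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_dcd <- function(traj, file) {
  con <- file(file, "wb")
  on.exit(close(con))
  nf <- n_frames(traj)
  na <- dim(traj$coords)[2]
  icntrl <- integer(20)
  icntrl[1] <- nf          # frames
  icntrl[2] <- 1L          # first step
  icntrl[3] <- 1L          # save interval
  icntrl[4] <- nf
  icntrl[11] <- 1L         # crystal record present
  icntrl[20] <- 24L        # CHARMM version flag
  hdr <- c(charToRaw("CORD"),
           writeBin(icntrl[1:9], raw(), size = 4, endian = "little"),
           writeBin(as.numeric(traj$dt / .AKMA_PS), raw(), size = 4,
                    endian = "little"),
           writeBin(icntrl[11:20], raw(), size = 4, endian = "little"))
  .write_record(con, hdr)
  title <- sprintf("%-80s", "synthetic nanozyme trajectory")
  .write_record(con, c(writeBin(1L, raw(), size = 4, endian = "little"),
                       charToRaw(title)))
  .write_record(con, writeBin(as.integer(na), raw(), size = 4, endian = "little"))
  for (f in seq_len(nf)) {
    box <- .as_box(traj$box[f, , ])
    L <- diag(box) * 10  # nm -> Angstrom; orthorhombic cell assumed on write
    cell <- c(L[1], 0, L[2], 0, 0, L[3])  # A, cos(g), B, cos(b), cos(a), C
    .write_record(con, writeBin(as.numeric(cell), raw(), size = 8,
                                endian = "little"))
    for (k in 1:3)
      .write_record(con, writeBin(as.numeric(traj$coords[f, , k] * 10), raw(),
                                  size = 4, endian = "little"))
  }
  invisible(file)
}

# returns list(coords [nf x na x 3] nm, box [nf x 3 x 3] nm, dt ps)
.read_dcd <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  hdr <- .read_record(con)
  if (is.null(hdr) || rawToChar(hdr[1:4]) != "CORD")
    ns_abort("not a DCD file (missing CORD magic)", "format_error")
  ic <- readBin(hdr[5:84], "integer", 20, size = 4, endian = "little")
  nf <- ic[1]
  delta <- readBin(hdr[(4 + 9 * 4 + 1):(4 + 10 * 4)], "numeric", 1, size = 4,
                   endian = "little")
  has_cell <- ic[11] == 1
  .read_record(con)  # titles
  na <- readBin(.read_record(con), "integer", 1, size = 4, endian = "little")
  coords <- array(NA_real_, c(nf, na, 3))
  box <- array(NA_real_, c(nf, 3, 3))
  for (f in seq_len(nf)) {
    if (has_cell) {
      cell <- readBin(.read_record(con), "numeric", 6, size = 8,
                      endian = "little")
      box[f, , ] <- diag(cell[c(1, 3, 6)] / 10)
    } else box[f, , ] <- diag(3) * NA_real_
    for (k in 1:3)
      coords[f, , k] <- readBin(.read_record(con), "numeric", na, size = 4,
                                endian = "little") / 10
  }
  list(coords = coords, box = box, dt = delta * .AKMA_PS)
}
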