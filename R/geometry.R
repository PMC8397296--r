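#' Minimum-image periodic distance
#'
#' Euclidean distance between points under periodic boundary conditions using
#' the minimum-image convention. The box is given as a 3x3 matrix whose rows
#' are the lattice vectors in nm (GROMACS convention); orthorhombic and
#' triclinic cells are supported. For triclinic cells the fractional-rounding
#' image is refined by an explicit search over neighbouring image shifts.
#'
#' @param a,b Numeric 3-vectors, or n x 3 matrices of positions (nm).
#' @param box 3x3 matrix of lattice vectors (rows), or a length-3 vector of
#'   orthorhombic edge lengths.
#' @return Distance(s) in nm; a scalar for vector input, a length-n vector for
#'   matrix input.
#' @export
periodic_distance <- function(a, b, box) {
  box <- .as_box(box)
  a <- .as_coord_matrix(a)
  b <- .as_coord_matrix(b)
  if (nrow(a) == 1 && nrow(b) > 1) a <- a[rep(1, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1 && nrow(a) > 1) b <- b[rep(1, nrow(a)), , drop = FALSE]
  stopifnot(nrow(a) == nrow(b))
  d <- .min_image(a - b, box)
  unname(sqrt(rowSums(d * d)))
}

.as_coord_matrix <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3) else as.matrix(x)
}

.as_box <- function(box) {
  if (is.null(dim(box))) box <- diag(as.numeric(box), 3)
  box <- as.matrix(box)
  if (!all(dim(box) == c(3, 3)))
    ns_abort("box must be a 3x3 matrix or length-3 edge vector", "geometry_error")
  if (abs(det(box)) < 1e-12)
    ns_abort("degenerate (zero-volume) simulation box", "geometry_error")
  box
}

.is_orthorhombic <- function(box) {
  all(abs(box[upper.tri(box) | lower.tri(box)]) < 1e-12)
}

# minimum-image displacement vectors; d is an n x 3 matrix of raw differences
.min_image <- function(d, box) {
  d <- .as_coord_matrix(d)
  if (.is_orthorhombic(box)) {
    L <- diag(box)
    for (k in 1:3) d[, k] <- d[, k] - L[k] * round(d[, k] / L[k])
    return(d)
  }
  inv <- solve(box)
  s <- d %*% inv
  s <- s - round(s)
  best <- s %*% box
  bestd2 <- rowSums(best * best)
  # triclinic: rounding in fractional space can miss the true image
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    if (i == 0 && j == 0 && k == 0) next
    cand <- best + matrix(rep(c(i, j, k) %*% box, nrow(best)),
                          ncol = 3, byrow = TRUE)
    d2 <- rowSums(cand * cand)
    take <- d2 < bestd2
    if (any(take)) {
      best[take, ] <- cand[take, , drop = FALSE]
      bestd2[take] <- d2[take]
    }
  }
  best
}

# cross distance matrix |A| x |B| under minimum image (orthorhombic fast path;
# fractional wrap for triclinic)
.pdist_cross <- function(A, B, box) {
  A <- .as_coord_matrix(A); B <- .as_coord_matrix(B)
  box <- .as_box(box)
  if (.is_orthorhombic(box)) {
    L <- diag(box)
    d2 <- 0
    for (k in 1:3) {
      dk <- outer(A[, k], B[, k], "-")
      dk <- dk - L[k] * round(dk / L[k])
      d2 <- d2 + dk * dk
    }
    return(sqrt(d2))
  }
  inv <- solve(box)
  SA <- A %*% inv; SB <- B %*% inv
  ds <- lapply(1:3, function(k) {
    dk <- outer(SA[, k], SB[, k], "-")
    dk - round(dk)
  })
  d2 <- 0
  for (k in 1:3) {
    cart <- ds[[1]] * box[1, k] + ds[[2]] * box[2, k] + ds[[3]] * box[3, k]
    d2 <- d2 + cart * cart
  }
  sqrt(d2)
}

#' Mass-weighted centre of mass
#'
#' Mass-weighted mean position of a selection in one frame. Coordinates are
#' unwrapped with respect to the first selected atom via minimum-image
#' displacements before averaging, so a selection straddling a periodic
#' boundary yields the physically meaningful centre.
#'
#' @param topology A [load_topology()] topology tibble.
#' @param frame An n_atoms x 3 coordinate matrix (nm).
#' @param roles Character vector of roles selecting the atoms (see
#'   [atom_roles()]); alternatively pass explicit `indices`.
#' @param box Box matrix for the frame (3x3 or edge lengths).
#' @param indices Optional explicit atom indices overriding `roles`.
#' @return Numeric 3-vector (nm).
#' @export
center_of_mass <- function(topology, frame, roles = "GOLD", box, indices = NULL) {
  idx <- indices %||% which(topology$role %in% roles)
  if (length(idx) == 0)
    ns_abort("empty selection for centre of mass", "selection_error")
  x <- .as_coord_matrix(frame)[idx, , drop = FALSE]
  m <- topology$mass[idx]
  ref <- x[1, ]
  disp <- .min_image(sweep(x, 2, ref), .as_box(box))
  unname(ref + colSums(disp * m) / sum(m))
}

# Kabsch superposition: rotate+translate each frame onto frame 1 using the fit
# selection (no PBC; the fit selection is assumed compact, e.g. the gold core).
.superpose <- function(coords, fit_idx) {
  nf <- dim(coords)[1]
  ref <- coords[1, fit_idx, , drop = TRUE]
  if (is.null(dim(ref))) ref <- matrix(ref, ncol = 3)
  ref_c <- colMeans(ref)
  ref0 <- sweep(ref, 2, ref_c)
  out <- coords
  for (f in seq_len(nf)) {
    mob <- coords[f, fit_idx, , drop = TRUE]
    if (is.null(dim(mob))) mob <- matrix(mob, ncol = 3)
    mob_c <- colMeans(mob)
    H <- crossprod(sweep(mob, 2, mob_c), ref0)
    sv <- svd(H)
    dsign <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, dsign)) %*% t(sv$u)
    all_f <- coords[f, , , drop = TRUE]
    out[f, , ] <- sweep(sweep(all_f, 2, mob_c) %*% t(R), 2, ref_c, "+")
  }
  out
}
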