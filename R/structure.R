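#' Radial distribution function and cumulative coordination number
#'
#' Computes g(r) and the running coordination number N(r) of a target
#' selection around a reference selection, averaged over frames, under
#' periodic boundary conditions. g(r) is normalised by the ideal-gas density
#' of the target selection in the box; N(r) is the mean number of target
#' atoms within r of a reference atom, so N(r) -> n_target as r grows (minus
#' self-pairs when the selections overlap).
#'
#' With \code{from_center = TRUE} the reference is the single per-frame
#' centre of mass of the gold core — the convention used for describing how
#' monolayer segments, Zn, Cl and water are layered around the particle.
#'
#' @param traj Trajectory.
#' @param topology Topology tibble.
#' @param reference,target Role sets (character vectors, see [atom_roles()])
#'   or explicit index vectors.
#' @param bin_width Bin width (nm).
#' @param r_max Histogram range (nm); must not exceed half the shortest box
#'   edge. Default: half the shortest box edge.
#' @param from_center Use the gold-core centre of mass as the (single)
#'   reference point.
#' @return A tibble of class \code{nanosite_rdf} with columns \code{r}
#'   (bin centre, nm), \code{g} and \code{n_cum}.
#' @export
radial_distribution <- function(traj, topology, reference, target,
                                bin_width = 0.02, r_max = NULL,
                                from_center = FALSE) {
  tgt <- .resolve_selection(topology, target)
  if (length(tgt) == 0) ns_abort("empty target selection", "selection_error")
  nf <- n_frames(traj)
  box0 <- .frame_box(traj, 1)
  half_min <- min(diag(.as_box(box0))) / 2
  r_max <- r_max %||% half_min
  if (r_max > half_min + 1e-9)
    ns_abort("r_max exceeds half the shortest box edge", "geometry_error")
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, edges[length(edges)] + bin_width)
  hist_acc <- numeric(length(edges) - 1)
  nref_total <- 0
  vol <- abs(det(.as_box(box0)))
  self_overlap <- 0
  for (f in seq_len(nf)) {
    xyz <- .frame(traj, f)
    box <- .frame_box(traj, f)
    if (from_center) {
      refpts <- matrix(center_of_mass(topology, xyz, roles = "GOLD", box = box),
                       ncol = 3)
      nref <- 1
    } else {
      ref <- .resolve_selection(topology, reference)
      if (length(ref) == 0) ns_abort("empty reference selection", "selection_error")
      refpts <- xyz[ref, , drop = FALSE]
      nref <- length(ref)
      if (f == 1) self_overlap <- length(intersect(ref, tgt))
    }
    d <- .pdist_cross(refpts, xyz[tgt, , drop = FALSE], box)
    d <- d[d > 1e-9 & d <= r_max]
    hist_acc <- hist_acc + .bin_counts(d, edges)
    nref_total <- nref_total + nref
  }
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  shell_vol <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  rho <- length(tgt) / vol
  mean_counts <- hist_acc / nref_total
  out <- tibble(r = centers, g = mean_counts / (rho * shell_vol),
                n_cum = cumsum(mean_counts))
  attr(out, "reference") <- if (from_center) "gold_com" else reference
  attr(out, "target") <- target
  attr(out, "bin_width") <- bin_width
  class(out) <- c("nanosite_rdf", class(out))
  out
}

.bin_counts <- function(d, edges) {
  if (length(d) == 0) return(numeric(length(edges) - 1))
  idx <- pmin(findInterval(d, edges, left.open = TRUE), length(edges) - 1)
  idx[idx == 0] <- 1
  tabulate(idx, nbins = length(edges) - 1)
}

.resolve_selection <- function(topology, sel) {
  if (is.numeric(sel)) return(as.integer(sel))
  select_atoms(topology, roles = sel)
}

#' Per-shell mean atom counts around the gold core
#'
#' Mean number of target atoms whose distance to the per-frame gold-core
#' centre of mass lies in each half-open shell \code{[r_lo, r_hi)}.
#'
#' @param traj Trajectory.
#' @param topology Topology tibble.
#' @param target Role set or index vector.
#' @param shells Two-column matrix or data frame of (r_lo, r_hi) in nm;
#'   shells must be ordered and non-overlapping.
#' @return Tibble with columns \code{r_lo}, \code{r_hi}, \code{mean_count}.
#' @export
shell_counts <- function(traj, topology, target, shells) {
  shells <- as.matrix(shells)
  if (any(shells[, 2] <= shells[, 1]) ||
      (nrow(shells) > 1 && any(shells[-1, 1] < shells[-nrow(shells), 2])))
    ns_abort("shells must be ordered and non-overlapping", "config_error")
  tgt <- .resolve_selection(topology, target)
  if (length(tgt) == 0) ns_abort("empty target selection", "selection_error")
  nf <- n_frames(traj)
  acc <- numeric(nrow(shells))
  for (f in seq_len(nf)) {
    xyz <- .frame(traj, f)
    box <- .frame_box(traj, f)
    com <- center_of_mass(topology, xyz, roles = "GOLD", box = box)
    d <- .pdist_cross(matrix(com, ncol = 3), xyz[tgt, , drop = FALSE], box)[1, ]
    for (s in seq_len(nrow(shells)))
      acc[s] <- acc[s] + sum(d >= shells[s, 1] & d < shells[s, 2])
  }
  tibble(r_lo = shells[, 1], r_hi = shells[, 2], mean_count = acc / nf)
}

#' Root-mean-square fluctuation per atom
#'
#' Each frame is rigid-body superposed onto the first frame using the fit
#' selection (the gold core by default — the rigid body of record), then the
#' per-atom RMSF about its mean position is computed over frames.
#'
#' @param traj Trajectory (>= 2 frames).
#' @param topology Topology tibble.
#' @param fit Role set (or indices) used for the superposition.
#' @param target Role set (or indices) to report; default all atoms.
#' @return Tibble with columns \code{index}, \code{name}, \code{role},
#'   \code{rmsf} (nm).
#' @export
rmsf <- function(traj, topology, fit = "GOLD", target = NULL) {
  if (n_frames(traj) < 2)
    ns_abort("RMSF needs at least 2 frames", "insufficient_data_error")
  fit_idx <- .resolve_selection(topology, fit)
  if (length(fit_idx) == 0) ns_abort("empty fit selection", "selection_error")
  tgt <- if (is.null(target)) seq_len(nrow(topology))
         else .resolve_selection(topology, target)
  sup <- .superpose(traj$coords, fit_idx)
  mean_pos <- apply(sup[, tgt, , drop = FALSE], c(2, 3), mean)
  dev2 <- 0
  for (f in seq_len(n_frames(traj))) {
    d <- sup[f, tgt, , drop = TRUE]
    if (is.null(dim(d))) d <- matrix(d, ncol = 3)
    dev2 <- dev2 + rowSums((d - mean_pos)^2)
  }
  tibble(index = topology$index[tgt], name = topology$name[tgt],
         role = topology$role[tgt],
         rmsf = sqrt(dev2 / n_frames(traj)))
}

#' Radius of gyration
#'
#' Mass-weighted radius of gyration of a selection about its centre of mass,
#' per frame, with mean and standard deviation over frames.
#'
#' @param traj Trajectory.
#' @param topology Topology tibble.
#' @param selection Role set or index vector.
#' @return Tibble of class \code{nanosite_rg} with columns \code{frame},
#'   \code{time_ps}, \code{rg}; attributes \code{mean} and \code{sd}.
#' @export
radius_of_gyration <- function(traj, topology, selection) {
  idx <- .resolve_selection(topology, selection)
  if (length(idx) == 0) ns_abort("empty selection", "selection_error")
  m <- topology$mass[idx]
  rg <- vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- .frame(traj, f)[idx, , drop = FALSE]
    com <- colSums(xyz * m) / sum(m)
    sqrt(sum(m * rowSums(sweep(xyz, 2, com)^2)) / sum(m))
  }, numeric(1))
  out <- tibble(frame = seq_len(n_frames(traj)), time_ps = traj$times, rg = rg)
  attr(out, "mean") <- mean(rg); attr(out, "sd") <- sd(rg)
  class(out) <- c("nanosite_rg", class(out))
  out
}

#' Shape eccentricity from principal moments of inertia
#'
#' \eqn{e = 1 - I_{min} / I_{avg}} computed from the principal moments of the
#' selection's inertia tensor; 0 for a spherically symmetric body, -> 1 for a
#' rod.
#'
#' @inheritParams radius_of_gyration
#' @return Tibble with columns \code{frame}, \code{time_ps},
#'   \code{eccentricity}; attributes \code{mean} and \code{sd}.
#' @export
eccentricity <- function(traj, topology, selection) {
  idx <- .resolve_selection(topology, selection)
  if (length(idx) < 3) ns_abort("need at least 3 atoms", "selection_error")
  m <- topology$mass[idx]
  ecc <- vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- .frame(traj, f)[idx, , drop = FALSE]
    com <- colSums(xyz * m) / sum(m)
    x <- sweep(xyz, 2, com)
    r2 <- rowSums(x^2)
    I <- diag(sum(m * r2), 3) - crossprod(x * sqrt(m))
    # crossprod(x*sqrt(m)) = sum_i m_i x_i x_i^T
    ev <- eigen(I, symmetric = TRUE, only.values = TRUE)$values
    if (max(ev) < 1e-14 || min(ev) < 1e-12 * max(ev))
      ns_abort("degenerate (collinear) selection for eccentricity",
               "geometry_error")
    1 - min(ev) / mean(ev)
  }, numeric(1))
  out <- tibble(frame = seq_len(n_frames(traj)), time_ps = traj$times,
                eccentricity = ecc)
  attr(out, "mean") <- mean(ecc); attr(out, "sd") <- sd(ecc)
  out
}
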