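#' Rotational (P2) autocorrelation of bond vectors in a trajectory
#'
#' For each supplied atom pair, the unit vector from the first to the second
#' atom is tracked after superposing every frame onto the first frame on the
#' gold core (so overall particle tumbling — absent by construction in the
#' synthetic fixtures — does not contaminate the internal decay). Pairs
#' sharing a label are averaged into one autocorrelation.
#'
#' @param traj Trajectory (>= 2 frames).
#' @param topology Topology tibble.
#' @param pairs Data frame with columns \code{from}, \code{to} (atom indices)
#'   and optional \code{label}; pairs with the same label are averaged.
#' @param max_lag Largest lag in ps (default half the trajectory).
#' @param fit Role set for the superposition; \code{NULL} disables fitting.
#' @return Tibble with columns \code{label}, \code{lag_ps}, \code{acf}.
#' @export
rotational_acf <- function(traj, topology, pairs, max_lag = NULL,
                           fit = "GOLD") {
  if (n_frames(traj) < 2)
    ns_abort("need at least 2 frames", "insufficient_data_error")
  pairs <- as_tibble(pairs)
  if (!"label" %in% names(pairs)) pairs$label <- "all"
  coords <- traj$coords
  if (!is.null(fit)) {
    fit_idx <- .resolve_selection(topology, fit)
    if (length(fit_idx) >= 3) coords <- .superpose(coords, fit_idx)
  }
  out <- list()
  for (lb in unique(pairs$label)) {
    pp <- pairs[pairs$label == lb, ]
    vecs <- array(NA_real_, c(dim(coords)[1], 3, nrow(pp)))
    for (j in seq_len(nrow(pp))) {
      v <- coords[, pp$to[j], ] - coords[, pp$from[j], ]
      nrm <- sqrt(rowSums(v * v))
      if (any(nrm < 1e-12))
        ns_abort(sprintf("coincident atoms %d/%d at frame %d",
                         pp$from[j], pp$to[j], which(nrm < 1e-12)[1]),
                 "geometry_error")
      vecs[, , j] <- v
    }
    a <- p2_acf(vecs, dt = traj$dt, max_lag = max_lag)
    a$label <- lb
    out[[lb]] <- a[, c("label", "lag_ps", "acf")]
  }
  dplyr::bind_rows(out)
}

#' CH-vector P2 autocorrelation for one carbon position
#'
#' Builds the CH bond vectors for every ligand's copy of the named carbon
#' (hydrogens are matched by the naming convention H<k> next to C<k>, or by
#' proximity < 0.12 nm in the first frame), superposes frames on the gold
#' core, and returns the P2 autocorrelation averaged over all equivalent
#' carbons and attached hydrogens.
#'
#' @param traj Trajectory.
#' @param topology Topology tibble.
#' @param carbon Atom name of the carbon (e.g. \code{"C7"}, \code{"C12"}).
#' @param max_lag Largest lag in ps.
#' @param fit Role set for superposition (default gold core).
#' @return Tibble with columns \code{lag_ps}, \code{acf}.
#' @export
ch_acf <- function(traj, topology, carbon, max_lag = NULL, fit = "GOLD") {
  cidx <- select_atoms(topology, names = carbon)
  if (length(cidx) == 0)
    ns_abort(paste0("no atoms named ", carbon), "selection_error")
  if (any(topology$element[cidx] != "C"))
    ns_abort(paste0(carbon, " is not a carbon position"), "labeling_error")
  pairs <- list()
  x1 <- .frame(traj, 1)
  box1 <- .frame_box(traj, 1)
  for (ci in cidx) {
    hname <- sub("^C", "H", carbon)
    h <- select_atoms(topology, names = hname, ligand = topology$ligand_id[ci])
    if (length(h) == 0) {
      hyd <- which(topology$element == "H")
      if (length(hyd) > 0) {
        d <- .pdist_cross(x1[ci, , drop = FALSE],
                          x1[hyd, , drop = FALSE], box1)[1, ]
        h <- hyd[d < 0.12]
      }
    }
    if (length(h) == 0)
      ns_abort(sprintf("carbon atom %d (%s) has no attached hydrogen",
                       ci, carbon), "labeling_error")
    for (hi in h) pairs[[length(pairs) + 1]] <- tibble(from = ci, to = hi)
  }
  pr <- dplyr::bind_rows(pairs)
  pr$label <- carbon
  rotational_acf(traj, topology, pr, max_lag = max_lag,
                 fit = fit)[, c("lag_ps", "acf")]
}
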