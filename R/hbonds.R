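#' Geometric hydrogen-bond detection
#'
#' A hydrogen bond exists between a donor D (bearing hydrogen H) and an
#' acceptor A when the D...A distance is at most `d_cut` and the H-D...A
#' angle is at most `angle_cut` — the de facto standard geometric criterion
#' in MD analysis (defaults 0.35 nm / 30 degrees). Hydrogens are paired with
#' their donors by covalent proximity (< 0.18 nm) in the first frame; a
#' hydrogen without a bonded donor is a labelling error.
#'
#' Each bond is tagged \code{interligand} (donor and acceptor on distinct
#' ligands), \code{intraligand} (same ligand), \code{ligand_water} (one side
#' is water), or \code{other}.
#'
#' @param traj Trajectory.
#' @param topology Topology tibble.
#' @param donors,hydrogens,acceptors Role sets or index vectors.
#' @param d_cut Donor-acceptor cutoff (nm), inclusive.
#' @param angle_cut H-D...A angle cutoff (degrees), inclusive.
#' @return List with \code{bonds}, a tibble (frame, donor, hydrogen, acceptor,
#'   distance, angle, tag), and \code{summary}, mean +/- sd bonds per frame
#'   overall and by tag.
#' @export
hydrogen_bonds <- function(traj, topology, donors, hydrogens, acceptors,
                           d_cut = 0.35, angle_cut = 30) {
  don <- .resolve_selection(topology, donors)
  hyd <- .resolve_selection(topology, hydrogens)
  acc <- .resolve_selection(topology, acceptors)
  if (!length(don) || !length(hyd) || !length(acc))
    ns_abort("empty donor/hydrogen/acceptor selection", "selection_error")
  x1 <- .frame(traj, 1); box1 <- .frame_box(traj, 1)
  dh <- .pdist_cross(x1[hyd, , drop = FALSE], x1[don, , drop = FALSE], box1)
  don_of <- don[apply(dh, 1, which.min)]
  if (any(apply(dh, 1, min) > 0.18)) {
    bad <- hyd[apply(dh, 1, min) > 0.18][1]
    ns_abort(sprintf("hydrogen atom %d has no bonded donor within 0.18 nm", bad),
             "labeling_error")
  }
  nf <- n_frames(traj)
  res <- list()
  for (f in seq_len(nf)) {
    xyz <- .frame(traj, f); box <- .frame_box(traj, f)
    da <- .pdist_cross(xyz[don_of, , drop = FALSE], xyz[acc, , drop = FALSE], box)
    hits <- which(da <= d_cut & da > 1e-9, arr.ind = TRUE)
    if (nrow(hits) == 0) next
    hi <- hyd[hits[, 1]]; di <- don_of[hits[, 1]]; ai <- acc[hits[, 2]]
    keep <- di != ai
    hi <- hi[keep]; di <- di[keep]; ai <- ai[keep]
    if (!length(hi)) next
    vh <- .min_image(xyz[hi, , drop = FALSE] - xyz[di, , drop = FALSE], box)
    va <- .min_image(xyz[ai, , drop = FALSE] - xyz[di, , drop = FALSE], box)
    csa <- rowSums(vh * va) /
      (sqrt(rowSums(vh * vh)) * sqrt(rowSums(va * va)))
    ang <- acos(pmin(1, pmax(-1, csa))) * 180 / pi
    ok <- ang <= angle_cut
    if (!any(ok)) next
    res[[length(res) + 1]] <- tibble(
      frame = f, donor = di[ok], hydrogen = hi[ok], acceptor = ai[ok],
      distance = da[hits[, 1:2, drop = FALSE]][keep][ok], angle = ang[ok])
  }
  bonds <- if (length(res)) dplyr::bind_rows(res) else
    tibble(frame = integer(), donor = integer(), hydrogen = integer(),
           acceptor = integer(), distance = numeric(), angle = numeric())
  bonds$tag <- .hb_tag(topology, bonds$donor, bonds$acceptor)
  counts <- tabulate(bonds$frame, nbins = nf)
  summ <- dplyr::bind_rows(
    tibble(tag = "all", mean = mean(counts), sd = sd(counts)),
    dplyr::group_by(bonds, .data$tag) |>
      dplyr::summarise(mean = dplyr::n() / nf, .groups = "drop") |>
      dplyr::mutate(sd = vapply(.data$tag, function(tg) {
        sd(tabulate(bonds$frame[bonds$tag == tg], nbins = nf))
      }, numeric(1))))
  list(bonds = bonds, summary = summ)
}

.hb_tag <- function(topology, donor, acceptor) {
  ld <- topology$ligand_id[donor]; la <- topology$ligand_id[acceptor]
  wd <- topology$role[donor] %in% c("WATER_O", "WATER_H")
  wa <- topology$role[acceptor] %in% c("WATER_O", "WATER_H")
  dplyr::case_when(
    (wd & !is.na(la)) | (wa & !is.na(ld)) ~ "ligand_water",
    !is.na(ld) & !is.na(la) & ld != la ~ "interligand",
    !is.na(ld) & !is.na(la) & ld == la ~ "intraligand",
    .default = "other")
}

#' Close contacts between two selections
#'
#' Unordered atom pairs (one from each selection) whose minimum-image
#' distance is at most `cutoff`, per frame, with the per-frame count summary
#' used for Zn...O8, Zn...water and Zn...Cl tallies (the latter two at the
#' 0.25 nm cutoff).
#'
#' @param traj Trajectory.
#' @param topology Topology tibble.
#' @param group_a,group_b Role sets or index vectors.
#' @param cutoff Distance cutoff (nm), inclusive.
#' @return List with \code{contacts} tibble (frame, a, b, distance) and
#'   \code{summary} (mean, sd of per-frame counts).
#' @export
close_contacts <- function(traj, topology, group_a, group_b, cutoff) {
  A <- .resolve_selection(topology, group_a)
  B <- .resolve_selection(topology, group_b)
  if (!length(A) || !length(B))
    ns_abort("empty contact selection", "selection_error")
  nf <- n_frames(traj)
  res <- list()
  for (f in seq_len(nf)) {
    xyz <- .frame(traj, f); box <- .frame_box(traj, f)
    d <- .pdist_cross(xyz[A, , drop = FALSE], xyz[B, , drop = FALSE], box)
    hits <- which(d <= cutoff & d > 1e-9, arr.ind = TRUE)
    if (nrow(hits) == 0) next
    ai <- A[hits[, 1]]; bi <- B[hits[, 2]]
    keep <- ai != bi
    if (any(duplicated(cbind(pmin(ai, bi), pmax(ai, bi))))) {
      dup <- duplicated(cbind(pmin(ai, bi), pmax(ai, bi)))
      keep <- keep & !dup
    }
    if (!any(keep)) next
    res[[length(res) + 1]] <- tibble(frame = f, a = ai[keep], b = bi[keep],
                                     distance = d[hits[, , drop = FALSE]][keep])
  }
  contacts <- if (length(res)) dplyr::bind_rows(res) else
    tibble(frame = integer(), a = integer(), b = integer(),
           distance = numeric())
  counts <- tabulate(contacts$frame, nbins = nf)
  list(contacts = contacts,
       summary = tibble(mean = mean(counts), sd = sd(counts)))
}
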