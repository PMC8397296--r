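#' Event schedules for the synthetic generator
#'
#' A schedule is a tibble of planted events, one row per event, with columns
#' \code{kind} (one of \code{ZN_PAIR}, \code{MONO_BINDING}, \code{BI_BINDING},
#' \code{PRECAT_1}, \code{PRECAT_2}, \code{PRECAT_3}), \code{zn1}/\code{zn2}
#' (ligand ids of the participating Zn; \code{zn2 = NA} for single-Zn kinds),
#' \code{substrate} (substrate id or \code{NA}), \code{start} (first frame,
#' 1-based), \code{duration} (frames), and planted geometry columns
#' \code{d_znzn}, \code{d1}, \code{d2}, \code{d3}, \code{d4}, \code{d5} (nm;
#' \code{NA} where not applicable). During the scheduled interval the
#' generator places the participants so these distances hold exactly; outside
#' it the same atoms are kept beyond 1.5x the relevant detection cutoff.
#'
#' Intervals of events sharing a participant must not overlap, and all frames
#' must lie inside the trajectory.
#'
#' @param ... Tibbles or data frames of schedule rows (see
#'   [schedule_event()]).
#' @param n_frames Trajectory length the schedule must fit in.
#' @return A validated schedule tibble.
#' @export
event_schedule <- function(..., n_frames) {
  sch <- dplyr::bind_rows(...)
  if (nrow(sch) == 0) return(sch)
  need <- c("kind", "zn1", "zn2", "substrate", "start", "duration",
            "d_znzn", "d1", "d2", "d3", "d4", "d5")
  for (cn in setdiff(need, names(sch))) sch[[cn]] <- NA_real_
  sch <- sch[, need]
  kinds <- c("ZN_PAIR", "MONO_BINDING", "BI_BINDING",
             "PRECAT_1", "PRECAT_2", "PRECAT_3")
  if (!all(sch$kind %in% kinds))
    ns_abort("unknown event kind in schedule", "schedule_error")
  if (any(sch$start < 1 | sch$start + sch$duration - 1 > n_frames))
    ns_abort("scheduled event exceeds trajectory length", "schedule_error")
  # per-participant overlap check
  parts <- function(row) {
    c(paste0("zn", stats::na.omit(c(row$zn1, row$zn2))),
      if (!is.na(row$substrate)) paste0("sub", row$substrate))
  }
  for (p in unique(unlist(lapply(seq_len(nrow(sch)), function(i) parts(sch[i, ]))))) {
    hit <- vapply(seq_len(nrow(sch)), function(i) p %in% parts(sch[i, ]), logical(1))
    iv <- sch[hit, ]
    iv <- iv[order(iv$start), ]
    if (nrow(iv) > 1 &&
        any(iv$start[-1] <= (iv$start + iv$duration - 1)[-nrow(iv)]))
      ns_abort(paste0("overlapping scheduled intervals for participant ", p),
               "schedule_error")
  }
  sch
}

#' @rdname event_schedule
#' @param kind Event kind.
#' @param zn1,zn2 Ligand ids of participating Zn ions.
#' @param substrate Substrate id.
#' @param start First frame (1-based).
#' @param duration Duration in frames.
#' @param d_znzn Planted Zn-Zn distance (nm; ZN_PAIR).
#' @param d1,d2,d3 Planted O4-Zn / O5-Zn / O3-Zn distances (nm).
#' @param d4,d5 Planted Zn-water-oxygen and water-oxygen-O3 distances (nm) for
#'   solvated complexes; leave \code{NA} for unsolvated events.
#' @export
schedule_event <- function(kind, zn1, zn2 = NA, substrate = NA, start,
                           duration, d_znzn = NA, d1 = NA, d2 = NA, d3 = NA,
                           d4 = NA, d5 = NA) {
  tibble(kind = kind, zn1 = zn1, zn2 = zn2, substrate = substrate,
         start = start, duration = duration, d_znzn = d_znzn,
         d1 = d1, d2 = d2, d3 = d3, d4 = d4, d5 = d5)
}

#' Generate a synthetic trajectory with planted events
#'
#' Baseline motion is independent Gaussian jitter (sd `jitter_sigma`) about
#' each atom's initial position; substrate molecules instead perform a rigid
#' reflected random walk in the solvent shell. During each scheduled event
#' the participating atoms (Zn, substrate oxygens, and one water for solvated
#' complexes) are placed so the planted distances hold exactly; outside the
#' scheduled interval the same atoms sit at their homes, farther than 1.5x
#' the relevant cutoff from each other. The output is bitwise-reproducible
#' from `config$seed`.
#'
#' @param np Output of [build_nanoparticle()].
#' @param schedule An [event_schedule()] tibble (may be empty/NULL).
#' @param config The [synthetic_config()] used to build `np`.
#' @param gro,dcd Optional output paths; when given the trajectory is also
#'   written to disk so the file readers are exercised end to end.
#' @return A \code{nanosite_trajectory}.
#' @export
generate_trajectory <- function(np, schedule = NULL, config, gro = NULL,
                                dcd = NULL) {
  topo <- np$topology
  base <- np$frame
  nfr <- config$n_frames
  na <- nrow(topo)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed + 1L)

  ctr <- rep(config$box_edge / 2, 3)
  zn_idx <- setNames(select_atoms(topo, roles = "ZN"),
                     topo$ligand_id[select_atoms(topo, roles = "ZN")])
  sub_ids <- sort(unique(stats::na.omit(topo$substrate_id)))
  sub_atoms <- lapply(sub_ids, function(s) select_atoms(topo, substrate = s))
  names(sub_atoms) <- sub_ids
  wat_o <- select_atoms(topo, roles = "WATER_O")

  coords <- array(NA_real_, c(nfr, na, 3))
  # baseline jitter about initial positions
  for (f in seq_len(nfr)) {
    coords[f, , ] <- base +
      matrix(rnorm(3 * na, sd = config$jitter_sigma), ncol = 3)
  }
  # substrates: rigid reflected random walk, kept outside the monolayer
  lig_len <- 13 * 0.15 + 0.21
  r_excl <- config$core_radius + 0.08 + lig_len + 0.45
  for (s in seq_along(sub_ids)) {
    idx <- sub_atoms[[s]]
    offs <- sweep(base[idx, , drop = FALSE], 2,
                  base[idx[1], ])  # internal geometry
    pos <- base[idx[1], ]
    step_sd <- max(config$jitter_sigma, 0.02)
    for (f in seq_len(nfr)) {
      pos <- pos + rnorm(3, sd = step_sd)
      pos <- pmin(pmax(pos, 0.1), config$box_edge - 0.1)
      d <- sqrt(sum((pos - ctr)^2))
      if (d < r_excl) pos <- ctr + (pos - ctr) * (r_excl / max(d, 1e-9))
      coords[f, idx, ] <- sweep(offs, 2, pos, "+")
    }
  }

  if (!is.null(schedule) && nrow(schedule) > 0) {
    schedule <- event_schedule(schedule, n_frames = nfr)
    for (i in seq_len(nrow(schedule))) {
      ev <- schedule[i, ]
      frames <- seq(ev$start, ev$start + ev$duration - 1)
      pl <- .event_placement(ev, topo, base, zn_idx, sub_atoms, wat_o)
      for (f in frames) for (j in seq_along(pl$idx))
        coords[f, pl$idx[j], ] <- pl$pos[j, ]
    }
  }

  tr <- trajectory(coords, diag(config$box_edge, 3), dt = config$dt)
  if (!is.null(gro)) write_gro(topo, coords, diag(config$box_edge, 3), gro,
                               times = tr$times)
  if (!is.null(dcd)) write_dcd(tr, dcd)
  tr
}

# Exact-geometry placement for one scheduled event. Returns atom indices and
# their fixed positions during the event. All templates hang off Zn1's home
# position; u is the outward radial axis there, v/w tangentials.
.event_placement <- function(ev, topo, base, zn_idx, sub_atoms, wat_o) {
  kind <- ev$kind
  z1 <- zn_idx[[as.character(ev$zn1)]]
  if (is.null(z1) || is.na(z1))
    ns_abort("schedule references an unknown Zn ligand id", "schedule_error")
  ctr <- colMeans(base[topo$role == "GOLD", , drop = FALSE])
  p1 <- base[z1, ]
  ax <- .frame_axes(p1 - ctr)
  u <- ax$u; v <- ax$v; w <- ax$w
  idx <- z1; pos <- matrix(p1, ncol = 3)

  add <- function(i, p) {
    idx <<- c(idx, i); pos <<- rbind(pos, p)
  }

  if (kind == "ZN_PAIR") {
    z2 <- zn_idx[[as.character(ev$zn2)]]
    if (is.null(z2)) ns_abort("ZN_PAIR needs zn2", "schedule_error")
    add(z2, p1 + ev$d_znzn * v)
    return(list(idx = idx, pos = pos))
  }

  sidx <- sub_atoms[[as.character(ev$substrate)]]
  if (is.null(sidx)) ns_abort("schedule references unknown substrate id",
                              "schedule_error")
  nm <- topo$name[sidx]
  iP <- sidx[nm == "P"]; iO3 <- sidx[nm == "O3"]
  iO4 <- sidx[nm == "O4"]; iO5 <- sidx[nm == "O5"]
  sep <- 0.45  # working Zn1-Zn2 separation for two-Zn complexes

  if (kind == "MONO_BINDING") {
    add(iO4, p1 + ev$d1 * u)
    add(iP,  p1 + (ev$d1 + 0.15) * u)
    add(iO5, p1 + (ev$d1 + 0.30) * u)
    add(iO3, p1 + (ev$d1 + 0.45) * u)
  } else if (kind == "BI_BINDING") {
    z2 <- zn_idx[[as.character(ev$zn2)]]
    p2 <- p1 + sep * v
    add(z2, p2)
    add(iO4, p1 + ev$d1 * u)
    add(iO5, p2 + ev$d2 * u)
    add(iP, (p1 + p2) / 2 + (max(ev$d1, ev$d2) + 0.12) * u)
    add(iO3, (p1 + p2) / 2 + (max(ev$d1, ev$d2) + 0.45) * u)
  } else if (kind == "PRECAT_1") {
    o3 <- p1 + ev$d3 * (-v)
    add(iO4, p1 + ev$d1 * u)
    add(iO5, p1 + ev$d2 * (0.5 * u + sqrt(0.75) * w) /
          sqrt(sum((0.5 * u + sqrt(0.75) * w)^2)))
    add(iO3, o3)
    add(iP, p1 + (max(ev$d1, ev$d2) + 0.12) * u)
    .add_water(ev, p1, o3, u, v, w, wat_o, topo, add)
  } else if (kind == "PRECAT_2") {
    z2 <- zn_idx[[as.character(ev$zn2)]]
    p2 <- p1 + sep * v
    o3 <- p1 + ev$d3 * (-v)
    add(z2, p2)
    add(iO4, p1 + ev$d1 * u)
    add(iO5, p2 + ev$d2 * u)
    add(iO3, o3)
    add(iP, (p1 + p2) / 2 + (max(ev$d1, ev$d2) + 0.12) * u)
    .add_water(ev, p1, o3, u, v, w, wat_o, topo, add)
  } else if (kind == "PRECAT_3") {
    z2 <- zn_idx[[as.character(ev$zn2)]]
    p2 <- p1 + sep * v
    o3 <- p2 + ev$d3 * u
    add(z2, p2)
    add(iO4, p1 + ev$d1 * u)
    add(iO5, p1 + (ev$d1 + 0.40) * u)
    add(iO3, o3)
    add(iP, p1 + (ev$d1 + 0.20) * u)
    .add_water(ev, p2, o3, u, v, w, wat_o, topo, add)
  } else ns_abort(paste0("unhandled event kind ", kind), "schedule_error")
  list(idx = idx, pos = pos)
}

# place one water oxygen (plus its H's) at exactly d4 from zn_pos and, if d5
# given, exactly d5 from o3_pos (two-sphere intersection in the zn-o3 plane)
.add_water <- function(ev, zn_pos, o3_pos, u, v, w, wat_o, topo, add) {
  if (is.na(ev$d4)) return(invisible())
  iw <- wat_o[1]
  if (is.na(iw)) ns_abort("schedule plants a water but system has none",
                          "schedule_error")
  if (is.na(ev$d5)) {
    p <- zn_pos + ev$d4 * w
  } else {
    L <- sqrt(sum((o3_pos - zn_pos)^2))
    if (ev$d4 + ev$d5 < L || abs(ev$d4 - ev$d5) > L)
      ns_abort(sprintf(
        "infeasible solvation geometry: |Zn-O3| = %.3f nm unreachable with d4 = %.3f, d5 = %.3f",
        L, ev$d4, ev$d5), "schedule_error")
    e1 <- (o3_pos - zn_pos) / L
    a <- (ev$d4^2 - ev$d5^2 + L^2) / (2 * L)
    h <- sqrt(max(0, ev$d4^2 - a^2))
    e2 <- w - sum(w * e1) * e1
    if (sqrt(sum(e2^2)) < 1e-8) e2 <- u - sum(u * e1) * e1
    e2 <- e2 / sqrt(sum(e2^2))
    p <- zn_pos + a * e1 + h * e2
  }
  add(iw, p)
  hs <- select_atoms(topo, roles = "WATER_H")
  hs <- hs[hs > iw][1:2]  # the two hydrogens following this oxygen
  if (!anyNA(hs)) {
    add(hs[1], p + c(0.096, 0, 0))
    add(hs[2], p + c(-0.024, 0.093, 0))
  }
  invisible()
}
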