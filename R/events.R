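#' Bimetallic Zn-Zn proximity series
#'
#' For every unordered pair of Zn ions, a per-frame boolean: minimum-image
#' distance at most `cutoff` (0.50 nm defines a bimetallic site; 0.55 and
#' 0.63 nm are the sensitivity settings). Pairs with at least one TRUE frame
#' are the "unique sites" tally.
#'
#' @param traj Trajectory.
#' @param topology Topology tibble (>= 2 Zn).
#' @param cutoff Zn-Zn distance cutoff (nm), inclusive.
#' @return List with \code{pairs} (tibble zn_i, zn_j of ligand ids, plus
#'   \code{ever} flag), \code{series} (logical matrix pairs x frames), and
#'   \code{n_unique_sites}.
#' @export
detect_zn_pair_series <- function(traj, topology, cutoff = 0.50) {
  zn <- select_atoms(topology, roles = "ZN")
  if (length(zn) < 2) ns_abort("need at least two Zn ions", "selection_error")
  stopifnot(cutoff > 0)
  lig <- topology$ligand_id[zn]
  np <- length(zn)
  pr <- which(upper.tri(matrix(0, np, np)), arr.ind = TRUE)
  nf <- n_frames(traj)
  series <- matrix(FALSE, nrow(pr), nf)
  for (f in seq_len(nf)) {
    d <- .pdist_cross(.frame(traj, f)[zn, , drop = FALSE],
                      .frame(traj, f)[zn, , drop = FALSE],
                      .frame_box(traj, f))
    series[, f] <- d[pr] <= cutoff
  }
  pairs <- tibble(zn_i = lig[pr[, 1]], zn_j = lig[pr[, 2]],
                  ever = rowSums(series) > 0)
  list(pairs = pairs, series = series, n_unique_sites = sum(pairs$ever))
}

#' Segment a boolean series into maximal events
#'
#' Maximal runs of consecutive TRUE frames; the existence time of a run is
#' its length times the frame spacing, so a single TRUE frame yields the
#' sampling floor (5 ps at the default spacing). By default one FALSE frame
#' ends an event; `gap_tolerance` (frames) bridges short interruptions for
#' sensitivity analysis.
#'
#' @param series Logical vector (one element per frame).
#' @param dt Frame spacing (ps), > 0.
#' @param gap_tolerance Number of FALSE frames to bridge (default 0).
#' @return Tibble with columns \code{start} (frame, 1-based),
#'   \code{duration} (frames), \code{existence_ps}.
#' @export
segment_events <- function(series, dt, gap_tolerance = 0) {
  stopifnot(dt > 0)
  if (length(series) == 0 || !any(series))
    return(tibble(start = integer(), duration = integer(),
                  existence_ps = numeric()))
  s <- as.logical(series)
  if (gap_tolerance > 0) {
    r <- rle(s)
    fill <- !r$values & r$lengths <= gap_tolerance
    # only bridge gaps strictly between TRUE runs
    inner <- seq_along(r$values) > 1 & seq_along(r$values) < length(r$values)
    r$values[fill & inner] <- TRUE
    s <- inverse.rle(r)
  }
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble(start = as.integer(starts[keep]),
         duration = as.integer(r$lengths[keep]),
         existence_ps = r$lengths[keep] * dt)
}

# O-Zn distance matrix for one substrate in one frame: rows O3, O4, O5
.substrate_zn_dists <- function(xyz, box, topology, substrate) {
  zn <- select_atoms(topology, roles = "ZN")
  o <- c(select_atoms(topology, roles = "SUB_O3", substrate = substrate),
         select_atoms(topology, roles = "SUB_O4", substrate = substrate),
         select_atoms(topology, roles = "SUB_O5", substrate = substrate))
  if (length(o) != 3)
    ns_abort(sprintf("substrate %d lacks labelled O3/O4/O5", substrate),
             "labeling_error")
  d <- .pdist_cross(xyz[o, , drop = FALSE], xyz[zn, , drop = FALSE], box)
  rownames(d) <- c("O3", "O4", "O5")
  colnames(d) <- topology$ligand_id[zn]
  d
}

#' Classify substrate binding from O-Zn distances
#'
#' Distance-matrix classifier for one substrate: rows O3 (hydroxyl oxygen),
#' O4, O5 (phosphoryl oxygens); columns Zn ions. A bimetallic binding
#' complex requires the two phosphoryl oxygens to coordinate two different
#' Zn ions simultaneously (each within `o_cut`); a monometallic complex
#' requires at least one phosphoryl oxygen on exactly one Zn with no second
#' Zn involved in binding any substrate oxygen.
#'
#' \code{classify_binding()} evaluates one frame of a trajectory;
#' \code{classify_binding_dists()} is the distance-level core used by both
#' the trajectory path and exhaustive truth-table checks.
#'
#' @param traj Trajectory.
#' @param topology Topology tibble.
#' @param frame Frame index.
#' @param substrate Substrate id.
#' @param o_cut O-Zn cutoff (nm), inclusive (0.25 nm).
#' @param d Distance matrix with rows O3, O4, O5 and one column per Zn
#'   (column names = Zn identities).
#' @return List with \code{state} in \code{NONE, MONO_BINDING, BI_BINDING}
#'   and \code{zn} (character vector of involved Zn identities).
#' @export
classify_binding <- function(traj, topology, frame, substrate, o_cut = 0.25) {
  d <- .substrate_zn_dists(.frame(traj, frame), .frame_box(traj, frame),
                           topology, substrate)
  classify_binding_dists(d, o_cut)
}

#' @rdname classify_binding
#' @export
classify_binding_dists <- function(d, o_cut = 0.25) {
  zn_names <- colnames(d) %||% as.character(seq_len(ncol(d)))
  c4 <- d["O4", ] <= o_cut
  c5 <- d["O5", ] <= o_cut
  any_o <- d["O3", ] <= o_cut | c4 | c5
  # bimetallic: distinct Zn pair (a, b) with O4-a and O5-b both bound
  for (a in which(c4)) for (b in which(c5)) if (a != b)
    return(list(state = "BI_BINDING", zn = zn_names[c(a, b)]))
  involved <- which(any_o)
  if (length(involved) == 1 && (c4[involved] || c5[involved]))
    return(list(state = "MONO_BINDING", zn = zn_names[involved]))
  list(state = "NONE", zn = character(0))
}

#' Classify precatalytic complexes from O-Zn distances
#'
#' Types, checked in the order 2, 3, 1 (bimetallic evidence outranks
#' pseudo-bimetallic outranks monometallic):
#' \describe{
#'   \item{PRECAT_2 (bimetallic)}{O4 and O5 bound to two different Zn
#'     (d1, d2 <= threshold) while one of those Zn also coordinates the
#'     hydroxyl oxygen O3 (d3 <= threshold).}
#'   \item{PRECAT_3 (pseudo-bimetallic)}{exactly one Zn coordinates O4
#'     and/or O5 while a second Zn interacts only with O3.}
#'   \item{PRECAT_1 (monometallic)}{a single Zn coordinates O3, O4 and O5
#'     and no other Zn contacts any of them.}
#' }
#'
#' @inheritParams classify_binding
#' @param threshold O-Zn threshold (nm), inclusive (0.25 nm).
#' @return List with \code{state} in \code{NONE, PRECAT_1..3}, \code{zn}
#'   (involved Zn identities), and \code{geometry} (named d1, d2, d3 in nm
#'   for the classified arrangement; NA when NONE).
#' @export
classify_precatalytic <- function(traj, topology, frame, substrate,
                                  threshold = 0.25) {
  d <- .substrate_zn_dists(.frame(traj, frame), .frame_box(traj, frame),
                           topology, substrate)
  classify_precatalytic_dists(d, threshold)
}

#' @rdname classify_binding
#' @param threshold O-Zn threshold (nm), inclusive.
#' @export
classify_precatalytic_dists <- function(d, threshold = 0.25) {
  zn_names <- colnames(d) %||% as.character(seq_len(ncol(d)))
  t <- threshold
  c3 <- d["O3", ] <= t; c4 <- d["O4", ] <= t; c5 <- d["O5", ] <= t
  none <- list(state = "NONE", zn = character(0),
               geometry = c(d1 = NA_real_, d2 = NA_real_, d3 = NA_real_))
  # type 2: O4-Zn_a, O5-Zn_b (a != b), O3 on a or b
  for (a in which(c4)) for (b in which(c5)) if (a != b && (c3[a] || c3[b]))
    return(list(state = "PRECAT_2", zn = zn_names[c(a, b)],
                geometry = c(d1 = d["O4", a], d2 = d["O5", b],
                             d3 = min(d["O3", c(a, b)][c(c3[a], c3[b])]))))
  # type 3: exactly one Zn on the phosphoryl oxygens, another Zn on O3 only
  phos <- which(c4 | c5)
  if (length(phos) == 1) {
    a <- phos
    others <- setdiff(which(c3), a)
    if (length(others) >= 1) {
      b <- others[which.min(d["O3", others])]
      return(list(state = "PRECAT_3", zn = zn_names[c(a, b)],
                  geometry = c(d1 = unname(d["O4", a]),
                               d2 = unname(d["O5", a]),
                               d3 = unname(d["O3", b]))))
    }
  }
  # type 1: one Zn holds all three oxygens, no other Zn contacts any
  all3 <- which(c3 & c4 & c5)
  touched <- which(c3 | c4 | c5)
  if (length(all3) == 1 && length(touched) == 1)
    return(list(state = "PRECAT_1", zn = zn_names[all3],
                geometry = c(d1 = unname(d["O4", all3]),
                             d2 = unname(d["O5", all3]),
                             d3 = unname(d["O3", all3]))))
  none
}

#' Solvation and nucleophile-activation flags
#'
#' A complex is \emph{solvated} when at least one water oxygen lies strictly
#' within 0.20 nm (d4) of any of its Zn ions; the \emph{nucleophile is
#' ready} when such a Zn-bound water oxygen lies strictly within 0.25 nm
#' (d5) of the substrate's hydroxyl oxygen O3.
#'
#' @param traj Trajectory.
#' @param topology Topology tibble.
#' @param frame Frame index.
#' @param zn_ligand_ids Ligand ids of the complex's Zn ions.
#' @param substrate Substrate id.
#' @param d4_cut,d5_cut Cutoffs in nm (strict, as defined).
#' @return Named logical vector \code{c(solvated, nucleophile_ready)}.
#' @export
solvation_flags <- function(traj, topology, frame, zn_ligand_ids, substrate,
                            d4_cut = 0.20, d5_cut = 0.25) {
  stopifnot(length(zn_ligand_ids) >= 1)
  xyz <- .frame(traj, frame); box <- .frame_box(traj, frame)
  zn <- select_atoms(topology, roles = "ZN")
  zn <- zn[topology$ligand_id[zn] %in% zn_ligand_ids]
  wo <- select_atoms(topology, roles = "WATER_O")
  if (length(wo) == 0)
    return(c(solvated = FALSE, nucleophile_ready = FALSE))
  dzw <- .pdist_cross(xyz[zn, , drop = FALSE], xyz[wo, , drop = FALSE], box)
  bound <- which(apply(dzw, 2, min) < d4_cut)
  solv <- length(bound) > 0
  nuc <- FALSE
  if (solv) {
    o3 <- select_atoms(topology, roles = "SUB_O3", substrate = substrate)
    if (length(o3) == 1) {
      dwo3 <- .pdist_cross(xyz[wo[bound], , drop = FALSE],
                           xyz[o3, , drop = FALSE], box)[, 1]
      nuc <- any(dwo3 < d5_cut)
    }
  }
  c(solvated = solv, nucleophile_ready = nuc)
}

#' Build events of a given kind from a trajectory
#'
#' Composes the per-frame detector for `kind` with event segmentation per
#' identity. Identities are: an unordered Zn pair for \code{"znpair"}; a
#' (state, Zn ids, substrate) triple for \code{"binding"} and
#' \code{"precat"} — a run ends when the state or the involved Zn change.
#' Each event carries its start time, existence time, the median over the
#' event's frames of the involved Zn's distances to the gold-core centre of
#' mass (pooled over both Zn for pairs), and, for substrate complexes,
#' any-frame solvation / nucleophile flags.
#'
#' @param traj Trajectory.
#' @param topology Topology tibble.
#' @param kind One of \code{"znpair"}, \code{"binding"}, \code{"precat"}.
#' @param cutoff Zn-Zn cutoff (nm) for \code{"znpair"}.
#' @param o_cut,threshold O-Zn cutoffs (nm) for binding / precatalytic
#'   classification.
#' @param gap_tolerance Frames of interruption to bridge (default 0).
#' @return Tibble of class \code{nanosite_events}: \code{kind},
#'   \code{state}, \code{zn} (comma-separated ligand ids), \code{substrate},
#'   \code{start_ps}, \code{existence_ps}, \code{median_core_nm},
#'   \code{solvated}, \code{nucleophile_ready}.
#' @export
build_events <- function(traj, topology, kind = c("znpair", "binding", "precat"),
                         cutoff = 0.50, o_cut = 0.25, threshold = 0.25,
                         gap_tolerance = 0) {
  kind <- match.arg(kind)
  nf <- n_frames(traj)
  dt <- traj$dt
  # per-frame core c.o.m. distance of each Zn
  zn <- select_atoms(topology, roles = "ZN")
  zn_lig <- topology$ligand_id[zn]
  core_d <- matrix(NA_real_, length(zn), nf)
  for (f in seq_len(nf)) {
    xyz <- .frame(traj, f); box <- .frame_box(traj, f)
    com <- center_of_mass(topology, xyz, roles = "GOLD", box = box)
    core_d[, f] <- .pdist_cross(xyz[zn, , drop = FALSE],
                                matrix(com, ncol = 3), box)[, 1]
  }
  events <- list()
  emit <- function(state, zn_ids, substrate, seg) {
    for (i in seq_len(nrow(seg))) {
      frames <- seq(seg$start[i], seg$start[i] + seg$duration[i] - 1)
      med <- stats::median(core_d[zn_lig %in% zn_ids, frames])
      solv <- c(solvated = NA, nucleophile_ready = NA)
      if (!is.na(substrate)) {
        fl <- vapply(frames, function(f)
          solvation_flags(traj, topology, f, zn_ids, substrate),
          logical(2))
        solv <- c(solvated = any(fl[1, ]), nucleophile_ready = any(fl[2, ]))
      }
      events[[length(events) + 1]] <<- tibble(
        kind = kind, state = state,
        zn = paste(sort(zn_ids), collapse = ","),
        substrate = substrate,
        start_ps = traj$times[seg$start[i]],
        existence_ps = seg$existence_ps[i],
        median_core_nm = med,
        solvated = solv[["solvated"]],
        nucleophile_ready = solv[["nucleophile_ready"]])
    }
  }

  if (kind == "znpair") {
    det <- detect_zn_pair_series(traj, topology, cutoff = cutoff)
    for (p in which(det$pairs$ever)) {
      seg <- segment_events(det$series[p, ], dt, gap_tolerance)
      emit("ZN_PAIR", c(det$pairs$zn_i[p], det$pairs$zn_j[p]), NA_integer_, seg)
    }
  } else {
    classify <- if (kind == "binding") {
      function(d) classify_binding_dists(d, o_cut)
    } else {
      function(d) classify_precatalytic_dists(d, threshold)
    }
    for (s in sort(unique(stats::na.omit(topology$substrate_id)))) {
      labels <- character(nf); states <- character(nf); zns <- vector("list", nf)
      for (f in seq_len(nf)) {
        d <- .substrate_zn_dists(.frame(traj, f), .frame_box(traj, f),
                                 topology, s)
        cl <- classify(d)
        states[f] <- cl$state
        zns[[f]] <- sort(as.integer(cl$zn))
        labels[f] <- if (cl$state == "NONE") "NONE" else
          paste(cl$state, paste(zns[[f]], collapse = ","), sep = "|")
      }
      for (lb in setdiff(unique(labels), "NONE")) {
        seg <- segment_events(labels == lb, dt, gap_tolerance)
        f1 <- which(labels == lb)[1]
        emit(states[f1], zns[[f1]], s, seg)
      }
    }
  }
  out <- if (length(events)) dplyr::bind_rows(events) else
    tibble(kind = character(), state = character(), zn = character(),
           substrate = integer(), start_ps = numeric(),
           existence_ps = numeric(), median_core_nm = numeric(),
           solvated = logical(), nucleophile_ready = logical())
  class(out) <- c("nanosite_events", class(out))
  attr(out, "dt") <- dt
  out
}

#' State-transition counts for substrate complexes
#'
#' Counts consecutive-frame transitions between distinct states (self
#' transitions excluded), aggregated over substrates.
#'
#' @param state_series A list of character vectors (one per substrate, one
#'   state per frame) or a single character vector.
#' @return Tibble with columns \code{from}, \code{to}, \code{count},
#'   containing all ordered pairs of observed states.
#' @export
transition_counts <- function(state_series) {
  if (!is.list(state_series)) state_series <- list(state_series)
  states <- c("NONE", "MONO_BINDING", "BI_BINDING",
              "PRECAT_1", "PRECAT_2", "PRECAT_3")
  m <- matrix(0L, length(states), length(states),
              dimnames = list(states, states))
  for (s in state_series) {
    if (length(s) < 2) next
    a <- s[-length(s)]; b <- s[-1]
    keep <- a != b
    for (i in which(keep)) m[a[i], b[i]] <- m[a[i], b[i]] + 1L
  }
  out <- as_tibble(as.table(m), .name_repair = "minimal")
  names(out) <- c("from", "to", "count")
  out$count <- as.integer(out$count)
  out
}
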