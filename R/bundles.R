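#' Interligand hydrogen-bond graph for one frame
#'
#' Nodes are ligand ids; an edge joins two distinct ligands sharing at least
#' one qualifying hydrogen bond (duplicates collapse; self-loops excluded).
#'
#' @param hb_frame Tibble of hydrogen bonds for one frame (columns
#'   \code{donor}, \code{acceptor}).
#' @param topology Topology tibble.
#' @return An igraph graph whose vertices are all ligand ids of the topology.
#' @export
interligand_hb_graph <- function(hb_frame, topology) {
  ids <- sort(unique(stats::na.omit(topology$ligand_id)))
  ld <- topology$ligand_id[hb_frame$donor]
  la <- topology$ligand_id[hb_frame$acceptor]
  if (nrow(hb_frame) > 0 && (anyNA(ld) | anyNA(la)))
    ns_abort("hydrogen-bond entry involves atoms without ligand ids",
             "labeling_error")
  keep <- !is.na(ld) & !is.na(la) & ld != la
  edges <- unique(cbind(pmin(ld[keep], la[keep]), pmax(ld[keep], la[keep])))
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(ids))
  if (nrow(edges) > 0)
    g <- igraph::add_edges(g, t(matrix(match(edges, ids), ncol = 2)))
  g
}

#' Detect hydrogen-bonded ligand bundles
#'
#' Bundles are groups of more than two coating ligands simultaneously
#' interconnected by interligand C=O8...H-N9 hydrogen bonds: per frame, the
#' connected components of size >= 3 of the interligand HB graph. The
#' size-frequency table reports, for sizes 3..6 and a ">6" bucket, both the
#' fraction of frames containing at least one bundle of exactly that size
#' and the raw bundle count, so either normalisation convention can be read
#' off.
#'
#' @param traj Trajectory.
#' @param topology Topology tibble.
#' @param d_cut,angle_cut Hydrogen-bond criterion (see [hydrogen_bonds()]).
#' @return List with \code{records} (tibble: frame, size, members) and
#'   \code{frequency} (tibble: size, frequency, count).
#' @export
detect_bundles <- function(traj, topology, d_cut = 0.35, angle_cut = 30) {
  n9h <- select_atoms(topology, names = "HN9")
  n9 <- select_atoms(topology, roles = "N9")
  o8 <- select_atoms(topology, roles = "O8")
  hb <- hydrogen_bonds(traj, topology, donors = n9, hydrogens = n9h,
                       acceptors = o8, d_cut = d_cut, angle_cut = angle_cut)
  nf <- n_frames(traj)
  recs <- list()
  for (f in unique(hb$bonds$frame)) {
    g <- interligand_hb_graph(hb$bonds[hb$bonds$frame == f, ], topology)
    comp <- igraph::components(g)
    for (ci in which(comp$csize >= 3)) {
      members <- as.integer(igraph::V(g)$name[comp$membership == ci])
      recs[[length(recs) + 1]] <- tibble(frame = f,
                                         size = length(members),
                                         members = list(sort(members)))
    }
  }
  records <- if (length(recs)) dplyr::bind_rows(recs) else
    tibble(frame = integer(), size = integer(), members = list())
  sizes <- c("3", "4", "5", "6", ">6")
  bucket <- function(s) ifelse(s > 6, ">6", as.character(s))
  freq <- vapply(sizes, function(s) {
    length(unique(records$frame[bucket(records$size) == s])) / nf
  }, numeric(1))
  cnt <- vapply(sizes, function(s) sum(bucket(records$size) == s), numeric(1))
  list(records = records,
       frequency = tibble(size = sizes, frequency = unname(freq),
                          count = as.integer(unname(cnt))))
}
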