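# Small reusable fixtures, all built in code.

# compact nanoparticle: few ligands, modest solvent, fast to analyse
small_config <- function(n_frames = 20, jitter = 0.02, seed = 11, ...) {
  synthetic_config(n_ligands = 12, n_substrates = 2, n_waters = 40, n_cl = 10,
                   n_frames = n_frames, jitter_sigma = jitter, seed = seed, ...)
}

small_np <- function(...) build_nanoparticle(small_config(...))

# static trajectory (no jitter, no schedule) around a prebuilt particle
static_traj <- function(np, n_frames = 5, dt = 5, box_edge = 9) {
  na <- nrow(np$topology)
  coords <- array(NA_real_, c(n_frames, na, 3))
  for (f in seq_len(n_frames)) coords[f, , ] <- np$frame
  trajectory(coords, diag(box_edge, 3), dt = dt)
}

# trajectory from an explicit list of coordinate matrices
traj_from_frames <- function(frames, box = diag(10, 3), dt = 5) {
  coords <- array(NA_real_, c(length(frames), nrow(frames[[1]]), 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  trajectory(coords, box, dt = dt)
}

# bare topology from atom descriptions (name, resname, resid triples)
bare_topology <- function(name, resname, resid) {
  nanosite:::.finish_topology(tibble::tibble(
    name = name, resid = resid, resname = resname,
    role = nanosite:::.apply_label_map(label_map_preset("aunp2"),
                                       resname, name)))
}

# brute-force minimum-image distance via explicit 27-image enumeration
brute_min_image <- function(a, b, box, range = -1:1) {
  box <- if (is.null(dim(box))) diag(box, 3) else box
  best <- Inf
  for (i in range) for (j in range) for (k in range) {
    shift <- i * box[1, ] + j * box[2, ] + k * box[3, ]
    best <- min(best, sqrt(sum((a - b - shift)^2)))
  }
  best
}

# union-find connected components (oracle for graph/bundle decomposition)
brute_components <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  if (length(edges)) for (e in edges) {
    ra <- find(e[1]); rb <- find(e[2])
    if (ra != rb) parent[[ra]] <- rb
  }
  split(nodes, vapply(nodes, find, character(1)))
}

# distance matrix for the classifier truth tables: rows O3/O4/O5, cols Zn
dist_matrix <- function(o3, o4, o5) {
  m <- rbind(O3 = o3, O4 = o4, O5 = o5)
  colnames(m) <- paste0("zn", seq_len(ncol(m)))
  m
}

# literal truth-table oracle transcribing the complex definitions
oracle_precat <- function(d, t = 0.25) {
  c3 <- d["O3", ] <= t; c4 <- d["O4", ] <= t; c5 <- d["O5", ] <= t
  nzn <- ncol(d)
  for (a in seq_len(nzn)) for (b in seq_len(nzn)) {
    if (a == b) next
    if (c4[a] && c5[b] && (c3[a] || c3[b])) return("PRECAT_2")
  }
  phos <- which(c4 | c5)
  if (length(phos) == 1) {
    a <- phos
    for (b in setdiff(seq_len(nzn), a))
      if (c3[b] && !c4[b] && !c5[b]) return("PRECAT_3")
  }
  for (a in seq_len(nzn)) {
    if (c3[a] && c4[a] && c5[a] &&
        !any(c3[-a] | c4[-a] | c5[-a])) return("PRECAT_1")
  }
  "NONE"
}

oracle_binding <- function(d, t = 0.25) {
  c3 <- d["O3", ] <= t; c4 <- d["O4", ] <= t; c5 <- d["O5", ] <= t
  nzn <- ncol(d)
  for (a in seq_len(nzn)) for (b in seq_len(nzn))
    if (a != b && c4[a] && c5[b]) return("BI_BINDING")
  touched <- which(c3 | c4 | c5)
  if (length(touched) == 1 && (c4[touched] || c5[touched]))
    return("MONO_BINDING")
  "NONE"
}
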