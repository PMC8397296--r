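#' Synthetic nanozyme configuration
#'
#' Parameters of the synthetic fixture generator. Defaults emulate the
#' simulated Au144(SR)60 systems: a ~1.6 nm diameter gold core carrying 60
#' surface-anchored flexible ligands each terminating in a Zn(II)-chelating
#' TACN crown, 10 diffusing phosphodiester substrate molecules, explicit
#' water and chloride counterions, sampled every 5 ps. Water and box size are
#' fixture-scale stand-ins (the real systems hold ~27,000 waters in a rhombic
#' dodecahedron); every analysis here is geometric or statistical, so only
#' relative geometry and event statistics matter.
#'
#' @param core_radius Gold core radius (nm). Default 0.8 (1.6 nm diameter).
#' @param n_ligands Number of coating ligands (and chelated Zn). Default 60.
#' @param n_substrates Number of substrate molecules. Default 10.
#' @param n_waters Number of water molecules. Default 300.
#' @param n_cl Number of chloride ions. Default 110 (neutralising 60 Zn2+
#'   against 10 singly charged substrates).
#' @param box_edge Cubic box edge (nm). Default 9.
#' @param jitter_sigma Per-frame Gaussian positional jitter (nm). Default 0.02.
#' @param dt Frame spacing (ps). Default 5.
#' @param n_frames Number of frames to generate. Default 200.
#' @param linker Linker chemistry preset: "aunp2" (alkyl C12/C15) or "aunp3"
#'   (PEG O12/O15); affects atom naming only.
#' @param seed Integer seed; every generator output is reproducible from it.
#' @return A list of class \code{nanosite_config}.
#' @export
synthetic_config <- function(core_radius = 0.8, n_ligands = 60,
                             n_substrates = 10, n_waters = 300, n_cl = 110,
                             box_edge = 9, jitter_sigma = 0.02, dt = 5,
                             n_frames = 200, linker = c("aunp2", "aunp3"),
                             seed = 1L) {
  linker <- match.arg(linker)
  stopifnot(core_radius > 0, box_edge > 0, dt > 0, jitter_sigma >= 0,
            n_ligands >= 0, n_substrates >= 0, n_waters >= 0, n_cl >= 0,
            n_frames >= 1)
  structure(list(core_radius = core_radius, n_ligands = n_ligands,
                 n_substrates = n_substrates, n_waters = n_waters, n_cl = n_cl,
                 box_edge = box_edge, jitter_sigma = jitter_sigma, dt = dt,
                 n_frames = n_frames, linker = linker, seed = as.integer(seed)),
            class = "nanosite_config")
}

# deterministic quasi-uniform points on the unit sphere (Fibonacci lattice)
.fibonacci_sphere <- function(n) {
  if (n == 0) return(matrix(numeric(0), ncol = 3))
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# orthonormal frame with first axis u
.frame_axes <- function(u) {
  u <- u / sqrt(sum(u^2))
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- a - sum(a * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  list(u = u, v = v, w = w)
}

#' Build a synthetic labelled nanoparticle
#'
#' Constructs the initial structure: gold beads on (and one at the centre of)
#' a sphere of `core_radius`, `n_ligands` anchors on a deterministic
#' Fibonacci lattice, each ligand a radial chain of beads in the order S,
#' C1..C7, O8, N9, linker-12, linker-15, N18, O19, and a TACN crown of three
#' nitrogens with one Zn placed exactly 0.21 nm from each crown nitrogen.
#' Amide hydrogens (on N9/N18) and one aliphatic hydrogen per chain carbon
#' are included so hydrogen-bond and CH-vector analyses can run. Substrates
#' (P, O3, O4, O5), waters (OW, HW1, HW2) and Cl are placed uniformly outside
#' the monolayer with a 0.2 nm minimum separation; placement failure after
#' bounded retries is a packing error.
#'
#' The particle is centred at the box centre.
#'
#' @param config A [synthetic_config()].
#' @return List with elements \code{topology} (labelled topology tibble),
#'   \code{frame} (n x 3 nm coordinate matrix), \code{box} (3x3 nm).
#' @export
build_nanoparticle <- function(config) {
  stopifnot(inherits(config, "nanosite_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)

  ctr <- rep(config$box_edge / 2, 3)
  rows <- list(); coords <- list()
  resid <- 0L

  # gold core: centre bead + two shells for a solid-ish cluster
  gold_pts <- rbind(c(0, 0, 0),
                    .fibonacci_sphere(48) * config$core_radius * 0.55,
                    .fibonacci_sphere(95) * config$core_radius)
  gold_pts <- sweep(gold_pts, 2, colMeans(gold_pts))  # c.o.m. exactly at centre
  resid <- resid + 1L
  rows[[1]] <- tibble(name = "AU", resid = resid, resname = "AUC")[rep(1, nrow(gold_pts)), ]
  coords[[1]] <- sweep(gold_pts, 2, ctr, "+")

  linker_names <- if (config$linker == "aunp2") c("C12", "C15") else c("O12", "O15")
  chain_names <- c("S", paste0("C", 1:7), "O8", "N9", linker_names, "N18", "O19")
  spacing <- 0.15  # nm between successive chain beads
  anchors <- .fibonacci_sphere(config$n_ligands)
  for (l in seq_len(config$n_ligands)) {
    resid <- resid + 1L
    ax <- .frame_axes(anchors[l, ])
    u <- ax$u; v <- ax$v; w <- ax$w
    base_r <- config$core_radius + 0.08
    nm <- character(0); xyz <- NULL
    for (k in seq_along(chain_names)) {
      pos <- u * (base_r + (k - 1) * spacing)
      nm <- c(nm, chain_names[k]); xyz <- rbind(xyz, pos)
      if (grepl("^C[0-9]+$", chain_names[k])) {  # aliphatic H for CH vectors
        nm <- c(nm, sub("^C", "H", chain_names[k]))
        xyz <- rbind(xyz, pos + 0.109 * v)
      }
      if (chain_names[k] %in% c("N9", "N18")) {  # amide hydrogen
        nm <- c(nm, paste0("H", chain_names[k]))
        xyz <- rbind(xyz, pos + 0.101 * w)
      }
    }
    # TACN crown: three N on a circle, Zn on the axis 0.21 nm from each N
    rho <- 0.08
    crown_r <- base_r + length(chain_names) * spacing
    for (j in 1:3) {
      ang <- 2 * pi * (j - 1) / 3
      nm <- c(nm, paste0("NT", j))
      xyz <- rbind(xyz, u * crown_r + rho * (cos(ang) * v + sin(ang) * w))
    }
    h <- sqrt(0.21^2 - rho^2)
    nm <- c(nm, "ZN")
    xyz <- rbind(xyz, u * (crown_r + h))
    rows[[length(rows) + 1]] <- tibble(name = nm, resid = resid, resname = "LIG")
    coords[[length(coords) + 1]] <- sweep(xyz, 2, ctr, "+")
  }

  lig_len <- (length(chain_names)) * spacing + 0.21
  shell_lo <- config$core_radius + 0.08 + lig_len + 0.5  # outside the monolayer
  shell_hi <- config$box_edge / 2 - 0.2
  if (config$n_substrates + config$n_waters + config$n_cl > 0 &&
      shell_hi <= shell_lo)
    ns_abort("box too small to place solvent outside the monolayer",
             "packing_error")

  placed <- do.call(rbind, coords)
  place_one <- function(min_sep = 0.2, max_try = 2000) {
    for (i in seq_len(max_try)) {
      p <- runif(3, 0, config$box_edge)
      d <- sqrt(sum((p - ctr)^2))
      if (d < shell_lo || d > shell_hi) next
      dmin <- min(.pdist_cross(matrix(p, ncol = 3), placed,
                               diag(config$box_edge, 3)))
      if (dmin >= min_sep) return(p)
    }
    ns_abort("could not place a particle without overlap (box too crowded)",
             "packing_error")
  }

  for (s in seq_len(config$n_substrates)) {
    resid <- resid + 1L
    p <- place_one(0.3)
    # compact phosphate stub: P with O3 (hydroxyl), O4/O5 (phosphoryl)
    xyz <- rbind(p,
                 p + c(0.16, 0, 0),
                 p + c(-0.08, 0.14, 0),
                 p + c(-0.08, -0.14, 0))
    rows[[length(rows) + 1]] <- tibble(name = c("P", "O3", "O4", "O5"),
                                       resid = resid, resname = "HPN")
    coords[[length(coords) + 1]] <- xyz
    placed <- rbind(placed, xyz)
  }
  for (s in seq_len(config$n_waters)) {
    resid <- resid + 1L
    p <- place_one(0.2)
    xyz <- rbind(p, p + c(0.096, 0, 0), p + c(-0.024, 0.093, 0))
    rows[[length(rows) + 1]] <- tibble(name = c("OW", "HW1", "HW2"),
                                       resid = resid, resname = "SOL")
    coords[[length(coords) + 1]] <- xyz
    placed <- rbind(placed, xyz)
  }
  for (s in seq_len(config$n_cl)) {
    resid <- resid + 1L
    p <- place_one(0.2)
    rows[[length(rows) + 1]] <- tibble(name = "CL", resid = resid, resname = "CL")
    coords[[length(coords) + 1]] <- matrix(p, ncol = 3)
    placed <- rbind(placed, matrix(p, ncol = 3))
  }

  atoms <- dplyr::bind_rows(rows)
  frame <- do.call(rbind, coords)
  map <- label_map_preset(config$linker)
  atoms$role <- .apply_label_map(map, atoms$resname, atoms$name)
  if (anyNA(atoms$role)) atoms$role[is.na(atoms$role)] <- "OTHER"
  topo <- .finish_topology(atoms)
  list(topology = topo, frame = frame, box = diag(config$box_edge, 3))
}

#' Uniform ideal-gas frame
#'
#' `n` i.i.d. uniform positions in a cubic box — the control system whose
#' radial distribution function is identically 1.
#'
#' @param n Number of points (>= 2).
#' @param box_edge Cubic box edge (nm).
#' @param seed Integer seed.
#' @return n x 3 coordinate matrix (nm).
#' @export
generate_uniform_gas <- function(n, box_edge, seed = 1L) {
  stopifnot(n >= 2, box_edge > 0)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  matrix(runif(3 * n, 0, box_edge), ncol = 3)
}

#' Sample event durations from an exponential lifetime law
#'
#' Draws `n` existence times from an exponential distribution with decay rate
#' `lambda_true` (ns^-1) and discretises them to whole frames of spacing `dt`
#' (ps), rounding up so every event lasts at least one frame — the finite
#' sampling floor of a trajectory analysed every `dt` ps.
#'
#' @param n Number of events.
#' @param lambda_true Decay rate (ns^-1), > 0.
#' @param dt Frame spacing (ps).
#' @param seed Integer seed.
#' @return Integer vector of durations in frames.
#' @export
sample_event_durations <- function(n, lambda_true, dt = 5, seed = 1L) {
  stopifnot(lambda_true > 0, dt > 0, n >= 0)
  if (n == 0) return(integer(0))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  x_ns <- rexp(n, rate = lambda_true)
  pmax(1L, as.integer(ceiling(x_ns * 1000 / dt)))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}
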