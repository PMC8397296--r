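#' Load a labelled topology from a coordinate file
#'
#' Reads a PDB or GRO coordinate file and assigns every atom a semantic role
#' using a label map (see [label_map()]). The result is a tibble with one row
#' per atom and columns \code{index} (1-based, dense), \code{name},
#' \code{resid}, \code{resname}, \code{role}, \code{ligand_id} (dense id of
#' the coating ligand the atom belongs to, \code{NA} otherwise),
#' \code{substrate_id}, \code{element} and \code{mass} (amu). PDB coordinates
#' (Angstrom) are converted to nm on load; the initial frame is attached as
#' attribute \code{"frame"} together with the box (\code{"box"}, nm).
#'
#' Each Zn is required to be chelated: its residue must contain at least one
#' TACN nitrogen, and the Zn inherits that residue's ligand id.
#'
#' @param file Path to a \code{.pdb} or \code{.gro} file.
#' @param map A label map (see [label_map()], [label_map_preset()],
#'   [read_label_map()]).
#' @param quiet Suppress the unmatched-atom warning summary.
#' @return A \code{nanosite_topology} tibble.
#' @export
load_topology <- function(file, map, quiet = FALSE) {
  if (!file.exists(file))
    ns_abort(paste0("cannot read coordinate file: ", file), "format_error")
  ext <- tolower(tools::file_ext(file))
  raw <- switch(ext,
    gro = .read_gro_atoms(file),
    pdb = .read_pdb_atoms(file),
    ns_abort(paste0("unsupported coordinate format: .", ext), "format_error"))
  atoms <- raw$atoms
  roles <- .apply_label_map(map, atoms$resname, atoms$name)
  unmatched <- is.na(roles)
  if (any(unmatched)) {
    if (is.null(map$default)) {
      orphans <- unique(paste0(atoms$resname[unmatched], "/", atoms$name[unmatched]))
      ns_abort(paste0("label map matches no rule and declares no default for: ",
                      paste(orphans, collapse = ", ")), "labeling_error")
    }
    roles[unmatched] <- map$default
    if (!quiet)
      warn(sprintf("%d atom(s) assigned default role %s", sum(unmatched), map$default))
  }
  atoms$role <- roles
  topo <- .finish_topology(atoms)
  attr(topo, "frame") <- raw$coords
  attr(topo, "box") <- raw$box
  topo
}

# common post-processing: ligand/substrate ids, masses, Zn chelation check
.finish_topology <- function(atoms) {
  atoms <- as_tibble(atoms)
  atoms$index <- seq_len(nrow(atoms))
  # membership by residue: every atom of a ligand/substrate residue carries
  # the molecule id (including hydrogens and other unlabelled atoms)
  lig_res <- sort(unique(atoms$resid[atoms$role %in% .ligand_roles()]))
  atoms$ligand_id <- match(atoms$resid, lig_res)
  sub_res <- sort(unique(atoms$resid[atoms$role %in% .substrate_roles()]))
  atoms$substrate_id <- match(atoms$resid, sub_res)
  el <- unname(.role_elements[atoms$role])
  other <- atoms$role == "OTHER"
  el[other] <- .guess_element(atoms$name[other])
  atoms$element <- el
  atoms$mass <- unname(.element_masses[el])
  if (anyNA(atoms$mass) || any(atoms$mass <= 0))
    ns_abort("could not assign a positive mass to every atom", "labeling_error")
  zn <- which(atoms$role == "ZN")
  for (i in zn) {
    same_res <- atoms$resid == atoms$resid[i]
    if (!any(atoms$role[same_res] == "TACN_N"))
      ns_abort(sprintf("Zn atom %d (resid %d) has no TACN nitrogen in its residue",
                       atoms$index[i], atoms$resid[i]), "labeling_error")
  }
  cols <- c("index", "name", "resid", "resname", "role",
            "ligand_id", "substrate_id", "element", "mass")
  out <- atoms[, cols]
  class(out) <- c("nanosite_topology", class(out))
  out
}

#' @export
print.nanosite_topology <- function(x, ...) {
  cat(sprintf("<nanosite topology: %d atoms, %d ligands, %d Zn, %d substrates>\n",
              nrow(x), n_ligands(x), n_zn(x), n_substrates(x)))
  NextMethod()
}

#' Topology counts
#'
#' Number of coating ligands, chelated Zn ions, and substrate molecules in a
#' labelled topology.
#'
#' @param topology A topology tibble.
#' @return Integer count.
#' @export
n_ligands <- function(topology) length(unique(stats::na.omit(topology$ligand_id)))

#' @rdname n_ligands
#' @export
n_zn <- function(topology) sum(topology$role == "ZN")

#' @rdname n_ligands
#' @export
n_substrates <- function(topology) length(unique(stats::na.omit(topology$substrate_id)))

#' Select atom indices by role, name, or molecule
#'
#' @param topology A topology tibble.
#' @param roles Character vector of roles (see [atom_roles()]).
#' @param names Character vector of atom names.
#' @param ligand,substrate Restrict to given ligand / substrate ids.
#' @return Integer vector of atom indices (1-based).
#' @export
select_atoms <- function(topology, roles = NULL, names = NULL,
                         ligand = NULL, substrate = NULL) {
  keep <- rep(TRUE, nrow(topology))
  if (!is.null(roles)) keep <- keep & topology$role %in% roles
  if (!is.null(names)) keep <- keep & topology$name %in% names
  if (!is.null(ligand)) keep <- keep & topology$ligand_id %in% ligand
  if (!is.null(substrate)) keep <- keep & topology$substrate_id %in% substrate
  which(keep)
}

.read_pdb_atoms <- function(file) {
  pdb <- tryCatch(bio3d::read.pdb(file, verbose = FALSE),
                  error = function(e) ns_abort(paste0("unreadable PDB: ",
                                                      conditionMessage(e)),
                                               "format_error"))
  a <- pdb$atom
  coords <- cbind(a$x, a$y, a$z) / 10  # Angstrom -> nm
  box <- diag(c(100, 100, 100))        # PDB fixtures: effectively aperiodic
  list(atoms = tibble(name = trimws(a$elety), resid = a$resno,
                      resname = trimws(a$resid)),
       coords = coords, box = box)
}
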