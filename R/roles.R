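#' Atom roles
#'
#' Every atom in a labelled topology carries one semantic role tying the raw
#' coordinate file to the chemistry of a Zn(II)-TACN gold nanozyme: the gold
#' core, the anchoring sulfur, the inner alkyl chain (C1..C7), the inner amide
#' (O8, N9), the flexible linker (positions 12 and 15), the outer amide (N18,
#' O19), the TACN crown, the chelated Zn, the phosphodiester substrate
#' (P, O3 hydroxyl oxygen, O4/O5 phosphoryl oxygens), water, and chloride.
#' Atoms that match no rule may be assigned \code{"OTHER"}.
#'
#' @return Character vector of all recognised role names.
#' @export
atom_roles <- function() {
  c("GOLD", "SULFUR", paste0("ALKYL_C", 1:7), "O8", "N9",
    "LINKER_12", "LINKER_15", "N18", "O19", "TACN_N", "TACN_C",
    "ZN", "SUB_P", "SUB_O3", "SUB_O4", "SUB_O5", "SUB_OTHER",
    "WATER_O", "WATER_H", "CL", "OTHER")
}

# roles considered part of a coating ligand (share a ligand id with their Zn)
.ligand_roles <- function() {
  c("SULFUR", paste0("ALKYL_C", 1:7), "O8", "N9", "LINKER_12", "LINKER_15",
    "N18", "O19", "TACN_N", "TACN_C", "ZN")
}

.substrate_roles <- function() c("SUB_P", "SUB_O3", "SUB_O4", "SUB_O5", "SUB_OTHER")

# standard atomic masses (amu), keyed by element symbol
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  CL = 35.45, ZN = 65.38, AU = 196.967, `NA` = 22.990, K = 39.098
)

# element for each role; OTHER falls back to a name-based guess
.role_elements <- c(
  GOLD = "AU", SULFUR = "S", O8 = "O", N9 = "N", LINKER_12 = "C",
  LINKER_15 = "C", N18 = "N", O19 = "O", TACN_N = "N", TACN_C = "C",
  ZN = "ZN", SUB_P = "P", SUB_O3 = "O", SUB_O4 = "O", SUB_O5 = "O",
  SUB_OTHER = "C", WATER_O = "O", WATER_H = "H", CL = "CL", OTHER = "C",
  setNames(rep("C", 7), paste0("ALKYL_C", 1:7))
)

.guess_element <- function(name) {
  up <- toupper(gsub("[^A-Za-z].*$", "", name))
  two <- substr(up, 1, 2)
  one <- substr(up, 1, 1)
  ifelse(two %in% c("AU", "ZN", "CL", "NA", "OW", "HW"),
         c(AU = "AU", ZN = "ZN", CL = "CL", `NA` = "NA",
           OW = "O", HW = "H")[two],
         ifelse(one %in% names(.element_masses), one, "C"))
}

#' Label maps: assigning roles to atoms
#'
#' A label map is an explicit, user-supplied configuration translating
#' (residue name, atom name) pairs of a coordinate file into [atom_roles()].
#' Standard coordinate formats carry no semantics, so this layer is always
#' explicit. A map is a list with elements \describe{
#'   \item{rules}{a data frame with columns \code{resname}, \code{name},
#'     \code{role}; \code{resname = "*"} matches any residue name.}
#'   \item{default}{optional role assigned to unmatched atoms; if absent,
#'     unmatched atoms raise a labelling error.}
#' }
#'
#' \code{label_map()} builds a map from a rules data frame;
#' \code{read_label_map()} reads one from a YAML file with keys \code{rules}
#' (list of \code{\{resname, name, role\}}) and optional \code{default};
#' \code{label_map_preset()} returns the shipped presets matching the
#' synthetic generator's naming for the two nanozymes studied (alkyl-linker
#' "aunp2" and PEG-linker "aunp3", which differ only in linker atom names
#' C12/C15 vs O12/O15).
#'
#' @param rules Data frame with columns \code{resname}, \code{name}, \code{role}.
#' @param default Optional default role for unmatched atoms.
#' @param path Path to a YAML label-map file.
#' @param which Preset name, \code{"aunp2"} or \code{"aunp3"}.
#' @return A label map list.
#' @export
label_map <- function(rules, default = NULL) {
  rules <- as_tibble(rules)
  stopifnot(all(c("resname", "name", "role") %in% names(rules)))
  bad <- setdiff(rules$role, atom_roles())
  if (length(bad) > 0)
    ns_abort(paste0("unknown role(s) in label map: ", paste(bad, collapse = ", ")),
             "labeling_error")
  if (!is.null(default) && !default %in% atom_roles())
    ns_abort(paste0("unknown default role: ", default), "labeling_error")
  structure(list(rules = rules, default = default), class = "nanosite_label_map")
}

#' @rdname label_map
#' @export
read_label_map <- function(path) {
  y <- yaml::read_yaml(path)
  rules <- dplyr::bind_rows(lapply(y$rules, function(r) {
    tibble(resname = r$resname %||% "*", name = r$name, role = r$role)
  }))
  label_map(rules, default = y$default)
}

#' @rdname label_map
#' @export
label_map_preset <- function(which = c("aunp2", "aunp3")) {
  which <- match.arg(which)
  linker <- if (which == "aunp2") c("C12", "C15") else c("O12", "O15")
  linker_h <- if (which == "aunp2") c("H12", "H15") else character(0)
  lig <- tibble(
    resname = "LIG",
    name = c("S", paste0("C", 1:7), "O8", "N9", linker, "N18", "O19",
             paste0("NT", 1:3), "ZN",
             paste0("H", 1:7), "HN9", "HN18", linker_h),
    role = c("SULFUR", paste0("ALKYL_C", 1:7), "O8", "N9",
             "LINKER_12", "LINKER_15", "N18", "O19",
             rep("TACN_N", 3), "ZN",
             rep("OTHER", 9 + length(linker_h)))
  )
  other <- tibble(
    resname = c("AUC", "HPN", "HPN", "HPN", "HPN", "SOL", "SOL", "SOL", "CL"),
    name    = c("AU", "P", "O3", "O4", "O5", "OW", "HW1", "HW2", "CL"),
    role    = c("GOLD", "SUB_P", "SUB_O3", "SUB_O4", "SUB_O5",
                "WATER_O", "WATER_H", "WATER_H", "CL")
  )
  label_map(dplyr::bind_rows(lig, other))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# apply a label map to (resname, name) vectors -> role vector (NA = unmatched)
.apply_label_map <- function(map, resname, name) {
  roles <- rep(NA_character_, length(name))
  r <- map$rules
  exact <- r$resname != "*"
  key_all <- paste(resname, name, sep = "\r")
  if (any(exact)) {
    kr <- paste(r$resname[exact], r$name[exact], sep = "\r")
    m <- match(key_all, kr)
    roles[!is.na(m)] <- r$role[exact][m[!is.na(m)]]
  }
  if (any(!exact)) {
    m2 <- match(name, r$name[!exact])
    fill <- is.na(roles) & !is.na(m2)
    roles[fill] <- r$role[!exact][m2[fill]]
  }
  roles
}
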