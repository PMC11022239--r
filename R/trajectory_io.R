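# Frame container and multi-model PDB / component-map I/O.

wrap_coords <- function(xyz, L) xyz - L * floor(xyz / L)

#' Construct a trajectory frame
#'
#' A frame is one snapshot: wrapped atom coordinates in a cubic periodic box
#' plus the labeling that ties every atom to a component (molecule or ion),
#' a component kind, a chemical group and an atomic radius.
#'
#' @param coords `n_atoms x 3` numeric matrix, Angstrom. Coordinates are
#'   wrapped into `[0, box_length)` on construction.
#' @param box_length cubic box edge, Angstrom.
#' @param atom_component integer vector mapping each atom to a component index
#'   (1-based, components numbered consecutively).
#' @param component_kind character vector, one of [COMPONENT_KINDS] per
#'   component.
#' @param atom_group character vector of chemical-group labels per atom.
#' @param atom_radius numeric vector of atomic radii per atom, Angstrom.
#' @param atom_label optional atom names (defaults `A1..An`).
#' @param component_resname optional residue names per component (defaults
#'   derived from kind).
#' @param component_chain optional chain identifiers per component.
#' @return an object of class `md_frame`.
#' @export
md_frame <- function(coords, box_length, atom_component, component_kind,
                     atom_group, atom_radius, atom_label = NULL,
                     component_resname = NULL, component_chain = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (ncol(coords) != 3L || !is.numeric(coords)) stop("coords must be n x 3 numeric")
  if (any(!is.finite(coords))) stop("all coordinates must be finite")
  if (!is.finite(box_length) || box_length <= 0) stop("box_length must be positive")
  atom_component <- as.integer(atom_component)
  if (length(atom_component) != n) stop("atom_component must map every atom")
  nc <- max(atom_component)
  if (min(atom_component) < 1L || !all(seq_len(nc) %in% atom_component))
    stop("components must be numbered consecutively from 1 and each own >= 1 atom")
  if (length(component_kind) != nc) stop("component_kind must have one entry per component")
  if (!all(component_kind %in% COMPONENT_KINDS)) stop("unknown component kind")
  if (length(atom_group) != n || length(atom_radius) != n)
    stop("atom_group and atom_radius must have one entry per atom")
  if (any(!is.finite(atom_radius)) || any(atom_radius <= 0))
    stop("atom radii must be positive")
  if (is.null(atom_label)) atom_label <- paste0("A", seq_len(n))
  if (is.null(component_resname)) {
    default_res <- c(PEPTIDE = "CHH", DRUG = "DRG", ZN = "ZN",
                     NO3 = "NO3", CL = "CL")
    component_resname <- unname(default_res[component_kind])
  }
  if (is.null(component_chain)) component_chain <- rep("A", nc)
  structure(list(coords = unname(wrap_coords(coords, box_length)),
                 box_length = as.numeric(box_length),
                 atom_component = atom_component,
                 component_kind = as.character(component_kind),
                 atom_group = as.character(atom_group),
                 atom_radius = as.numeric(atom_radius),
                 atom_label = as.character(atom_label),
                 component_resname = as.character(component_resname),
                 component_chain = as.character(component_chain)),
            class = "md_frame")
}

#' @export
print.md_frame <- function(x, ...) {
  tab <- table(factor(x$component_kind, levels = COMPONENT_KINDS))
  cat(sprintf("md_frame: %d atoms, %d components (%s), box %.2f Angstrom\n",
              nrow(x$coords), n_components(x),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              x$box_length))
  invisible(x)
}

#' Number of components in a frame
#' @param frame an `md_frame`.
#' @export
n_components <- function(frame) length(frame$component_kind)

# Atom row indices of one component.
component_atoms <- function(frame, i) which(frame$atom_component == i)

# Assemble a frame from per-component template placements.
# placements: list of list(kind=, coords=) in component order.
frame_from_placements <- function(placements, templates, box_length) {
  kinds <- vapply(placements, `[[`, "", "kind")
  specs <- lapply(templates[kinds], `[[`, "spec")
  coords <- do.call(rbind, lapply(placements, `[[`, "coords"))
  md_frame(coords, box_length,
           atom_component = rep(seq_along(placements),
                                vapply(specs, `[[`, 0L, "n_atoms")),
           component_kind = kinds,
           atom_group = unlist(lapply(specs, `[[`, "group_labels")),
           atom_radius = unlist(lapply(specs, `[[`, "atom_radii")),
           atom_label = unlist(lapply(specs, `[[`, "atom_labels")))
}

# -- component map -------------------------------------------------------------

default_element_radius <- function(atom_name) {
  el <- toupper(substr(trimws(atom_name), 1, 1))
  two <- toupper(trimws(atom_name))
  if (two %in% c("ZN")) return(1.2)
  if (two %in% c("CL")) return(1.8)
  switch(el, C = 1.7, N = 1.55, O = 1.52, S = 1.8, H = 1.2, P = 1.8, 1.7)
}

#' Load a component/group map from a YAML config
#'
#' The map assigns every residue name a component kind and net charge, and
#' every (residue, atom) pair a chemical-group label and radius. A missing
#' radius falls back to an element-based default with a warning. An optional
#' `box_length` entry supplies the box when the trajectory lacks a CRYST1
#' record, and an optional `analysis` block overrides [analysis_config()]
#' defaults.
#'
#' @param path YAML file with top-level keys `residues`, `atoms`, and
#'   optionally `box_length` and `analysis`.
#' @return a `component_map`: list with `residues` (data.frame resname, kind,
#'   charge), `atoms` (data.frame resname, atom, group, radius), `box_length`
#'   (or `NULL`) and `config` (an `analysis_config`).
#' @export
load_component_map <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$residues)) stop("component map must contain a 'residues' table")
  resnames <- names(raw$residues)
  if (anyDuplicated(resnames)) stop("duplicate residue entries in component map")
  kinds <- vapply(raw$residues, function(r) as.character(r$kind), "")
  bad <- setdiff(kinds, COMPONENT_KINDS)
  if (length(bad))
    stop("unknown component kind(s) in map: ", paste(unique(bad), collapse = ", "))
  residues <- data.frame(
    resname = resnames, kind = kinds,
    charge = vapply(raw$residues, function(r) as.integer(r$charge %||% 0L), 0L),
    stringsAsFactors = FALSE)

  atoms <- data.frame(resname = character(), atom = character(),
                      group = character(), radius = numeric(),
                      stringsAsFactors = FALSE)
  if (!is.null(raw$atoms)) {
    rows <- list()
    for (res in names(raw$atoms)) {
      for (at in names(raw$atoms[[res]])) {
        entry <- raw$atoms[[res]][[at]]
        radius <- entry$radius
        if (is.null(radius)) {
          radius <- default_element_radius(at)
          warning(sprintf("no radius for %s/%s; using element default %.2f",
                          res, at, radius))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          resname = res, atom = at,
          group = as.character(entry$group %||% "ungrouped"),
          radius = as.numeric(radius), stringsAsFactors = FALSE)
      }
    }
    atoms <- do.call(rbind, rows)
  }
  cfg_args <- raw$analysis %||% list()
  structure(list(residues = residues, atoms = atoms,
                 box_length = raw$box_length,
                 config = do.call(analysis_config, cfg_args)),
            class = "component_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a component map from molecule templates
#'
#' Convenience for synthetic systems: builds the residue and atom tables of a
#' `component_map` directly from a template set, so generated trajectories can
#' be written to PDB and re-read without a hand-written config.
#'
#' @param templates named list of `molecule_template` (as from
#'   [default_templates()]).
#' @param box_length optional box edge recorded in the map.
#' @param config an [analysis_config()].
#' @return a `component_map`.
#' @export
component_map_from_templates <- function(templates, box_length = NULL,
                                         config = analysis_config()) {
  default_res <- c(PEPTIDE = "CHH", DRUG = "DRG", ZN = "ZN",
                   NO3 = "NO3", CL = "CL")
  residues <- do.call(rbind, lapply(names(templates), function(k) {
    sp <- templates[[k]]$spec
    data.frame(resname = default_res[[k]], kind = sp$kind,
               charge = sp$net_charge, stringsAsFactors = FALSE)
  }))
  atoms <- do.call(rbind, lapply(names(templates), function(k) {
    sp <- templates[[k]]$spec
    data.frame(resname = default_res[[k]], atom = sp$atom_labels,
               group = sp$group_labels, radius = sp$atom_radii,
               stringsAsFactors = FALSE)
  }))
  structure(list(residues = residues, atoms = atoms, box_length = box_length,
                 config = config),
            class = "component_map")
}

# -- multi-model PDB -----------------------------------------------------------

#' Write frames to a multi-model PDB file
#'
#' Standard MODEL/ENDMDL blocks with a CRYST1 record for the cubic cell and
#' fixed-width ATOM records (coordinates `%8.3f`). Output is deterministic:
#' identical frames give byte-identical files.
#'
#' @param frames a single `md_frame` or a list of them (equal labeling).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(frames, path) {
  if (inherits(frames, "md_frame")) frames <- list(frames)
  if (!length(frames)) stop("frames must be nonempty")
  con <- file(path, open = "wb")
  on.exit(close(con))
  f1 <- frames[[1L]]
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     f1$box_length, f1$box_length, f1$box_length, 90, 90, 90),
             con)
  ion_res <- c("ZN", "NO3", "CL")
  for (m in seq_along(frames)) {
    fr <- frames[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    rec <- ifelse(fr$component_resname[fr$atom_component] %in% ion_res,
                  "HETATM", "ATOM  ")
    serial <- seq_len(nrow(fr$coords))
    lines <- sprintf("%s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                     rec, serial %% 100000L,
                     substr(fr$atom_label[serial], 1, 4),
                     substr(fr$component_resname[fr$atom_component], 1, 4),
                     substr(fr$component_chain[fr$atom_component], 1, 1),
                     fr$atom_component %% 10000L,
                     fr$coords[, 1], fr$coords[, 2], fr$coords[, 3],
                     1, 0)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB trajectory
#'
#' Parses MODEL/ENDMDL blocks into one [md_frame()] each. Coordinates come
#' from the fixed PDB columns (31-38, 39-46, 47-54); the box from CRYST1 or,
#' failing that, from the component map. Atoms are grouped into components by
#' (chain, residue number, residue name), in order of first appearance.
#'
#' @param path PDB file.
#' @param component_map a `component_map` from [load_component_map()] or
#'   [component_map_from_templates()].
#' @return list of `md_frame`.
#' @export
read_multimodel_pdb <- function(path, component_map) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  tag <- substr(lines, 1, 6)
  box <- NULL
  cr <- which(tag == "CRYST1")
  if (length(cr)) box <- as.numeric(substr(lines[cr[1L]], 7, 15))
  if (is.null(box) || !is.finite(box)) box <- component_map$box_length
  if (is.null(box)) stop("no CRYST1 record and no box_length in component map")

  model_starts <- which(tag == "MODEL ")
  model_ends <- which(tag == "ENDMDL")
  if (!length(model_starts)) {  # single implicit model
    model_starts <- 1L; model_ends <- length(lines)
  }
  if (length(model_starts) != length(model_ends))
    stop("unbalanced MODEL/ENDMDL records")

  res_tab <- component_map$residues
  atom_tab <- component_map$atoms
  akey <- paste(atom_tab$resname, atom_tab$atom)

  lapply(seq_along(model_starts), function(m) {
    block <- lines[model_starts[m]:model_ends[m]]
    is_atom <- substr(block, 1, 6) %in% c("ATOM  ", "HETATM")
    rows <- block[is_atom]
    if (!length(rows)) stop("MODEL ", m, " contains no atoms")
    x <- as.numeric(substr(rows, 31, 38))
    y <- as.numeric(substr(rows, 39, 46))
    z <- as.numeric(substr(rows, 47, 54))
    bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
    if (length(bad))
      stop(sprintf("missing/invalid coordinates in MODEL %d at line %d", m,
                   model_starts[m] + which(is_atom)[bad[1L]] - 1L))
    resname <- trimws(substr(rows, 18, 21))
    chain <- substr(rows, 22, 22)
    resseq <- trimws(substr(rows, 23, 26))
    aname <- trimws(substr(rows, 13, 16))

    unmapped <- setdiff(unique(resname), res_tab$resname)
    if (length(unmapped))
      stop("residue name(s) not in component map: ",
           paste(unmapped, collapse = ", "))
    comp_key <- paste(chain, resseq, resname)
    comp_id <- match(comp_key, unique(comp_key))
    first <- !duplicated(comp_id)
    kind <- res_tab$kind[match(resname[first], res_tab$resname)]

    idx <- match(paste(resname, aname), akey)
    group <- ifelse(is.na(idx), "ungrouped", atom_tab$group[idx])
    radius <- ifelse(is.na(idx),
                     vapply(aname, default_element_radius, 0),
                     atom_tab$radius[idx])
    md_frame(cbind(x, y, z), box, comp_id, kind, group, radius,
             atom_label = aname, component_resname = resname[first],
             component_chain = chain[first])
  })
}

#' Write a component map to YAML
#'
#' @param map a `component_map`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_component_map <- function(map, path) {
  residues <- setNames(lapply(seq_len(nrow(map$residues)), function(i)
    list(kind = map$residues$kind[i], charge = map$residues$charge[i])),
    map$residues$resname)
  atoms <- lapply(split(map$atoms, map$atoms$resname), function(df)
    setNames(lapply(seq_len(nrow(df)), function(i)
      list(group = df$group[i], radius = df$radius[i])), df$atom))
  out <- list(residues = residues, atoms = atoms)
  if (!is.null(map$box_length)) out$box_length <- map$box_length
  yaml::write_yaml(out, path)
  invisible(path)
}
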