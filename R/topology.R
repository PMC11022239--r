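#' @useDynLib coassembly, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd setNames predict
#' @importFrom utils head read.delim write.table
NULL

#' Component kinds recognised by the analysis
#'
#' The five component taxa of a peptide/drug/ion co-assembly system:
#' cyclic dipeptide (`PEPTIDE`), small-molecule drug (`DRUG`), zinc cation
#' (`ZN`), nitrate anion (`NO3`) and chloride anion (`CL`).
#'
#' @export
COMPONENT_KINDS <- c("PEPTIDE", "DRUG", "ZN", "NO3", "CL")

#' Construct a component specification
#'
#' A `component_spec` describes one molecular species: its kind, net charge
#' (elementary charge units), and per-atom labels, chemical-group labels and
#' van der Waals radii.
#'
#' @param kind one of [COMPONENT_KINDS].
#' @param net_charge integer net charge in elementary charge units.
#' @param atom_labels character vector of atom names.
#' @param group_labels character vector of chemical-group names, parallel to
#'   `atom_labels`.
#' @param atom_radii numeric vector of atomic radii in Angstrom, all positive.
#' @return an object of class `component_spec`.
#' @examples
#' component_spec("ZN", +2, "ZN", "zinc", 1.2)
#' @export
component_spec <- function(kind, net_charge, atom_labels, group_labels, atom_radii) {
  kind <- match.arg(kind, COMPONENT_KINDS)
  n <- length(atom_labels)
  if (length(group_labels) != n || length(atom_radii) != n)
    stop("atom_labels, group_labels and atom_radii must have equal length")
  if (n < 1L) stop("a component needs at least one atom")
  if (any(!is.finite(atom_radii)) || any(atom_radii <= 0))
    stop("all atom radii must be positive")
  net_charge <- as.integer(net_charge)
  if (kind == "ZN" && (n != 1L || net_charge != 2L))
    stop("ZN must be a single atom with net charge +2")
  if (kind == "NO3" && net_charge != -1L) stop("NO3 must have net charge -1")
  if (kind == "CL" && (n != 1L || net_charge != -1L))
    stop("CL must be a single atom with net charge -1")
  structure(list(kind = kind, net_charge = net_charge, n_atoms = n,
                 atom_labels = as.character(atom_labels),
                 group_labels = as.character(group_labels),
                 atom_radii = as.numeric(atom_radii)),
            class = "component_spec")
}

#' Build a neutral system composition
#'
#' Applies the neutralization convention of the simulated co-assembly setups:
#' nitrate counterions absorb the Zn2+ charge and any negative drug charge;
#' chloride is added only when the drug carries positive charge. The returned
#' composition always has zero net charge (the cyclic dipeptide itself is
#' neutral).
#'
#' For 48 peptides, 12 drugs and 48 Zn2+ this yields 96 NO3- for a neutral
#' drug, 72 NO3- for a -2 drug, and 96 NO3- plus 12 Cl- for a +1 drug.
#'
#' @param n_peptide,n_drug,n_zn non-negative component counts.
#' @param drug_charge integer net charge per drug copy.
#' @param box_length cubic box edge length in Angstrom.
#' @param drug_name optional drug label carried through outputs.
#' @return an object of class `system_composition` with fields `n_peptide`,
#'   `n_drug`, `drug_charge`, `n_zn`, `n_no3`, `n_cl`, `box_length`,
#'   `drug_name`.
#' @examples
#' build_composition(48, 12, +1, 48, 83)  # 96 NO3-, 12 Cl-
#' build_composition(48, 12, -2, 48, 83)  # 72 NO3-
#' @export
build_composition <- function(n_peptide, n_drug, drug_charge, n_zn,
                              box_length = 83, drug_name = "DRG") {
  counts <- c(n_peptide = n_peptide, n_drug = n_drug, n_zn = n_zn)
  if (any(counts < 0)) stop("component counts must be non-negative")
  if (any(counts != round(counts))) stop("component counts must be integers")
  if (!is.finite(box_length) || box_length <= 0) stop("box_length must be positive")
  drug_charge <- as.integer(drug_charge)
  n_no3 <- if (drug_charge < 0L) 2L * n_zn + n_drug * drug_charge else 2L * n_zn
  n_cl <- if (drug_charge > 0L) n_drug * drug_charge else 0L
  if (n_no3 < 0L)
    stop("drug charge too negative: required nitrate count would be negative")
  comp <- structure(list(n_peptide = as.integer(n_peptide),
                         n_drug = as.integer(n_drug),
                         drug_charge = drug_charge,
                         n_zn = as.integer(n_zn),
                         n_no3 = as.integer(n_no3),
                         n_cl = as.integer(n_cl),
                         box_length = as.numeric(box_length),
                         drug_name = as.character(drug_name)),
                    class = "system_composition")
  stopifnot(net_charge(comp) == 0L)
  comp
}

#' Net charge of a system composition
#'
#' @param composition a `system_composition`.
#' @return integer net charge (zero for anything built by
#'   [build_composition()]).
#' @export
net_charge <- function(composition) {
  with(composition, 2L * n_zn + drug_charge * n_drug - n_no3 - n_cl)
}

#' @export
print.system_composition <- function(x, ...) {
  cat(sprintf("System composition (%s): %d peptide, %d drug (q=%+d), %d Zn2+, %d NO3-, %d Cl-\n",
              x$drug_name, x$n_peptide, x$n_drug, x$drug_charge,
              x$n_zn, x$n_no3, x$n_cl))
  cat(sprintf("  cubic box %.1f Angstrom, net charge %d\n",
              x$box_length, net_charge(x)))
  invisible(x)
}

#' Drug-to-peptide ratio of the simulation setup
#'
#' The ratio of drug copies to peptide copies placed in the box (0.25, i.e.
#' 1:4, for the standard 12-drug/48-peptide setup).
#'
#' @param composition a `system_composition` with at least one peptide.
#' @return `n_drug / n_peptide`.
#' @export
initial_drug_peptide_ratio <- function(composition) {
  if (composition$n_peptide == 0L)
    stop("drug:peptide ratio undefined for a system without peptides")
  composition$n_drug / composition$n_peptide
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the cluster analysis. Defaults follow the
#' standard protocol: 3.5 Angstrom any-atom contact cutoff, clusters of more
#' than 30 components (size >= 31), a 2.6 Angstrom solvent probe and 960
#' Shrake-Rupley sphere points.
#'
#' @param contact_cutoff any-atom contact distance cutoff, Angstrom.
#' @param min_cluster_size smallest cluster size retained by the size filter.
#' @param probe_radius solvent probe radius, Angstrom.
#' @param sasa_points number of deterministic unit-sphere test points per atom.
#' @param frame_stride analyze every `frame_stride`-th frame.
#' @param rng_seed integer seed recorded for stochastic stages.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(contact_cutoff = 3.5, min_cluster_size = 31L,
                            probe_radius = 2.6, sasa_points = 960L,
                            frame_stride = 1L, rng_seed = 1L) {
  if (contact_cutoff <= 0) stop("contact_cutoff must be positive")
  if (min_cluster_size < 2) stop("min_cluster_size must be at least 2")
  if (probe_radius < 0) stop("probe_radius must be non-negative")
  if (sasa_points < 16) stop("sasa_points must be at least 16")
  if (frame_stride < 1) stop("frame_stride must be at least 1")
  structure(list(contact_cutoff = as.numeric(contact_cutoff),
                 min_cluster_size = as.integer(min_cluster_size),
                 probe_radius = as.numeric(probe_radius),
                 sasa_points = as.integer(sasa_points),
                 frame_stride = as.integer(frame_stride),
                 rng_seed = as.integer(rng_seed)),
            class = "analysis_config")
}

# -- coarse molecule templates -------------------------------------------------

ring_coords <- function(n, radius, z = 0) {
  ang <- 2 * pi * (seq_len(n) - 1) / n
  cbind(radius * cos(ang), radius * sin(ang), rep(z, n))
}

center_coords <- function(xyz) {
  sweep(xyz, 2, colMeans(xyz))
}

#' Construct a rigid molecule template
#'
#' A template pairs a [component_spec()] with local pseudo-atom coordinates
#' (Angstrom) centered on the molecular centroid. Templates are rigid bodies:
#' the generators translate/rotate them but never deform them.
#'
#' @param spec a `component_spec`.
#' @param local_coords `n_atoms x 3` matrix of coordinates whose centroid is
#'   the origin.
#' @return an object of class `molecule_template`.
#' @export
molecule_template <- function(spec, local_coords) {
  local_coords <- as.matrix(local_coords)
  if (!is.numeric(local_coords) || ncol(local_coords) != 3L ||
      nrow(local_coords) != spec$n_atoms)
    stop("local_coords must be an n_atoms x 3 numeric matrix")
  local_coords <- center_coords(local_coords)
  if (max(abs(colMeans(local_coords))) > 1e-9)
    stop("template centroid must be at the origin")
  if (spec$n_atoms > 1L) {
    d <- as.matrix(stats::dist(local_coords))
    if (min(d[upper.tri(d)]) <= 0.5)
      stop("intra-molecule atom distances must exceed 0.5 Angstrom")
  }
  structure(list(spec = spec, local_coords = unname(local_coords)),
            class = "molecule_template")
}

#' Default coarse-grained molecule templates
#'
#' Pseudo-atom stand-ins for the co-assembling species, detailed enough for
#' contact, group and SASA analysis without a force field:
#' \describe{
#'   \item{PEPTIDE}{cyclic dihistidine: a 4-atom diketopiperazine ring
#'     (`cyclic_ring`) flanked by two 3-atom imidazole groups
#'     (`imidazole_1`, `imidazole_2`); 10 atoms, neutral.}
#'   \item{DRUG}{generic 8-atom drug with a 2-atom `charged_group`, a 3-atom
#'     `polar_group` and a 3-atom `hydrophobic_group`; net charge set by
#'     `drug_charge`.}
#'   \item{ZN}{one 1.2 Angstrom pseudo-atom, charge +2.}
#'   \item{NO3}{trigonal-planar nitrate, 4 atoms, charge -1.}
#'   \item{CL}{one 1.8 Angstrom pseudo-atom, charge -1.}
#' }
#'
#' @param drug_charge integer net charge assigned to the DRUG template.
#' @param drug_name residue name used for the drug in PDB output.
#' @return named list of `molecule_template` objects keyed by kind.
#' @export
default_templates <- function(drug_charge = 0L, drug_name = "DRG") {
  # peptide: diketopiperazine ring in the xy plane, imidazoles above/below
  ring <- ring_coords(4L, 1.4)
  imid1 <- sweep(ring_coords(3L, 1.1), 2, c(2.9, 0, 1.4), `+`)
  imid2 <- sweep(ring_coords(3L, 1.1), 2, c(-2.9, 0, -1.4), `+`)
  pep_xyz <- rbind(ring, imid1, imid2)
  pep <- component_spec(
    "PEPTIDE", 0L,
    atom_labels = c(paste0("CR", 1:4), paste0("IA", 1:3), paste0("IB", 1:3)),
    group_labels = c(rep("cyclic_ring", 4), rep("imidazole_1", 3),
                     rep("imidazole_2", 3)),
    atom_radii = c(rep(1.7, 4), rep(1.55, 3), rep(1.55, 3)))

  drug_xyz <- rbind(
    cbind(c(-2.4, -2.4), c(-0.7, 0.7), c(0, 0)),            # charged
    sweep(ring_coords(3L, 1.0), 2, c(0, 0, 0.9), `+`),      # polar
    sweep(ring_coords(3L, 1.2), 2, c(2.5, 0, -0.6), `+`))   # hydrophobic
  drg <- component_spec(
    "DRUG", drug_charge,
    atom_labels = c("Q1", "Q2", "P1", "P2", "P3", "H1", "H2", "H3"),
    group_labels = c(rep("charged_group", 2), rep("polar_group", 3),
                     rep("hydrophobic_group", 3)),
    atom_radii = c(1.5, 1.5, 1.52, 1.52, 1.52, 1.7, 1.7, 1.7))

  no3_xyz <- rbind(c(0, 0, 0), ring_coords(3L, 1.25))
  list(
    PEPTIDE = molecule_template(pep, pep_xyz),
    DRUG = molecule_template(drg, drug_xyz),
    ZN = molecule_template(
      component_spec("ZN", 2L, "ZN", "zinc", 1.2), matrix(0, 1, 3)),
    NO3 = molecule_template(
      component_spec("NO3", -1L, c("N", "O1", "O2", "O3"),
                     rep("nitrate", 4), c(1.55, 1.52, 1.52, 1.52)),
      no3_xyz),
    CL = molecule_template(
      component_spec("CL", -1L, "CL", "chloride", 1.8), matrix(0, 1, 3))
  )
}

# Per-kind component counts of a composition, in canonical kind order.
composition_counts <- function(composition) {
  c(PEPTIDE = composition$n_peptide, DRUG = composition$n_drug,
    ZN = composition$n_zn, NO3 = composition$n_no3, CL = composition$n_cl)
}
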