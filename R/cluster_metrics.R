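# Per-cluster structural statistics: composition percentages, drug
# encapsulation, count ratios, radius of gyration, Shrake-Rupley SASA burial
# and size-binned ensemble profiles.

#' Percentage composition of a cluster
#'
#' @param cluster a `cluster`.
#' @return named numeric vector over [COMPONENT_KINDS], percentages summing
#'   to 100.
#' @export
composition_percentages <- function(cluster) {
  if (!length(cluster$members)) stop("empty cluster")
  tab <- table(factor(cluster$kinds, levels = COMPONENT_KINDS))
  setNames(100 * as.numeric(tab) / cluster$size, COMPONENT_KINDS)
}

n_drugs_in <- function(cluster) sum(cluster$kinds == "DRUG")

#' Drug-encapsulation probabilities of a cluster ensemble
#'
#' @param clusters nonempty list of `cluster`.
#' @return named numeric vector `p_no_drug`, `p_ge1_drug`, `p_ge2_drug`:
#'   the fraction of clusters containing zero, at least one, and at least two
#'   drug molecules (`p_no_drug + p_ge1_drug == 1`).
#' @export
encapsulation_summary <- function(clusters) {
  if (!length(clusters)) stop("encapsulation summary of an empty cluster list")
  nd <- vapply(clusters, n_drugs_in, 0L)
  c(p_no_drug = mean(nd == 0L),
    p_ge1_drug = mean(nd >= 1L),
    p_ge2_drug = mean(nd >= 2L))
}

#' Percentage of the system's drugs encapsulated in one cluster
#'
#' @param cluster a `cluster`.
#' @param total_drugs total number of drug copies in the system (> 0).
#' @return `100 * n_drugs_in_cluster / total_drugs`.
#' @export
drug_encapsulation_percentage <- function(cluster, total_drugs) {
  if (total_drugs <= 0) stop("total_drugs must be positive")
  100 * n_drugs_in(cluster) / total_drugs
}

#' Drug/peptide and Zn/peptide count ratios of a cluster
#'
#' @param cluster a `cluster`.
#' @return named vector `drug_peptide_ratio`, `zn_peptide_ratio`; both `NA`
#'   (with a warning) for a peptide-free cluster.
#' @export
cluster_ratios <- function(cluster) {
  np <- sum(cluster$kinds == "PEPTIDE")
  if (np == 0L) {
    warning("cluster contains no peptides; ratios undefined")
    return(c(drug_peptide_ratio = NA_real_, zn_peptide_ratio = NA_real_))
  }
  c(drug_peptide_ratio = sum(cluster$kinds == "DRUG") / np,
    zn_peptide_ratio = sum(cluster$kinds == "ZN") / np)
}

#' Radius of gyration of a point set
#'
#' Root-mean-square distance of the atoms from their centroid, uniform
#' weights. Pass unwrapped coordinates (see [unwrap_cluster()]) so the value
#' is meaningful for boundary-straddling clusters.
#'
#' @param coords `n x 3` matrix, Angstrom.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(coords) {
  coords <- as.matrix(coords)
  d <- sweep(coords, 2, colMeans(coords))
  sqrt(mean(rowSums(d * d)))
}

#' SASA burial ratio of one component within its cluster
#'
#' Shrake-Rupley with a deterministic Fibonacci point lattice: each atom's
#' accessible area is the fraction of `n_points` test points on its inflated
#' sphere (radius + probe) outside every other inflated atom, times
#' `4*pi*(r+probe)^2`. The ratio divides the component's SASA inside the
#' cluster (all cluster atoms occluding) by its SASA in isolation (own atoms
#' only), as a percentage: 100 means fully exposed, 0 fully buried.
#'
#' @param frame the source [md_frame()].
#' @param cluster a `cluster` containing `component`.
#' @param component global component index.
#' @param probe_radius solvent probe radius, Angstrom.
#' @param n_points sphere test points per atom (>= 16).
#' @param unwrapped optional precomputed [unwrap_cluster()] result.
#' @return percentage in [0, 100].
#' @export
sasa_ratio <- function(frame, cluster, component, probe_radius = 2.6,
                       n_points = 960L, unwrapped = NULL) {
  ratios <- cluster_sasa_ratios(frame, cluster, probe_radius, n_points,
                                unwrapped)
  if (!as.character(component) %in% names(ratios))
    stop("component ", component, " is not a member of the cluster")
  ratios[[as.character(component)]]
}

#' SASA burial ratios of every component of a cluster
#'
#' @inheritParams sasa_ratio
#' @return named numeric vector, one percentage per member component (names
#'   are global component indices).
#' @export
cluster_sasa_ratios <- function(frame, cluster, probe_radius = 2.6,
                                n_points = 960L, unwrapped = NULL) {
  if (n_points < 16) stop("n_points must be at least 16")
  if (is.null(unwrapped)) unwrapped <- unwrap_cluster(frame, cluster)
  coords <- unwrapped$coords
  radii <- frame$atom_radius[unwrapped$atom_rows]
  frac_in <- cpp_exposed_fraction(coords, radii, probe_radius,
                                  as.integer(n_points))
  area <- 4 * pi * (radii + probe_radius)^2
  out <- vapply(cluster$members, function(ci) {
    sel <- unwrapped$atom_component == ci
    frac_iso <- cpp_exposed_fraction(coords[sel, , drop = FALSE], radii[sel],
                                     probe_radius, as.integer(n_points))
    iso <- sum(frac_iso * area[sel])
    if (iso <= 0) stop("isolated SASA is zero; check radii and probe")
    100 * sum(frac_in[sel] * area[sel]) / iso
  }, 0)
  setNames(out, as.character(cluster$members))
}

#' Absolute Shrake-Rupley SASA of a point set
#'
#' @param coords `n x 3` matrix (no periodicity; unwrap first).
#' @param radii per-atom radii, Angstrom.
#' @param probe_radius probe radius, Angstrom.
#' @param n_points sphere points per atom.
#' @return total accessible area, Angstrom^2.
#' @export
shrake_rupley_sasa <- function(coords, radii, probe_radius = 2.6,
                               n_points = 960L) {
  frac <- cpp_exposed_fraction(as.matrix(coords), radii, probe_radius,
                               as.integer(n_points))
  sum(frac * 4 * pi * (radii + probe_radius)^2)
}

#' Full statistics row for one cluster
#'
#' @param frame source frame.
#' @param cluster a `cluster`.
#' @param total_drugs total drug copies in the system.
#' @param config an [analysis_config()] (probe radius, SASA points).
#' @param sasa compute SASA ratios (the expensive part)?
#' @return one-row data.frame: size, per-kind composition percentages, drug
#'   count and encapsulation percentage, count ratios, radius of gyration,
#'   and per-kind mean SASA ratios (`NA` for kinds absent from the cluster).
#' @export
cluster_stats <- function(frame, cluster, total_drugs,
                          config = analysis_config(), sasa = TRUE) {
  comp <- composition_percentages(cluster)
  ratios <- suppressWarnings(cluster_ratios(cluster))
  unw <- unwrap_cluster(frame, cluster)
  rg <- radius_of_gyration(unw$coords)
  sasa_kind <- setNames(rep(NA_real_, 5L), COMPONENT_KINDS)
  if (sasa) {
    sr <- cluster_sasa_ratios(frame, cluster, config$probe_radius,
                              config$sasa_points, unwrapped = unw)
    for (k in unique(cluster$kinds))
      sasa_kind[[k]] <- mean(sr[cluster$kinds == k])
  }
  data.frame(frame = cluster$frame_index, size = cluster$size,
             pct_peptide = comp[["PEPTIDE"]], pct_drug = comp[["DRUG"]],
             pct_zn = comp[["ZN"]], pct_no3 = comp[["NO3"]],
             pct_cl = comp[["CL"]],
             n_drugs = n_drugs_in(cluster),
             drug_encap_pct = if (total_drugs > 0)
               drug_encapsulation_percentage(cluster, total_drugs) else NA_real_,
             drug_peptide_ratio = ratios[["drug_peptide_ratio"]],
             zn_peptide_ratio = ratios[["zn_peptide_ratio"]],
             rg = rg,
             sasa_peptide = sasa_kind[["PEPTIDE"]],
             sasa_drug = sasa_kind[["DRUG"]],
             sasa_zn = sasa_kind[["ZN"]],
             sasa_no3 = sasa_kind[["NO3"]],
             sasa_cl = sasa_kind[["CL"]],
             stringsAsFactors = FALSE)
}

#' Size-binned ensemble profiles
#'
#' Groups per-cluster statistics into half-open size bins
#' `[lo, lo + bin_width)` anchored at the smallest observed size and reports
#' the cluster count plus mean and standard deviation of every numeric
#' statistic per bin. A single-member bin has its sd reported as 0 and is
#' flagged by `sd_defined = FALSE`.
#'
#' @param stats data.frame of per-cluster rows (from [cluster_stats()]).
#' @param bin_width bin width in cluster-size units (>= 1).
#' @return data.frame, one row per occupied bin.
#' @export
size_binned_profiles <- function(stats, bin_width = 10L) {
  if (bin_width < 1) stop("bin_width must be at least 1")
  if (!nrow(stats)) return(data.frame())
  lo0 <- min(stats$size)
  bin <- floor((stats$size - lo0) / bin_width)
  num_cols <- setdiff(names(stats)[vapply(stats, is.numeric, TRUE)],
                      c("frame"))
  rows <- lapply(sort(unique(bin)), function(b) {
    sub <- stats[bin == b, , drop = FALSE]
    out <- data.frame(bin_lo = lo0 + b * bin_width,
                      bin_hi = lo0 + (b + 1) * bin_width - 1,
                      n_clusters = nrow(sub),
                      sd_defined = nrow(sub) > 1L)
    for (cn in num_cols) {
      out[[paste0("mean_", cn)]] <- mean(sub[[cn]], na.rm = TRUE)
      out[[paste0("sd_", cn)]] <-
        if (nrow(sub) > 1L) sd(sub[[cn]], na.rm = TRUE) else 0
    }
    out
  })
  do.call(rbind, rows)
}
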