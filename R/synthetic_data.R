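# Synthetic configuration generators: planted clusters with exact ground
# truth, and a coarse-grained rigid-body Metropolis Monte Carlo co-assembly
# process with tunable kind-pair affinities.

kind_code <- function(kind) match(kind, COMPONENT_KINDS) - 1L

# minimum-image minimum inter-atom distance between two coordinate sets
min_mi_dist <- function(A, B, L) {
  dx <- outer(A[, 1], B[, 1], `-`); dx <- dx - L * round(dx / L)
  dy <- outer(A[, 2], B[, 2], `-`); dy <- dy - L * round(dy / L)
  dz <- outer(A[, 3], B[, 3], `-`); dz <- dz - L * round(dz / L)
  sqrt(min(dx * dx + dy * dy + dz * dz))
}

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s <- sin(angle); t <- 1 - c_
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  matrix(c(t * x * x + c_,     t * x * y - s * z, t * x * z + s * y,
           t * x * y + s * z,  t * y * y + c_,    t * y * z - s * x,
           t * x * z - s * y,  t * y * z + s * x, t * z * z + c_),
         3, 3, byrow = TRUE)
}

random_orientation <- function(xyz) {
  if (nrow(xyz) == 1L) return(xyz)
  xyz %*% t(rotation_matrix(rnorm(3), runif(1, 0, 2 * pi)))
}

#' Square-well affinity model for the Monte Carlo generator
#'
#' Component pairs closer than `r_well` (any-atom) contribute `-eps(a, b)` to
#' the configuration energy; any inter-atom distance below the hard core
#' `sigma` is forbidden; like-charged ion pairs (Zn2+/Zn2+, NO3-/NO3-) within
#' the well additionally pay `repulsion_penalty`. `eps` entries for those two
#' diagonal pairs must be non-positive.
#'
#' @param eps named numeric vector of well depths in kT, names of the form
#'   `"KIND1-KIND2"` (symmetrized automatically); unnamed pairs default to 0.
#' @param sigma hard-core diameter, Angstrom.
#' @param r_well attraction range, Angstrom; defaults to the 3.5 Angstrom
#'   contact cutoff so "interacting" means the same thing to the generator
#'   and the analyzer.
#' @param repulsion_penalty energy (kT) added for like-ion pairs in the well.
#' @return an object of class `affinity_model` holding a symmetric 5x5
#'   epsilon matrix over [COMPONENT_KINDS].
#' @examples
#' affinity_model(c("DRUG-NO3" = 3, "PEPTIDE-PEPTIDE" = 2))
#' @export
affinity_model <- function(eps = numeric(), sigma = 2.0, r_well = 3.5,
                           repulsion_penalty = 2.0) {
  if (sigma >= r_well) stop("sigma must be smaller than r_well")
  if (repulsion_penalty < 0) stop("repulsion_penalty must be non-negative")
  E <- matrix(0, 5, 5, dimnames = list(COMPONENT_KINDS, COMPONENT_KINDS))
  if (length(eps)) {
    parts <- strsplit(names(eps), "-", fixed = TRUE)
    for (k in seq_along(eps)) {
      a <- parts[[k]][1]; b <- parts[[k]][2]
      if (!a %in% COMPONENT_KINDS || !b %in% COMPONENT_KINDS)
        stop("unknown kind in affinity name: ", names(eps)[k])
      E[a, b] <- eps[[k]]; E[b, a] <- eps[[k]]
    }
  }
  if (E["ZN", "ZN"] > 0 || E["NO3", "NO3"] > 0)
    stop("ZN-ZN and NO3-NO3 affinities must be non-positive (repulsive pairs)")
  structure(list(eps = E, sigma = as.numeric(sigma),
                 r_well = as.numeric(r_well),
                 repulsion_penalty = as.numeric(repulsion_penalty)),
            class = "affinity_model")
}

#' Preset affinity models emulating the drug classes
#'
#' Three qualitative interaction signatures on top of a common
#' peptide/ion scaffold (peptide-peptide 2, peptide-Zn 2.5, Zn-NO3 3,
#' peptide-NO3 1.5 kT):
#' \describe{
#'   \item{no3_affine}{drug coordinates nitrate (drug-NO3 3.5 kT,
#'     drug-peptide 2 kT) - the epirubicin/doxorubicin-like signature.}
#'   \item{zn_affine}{drug coordinates zinc (drug-ZN 3.5 kT, drug-peptide
#'     2 kT) - the methotrexate-like signature.}
#'   \item{inert}{all drug affinities zero - the cisplatin-like
#'     non-assembling drug.}
#' }
#'
#' @param class one of `"no3_affine"`, `"zn_affine"`, `"inert"`.
#' @param drug_strength well depth (kT) of the drug's preferred ion contact.
#' @return an `affinity_model`.
#' @export
drug_affinity_preset <- function(class = c("no3_affine", "zn_affine", "inert"),
                                 drug_strength = 3.5) {
  class <- match.arg(class)
  base <- c("PEPTIDE-PEPTIDE" = 2.0, "PEPTIDE-ZN" = 2.5,
            "ZN-NO3" = 3.0, "PEPTIDE-NO3" = 1.5)
  extra <- switch(class,
    no3_affine = c("DRUG-NO3" = drug_strength, "DRUG-PEPTIDE" = 2.0),
    zn_affine = c("DRUG-ZN" = drug_strength, "DRUG-PEPTIDE" = 2.0),
    inert = numeric())
  affinity_model(c(base, extra))
}

# expand a composition into an ordered vector of component kinds
composition_kinds <- function(composition) {
  counts <- composition_counts(composition)
  rep(names(counts), counts)
}

#' Generate a configuration with planted clusters and exact ground truth
#'
#' Builds each requested cluster by sequential contact attachment: every new
#' member is placed with its minimum inter-atom distance to an already-placed
#' member drawn from `[sigma, cutoff)`, so the cluster is connected at the
#' contact cutoff by construction. Whole clusters and all scattered
#' components are then placed in the periodic box with any-atom separation
#' greater than `cutoff + 1` Angstrom, so detection must recover exactly the
#' planted partition.
#'
#' @param composition a `system_composition`.
#' @param templates named list of `molecule_template` per kind.
#' @param cluster_compositions list of named per-kind count vectors, one per
#'   planted cluster (e.g. `list(c(PEPTIDE = 3, ZN = 1))`); each cluster
#'   needs >= 2 members. Components not used by any cluster are scattered.
#' @param seed integer seed.
#' @param cutoff contact cutoff, Angstrom.
#' @param sigma hard-core minimum separation, Angstrom.
#' @param max_attempts placement attempts per entity before giving up.
#' @return list with `frame` (an [md_frame()]) and `truth` (list with
#'   `memberships`, a list of component-index vectors, and `scattered`).
#' @export
generate_planted_configuration <- function(composition, templates,
                                           cluster_compositions = list(),
                                           seed = 1L, cutoff = 3.5,
                                           sigma = 2.0,
                                           max_attempts = 2000L) {
  set.seed(as.integer(seed))
  L <- composition$box_length
  avail <- composition_counts(composition)
  used <- setNames(integer(5), names(avail))
  for (cc in cluster_compositions) {
    if (sum(cc) < 2) stop("each planted cluster needs at least 2 members")
    used[names(cc)] <- used[names(cc)] + cc
  }
  if (any(used > avail))
    stop("cluster compositions exceed the system composition")

  # per-cluster unwrapped builds around the origin
  build_cluster <- function(kinds) {
    kinds <- sample(kinds)
    placed <- list(list(kind = kinds[1],
                        coords = random_orientation(
                          templates[[kinds[1]]]$local_coords)))
    for (k in kinds[-1]) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        anchor <- placed[[sample.int(length(placed), 1L)]]
        target <- runif(1, sigma + 0.05, cutoff - 0.05)
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        loc <- random_orientation(templates[[k]]$local_coords)
        anchor_atom <- anchor$coords[sample.int(nrow(anchor$coords), 1L), ]
        f <- function(t) {
          cand <- sweep(loc, 2, anchor_atom + t * dir, `+`)
          min(as.matrix(stats::dist(rbind(anchor$coords, cand)))[
            seq_len(nrow(anchor$coords)),
            nrow(anchor$coords) + seq_len(nrow(cand))]) - target
        }
        hi <- 30
        if (f(hi) < 0) next
        t_star <- stats::uniroot(f, c(0, hi), tol = 1e-6)$root
        cand <- sweep(loc, 2, anchor_atom + t_star * dir, `+`)
        others <- do.call(rbind, lapply(placed, `[[`, "coords"))
        dmin <- min(as.matrix(stats::dist(rbind(others, cand)))[
          seq_len(nrow(others)), nrow(others) + seq_len(nrow(cand))])
        if (dmin >= sigma) {
          placed[[length(placed) + 1L]] <- list(kind = k, coords = cand)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("failed to attach a component to a planted cluster")
    }
    placed
  }

  clusters <- lapply(cluster_compositions, function(cc)
    build_cluster(rep(names(cc), cc)))
  scattered_kinds <- rep(names(avail), avail - used)

  # place entities (whole clusters, then scattered singles) in the box
  placements <- list()       # per component: kind + absolute coords
  memberships <- list()
  placed_atoms <- matrix(numeric(0), 0, 3)
  place_entity <- function(ent_coords) {
    for (att in seq_len(max_attempts)) {
      shift <- runif(3, 0, L)
      cand <- sweep(ent_coords, 2, shift, `+`)
      if (nrow(placed_atoms) == 0L ||
          min_mi_dist(cand, placed_atoms, L) > cutoff + 1.0)
        return(cand)
    }
    stop("could not place configuration: box too crowded for the requested ",
         "separation (increase box_length or reduce clusters)")
  }

  comp_counter <- 0L
  for (cl in clusters) {
    ent <- do.call(rbind, lapply(cl, `[[`, "coords"))
    ent <- sweep(ent, 2, colMeans(ent))
    abs_coords <- place_entity(ent)
    placed_atoms <- rbind(placed_atoms, abs_coords)
    offset <- 0L
    ids <- integer(0)
    for (p in cl) {
      n <- nrow(p$coords)
      comp_counter <- comp_counter + 1L
      ids <- c(ids, comp_counter)
      placements[[comp_counter]] <- list(
        kind = p$kind, coords = abs_coords[offset + seq_len(n), , drop = FALSE])
      offset <- offset + n
    }
    memberships[[length(memberships) + 1L]] <- ids
  }
  scattered <- integer(0)
  for (k in scattered_kinds) {
    loc <- random_orientation(templates[[k]]$local_coords)
    abs_coords <- place_entity(loc)
    placed_atoms <- rbind(placed_atoms, abs_coords)
    comp_counter <- comp_counter + 1L
    scattered <- c(scattered, comp_counter)
    placements[[comp_counter]] <- list(kind = k, coords = abs_coords)
  }

  frame <- frame_from_placements(placements, templates, L)
  list(frame = frame,
       truth = list(memberships = memberships, scattered = scattered))
}

#' Generate a Monte Carlo co-assembly trajectory
#'
#' Runs single-component rigid-body Metropolis Monte Carlo (random
#' translation up to `trans_step`; random rotation up to `rot_step` for
#' multi-atom components) at constant volume under the square-well
#' [affinity_model()], with minimum-image periodic boundaries, and samples a
#' frame every `sample_every` sweeps. Identical composition, affinity and
#' seed give an identical trajectory.
#'
#' @param composition a `system_composition`.
#' @param templates named list of `molecule_template` per kind.
#' @param affinity an `affinity_model`.
#' @param n_sweeps number of MC sweeps (one attempted move per component
#'   each).
#' @param sample_every sampling stride in sweeps.
#' @param kT temperature in reduced units.
#' @param seed integer seed.
#' @param trans_step maximum translation per move, Angstrom.
#' @param rot_step maximum rotation angle per move, radians.
#' @param check_every recompute the total energy every this many moves to
#'   bound incremental-energy drift (0 disables).
#' @return list of [md_frame()] objects with attributes `acceptance_rate`,
#'   `max_energy_drift`, `final_energy` and `seed`.
#' @export
generate_mc_trajectory <- function(composition, templates, affinity,
                                   n_sweeps = 200L, sample_every = 20L,
                                   kT = 1.0, seed = 1L, trans_step = 2.0,
                                   rot_step = pi / 2, check_every = 0L) {
  stopifnot(n_sweeps >= 1, sample_every >= 1, kT > 0)
  set.seed(as.integer(seed))
  L <- composition$box_length
  kinds <- composition_kinds(composition)
  if (!length(kinds)) stop("empty composition")
  sigma <- affinity$sigma

  # sequential random insertion honoring the hard core
  placements <- list()
  placed_atoms <- matrix(numeric(0), 0, 3)
  for (k in kinds) {
    ok <- FALSE
    for (att in 1:1000) {
      cand <- sweep(random_orientation(templates[[k]]$local_coords), 2,
                    runif(3, 0, L), `+`)
      if (nrow(placed_atoms) == 0L ||
          min_mi_dist(cand, placed_atoms, L) >= sigma) {
        placements[[length(placements) + 1L]] <- list(kind = k, coords = cand)
        placed_atoms <- rbind(placed_atoms, cand)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("initial placement failed: hard-core constraints ",
                  "unsatisfiable (box too small)")
  }

  n_at <- vapply(placements, function(p) nrow(p$coords), 0L)
  start0 <- cumsum(c(0L, head(n_at, -1L)))
  res <- cpp_mc_run(do.call(rbind, lapply(placements, `[[`, "coords")),
                    start0, n_at, kind_code(kinds), L, affinity$eps,
                    sigma, affinity$r_well, affinity$repulsion_penalty,
                    kT, trans_step, rot_step,
                    as.integer(n_sweeps), as.integer(sample_every),
                    as.integer(check_every))

  proto <- frame_from_placements(placements, templates, L)
  frames <- lapply(res$frames, function(snap)
    md_frame(snap, L, proto$atom_component, proto$component_kind,
             proto$atom_group, proto$atom_radius, proto$atom_label,
             proto$component_resname, proto$component_chain))
  attr(frames, "acceptance_rate") <- res$n_accept / res$n_moves
  attr(frames, "max_energy_drift") <- res$max_energy_drift
  attr(frames, "final_energy") <- res$energy
  attr(frames, "seed") <- as.integer(seed)
  frames
}

#' Square-well configuration energy of a frame
#'
#' Recomputes the total pair energy of a frame under an [affinity_model()]
#' from scratch (no incremental bookkeeping); used to audit the Monte Carlo
#' engine.
#'
#' @param frame an `md_frame`.
#' @param affinity an `affinity_model`.
#' @return list with `energy` (kT) and `hardcore` (TRUE if any inter-atom
#'   distance violates sigma).
#' @export
configuration_energy <- function(frame, affinity) {
  ord <- order(frame$atom_component)
  coords <- frame$coords[ord, , drop = FALSE]
  comp <- frame$atom_component[ord]
  n_at <- as.integer(table(comp))
  start0 <- cumsum(c(0L, head(n_at, -1L)))
  cpp_total_energy(coords, start0, n_at, kind_code(frame$component_kind),
                   frame$box_length, affinity$eps, affinity$sigma,
                   affinity$r_well, affinity$repulsion_penalty)
}
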