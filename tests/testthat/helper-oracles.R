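# Shared fixtures and independent oracles for the test suite.
# Oracles deliberately use plain all-pairs / exhaustive enumeration so they
# share no code path with the package implementations they check.

# minimum-image distance between two coordinate sets, all atom pairs
mi_pair_dists <- function(A, B, L) {
  dx <- outer(A[, 1], B[, 1], `-`); dx <- dx - L * round(dx / L)
  dy <- outer(A[, 2], B[, 2], `-`); dy <- dy - L * round(dy / L)
  dz <- outer(A[, 3], B[, 3], `-`); dz <- dz - L * round(dz / L)
  sqrt(dx^2 + dy^2 + dz^2)
}

# all-pairs brute-force contact edges of a frame (oracle for contact_pairs)
brute_force_edges <- function(frame, cutoff) {
  nc <- length(frame$component_kind)
  atoms <- lapply(seq_len(nc), function(i)
    frame$coords[frame$atom_component == i, , drop = FALSE])
  out <- list()
  for (i in seq_len(nc - 1L)) {
    for (j in (i + 1L):nc) {
      d <- min(mi_pair_dists(atoms[[i]], atoms[[j]], frame$box_length))
      if (d < cutoff) out[[length(out) + 1L]] <- c(i, j, d)
    }
  }
  if (!length(out))
    return(data.frame(i = integer(), j = integer(), min_dist = numeric()))
  m <- do.call(rbind, out)
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]), min_dist = m[, 3])
}

# brute-force connected components with >= 2 members via repeated expansion
brute_force_partition <- function(n, edges) {
  groups <- as.list(seq_len(n))
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      gi <- which(vapply(groups, function(g) edges$i[k] %in% g, TRUE))
      gj <- which(vapply(groups, function(g) edges$j[k] %in% g, TRUE))
      if (gi != gj) {
        groups[[gi]] <- sort(c(groups[[gi]], groups[[gj]]))
        groups[[gj]] <- NULL
      }
    }
  }
  Filter(function(g) length(g) >= 2L, groups)
}

# frame of randomly placed components (mixed kinds), no separation control
random_mixed_frame <- function(n_comp, L, seed,
                               kind_pool = c("PEPTIDE", "DRUG", "ZN", "NO3")) {
  set.seed(seed)
  tpl <- default_templates(1L)
  kinds <- sample(kind_pool, n_comp, replace = TRUE)
  placements <- lapply(kinds, function(k) {
    loc <- tpl[[k]]$local_coords
    if (nrow(loc) > 1L) {
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      th <- runif(1, 0, 2 * pi)
      c_ <- cos(th); s <- sin(th); t <- 1 - c_
      R <- matrix(c(t * ax[1]^2 + c_, t * ax[1] * ax[2] - s * ax[3],
                    t * ax[1] * ax[3] + s * ax[2],
                    t * ax[1] * ax[2] + s * ax[3], t * ax[2]^2 + c_,
                    t * ax[2] * ax[3] - s * ax[1],
                    t * ax[1] * ax[3] - s * ax[2],
                    t * ax[2] * ax[3] + s * ax[1], t * ax[3]^2 + c_),
                  3, 3, byrow = TRUE)
      loc <- loc %*% t(R)
    }
    sweep(loc, 2, runif(3, 0, L), `+`)
  })
  specs <- lapply(tpl[kinds], `[[`, "spec")
  md_frame(do.call(rbind, placements), L,
           atom_component = rep(seq_len(n_comp),
                                vapply(specs, `[[`, 0L, "n_atoms")),
           component_kind = kinds,
           atom_group = unlist(lapply(specs, `[[`, "group_labels")),
           atom_radius = unlist(lapply(specs, `[[`, "atom_radii")),
           atom_label = unlist(lapply(specs, `[[`, "atom_labels")))
}

# frame of single-atom components at given coordinates
point_frame <- function(coords, L, kinds = NULL) {
  n <- nrow(coords)
  if (is.null(kinds)) kinds <- rep("ZN", n)
  md_frame(coords, L, seq_len(n), kinds,
           atom_group = rep("pt", n), atom_radius = rep(1.5, n))
}

# build a bare cluster object from an explicit graph (for motif tests)
graph_cluster <- function(kinds, edges, frame_index = 1L) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2L)
    edges <- data.frame(i = integer(), j = integer())
  names(edges)[1:2] <- c("i", "j")
  if (!"min_dist" %in% names(edges))
    edges$min_dist <- rep(1.0, nrow(edges))
  structure(list(members = seq_along(kinds), size = length(kinds),
                 kinds = kinds, frame_index = frame_index,
                 edges = edges),
            class = "cluster")
}

# exhaustive triplet enumeration over unordered component triples (oracle)
brute_force_triplets <- function(kinds, edges) {
  letter <- c(PEPTIDE = "P", DRUG = "D", ZN = "Z", NO3 = "N", CL = "C")[kinds]
  n <- length(kinds)
  adj <- matrix(FALSE, n, n)
  if (nrow(edges))
    for (k in seq_len(nrow(edges))) {
      adj[edges$i[k], edges$j[k]] <- TRUE
      adj[edges$j[k], edges$i[k]] <- TRUE
    }
  counts <- setNames(integer(length(TRIPLET_PATTERNS)), TRIPLET_PATTERNS)
  if (n < 3) return(counts)
  for (m in seq_len(n)) {
    if (letter[m] == "C") next
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        if (a == m || b == m) next
        if (!letter[a] %in% c("P", "D") || !letter[b] %in% c("P", "D")) next
        if (adj[m, a] && adj[m, b]) {
          fl <- sort(factor(c(letter[a], letter[b]), levels = c("P", "D")))
          lab <- paste0(fl[1], letter[m], fl[2])
          counts[[lab]] <- counts[[lab]] + 1L
        }
      }
    }
  }
  counts
}

# separable / permuted Gaussian feature sets for the classifier tests
gaussian_feature_set <- function(n_per_class, n_classes = 3L, margin = 5,
                                 seed = 1L) {
  set.seed(seed)
  rows <- lapply(seq_len(n_classes), function(cl) {
    centers <- rep(0, length(FEATURE_NAMES))
    centers[cl] <- margin          # class-specific offset in one coordinate
    centers[cl + 3L] <- -margin / 2
    m <- matrix(rnorm(n_per_class * length(FEATURE_NAMES)), n_per_class) +
      matrix(centers, n_per_class, length(FEATURE_NAMES), byrow = TRUE)
    df <- as.data.frame(m)
    names(df) <- FEATURE_NAMES
    df$label <- paste0("CLASS", cl)
    df
  })
  do.call(rbind, rows)
}

default_composition <- function(drug_charge = 1L, box_length = 83) {
  build_composition(48, 12, drug_charge, 48, box_length)
}
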