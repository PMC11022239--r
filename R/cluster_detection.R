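# Contact-graph construction under periodic boundaries and extraction of
# multicomponent clusters (connected components with >= 2 members).

#' Build the contact graph of a frame
#'
#' Two components interact when any pair of their atoms lies strictly closer
#' than `cutoff` under the minimum-image convention. The search uses a cell
#' list when the box admits one, but the edge set is identical to an
#' all-pairs scan.
#'
#' @param frame an [md_frame()].
#' @param cutoff contact cutoff, Angstrom; must be below half the box edge
#'   for the minimum image to be unambiguous.
#' @return an object of class `contact_graph`: `n_components`, `kinds`,
#'   `edges` (data.frame `i`, `j`, `min_dist` with `i < j`), `cutoff`.
#' @export
contact_pairs <- function(frame, cutoff = 3.5) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (cutoff >= frame$box_length / 2)
    stop("cutoff must be below half the box length (minimum image validity)")
  e <- cpp_contact_pairs(frame$coords, frame$atom_component,
                         frame$box_length, cutoff)
  structure(list(n_components = n_components(frame),
                 kinds = frame$component_kind,
                 edges = as.data.frame(e),
                 cutoff = cutoff),
            class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  cat(sprintf("contact_graph: %d components, %d edges (cutoff %.2f Angstrom)\n",
              x$n_components, nrow(x$edges), x$cutoff))
  invisible(x)
}

#' Extract clusters from a contact graph
#'
#' Clusters are the connected components of the contact graph with at least
#' two members; isolated components are not clusters.
#'
#' @param graph a `contact_graph`.
#' @param frame_index index of the source frame, carried into each cluster.
#' @return list of `cluster` objects: `members` (component indices), `size`,
#'   `kinds` (per member), `frame_index`, `edges` (the induced edge subset).
#' @export
find_clusters <- function(graph, frame_index = 1L) {
  n <- graph$n_components
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_len(nrow(graph$edges))) {
    ri <- find(graph$edges$i[k]); rj <- find(graph$edges$j[k])
    if (ri != rj) parent[ri] <- rj
  }
  root <- vapply(seq_len(n), find, 0L)
  groups <- split(seq_len(n), root)
  groups <- groups[lengths(groups) >= 2L]
  eroot <- root[graph$edges$i]
  clusters <- lapply(groups, function(members) {
    structure(list(members = members,
                   size = length(members),
                   kinds = graph$kinds[members],
                   frame_index = as.integer(frame_index),
                   edges = graph$edges[eroot == root[members[1L]], ,
                                       drop = FALSE]),
              class = "cluster")
  })
  names(clusters) <- NULL
  clusters[order(-vapply(clusters, `[[`, 0L, "size"))]
}

#' @export
print.cluster <- function(x, ...) {
  tab <- table(factor(x$kinds, levels = COMPONENT_KINDS))
  cat(sprintf("cluster (frame %d): size %d [%s], %d contact edges\n",
              x$frame_index, x$size,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

#' Detect clusters in one frame
#'
#' Convenience wrapper: [contact_pairs()] followed by [find_clusters()].
#'
#' @inheritParams contact_pairs
#' @inheritParams find_clusters
#' @export
detect_clusters <- function(frame, cutoff = 3.5, frame_index = 1L) {
  find_clusters(contact_pairs(frame, cutoff), frame_index)
}

#' Size-filter a cluster list
#'
#' Keeps clusters of at least `min_size` members. The default 31 implements
#' the "more than 30 peptides, ions, and drugs" focus on high-complexity
#' assemblies. Output is ordered by (frame index, descending size).
#'
#' @param clusters list of `cluster`.
#' @param min_size smallest retained size (>= 2).
#' @export
filter_clusters <- function(clusters, min_size = 31L) {
  if (min_size < 2) stop("min_size must be at least 2")
  keep <- clusters[vapply(clusters, `[[`, 0L, "size") >= min_size]
  keep[order(vapply(keep, `[[`, 0L, "frame_index"),
             -vapply(keep, `[[`, 0L, "size"))]
}

# minimum-image min distance and argmin atom pair between two components
mi_closest_atoms <- function(frame, ci, cj) {
  A <- frame$coords[component_atoms(frame, ci), , drop = FALSE]
  B <- frame$coords[component_atoms(frame, cj), , drop = FALSE]
  L <- frame$box_length
  dx <- outer(A[, 1], B[, 1], `-`); dx <- dx - L * round(dx / L)
  dy <- outer(A[, 2], B[, 2], `-`); dy <- dy - L * round(dy / L)
  dz <- outer(A[, 3], B[, 3], `-`); dz <- dz - L * round(dz / L)
  d2 <- dx * dx + dy * dy + dz * dz
  w <- arrayInd(which.min(d2), dim(d2))
  list(dist = sqrt(d2[w]), a = w[1], b = w[2])
}

#' Unwrap a cluster across periodic boundaries
#'
#' Rebuilds contiguous coordinates for one cluster by breadth-first traversal
#' of its contact edges: each newly visited component is translated by the
#' lattice vector that realizes the minimum-image distance to its
#' already-placed neighbor. After unwrapping, every contact edge's plain
#' Euclidean distance equals its minimum-image distance.
#'
#' @param frame the source [md_frame()].
#' @param cluster a `cluster` from [find_clusters()].
#' @param tol consistency tolerance, Angstrom.
#' @return list with `coords` (cluster atoms, unwrapped), `atom_rows` (their
#'   row indices in `frame$coords`), `atom_component` (global component index
#'   per atom), `members`.
#' @export
unwrap_cluster <- function(frame, cluster, tol = 1e-6) {
  members <- cluster$members
  L <- frame$box_length
  # make each component internally contiguous first: wrapped storage can
  # split a boundary-straddling molecule between the two box faces
  internal <- lapply(members, function(ci) {
    A <- frame$coords[component_atoms(frame, ci), , drop = FALSE]
    delta <- sweep(A, 2, A[1L, ])
    sweep(delta - L * round(delta / L), 2, A[1L, ], `+`)
  })
  names(internal) <- as.character(members)
  adj <- split(c(cluster$edges$j, cluster$edges$i),
               c(cluster$edges$i, cluster$edges$j))
  shift <- matrix(NA_real_, length(members), 3)
  rownames(shift) <- as.character(members)
  shift[1L, ] <- 0
  queue <- members[1L]
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    scur <- shift[as.character(cur), ]
    for (nb in adj[[as.character(cur)]]) {
      if (!is.na(shift[as.character(nb), 1L])) next
      cl <- mi_closest_atoms(frame, cur, nb)
      a_xyz <- internal[[as.character(cur)]][cl$a, ] + scur
      b_xyz <- internal[[as.character(nb)]][cl$b, ]
      shift[as.character(nb), ] <- -L * round((b_xyz - a_xyz) / L)
      queue <- c(queue, nb)
    }
  }
  if (anyNA(shift)) stop("cluster edge list does not connect all members")

  atom_rows <- unlist(lapply(members, component_atoms, frame = frame))
  coords <- unname(do.call(rbind, internal) +
                     shift[as.character(frame$atom_component[atom_rows]), ])

  # consistency: every edge's unwrapped distance must match minimum image
  for (k in seq_len(nrow(cluster$edges))) {
    i <- cluster$edges$i[k]; j <- cluster$edges$j[k]
    A <- coords[frame$atom_component[atom_rows] == i, , drop = FALSE]
    B <- coords[frame$atom_component[atom_rows] == j, , drop = FALSE]
    d <- sqrt(min(outer(A[, 1], B[, 1], `-`)^2 +
                  outer(A[, 2], B[, 2], `-`)^2 +
                  outer(A[, 3], B[, 3], `-`)^2))
    if (abs(d - cluster$edges$min_dist[k]) > tol)
      stop("no consistent unwrapping exists (cluster percolates the box)")
  }
  if (any(apply(coords, 2, function(v) diff(range(v))) >= L))
    stop("unwrapped cluster spans the full box (percolating cluster)")
  list(coords = coords, atom_rows = atom_rows,
       atom_component = frame$atom_component[atom_rows], members = members)
}

#' Tabulate clusters for export
#'
#' @param clusters list of `cluster`.
#' @return data.frame with frame, cluster id, size, per-kind counts and the
#'   member index list.
#' @export
clusters_table <- function(clusters) {
  if (!length(clusters))
    return(data.frame(frame = integer(), cluster_id = integer(),
                      size = integer(), n_peptide = integer(),
                      n_drug = integer(), n_zn = integer(),
                      n_no3 = integer(), n_cl = integer(),
                      members = character(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(seq_along(clusters), function(k) {
    cl <- clusters[[k]]
    tab <- table(factor(cl$kinds, levels = COMPONENT_KINDS))
    data.frame(frame = cl$frame_index, cluster_id = k, size = cl$size,
               n_peptide = as.integer(tab[["PEPTIDE"]]),
               n_drug = as.integer(tab[["DRUG"]]),
               n_zn = as.integer(tab[["ZN"]]),
               n_no3 = as.integer(tab[["NO3"]]),
               n_cl = as.integer(tab[["CL"]]),
               members = paste(cl$members, collapse = ","),
               stringsAsFactors = FALSE)
  }))
}
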