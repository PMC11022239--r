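# Pairwise interaction profiles, mediated triplet motifs (PDP, DND, DZD, ...)
# and chemical-group contact decomposition.

KIND_LETTER <- c(PEPTIDE = "P", DRUG = "D", ZN = "Z", NO3 = "N", CL = "C")

#' Canonical mediated-triplet patterns
#'
#' Labels are written flank-middle-flank with the flanks (always peptide or
#' drug) sorted P before D: six molecule-mediated patterns (PPP, PDP, PPD,
#' PDD, DPD, DDD) and six ion-mediated ones (PZP, PZD, DZD, PNP, PND, DND).
#' `PND` also covers DNP.
#'
#' @export
TRIPLET_PATTERNS <- c("PPP", "PDP", "PPD", "PDD", "DPD", "DDD",
                      "PZP", "PZD", "DZD", "PNP", "PND", "DND")

triplet_label <- function(middle, f1, f2) {
  fl <- sort(factor(c(f1, f2), levels = c("P", "D")))
  paste0(as.character(fl[1]), middle, as.character(fl[2]))
}

cluster_adjacency <- function(cluster) {
  adj <- split(c(cluster$edges$j, cluster$edges$i),
               c(cluster$edges$i, cluster$edges$j))
  adj
}

#' Pairwise interaction profile of a cluster ensemble
#'
#' Tallies contact edges by unordered kind pair across all clusters, drops
#' the repulsive like-ion pairs (Zn2+/Zn2+ and NO3-/NO3-), and normalizes to
#' a probability distribution. Conditional profiles for peptide and drug
#' endpoints (distribution over partner kinds) are reported alongside.
#'
#' @param clusters nonempty list of `cluster`.
#' @return list with `pair_probability` (named vector, sums to 1 when any
#'   admissible edge exists), `counts`, and `conditional` (list with
#'   `PEPTIDE` and `DRUG` partner distributions).
#' @export
pairwise_profile <- function(clusters) {
  if (!length(clusters)) stop("pairwise profile of an empty cluster list")
  pairs <- do.call(rbind, lapply(clusters, function(cl) {
    if (!nrow(cl$edges)) return(NULL)
    ik <- cl$kinds[match(cl$edges$i, cl$members)]
    jk <- cl$kinds[match(cl$edges$j, cl$members)]
    data.frame(a = pmin(ik, jk), b = pmax(ik, jk), stringsAsFactors = FALSE)
  }))
  excluded <- (pairs$a == "NO3" & pairs$b == "NO3") |
              (pairs$a == "ZN" & pairs$b == "ZN")
  pairs <- pairs[!excluded, , drop = FALSE]
  lab <- paste(pairs$a, pairs$b, sep = "-")
  counts <- table(lab)
  prob <- as.numeric(counts) / sum(counts)
  names(prob) <- names(counts)
  conditional <- lapply(c(PEPTIDE = "PEPTIDE", DRUG = "DRUG"), function(k) {
    sel <- pairs$a == k | pairs$b == k
    if (!any(sel)) return(numeric())
    partner <- ifelse(pairs$a[sel] == k, pairs$b[sel], pairs$a[sel])
    # a k-k edge has two k endpoints but one partner draw either way
    tab <- table(partner)
    setNames(as.numeric(tab) / sum(tab), names(tab))
  })
  list(pair_probability = prob, counts = counts, conditional = conditional)
}

#' Mediated-triplet motif probabilities of one cluster
#'
#' A triplet is a component `m` (the mediator, any kind except chloride) in
#' simultaneous contact with two distinct peptide/drug flanks; each unordered
#' flank pair counts one occurrence of the canonical pattern
#' (see [TRIPLET_PATTERNS]). With `normalization = "cluster"` probabilities
#' sum to 1 over all triplets observed in the cluster; with
#' `normalization = "middle"` they sum to 1 within each mediator kind.
#'
#' @param cluster a `cluster`.
#' @param normalization `"cluster"` or `"middle"`.
#' @return list with integer `counts` and numeric `probability`, both named
#'   by [TRIPLET_PATTERNS] (all zero when no triplet exists).
#' @export
mediated_triplets <- function(cluster, normalization = c("cluster", "middle")) {
  normalization <- match.arg(normalization)
  counts <- setNames(integer(length(TRIPLET_PATTERNS)), TRIPLET_PATTERNS)
  if (cluster$size >= 3L && nrow(cluster$edges)) {
    adj <- cluster_adjacency(cluster)
    letter <- setNames(KIND_LETTER[cluster$kinds], as.character(cluster$members))
    for (m in cluster$members) {
      mk <- letter[[as.character(m)]]
      if (mk == "C") next
      nb <- adj[[as.character(m)]]
      if (is.null(nb)) next
      fl <- nb[letter[as.character(nb)] %in% c("P", "D")]
      if (length(fl) < 2L) next
      cmb <- utils::combn(length(fl), 2L)
      for (q in seq_len(ncol(cmb))) {
        lab <- triplet_label(mk, letter[[as.character(fl[cmb[1, q]])]],
                             letter[[as.character(fl[cmb[2, q]])]])
        counts[[lab]] <- counts[[lab]] + 1L
      }
    }
  }
  prob <- setNames(numeric(length(TRIPLET_PATTERNS)), TRIPLET_PATTERNS)
  if (normalization == "cluster") {
    tot <- sum(counts)
    if (tot > 0) prob <- counts / tot
  } else {
    middle <- substr(TRIPLET_PATTERNS, 2, 2)
    for (mk in unique(middle)) {
      sel <- middle == mk
      tot <- sum(counts[sel])
      if (tot > 0) prob[sel] <- counts[sel] / tot
    }
  }
  list(counts = counts, probability = prob)
}

#' Ensemble triplet profile
#'
#' Equal-weight average of per-cluster triplet probabilities over all
#' clusters that contain at least one triplet.
#'
#' @param clusters list of `cluster`.
#' @param normalization passed to [mediated_triplets()].
#' @return named probability vector over [TRIPLET_PATTERNS] (zero vector if
#'   no cluster has triplets).
#' @export
ensemble_triplet_profile <- function(clusters,
                                     normalization = c("cluster", "middle")) {
  normalization <- match.arg(normalization)
  per <- lapply(clusters, mediated_triplets, normalization = normalization)
  probs <- do.call(rbind, lapply(per, `[[`, "probability"))
  has <- vapply(per, function(p) sum(p$counts) > 0, TRUE)
  if (!any(has))
    return(setNames(numeric(length(TRIPLET_PATTERNS)), TRIPLET_PATTERNS))
  colMeans(probs[has, , drop = FALSE])
}

#' Mediation probability per component kind
#'
#' For each kind, the fraction of its components acting as a mediator (>= 2
#' peptide/drug contact neighbors) within their cluster, averaged with equal
#' weight over the clusters that contain that kind.
#'
#' @param clusters nonempty list of `cluster`.
#' @return named numeric vector over PEPTIDE, DRUG, ZN, NO3 (`NA` when the
#'   kind occurs in no cluster).
#' @export
mediation_by_ions <- function(clusters) {
  if (!length(clusters)) stop("mediation summary of an empty cluster list")
  kinds <- c("PEPTIDE", "DRUG", "ZN", "NO3")
  per_cluster <- lapply(clusters, function(cl) {
    adj <- cluster_adjacency(cl)
    letter <- setNames(KIND_LETTER[cl$kinds], as.character(cl$members))
    is_med <- vapply(cl$members, function(m) {
      nb <- adj[[as.character(m)]]
      sum(letter[as.character(nb)] %in% c("P", "D")) >= 2L
    }, TRUE)
    vapply(kinds, function(k) {
      sel <- cl$kinds == k
      if (!any(sel)) NA_real_ else mean(is_med[sel])
    }, 0)
  })
  mat <- do.call(rbind, per_cluster)
  out <- colMeans(mat, na.rm = TRUE)
  out[colSums(!is.na(mat)) == 0L] <- NA_real_
  out
}

#' Chemical-group contact profile
#'
#' Decomposes peptide/drug contacts to the chemical-group level: for every
#' group instance of a peptide or drug in a cluster, a contact with a partner
#' (an ion kind, or a group of another peptide/drug) exists when any atom of
#' the group lies within `cutoff` of any atom of the partner
#' (minimum image). Counts are normalized per source group label so each
#' row's partner probabilities sum to 1.
#'
#' @param frame source [md_frame()]; every atom must carry a group label.
#' @param clusters list of `cluster` detected in that frame.
#' @param cutoff contact cutoff, Angstrom.
#' @return list with `counts` and `probability`: data.frames with columns
#'   `source_group`, `partner`, `count` / `prob`.
#' @export
group_contact_profile <- function(frame, clusters, cutoff = 3.5) {
  miss <- which(is.na(frame$atom_group) | frame$atom_group == "")
  if (length(miss))
    stop("atoms without a group label: ",
         paste(head(miss, 5), collapse = ", "))
  acc <- list()
  bump <- function(g, p) {
    key <- paste0(g, "\r", p)
    acc[[key]] <<- (acc[[key]] %||% 0L) + 1L
  }
  moleculish <- c("PEPTIDE", "DRUG")
  for (cl in clusters) {
    for (k in seq_len(nrow(cl$edges))) {
      i <- cl$edges$i[k]; j <- cl$edges$j[k]
      ki <- cl$kinds[match(i, cl$members)]
      kj <- cl$kinds[match(j, cl$members)]
      if (!(ki %in% moleculish) && !(kj %in% moleculish)) next
      ai <- component_atoms(frame, i); aj <- component_atoms(frame, j)
      A <- frame$coords[ai, , drop = FALSE]
      B <- frame$coords[aj, , drop = FALSE]
      L <- frame$box_length
      dx <- outer(A[, 1], B[, 1], `-`); dx <- dx - L * round(dx / L)
      dy <- outer(A[, 2], B[, 2], `-`); dy <- dy - L * round(dy / L)
      dz <- outer(A[, 3], B[, 3], `-`); dz <- dz - L * round(dz / L)
      close <- sqrt(dx * dx + dy * dy + dz * dz) < cutoff
      gi <- frame$atom_group[ai]; gj <- frame$atom_group[aj]
      if (ki %in% moleculish) {
        partners_j <- if (kj %in% moleculish) unique(gj) else kj
        for (g in unique(gi)) {
          rows <- gi == g
          for (p in partners_j) {
            cols <- if (kj %in% moleculish) gj == p else rep(TRUE, length(gj))
            if (any(close[rows, cols, drop = FALSE])) bump(g, p)
          }
        }
      }
      if (kj %in% moleculish) {
        partners_i <- if (ki %in% moleculish) unique(gi) else ki
        for (g in unique(gj)) {
          cols <- gj == g
          for (p in partners_i) {
            rows <- if (ki %in% moleculish) gi == p else rep(TRUE, length(gi))
            if (any(close[rows, cols, drop = FALSE])) bump(g, p)
          }
        }
      }
    }
  }
  if (!length(acc))
    return(list(counts = data.frame(source_group = character(),
                                    partner = character(), count = integer(),
                                    stringsAsFactors = FALSE),
                probability = data.frame(source_group = character(),
                                         partner = character(),
                                         prob = numeric(),
                                         stringsAsFactors = FALSE)))
  parts <- do.call(rbind, strsplit(names(acc), "\r", fixed = TRUE))
  counts <- data.frame(source_group = parts[, 1], partner = parts[, 2],
                       count = unlist(acc, use.names = FALSE),
                       stringsAsFactors = FALSE)
  counts <- counts[order(counts$source_group, counts$partner), ]
  rownames(counts) <- NULL
  probability <- do.call(rbind, lapply(split(counts, counts$source_group),
    function(df) {
      df$prob <- df$count / sum(df$count)
      df[c("source_group", "partner", "prob")]
    }))
  rownames(probability) <- NULL
  list(counts = counts, probability = probability)
}
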