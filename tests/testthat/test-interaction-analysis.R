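test_that("pairwise profile excludes repulsive like-ion pairs and normalizes", {
  cl <- graph_cluster(c("PEPTIDE", "DRUG"), cbind(1, 2))
  p <- pairwise_profile(list(cl))
  expect_equal(unname(p$pair_probability["DRUG-PEPTIDE"]), 1)

  cl2 <- graph_cluster(c("PEPTIDE", "PEPTIDE", "ZN", "ZN"),
                       rbind(c(1, 2), c(2, 3), c(3, 4)))
  p2 <- pairwise_profile(list(cl2))
  expect_false("ZN-ZN" %in% names(p2$pair_probability))
  expect_equal(unname(p2$pair_probability[c("PEPTIDE-PEPTIDE", "PEPTIDE-ZN")]),
               c(0.5, 0.5))
  expect_equal(sum(p2$pair_probability), 1)

  cl3 <- graph_cluster(c("NO3", "NO3", "DRUG"), rbind(c(1, 2), c(2, 3)))
  p3 <- pairwise_profile(list(cl3))
  expect_false("NO3-NO3" %in% names(p3$pair_probability))
  expect_equal(unname(p3$pair_probability["DRUG-NO3"]), 1)
})

test_that("pairwise profile equals a brute-force edge tally on random graphs", {
  set.seed(23)
  for (r in 1:20) {
    n <- sample(5:25, 1)
    kinds <- sample(COMPONENT_KINDS[1:4], n, replace = TRUE)
    ed <- t(combn(n, 2))
    ed <- ed[runif(nrow(ed)) < 0.3, , drop = FALSE]
    if (!nrow(ed)) next
    cl <- graph_cluster(kinds, ed)
    p <- pairwise_profile(list(cl))
    lab <- apply(ed, 1, function(e)
      paste(sort(c(kinds[e[1]], kinds[e[2]])), collapse = "-"))
    lab <- lab[!lab %in% c("ZN-ZN", "NO3-NO3")]
    if (!length(lab)) next
    want <- table(lab) / length(lab)
    expect_equal(sum(p$pair_probability), 1, tolerance = 1e-9)
    for (nm in names(want))
      expect_equal(unname(p$pair_probability[nm]), unname(want[nm]))
  }
})

test_that("minimal motifs are labeled canonically", {
  # P-D-P path: one PDP triplet
  cl <- graph_cluster(c("PEPTIDE", "DRUG", "PEPTIDE"), rbind(c(1, 2), c(2, 3)))
  t1 <- mediated_triplets(cl)
  expect_equal(unname(t1$counts["PDP"]), 1L)
  expect_equal(unname(t1$probability["PDP"]), 1)
  # nitrate star with two drugs and one peptide: DND x1, PND x2
  star <- graph_cluster(c("NO3", "DRUG", "DRUG", "PEPTIDE"),
                        rbind(c(1, 2), c(1, 3), c(1, 4)))
  t2 <- mediated_triplets(star)
  expect_equal(unname(t2$counts[c("DND", "PND")]), c(1L, 2L))
  expect_equal(unname(t2$probability[c("DND", "PND")]), c(1 / 3, 2 / 3))
  # triangle of peptides: each member mediates once
  tri <- graph_cluster(rep("PEPTIDE", 3), rbind(c(1, 2), c(2, 3), c(1, 3)))
  t3 <- mediated_triplets(tri)
  expect_equal(unname(t3$counts["PPP"]), 3L)
  # clusters below 3 members yield an empty table
  expect_equal(sum(mediated_triplets(graph_cluster(c("PEPTIDE", "DRUG"),
                                                   cbind(1, 2)))$counts), 0L)
  # chloride never mediates
  clcl <- graph_cluster(c("CL", "PEPTIDE", "PEPTIDE"),
                        rbind(c(1, 2), c(1, 3)))
  expect_equal(sum(mediated_triplets(clcl)$counts), 0L)
})

test_that("triplet counts equal exhaustive enumeration on random graphs", {
  set.seed(57)
  for (r in 1:100) {
    n <- sample(4:15, 1)
    kinds <- sample(COMPONENT_KINDS, n, replace = TRUE)
    ed <- t(combn(n, 2))
    ed <- ed[runif(nrow(ed)) < 0.35, , drop = FALSE]
    cl <- graph_cluster(kinds, ed)
    got <- mediated_triplets(cl)
    want <- brute_force_triplets(kinds, cl$edges)
    expect_identical(unname(got$counts), unname(want))
    if (sum(want) > 0) expect_equal(sum(got$probability), 1, tolerance = 1e-9)
  }
})

test_that("per-middle normalization sums to one within each mediator kind", {
  star <- graph_cluster(c("NO3", "DRUG", "DRUG", "PEPTIDE", "ZN"),
                        rbind(c(1, 2), c(1, 3), c(1, 4), c(5, 2), c(5, 4)))
  t1 <- mediated_triplets(star, normalization = "middle")
  expect_equal(sum(t1$probability[c("PNP", "PND", "DND")]), 1)
  expect_equal(sum(t1$probability[c("PZP", "PZD", "DZD")]), 1)
})

test_that("mediation probability is the share of components bridging two molecules", {
  # zinc bridging two peptides mediates; singly-bonded zinc does not
  cl <- graph_cluster(c("ZN", "PEPTIDE", "PEPTIDE"), rbind(c(1, 2), c(1, 3)))
  m <- mediation_by_ions(list(cl))
  expect_equal(unname(m["ZN"]), 1)
  cl2 <- graph_cluster(c("ZN", "PEPTIDE", "PEPTIDE"),
                       rbind(c(1, 2), c(2, 3)))
  m2 <- mediation_by_ions(list(cl2))
  expect_equal(unname(m2["ZN"]), 0)
  # neither peptide has two peptide/drug neighbors (the zinc does not count)
  expect_equal(unname(m2["PEPTIDE"]), 0)
  expect_true(is.na(m2[["DRUG"]]))
  # recount on random graphs
  set.seed(71)
  for (r in 1:20) {
    n <- sample(4:12, 1)
    kinds <- sample(COMPONENT_KINDS[1:4], n, replace = TRUE)
    ed <- t(combn(n, 2))
    ed <- ed[runif(nrow(ed)) < 0.4, , drop = FALSE]
    cl <- graph_cluster(kinds, ed)
    m <- mediation_by_ions(list(cl))
    adjm <- matrix(FALSE, n, n)
    for (k in seq_len(nrow(ed))) {
      adjm[ed[k, 1], ed[k, 2]] <- TRUE; adjm[ed[k, 2], ed[k, 1]] <- TRUE
    }
    deg <- vapply(seq_len(n), function(i)
      sum(adjm[i, ] & kinds %in% c("PEPTIDE", "DRUG")), 0L)
    for (k in c("PEPTIDE", "DRUG", "ZN", "NO3")) {
      if (!any(kinds == k)) expect_true(is.na(m[[k]]))
      else expect_equal(unname(m[k]), mean(deg[kinds == k] >= 2))
    }
  }
})

test_that("group contacts resolve which chemical group touches the partner", {
  tpl <- default_templates(1L)
  pep <- tpl$PEPTIDE$local_coords
  # place a zinc 2.5 Angstrom from an imidazole_1 atom, far from the ring
  imid_atom <- pep[5, ]
  dir <- imid_atom / sqrt(sum(imid_atom^2))
  zn_pos <- imid_atom + 2.5 * dir
  coords <- rbind(sweep(pep, 2, c(20, 20, 20), `+`), zn_pos + c(20, 20, 20))
  sp <- tpl$PEPTIDE$spec
  f <- md_frame(coords, 50, c(rep(1L, 10), 2L), c("PEPTIDE", "ZN"),
                atom_group = c(sp$group_labels, "zinc"),
                atom_radius = c(sp$atom_radii, 1.2))
  cl <- detect_clusters(f, 3.5)
  expect_length(cl, 1L)
  prof <- group_contact_profile(f, cl, 3.5)
  imid_rows <- prof$probability[prof$probability$source_group == "imidazole_1", ]
  expect_equal(imid_rows$prob[imid_rows$partner == "ZN"], 1)
  expect_false("cyclic_ring" %in% prof$counts$source_group)
  # no contacts -> empty profile
  empty <- group_contact_profile(f, list(), 3.5)
  expect_identical(nrow(empty$counts), 0L)
})

test_that("group contact probabilities average over repeated observations", {
  # two single-atom drugs flanking one peptide-like group across two frames:
  # the drug charged_group touches ZN in one frame and NO3 in the other
  mk <- function(partner_kind) {
    coords <- rbind(c(10, 10, 10), c(12.5, 10, 10))
    md_frame(coords, 40, c(1L, 2L), c("DRUG", partner_kind),
             atom_group = c("charged_group",
                            if (partner_kind == "ZN") "zinc" else "nitrate"),
             atom_radius = c(1.5, 1.3))
  }
  f1 <- mk("ZN"); f2 <- mk("NO3")
  c1 <- group_contact_profile(f1, detect_clusters(f1, 3.5), 3.5)$counts
  c2 <- group_contact_profile(f2, detect_clusters(f2, 3.5), 3.5)$counts
  pooled <- rbind(c1, c2)
  agg <- aggregate(count ~ source_group + partner, pooled, sum)
  probs <- agg$count[agg$source_group == "charged_group"] /
    sum(agg$count[agg$source_group == "charged_group"])
  expect_equal(probs, c(0.5, 0.5))
})

test_that("probability tables from detected ensembles sum to one", {
  comp <- build_composition(12, 4, 1, 12, 60)
  tpl <- default_templates(1L)
  g <- generate_planted_configuration(
    comp, tpl, list(c(PEPTIDE = 4, DRUG = 2, ZN = 2, NO3 = 3),
                    c(PEPTIDE = 3, ZN = 1, NO3 = 2)), seed = 13)
  cl <- detect_clusters(g$frame, 3.5)
  pw <- pairwise_profile(cl)
  expect_equal(sum(pw$pair_probability), 1, tolerance = 1e-9)
  for (cond in pw$conditional)
    if (length(cond)) expect_equal(sum(cond), 1, tolerance = 1e-9)
  tp <- ensemble_triplet_profile(cl)
  if (sum(tp) > 0) expect_equal(sum(tp), 1, tolerance = 1e-9)
  gp <- group_contact_profile(g$frame, cl, 3.5)
  for (sg in unique(gp$probability$source_group))
    expect_equal(sum(gp$probability$prob[gp$probability$source_group == sg]),
                 1, tolerance = 1e-9)
})
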