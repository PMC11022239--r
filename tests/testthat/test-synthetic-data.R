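test_that("affinity model enforces symmetry and repulsive ion diagonals", {
  a <- affinity_model(c("DRUG-NO3" = 3, "PEPTIDE-DRUG" = 1.5))
  expect_identical(a$eps, t(a$eps))
  expect_equal(a$eps["NO3", "DRUG"], 3)
  expect_error(affinity_model(c("ZN-ZN" = 1)), "repulsive")
  expect_error(affinity_model(sigma = 4, r_well = 3.5), "smaller")
  presets <- lapply(c("no3_affine", "zn_affine", "inert"),
                    drug_affinity_preset)
  expect_gt(presets[[1]]$eps["DRUG", "NO3"], presets[[1]]$eps["DRUG", "ZN"])
  expect_gt(presets[[2]]$eps["DRUG", "ZN"], presets[[2]]$eps["DRUG", "NO3"])
  expect_true(all(presets[[3]]$eps["DRUG", ] == 0))
})

test_that("planted configurations are recovered exactly by detection", {
  comp <- build_composition(48, 12, 1, 48, 83)
  tpl <- default_templates(1L)
  ccs <- list(c(PEPTIDE = 6, ZN = 2, NO3 = 3, DRUG = 2),
              c(PEPTIDE = 4, DRUG = 1),
              c(ZN = 1, NO3 = 2))
  for (seed in c(7, 8, 9)) {
    g <- generate_planted_configuration(comp, tpl, ccs, seed = seed)
    cl <- detect_clusters(g$frame, 3.5)
    got <- lapply(cl, function(c1) sort(c1$members))
    want <- lapply(g$truth$memberships, sort)
    expect_identical(got[order(vapply(got, min, 0L))],
                     want[order(vapply(want, min, 0L))])
    # scattered components carry no contacts at all
    iso <- setdiff(seq_len(n_components(g$frame)), unlist(want))
    expect_identical(sort(g$truth$scattered), iso)
    edges <- contact_pairs(g$frame, 3.5)$edges
    expect_false(any(edges$i %in% iso | edges$j %in% iso))
  }
})

test_that("a minimal two-member cluster and an all-scattered system behave", {
  comp <- build_composition(2, 0, 0, 0, 100)
  tpl <- default_templates(0L)
  g <- generate_planted_configuration(comp, tpl, list(c(PEPTIDE = 2)),
                                      seed = 1)
  cl <- detect_clusters(g$frame, 3.5)
  expect_length(cl, 1L)
  expect_identical(cl[[1]]$size, 2L)

  g0 <- generate_planted_configuration(build_composition(5, 2, 0, 5, 83),
                                       default_templates(0L), list(),
                                       seed = 3)
  expect_length(detect_clusters(g0$frame, 3.5), 0L)
  # every component (including the 10 auto-added nitrates) is scattered
  expect_length(g0$truth$scattered,
                5L + 2L + 5L + build_composition(5, 2, 0, 5, 83)$n_no3)
})

test_that("overfull boxes raise placement errors", {
  tpl <- default_templates(0L)
  crowded <- build_composition(0, 0, 0, 64, 8)
  expect_error(generate_planted_configuration(crowded, tpl, list(), seed = 1,
                                              max_attempts = 50L),
               "too crowded")
  expect_error(generate_planted_configuration(comp <- crowded, tpl,
                                              list(c(ZN = 1)), seed = 1),
               "at least 2 members")
})

test_that("MC trajectories are reproducible and energy bookkeeping is exact", {
  comp <- build_composition(8, 3, 1, 8, 35)
  tpl <- default_templates(1L)
  aff <- drug_affinity_preset("no3_affine")
  t1 <- generate_mc_trajectory(comp, tpl, aff, n_sweeps = 60,
                               sample_every = 20, seed = 11,
                               check_every = 50)
  t2 <- generate_mc_trajectory(comp, tpl, aff, n_sweeps = 60,
                               sample_every = 20, seed = 11,
                               check_every = 50)
  expect_identical(lapply(t1, `[[`, "coords"), lapply(t2, `[[`, "coords"))
  t3 <- generate_mc_trajectory(comp, tpl, aff, n_sweeps = 60,
                               sample_every = 20, seed = 12)
  expect_false(identical(t1[[1]]$coords, t3[[1]]$coords))
  expect_lt(attr(t1, "max_energy_drift"), 1e-8)
  # the incremental final energy matches a from-scratch recomputation
  final <- configuration_energy(t1[[length(t1)]], aff)
  expect_false(final$hardcore)
  expect_equal(final$energy, attr(t1, "final_energy"), tolerance = 1e-8)
})

test_that("a non-interacting single particle accepts every move and samples uniformly", {
  comp <- build_composition(1, 0, 0, 0, 80)   # one neutral peptide, no ions
  tpl <- default_templates(0L)
  free <- affinity_model(repulsion_penalty = 0)
  pvals <- vapply(1:3, function(seed) {
    tr <- generate_mc_trajectory(comp, tpl, free, n_sweeps = 1000,
                                 sample_every = 1, seed = seed,
                                 trans_step = 40)
    expect_equal(attr(tr, "acceptance_rate"), 1.0)
    x <- vapply(tr, function(f) f$coords[1, 1], 0)
    stats::chisq.test(table(cut(x, breaks = seq(0, 80, by = 8))))$p.value
  }, 0)
  expect_gt(mean(pvals), 0.01)
})

test_that("a deep two-body well keeps the pair in contact almost always", {
  comp <- build_composition(0, 0, 0, 1, 12)   # one Zn ...
  comp$n_no3 <- 1L                            # ... plus one nitrate probe
  tpl <- default_templates(0L)
  aff <- affinity_model(c("ZN-NO3" = 5))
  tr <- generate_mc_trajectory(comp, tpl, aff, n_sweeps = 3000,
                               sample_every = 5, seed = 21, trans_step = 3)
  contact <- vapply(tr, function(f)
    nrow(contact_pairs(f, 3.5)$edges) == 1L, TRUE)
  expect_gt(mean(contact), 0.9)
})

test_that("MC initial placement fails loudly in an impossible box", {
  comp <- build_composition(0, 0, 0, 200, 6)
  tpl <- default_templates(0L)
  expect_error(generate_mc_trajectory(comp, tpl, affinity_model(),
                                      n_sweeps = 1, seed = 1),
               "hard-core")
})
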