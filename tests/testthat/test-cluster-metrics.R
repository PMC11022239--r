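test_that("composition percentages tally members and sum to 100", {
  cl <- graph_cluster(c("PEPTIDE", "PEPTIDE", "ZN", "NO3"),
                      cbind(1:3, 2:4))
  pct <- composition_percentages(cl)
  expect_equal(unname(pct[c("PEPTIDE", "ZN", "NO3", "DRUG")]),
               c(50, 25, 25, 0))
  expect_equal(sum(pct), 100)
  all_p <- graph_cluster(rep("PEPTIDE", 5), cbind(1:4, 2:5))
  expect_equal(unname(composition_percentages(all_p)["PEPTIDE"]), 100)
  # random recount
  set.seed(9)
  for (r in 1:20) {
    kinds <- sample(COMPONENT_KINDS, sample(3:30, 1), replace = TRUE)
    cl <- graph_cluster(kinds, cbind(seq_along(kinds)[-1] - 1,
                                     seq_along(kinds)[-1]))
    pct <- composition_percentages(cl)
    expect_equal(sum(pct), 100, tolerance = 1e-6)
    for (k in COMPONENT_KINDS)
      expect_equal(unname(pct[k]), 100 * sum(kinds == k) / length(kinds))
  }
})

test_that("encapsulation summary counts drug-bearing clusters", {
  mk <- function(nd) graph_cluster(c(rep("DRUG", nd),
                                     rep("PEPTIDE", 4 - nd)),
                                   cbind(1:3, 2:4))
  s <- encapsulation_summary(lapply(c(0, 1, 2, 3), mk))
  expect_equal(unname(s), c(0.25, 0.75, 0.50))
  expect_equal(s[["p_no_drug"]] + s[["p_ge1_drug"]], 1)
  expect_lte(s[["p_ge2_drug"]], s[["p_ge1_drug"]])
  s0 <- encapsulation_summary(lapply(c(0, 0), mk))
  expect_equal(unname(s0), c(1, 0, 0))
  expect_error(encapsulation_summary(list()), "empty")
})

test_that("drug encapsulation percentage is relative to the system total", {
  mk <- function(nd) graph_cluster(c(rep("DRUG", nd), "PEPTIDE"),
                                   cbind(seq_len(nd), rep(nd + 1, nd)))
  expect_equal(drug_encapsulation_percentage(mk(6), 12), 50)
  expect_equal(drug_encapsulation_percentage(mk(0), 12), 0)
  expect_equal(drug_encapsulation_percentage(mk(12), 12), 100)
  expect_error(drug_encapsulation_percentage(mk(1), 0), "positive")
})

test_that("count ratios divide by the peptide count and flag its absence", {
  cl <- graph_cluster(c(rep("PEPTIDE", 4), "DRUG", rep("ZN", 4)),
                      cbind(1:8, 2:9))
  expect_equal(unname(cluster_ratios(cl)), c(0.25, 1.0))
  cl2 <- graph_cluster(c(rep("PEPTIDE", 10), rep("DRUG", 3), rep("ZN", 8)),
                       cbind(1:20, 2:21))
  expect_equal(unname(cluster_ratios(cl2)), c(0.3, 0.8))
  nop <- graph_cluster(c("DRUG", "ZN"), cbind(1, 2))
  expect_warning(r <- cluster_ratios(nop), "no peptides")
  expect_true(all(is.na(r)))
})

test_that("radius of gyration matches closed forms and the pairwise identity", {
  expect_equal(radius_of_gyration(matrix(c(4, 5, 6), 1)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1.0)
  set.seed(31)
  for (r in 1:5) {
    X <- matrix(rnorm(50 * 3, sd = 4), 50)
    # independent identity: Rg^2 = sum of squared pair distances / (2 N^2)
    d2 <- as.matrix(dist(X))^2
    expect_equal(radius_of_gyration(X), sqrt(sum(d2) / (2 * nrow(X)^2)),
                 tolerance = 1e-9)
    # invariance under rigid motions
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, 0, 2 * pi)
    c_ <- cos(th); s <- sin(th); t <- 1 - c_
    R <- matrix(c(t * ax[1]^2 + c_, t * ax[1] * ax[2] - s * ax[3],
                  t * ax[1] * ax[3] + s * ax[2],
                  t * ax[1] * ax[2] + s * ax[3], t * ax[2]^2 + c_,
                  t * ax[2] * ax[3] - s * ax[1],
                  t * ax[1] * ax[3] - s * ax[2],
                  t * ax[2] * ax[3] + s * ax[1], t * ax[3]^2 + c_),
                3, 3, byrow = TRUE)
    Y <- sweep(X %*% t(R), 2, rnorm(3, sd = 10), `+`)
    expect_equal(radius_of_gyration(Y), radius_of_gyration(X),
                 tolerance = 1e-9)
  }
})

test_that("single-sphere SASA matches 4*pi*(r+probe)^2 within 1%", {
  r <- 1.7; rp <- 2.6
  got <- shrake_rupley_sasa(matrix(0, 1, 3), r, rp, 960)
  expect_equal(got, 4 * pi * (r + rp)^2, tolerance = 0.01)
  # and exactly 100% exposure as a ratio
  f <- point_frame(rbind(c(10, 10, 10), c(14, 10, 10)), 50)
  cl <- detect_clusters(f, 4.5)[[1]]
  # two spheres beyond occlusion range (r+probe small): fully exposed
  ratios <- cluster_sasa_ratios(f, cl, probe_radius = 0.2, n_points = 960)
  expect_equal(unname(ratios), c(100, 100), tolerance = 1e-9)
})

test_that("two overlapping spheres match the spherical-cap closed form within 2%", {
  r <- 1.5; rp <- 1.0; R <- r + rp; d <- 3.0
  got <- shrake_rupley_sasa(rbind(c(0, 0, 0), c(d, 0, 0)), c(r, r), rp, 960)
  h <- R - d / 2                     # buried cap height on each sphere
  want <- 2 * (4 * pi * R^2 - 2 * pi * R * h)
  expect_equal(got, want, tolerance = 0.02)
})

test_that("a sphere enclosed by an overlapping shell is fully buried", {
  golden <- pi * (3 - sqrt(5))
  k <- 0:31
  z <- 1 - 2 * (k + 0.5) / 32
  rad <- sqrt(pmax(0, 1 - z^2))
  shell <- 2.5 * cbind(rad * cos(golden * k), rad * sin(golden * k), z)
  coords <- rbind(c(0, 0, 0), shell)
  frac <- coassembly:::cpp_exposed_fraction(coords, c(1.5, rep(2, 32)), 1.0,
                                            960)
  expect_lt(frac[1], 0.02)
})

test_that("adding neighbors never increases any atom's exposure", {
  set.seed(17)
  for (r in 1:5) {
    X <- matrix(runif(12 * 3, 0, 6), 12)
    radii <- runif(12, 1.2, 1.8)
    sub <- coassembly:::cpp_exposed_fraction(X[1:6, ], radii[1:6], 1.4, 240)
    full <- coassembly:::cpp_exposed_fraction(X, radii, 1.4, 240)
    expect_true(all(full[1:6] <= sub + 1e-12))
  }
})

test_that("cluster stats rows are internally consistent", {
  comp <- build_composition(12, 4, 1, 12, 83)
  tpl <- default_templates(1L)
  g <- generate_planted_configuration(
    comp, tpl, list(c(PEPTIDE = 4, DRUG = 2, ZN = 2, NO3 = 3)), seed = 5)
  cl <- detect_clusters(g$frame, 3.5)[[1]]
  st <- cluster_stats(g$frame, cl, comp$n_drug)
  expect_equal(st$size, 11)
  expect_equal(st$pct_peptide + st$pct_drug + st$pct_zn + st$pct_no3 +
                 st$pct_cl, 100, tolerance = 1e-6)
  expect_equal(st$drug_encap_pct, 100 * 2 / 4)
  expect_equal(st$drug_peptide_ratio, 0.5)
  expect_gt(st$rg, 0)
  sasa_cols <- c(st$sasa_peptide, st$sasa_drug, st$sasa_zn, st$sasa_no3)
  expect_true(all(sasa_cols >= 0 & sasa_cols <= 100))
  expect_true(is.na(st$sasa_cl))
})

test_that("size-binned profiles bin half-open and flag single-member bins", {
  stats <- data.frame(frame = 1L, size = c(31L, 35L, 72L),
                      rg = c(10, 12, 20))
  prof <- size_binned_profiles(stats, 40L)
  expect_equal(prof$bin_lo, c(31, 71))
  expect_equal(prof$n_clusters, c(2L, 1L))
  expect_equal(prof$mean_rg, c(11, 20))
  expect_equal(prof$sd_rg, c(sd(c(10, 12)), 0))
  expect_identical(prof$sd_defined, c(TRUE, FALSE))
  # recount oracle on random stats
  set.seed(4)
  stats2 <- data.frame(frame = 1L, size = sample(31:120, 60, TRUE),
                       rg = runif(60, 5, 40))
  prof2 <- size_binned_profiles(stats2, 10L)
  expect_equal(sum(prof2$n_clusters), 60L)
  for (k in seq_len(nrow(prof2))) {
    sel <- stats2$size >= prof2$bin_lo[k] & stats2$size <= prof2$bin_hi[k]
    expect_identical(prof2$n_clusters[k], sum(sel))
    expect_equal(prof2$mean_rg[k], mean(stats2$rg[sel]))
  }
})
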