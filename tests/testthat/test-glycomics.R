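test_that("linkage areas rescale per parent to the monosaccharide shares", {
  p <- glycan_profile("f", c(Glc = 0.8, Xyl = 0.2),
                      linkage_raw = c("4-Glc" = 30, "T-Glc" = 70, "2-Xyl" = 50))
  p <- normalize_linkages(p)
  expect_equal(p$linkage_norm[["4-Glc"]], 0.24)
  expect_equal(p$linkage_norm[["T-Glc"]], 0.56)
  expect_equal(p$linkage_norm[["2-Xyl"]], 0.2)

  # raw shares already matching the mono shares are a fixed point
  q <- glycan_profile("g", c(Glc = 0.6, Xyl = 0.4),
                      linkage_raw = c("4-Glc" = 0.6, "2-Xyl" = 0.4))
  q <- normalize_linkages(q)
  expect_equal(q$linkage_norm[["4-Glc"]], 0.6)
  expect_equal(q$linkage_norm[["2-Xyl"]], 0.4)
})

test_that("monosaccharides without linkage annotation keep their mass", {
  p <- glycan_profile("f", c(Glc = 1))
  expect_warning(p <- normalize_linkages(p), "unannotated-Glc")
  expect_equal(p$linkage_norm, c("unannotated-Glc" = 1))
})

test_that("normalization conserves mass on random profiles", {
  for (seed in 1:100) {
    p <- suppressWarnings(normalize_linkages(random_profile(seed)))
    expect_lt(abs(sum(p$linkage_norm) - 1), 1e-9)
    for (m in names(p$mono_abundance)) {
      sub <- p$linkage_norm[grepl(paste0("-", m, "$"), names(p$linkage_norm))]
      expect_lt(abs(sum(sub) - p$mono_abundance[[m]]), 1e-12)
    }
  }
})

test_that("profile matrices take the feature union with zero fill", {
  a <- normalize_linkages(glycan_profile("a", c(Glc = 1),
                                         linkage_raw = c("4-Glc" = 1)))
  b <- normalize_linkages(glycan_profile("b", c(Xyl = 1),
                                         linkage_raw = c("2-Xyl" = 1)))
  m <- build_profile_matrix(list(a, b), "linkage")
  expect_setequal(colnames(m), c("4-Glc", "2-Xyl"))
  expect_equal(m["a", "2-Xyl"], 0)
  expect_equal(m["b", "4-Glc"], 0)

  single <- build_profile_matrix(list(a), "mono")
  expect_equal(unname(single[1, ]), 1)

  fibers <- simulate_fibers(simulation_config(seed = 11, n_fibers = 3))
  mm <- build_profile_matrix(fibers, "mono")
  expect_lt(max(abs(rowSums(mm) - 1)), 1e-9)

  expect_error(build_profile_matrix(list(glycan_profile("c", c(Glc = 1))),
                                    "linkage"), "normalize_linkages")
})

test_that("clustering recovers planted groups and records a valid cut", {
  cfg <- simulation_config(n_groups = 2, n_fibers = 10,
                           dirichlet_concentration = 200, seed = 7)
  fibers <- simulate_fibers(cfg)
  m <- build_profile_matrix(fibers, "mono")
  grp <- phyloglycomic_cluster(m, k = 2)
  expect_equal(ari(grp$labels[names(attr(fibers, "true_groups"))],
                   attr(fibers, "true_groups")), 1.0)
  # the recorded height reproduces the labels
  recut <- stats::cutree(grp$dendrogram, h = grp$cut_height)
  expect_equal(ari(recut[names(grp$labels)], grp$labels), 1.0)
})

test_that("clustering handles degenerate k and duplicate profiles", {
  m <- rbind(f1 = c(0.5, 0.5), f2 = c(0.5, 0.5), f3 = c(0.9, 0.1))
  grp2 <- phyloglycomic_cluster(m, k = 2)
  expect_equal(min(grp2$dendrogram$height), 0)
  expect_equal(grp2$labels[["f1"]], grp2$labels[["f2"]])
  grp1 <- phyloglycomic_cluster(m, k = 1)
  expect_true(all(grp1$labels == "A"))
  expect_error(phyloglycomic_cluster(m, k = 4), "k must lie")
})

test_that("cluster partitions are invariant to fiber input order", {
  cfg <- simulation_config(n_groups = 3, n_fibers = 9, seed = 13)
  fibers <- simulate_fibers(cfg)
  m <- build_profile_matrix(fibers, "mono")
  g1 <- phyloglycomic_cluster(m, k = 3)$labels
  perm <- c(5, 2, 9, 1, 7, 3, 8, 6, 4)
  g2 <- phyloglycomic_cluster(m[perm, ], k = 3)$labels
  expect_equal(ari(g1[rownames(m)], g2[rownames(m)]), 1.0)
})

test_that("size summaries report dominant bin and large-molecule fraction", {
  p1 <- glycan_profile("a", c(Glc = 1), size_bins = c("0.21-0.93" = 1))
  s1 <- size_distribution_summary(p1)
  expect_equal(s1$dominant_bin, "0.21-0.93")
  expect_equal(s1$fraction_above_threshold, 0)

  p2 <- glycan_profile("b", c(Glc = 1),
                       size_bins = c(">1000" = 0.6, "105-851" = 0.4))
  expect_equal(size_distribution_summary(p2)$fraction_above_threshold, 0.6)

  p3 <- glycan_profile("c", c(Glc = 1),
                       size_bins = c("105-851" = 0.25, ">1000" = 0.25,
                                     "0.21-0.93" = 0.25, "7.76-105" = 0.25))
  # ties break toward the smallest size range
  expect_equal(size_distribution_summary(p3)$dominant_bin, "0.21-0.93")

  expect_error(size_distribution_summary(glycan_profile("d", c(Glc = 1))),
               "size_bins")
})

test_that("novel fibers classify to the nearest phyloglycomic group", {
  cfg <- simulation_config(n_groups = 3, n_fibers = 9,
                           dirichlet_concentration = 500, seed = 17)
  fibers <- simulate_fibers(cfg)
  m <- build_profile_matrix(fibers, "mono")
  grp <- phyloglycomic_cluster(m, k = 3)

  hit <- classify_novel_fiber(fibers[[1]], fibers, grp)
  expect_equal(hit$predicted_group, grp$labels[[fibers[[1]]$fiber_id]])
  expect_lt(min(hit$fiber_distances), 1e-12)

  # 70/30 template mixture lands in the dominant template's group
  mix <- 0.7 * cfg$mono_templates[1, ] + 0.3 * cfg$mono_templates[2, ]
  novel <- glycan_profile("novel", mix / sum(mix))
  truth <- attr(fibers, "true_groups")
  pred <- classify_novel_fiber(novel, fibers, grp)
  expect_equal(pred$predicted_group,
               grp$labels[[names(truth)[truth == "A"][1]]])

  # all mass on an unseen monosaccharide still classifies, with a warning
  alien <- glycan_profile("alien", c(Rha = 1))
  expect_warning(far <- classify_novel_fiber(alien, fibers, grp), "unseen")
  expect_true(far$predicted_group %in% grp$labels)
  expect_equal(far$off_support, 1)
})
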