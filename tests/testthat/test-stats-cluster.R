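test_that("descriptive statistics use sample std and a scale-invariant CV", {
  set.seed(8)
  df <- data.frame(a = rnorm(40, 50, 9), b = runif(40, 1, 3))
  st <- descriptive_stats(df)
  expect_equal(st$mean[1], mean(df$a))
  expect_equal(st$std[1], sd(df$a))
  expect_equal(st$cv_percent[1], 100 * sd(df$a) / mean(df$a))
  expect_true(all(st$min <= st$mean & st$mean <= st$max))

  const <- data.frame(x = rep(4, 10))
  expect_equal(descriptive_stats(const)$cv_percent, 0)

  centered <- data.frame(x = c(-1, 1, -2, 2))
  expect_true(is.na(descriptive_stats(centered)$cv_percent))

  scaled <- descriptive_stats(data.frame(a = df$a * 7.3))
  expect_equal(scaled$cv_percent, st$cv_percent[1])

  expect_equal(round(cv_percent(33.13, 15.51), 2), 46.82)
})

test_that("pearson correlations recover programmed couplings and flag degeneracy", {
  expect_equal(pearson_corr(data.frame(x = 1:10, y = 1:10))["x", "y"], 1)
  expect_equal(pearson_corr(data.frame(x = 1:10, y = -(1:10)))["x", "y"], -1)
  expect_warning(cm <- pearson_corr(data.frame(x = 1:10, z = rep(2, 10))),
                 "zero-variance")
  expect_true(is.na(cm["x", "z"]))

  panel <- make_genotype_panel(95, seed = 21)
  recs <- do.call(rbind, lapply(seq_along(panel), function(i) {
    nl <- leaf_count_trajectory(panel[[i]], "control", 1:4)[4]
    cbind(simulate_destructive(panel[[i]], "control", nl, seed = 500 + i), NL = nl)
  }))
  cm <- pearson_corr(recs, c("NL", "leaf_weight_g", "biomass_weight_g"))
  expect_gte(cm["NL", "leaf_weight_g"], 0.85)
  expect_gt(cm["leaf_weight_g", "biomass_weight_g"], 0.5)
})

test_that("greedy detection matching scores forced cases exactly", {
  gt <- make_tips(cbind(c(100, 200, 300), c(100, 200, 300)))
  same <- match_detections(gt, gt, tau_px = 16)
  expect_equal(same$precision, 1)
  expect_equal(same$recall, 1)
  expect_equal(same$count_accuracy_percent, 100)

  pred <- make_tips(cbind(c(100, 200, 300, 500), c(100, 200, 300, 500)))
  extra <- match_detections(pred, gt, tau_px = 16)
  expect_equal(extra$precision, 3 / 4)
  expect_equal(extra$recall, 1)
  expect_equal(extra$true_positives + extra$false_negatives, 3)

  none <- match_detections(pred, make_tips(matrix(numeric(0), ncol = 2)), tau_px = 16)
  expect_true(is.na(none$count_accuracy_percent))
})

test_that("greedy matching tracks the exhaustive optimal assignment", {
  set.seed(31)
  for (i in 1:40) {
    ng <- sample(2:6, 1); np <- sample(2:6, 1)
    # tau-separated ground truth: greedy must equal optimal
    repeat {
      gtp <- cbind(runif(ng, 0, 300), runif(ng, 0, 300))
      if (ng == 1 || min(dist(gtp)) > 2 * 20) break
    }
    prp <- gtp[sample(ng, np, replace = TRUE), , drop = FALSE] +
      matrix(runif(np * 2, -15, 15), ncol = 2)
    prp <- pmin(pmax(prp, 0), 639)
    rep_ <- match_detections(make_tips(prp), make_tips(gtp), tau_px = 20)
    expect_equal(rep_$true_positives, optimal_match_count(prp, gtp, 20))
  }
  # tau-separated (but not 2*tau-separated) ground truth: within 1 of optimal
  for (i in 1:40) {
    ng <- sample(2:6, 1); np <- sample(2:6, 1)
    repeat {
      gtp <- cbind(runif(ng, 0, 150), runif(ng, 0, 150))
      if (ng == 1 || min(dist(gtp)) > 25) break
    }
    prp <- cbind(runif(np, 0, 150), runif(np, 0, 150))
    rep_ <- match_detections(make_tips(prp), make_tips(gtp), tau_px = 25)
    expect_gte(rep_$true_positives, optimal_match_count(prp, gtp, 25) - 1L)
  }
})

test_that("matching recall/precision swap symmetrically on tau-separated sets", {
  set.seed(4)
  gtp <- cbind(seq(40, 600, by = 80), seq(40, 600, by = 80))
  prp <- gtp[1:6, ] + matrix(runif(12, -5, 5), ncol = 2)
  a <- match_detections(make_tips(prp), make_tips(gtp), tau_px = 16)
  b <- match_detections(make_tips(gtp), make_tips(prp), tau_px = 16)
  expect_equal(a$recall, b$precision)
  expect_equal(a$precision, b$recall)
})

test_that("clustering separates programmed tolerance groups and is permutation invariant", {
  panel <- c(
    lapply(1:10, function(i) genotype_spec(sprintf("T%02d", i), "erect",
      base_leaf_count = 12 + i %% 4, emergence_rate_control = 6 + i %% 3,
      drought_emergence_factor = 0.9, seed = i)),
    lapply(1:10, function(i) genotype_spec(sprintf("S%02d", i), "spread",
      base_leaf_count = 14 + i %% 4, emergence_rate_control = 6 + i %% 3,
      drought_emergence_factor = 0.3, seed = 100 + i))
  )
  feats <- do.call(rbind, lapply(panel, function(g) {
    dd <- delta_leaves(leaf_count_trajectory(g, "drought", 1:4), 1:4, 1, 4)
    dc <- delta_leaves(leaf_count_trajectory(g, "control", 1:4), 1:4, 1, 4)
    data.frame(genotype_id = g$genotype_id,
               NL_drought = leaf_count_trajectory(g, "drought", 1:4)[4],
               ler = as.numeric(ler(dd, dc)))
  }))
  tree <- cluster_genotypes(feats, k = 2)
  grp <- tree$assignments
  expect_length(unique(grp[grepl("^T", names(grp))]), 1)
  expect_length(unique(grp[grepl("^S", names(grp))]), 1)
  expect_false(grp[["T01"]] == grp[["S01"]])

  perm <- sample(nrow(feats))
  tree2 <- cluster_genotypes(feats[perm, ], k = 2)
  grp2 <- tree2$assignments[names(grp)]
  expect_true(all((grp == grp[["T01"]]) == (grp2 == grp2[["T01"]])))
})

test_that("clustering edge cases: duplicates merge at height zero, singleton trees, bad k", {
  m <- rbind(a = c(1, 2), b = c(1, 2), c = c(5, 9))
  tree <- cluster_genotypes(m, k = 2)
  expect_equal(min(tree$hclust$height), 0)
  expect_equal(tree$assignments[["a"]], tree$assignments[["b"]])

  single <- cluster_genotypes(rbind(only = c(1, 2, 3)))
  expect_identical(single$labels, "only")
  expect_identical(unname(single$assignments), 1L)

  expect_error(cluster_genotypes(m, k = 5), "exceed")
})

test_that("newick export writes merge-height branch lengths and round-trips through ape", {
  single <- cluster_genotypes(rbind(A = c(0, 1)))
  expect_identical(export_newick(single), "(A);")

  two <- cluster_genotypes(rbind(A = c(0, 0), B = c(3, 4)), linkage = "average")
  h <- two$hclust$height[1]
  expect_identical(export_newick(two), sprintf("(A:%g,B:%g);", h, h))

  set.seed(17)
  m <- matrix(rnorm(8 * 3), 8, dimnames = list(LETTERS[1:8], NULL))
  tree <- cluster_genotypes(m, linkage = "complete")
  tmp <- withr::local_tempfile(fileext = ".nwk")
  export_newick(tree, tmp)
  phy <- ape::read.tree(tmp)
  expect_setequal(phy$tip.label, LETTERS[1:8])
  # identical topology: same split sets as the hclust-derived ape tree
  ref <- ape::as.phylo(tree$hclust)
  expect_equal(ape::dist.topo(ape::unroot(phy), ape::unroot(ref))[1], 0)
  # ultrametric: branch lengths reconstruct the merge heights
  expect_true(ape::is.ultrametric(phy, tol = 1e-8))
})
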