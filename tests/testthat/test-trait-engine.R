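test_that("counting leaves is the tip-set cardinality", {
  expect_identical(count_leaves(make_tips(matrix(numeric(0), ncol = 2))), 0L)
  set.seed(1)
  expect_identical(count_leaves(make_tips(cbind(runif(42, 0, 600), runif(42, 0, 600)))), 42L)
  g <- genotype_spec("G", "spread", base_leaf_count = 23, erectness = 0.3, seed = 3)
  p <- render_plant(g, "control", 1, scene_spec(), seed = 3)
  expect_identical(count_leaves(p$tips), p$leaf_count)
})

test_that("monotone-chain hull matches independent oracles and handles degeneracy", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  h <- convex_hull(sq)
  expect_equal(nrow(h), 4)
  expect_setequal(paste(h[, 1], h[, 2]), paste(sq[1:4, 1], sq[1:4, 2]))

  col3 <- rbind(c(0, 0), c(1, 1), c(2, 2))
  hd <- convex_hull(col3)
  expect_equal(hull_area(hd), 0)

  expect_error(convex_hull(matrix(numeric(0), ncol = 2)), "at least one")

  set.seed(99)
  for (i in 1:200) {
    n <- sample(3:30, 1)
    pts <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    mine <- convex_hull(pts)
    oracle <- gift_wrap_hull(pts)
    expect_setequal(paste(round(mine[, 1], 9), round(mine[, 2], 9)),
                    paste(round(oracle[, 1], 9), round(oracle[, 2], 9)))
    base_idx <- grDevices::chull(pts)   # second, independent cross-check
    expect_setequal(paste(mine[, 1], mine[, 2]),
                    paste(pts[base_idx, 1], pts[base_idx, 2]))
  }
})

test_that("hull area agrees with fan triangulation, scales quadratically, ignores interior points", {
  expect_equal(hull_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), 1), 1.0)

  set.seed(7)
  for (i in 1:50) {
    pts <- cbind(runif(12, 0, 50), runif(12, 0, 50))
    v <- convex_hull(pts)
    expect_equal(hull_area(v), fan_triangulation_area(v), tolerance = 1e-9)
    s <- runif(1, 0.5, 3)
    expect_equal(hull_area(convex_hull(pts * s)), s^2 * hull_area(v),
                 tolerance = 1e-9)
    interior <- colMeans(pts[grDevices::chull(pts), ])
    expect_equal(hull_area(convex_hull(rbind(pts, interior))), hull_area(v))
  }
})

test_that("bounding box extent, aspect ratio and leaves-per-hull follow their formulas", {
  pts <- rbind(c(10, 20), c(110, 20), c(110, 70), c(10, 70))
  bb <- bounding_box_area(pts, cm_per_pixel = 0.1)
  expect_equal(bb$bba_cm2, 50.0)
  expect_equal(bb$width_cm, 10.0)
  expect_equal(bb$length_cm, 5.0)

  one <- bounding_box_area(rbind(c(5, 5)), 1)
  expect_equal(unlist(one), c(bba_cm2 = 0, width_cm = 0, length_cm = 0))
  expect_error(bounding_box_area(matrix(numeric(0), ncol = 2)), "non-empty")

  expect_equal(plant_aspect_ratio(7, 7), 1)
  expect_equal(plant_aspect_ratio(10, 5), 2)
  expect_equal(plant_aspect_ratio(3, 11) * plant_aspect_ratio(11, 3), 1)
  par0 <- plant_aspect_ratio(4, 0)
  expect_true(is.na(par0))
  expect_true(attr(par0, "undefined"))

  expect_equal(leaves_per_hull(42, 6230.512), 42 / 6230.512)
  expect_equal(round(leaves_per_hull(42, 6230.512), 6), 0.006741)
  expect_equal(leaves_per_hull(0, 100), 0)
  expect_equal(leaves_per_hull(10, 200), 2 * leaves_per_hull(10, 400))
  und <- leaves_per_hull(5, 0)
  expect_true(is.na(und) && attr(und, "undefined"))
  expect_error(leaves_per_hull(-1, 10), ">= 0")
})

test_that("hull area never exceeds bounding box area", {
  set.seed(13)
  for (i in 1:500) {
    n <- sample(2:40, 1)
    pts <- cbind(runif(n, 0, 200), runif(n, 0, 200))
    cha <- hull_area(convex_hull(pts), 0.25)
    bba <- bounding_box_area(pts, 0.25)$bba_cm2
    expect_lte(cha, bba + 1e-9)
  }
})

test_that("side-view height and elongation rate behave on fixtures", {
  rect <- matrix(FALSE, 200, 100); rect[51:170, 30:60] <- TRUE
  # soil line one row below the lowest plant row: 120 px of plant
  expect_equal(plant_height(rect, baseline_row = 171, cm_per_pixel = 0.1), 12.0)
  expect_equal(plant_height(matrix(FALSE, 10, 10), 10, 1), 0)

  stacked <- matrix(FALSE, 100, 50)
  stacked[80:90, 10:40] <- TRUE   # lower blob
  stacked[20:30, 20:30] <- TRUE   # upper blob
  expect_equal(plant_height(stacked, baseline_row = 95, cm_per_pixel = 1), 75)

  expect_equal(elongation_rate(1:4, rep(8, 4)), 0)
  expect_equal(elongation_rate(1:4, c(10, 12, 14, 16)), 2.0)
  expect_error(elongation_rate(1, 10), ">= 2")
  expect_error(elongation_rate(c(2, 1), c(1, 2)), "increasing")

  set.seed(5)
  ts <- 1:5
  slopes <- replicate(200, {
    h <- 4 + 1.5 * ts + rnorm(5, 0, 0.4)
    elongation_rate(ts, h)
  })
  expect_equal(mean(slopes), 1.5, tolerance = 0.05)
})

test_that("trait records satisfy their internal invariants on synthetic plants", {
  g <- genotype_spec("G9", "open", base_leaf_count = 16, erectness = 0.15, seed = 77)
  sc <- scene_spec()
  for (ts in c(1L, 3L)) {
    p <- render_plant(g, "control", ts, sc, seed = 77)
    tr <- trait_record(p$tips, sc$cm_per_pixel, genotype_id = "G9",
                       treatment = "control", time_snap = ts,
                       height_cm = p$height_cm)
    expect_identical(tr$NL, p$leaf_count)
    expect_lte(tr$CHA_cm2, tr$BBA_cm2 + 1e-9)
    expect_equal(tr$NLPCHA_per_cm2, tr$NL / tr$CHA_cm2)
    expect_equal(tr$PAR, tr$width_cm / tr$length_cm)
  }
  # control trajectories have non-decreasing NL and BBA
  recs <- lapply(1:5, function(ts) {
    p <- render_plant(g, "control", ts, sc, seed = 77)
    trait_record(p$tips, sc$cm_per_pixel, time_snap = ts)
  })
  nl <- vapply(recs, `[[`, numeric(1), "NL")
  expect_false(is.unsorted(nl))
})
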