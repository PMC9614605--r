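test_that("excess-green segmentation has closed-form behavior and matches the generator silhouette", {
  gray <- array(128, dim = c(8, 8, 3))
  expect_false(any(segment_plant(gray, min_area_px = 1)))

  px <- array(0, dim = c(4, 4, 3)); px[2, 2, 2] <- 255
  expect_true(segment_plant(px, min_area_px = 1)[2, 2])
  expect_equal(sum(segment_plant(px, min_area_px = 1)), 1)

  expect_error(segment_plant(matrix(1, 4, 4)), "RGB")

  g <- genotype_spec("G1", "semi_erect", base_leaf_count = 12, erectness = 0.6,
                     seed = 31)
  p <- render_plant(g, "control", 2, scene_spec(), seed = 31)
  mask <- segment_plant(p$image)
  iou <- sum(mask & p$silhouette) / sum(mask | p$silhouette)
  expect_gte(iou, 0.90)
})

test_that("thinning yields one-pixel-wide skeletons inside the mask with preserved topology", {
  bar <- matrix(FALSE, 20, 60); bar[9:11, 5:55] <- TRUE
  sk <- skeletonize_mask(bar)
  expect_true(is_one_px_wide(sk))
  expect_true(all(which(sk) %in% which(bar)))
  expect_equal(count_components8(sk), 1)

  expect_false(any(skeletonize_mask(matrix(FALSE, 10, 10))))

  plus <- matrix(FALSE, 41, 41)
  plus[19:23, 3:39] <- TRUE
  plus[3:39, 19:23] <- TRUE
  skp <- skeletonize_mask(plus)
  m <- matrix(as.integer(skp), 41, 41)
  nbr <- function(mm) {
    s <- function(dr, dc) {
      o <- matrix(0L, nrow(mm), ncol(mm))
      rs <- seq_len(nrow(mm)) - dr; cs <- seq_len(ncol(mm)) - dc
      okr <- rs >= 1 & rs <= nrow(mm); okc <- cs >= 1 & cs <= ncol(mm)
      o[okr, okc] <- mm[rs[okr], cs[okc]]; o
    }
    s(-1,0)+s(-1,1)+s(0,1)+s(1,1)+s(1,0)+s(1,-1)+s(0,-1)+s(-1,-1)
  }
  expect_equal(sum(m == 1 & nbr(m) == 1), 4)

  # topology preserved across disjoint components
  two <- matrix(FALSE, 30, 30)
  two[5:8, 5:25] <- TRUE; two[20:23, 5:25] <- TRUE
  expect_equal(count_components8(skeletonize_mask(two)), 2)
})

test_that("endpoint counts on hand-built skeletons match the analytic values", {
  blank <- function() matrix(FALSE, 60, 60)
  draw <- function(m, rs, cs) { m[cbind(rs, cs)] <- TRUE; m }
  n_tips <- function(m) count_leaves(detect_tips(m, prune_len_px = 0,
                                                 merge_radius_px = 0))
  line <- draw(blank(), rep(30, 50), 5:54)                 # straight line
  expect_equal(n_tips(line), 2)
  ell <- draw(draw(blank(), 10:40, rep(10, 31)), rep(40, 30), 11:40)  # L
  expect_equal(n_tips(ell), 2)
  tee <- draw(draw(blank(), rep(10, 41), 10:50), 11:40, rep(30, 30))  # T
  expect_equal(n_tips(tee), 3)
  plus <- draw(draw(blank(), rep(30, 41), 10:50), 10:50, rep(30, 41)) # plus
  expect_equal(n_tips(plus), 4)
  wye <- draw(draw(draw(blank(), 30:50, rep(30, 21)),
                   29:15, 29:15), 29:15, 31:45)                       # Y
  expect_equal(n_tips(wye), 3)
})

test_that("detect_tips enforces the thin-skeleton contract and behaves on edge cases", {
  thick <- matrix(FALSE, 10, 10); thick[4:6, 4:6] <- TRUE
  expect_error(detect_tips(thick), "one pixel wide")

  empty <- matrix(FALSE, 10, 10)
  expect_identical(count_leaves(detect_tips(empty)), 0L)

  line <- matrix(FALSE, 40, 60); line[20, 5:54] <- TRUE
  ts <- detect_tips(line, prune_len_px = 0, merge_radius_px = 0)
  expect_equal(count_leaves(ts), 2)
  expect_setequal(round(ts$tips$cx_px), c(4, 53))

  # determinism / idempotence of the full parameterization
  g <- genotype_spec("G1", "erect", base_leaf_count = 8, erectness = 0.8, seed = 13)
  p <- render_plant(g, "control", 1, scene_spec(), seed = 13)
  sk <- skeletonize_mask(segment_plant(p$image))
  t1 <- detect_tips(sk, image_id = "a")
  t2 <- detect_tips(sk, image_id = "a")
  expect_identical(t1, t2)
})

test_that("close endpoints merge to their centroid and culm exclusion drops central endpoints", {
  m <- matrix(FALSE, 40, 80)
  m[18, 5:40] <- TRUE   # endpoints at x=4,39 (y=17)
  m[22, 5:40] <- TRUE   # endpoints at x=4,39 (y=21)
  ts <- detect_tips(m, prune_len_px = 0, merge_radius_px = 6)
  expect_equal(count_leaves(ts), 2)          # the two line-ends on each side merge
  expect_setequal(round(ts$tips$cy_px), c(19, 19))

  ts2 <- detect_tips(m, prune_len_px = 0, merge_radius_px = 0)
  expect_equal(count_leaves(ts2), 4)

  # culm exclusion: endpoints near the foreground centroid are dropped
  ts3 <- detect_tips(m, prune_len_px = 0, merge_radius_px = 0,
                     culm_exclusion_px = 25)
  expect_lt(count_leaves(ts3), 4)
})

test_that("sparse synthetic plants are counted exactly, each tip near its ground truth", {
  g <- genotype_spec("G1", "erect", base_leaf_count = 8, erectness = 0.8,
                     leaf_len_px = allometric_leaf_len(8, 0.8), seed = 17)
  sc <- scene_spec()
  p <- render_plant(g, "control", 1, sc, seed = 17)
  pred <- detect_plant(p)
  expect_equal(count_leaves(pred), 8)
  d <- sqrt(outer(pred$tips$cx_px, p$tips$tips$cx_px, "-")^2 +
              outer(pred$tips$cy_px, p$tips$tips$cy_px, "-")^2)
  expect_true(all(apply(d, 2, min) <= sc$box_size_px))
})

test_that("YOLO label I/O follows the normalized center format and round-trips", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines("0 0.5 0.5 0.1 0.1", tmp)
  ts <- read_yolo_labels(tmp, 608, 608)
  expect_equal(ts$tips$cx_px, 304)
  expect_equal(ts$tips$cy_px, 304)
  expect_equal(ts$tips$w_px, 60.8)

  writeLines(character(0), tmp)
  expect_identical(count_leaves(read_yolo_labels(tmp, 608, 608)), 0L)

  writeLines(c("0 0.5 0.5 0.1 0.1", "1 0.2 0.2 0.1 0.1"), tmp)
  expect_warning(ts2 <- read_yolo_labels(tmp, 608, 608), "skipped")
  expect_equal(count_leaves(ts2), 1)

  writeLines("0 1.5 0.5 0.1 0.1", tmp)
  expect_error(read_yolo_labels(tmp, 608, 608), "out of")

  set.seed(42)
  pts <- cbind(runif(25, 0, 639), runif(25, 0, 479))
  orig <- tip_set(
    data.frame(cx_px = pts[, 1], cy_px = pts[, 2], w_px = 16, h_px = 16,
               confidence = 1),
    image_id = "rt", image_width_px = 640, image_height_px = 480
  )
  write_yolo_labels(orig, tmp)
  back <- read_yolo_labels(tmp, 640, 480)
  expect_equal(back$tips$cx_px, orig$tips$cx_px, tolerance = 1e-5)
  expect_equal(back$tips$cy_px, orig$tips$cy_px, tolerance = 1e-5)
  # write(read(f)) reproduces the file byte for byte
  tmp2 <- withr::local_tempfile(fileext = ".txt")
  write_yolo_labels(back, tmp2)
  expect_identical(readLines(tmp2), readLines(tmp))
})
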