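#' Run the classical detection chain on one image
#'
#' Convenience composition of [segment_plant()], [skeletonize_mask()] and
#' [detect_tips()] with the pipeline defaults.
#'
#' @param image RGB array, or a `synthetic_plant` (its image is used).
#' @param exg_threshold,min_area_px Passed to [segment_plant()].
#' @param prune_len_px,merge_radius_px,culm_exclusion_px,box_size_px Passed
#'   to [detect_tips()].
#' @param image_id Identifier stored on the result.
#' @return A [tip_set()] of detections.
#' @export
detect_plant <- function(image, exg_threshold = 0, min_area_px = 20L,
                         prune_len_px = 8L, merge_radius_px = 8,
                         culm_exclusion_px = 0, box_size_px = 16L,
                         image_id = "image") {
  if (inherits(image, "synthetic_plant")) {
    image_id <- image$tips$image_id
    image <- image$image
  }
  mask <- segment_plant(image, exg_threshold, min_area_px)
  skel <- skeletonize_mask(mask)
  detect_tips(skel, prune_len_px = prune_len_px,
              merge_radius_px = merge_radius_px,
              culm_exclusion_px = culm_exclusion_px,
              box_size_px = box_size_px, image_id = image_id)
}

#' Seeded synthetic evaluation suites for the tip detector
#'
#' The sparse regime emulates small, sparsely spread plants: 8-15 leaves,
#' erect/semi-erect architecture, ground-truth tips separated by at least
#' half a box edge. The dense regime emulates large crowded canopies: 60-100
#' leaves, spread/open architecture, overlapping blades permitted and no
#' separation guarantee.
#'
#' @param n Number of plants.
#' @param regime `"sparse"` or `"dense"`.
#' @param seed Integer master seed; plant `i` uses `seed * 1000 + i`.
#' @param scene A [scene_spec()]; by default the dense regime uses a
#'   768 px frame at the same 0.25 cm/px optical scale, since canopies of
#'   60-100 leaves spread close to 1.8 m and would not fit the 640 px
#'   frame used for small sparse plants.
#' @return List of `synthetic_plant` objects.
#' @export
simulate_detection_suite <- function(n = 50, regime = c("sparse", "dense"),
                                     seed = 1L, scene = NULL) {
  regime <- match.arg(regime)
  scene <- scene %||% if (regime == "dense") {
    scene_spec(image_width_px = 768L, image_height_px = 768L)
  } else {
    scene_spec()
  }
  n <- as.integer(n)
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    plant_seed <- as.integer(seed) * 1000L + i
    if (regime == "sparse") {
      counts <- 8:15
      arch <- c("erect", "semi_erect")[1 + i %% 2]
      erect <- if (arch == "erect") 0.8 else 0.6
    } else {
      counts <- as.integer(round(seq(60, 100, length.out = 9)))
      arch <- c("spread", "open")[1 + i %% 2]
      erect <- if (arch == "spread") 0.3 else 0.15
    }
    nl <- counts[1 + (i - 1) %% length(counts)]
    g <- genotype_spec(
      genotype_id = sprintf("%s%03d", toupper(substr(regime, 1, 1)), i),
      archetype = arch,
      base_leaf_count = nl,
      emergence_rate_control = 6,
      drought_emergence_factor = 0.6,
      erectness = erect,
      rolling_factor = 0.3,
      leaf_len_px = allometric_leaf_len(nl, erect, scene),
      seed = plant_seed
    )
    render_plant(g, "control", time_snap = 1L, scene = scene, seed = plant_seed)
  })
}

#' Score the classical detector on a suite of synthetic plants
#'
#' Runs the full detection chain on each plant and matches detections
#' against the generator's exact ground truth (`tau_px` defaulting to the
#' ground-truth box edge).
#'
#' @param plants List of `synthetic_plant` objects (e.g. from
#'   [simulate_detection_suite()]).
#' @param tau_px Match radius; defaults to the scene box edge.
#' @param ... Detector parameters forwarded to [detect_plant()].
#' @return Data frame with one row per plant: `image_id`, `leaf_count`,
#'   `detected`, `count_accuracy_percent`, `precision`, `recall`.
#' @export
evaluate_detector <- function(plants, tau_px = NULL, ...) {
  rows <- lapply(plants, function(p) {
    tau <- tau_px %||% p$scene$box_size_px
    pred <- detect_plant(p, box_size_px = p$scene$box_size_px, ...)
    rep_ <- match_detections(pred, p$tips, tau_px = tau)
    data.frame(
      image_id = p$tips$image_id,
      leaf_count = p$leaf_count,
      detected = count_leaves(pred),
      count_accuracy_percent = as.numeric(rep_$count_accuracy_percent),
      precision = as.numeric(rep_$precision),
      recall = as.numeric(rep_$recall),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
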