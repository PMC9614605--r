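#' Configuration for an end-to-end pipeline run
#'
#' A single serializable object holding every stage's parameters, so any
#' published number can be traced to its configuration. Round-trips through
#' JSON with [write_run_config()] / [read_run_config()].
#'
#' @param panel_n Number of synthetic genotypes.
#' @param time_snaps Time snaps to image (must contain `ts_start` and
#'   `ts_peak`).
#' @param ts_start,ts_peak Window of the emergence-rate index.
#' @param scene A [scene_spec()].
#' @param exg_threshold,min_area_px,prune_len_px,merge_radius_px,culm_exclusion_px
#'   Detector parameters.
#' @param cluster_k Number of genotype groups for the dendrogram cut.
#' @param cluster_linkage Linkage for [cluster_genotypes()].
#' @param seed Global seed; stage randomness derives from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(panel_n = 8L, time_snaps = c(1L, 4L),
                       ts_start = 1L, ts_peak = 4L,
                       scene = scene_spec(),
                       exg_threshold = 0, min_area_px = 20L,
                       prune_len_px = 8L, merge_radius_px = 8,
                       culm_exclusion_px = 0,
                       cluster_k = 2L, cluster_linkage = "average",
                       seed = 1L) {
  if (!all(c(ts_start, ts_peak) %in% time_snaps)) {
    stop("`time_snaps` must contain `ts_start` and `ts_peak`", call. = FALSE)
  }
  structure(
    list(
      panel_n = as.integer(panel_n),
      time_snaps = as.integer(sort(unique(time_snaps))),
      ts_start = as.integer(ts_start), ts_peak = as.integer(ts_peak),
      scene = scene,
      exg_threshold = exg_threshold, min_area_px = as.integer(min_area_px),
      prune_len_px = as.integer(prune_len_px),
      merge_radius_px = merge_radius_px,
      culm_exclusion_px = culm_exclusion_px,
      cluster_k = as.integer(cluster_k),
      cluster_linkage = cluster_linkage,
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$scene <- unclass(x$scene)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- do.call(scene_spec, as.list(x$scene))
  x$scene <- NULL
  do.call(run_config, c(x, list(scene = sc)))
}

.log_stage <- function(stage, ...) {
  message(sprintf("[paddyphenom:%s] %s", stage, sprintf(...)))
}

#' Pipeline stages
#'
#' Each stage is runnable standalone against an output directory laid out
#' as `images/` (PNG + ground-truth YOLO labels + `manifest.csv`),
#' `detections/` (predicted YOLO labels), and top-level CSV/JSON tables.
#' [run_all()] executes them in order.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return Each stage returns its main table invisibly.
#' @name pipeline-stages
NULL

#' @rdname pipeline-stages
#' @export
stage_generate <- function(config, out_dir) {
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- make_genotype_panel(config$panel_n, seed = config$seed)
  rows <- list(); drecs <- list(); idx <- 0L
  for (g in panel) {
    for (treatment in c("control", "drought")) {
      traj <- leaf_count_trajectory(g, treatment, config$time_snaps)
      for (si in seq_along(config$time_snaps)) {
        idx <- idx + 1L
        ts <- config$time_snaps[si]
        plant_seed <- config$seed * 1000L + idx
        p <- render_plant(g, treatment, ts, config$scene, seed = plant_seed)
        paths <- write_plant(p, img_dir)
        rows[[idx]] <- data.frame(
          genotype_id = g$genotype_id, treatment = treatment, time_snap = ts,
          leaf_count = p$leaf_count, height_cm = p$height_cm,
          seed = plant_seed, image = basename(paths["image"]),
          labels = basename(paths["labels"]), stringsAsFactors = FALSE
        )
      }
      drecs[[paste(g$genotype_id, treatment)]] <- simulate_destructive(
        g, treatment, leaf_count = traj[match(config$ts_peak, config$time_snaps)],
        seed = config$seed * 1000L + idx
      )
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(img_dir, "manifest.csv"), row.names = FALSE)
  destructive <- do.call(rbind, drecs)
  rownames(destructive) <- NULL
  utils::write.csv(destructive, file.path(out_dir, "destructive.csv"),
                   row.names = FALSE)
  .log_stage("generate", "%d genotypes, %d images", length(panel), nrow(manifest))
  invisible(manifest)
}

#' @rdname pipeline-stages
#' @export
stage_detect <- function(config, out_dir) {
  img_dir <- file.path(out_dir, "images")
  det_dir <- file.path(out_dir, "detections")
  dir.create(det_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- utils::read.csv(file.path(img_dir, "manifest.csv"))
  for (i in seq_len(nrow(manifest))) {
    img <- read_plant_image(file.path(img_dir, manifest$image[i]))
    pred <- detect_plant(
      img, exg_threshold = config$exg_threshold,
      min_area_px = config$min_area_px, prune_len_px = config$prune_len_px,
      merge_radius_px = config$merge_radius_px,
      culm_exclusion_px = config$culm_exclusion_px,
      box_size_px = config$scene$box_size_px,
      image_id = tools::file_path_sans_ext(manifest$image[i])
    )
    write_yolo_labels(pred, file.path(det_dir, manifest$labels[i]))
  }
  .log_stage("detect", "%d images processed", nrow(manifest))
  invisible(manifest)
}

#' @rdname pipeline-stages
#' @export
stage_traits <- function(config, out_dir) {
  img_dir <- file.path(out_dir, "images")
  det_dir <- file.path(out_dir, "detections")
  manifest <- utils::read.csv(file.path(img_dir, "manifest.csv"))
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    tips <- read_yolo_labels(
      file.path(det_dir, manifest$labels[i]),
      config$scene$image_width_px, config$scene$image_height_px
    )
    trait_record(
      tips, cm_per_pixel = config$scene$cm_per_pixel,
      genotype_id = manifest$genotype_id[i],
      treatment = manifest$treatment[i],
      time_snap = manifest$time_snap[i],
      height_cm = manifest$height_cm[i]
    )
  })
  traits <- do.call(rbind, rows)
  utils::write.csv(traits, file.path(out_dir, "traits.csv"), row.names = FALSE)
  .log_stage("traits", "%d trait records", nrow(traits))
  invisible(traits)
}

#' @rdname pipeline-stages
#' @export
stage_ler <- function(config, out_dir) {
  traits <- utils::read.csv(file.path(out_dir, "traits.csv"))
  counts <- data.frame(
    genotype_id = traits$genotype_id, treatment = traits$treatment,
    time_snap = traits$time_snap, leaf_count = traits$NL
  )
  lt <- ler_table(counts, ts_start = config$ts_start, ts_peak = config$ts_peak)
  utils::write.csv(lt, file.path(out_dir, "ler.csv"), row.names = FALSE)
  .log_stage("ler", "%d genotypes indexed", nrow(lt))
  invisible(lt)
}

#' @rdname pipeline-stages
#' @export
stage_evaluate <- function(config, out_dir) {
  img_dir <- file.path(out_dir, "images")
  det_dir <- file.path(out_dir, "detections")
  manifest <- utils::read.csv(file.path(img_dir, "manifest.csv"))
  w <- config$scene$image_width_px; h <- config$scene$image_height_px
  per_image <- lapply(seq_len(nrow(manifest)), function(i) {
    gt <- read_yolo_labels(file.path(img_dir, manifest$labels[i]), w, h)
    pred <- read_yolo_labels(file.path(det_dir, manifest$labels[i]), w, h)
    r <- match_detections(pred, gt, tau_px = config$scene$box_size_px)
    list(image = manifest$image[i],
         true_positives = r$true_positives,
         false_positives = r$false_positives,
         false_negatives = r$false_negatives,
         precision = as.numeric(r$precision),
         recall = as.numeric(r$recall),
         count_accuracy_percent = as.numeric(r$count_accuracy_percent))
  })
  acc <- vapply(per_image, `[[`, numeric(1), "count_accuracy_percent")
  report <- list(
    n_images = nrow(manifest),
    mean_count_accuracy_percent = mean(acc, na.rm = TRUE),
    mean_precision = mean(vapply(per_image, `[[`, numeric(1), "precision")),
    mean_recall = mean(vapply(per_image, `[[`, numeric(1), "recall")),
    per_image = per_image
  )
  jsonlite::write_json(report, file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA)
  .log_stage("evaluate", "mean count accuracy %.1f%%",
             report$mean_count_accuracy_percent)
  invisible(report)
}

#' @rdname pipeline-stages
#' @export
stage_cluster <- function(config, out_dir) {
  traits <- utils::read.csv(file.path(out_dir, "traits.csv"))
  lt <- utils::read.csv(file.path(out_dir, "ler.csv"))
  peak <- traits[traits$time_snap == config$ts_peak, ]
  wide <- merge(
    stats::reshape(
      peak[, c("genotype_id", "treatment", "NL")],
      idvar = "genotype_id", timevar = "treatment", direction = "wide"
    ),
    lt[, c("genotype_id", "ler_percent")], by = "genotype_id"
  )
  mat <- wide[!is.na(wide$ler_percent), ]
  tree <- cluster_genotypes(mat, linkage = config$cluster_linkage,
                            k = min(config$cluster_k, nrow(mat)))
  export_newick(tree, file.path(out_dir, "dendrogram.nwk"))
  utils::write.csv(
    data.frame(genotype_id = names(tree$assignments),
               group = as.integer(tree$assignments)),
    file.path(out_dir, "clusters.csv"), row.names = FALSE
  )
  .log_stage("cluster", "%d genotypes in %d groups", length(tree$labels),
             length(unique(tree$assignments)))
  invisible(tree)
}

#' Run the whole pipeline and emit a hashed manifest
#'
#' Executes generate, detect, traits, ler, evaluate and cluster in order.
#' A stage failure aborts with the stage name; partial outputs are
#' retained. The returned manifest lists every produced file with its MD5
#' content hash, so a rerun with the same configuration and seed can be
#' checked for bit-identical reproduction.
#'
#' @param config A [run_config()].
#' @param out_dir Writable output directory.
#' @return Data frame (`file`, `md5`) of all outputs, invisibly; also
#'   written to `run_manifest.csv`.
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_run_config(config, file.path(out_dir, "config.json"))
  stages <- list(
    generate = stage_generate, detect = stage_detect, traits = stage_traits,
    ler = stage_ler, evaluate = stage_evaluate, cluster = stage_cluster
  )
  for (nm in names(stages)) {
    tryCatch(
      stages[[nm]](config, out_dir),
      error = function(e) {
        stop(sprintf("pipeline stage '%s' failed: %s", nm, conditionMessage(e)),
             call. = FALSE)
      }
    )
  }
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "run_manifest.csv"]
  manifest <- data.frame(
    file = sub(paste0("^", out_dir, "/?"), "", files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE
  )
  manifest <- manifest[order(manifest$file), ]
  utils::write.csv(manifest, file.path(out_dir, "run_manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
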