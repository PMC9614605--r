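# Procedural top-view rice plant renderer.
#
# Blades radiate from a central culm disk as tapered, slightly curved
# strokes; the distal endpoint of each blade centerline is recorded as a
# ground-truth leaf tip. Plant pixels strictly satisfy the excess-green
# inequality 2G - R - B > 0 before noise and the background strictly
# violates it, so segmentation has an exact answer.

# Stamp filled disks of the given radii at (x, y) (0-based pixel coords)
# into a logical nr x nc mask. Vectorized by unique integer radius.
stamp_disks <- function(mask, xs, ys, radii) {
  nr <- nrow(mask); nc <- ncol(mask)
  rr <- pmax(0L, as.integer(round(radii)))
  cx <- as.integer(round(xs)) + 1L  # matrix col
  cy <- as.integer(round(ys)) + 1L  # matrix row
  for (r in sort(unique(rr))) {
    sel <- rr == r
    if (!any(sel)) next
    off <- expand.grid(dy = -r:r, dx = -r:r)
    off <- off[off$dx^2 + off$dy^2 <= r^2 + 0.25, , drop = FALSE]
    rows <- rep(cy[sel], each = nrow(off)) + off$dy
    cols <- rep(cx[sel], each = nrow(off)) + off$dx
    ok <- rows >= 1L & rows <= nr & cols >= 1L & cols <= nc
    mask[cbind(rows[ok], cols[ok])] <- TRUE
  }
  mask
}

# Per-leaf geometry: basal points, azimuths, lengths, widths, curvature.
# Blades arise from a basal clump whose radius grows with leaf count (a
# potted rice plant is a clump of tillers, not a single point), so in a
# top view most tips clear their neighbors, as in real imagery. Returns
# the tip position of every blade.
.blade_geometry <- function(n_leaves, g, treatment, center, scene) {
  width_mult <- if (treatment == "drought") 1 - g$rolling_factor else 1
  radial_mult <- 1 - 0.5 * g$erectness
  base_gap <- 2 * pi / n_leaves
  sparse_sep <- g$archetype %in% c("erect", "semi_erect") && n_leaves <= 15
  jitter_frac <- if (sparse_sep) 0.15 else 0.45

  azimuth <- 2 * pi * (seq_len(n_leaves) - 1) / n_leaves +
    stats::runif(n_leaves, -jitter_frac, jitter_frac) * base_gap +
    stats::runif(1, 0, 2 * pi)
  # basal clump: radius widens with tillering; each blade arises on the
  # side of the clump it points to (tillers fan outward), so blades do not
  # sweep back across the crown. In the sparse regime (young erect plants,
  # whose few blades diverge cleanly in a top view) bases sit exactly on
  # their blade's azimuth, so blades never cross.
  clump_r <- 5 + n_leaves / 5
  br <- clump_r * sqrt(stats::runif(n_leaves))
  bth <- azimuth +
    if (sparse_sep) 0 else stats::runif(n_leaves, -0.6, 0.6)
  base <- cbind(center[1] + br * cos(bth), center[2] + br * sin(bth))
  len <- g$leaf_len_px * radial_mult * stats::runif(n_leaves, 0.7, 1.3)
  # keep blades inside a margin of the frame where possible
  max_r <- min(scene$image_width_px, scene$image_height_px) / 2 -
    scene$box_size_px - clump_r
  len <- pmin(len, max_r)
  width <- pmax(1.5, g$leaf_width_px * width_mult * stats::runif(n_leaves, 0.85, 1.15))
  # erect genotypes hold blades straight; top-view curvature comes from
  # the drooping habit of spread/open types
  bend <- stats::runif(n_leaves, -0.2, 0.2) * (1 - g$erectness)
  # fraction of the blade projecting as a thin sheath trace: the proximal
  # part of an arching blade rises steeply and projects near-vertically in
  # a top view, so only the distal lamina shows at full width
  sheath_frac <- stats::runif(n_leaves, 0.25, 0.35)

  tip_of <- function(i, li) {
    th <- azimuth[i]
    c(base[i, 1] + li * cos(th) - bend[i] * li * sin(th),
      base[i, 2] + li * sin(th) + bend[i] * li * cos(th))
  }
  tips <- t(vapply(seq_len(n_leaves), function(i) tip_of(i, len[i]), numeric(2)))

  if (sparse_sep && n_leaves >= 2) {
    # guarantee the sparse-regime tip separation (>= box/2, enforced with
    # a margin so skeleton-endpoint localization jitter cannot collapse a
    # pair back under the radius) by radial staggering; deterministic,
    # bounded number of repair passes
    min_sep <- scene$box_size_px / 2 + 4
    for (pass in 1:25) {
      d <- as.matrix(stats::dist(tips)); diag(d) <- Inf
      bad <- which(d < min_sep, arr.ind = TRUE)
      if (nrow(bad) == 0) break
      i <- max(bad[1, ])
      len[i] <- max(len[i] * 0.88, g$leaf_len_px * radial_mult * 0.4)
      tips[i, ] <- tip_of(i, len[i])
    }
  }
  list(base = base, azimuth = azimuth, len = len, width = width,
       bend = bend, sheath_frac = sheath_frac, tips = tips)
}

#' Render a synthetic top-view rice plant with exact ground truth
#'
#' Draws the plant at the leaf count given by [leaf_count_trajectory()] for
#' the requested treatment and time snap. Every blade contributes exactly
#' one ground-truth tip (a fixed-size square box centered on the blade's
#' distal endpoint); tips of blades truncated at the image border are
#' clamped inside, never dropped, so the one-tip-per-leaf invariant holds
#' exactly. Identical arguments and seed reproduce a bit-identical image.
#'
#' @param g A [genotype_spec()].
#' @param treatment `"control"` or `"drought"`.
#' @param time_snap Integer in 1..5.
#' @param scene A [scene_spec()].
#' @param seed Integer seed (defaults to the genotype's own seed).
#' @param leaf_count Optional override of the trajectory leaf count
#'   (e.g. to render fixed-density evaluation suites); `NULL` uses the
#'   growth model.
#' @return An object of class `synthetic_plant`: list with `image`
#'   (height x width x 3 integer array, 0-255), `tips` (a [tip_set()] of
#'   ground truth), `silhouette` (pre-noise logical plant mask),
#'   `leaf_count`, `genotype_id`, `treatment`, `time_snap`, `height_cm`,
#'   `scene` and `seed`.
#' @export
render_plant <- function(g, treatment = c("control", "drought"),
                         time_snap = 1L, scene = scene_spec(),
                         seed = g$seed, leaf_count = NULL) {
  treatment <- match.arg(treatment)
  stopifnot(inherits(g, "genotype_spec"), inherits(scene, "scene_spec"))
  time_snap <- as.integer(time_snap)
  if (time_snap < 1L || time_snap > 5L) stop("`time_snap` must be in 1..5", call. = FALSE)
  n_leaves <- if (is.null(leaf_count)) {
    leaf_count_trajectory(g, treatment, time_snap)
  } else {
    as.integer(leaf_count)
  }
  if (n_leaves < 0L) stop("`leaf_count` must be >= 0", call. = FALSE)

  w <- scene$image_width_px; h <- scene$image_height_px
  image_id <- sprintf("%s_%s_TS%d", g$genotype_id, treatment, time_snap)

  with_seed(seed, {
    sil <- matrix(FALSE, h, w)
    tips_df <- data.frame(
      cx_px = numeric(0), cy_px = numeric(0),
      w_px = numeric(0), h_px = numeric(0), confidence = numeric(0)
    )
    center <- c((w - 1) / 2, (h - 1) / 2)

    if (n_leaves > 0) {
      geo <- .blade_geometry(n_leaves, g, treatment, center, scene)
      # culm/crown disk: covers the basal clump so every sheath is anchored
      culm_r <- max(4, 5 + n_leaves / 5 + 2)
      sil <- stamp_disks(sil, center[1], center[2], culm_r)
      for (i in seq_len(n_leaves)) {
        li <- geo$len[i]; th <- geo$azimuth[i]; b <- geo$bend[i]
        ts <- seq(0, 1, length.out = max(8L, ceiling(li * 1.6)))
        r <- ts * li
        px <- geo$base[i, 1] + r * cos(th) - b * r * ts * sin(th)
        py <- geo$base[i, 2] + r * sin(th) + b * r * ts * cos(th)
        # thin sheath trace proximally, tapered lamina distally, with a
        # smooth widening ramp between the two (no blunt shoulder)
        fs <- geo$sheath_frac[i]
        lam <- pmax(0, (ts - fs) / (1 - fs))
        lam_rad <- (geo$width[i] / 2) * (1 - 0.9 * lam)
        ramp <- pmin(1, lam / 0.15)
        rad <- pmax(0.4, 0.8 + ramp * (lam_rad - 0.8))
        sil <- stamp_disks(sil, px, py, rad)
        # ground-truth tip: distal centerline endpoint, clamped inside
        tips_df[i, ] <- c(
          clamp(px[length(px)], 0, w - 1),
          clamp(py[length(py)], 0, h - 1),
          scene$box_size_px, scene$box_size_px, 1
        )
      }
    }

    # colorize: background violates ExG, plant satisfies it, both strictly
    img <- array(0, dim = c(h, w, 3))
    img[, , 1] <- 110; img[, , 2] <- 95; img[, , 3] <- 100   # ExG = -20
    greens <- matrix(stats::runif(h * w, 130, 165), h, w)
    reds <- matrix(stats::runif(h * w, 55, 80), h, w)
    blues <- matrix(stats::runif(h * w, 40, 65), h, w)
    r_ch <- img[, , 1]; g_ch <- img[, , 2]; b_ch <- img[, , 3]
    r_ch[sil] <- reds[sil]; g_ch[sil] <- greens[sil]; b_ch[sil] <- blues[sil]
    img[, , 1] <- r_ch; img[, , 2] <- g_ch; img[, , 3] <- b_ch
    if (scene$background_noise_sd > 0) {
      img <- img + array(stats::rnorm(h * w * 3, 0, scene$background_noise_sd),
                         dim = c(h, w, 3))
    }
    img <- array(as.integer(round(clamp(img, 0, 255))), dim = c(h, w, 3))

    gf <- if (treatment == "drought") g$drought_emergence_factor else 1
    height_cm <- scene$cm_per_pixel * g$leaf_len_px *
      (0.6 + 0.4 * g$erectness) * (1 + 0.08 * (time_snap - 1) * gf)

    structure(
      list(
        image = img,
        tips = tip_set(tips_df, image_id = image_id,
                       image_width_px = w, image_height_px = h),
        silhouette = sil,
        leaf_count = n_leaves,
        genotype_id = g$genotype_id,
        treatment = treatment,
        time_snap = time_snap,
        height_cm = height_cm,
        scene = scene,
        seed = as.integer(seed)
      ),
      class = "synthetic_plant"
    )
  })
}

#' @export
print.synthetic_plant <- function(x, ...) {
  cat(sprintf(
    "<synthetic_plant> %s: %d leaves, %dx%d px, height %.1f cm\n",
    x$tips$image_id, x$leaf_count,
    x$scene$image_width_px, x$scene$image_height_px, x$height_cm
  ))
  invisible(x)
}

#' Write a synthetic plant to disk as PNG plus YOLO ground-truth labels
#'
#' @param plant A `synthetic_plant`.
#' @param dir Output directory (created if missing).
#' @param stem File basename (defaults to the plant's image id); the label
#'   file shares the basename with a `.txt` extension.
#' @return Invisibly, a character vector `c(image =, labels =)` of the
#'   written paths.
#' @export
write_plant <- function(plant, dir, stem = NULL) {
  stopifnot(inherits(plant, "synthetic_plant"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- stem %||% plant$tips$image_id
  img_path <- file.path(dir, paste0(stem, ".png"))
  lab_path <- file.path(dir, paste0(stem, ".txt"))
  png::writePNG(plant$image / 255, img_path)
  write_yolo_labels(plant$tips, lab_path)
  invisible(c(image = img_path, labels = lab_path))
}

#' Read an RGB image into the 0-255 array convention used by the pipeline
#'
#' @param path PNG or TIFF file.
#' @return height x width x 3 numeric array with values in 0..255.
#' @export
read_plant_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("package 'tiff' is required to read TIFF images", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE] * 255
}
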