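#' Tip detections or annotations for one image
#'
#' Coordinates are 0-based continuous pixel units, x rightward and y
#' downward, box centers at (`cx_px`, `cy_px`). Ground-truth boxes are
#' fixed-size squares (`w_px == h_px`), matching the annotation convention
#' in which the tip is centered in a small square bounding box.
#'
#' @param tips Data frame with columns `cx_px`, `cy_px`, `w_px`, `h_px`,
#'   `confidence` (one row per tip; zero rows allowed).
#' @param image_id Identifier of the source image.
#' @param image_width_px,image_height_px Image dimensions in pixels.
#' @return An object of class `tip_set`.
#' @export
tip_set <- function(tips = data.frame(cx_px = numeric(0), cy_px = numeric(0),
                                      w_px = numeric(0), h_px = numeric(0),
                                      confidence = numeric(0)),
                    image_id = "image", image_width_px, image_height_px) {
  need <- c("cx_px", "cy_px", "w_px", "h_px", "confidence")
  if (!all(need %in% names(tips))) {
    stop("`tips` must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  tips <- as.data.frame(tips)[need]
  if (nrow(tips) > 0) {
    if (any(tips$cx_px < 0 | tips$cx_px >= image_width_px |
            tips$cy_px < 0 | tips$cy_px >= image_height_px)) {
      stop("tip centers must lie inside the image bounds", call. = FALSE)
    }
    if (any(tips$confidence < 0 | tips$confidence > 1)) {
      stop("`confidence` must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(
      image_id = as.character(image_id),
      image_width_px = as.integer(image_width_px),
      image_height_px = as.integer(image_height_px),
      tips = tips
    ),
    class = "tip_set"
  )
}

#' @export
print.tip_set <- function(x, ...) {
  cat(sprintf("<tip_set> %s: %d tips on %dx%d px\n",
              x$image_id, nrow(x$tips), x$image_width_px, x$image_height_px))
  invisible(x)
}

#' Number of leaves in a tip set
#'
#' Under the one-tip-per-leaf hypothesis the leaf count of a plant equals
#' the number of detected leaf tips.
#'
#' @param tips A [tip_set()].
#' @return Integer leaf count.
#' @export
count_leaves <- function(tips) {
  stopifnot(inherits(tips, "tip_set"))
  nrow(tips$tips)
}

# Endpoints of a 0/1 skeleton: pixels with exactly one foreground
# 8-neighbor. Returns a matrix of (row, col) 1-based indices.
.skeleton_endpoints <- function(m) {
  nb <- neighbor_count(m)
  which(m == 1 & nb == 1, arr.ind = TRUE)
}

# Remove spurs shorter than prune_len (strictly): from each endpoint, walk
# along the skeleton; if a branch point is met in fewer than prune_len
# steps, the walked pixels are deleted. Branch points are identified by
# crossing number (>= 3 0->1 transitions around the pixel), which is
# robust to the staircase corners of 8-connected curves, where a plain
# neighbor count would see a spurious junction.
#
# Terminal branches are removed shortest-first with local reassessment:
# when a one-pixel artifact prong forks a blade just behind its true tip,
# removing the prong first dissolves the junction, so the walk from the
# true tip then continues through it and the tip survives. Removing the
# longer branch first would instead leave a blunt cap with no endpoint.
.prune_spurs <- function(m, prune_len) {
  if (prune_len < 1) return(m)
  # 4-neighbors first, so curve walking prefers them over diagonal shortcuts
  nbr_off <- cbind(
    dr = c(-1, 1, 0, 0, -1, -1, 1, 1),
    dc = c(0, 0, -1, 1, -1, 1, -1, 1)
  )
  nb <- neighbor_count(m)
  tr <- .transitions(m)

  walk <- function(ep) {
    path <- matrix(ep, ncol = 2)
    cur <- ep
    for (step in seq_len(max(prune_len - 1L, 0L))) {
      cand <- sweep(nbr_off, 2, as.integer(cur), `+`)
      keep <- cand[, 1] >= 1 & cand[, 1] <= nrow(m) &
        cand[, 2] >= 1 & cand[, 2] <= ncol(m)
      cand <- cand[keep, , drop = FALSE]
      fg <- cand[m[cand] == 1, , drop = FALSE]
      visited <- paste(path[, 1], path[, 2])
      fg <- fg[!(paste(fg[, 1], fg[, 2]) %in% visited), , drop = FALSE]
      if (nrow(fg) == 0) return(list(spur = FALSE))  # isolated segment: keep
      if (any(tr[fg] >= 3)) return(list(spur = TRUE, path = path))
      nxt <- fg[1, ]
      path <- rbind(path, nxt)
      cur <- nxt
    }
    list(spur = FALSE)
  }

  refresh <- function(path) {
    # recompute nb/tr on a window around deleted pixels
    r0 <- max(1L, min(path[, 1]) - 2L); r1 <- min(nrow(m), max(path[, 1]) + 2L)
    c0 <- max(1L, min(path[, 2]) - 2L); c1 <- min(ncol(m), max(path[, 2]) + 2L)
    rr0 <- max(1L, r0 - 1L); rr1 <- min(nrow(m), r1 + 1L)
    cc0 <- max(1L, c0 - 1L); cc1 <- min(ncol(m), c1 + 1L)
    sub <- m[rr0:rr1, cc0:cc1, drop = FALSE]
    ir <- (r0:r1) - rr0 + 1L; ic <- (c0:c1) - cc0 + 1L
    nb[r0:r1, c0:c1] <<- neighbor_count(sub)[ir, ic]
    tr[r0:r1, c0:c1] <<- .transitions(sub)[ir, ic]
  }

  eps <- which(m == 1 & nb == 1, arr.ind = TRUE)
  if (nrow(eps) == 0) return(m)
  first <- lapply(seq_len(nrow(eps)), function(k) walk(eps[k, ]))
  len0 <- vapply(first, function(x) if (x$spur) nrow(x$path) else Inf, numeric(1))
  for (k in order(len0)) {
    if (!is.finite(len0[k])) next
    if (m[eps[k, 1], eps[k, 2]] == 0) next  # consumed by an earlier removal
    res <- walk(eps[k, ])                   # re-walk with the current state
    if (res$spur) {
      m[res$path] <- 0L
      refresh(res$path)
    }
  }
  m
}

#' Detect leaf tips as skeleton endpoints
#'
#' An endpoint is a skeleton pixel with exactly one 8-neighbor on the
#' skeleton. Spurs shorter than `prune_len_px` (thinning artifacts) are
#' removed first; surviving endpoints closer than `merge_radius_px` are
#' merged to their centroid (the surrogate for detector non-max
#' suppression); endpoints within `culm_exclusion_px` of the foreground
#' centroid can optionally be discarded, since the culm area is too crowded
#' for tip counting. Each surviving endpoint is emitted as a fixed-size
#' square box with confidence 1.
#'
#' @param skeleton One-pixel-wide skeleton from [skeletonize_mask()].
#' @param prune_len_px Spur-length threshold in pixels (default 8).
#' @param merge_radius_px Endpoint merge radius (default 8, half the
#'   ground-truth box edge).
#' @param culm_exclusion_px Radius around the skeleton centroid within which
#'   endpoints are dropped; 0 (default) disables the exclusion.
#' @param box_size_px Emitted box edge (default 16).
#' @param image_id Identifier stored on the result.
#' @return A [tip_set()] of detections.
#' @export
detect_tips <- function(skeleton, prune_len_px = 8L, merge_radius_px = 8,
                        culm_exclusion_px = 0, box_size_px = 16L,
                        image_id = "image") {
  m <- matrix(as.integer(skeleton != 0), nrow(skeleton), ncol(skeleton))
  if (!is_one_px_wide(m)) {
    stop("`skeleton` is not one pixel wide; run skeletonize_mask() first",
         call. = FALSE)
  }
  h <- nrow(m); w <- ncol(m)
  m <- .prune_spurs(m, prune_len_px)
  eps <- .skeleton_endpoints(m)

  pts <- if (nrow(eps) == 0) {
    matrix(numeric(0), ncol = 2)
  } else {
    # matrix (row, col) 1-based -> (x, y) 0-based
    cbind(x = eps[, 2] - 1, y = eps[, 1] - 1)
  }

  if (nrow(pts) >= 2 && merge_radius_px > 0) {
    # complete linkage: a group is merged only if its endpoints are all
    # within the merge radius of each other (no single-linkage chaining)
    grp <- stats::cutree(
      stats::hclust(stats::dist(pts), method = "complete"),
      h = merge_radius_px
    )
    pts <- do.call(rbind, lapply(split(seq_len(nrow(pts)), grp), function(i) {
      colMeans(pts[i, , drop = FALSE])
    }))
  }

  if (nrow(pts) >= 1 && culm_exclusion_px > 0) {
    fg <- which(m == 1, arr.ind = TRUE)
    if (nrow(fg) > 0) {
      cen <- c(mean(fg[, 2]) - 1, mean(fg[, 1]) - 1)
      d <- sqrt((pts[, 1] - cen[1])^2 + (pts[, 2] - cen[2])^2)
      pts <- pts[d >= culm_exclusion_px, , drop = FALSE]
    }
  }

  tip_set(
    data.frame(
      cx_px = clamp(pts[, 1], 0, w - 1),
      cy_px = clamp(pts[, 2], 0, h - 1),
      w_px = rep(box_size_px, nrow(pts)),
      h_px = rep(box_size_px, nrow(pts)),
      confidence = rep(1, nrow(pts))
    ),
    image_id = image_id, image_width_px = w, image_height_px = h
  )
}

#' Read and write YOLO-format tip label files
#'
#' The YOLO txt dialect stores one object per line as
#' `class cx cy w h` with center coordinates and box dimensions normalized
#' to `[0, 1]` by the image dimensions. Only class 0 (leaf tip) is valid:
#' lines with another class are skipped with a warning; lines with
#' out-of-range coordinates raise an error. `write_yolo_labels()` uses a
#' fixed 6-decimal format, so write-then-read round-trips to 1e-6.
#'
#' @param path Label file path.
#' @param image_width_px,image_height_px Pixel dimensions of the image the
#'   labels refer to (YOLO files do not store them).
#' @param image_id Identifier stored on the result (defaults to the file
#'   basename).
#' @return `read_yolo_labels()`: a [tip_set()].
#' @export
read_yolo_labels <- function(path, image_width_px, image_height_px,
                             image_id = tools::file_path_sans_ext(basename(path))) {
  lines <- if (file.exists(path)) readLines(path, warn = FALSE) else {
    stop("label file not found: ", path, call. = FALSE)
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "[[:space:]]+")[[1]]
    if (length(f) != 5L) {
      stop(sprintf("line %d of %s: expected 5 fields, got %d", i, path, length(f)),
           call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) stop(sprintf("line %d of %s: non-numeric field", i, path), call. = FALSE)
    if (v[1] != 0) {
      warning(sprintf("line %d of %s: class %s is not a leaf tip, skipped",
                      i, path, f[1]), call. = FALSE)
      return(NULL)
    }
    if (any(v[2:5] < 0 | v[2:5] > 1)) {
      stop(sprintf("line %d of %s: normalized coordinate out of [0, 1]", i, path),
           call. = FALSE)
    }
    v
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(tip_set(image_id = image_id, image_width_px = image_width_px,
                   image_height_px = image_height_px))
  }
  m <- do.call(rbind, rows)
  tip_set(
    data.frame(
      cx_px = clamp(m[, 2] * image_width_px, 0, image_width_px - 1e-9),
      cy_px = clamp(m[, 3] * image_height_px, 0, image_height_px - 1e-9),
      w_px = m[, 4] * image_width_px,
      h_px = m[, 5] * image_height_px,
      confidence = rep(1, nrow(m))
    ),
    image_id = image_id, image_width_px = image_width_px,
    image_height_px = image_height_px
  )
}

#' @rdname read_yolo_labels
#' @param tips A [tip_set()] to serialize.
#' @return `write_yolo_labels()`: the path, invisibly.
#' @export
write_yolo_labels <- function(tips, path) {
  stopifnot(inherits(tips, "tip_set"))
  df <- tips$tips
  lines <- sprintf(
    "0 %.6f %.6f %.6f %.6f",
    df$cx_px / tips$image_width_px,
    df$cy_px / tips$image_height_px,
    df$w_px / tips$image_width_px,
    df$h_px / tips$image_height_px
  )
  writeLines(lines, path)
  invisible(path)
}
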