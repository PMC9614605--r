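#' Convex hull of 2-D points (monotone chain)
#'
#' Computes the convex hull of the tip coordinates with the Andrew monotone
#' chain algorithm. Vertices are returned in counter-clockwise order (for a
#' y-up frame; on image coordinates with y downward the same cyclic order
#' reads clockwise on screen) with no three collinear vertices retained.
#' Degenerate input (fewer than 3 distinct points, or all collinear)
#' returns the extreme pair or single point.
#'
#' @param points Two-column matrix or data frame of (x, y) coordinates.
#' @return Two-column matrix of hull vertices.
#' @export
convex_hull <- function(points) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  if (nrow(pts) == 0) stop("`points` must contain at least one point", call. = FALSE)
  storage.mode(pts) <- "double"
  pts <- unique(pts)
  ord <- order(pts[, 1], pts[, 2])
  pts <- pts[ord, , drop = FALSE]
  n <- nrow(pts)
  if (n == 1) return(pts)
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  build <- function(idx) {
    st <- integer(0)
    for (i in idx) {
      while (length(st) >= 2 &&
             cross(pts[st[length(st) - 1], ], pts[st[length(st)], ], pts[i, ]) <= 0) {
        st <- st[-length(st)]
      }
      st <- c(st, i)
    }
    st
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  hull <- c(lower[-length(lower)], upper[-length(upper)])
  if (length(hull) < 3) {
    # collinear: degenerate hull is the extreme pair
    return(pts[c(1, n), , drop = FALSE])
  }
  pts[hull, , drop = FALSE]
}

#' Convex hull area (CHA)
#'
#' Shoelace polygon area of the hull vertices, converted from px^2 to cm^2.
#' Degenerate hulls (point or segment) have area 0.
#'
#' @param vertices Hull vertices from [convex_hull()].
#' @param cm_per_pixel Optical scale.
#' @return Area in cm^2.
#' @export
hull_area <- function(vertices, cm_per_pixel = 1) {
  v <- as.matrix(vertices)
  if (nrow(v) < 3) return(0)
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2 * cm_per_pixel^2
}

#' Bounding box area (BBA), plant width and length
#'
#' Axis-aligned extent of the tip coordinates (or of a mask's foreground).
#' Width is the x-extent and length the y-extent of the top view; the two
#' can be swapped with `swap_axes` since the orientation convention for a
#' top view is a modeling choice.
#'
#' @param points Two-column matrix of (x, y) coordinates, or a `plant_mask`.
#' @param cm_per_pixel Optical scale.
#' @param swap_axes Swap the width/length roles.
#' @return Named list `bba_cm2`, `width_cm`, `length_cm`.
#' @export
bounding_box_area <- function(points, cm_per_pixel = 1, swap_axes = FALSE) {
  if (inherits(points, "plant_mask") || (is.matrix(points) && is.logical(points))) {
    fg <- which(points != 0, arr.ind = TRUE)
    if (nrow(fg) == 0) stop("empty mask has no bounding box", call. = FALSE)
    pts <- cbind(fg[, 2] - 1, fg[, 1] - 1)
  } else {
    pts <- as.matrix(points)[, 1:2, drop = FALSE]
    if (nrow(pts) == 0) stop("`points` must be non-empty", call. = FALSE)
  }
  width <- diff(range(pts[, 1])) * cm_per_pixel
  length_ <- diff(range(pts[, 2])) * cm_per_pixel
  if (swap_axes) { tmp <- width; width <- length_; length_ <- tmp }
  list(bba_cm2 = width * length_, width_cm = width, length_cm = length_)
}

#' Plant aspect ratio (PAR)
#'
#' Ratio of plant width to length; proxies canopy spread vs erectness from
#' the top view. A zero length yields `NA` with an `undefined` attribute
#' rather than an error.
#'
#' @param width_cm,length_cm Plant extents.
#' @return The ratio, or flagged `NA` when undefined.
#' @export
plant_aspect_ratio <- function(width_cm, length_cm) {
  if (length_cm == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  width_cm / length_cm
}

#' Number of leaves per convex hull area (NLPCHA)
#'
#' Canopy-density trait: leaf count divided by the hull area. A zero hull
#' area with a positive leaf count is flagged undefined; zero leaves give 0.
#'
#' @param nl Leaf count (>= 0).
#' @param cha_cm2 Convex hull area in cm^2 (>= 0).
#' @return Leaves per cm^2, or flagged `NA` when undefined.
#' @export
leaves_per_hull <- function(nl, cha_cm2) {
  if (nl < 0 || cha_cm2 < 0) stop("`nl` and `cha_cm2` must be >= 0", call. = FALSE)
  if (nl == 0) return(0)
  if (cha_cm2 == 0) return(structure(NA_real_, undefined = TRUE))
  nl / cha_cm2
}

#' Plant height from a side-view mask
#'
#' Height is the distance from the pot baseline row up to the topmost
#' foreground row, in cm. An empty mask has height 0.
#'
#' @param side_mask A `plant_mask` from the side view.
#' @param baseline_row 1-based row index of the pot rim / soil line.
#' @param cm_per_pixel Optical scale.
#' @return Height in cm.
#' @export
plant_height <- function(side_mask, baseline_row, cm_per_pixel = 1) {
  if (baseline_row < 1 || baseline_row > nrow(side_mask)) {
    stop("`baseline_row` must be a row of the mask", call. = FALSE)
  }
  fg_rows <- which(rowSums(side_mask != 0) > 0)
  if (length(fg_rows) == 0) return(0)
  max(0, (baseline_row - min(fg_rows)) * cm_per_pixel)
}

#' Plant elongation rate (PER)
#'
#' Least-squares slope of plant height against time snap, in cm per snap.
#'
#' @param time_snaps Strictly increasing time snaps (>= 2 values).
#' @param heights_cm Heights matching `time_snaps`.
#' @return Slope in cm/snap.
#' @export
elongation_rate <- function(time_snaps, heights_cm) {
  if (length(time_snaps) < 2 || length(heights_cm) != length(time_snaps)) {
    stop("need >= 2 paired (time_snap, height) observations", call. = FALSE)
  }
  if (is.unsorted(time_snaps, strictly = TRUE)) {
    stop("`time_snaps` must be strictly increasing", call. = FALSE)
  }
  unname(stats::coef(stats::lm(heights_cm ~ time_snaps))[2])
}

#' Assemble the per-plant i-trait record from tip coordinates
#'
#' Computes NL, CHA, BBA, PAR and NLPCHA from a tip set (the hull is taken
#' over tip centers, the protocol under which a detector's tip coordinates
#' are the only geometry available), with pixel-to-cm scaling.
#'
#' @param tips A [tip_set()].
#' @param cm_per_pixel Optical scale.
#' @param genotype_id,treatment,time_snap,height_cm Optional metadata
#'   carried into the record.
#' @param swap_axes Passed to [bounding_box_area()].
#' @return One-row data frame with columns `genotype_id`, `treatment`,
#'   `time_snap`, `NL`, `CHA_cm2`, `BBA_cm2`, `PAR`, `NLPCHA_per_cm2`,
#'   `width_cm`, `length_cm`, `height_cm`.
#' @export
trait_record <- function(tips, cm_per_pixel,
                         genotype_id = NA_character_,
                         treatment = NA_character_,
                         time_snap = NA_integer_,
                         height_cm = NA_real_,
                         swap_axes = FALSE) {
  stopifnot(inherits(tips, "tip_set"))
  nl <- count_leaves(tips)
  if (nl == 0) {
    cha <- 0; bb <- list(bba_cm2 = 0, width_cm = 0, length_cm = 0)
    par_ <- NA_real_; nlpcha <- 0
  } else {
    pts <- as.matrix(tips$tips[, c("cx_px", "cy_px")])
    cha <- hull_area(convex_hull(pts), cm_per_pixel)
    bb <- if (nl == 1) {
      list(bba_cm2 = 0, width_cm = 0, length_cm = 0)
    } else {
      bounding_box_area(pts, cm_per_pixel, swap_axes)
    }
    par_ <- as.numeric(plant_aspect_ratio(bb$width_cm, bb$length_cm))
    nlpcha <- as.numeric(leaves_per_hull(nl, cha))
  }
  data.frame(
    genotype_id = genotype_id, treatment = treatment,
    time_snap = as.integer(time_snap),
    NL = nl, CHA_cm2 = cha, BBA_cm2 = bb$bba_cm2, PAR = par_,
    NLPCHA_per_cm2 = nlpcha,
    width_cm = bb$width_cm, length_cm = bb$length_cm,
    height_cm = height_cm,
    stringsAsFactors = FALSE
  )
}
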