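#' Segment the plant from a top-view RGB image by excess green
#'
#' Foreground is the set of pixels whose excess-green index
#' `ExG = 2G - R - B` exceeds `exg_threshold`, after removal of connected
#' components smaller than `min_area_px` (speckle noise). This classical
#' vegetation-index segmentation needs no learned model and is exact on the
#' synthetic scenes, whose plant pixels satisfy `ExG > 0` by construction.
#'
#' @param image RGB array (height x width x 3), values on any common scale.
#' @param exg_threshold Threshold on `2G - R - B`; default 0.
#' @param min_area_px Minimum connected-component area kept; default 20.
#' @return A `plant_mask`: logical matrix with the image's dimensions,
#'   `TRUE` on the plant.
#' @export
segment_plant <- function(image, exg_threshold = 0, min_area_px = 20L) {
  if (length(dim(image)) != 3L || dim(image)[3] < 3L) {
    stop("`image` must be an RGB array (height x width x 3)", call. = FALSE)
  }
  exg <- 2 * image[, , 2, drop = TRUE] - image[, , 1, drop = TRUE] -
    image[, , 3, drop = TRUE]
  exg <- matrix(exg, dim(image)[1], dim(image)[2])
  mask <- exg > exg_threshold
  if (min_area_px > 1L && any(mask)) {
    memb <- .label8(mask)
    sizes <- tabulate(memb$membership)
    drop <- sizes[memb$membership] < min_area_px
    mask[memb$idx[drop]] <- FALSE
  }
  structure(mask, class = c("plant_mask", "matrix", "array"))
}

# Exact 8-connected component labeling of a logical matrix, via the pixel
# adjacency graph (1-px diagonal runs are single components, unlike the
# labeling of common 4-connected labelers).
.label8 <- function(mask) {
  idx <- which(mask)
  id <- matrix(0L, nrow(mask), ncol(mask))
  id[idx] <- seq_along(idx)
  edges <- integer(0)
  for (sh in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    nbr <- shift_mat(id, sh[1], sh[2])
    sel <- id > 0L & nbr > 0L
    if (any(sel)) edges <- c(edges, rbind(id[sel], nbr[sel]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  list(idx = idx, membership = igraph::components(g)$membership)
}

as_plant_mask <- function(m) {
  stopifnot(is.matrix(m))
  structure(m != 0, class = c("plant_mask", "matrix", "array"))
}
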