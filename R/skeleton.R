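# Zhang-Suen topological thinning, fully vectorized over the image.
#
# Each iteration flags deletable contour pixels in two sub-iterations using
# the classic conditions on the 8-neighborhood sequence P2..P9 (clockwise
# from north): 2 <= B(P1) <= 6 foreground neighbors, exactly one 0->1
# transition A(P1) == 1, and the directional products that bias deletion to
# alternate sides. Deletion preserves connectivity, so the skeleton keeps
# one component per mask component.

.thin_pass <- function(m, sub) {
  # neighbor layout (dr, dc): P2=N, P3=NE, P4=E, P5=SE, P6=S, P7=SW, P8=W, P9=NW
  p2 <- shift_mat(m, -1, 0);  p3 <- shift_mat(m, -1, 1)
  p4 <- shift_mat(m, 0, 1);   p5 <- shift_mat(m, 1, 1)
  p6 <- shift_mat(m, 1, 0);   p7 <- shift_mat(m, 1, -1)
  p8 <- shift_mat(m, 0, -1);  p9 <- shift_mat(m, -1, -1)
  b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
       (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
       (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
  cond <- if (sub == 1L) {
    (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
  } else {
    (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
  }
  del <- m == 1 & b >= 2 & b <= 6 & a == 1 & cond
  m[del] <- 0L
  list(m = m, changed = any(del))
}

# 0->1 transition count around each pixel (used by the 2x2 cleanup).
.transitions <- function(m) {
  p2 <- shift_mat(m, -1, 0);  p3 <- shift_mat(m, -1, 1)
  p4 <- shift_mat(m, 0, 1);   p5 <- shift_mat(m, 1, 1)
  p6 <- shift_mat(m, 1, 0);   p7 <- shift_mat(m, 1, -1)
  p8 <- shift_mat(m, 0, -1);  p9 <- shift_mat(m, -1, -1)
  (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
    (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
    (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
}

# TRUE when pixel (r, c) can be deleted without breaking connectivity:
# after deletion, every pair of its foreground 8-neighbors must stay
# connected within a (2*rad+1)-square window BFS.
.deletable_in_window <- function(m, r, c, rad = 7L) {
  nbrs <- expand.grid(dr = -1:1, dc = -1:1)
  nbrs <- nbrs[!(nbrs$dr == 0 & nbrs$dc == 0), ]
  nr <- r + nbrs$dr; nc_ <- c + nbrs$dc
  ok <- nr >= 1 & nr <= nrow(m) & nc_ >= 1 & nc_ <= ncol(m)
  nr <- nr[ok]; nc_ <- nc_[ok]
  fg <- m[cbind(nr, nc_)] == 1
  if (sum(fg) <= 1) return(FALSE)  # endpoint or isolated: keep
  r0 <- max(1L, r - rad); r1 <- min(nrow(m), r + rad)
  c0 <- max(1L, c - rad); c1 <- min(ncol(m), c + rad)
  win <- m[r0:r1, c0:c1]
  win[r - r0 + 1L, c - c0 + 1L] <- 0L
  # BFS from the first neighbor, must reach all the others
  seeds <- cbind(nr[fg] - r0 + 1L, nc_[fg] - c0 + 1L)
  reach <- matrix(FALSE, nrow(win), ncol(win))
  frontier <- seeds[1, , drop = FALSE]
  reach[frontier] <- TRUE
  off <- as.matrix(nbrs)
  while (nrow(frontier) > 0) {
    cand <- do.call(rbind, lapply(seq_len(nrow(off)), function(k) {
      cbind(frontier[, 1] + off[k, 1], frontier[, 2] + off[k, 2])
    }))
    keep <- cand[, 1] >= 1 & cand[, 1] <= nrow(win) &
      cand[, 2] >= 1 & cand[, 2] <= ncol(win)
    cand <- cand[keep, , drop = FALSE]
    cand <- cand[win[cand] == 1 & !reach[cand], , drop = FALSE]
    if (nrow(cand) == 0) break
    cand <- unique(cand)
    reach[cand] <- TRUE
    frontier <- cand
  }
  all(reach[seeds])
}

#' Thin a binary plant mask to a one-pixel-wide medial skeleton
#'
#' Topology-preserving thinning: the skeleton is a subset of the mask,
#' 8-connected, and keeps the mask's connected-component count. A final
#' sequential cleanup removes redundant pixels from any residual fully-set
#' 2x2 block (a pixel is removed only if it is 8-simple, i.e. exactly one
#' 0->1 transition around it, so connectivity is never broken), ensuring
#' the strict one-pixel-wide contract the endpoint detector relies on.
#'
#' @param mask A `plant_mask` (or any logical/0-1 matrix).
#' @return A `plant_mask` holding the skeleton.
#' @export
skeletonize_mask <- function(mask) {
  m0 <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (!any(m0 == 1)) return(as_plant_mask(m0))
  # thin on the mask's bounding box (plus margin) only
  fg <- which(m0 == 1, arr.ind = TRUE)
  r0 <- max(1L, min(fg[, 1]) - 2L); r1 <- min(nrow(m0), max(fg[, 1]) + 2L)
  c0 <- max(1L, min(fg[, 2]) - 2L); c1 <- min(ncol(m0), max(fg[, 2]) + 2L)
  m <- m0[r0:r1, c0:c1, drop = FALSE]
  repeat {
    s1 <- .thin_pass(m, 1L); m <- s1$m
    s2 <- .thin_pass(m, 2L); m <- s2$m
    if (!s1$changed && !s2$changed) break
  }
  # Sequential cleanup of fully-set 2x2 blocks. Zhang-Suen leaves such
  # blocks at X-crossings of blades, where no pixel is locally simple
  # (crossing number 2 all around). A block pixel is removed only if its
  # foreground neighbors remain mutually connected in a local window after
  # deletion, so topology is provably preserved; one removal per pass.
  repeat {
    blk <- m == 1 & shift_mat(m, 0, 1) == 1 & shift_mat(m, 1, 0) == 1 &
      shift_mat(m, 1, 1) == 1
    idx <- which(blk)
    if (length(idx) == 0) break
    removed_any <- FALSE
    for (i in idx) {
      rc <- arrayInd(i, dim(m))  # anchor is the block's bottom-right pixel
      for (dr in -1:0) {
        for (dc in -1:0) {
          r <- rc[1] + dr; c <- rc[2] + dc
          if (m[r, c] == 1 && .deletable_in_window(m, r, c)) {
            m[r, c] <- 0L
            removed_any <- TRUE
            break
          }
        }
        if (removed_any) break
      }
      if (removed_any) break
    }
    if (!removed_any) break  # give up rather than break topology
  }
  out <- matrix(0L, nrow(m0), ncol(m0))
  out[r0:r1, c0:c1] <- m
  as_plant_mask(out)
}

#' @rdname skeletonize_mask
#' @param skeleton Candidate skeleton matrix.
#' @return `is_one_px_wide()`: `TRUE` when the skeleton contains no
#'   fully-set 2x2 block.
#' @export
is_one_px_wide <- function(skeleton) {
  m <- matrix(as.integer(skeleton != 0), nrow(skeleton), ncol(skeleton))
  !any(m == 1 & shift_mat(m, 0, 1) == 1 & shift_mat(m, 1, 0) == 1 &
         shift_mat(m, 1, 1) == 1)
}
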