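# Independent oracles used to cross-check the package's geometry and
# matching code. These deliberately use different algorithms from the
# implementations they verify.

# Jarvis gift-wrapping convex hull: returns the hull vertex coordinates
# (order unspecified; compare as sets).
gift_wrap_hull <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n <= 2) return(pts)
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  start <- which.min(pts[, 1] + 1e-12 * pts[, 2])
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    nxt <- if (cur == 1L) 2L else 1L
    for (j in seq_len(n)) {
      if (j == cur || j == nxt) next
      cr <- cross(pts[cur, ], pts[nxt, ], pts[j, ])
      if (cr < 0 ||
          (cr == 0 && sum((pts[j, ] - pts[cur, ])^2) >
             sum((pts[nxt, ] - pts[cur, ])^2))) {
        nxt <- j
      }
    }
    cur <- nxt
    if (cur == start || length(hull) > n) break
  }
  pts[hull, , drop = FALSE]
}

# Polygon area by fan triangulation from the first vertex.
fan_triangulation_area <- function(v) {
  v <- as.matrix(v)
  if (nrow(v) < 3) return(0)
  a <- 0
  for (i in 2:(nrow(v) - 1)) {
    a <- a + abs(
      (v[i, 1] - v[1, 1]) * (v[i + 1, 2] - v[1, 2]) -
        (v[i, 2] - v[1, 2]) * (v[i + 1, 1] - v[1, 1])
    ) / 2
  }
  a
}

# Exhaustive maximum bipartite matching between pred and gt points under a
# distance cap; returns the maximum number of matched pairs. Feasible for
# small instances only.
optimal_match_count <- function(pred, gt, tau) {
  np <- nrow(pred); ng <- nrow(gt)
  if (np == 0 || ng == 0) return(0L)
  d <- sqrt(outer(pred[, 1], gt[, 1], "-")^2 + outer(pred[, 2], gt[, 2], "-")^2)
  ok <- d <= tau
  best <- 0L
  rec <- function(i, used, count) {
    if (count + (np - i + 1) <= best) return()
    if (i > np) { best <<- max(best, count); return() }
    rec(i + 1L, used, count)            # leave pred i unmatched
    for (j in which(ok[i, ] & !used)) {
      used2 <- used; used2[j] <- TRUE
      rec(i + 1L, used2, count + 1L)
    }
  }
  rec(1L, logical(ng), 0L)
  best
}

# 8-connected component count of a logical/0-1 matrix, by BFS.
count_components8 <- function(m) {
  m <- m != 0
  seen <- matrix(FALSE, nrow(m), ncol(m))
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  n <- 0L
  todo <- which(m & !seen, arr.ind = TRUE)
  while (nrow(todo) > 0) {
    n <- n + 1L
    frontier <- todo[1, , drop = FALSE]
    seen[frontier] <- TRUE
    while (nrow(frontier) > 0) {
      cand <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k) {
        cbind(frontier[, 1] + offs$dr[k], frontier[, 2] + offs$dc[k])
      }))
      keep <- cand[, 1] >= 1 & cand[, 1] <= nrow(m) &
        cand[, 2] >= 1 & cand[, 2] <= ncol(m)
      cand <- unique(cand[keep, , drop = FALSE])
      cand <- cand[m[cand] & !seen[cand], , drop = FALSE]
      seen[cand] <- TRUE
      frontier <- cand
    }
    todo <- which(m & !seen, arr.ind = TRUE)
  }
  n
}

# Quick tip_set builder for tests.
make_tips <- function(xy, w = 640, h = 640, box = 16) {
  xy <- matrix(xy, ncol = 2)
  if (nrow(xy) == 0) {
    return(tip_set(image_id = "test", image_width_px = w, image_height_px = h))
  }
  tip_set(
    data.frame(cx_px = xy[, 1], cy_px = xy[, 2],
               w_px = box, h_px = box, confidence = 1),
    image_id = "test", image_width_px = w, image_height_px = h
  )
}
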