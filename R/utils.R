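#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. All stochastic generator functions route through this so
# their outputs are pure functions of (arguments, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shift a matrix by (dr, dc), zero-padding the vacated border. Used by the
# vectorized thinning and neighbor-count kernels.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  ok_r <- rs >= 1L & rs <= nr
  ok_c <- cs >= 1L & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# Count of foreground 8-neighbors at every pixel of a 0/1 matrix.
neighbor_count <- function(m) {
  shift_mat(m, -1, 0) + shift_mat(m, -1, 1) + shift_mat(m, 0, 1) +
    shift_mat(m, 1, 1) + shift_mat(m, 1, 0) + shift_mat(m, 1, -1) +
    shift_mat(m, 0, -1) + shift_mat(m, -1, -1)
}
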