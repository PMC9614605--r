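#' Descriptive statistics for a trait table
#'
#' One row per trait column with min, max, mean, sample standard deviation
#' (n - 1 denominator) and the coefficient of variation
#' `CV = 100 * std / mean`. A zero-mean column has its CV flagged `NA`.
#' Full precision is retained; round on export if a fixed number of
#' decimals is wanted.
#'
#' @param table Data frame; all numeric columns (or those named in
#'   `traits`) are summarized.
#' @param traits Optional character vector of column names.
#' @return Data frame with columns `trait_name`, `min`, `max`, `mean`,
#'   `std`, `cv_percent`.
#' @export
descriptive_stats <- function(table, traits = NULL) {
  cols <- traits %||% names(table)[vapply(table, is.numeric, logical(1))]
  rows <- lapply(cols, function(cn) {
    x <- table[[cn]]
    if (!is.numeric(x)) stop("column `", cn, "` is not numeric", call. = FALSE)
    x <- x[!is.na(x)]
    if (length(x) < 2) stop("column `", cn, "` needs >= 2 observations", call. = FALSE)
    m <- mean(x); s <- stats::sd(x)
    data.frame(
      trait_name = cn, min = min(x), max = max(x), mean = m, std = s,
      cv_percent = if (m == 0) NA_real_ else cv_percent(m, s),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Coefficient of variation from a mean/std pair
#'
#' @param mean,std Summary statistics of a trait.
#' @return `100 * std / mean`.
#' @export
cv_percent <- function(mean, std) 100 * std / mean

#' Pearson correlation matrix over trait columns
#'
#' Product-moment correlations on pairwise-complete observations.
#' Zero-variance columns yield `NA` entries with a warning rather than an
#' error.
#'
#' @param table Data frame of numeric trait columns.
#' @param traits Optional subset of column names.
#' @return Correlation matrix.
#' @export
pearson_corr <- function(table, traits = NULL) {
  cols <- traits %||% names(table)[vapply(table, is.numeric, logical(1))]
  m <- as.matrix(table[cols])
  zero_var <- apply(m, 2, function(x) stats::var(x, na.rm = TRUE)) == 0
  if (any(zero_var)) {
    warning("zero-variance column(s): ", paste(cols[zero_var], collapse = ", "),
            "; correlations set to NA", call. = FALSE)
  }
  suppressWarnings(stats::cor(m, use = "pairwise.complete.obs",
                              method = "pearson"))
}

#' Match predicted against ground-truth tips and score the detection
#'
#' Greedy matching in ascending center-distance order: a prediction and a
#' ground-truth tip match iff their centers are within `tau_px`, and each
#' is used at most once. Besides precision and recall the report carries
#' the leaf-counting accuracy
#' `100 * (1 - |NL_pred - NL_gt| / NL_gt)`, the score under which counting
#' performance is quoted (undefined when the ground truth is empty).
#'
#' @param pred,gt [tip_set()] objects for the same image.
#' @param tau_px Match radius in pixels; defaults to the ground-truth box
#'   edge (16 at native scale).
#' @return List of class `match_report`: `true_positives`,
#'   `false_positives`, `false_negatives`, `precision`, `recall`,
#'   `count_accuracy_percent`.
#' @export
match_detections <- function(pred, gt, tau_px = 16) {
  stopifnot(inherits(pred, "tip_set"), inherits(gt, "tip_set"))
  np <- nrow(pred$tips); ng <- nrow(gt$tips)
  tp <- 0L
  if (np > 0 && ng > 0) {
    dx <- outer(pred$tips$cx_px, gt$tips$cx_px, `-`)
    dy <- outer(pred$tips$cy_px, gt$tips$cy_px, `-`)
    d <- sqrt(dx^2 + dy^2)
    cand <- which(d <= tau_px, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      used_p <- logical(np); used_g <- logical(ng)
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_p[i] && !used_g[j]) {
          used_p[i] <- TRUE; used_g[j] <- TRUE
          tp <- tp + 1L
        }
      }
    }
  }
  fp <- np - tp; fn <- ng - tp
  precision <- if (tp + fp == 0) structure(0, undefined = TRUE) else tp / (tp + fp)
  recall <- if (tp + fn == 0) structure(0, undefined = TRUE) else tp / (tp + fn)
  count_acc <- if (ng == 0) {
    structure(NA_real_, undefined = TRUE)
  } else {
    100 * (1 - abs(np - ng) / ng)
  }
  structure(
    list(true_positives = tp, false_positives = fp, false_negatives = fn,
         precision = precision, recall = recall,
         count_accuracy_percent = count_acc),
    class = "match_report"
  )
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(
    "<match_report> TP=%d FP=%d FN=%d | precision %.3f, recall %.3f, count accuracy %.1f%%\n",
    x$true_positives, x$false_positives, x$false_negatives,
    x$precision, x$recall, x$count_accuracy_percent
  ))
  invisible(x)
}

#' Hierarchical clustering of genotypes on their trait vectors
#'
#' Traits are standardized (zero mean, unit variance; constant columns are
#' dropped with a warning) before Euclidean distances and agglomerative
#' clustering. Given identical input order the merge order is
#' deterministic (ties resolved to the lowest-index pair by the
#' agglomeration routine).
#'
#' @param mat Numeric matrix or data frame, one row per genotype; row names
#'   (or a `genotype_id` column) label the leaves.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @param k Number of groups for the cut (optional).
#' @param h Cut height, alternative to `k`.
#' @return Object of class `genotype_tree`: `hclust` (NULL for a single
#'   genotype), `labels`, `assignments` (named integer vector when a cut
#'   was requested), `linkage`.
#' @export
cluster_genotypes <- function(mat, linkage = c("average", "complete", "single"),
                              k = NULL, h = NULL) {
  linkage <- match.arg(linkage)
  if (is.data.frame(mat) && "genotype_id" %in% names(mat)) {
    rn <- mat$genotype_id
    mat <- as.matrix(mat[setdiff(names(mat), "genotype_id")])
    rownames(mat) <- rn
  } else {
    mat <- as.matrix(mat)
  }
  if (anyNA(mat)) stop("`mat` must not contain missing values", call. = FALSE)
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("G%03d", seq_len(nrow(mat)))
  n <- nrow(mat)
  if (!is.null(k) && k > n) stop("`k` cannot exceed the number of genotypes", call. = FALSE)

  if (n == 1) {
    return(structure(
      list(hclust = NULL, labels = rownames(mat),
           assignments = stats::setNames(1L, rownames(mat)), linkage = linkage),
      class = "genotype_tree"
    ))
  }
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant trait column(s): ",
            paste(colnames(mat)[sds == 0], collapse = ", "), call. = FALSE)
    mat <- mat[, sds > 0, drop = FALSE]
    if (ncol(mat) == 0) stop("no variable trait columns left", call. = FALSE)
  }
  z <- scale(mat)
  hc <- stats::hclust(stats::dist(z), method = linkage)
  assignments <- if (!is.null(k)) {
    stats::cutree(hc, k = k)
  } else if (!is.null(h)) {
    stats::cutree(hc, h = h)
  } else NULL
  structure(
    list(hclust = hc, labels = rownames(mat), assignments = assignments,
         linkage = linkage),
    class = "genotype_tree"
  )
}

#' @export
print.genotype_tree <- function(x, ...) {
  cat(sprintf("<genotype_tree> %d genotypes, %s linkage", length(x$labels), x$linkage))
  if (!is.null(x$assignments)) {
    cat(sprintf(", cut into %d groups", length(unique(x$assignments))))
  }
  cat("\n")
  invisible(x)
}

#' Export a genotype dendrogram as Newick
#'
#' Branch lengths are merge-height differences (leaves sit at height 0), so
#' the tree is ultrametric: both children of a node merged at height `h`
#' over leaves carry branch length `h`. A singleton tree serializes as
#' `"(A);"`.
#'
#' @param tree A [cluster_genotypes()] result.
#' @param path Optional file to write; the string is returned either way.
#' @return The Newick string, invisibly when `path` is given.
#' @export
export_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "genotype_tree"))
  fmt <- function(x) sub("\\.$", "", sub("0+$", "", sprintf("%.10f", x)))
  if (is.null(tree$hclust)) {
    nwk <- sprintf("(%s);", tree$labels[1])
  } else {
    hc <- tree$hclust
    node_str <- function(i) {
      # i indexes hc$merge rows; negative entries are leaves
      children <- hc$merge[i, ]
      part <- vapply(children, function(ch) {
        if (ch < 0) {
          sprintf("%s:%s", hc$labels[-ch], fmt(hc$height[i]))
        } else {
          sprintf("%s:%s", node_str(ch), fmt(hc$height[i] - hc$height[ch]))
        }
      }, character(1))
      sprintf("(%s,%s)", part[1], part[2])
    }
    nwk <- paste0(node_str(nrow(hc$merge)), ";")
  }
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
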