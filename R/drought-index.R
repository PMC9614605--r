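#' Leaves emerged between two time snaps
#'
#' @param counts Integer leaf counts, one per entry of `time_snaps`.
#' @param time_snaps Time snaps the counts belong to.
#' @param ts_start,ts_peak Start (drought onset) and peak-stress snaps;
#'   both must be present and `ts_peak > ts_start`.
#' @return `count(ts_peak) - count(ts_start)`.
#' @export
delta_leaves <- function(counts, time_snaps = seq_along(counts),
                         ts_start = 1L, ts_peak = 4L) {
  if (ts_peak <= ts_start) stop("`ts_peak` must exceed `ts_start`", call. = FALSE)
  i0 <- match(ts_start, time_snaps)
  i1 <- match(ts_peak, time_snaps)
  if (is.na(i0) || is.na(i1)) {
    stop(sprintf("time snaps %d and %d must both be present", ts_start, ts_peak),
         call. = FALSE)
  }
  as.integer(counts[i1] - counts[i0])
}

#' Leaf-emergence-rate stress tolerance index
#'
#' The index is the percentage ratio of leaves emerging under drought to
#' leaves emerging under control over the same window (drought onset to
#' peak stress), scaled into `[0, 100]`: values above 100 (drought
#' out-emerging control) are clipped, with the raw ratio retained in the
#' `raw` attribute. A zero control delta makes the index undefined (flagged
#' `NA`), never a division error.
#'
#' @param delta_drought,delta_control Leaf-count deltas (>= 0) under drought
#'   and control.
#' @return Index in `[0, 100]` (attribute `raw` holds the unclipped ratio),
#'   or flagged `NA` when the control delta is zero.
#' @export
ler <- function(delta_drought, delta_control) {
  if (delta_drought < 0 || delta_control < 0) {
    stop("leaf-count deltas must be >= 0", call. = FALSE)
  }
  if (delta_control == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  raw <- 100 * delta_drought / delta_control
  structure(clamp(raw, 0, 100), raw = raw)
}

#' Classify a tolerance index value into tolerance bands
#'
#' Bands form a non-overlapping partition of `[0, 100]`: `sensitive` below
#' 60, `moderate` in `[60, 75)`, `tolerant` at or above 75. (The source
#' bands are quoted loosely in the field -- "more than 75%" tolerant,
#' "65-85%" light tolerance, "less than 60%" sensitive -- so the package
#' fixes the deterministic partition above.) An undefined index maps to
#' `undefined`.
#'
#' @param ler_percent Index in `[0, 100]`, or `NA` for undefined.
#' @return One of `"tolerant"`, `"moderate"`, `"sensitive"`, `"undefined"`.
#' @export
classify_ler <- function(ler_percent) {
  vapply(as.numeric(ler_percent), function(x) {
    if (is.na(x)) return("undefined")
    if (x < 0 || x > 100) stop("`ler_percent` must lie in [0, 100]", call. = FALSE)
    if (x < 60) "sensitive" else if (x < 75) "moderate" else "tolerant"
  }, character(1))
}

#' Eq.-style biomass composition accounting
#'
#' Above-ground biomass weight is the sum of stem and leaf weight; stem and
#' leaf percentages are their shares of that total, which sum to 100
#' exactly whenever biomass is positive. Zero biomass flags the
#' percentages undefined.
#'
#' @param stem_weight_g,leaf_weight_g Component weights in grams (>= 0); a
#'   `destructive_record` row may be passed as the first argument instead.
#' @return List `BMW_g`, `stem_pct`, `leaf_pct` (percentages `NA`-flagged
#'   when `BMW_g == 0`).
#' @export
biomass_composition <- function(stem_weight_g, leaf_weight_g = NULL) {
  if (is.data.frame(stem_weight_g)) {
    rec <- stem_weight_g
    stem_weight_g <- rec$stem_weight_g
    leaf_weight_g <- rec$leaf_weight_g
  }
  if (any(stem_weight_g < 0) || any(leaf_weight_g < 0)) {
    stop("weights must be >= 0", call. = FALSE)
  }
  bmw <- stem_weight_g + leaf_weight_g
  if (any(bmw == 0)) {
    undef <- bmw == 0
    stem_pct <- ifelse(undef, NA_real_, 100 * stem_weight_g / bmw)
    leaf_pct <- ifelse(undef, NA_real_, 100 * leaf_weight_g / bmw)
    return(list(BMW_g = bmw, stem_pct = structure(stem_pct, undefined = TRUE),
                leaf_pct = structure(leaf_pct, undefined = TRUE)))
  }
  list(BMW_g = bmw, stem_pct = 100 * stem_weight_g / bmw,
       leaf_pct = 100 * leaf_weight_g / bmw)
}

#' Tolerance index table for a panel of genotypes
#'
#' Takes long-format leaf counts (one row per genotype, treatment,
#' optional replicate and time snap), averages the onset-to-peak deltas
#' over replicates within each treatment, and applies the index and the
#' classification bands per genotype.
#'
#' @param counts Data frame with columns `genotype_id`, `treatment`
#'   (`"control"`/`"drought"`), `time_snap`, `leaf_count` and optionally
#'   `replicate`.
#' @param ts_start,ts_peak Index window (defaults 1 and 4).
#' @return Data frame with one row per genotype: `genotype_id`,
#'   `delta_nl_drought`, `delta_nl_control`, `ler_percent`,
#'   `tolerance_class`.
#' @export
ler_table <- function(counts, ts_start = 1L, ts_peak = 4L) {
  need <- c("genotype_id", "treatment", "time_snap", "leaf_count")
  if (!all(need %in% names(counts))) {
    stop("`counts` must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"replicate" %in% names(counts)) counts$replicate <- 1L
  one_delta <- function(df) {
    # mean over replicates of the per-replicate delta
    mean(vapply(split(df, df$replicate), function(r) {
      delta_leaves(r$leaf_count[order(r$time_snap)], sort(r$time_snap),
                   ts_start, ts_peak)
    }, numeric(1)))
  }
  out <- lapply(split(counts, counts$genotype_id), function(gdf) {
    dd <- one_delta(gdf[gdf$treatment == "drought", , drop = FALSE])
    dc <- one_delta(gdf[gdf$treatment == "control", , drop = FALSE])
    l <- ler(dd, dc)
    data.frame(
      genotype_id = gdf$genotype_id[1],
      delta_nl_drought = dd, delta_nl_control = dc,
      ler_percent = as.numeric(l),
      tolerance_class = classify_ler(as.numeric(l)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
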