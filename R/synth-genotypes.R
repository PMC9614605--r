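#' Parametric description of a synthetic rice genotype
#'
#' A `genotype_spec` captures everything the synthetic renderer and the
#' growth model need to emulate one rice genotype under control and drought
#' treatments: its canopy architecture, how many leaves it starts with, how
#' fast leaves emerge per time snap, and how strongly drought suppresses
#' emergence and rolls the blades.
#'
#' `drought_emergence_factor` is the programmed ground truth for the
#' leaf-emergence-rate stress index: a factor of 0.5 means the genotype
#' realizes half its control emergence under drought, so its recovered
#' index should be close to 50%.
#'
#' @param genotype_id Character label, unique within a panel.
#' @param archetype Canopy architecture: `"erect"`, `"semi_erect"`,
#'   `"spread"` or `"open"`.
#' @param base_leaf_count Integer number of leaves at the first time snap
#'   (drought onset); must be >= 1.
#' @param emergence_rate_control Leaves emerging per time-snap interval
#'   under well-watered conditions.
#' @param drought_emergence_factor Fraction in `[0, 1]` of the control
#'   emergence realized under drought.
#' @param erectness Fraction in `[0, 1]`; radial foreshortening of blades in
#'   top view (1 = fully erect, blades project short).
#' @param rolling_factor Fraction in `[0, 1]`; blade-width shrink under
#'   drought (leaf rolling).
#' @param leaf_len_px,leaf_width_px Nominal blade length and base width in
#'   pixels at the synthetic scene scale.
#' @param seed Integer seed controlling all per-plant stochastic geometry.
#' @return An object of class `genotype_spec`.
#' @export
genotype_spec <- function(genotype_id,
                          archetype = c("erect", "semi_erect", "spread", "open"),
                          base_leaf_count = 12L,
                          emergence_rate_control = 6,
                          drought_emergence_factor = 0.6,
                          erectness = 0.5,
                          rolling_factor = 0.3,
                          leaf_len_px = 200,
                          leaf_width_px = 5,
                          seed = 1L) {
  archetype <- match.arg(archetype)
  base_leaf_count <- as.integer(base_leaf_count)
  if (is.na(base_leaf_count) || base_leaf_count < 1L) {
    stop("`base_leaf_count` must be an integer >= 1", call. = FALSE)
  }
  stopifnot(
    emergence_rate_control >= 0,
    drought_emergence_factor >= 0, drought_emergence_factor <= 1,
    erectness >= 0, erectness <= 1,
    rolling_factor >= 0, rolling_factor <= 1,
    leaf_len_px > 0, leaf_width_px > 0
  )
  structure(
    list(
      genotype_id = as.character(genotype_id),
      archetype = archetype,
      base_leaf_count = base_leaf_count,
      emergence_rate_control = emergence_rate_control,
      drought_emergence_factor = drought_emergence_factor,
      erectness = erectness,
      rolling_factor = rolling_factor,
      leaf_len_px = leaf_len_px,
      leaf_width_px = leaf_width_px,
      seed = as.integer(seed)
    ),
    class = "genotype_spec"
  )
}

#' @export
print.genotype_spec <- function(x, ...) {
  cat(sprintf(
    "<genotype_spec> %s [%s] base NL=%d, rate=%.2f/snap, drought factor=%.2f\n",
    x$genotype_id, x$archetype, x$base_leaf_count,
    x$emergence_rate_control, x$drought_emergence_factor
  ))
  invisible(x)
}

#' Imaging-scene parameters for the synthetic generator
#'
#' @param image_width_px,image_height_px Image dimensions in pixels.
#' @param cm_per_pixel Optical scale; converts pixel geometry to cm.
#' @param box_size_px Edge of the fixed-size square ground-truth tip box
#'   (default 16, the annotation convention the pipeline assumes).
#' @param background_noise_sd Standard deviation of the additive Gaussian
#'   intensity noise applied per channel after rendering.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_width_px = 640L, image_height_px = 640L,
                       cm_per_pixel = 0.25, box_size_px = 16L,
                       background_noise_sd = 3) {
  stopifnot(
    image_width_px >= 32, image_height_px >= 32,
    cm_per_pixel > 0, box_size_px >= 2, background_noise_sd >= 0
  )
  structure(
    list(
      image_width_px = as.integer(image_width_px),
      image_height_px = as.integer(image_height_px),
      cm_per_pixel = cm_per_pixel,
      box_size_px = as.integer(box_size_px),
      background_noise_sd = background_noise_sd
    ),
    class = "scene_spec"
  )
}

#' Allometric blade length for a target leaf count
#'
#' Canopy extent grows with leaf number in rice: leafy plants are large.
#' The generator couples the projected canopy radius to the leaf count so
#' that the convex hull area is about 148 cm2 per leaf, the mean
#' hull-area-to-leaf-number ratio of vegetative-stage panels under both
#' water regimes. At scale `s` cm/px that radius is
#' `sqrt(148 * NL / pi) / s` px; the blade length is the radius divided by
#' the erectness foreshortening, capped so blades stay inside the frame.
#'
#' @param leaf_count Target leaf number.
#' @param erectness Erectness of the genotype (radial foreshortening).
#' @param scene A [scene_spec()] (for the optical scale and frame cap).
#' @return Blade length in pixels.
#' @export
allometric_leaf_len <- function(leaf_count, erectness, scene = scene_spec()) {
  radial_mult <- 1 - 0.5 * erectness
  target_r <- sqrt(148 * max(leaf_count, 1) / pi) / scene$cm_per_pixel
  max_r <- min(scene$image_width_px, scene$image_height_px) / 2 -
    scene$box_size_px - (5 + leaf_count / 5)
  min(target_r / radial_mult, max_r / (1.3 * radial_mult))
}

# Archetype-specific parameter ranges used when sampling a panel.
.archetype_params <- list(
  erect      = list(erectness = c(0.70, 0.90), base = c(8L, 16L)),
  semi_erect = list(erectness = c(0.50, 0.70), base = c(10L, 20L)),
  spread     = list(erectness = c(0.20, 0.40), base = c(14L, 26L)),
  open       = list(erectness = c(0.05, 0.25), base = c(12L, 24L))
)

#' Generate a panel of synthetic genotypes
#'
#' Builds `n` genotype specifications cycling round-robin through the four
#' canopy archetypes, with drought emergence factors stratified to cover
#' `[0.2, 1.0]` so a panel always contains the full tolerance spectrum.
#' Deterministic for a fixed seed.
#'
#' @param n Number of genotypes (>= 1).
#' @param seed Integer seed.
#' @return A list of [genotype_spec()] objects with unique ids `G001`, ...
#' @export
make_genotype_panel <- function(n, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop("`n` must be an integer >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  with_seed(seed, {
    archetypes <- rep(c("erect", "semi_erect", "spread", "open"), length.out = n)
    # Stratified coverage of the drought tolerance spectrum, then shuffled
    # so tolerance is not confounded with archetype order.
    factors <- seq(0.2, 1.0, length.out = max(n, 2L))[seq_len(n)]
    factors <- sample(factors)
    lapply(seq_len(n), function(i) {
      pars <- .archetype_params[[archetypes[i]]]
      base_nl <- sample(seq(pars$base[1], pars$base[2]), 1L)
      # emergence rates span vigorous multi-tiller genotypes, so peak-stage
      # leaf counts cover the wide dispersion seen in destructive panels
      rate <- stats::runif(1, 4, 24)
      erect <- stats::runif(1, pars$erectness[1], pars$erectness[2])
      genotype_spec(
        genotype_id = sprintf("G%03d", i),
        archetype = archetypes[i],
        base_leaf_count = base_nl,
        emergence_rate_control = rate,
        drought_emergence_factor = factors[i],
        erectness = erect,
        rolling_factor = stats::runif(1, 0.1, 0.5),
        # canopy size coupled to the leaf count reached at peak stress
        leaf_len_px = allometric_leaf_len(base_nl + 3 * round(rate), erect) *
          stats::runif(1, 0.9, 1.1),
        leaf_width_px = stats::runif(1, 4, 7),
        seed = sample.int(1e6, 1L)
      )
    })
  })
}

#' Leaf-count trajectory across time snaps
#'
#' Leaf counts start at `base_leaf_count` at time snap 1 for both
#' treatments (TS1 is the shared internal-control baseline: drought starts
#' there, so the treatments have not yet diverged). Each subsequent
#' unit interval adds `round(emergence_rate_control)` leaves under control
#' and `round(emergence_rate_control * drought_emergence_factor)` under
#' drought. Rounding is applied per interval, not cumulatively, so
#' trajectories are integer, monotone and reproducible.
#'
#' @param g A [genotype_spec()].
#' @param treatment `"control"` or `"drought"`.
#' @param time_snaps Sorted ascending integer vector within 1..5.
#' @return Integer leaf counts, one per requested time snap.
#' @export
leaf_count_trajectory <- function(g, treatment = c("control", "drought"),
                                  time_snaps = 1:5) {
  treatment <- match.arg(treatment)
  stopifnot(inherits(g, "genotype_spec"))
  if (any(time_snaps < 1 | time_snaps > 5)) {
    stop("`time_snaps` must lie within 1..5", call. = FALSE)
  }
  if (is.unsorted(time_snaps, strictly = TRUE)) {
    stop("`time_snaps` must be sorted strictly ascending", call. = FALSE)
  }
  inc <- if (treatment == "control") {
    round(g$emergence_rate_control)
  } else {
    round(g$emergence_rate_control * g$drought_emergence_factor)
  }
  as.integer(g$base_leaf_count + (time_snaps - 1L) * inc)
}

#' Simulate a destructive biomass record
#'
#' Emulates destructive sampling at harvest: leaf weight is proportional to
#' leaf number (the allometric link that grounds the leaf-counting
#' hypothesis), stem weight is drawn so the leaf share of above-ground
#' biomass falls in `[0.30, 0.70]` in expectation, and root weight, leaf
#' area and stem area are positively coupled to biomass. Allometric
#' constants (0.35 g/leaf, 45 cm2 leaf area per g leaf, 7.6 cm2 stem area
#' per g stem, root weight 1.1 x above-ground biomass) reflect typical
#' pot-grown rice at the vegetative stage.
#'
#' @param g A [genotype_spec()].
#' @param treatment `"control"` or `"drought"`.
#' @param leaf_count Leaf number at sampling (>= 0).
#' @param seed Integer seed.
#' @param noise_sd Relative (multiplicative) noise standard deviation;
#'   default 0.1, set 0 for a noise-free record.
#' @return A one-row data frame of class `destructive_record` with columns
#'   `genotype_id`, `treatment`, `stem_weight_g`, `leaf_weight_g`,
#'   `root_weight_g`, `leaf_area_cm2`, `stem_area_cm2`, `biomass_weight_g`.
#' @export
simulate_destructive <- function(g, treatment = c("control", "drought"),
                                 leaf_count, seed = 1L, noise_sd = 0.1) {
  treatment <- match.arg(treatment)
  stopifnot(inherits(g, "genotype_spec"))
  if (!is.numeric(leaf_count) || length(leaf_count) != 1L || leaf_count < 0) {
    stop("`leaf_count` must be a single number >= 0", call. = FALSE)
  }
  with_seed(seed, {
    rel <- function() 1 + stats::rnorm(1, 0, noise_sd)
    lw <- 0.35 * leaf_count * rel()
    lw <- max(lw, 0)
    # target leaf share of above-ground biomass, uniform over [0.32, 0.68]
    share <- stats::runif(1, 0.32, 0.68)
    stw <- if (lw > 0) lw * (1 / share - 1) * rel() else 0
    stw <- max(stw, 0)
    bmw <- stw + lw
    rec <- data.frame(
      genotype_id = g$genotype_id,
      treatment = treatment,
      stem_weight_g = stw,
      leaf_weight_g = lw,
      root_weight_g = max(1.1 * bmw * rel(), 0),
      leaf_area_cm2 = max(45 * lw * rel(), 0),
      stem_area_cm2 = max(7.6 * stw * rel(), 0),
      biomass_weight_g = bmw,
      stringsAsFactors = FALSE
    )
    class(rec) <- c("destructive_record", class(rec))
    rec
  })
}
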