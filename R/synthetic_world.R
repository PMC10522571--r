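#' Synthetic world generation
#'
#' Self-consistent synthetic input layers emulating the statistical structure
#' of the real global data products: spatially smooth soil pH fields in a
#' five-interval depth stack, sand/clay composition fields, log-normally
#' distributed earthworm abundance with most cells below 100 individuals
#' m^-2, crop-specific positive yields and harvested areas, bimodal
#' (low/high) N application rates, and a partition into eight regions. A
#' known-truth mode constructs observed yields as baseline * (1 + E) so that
#' the full pipeline must recover the implanted attributable production
#' exactly.
#'
#' @name synthetic_world
NULL

UN_SDG_REGIONS <- c(
  "Sub-Saharan Africa",
  "Northern Africa and Western Asia",
  "Central and Southern Asia",
  "Eastern and South-Eastern Asia",
  "Latin America and the Caribbean",
  "Oceania (incl. Australia and New Zealand)",
  "Europe",
  "Northern America"
)

default_crop_table <- function() {
  data.frame(
    crop = c("wheat", "rice", "maize", "barley", "soybean", "dry_bean"),
    crop_type = c("cereal", "cereal", "cereal", "cereal", "legume", "legume"),
    yield_mean = c(3.5, 4.5, 5.5, 3.0, 2.8, 1.2),    # t ha^-1
    area_meanlog = log(c(400, 350, 450, 250, 300, 150)),  # ha per cell
    stringsAsFactors = FALSE
  )
}

#' Configuration of a synthetic world
#'
#' Defaults describe the study conditions the generator emulates: a 100 x 100
#' grid of 5-arcminute cells; abundance log-normal with median 30 individuals
#' m^-2 (so most cells fall below the 100 individuals m^-2 'low density'
#' threshold); smooth pH around 6.2 clipped to soil-plausible values; sand
#' and clay fields with sand + clay <= 100 everywhere; a two-component N-rate
#' mixture (about 15 vs 120 kg N ha^-1 yr^-1) so both N categories occur;
#' four cereals and two legumes; eight regions; 15% of abundance cells
#' missing.
#'
#' @param shape Grid dimensions `c(nrow, ncol)`.
#' @param cellsize Cell size in arcminutes.
#' @param seed Integer seed; a fixed seed makes the world fully reproducible.
#' @param crops data.frame with columns `crop`, `crop_type`, `yield_mean`,
#'   `area_meanlog`.
#' @param abundance_meanlog,abundance_sdlog Log-normal parameters of
#'   earthworm abundance (individuals m^-2).
#' @param ph_mean,ph_sd,ph_range Mean, spatial standard deviation and clip
#'   range of the pH field.
#' @param sand_range Clip range (percent) of the sand field.
#' @param n_low_frac Fraction of cropland receiving the low N rate.
#' @param n_low_mean,n_high_mean Mean N rates of the two mixture components
#'   (kg N ha^-1 yr^-1).
#' @param n_regions Number of regions (8 uses the standard region names).
#' @param missing_frac Fraction of abundance cells masked as missing.
#' @param soil_missing_frac Fraction of cells masked per soil depth layer
#'   (exercises renormalized depth weighting).
#' @param zero_area_frac Fraction of cells with zero harvested area per crop.
#' @param smoothness Gaussian kernel standard deviation (cells) used to
#'   smooth the white-noise fields.
#' @return List of class `world_config`.
#' @export
world_config <- function(shape = c(100, 100), cellsize = 5, seed = 1L,
                         crops = default_crop_table(),
                         abundance_meanlog = log(30), abundance_sdlog = 1.1,
                         ph_mean = 6.2, ph_sd = 0.8, ph_range = c(3.5, 9),
                         sand_range = c(5, 95),
                         n_low_frac = 0.45, n_low_mean = 15, n_high_mean = 120,
                         n_regions = 8, missing_frac = 0.15,
                         soil_missing_frac = 0.02, zero_area_frac = 0.3,
                         smoothness = 3) {
  if (length(shape) != 2L || any(shape < 1)) {
    stop("`shape` must be two positive integers", call. = FALSE)
  }
  fracs <- c(n_low_frac, missing_frac, soil_missing_frac, zero_area_frac)
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (!all(c("crop", "crop_type", "yield_mean", "area_meanlog") %in% names(crops))) {
    stop("`crops` must have columns crop, crop_type, yield_mean, area_meanlog",
         call. = FALSE)
  }
  if (!all(crops$crop_type %in% c("cereal", "legume"))) {
    stop("crop_type must be 'cereal' or 'legume'", call. = FALSE)
  }
  if (abundance_sdlog <= 0 || ph_sd < 0 || n_regions < 1) {
    stop("invalid distribution parameters", call. = FALSE)
  }
  structure(as.list(environment()), class = "world_config")
}

# Reflect-padded separable Gaussian blur; standardizes nothing.
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  blur1 <- function(x) {
    n <- length(x)
    ri <- min(r, n - 1L)
    xp <- c(rev(x[2:(ri + 1L)]), x, rev(x[(n - ri):(n - 1L)]))
    if (ri < r) {  # short vectors: pad further by edge replication
      xp <- c(rep(xp[1L], r - ri), xp, rep(xp[length(xp)], r - ri))
    }
    as.numeric(stats::filter(xp, k, sides = 2))[(r + 1L):(r + n)]
  }
  m <- apply(m, 2L, blur1)
  t(apply(m, 1L, blur1))
}

# Standardized smooth random field (mean 0, sd 1).
smooth_field <- function(nr, nc, sigma) {
  f <- gauss_blur(matrix(stats::rnorm(nr * nc), nr, nc), sigma)
  (f - mean(f)) / stats::sd(f)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic world
#'
#' Deterministic given `config$seed`. All layers share one geometry and
#' satisfy the preconditions of the downstream operations.
#'
#' @param config [world_config()].
#' @return List of class `synthetic_world` with elements `abundance`
#'   (`worm_grid`), `ph_stack` (list of 5 `worm_grid`s), `sand`, `clay`,
#'   `crops` (list of [crop_layer()]), `regions` ([region_map()]), and
#'   `config`.
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed)
  nr <- config$shape[1]; nc <- config$shape[2]
  n <- nr * nc
  origin <- c(-180 + config$cellsize / 120, 90 - config$cellsize / 120)
  mk <- function(v) worm_grid(matrix(v, nr, nc), origin = origin,
                              cellsize = config$cellsize)

  # earthworm abundance: log-normal, mildly smoothed in log space, masked
  ab_field <- exp(config$abundance_meanlog +
                    config$abundance_sdlog * smooth_field(nr, nc, config$smoothness / 2))
  ab_mask <- matrix(stats::runif(n) < config$missing_frac, nr, nc)
  ab_field[ab_mask] <- NA_real_
  abundance <- mk(ab_field)

  # pH depth stack: one smooth base field, slight increase with depth
  ph_base <- smooth_field(nr, nc, config$smoothness)
  depth_offset <- c(-0.10, -0.05, 0, 0.05, 0.10)
  ph_stack <- lapply(seq_along(depth_offset), function(l) {
    v <- clip(config$ph_mean + config$ph_sd * ph_base + depth_offset[l] +
                0.05 * stats::rnorm(n),
              config$ph_range[1], config$ph_range[2])
    v[stats::runif(n) < config$soil_missing_frac] <- NA_real_
    mk(v)
  })

  # texture: smooth sand field; clay takes a smooth fraction of the remainder
  sand_v <- clip(50 + 25 * smooth_field(nr, nc, config$smoothness),
                 config$sand_range[1], config$sand_range[2])
  clay_frac <- clip(0.45 + 0.30 * smooth_field(nr, nc, config$smoothness),
                    0.05, 0.80)
  clay_v <- (100 - sand_v) * clay_frac
  sand <- mk(sand_v); clay <- mk(clay_v)

  # N regime: spatially coherent low/high zones shared across crops
  n_zone <- smooth_field(nr, nc, config$smoothness)
  low_zone <- n_zone < stats::quantile(n_zone, config$n_low_frac)

  crops <- lapply(seq_len(nrow(config$crops)), function(i) {
    row <- config$crops[i, ]
    yield_v <- row$yield_mean * exp(0.30 * smooth_field(nr, nc, config$smoothness) +
                                      0.10 * stats::rnorm(n))
    area_v <- exp(stats::rnorm(n, row$area_meanlog, 0.8))
    area_v[stats::runif(n) < config$zero_area_frac] <- 0
    nlow <- clip(stats::rnorm(n, config$n_low_mean, 8), 0, 30)
    nhigh <- clip(stats::rnorm(n, config$n_high_mean, 40), 31, Inf)
    n_v <- ifelse(c(low_zone), nlow, nhigh)
    crop_layer(row$crop, yield = mk(yield_v), area = mk(area_v),
               n_rate = mk(n_v), crop_type = row$crop_type)
  })
  names(crops) <- config$crops$crop

  # regions: nearest-seed partition into contiguous zones
  seeds <- cbind(stats::runif(config$n_regions, 1, nr),
                 stats::runif(config$n_regions, 1, nc))
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  best <- matrix(Inf, nr, nc)
  codes <- matrix(1L, nr, nc)
  for (r in seq_len(config$n_regions)) {
    d <- (rows - seeds[r, 1])^2 + (cols - seeds[r, 2])^2
    upd <- d < best
    best[upd] <- d[upd]
    codes[upd] <- r
  }
  region_names <- if (config$n_regions == length(UN_SDG_REGIONS)) {
    UN_SDG_REGIONS
  } else {
    paste("Region", seq_len(config$n_regions))
  }
  regions <- region_map(category_grid(codes, levels = region_names,
                                      factor_name = "region",
                                      origin = origin,
                                      cellsize = config$cellsize))

  structure(list(abundance = abundance, ph_stack = ph_stack,
                 sand = sand, clay = clay, crops = crops, regions = regions,
                 config = config),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d x %d cells, %d crops, %d regions (seed %d)\n",
              x$config$shape[1], x$config$shape[2], length(x$crops),
              x$config$n_regions, x$config$seed))
  invisible(x)
}

#' Generate a synthetic world with a known implanted truth
#'
#' Draws baseline (without-earthworm) yields, evaluates the effect model to
#' get \eqn{E} per crop (restricted to cells with positive harvested area and
#' valid drivers), sets the observed yield to baseline * (1 + E), and returns
#' the exact attributable production baseline * E * area summed per region
#' and crop group. Running the full pipeline in counterfactual-division mode
#' on the observed yields recovers this truth exactly, because
#' y_obs / (1 + E) = baseline algebraically.
#'
#' @param config [world_config()].
#' @param params [effect_params()].
#' @return List of class `truth_world`: `world` (with observed yields
#'   substituted into the crop layers), `baseline_yields` (named list of
#'   `worm_grid`s), `effects` (named list of `effect_grid`s), and `truth`
#'   (the regional summary data.frame of the implanted contributions).
#' @export
generate_with_truth <- function(config = world_config(),
                                params = default_effect_params()) {
  world <- generate_world(config)
  ph_cat <- classify_ph(depth_weighted_average(world$ph_stack))
  tex_cat <- classify_texture(world$sand, world$clay)
  groups <- stats::setNames(config$crops$crop_type, config$crops$crop)

  baseline <- list(); effects <- list()
  contrib <- list(); observed <- list()
  for (crop in names(world$crops)) {
    cl <- world$crops[[crop]]
    eg <- earthworm_effect(cl, ph_cat, tex_cat, world$abundance, params)
    # restrict to this crop's production area
    ev <- eg$E$values
    ev[!(!is.na(cl$area$values) & cl$area$values > 0)] <- NA_real_
    eg$E$values <- ev
    base_y <- cl$yield                     # generated yields are the baseline
    obs_v <- base_y$values * ifelse(is.na(ev), 1, 1 + ev)
    world$crops[[crop]]$yield <- worm_grid(obs_v, origin = base_y$origin,
                                           cellsize = base_y$cellsize)
    contrib[[crop]] <- worm_grid(base_y$values * ev * cl$area$values,
                                 origin = base_y$origin, cellsize = base_y$cellsize)
    observed[[crop]] <- worm_grid(obs_v * cl$area$values,
                                  origin = base_y$origin, cellsize = base_y$cellsize)
    observed[[crop]]$values[is.na(ev)] <- NA_real_
    baseline[[crop]] <- base_y
    effects[[crop]] <- eg
  }
  truth <- regional_summary(contrib, observed, world$regions, groups)
  structure(list(world = world, baseline_yields = baseline,
                 effects = effects, truth = truth),
            class = "truth_world")
}
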