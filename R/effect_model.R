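#' Per-cell earthworm effect model
#'
#' The fractional yield effect of earthworms in grid cell \eqn{i} for crop
#' \eqn{k} is modeled multiplicatively:
#' \deqn{E_{i,k} = c_{i,k} \; p_i \; t_i \; n_{i,k} \; a_i \times 0.233}
#' where \eqn{c, p, t, n} are the category coefficients for crop type, soil
#' pH class, soil textural class and crop-specific N application rate class,
#' \eqn{a} is the continuous power-law multiplier of earthworm abundance, and
#' 0.233 is the average fractional increase in aboveground biomass with
#' earthworms. The factors are assumed to act independently (no interaction
#' terms). Cells missing any driver — notably cells without earthworm
#' abundance data — are excluded.
#'
#' @name effect_model
NULL

#' Bundle one crop's data layers
#'
#' @param crop Crop name.
#' @param yield `worm_grid`, observed yield (t ha^-1).
#' @param area `worm_grid`, harvested area (ha, >= 0).
#' @param n_rate `worm_grid`, N application rate for this crop
#'   (kg N ha^-1 yr^-1).
#' @param crop_type Either `"cereal"` or `"legume"`.
#' @return Object of class `crop_layer`.
#' @export
crop_layer <- function(crop, yield, area, n_rate, crop_type = c("cereal", "legume")) {
  crop_type <- match.arg(crop_type)
  align_check(list(yield, area, n_rate))
  if (any(yield$values < 0, na.rm = TRUE) || any(area$values < 0, na.rm = TRUE)) {
    stop("yields and harvested areas must be nonnegative", call. = FALSE)
  }
  structure(list(crop = crop, yield = yield, area = area, n_rate = n_rate,
                 crop_type = crop_type),
            class = "crop_layer")
}

#' @export
print.crop_layer <- function(x, ...) {
  cat(sprintf("<crop_layer> %s (%s), %d x %d cells\n",
              x$crop, x$crop_type, nrow(x$yield$values), ncol(x$yield$values)))
  invisible(x)
}

# Category labels of the effect table corresponding to crop_type labels.
CROP_TYPE_CATEGORY <- c(cereal = "Cereal grains", legume = "Legumes")

#' Full parameterization of the effect model
#'
#' @param coefficients Named list of `factor_coefficients` with entries
#'   `crop_type`, `soil_ph`, `soil_texture`, `n_rate`; default derived from
#'   the shipped effect-size table.
#' @param abundance_params [abundance_power_params()].
#' @param baseline_effect Baseline fractional effect (default 0.233).
#' @param contribution_mode `"counterfactual_division"` (observed yields are
#'   the with-earthworm state; default) or `"forward_multiplication"`
#'   (observed yields are the without-earthworm state).
#' @return Object of class `effect_params`.
#' @export
effect_params <- function(coefficients = derive_all_coefficients(read_effect_table()),
                          abundance_params = abundance_power_params(),
                          baseline_effect = BASELINE_EFFECT,
                          contribution_mode = c("counterfactual_division",
                                                "forward_multiplication")) {
  contribution_mode <- match.arg(contribution_mode)
  need <- c("crop_type", "soil_ph", "soil_texture", "n_rate")
  miss <- setdiff(need, names(coefficients))
  if (length(miss)) {
    stop("missing coefficient set(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(baseline_effect) || baseline_effect <= 0) {
    stop("`baseline_effect` must be positive", call. = FALSE)
  }
  structure(list(coefficients = coefficients,
                 abundance_params = abundance_params,
                 baseline_effect = baseline_effect,
                 contribution_mode = contribution_mode),
            class = "effect_params")
}

#' Default effect-model parameterization
#'
#' The shipped coefficient sets, published abundance power law and 0.233
#' baseline, in counterfactual-division mode.
#' @inheritParams effect_params
#' @return [effect_params()].
#' @export
default_effect_params <- function(contribution_mode = "counterfactual_division") {
  effect_params(contribution_mode = contribution_mode)
}

#' Evaluate the earthworm effect for one crop
#'
#' Computes \eqn{E = c \cdot p \cdot t \cdot n \cdot a \cdot} baseline per
#' cell. The result is missing wherever any driver (pH class, texture class,
#' N-rate class, or earthworm abundance) is missing. Negative user-supplied
#' coefficients are clamped at \eqn{E = 0} with a warning; the shipped
#' coefficients are all positive, so clamping never fires by default.
#'
#' @param crop [crop_layer()].
#' @param ph_cat `category_grid` of soil pH classes.
#' @param tex_cat `category_grid` of textural classes.
#' @param abundance `worm_grid` of earthworm abundance (individuals m^-2).
#' @param params [effect_params()].
#' @return List of class `effect_grid` with fields `crop` and `E`
#'   (a `worm_grid` of dimensionless fractional effects, >= 0 where valid).
#' @export
earthworm_effect <- function(crop, ph_cat, tex_cat, abundance,
                             params = default_effect_params()) {
  stopifnot(inherits(crop, "crop_layer"), inherits(params, "effect_params"))
  align_check(list(crop$yield, ph_cat, tex_cat, abundance))
  crop_cat <- CROP_TYPE_CATEGORY[[crop$crop_type]]
  c_coef <- params$coefficients$crop_type$coefficients[crop_cat]
  if (is.na(c_coef)) {
    stop(sprintf("no crop-type coefficient for '%s'", crop_cat), call. = FALSE)
  }
  p <- lookup_grid(ph_cat, params$coefficients$soil_ph$coefficients)
  t_ <- lookup_grid(tex_cat, params$coefficients$soil_texture$coefficients)
  n <- lookup_grid(classify_n_rate(crop$n_rate),
                   params$coefficients$n_rate$coefficients)
  a <- abundance_multiplier(abundance, params$abundance_params)
  E <- unname(c_coef) * p$values * t_$values * n$values * a$values *
    params$baseline_effect
  if (any(E < 0, na.rm = TRUE)) {
    warning("negative effect values clamped to 0 (negative coefficient supplied)",
            call. = FALSE)
    E[!is.na(E) & E < 0] <- 0
  }
  structure(list(crop = crop$crop,
                 E = worm_grid(E, origin = abundance$origin,
                               cellsize = abundance$cellsize)),
            class = "effect_grid")
}

#' @export
print.effect_grid <- function(x, ...) {
  cat(sprintf("<effect_grid> crop %s\n", x$crop))
  print(x$E)
  invisible(x)
}

# With- and without-earthworm yields under either convention.
yield_with_without <- function(y_obs, E, mode = c("counterfactual_division",
                                                  "forward_multiplication")) {
  mode <- match.arg(mode)
  Eg <- if (inherits(E, "effect_grid")) E$E else E
  align_check(list(y_obs, Eg))
  if (mode == "counterfactual_division") {
    list(y_with = y_obs,
         y_without = grid_map2(y_obs, Eg, function(y, e) y / (1 + e)))
  } else {
    list(y_with = grid_map2(y_obs, Eg, function(y, e) y * (1 + e)),
         y_without = y_obs)
  }
}

#' Counterfactual (without-earthworm) yield
#'
#' In `counterfactual_division` mode (default) the observed yield is taken as
#' the with-earthworm state and the counterfactual is
#' \eqn{y_{without} = y_{obs} / (1 + E)}, so the relative contribution of
#' earthworms to observed production is exactly \eqn{E / (1 + E)}. In
#' `forward_multiplication` mode the observed yield is the without-earthworm
#' state (returned unchanged) and the with-earthworm yield is
#' \eqn{y_{obs} (1 + E)}.
#'
#' @param y_obs `worm_grid` of observed yields (t ha^-1).
#' @param E An `effect_grid` or a `worm_grid` of fractional effects (>= 0).
#' @param mode Contribution convention.
#' @return `worm_grid` of without-earthworm yields.
#' @export
counterfactual_yield <- function(y_obs, E, mode = c("counterfactual_division",
                                                    "forward_multiplication")) {
  yield_with_without(y_obs, E, mode)$y_without
}

#' Attributable production per cell
#'
#' \eqn{(y_{with} - y_{without}) \times area}: the tonnes of production in
#' each cell attributable to earthworms. Zero where the harvested area is
#' zero; missing where either yield is missing.
#'
#' @param y_obs `worm_grid`, with-earthworm yield (t ha^-1).
#' @param y_without `worm_grid`, without-earthworm yield (t ha^-1).
#' @param area `worm_grid`, harvested area (ha, >= 0).
#' @return `worm_grid` of attributable production (t per cell).
#' @export
production_contribution <- function(y_obs, y_without, area) {
  align_check(list(y_obs, y_without, area))
  if (any(area$values < 0, na.rm = TRUE)) {
    stop("harvested area must be nonnegative", call. = FALSE)
  }
  v <- (y_obs$values - y_without$values) * area$values
  worm_grid(v, origin = y_obs$origin, cellsize = y_obs$cellsize)
}
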