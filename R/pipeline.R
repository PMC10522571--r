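#' End-to-end pipeline
#'
#' Classifies the soil and management layers, evaluates the earthworm effect
#' per crop masked to the crop's production area, converts effects into
#' with/without-earthworm yields and attributable production, and aggregates
#' regionally. This is the programmatic surface behind the `run` command.
#'
#' @param world A `synthetic_world` (or a list with the same elements:
#'   `abundance`, `ph_stack`, `sand`, `clay`, `crops`, `regions`).
#' @param params [effect_params()]; its `contribution_mode` selects the
#'   with/without convention.
#' @param denominator Passed to [regional_summary()].
#' @return List of class `worm_run` with per-crop `effects`, `contributions`
#'   and `observed` production grids, group-level area-weighted `effect_maps`,
#'   the regional `summary`, classified `ph_cat`/`tex_cat`, masked-cell
#'   counts, and the parameters used.
#' @export
run_pipeline <- function(world, params = default_effect_params(),
                         denominator = c("analyzed", "all")) {
  denominator <- match.arg(denominator)
  mode <- params$contribution_mode
  ph_cat <- classify_ph(depth_weighted_average(world$ph_stack))
  tex_cat <- classify_texture(world$sand, world$clay)
  groups <- vapply(world$crops, function(cl) cl$crop_type, character(1))

  effects <- list(); contrib <- list(); observed <- list(); areas <- list()
  masked_counts <- list()
  for (crop in names(world$crops)) {
    cl <- world$crops[[crop]]
    eg <- earthworm_effect(cl, ph_cat, tex_cat, world$abundance, params)
    in_area <- !is.na(cl$area$values) & cl$area$values > 0
    eg$E$values[!in_area] <- NA_real_
    masked_counts[[crop]] <- sum(in_area & is.na(eg$E$values))
    ww <- yield_with_without(cl$yield, eg, mode)
    con <- production_contribution(ww$y_with, ww$y_without, cl$area)
    obs <- grid_map2(ww$y_with, cl$area, `*`)
    effects[[crop]] <- eg
    contrib[[crop]] <- con
    observed[[crop]] <- obs
    areas[[crop]] <- cl$area
  }
  effect_maps <- lapply(split(names(groups), groups), function(crops) {
    area_weighted_effect(effects[crops], areas[crops])
  })
  summary <- regional_summary(contrib, observed, world$regions, groups,
                              denominator = denominator)
  structure(list(effects = effects, contributions = contrib,
                 observed = observed, effect_maps = effect_maps,
                 summary = summary, ph_cat = ph_cat, tex_cat = tex_cat,
                 masked_in_cropland = masked_counts,
                 params = params, denominator = denominator),
            class = "worm_run")
}

#' @export
print.worm_run <- function(x, ...) {
  cat(sprintf("<worm_run> %d crops, mode %s, denominator %s\n",
              length(x$effects), x$params$contribution_mode, x$denominator))
  print(x$summary[x$summary$region == "Global", ], row.names = FALSE)
  invisible(x)
}

write_run_manifest <- function(run, path, extra = list()) {
  ap <- run$params$abundance_params
  lines <- c(
    "wormyield run manifest",
    sprintf("package_version: %s",
            as.character(utils::packageVersion("wormyield"))),
    sprintf("contribution_mode: %s", run$params$contribution_mode),
    sprintf("denominator: %s", run$denominator),
    sprintf("baseline_effect: %.6g", run$params$baseline_effect),
    sprintf("abundance_power: prefactor=%.6g exponent=%.6g",
            ap$prefactor, ap$exponent),
    sprintf("crops: %s", paste(names(run$effects), collapse = ", ")),
    "masked_cropland_cells_per_crop (cells in production area lacking a valid effect):",
    sprintf("  %s: %d", names(run$masked_in_cropland),
            unlist(run$masked_in_cropland)),
    unlist(lapply(names(extra), function(k) sprintf("%s: %s", k, extra[[k]])))
  )
  writeLines(lines, path)
  invisible(path)
}
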