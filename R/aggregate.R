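#' Cross-crop and regional aggregation
#'
#' Harvested area weights per-crop effects into a single map, and region
#' identifiers aggregate attributable production into regional and global
#' summaries (per crop group: cereal, legume, all).
#'
#' @name aggregate
NULL

#' Region identifier map
#'
#' @param regions `category_grid` whose levels are region names. The default
#'   synthetic worlds use eight continental-scale agricultural regions
#'   following the UN SDG groupings (Australia/New Zealand combined with
#'   Oceania).
#' @return Object of class `region_map`.
#' @export
region_map <- function(regions) {
  stopifnot(inherits(regions, "category_grid"))
  structure(list(regions = regions, names = regions$levels), class = "region_map")
}

#' Harvested-area-weighted mean effect across crops
#'
#' Per cell, \eqn{\sum_k area_k E_k / \sum_k area_k} over crops whose effect
#' is valid and whose harvested area is positive in that cell. Cells with no
#' positive-area crop carrying a valid effect are missing.
#'
#' @param effects List of `effect_grid`s (or `worm_grid`s), one per crop.
#' @param areas List of `worm_grid`s of harvested area, parallel to `effects`.
#' @return `worm_grid` of area-weighted mean effects.
#' @export
area_weighted_effect <- function(effects, areas) {
  if (length(effects) != length(areas)) {
    stop("`effects` and `areas` must have the same length", call. = FALSE)
  }
  if (length(effects) == 0L) stop("need at least one crop", call. = FALSE)
  Es <- lapply(effects, function(e) if (inherits(e, "effect_grid")) e$E else e)
  align_check(c(Es, areas))
  geom <- grid_geometry(Es[[1L]])
  num <- matrix(0, geom$dim[1], geom$dim[2])
  den <- matrix(0, geom$dim[1], geom$dim[2])
  for (k in seq_along(Es)) {
    e <- Es[[k]]$values
    a <- areas[[k]]$values
    ok <- !is.na(e) & !is.na(a) & a > 0
    num[ok] <- num[ok] + a[ok] * e[ok]
    den[ok] <- den[ok] + a[ok]
  }
  out <- num / den
  out[den == 0] <- NA_real_
  worm_grid(out, origin = geom$origin, cellsize = geom$cellsize)
}

sum_by_region <- function(values, region_codes, n_regions) {
  ok <- !is.na(values)
  idx <- region_codes[ok]
  out <- numeric(n_regions + 1L)  # last slot: unassigned
  idx[is.na(idx)] <- n_regions + 1L
  agg <- rowsum(values[ok], idx)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Regional summary of observed and attributable production
#'
#' Sums observed production and attributable (earthworm) production per
#' region and crop group, and reports relative contributions as a percent of
#' observed production. A `Global` row holds the sums over all regions; cells
#' carrying production but no region identifier are counted under
#' `unassigned` (with a warning) so that the global row conserves totals.
#'
#' By default the observed-production denominator is restricted to the cells
#' actually analyzed (those with a valid contribution); cells lacking
#' earthworm data are excluded from numerator and denominator alike. Set
#' `denominator = "all"` to divide by all observed production instead.
#'
#' @param contributions Named list (by crop) of `worm_grid`s of attributable
#'   production (t per cell).
#' @param observed Named list (by crop) of `worm_grid`s of observed
#'   production (t per cell).
#' @param regions [region_map()].
#' @param groups Named character vector mapping crop name to crop group
#'   (e.g. `c(wheat = "cereal", soybean = "legume")`).
#' @param denominator `"analyzed"` (default) or `"all"`.
#' @return data.frame with columns `region`, `crop_group`, `observed_t`,
#'   `counterfactual_t`, `contribution_t`, `contribution_pct`. Regions with
#'   no observed production report `contribution_pct = NA`.
#' @export
regional_summary <- function(contributions, observed, regions, groups,
                             denominator = c("analyzed", "all")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(regions, "region_map"))
  crops <- names(contributions)
  if (is.null(crops) || !identical(sort(crops), sort(names(observed)))) {
    stop("`contributions` and `observed` must be named lists over the same crops",
         call. = FALSE)
  }
  miss_grp <- setdiff(crops, names(groups))
  if (length(miss_grp)) {
    stop("no crop group for: ", paste(miss_grp, collapse = ", "), call. = FALSE)
  }
  align_check(c(unname(contributions), unname(observed), list(regions$regions)))
  rcodes <- regions$regions$codes
  rnames <- c(regions$names, "unassigned")
  nr <- length(rnames)

  group_levels <- c(sort(unique(unname(groups[crops]))), "all")
  acc_con <- matrix(0, nr, length(group_levels),
                    dimnames = list(rnames, group_levels))
  acc_obs <- acc_con
  unassigned_cells <- 0L
  for (crop in crops) {
    con <- contributions[[crop]]$values
    obs <- observed[[crop]]$values
    if (denominator == "analyzed") obs[is.na(con)] <- NA_real_
    unassigned_cells <- unassigned_cells + sum(!is.na(con) & is.na(rcodes))
    g <- groups[[crop]]
    s_con <- sum_by_region(con, rcodes, length(regions$names))
    s_obs <- sum_by_region(obs, rcodes, length(regions$names))
    for (lev in c(g, "all")) {
      acc_con[, lev] <- acc_con[, lev] + s_con
      acc_obs[, lev] <- acc_obs[, lev] + s_obs
    }
  }
  if (unassigned_cells > 0L) {
    warning(sprintf("%d cell-crop value(s) had production but no region; reported as 'unassigned'",
                    unassigned_cells), call. = FALSE)
  } else {
    keep <- rnames != "unassigned"
    acc_con <- acc_con[keep, , drop = FALSE]
    acc_obs <- acc_obs[keep, , drop = FALSE]
    rnames <- rnames[keep]
  }
  # Global row: exact sum of the same summands
  acc_con <- rbind(acc_con, Global = colSums(acc_con))
  acc_obs <- rbind(acc_obs, Global = colSums(acc_obs))
  rnames <- c(rnames, "Global")

  out <- expand.grid(region = rnames, crop_group = group_levels,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$observed_t <- as.vector(acc_obs)
  out$contribution_t <- as.vector(acc_con)
  out$counterfactual_t <- out$observed_t - out$contribution_t
  out$contribution_pct <- ifelse(out$observed_t > 0,
                                 100 * out$contribution_t / out$observed_t,
                                 NA_real_)
  out[order(match(out$region, rnames), match(out$crop_group, group_levels)),
      c("region", "crop_group", "observed_t", "counterfactual_t",
        "contribution_t", "contribution_pct")]
}

#' Global summary (single all-covering region)
#'
#' Identical to [regional_summary()] with one region spanning every cell:
#' one row per crop group.
#'
#' @inheritParams regional_summary
#' @return data.frame with one row per crop group.
#' @export
global_summary <- function(contributions, observed, groups,
                           denominator = c("analyzed", "all")) {
  g1 <- contributions[[1L]]
  geom <- grid_geometry(g1)
  world <- region_map(category_grid(
    matrix(1L, geom$dim[1], geom$dim[2]), levels = "Global_",
    factor_name = "region", origin = geom$origin, cellsize = geom$cellsize))
  res <- regional_summary(contributions, observed, world, groups,
                          denominator = denominator)
  res <- res[res$region == "Global_", , drop = FALSE]
  res$region <- "Global"
  rownames(res) <- NULL
  res
}
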