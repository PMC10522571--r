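#' Layer preparation: soil depth aggregation, classification, upscaling
#'
#' Rules that turn raw gridded inputs into the categorical drivers of the
#' effect model: thickness-weighted merging of standard soil depth intervals,
#' threshold classification of pH / texture / N application rate, and block
#' averaging to a coarser resolution that excludes missing cells.
#'
#' @name geo_layers
NULL

# Standard soil depth intervals (cm): 0-5, 5-15, 15-30, 30-60, 60-100.
SOIL_DEPTH_THICKNESS <- c(5, 10, 15, 30, 40)

#' Thickness-weighted average of a soil depth stack
#'
#' Merges property rasters for the five standard depth intervals (0-5, 5-15,
#' 15-30, 30-60, 60-100 cm) into a single 0-100 cm value per cell, weighting
#' each layer by its thickness (weights 5, 10, 15, 30, 40 out of 100).
#'
#' @param layer_stack List of exactly five `worm_grid`s, shallowest first,
#'   sharing one geometry.
#' @param renormalize If `TRUE` (default), cells where some layers are missing
#'   use weights renormalized over the available layers; if `FALSE`, any
#'   missing layer makes the cell missing. All-missing cells are always
#'   missing.
#' @return A `worm_grid` of depth-weighted means.
#' @export
depth_weighted_average <- function(layer_stack, renormalize = TRUE) {
  if (!is.list(layer_stack) || length(layer_stack) != length(SOIL_DEPTH_THICKNESS)) {
    stop(sprintf("`layer_stack` must be a list of %d grids (one per depth interval)",
                 length(SOIL_DEPTH_THICKNESS)), call. = FALSE)
  }
  geom <- align_check(layer_stack)
  w <- SOIL_DEPTH_THICKNESS / sum(SOIL_DEPTH_THICKNESS)
  num <- matrix(0, geom$dim[1], geom$dim[2])
  den <- matrix(0, geom$dim[1], geom$dim[2])
  anymiss <- matrix(FALSE, geom$dim[1], geom$dim[2])
  for (l in seq_along(layer_stack)) {
    v <- layer_stack[[l]]$values
    ok <- !is.na(v)
    num[ok] <- num[ok] + w[l] * v[ok]
    den[ok] <- den[ok] + w[l]
    anymiss <- anymiss | !ok
  }
  out <- num / den
  out[den == 0] <- NA_real_
  if (!renormalize) out[anymiss] <- NA_real_
  worm_grid(out, origin = geom$origin, cellsize = geom$cellsize)
}

#' Classify soil pH into Low / Medium / High
#'
#' Low: pH < 5.6; Medium: 5.6 <= pH <= 7.0; High: pH > 7.0. The interval
#' boundaries belong to Medium. Values outside a plausible soil range are
#' flagged with a warning but still classified.
#'
#' @param ph `worm_grid` of pH values.
#' @param plausible Length-2 range used for the plausibility warning.
#' @return `category_grid` with levels Low, Medium, High (factor `soil_ph`).
#' @export
classify_ph <- function(ph, plausible = c(2, 11)) {
  v <- ph$values
  out_of_range <- !is.na(v) & (v < plausible[1] | v > plausible[2])
  if (any(out_of_range)) {
    warning(sprintf("%d pH value(s) outside plausible range [%g, %g]",
                    sum(out_of_range), plausible[1], plausible[2]), call. = FALSE)
  }
  codes <- matrix(NA_integer_, nrow(v), ncol(v))
  codes[!is.na(v) & v < 5.6] <- 1L
  codes[!is.na(v) & v >= 5.6 & v <= 7.0] <- 2L
  codes[!is.na(v) & v > 7.0] <- 3L
  category_grid(codes, levels = c("Low", "Medium", "High"),
                factor_name = "soil_ph",
                origin = ph$origin, cellsize = ph$cellsize)
}

#' Classify soil texture into Sandy / Loamy / Clayey
#'
#' Sandy: sand > 70%; Clayey: clay > 35%; Loamy otherwise (sand <= 70% and
#' clay <= 35%). Under the constraint sand + clay <= 100 the Sandy and Clayey
#' conditions cannot co-occur, so the classes partition the valid domain.
#'
#' @param sand,clay `worm_grid`s of sand and clay mass percentages (0-100),
#'   sharing one geometry.
#' @return `category_grid` with levels Sandy, Loamy, Clayey
#'   (factor `soil_texture`).
#' @export
classify_texture <- function(sand, clay) {
  align_check(list(sand, clay))
  s <- sand$values; c_ <- clay$values
  ok <- !is.na(s) & !is.na(c_)
  if (any(ok & (s < 0 | c_ < 0 | s + c_ > 100))) {
    stop("invalid texture composition: need sand, clay >= 0 and sand + clay <= 100",
         call. = FALSE)
  }
  codes <- matrix(NA_integer_, nrow(s), ncol(s))
  codes[ok] <- 2L                 # Loamy unless a threshold is exceeded
  codes[ok & s > 70] <- 1L
  codes[ok & c_ > 35] <- 3L
  category_grid(codes, levels = c("Sandy", "Loamy", "Clayey"),
                factor_name = "soil_texture",
                origin = sand$origin, cellsize = sand$cellsize)
}

#' Classify N application rate into Low / High
#'
#' Low: rate <= 30 kg N ha^-1 yr^-1 (inclusive); High above that.
#'
#' @param n_rate `worm_grid` of crop-specific N application rates
#'   (kg N ha^-1 yr^-1, >= 0).
#' @return `category_grid` with levels Low, High (factor `n_rate`).
#' @export
classify_n_rate <- function(n_rate) {
  v <- n_rate$values
  if (any(v < 0, na.rm = TRUE)) {
    stop("N application rates must be nonnegative", call. = FALSE)
  }
  codes <- matrix(NA_integer_, nrow(v), ncol(v))
  codes[!is.na(v) & v <= 30] <- 1L
  codes[!is.na(v) & v > 30] <- 2L
  category_grid(codes, levels = c("Low", "High"), factor_name = "n_rate",
                origin = n_rate$origin, cellsize = n_rate$cellsize)
}

#' Upscale a grid by block averaging, excluding missing cells
#'
#' Each coarse cell is the mean of the non-missing fine cells inside its
#' `block` x `block` footprint; a footprint with no valid cells is missing.
#' When the fine dimensions are not divisible by `block`, the grid is padded
#' with missing cells at its south and east edges.
#'
#' @param fine `worm_grid` at the fine resolution.
#' @param block Integer aggregation factor (>= 1).
#' @return `worm_grid` with cell size `fine$cellsize * block`; the origin cell
#'   center shifts to the center of the first coarse block.
#' @export
upscale_mean <- function(fine, block) {
  block <- as.integer(block)
  if (is.na(block) || block < 1L) stop("`block` must be an integer >= 1", call. = FALSE)
  if (block == 1L) return(fine)
  v <- fine$values
  nr <- ceiling(nrow(v) / block) * block
  nc <- ceiling(ncol(v) / block) * block
  vp <- matrix(NA_real_, nr, nc)
  vp[seq_len(nrow(v)), seq_len(ncol(v))] <- v
  ok <- !is.na(vp)
  vp[!ok] <- 0
  rgrp <- rep(seq_len(nr / block), each = block)
  cgrp <- rep(seq_len(nc / block), each = block)
  gsum <- t(rowsum(t(rowsum(vp, rgrp)), cgrp))
  gcnt <- t(rowsum(t(rowsum(ok + 0, rgrp)), cgrp))
  out <- gsum / gcnt
  out[gcnt == 0] <- NA_real_
  dimnames(out) <- NULL
  # cell centers: first coarse center sits (block-1)/2 fine cells SE of the
  # first fine center
  shift <- (block - 1) / 2 * fine$cellsize / 60
  worm_grid(out,
            origin = c(fine$origin[1] + shift, fine$origin[2] - shift),
            cellsize = fine$cellsize * block)
}
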