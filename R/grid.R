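#' Gridded raster field
#'
#' The package's universal raster currency: a 2-D numeric field with simple
#' georeferencing (cell-center registered, north-up, longitude-latitude axes)
#' and an explicit missing-data mask. Masked cells carry `NA` in `values` and
#' `TRUE` in `mask`; the two are kept in sync by construction.
#'
#' @param values Numeric matrix. Rows run north to south, columns west to east.
#' @param origin Length-2 numeric, longitude and latitude of the *center* of
#'   the north-west (top-left) cell, in degrees.
#' @param cellsize Cell size in arcminutes (> 0).
#' @param mask Optional logical matrix of the same shape; `TRUE` marks missing
#'   cells. `NA`s already present in `values` are always treated as missing.
#' @return An object of class `worm_grid` with fields `values`, `origin`,
#'   `cellsize`.
#' @export
worm_grid <- function(values, origin = c(-180, 90), cellsize = 5, mask = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(origin) != 2L || !is.numeric(origin)) {
    stop("`origin` must be numeric length 2 (lon, lat)", call. = FALSE)
  }
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0) {
    stop("`cellsize` must be a single positive number (arcminutes)", call. = FALSE)
  }
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(values))) {
      stop("`mask` and `values` must have identical shape", call. = FALSE)
    }
    values[mask] <- NA_real_
  }
  structure(
    list(values = values, origin = as.numeric(origin), cellsize = as.numeric(cellsize)),
    class = "worm_grid"
  )
}

#' @export
print.worm_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<worm_grid> %d x %d cells, %.4g' resolution, origin (%.4g, %.4g)\n",
    nrow(v), ncol(v), x$cellsize, x$origin[1], x$origin[2]
  ))
  ok <- !is.na(v)
  cat(sprintf(
    "  %d missing; range of valid cells: [%.4g, %.4g]\n",
    sum(!ok), if (any(ok)) min(v[ok]) else NA, if (any(ok)) max(v[ok]) else NA
  ))
  invisible(x)
}

#' @export
dim.worm_grid <- function(x) dim(x$values)

#' Missing-data mask of a grid
#'
#' @param g A `worm_grid` or `category_grid`.
#' @return Logical matrix, `TRUE` where the cell is missing.
#' @export
grid_mask <- function(g) {
  if (inherits(g, "category_grid")) is.na(g$codes) else is.na(g$values)
}

#' Grid geometry descriptor
#'
#' @param g A `worm_grid` or `category_grid`.
#' @return List with `dim`, `origin`, `cellsize`.
#' @export
grid_geometry <- function(g) {
  d <- if (inherits(g, "category_grid")) dim(g$codes) else dim(g$values)
  list(dim = d, origin = g$origin, cellsize = g$cellsize)
}

#' Validate that grids share a common geometry
#'
#' All downstream per-cell arithmetic assumes identical shape, origin and cell
#' size; this checks the assumption and returns the shared geometry.
#'
#' @param grids List of `worm_grid` / `category_grid` objects (at least one).
#' @param tol Numeric tolerance on origin and cell size comparisons, in the
#'   units of the fields themselves (degrees / arcminutes).
#' @return The shared geometry (as [grid_geometry()]), invisibly usable.
#' @export
align_check <- function(grids, tol = 1e-9) {
  if (!is.list(grids) || length(grids) < 1L) {
    stop("`grids` must be a non-empty list of grids", call. = FALSE)
  }
  ref <- grid_geometry(grids[[1L]])
  for (i in seq_along(grids)[-1L]) {
    g <- grid_geometry(grids[[i]])
    if (!identical(g$dim, ref$dim)) {
      stop(sprintf("grid %d shape (%d x %d) does not match (%d x %d)",
                   i, g$dim[1], g$dim[2], ref$dim[1], ref$dim[2]), call. = FALSE)
    }
    if (max(abs(g$origin - ref$origin)) > tol) {
      stop(sprintf("grid %d origin differs from reference", i), call. = FALSE)
    }
    if (abs(g$cellsize - ref$cellsize) > tol) {
      stop(sprintf("grid %d cell size differs from reference", i), call. = FALSE)
    }
  }
  ref
}

#' Categorical raster field
#'
#' A grid whose cells hold labels from a closed category set belonging to one
#' classification factor (soil pH class, textural class, N-rate class, region).
#' Stored as integer codes indexing `levels`, with `NA` for missing.
#'
#' @param codes Integer matrix of 1-based level codes (`NA` = missing).
#' @param levels Character vector of category labels (unique).
#' @param factor_name Name of the classification factor the labels belong to.
#' @inheritParams worm_grid
#' @return An object of class `category_grid`.
#' @export
category_grid <- function(codes, levels, factor_name,
                          origin = c(-180, 90), cellsize = 5) {
  if (!is.matrix(codes)) codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  levels <- as.character(levels)
  if (anyDuplicated(levels)) stop("category levels must be unique", call. = FALSE)
  bad <- !is.na(codes) & (codes < 1L | codes > length(levels))
  if (any(bad)) stop("category codes outside the level set", call. = FALSE)
  structure(
    list(codes = codes, levels = levels, factor_name = as.character(factor_name),
         origin = as.numeric(origin), cellsize = as.numeric(cellsize)),
    class = "category_grid"
  )
}

#' @export
print.category_grid <- function(x, ...) {
  cat(sprintf("<category_grid> factor '%s', %d x %d cells, levels: %s\n",
              x$factor_name, nrow(x$codes), ncol(x$codes),
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' @export
dim.category_grid <- function(x) dim(x$codes)

#' Labels of a categorical grid
#'
#' @param g A `category_grid`.
#' @return Character matrix of labels (`NA` where missing).
#' @export
category_labels <- function(g) {
  out <- matrix(g$levels[g$codes], nrow = nrow(g$codes))
  out
}

# Build a worm_grid carrying per-cell numbers looked up from a category grid.
# `table` is a named numeric vector keyed by category label. Every label that
# actually occurs in an unmasked cell must have an entry.
lookup_grid <- function(cat, table) {
  stopifnot(inherits(cat, "category_grid"))
  used <- cat$levels[sort(unique(cat$codes[!is.na(cat$codes)]))]
  unknown <- setdiff(used, names(table))
  if (length(unknown)) {
    stop(sprintf("no coefficient for category label(s): %s (factor '%s')",
                 paste(unknown, collapse = ", "), cat$factor_name), call. = FALSE)
  }
  lev_vals <- unname(table[cat$levels])
  v <- matrix(lev_vals[cat$codes], nrow = nrow(cat$codes))
  worm_grid(v, origin = cat$origin, cellsize = cat$cellsize)
}

# Elementwise binary op preserving geometry; NA propagates.
grid_map2 <- function(a, b, f) {
  align_check(list(a, b))
  worm_grid(f(a$values, b$values), origin = a$origin, cellsize = a$cellsize)
}

# Elementwise unary op preserving geometry.
grid_map <- function(g, f) {
  worm_grid(f(g$values), origin = g$origin, cellsize = g$cellsize)
}
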