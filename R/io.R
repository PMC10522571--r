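#' Raster and table input/output
#'
#' Grids are stored as ESRI ASCII grids (`.asc`): a plain-text single-band
#' raster format with an explicit `NODATA_value` that maps one-to-one onto the
#' missing-data mask. Category grids are stored as integer-coded `.asc` files
#' with a sidecar CSV legend (`code`, `factor`, `label`).
#'
#' @name io
NULL

#' Write a grid as an ESRI ASCII raster
#'
#' @param g `worm_grid` or `category_grid`.
#' @param path Output path (conventionally `.asc`).
#' @param nodata Value written for missing cells.
#' @return `path`, invisibly. For category grids a legend CSV is written next
#'   to the raster at `<path>.legend.csv`.
#' @export
write_asc <- function(g, path, nodata = -9999) {
  is_cat <- inherits(g, "category_grid")
  v <- if (is_cat) g$codes else g$values
  cs_deg <- g$cellsize / 60
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.12g", g$origin[1] - cs_deg / 2),
    sprintf("yllcorner %.12g", g$origin[2] + cs_deg / 2 - nrow(v) * cs_deg),
    sprintf("cellsize %.12g", cs_deg),
    sprintf("NODATA_value %g", nodata)
  )
  body <- apply(v, 1L, function(row) {
    row[is.na(row)] <- nodata
    paste(sprintf("%.17g", row), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  if (is_cat) {
    legend <- data.frame(code = seq_along(g$levels), factor = g$factor_name,
                         label = g$levels)
    utils::write.csv(legend, paste0(path, ".legend.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' If a sidecar legend (`<path>.legend.csv`) exists, the file is read as a
#' `category_grid`; otherwise as a `worm_grid`.
#'
#' @param path Path to the `.asc` file.
#' @return `worm_grid` or `category_grid`.
#' @export
read_asc <- function(path) {
  if (!file.exists(path)) stop("raster not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("ASCII grid body size does not match header in ", path, call. = FALSE)
  }
  v <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  v[v == nodata] <- NA_real_
  cs_deg <- hdr$cellsize
  origin <- c(hdr$xllcorner + cs_deg / 2,
              hdr$yllcorner + hdr$nrows * cs_deg - cs_deg / 2)
  legend_path <- paste0(path, ".legend.csv")
  if (file.exists(legend_path)) {
    legend <- utils::read.csv(legend_path, stringsAsFactors = FALSE)
    codes <- matrix(as.integer(v), nrow = nrow(v))
    return(category_grid(codes, levels = legend$label[order(legend$code)],
                         factor_name = legend$factor[[1L]],
                         origin = origin, cellsize = cs_deg * 60))
  }
  worm_grid(v, origin = origin, cellsize = cs_deg * 60)
}

#' Write a coefficient table as CSV
#'
#' @param tab data.frame from [coefficient_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_coefficient_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write an effect-size table as CSV
#'
#' @param effect_table data.frame as returned by [read_effect_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_effect_table <- function(effect_table, path) {
  utils::write.csv(effect_table, path, row.names = FALSE)
  invisible(path)
}
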