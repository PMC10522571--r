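#' Meta-analysis effect sizes and multiplicative coefficients
#'
#' Earthworm presence increases aboveground plant biomass by about 23.3% on
#' average across mesocosm add/exclude experiments, but the size of the effect
#' depends on crop type, soil pH, soil texture and nitrogen application rate.
#' The functions here turn transcribed per-category effect sizes (percent
#' biomass change, with meta-analytic sample sizes) into dimensionless
#' multiplicative coefficients: each category's coefficient is its effect
#' divided by the sample-size-weighted mean effect of its factor, so that the
#' weighted mean coefficient is 1 and the coefficients rescale the average
#' 23.3% effect up or down.
#'
#' @name meta_coefficients
NULL

#' Baseline fractional earthworm effect on aboveground biomass
#'
#' Average effect across the underlying meta-analysis (a 23.3% increase),
#' expressed as a fraction.
#' @export
BASELINE_EFFECT <- 0.233

#' Read the transcribed effect-size table
#'
#' Loads a CSV with columns `factor`, `category`, `sample_size`,
#' `effect_percent`, `applies_to_map`. The package ships a transcription of
#' the published per-category effect sizes as its default table.
#'
#' `applies_to_map = FALSE` marks categories (grasses) that have no
#' corresponding global crop data layer: they still enter the weighted mean
#' of their factor but receive no map coefficient.
#'
#' @param path Path to the CSV; default is the shipped table.
#' @return data.frame with one row per category.
#' @export
read_effect_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "effect_sizes.csv", package = "wormyield")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("effect-size table not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("factor", "category", "sample_size", "effect_percent")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("effect-size table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("effect-size table is empty", call. = FALSE)
  if (is.null(df$applies_to_map)) df$applies_to_map <- TRUE
  df$applies_to_map <- as.logical(df$applies_to_map)
  if (any(df$sample_size <= 0)) {
    stop("sample sizes must be positive", call. = FALSE)
  }
  dup <- duplicated(df[c("factor", "category")])
  if (any(dup)) stop("duplicate factor/category rows in effect table", call. = FALSE)
  df
}

check_one_factor <- function(categories) {
  if (!is.data.frame(categories) || nrow(categories) == 0L) {
    stop("need at least one effect-size category", call. = FALSE)
  }
  if (length(unique(categories$factor)) != 1L) {
    stop("all categories must belong to the same factor", call. = FALSE)
  }
  if (any(categories$sample_size <= 0)) {
    stop("sample sizes must be positive", call. = FALSE)
  }
  invisible(categories)
}

#' Sample-size-weighted mean effect for one factor
#'
#' \eqn{\bar e = \sum_j n_j e_j / \sum_j n_j} over all categories of the
#' factor, including categories that have no map layer (they still carry
#' meta-analytic information about the factor's average effect).
#'
#' @param categories data.frame rows of the effect table for a single factor.
#' @return Weighted mean effect, in percent.
#' @export
weighted_mean_effect <- function(categories) {
  check_one_factor(categories)
  sum(categories$sample_size * categories$effect_percent) /
    sum(categories$sample_size)
}

#' Derive multiplicative coefficients for one factor
#'
#' Coefficient for category \eqn{j} is \eqn{e_j / \bar e}: the ratio of the
#' category's effect to the factor's sample-size-weighted mean effect. By
#' construction the sample-size-weighted mean of the coefficients is 1.
#' Categories flagged `applies_to_map = FALSE` contribute to \eqn{\bar e} but
#' get no coefficient.
#'
#' @inheritParams weighted_mean_effect
#' @return List of class `factor_coefficients` with fields `factor`,
#'   `weighted_mean_effect_percent`, and `coefficients` (named numeric vector,
#'   one entry per mapped category).
#' @export
derive_coefficients <- function(categories) {
  check_one_factor(categories)
  wm <- weighted_mean_effect(categories)
  if (abs(wm) < .Machine$double.eps^0.5) {
    stop("weighted mean effect is zero; coefficients undefined", call. = FALSE)
  }
  keep <- categories$applies_to_map
  if (is.null(keep)) keep <- rep(TRUE, nrow(categories))
  co <- categories$effect_percent[keep] / wm
  names(co) <- categories$category[keep]
  structure(
    list(factor = categories$factor[[1L]],
         weighted_mean_effect_percent = wm,
         coefficients = co),
    class = "factor_coefficients"
  )
}

#' @export
print.factor_coefficients <- function(x, ...) {
  cat(sprintf("<factor_coefficients> %s (weighted mean effect %.2f%%)\n",
              x$factor, x$weighted_mean_effect_percent))
  print(round(x$coefficients, 3))
  invisible(x)
}

#' Derive coefficients for every factor in an effect table
#'
#' @param effect_table data.frame as returned by [read_effect_table()].
#' @return Named list of `factor_coefficients`, one per factor, in table order.
#' @export
derive_all_coefficients <- function(effect_table) {
  factors <- unique(effect_table$factor)
  out <- lapply(factors, function(f) {
    derive_coefficients(effect_table[effect_table$factor == f, , drop = FALSE])
  })
  names(out) <- factors
  out
}

#' Coefficient table as a flat data.frame
#'
#' One row per mapped category with its coefficient and the factor's weighted
#' mean effect; suitable for writing to CSV.
#'
#' @inheritParams derive_all_coefficients
#' @return data.frame with columns `factor`, `category`, `coefficient`,
#'   `weighted_mean_effect_percent`.
#' @export
coefficient_table <- function(effect_table = read_effect_table()) {
  all <- derive_all_coefficients(effect_table)
  do.call(rbind, lapply(all, function(fc) {
    data.frame(factor = fc$factor,
               category = names(fc$coefficients),
               coefficient = unname(fc$coefficients),
               weighted_mean_effect_percent = fc$weighted_mean_effect_percent,
               row.names = NULL)
  }))
}

#' Earthworm-abundance power-law parameters
#'
#' The continuous abundance response: multiplier \eqn{= k \cdot x^b} with
#' abundance \eqn{x} in individuals per square metre. The shipped defaults are
#' the published best-fit values \eqn{k = 0.1032}, \eqn{b = 0.409}; the
#' multiplier passes through 0 at zero abundance and reaches 1 near 258
#' individuals per square metre, so sparse earthworm populations scale the
#' average effect far below its mean.
#'
#' @param prefactor Positive scale \eqn{k}.
#' @param exponent Positive exponent \eqn{b}.
#' @return List of class `abundance_power_params`.
#' @export
abundance_power_params <- function(prefactor = 0.1032, exponent = 0.409) {
  if (!is.numeric(prefactor) || prefactor <= 0) {
    stop("`prefactor` must be positive", call. = FALSE)
  }
  if (!is.numeric(exponent) || exponent <= 0) {
    stop("`exponent` must be positive", call. = FALSE)
  }
  structure(list(prefactor = prefactor, exponent = exponent),
            class = "abundance_power_params")
}

#' Continuous abundance multiplier
#'
#' Evaluates \eqn{k \cdot x^b} elementwise. Strictly increasing in abundance,
#' zero at zero abundance; `NA` propagates.
#'
#' @param abundance Numeric vector/matrix of abundances (individuals m^-2,
#'   >= 0), or a [worm_grid()].
#' @param params [abundance_power_params()].
#' @return Same shape as `abundance`; a `worm_grid` in, a `worm_grid` out.
#' @export
abundance_multiplier <- function(abundance, params = abundance_power_params()) {
  if (inherits(abundance, "worm_grid")) {
    return(grid_map(abundance, function(v) abundance_multiplier(v, params)))
  }
  if (any(abundance < 0, na.rm = TRUE)) {
    stop("abundance must be nonnegative", call. = FALSE)
  }
  params$prefactor * abundance^params$exponent
}

#' Fit a power law to (abundance, multiplier) pairs
#'
#' Ordinary least squares on the log-log transformed points:
#' \eqn{\log m = \log k + b \log x}. On noiseless power-law data this recovers
#' the generating parameters to numerical precision. Provided for users who
#' wish to refit the abundance response from their own data; the shipped
#' default parameters are not altered by any refit.
#'
#' @param abundance Positive abundances (>= 2 points).
#' @param multiplier Positive multipliers, same length.
#' @return [abundance_power_params()] with the fitted values.
#' @export
fit_abundance_power <- function(abundance, multiplier) {
  if (length(abundance) != length(multiplier)) {
    stop("`abundance` and `multiplier` must have the same length", call. = FALSE)
  }
  if (length(abundance) < 2L) {
    stop("need at least two points to fit a power law", call. = FALSE)
  }
  if (any(abundance <= 0) || any(multiplier <= 0)) {
    stop("power-law fitting requires strictly positive values", call. = FALSE)
  }
  fit <- stats::lm(log(multiplier) ~ log(abundance))
  b <- unname(stats::coef(fit)[2L])
  k <- exp(unname(stats::coef(fit)[1L]))
  # a flat cloud fits b = 0 (constant); keep that honest rather than clamping
  structure(list(prefactor = k, exponent = b),
            class = "abundance_power_params")
}
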