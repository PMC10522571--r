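# Small fixtures shared across tests; everything built in code.

tiny_grid <- function(v, nr = NULL, nc = NULL, ...) {
  if (is.matrix(v)) return(worm_grid(v, ...))
  worm_grid(matrix(v, nr, nc), ...)
}

# A fully valid 4x4 world-by-hand with controllable drivers, for unit tests
# that should not depend on the synthetic generator.
hand_world <- function(ph = 6.0, sand = 40, clay = 20, n_rate = 10,
                       abundance = 100, yield = 5, area = 100,
                       crop_type = "cereal") {
  g <- function(x) worm_grid(matrix(x, 4, 4))
  list(
    abundance = g(abundance),
    ph_stack = replicate(5, g(ph), simplify = FALSE),
    sand = g(sand), clay = g(clay),
    crops = list(test = crop_layer("test", yield = g(yield), area = g(area),
                                   n_rate = g(n_rate), crop_type = crop_type)),
    regions = region_map(category_grid(matrix(1L, 4, 4), levels = "R1",
                                       factor_name = "region"))
  )
}

table1_factors <- function() split(read_effect_table(), read_effect_table()$factor)
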