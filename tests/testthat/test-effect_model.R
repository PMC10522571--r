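# Per-cell effect model, counterfactual yields, attributable production.

test_that("effect equals the hand-computed product of coefficients", {
  # cereal, Low pH, Clayey, Low N, abundance 100
  w <- hand_world(ph = 5.0, sand = 10, clay = 50, n_rate = 10, abundance = 100)
  params <- default_effect_params()
  eg <- earthworm_effect(w$crops$test, classify_ph(depth_weighted_average(w$ph_stack)),
                         classify_texture(w$sand, w$clay), w$abundance, params)
  co <- params$coefficients
  a <- 0.1032 * 100^0.409
  expected <- co$crop_type$coefficients[["Cereal grains"]] *
    co$soil_ph$coefficients[["Low"]] *
    co$soil_texture$coefficients[["Clayey"]] *
    co$n_rate$coefficients[["Low"]] * a * 0.233
  expect_equal(eg$E$values, matrix(expected, 4, 4))
  # the printed (rounded) coefficients give ~0.455 at this driver combination
  expect_equal(1.271 * 1.235 * 1.711 * 1.071 * a * 0.233, expected,
               tolerance = 2e-3)
})

test_that("zero abundance annihilates the effect; unit factors give the baseline", {
  w <- hand_world(abundance = 0)
  params <- default_effect_params()
  eg <- earthworm_effect(w$crops$test, classify_ph(depth_weighted_average(w$ph_stack)),
                         classify_texture(w$sand, w$clay), w$abundance, params)
  expect_equal(eg$E$values, matrix(0, 4, 4))

  unit <- lapply(c(crop_type = 1, soil_ph = 1, soil_texture = 1, n_rate = 1),
                 function(z) NULL)
  unit$crop_type <- list(factor = "crop_type", weighted_mean_effect_percent = 1,
                         coefficients = c("Cereal grains" = 1, "Legumes" = 1))
  unit$soil_ph <- list(factor = "soil_ph", weighted_mean_effect_percent = 1,
                       coefficients = c(Low = 1, Medium = 1, High = 1))
  unit$soil_texture <- list(factor = "soil_texture", weighted_mean_effect_percent = 1,
                            coefficients = c(Sandy = 1, Loamy = 1, Clayey = 1))
  unit$n_rate <- list(factor = "n_rate", weighted_mean_effect_percent = 1,
                      coefficients = c(Low = 1, High = 1))
  # abundance multiplier forced to 1 via k = 1, b -> handled by abundance = 1
  p1 <- effect_params(coefficients = unit,
                      abundance_params = abundance_power_params(1, 1))
  w1 <- hand_world(abundance = 1)
  eg1 <- earthworm_effect(w1$crops$test, classify_ph(depth_weighted_average(w1$ph_stack)),
                          classify_texture(w1$sand, w1$clay), w1$abundance, p1)
  expect_equal(eg1$E$values, matrix(0.233, 4, 4))
})

test_that("missing drivers mask the effect and negative coefficients clamp to zero", {
  w <- hand_world()
  ab <- w$abundance; ab$values[1, 1] <- NA
  ph_cat <- classify_ph(depth_weighted_average(w$ph_stack))
  tex <- classify_texture(w$sand, w$clay)
  eg <- earthworm_effect(w$crops$test, ph_cat, tex, ab)
  expect_true(is.na(eg$E$values[1, 1]))
  expect_false(anyNA(eg$E$values[-1]))

  neg <- default_effect_params()
  neg$coefficients$soil_ph$coefficients["Medium"] <- -1
  expect_warning(
    egn <- earthworm_effect(w$crops$test, ph_cat, tex, w$abundance, neg),
    "clamped")
  expect_equal(egn$E$values, matrix(0, 4, 4))
})

test_that("effect is monotone in abundance and in coefficient upgrades", {
  w <- hand_world()
  ph_cat <- classify_ph(depth_weighted_average(w$ph_stack))
  tex <- classify_texture(w$sand, w$clay)
  E_at <- function(ab) earthworm_effect(
    w$crops$test, ph_cat, tex, worm_grid(matrix(ab, 4, 4)))$E$values[1, 1]
  abs_seq <- c(0, 1, 10, 50, 100, 400)
  expect_true(all(diff(vapply(abs_seq, E_at, numeric(1))) > 0))

  # swapping Loamy -> Clayey (larger coefficient) never decreases E
  w_loam <- hand_world(sand = 40, clay = 20)
  w_clay <- hand_world(sand = 10, clay = 50)
  E_of <- function(w) earthworm_effect(
    w$crops$test, classify_ph(depth_weighted_average(w$ph_stack)),
    classify_texture(w$sand, w$clay), w$abundance)$E$values
  expect_true(all(E_of(w_clay) >= E_of(w_loam)))
})

test_that("vectorized effect equals a per-cell scalar oracle on random grids", {
  set.seed(11)
  params <- default_effect_params()
  nr <- 15; nc <- 12
  g <- function(v) worm_grid(matrix(v, nr, nc))
  ph_vals <- matrix(runif(nr * nc, 4, 8.5), nr, nc)
  sand_v <- matrix(runif(nr * nc, 5, 90), nr, nc)
  clay_v <- (100 - sand_v) * matrix(runif(nr * nc, 0.05, 0.8), nr, nc)
  nrate_v <- matrix(rexp(nr * nc, 1 / 40), nr, nc)
  ab_v <- matrix(rlnorm(nr * nc, log(30), 1), nr, nc)
  ab_v[sample(nr * nc, 20)] <- NA
  cl <- crop_layer("x", yield = g(5), area = g(10), n_rate = g(nrate_v),
                   crop_type = "legume")
  eg <- earthworm_effect(cl, classify_ph(g(ph_vals)),
                         classify_texture(g(sand_v), g(clay_v)), g(ab_v), params)
  co <- params$coefficients
  oracle <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(ab_v[i, j])) next
    p <- if (ph_vals[i, j] < 5.6) "Low" else if (ph_vals[i, j] <= 7) "Medium" else "High"
    t_ <- if (sand_v[i, j] > 70) "Sandy" else if (clay_v[i, j] > 35) "Clayey" else "Loamy"
    n <- if (nrate_v[i, j] <= 30) "Low" else "High"
    oracle[i, j] <- co$crop_type$coefficients[["Legumes"]] *
      co$soil_ph$coefficients[[p]] * co$soil_texture$coefficients[[t_]] *
      co$n_rate$coefficients[[n]] * 0.1032 * ab_v[i, j]^0.409 * 0.233
  }
  expect_equal(eg$E$values, oracle, tolerance = 1e-12)
})

test_that("counterfactual yields follow the chosen convention", {
  y <- tiny_grid(5, 2, 2)
  E <- tiny_grid(0.25, 2, 2)
  expect_equal(counterfactual_yield(y, E)$values, matrix(4, 2, 2))
  expect_equal(counterfactual_yield(y, tiny_grid(0, 2, 2))$values, matrix(5, 2, 2))
  # E = 1 halves the counterfactual: contribution is 50% of observed
  half <- counterfactual_yield(y, tiny_grid(1, 2, 2))
  expect_equal((y$values - half$values) / y$values, matrix(0.5, 2, 2))
  fwd <- counterfactual_yield(y, E, mode = "forward_multiplication")
  expect_equal(fwd$values, y$values)
  expect_error(counterfactual_yield(y, E, mode = "nonsense"))
})

test_that("production contribution multiplies yield gain by area with mask rules", {
  y_obs <- tiny_grid(c(5, 5, NA, 5), 2, 2)
  y_wo <- tiny_grid(c(4, 4, 4, 4), 2, 2)
  area <- tiny_grid(c(100, 0, 100, 50), 2, 2)
  con <- production_contribution(y_obs, y_wo, area)
  expect_equal(c(con$values), c(100, 0, NA, 50))
  expect_error(production_contribution(y_obs, y_wo, tiny_grid(-1, 2, 2)),
               "nonnegative")
})

test_that("relative contribution per cell equals E/(1+E) in division mode", {
  set.seed(12)
  E <- tiny_grid(matrix(rexp(25, 2), 5, 5))
  y <- tiny_grid(matrix(runif(25, 1, 10), 5, 5))
  y_wo <- counterfactual_yield(y, E)
  rel <- (y$values - y_wo$values) / y$values
  expect_equal(rel, E$values / (1 + E$values), tolerance = 1e-12)
  expect_true(all(rel >= 0 & rel < 1))
})
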