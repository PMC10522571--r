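# Area-weighted cross-crop effects and regional/global production summaries.

test_that("area-weighted effect averages by harvested area", {
  E1 <- tiny_grid(0.1, 2, 2); E2 <- tiny_grid(0.3, 2, 2)
  a_eq <- tiny_grid(50, 2, 2)
  expect_equal(area_weighted_effect(list(E1, E2), list(a_eq, a_eq))$values,
               matrix(0.2, 2, 2))
  expect_equal(area_weighted_effect(list(E1), list(a_eq))$values, E1$values)
  # zero-area crop contributes nothing
  expect_equal(area_weighted_effect(list(E1, E2),
                                    list(tiny_grid(0, 2, 2), a_eq))$values,
               matrix(0.3, 2, 2))
  # no valid crop anywhere -> missing
  expect_true(all(is.na(area_weighted_effect(
    list(E1), list(tiny_grid(0, 2, 2)))$values)))
  expect_error(area_weighted_effect(list(E1), list(a_eq, a_eq)), "same length")
  # output bounded by the per-cell effect range
  set.seed(21)
  Es <- replicate(3, tiny_grid(matrix(runif(16), 4, 4)), simplify = FALSE)
  As <- replicate(3, tiny_grid(matrix(rexp(16, 1 / 50), 4, 4)), simplify = FALSE)
  out <- area_weighted_effect(Es, As)$values
  lo <- Reduce(pmin, lapply(Es, function(g) g$values))
  hi <- Reduce(pmax, lapply(Es, function(g) g$values))
  expect_true(all(out >= lo - 1e-12 & out <= hi + 1e-12))
})

test_that("regional summary sums production and reports percent of observed", {
  codes <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  regions <- region_map(category_grid(codes, levels = c("A", "B"),
                                      factor_name = "region"))
  con <- list(wheat = tiny_grid(c(40, 60, 100, 0), 2, 2))
  obs <- list(wheat = tiny_grid(c(400, 600, 500, 500), 2, 2))
  res <- regional_summary(con, obs, regions, c(wheat = "cereal"))
  a <- res[res$region == "A" & res$crop_group == "cereal", ]
  expect_equal(a$observed_t, 1000)
  expect_equal(a$contribution_t, 100)
  expect_equal(a$contribution_pct, 10)
  expect_equal(a$counterfactual_t, 900)
  g <- res[res$region == "Global" & res$crop_group == "all", ]
  expect_equal(g$contribution_t, 200)
  expect_equal(g$observed_t, 2000)
})

test_that("regions without cropland report missing percent; unassigned cells warn", {
  codes <- matrix(c(1L, 1L, 2L, NA), 2, 2)
  regions <- region_map(category_grid(codes, levels = c("A", "Empty"),
                                      factor_name = "region"))
  con <- list(c1 = tiny_grid(c(5, 5, NA, 3), 2, 2))
  obs <- list(c1 = tiny_grid(c(50, 50, NA, 30), 2, 2))
  expect_warning(res <- regional_summary(con, obs, regions, c(c1 = "cereal")),
                 "unassigned")
  empty <- res[res$region == "Empty" & res$crop_group == "all", ]
  expect_equal(empty$observed_t, 0)
  expect_true(is.na(empty$contribution_pct))
  una <- res[res$region == "unassigned" & res$crop_group == "all", ]
  expect_equal(una$contribution_t, 3)
  # global conserves including unassigned cells
  g <- res[res$region == "Global" & res$crop_group == "all", ]
  expect_equal(g$contribution_t, 13)
})

test_that("denominator convention controls whether masked cells count as production", {
  codes <- matrix(1L, 2, 2)
  regions <- region_map(category_grid(codes, levels = "A", factor_name = "region"))
  con <- list(c1 = tiny_grid(c(10, NA, 10, NA), 2, 2))
  obs <- list(c1 = tiny_grid(c(100, 100, 100, 100), 2, 2))
  analyzed <- regional_summary(con, obs, regions, c(c1 = "cereal"))
  all_prod <- regional_summary(con, obs, regions, c(c1 = "cereal"),
                               denominator = "all")
  pa <- analyzed[analyzed$region == "A" & analyzed$crop_group == "all", ]
  pb <- all_prod[all_prod$region == "A" & all_prod$crop_group == "all", ]
  expect_equal(pa$contribution_pct, 10)   # 20 / 200
  expect_equal(pb$contribution_pct, 5)    # 20 / 400
})

test_that("global summary equals regional totals and label permutation is inert", {
  set.seed(22)
  codes <- matrix(sample(1:3, 36, replace = TRUE), 6, 6)
  regions <- region_map(category_grid(codes, levels = c("R1", "R2", "R3"),
                                      factor_name = "region"))
  con <- list(a = tiny_grid(matrix(rexp(36), 6, 6)),
              b = tiny_grid(matrix(rexp(36), 6, 6)))
  obs <- list(a = tiny_grid(matrix(rexp(36, 1 / 10), 6, 6)),
              b = tiny_grid(matrix(rexp(36, 1 / 10), 6, 6)))
  groups <- c(a = "cereal", b = "legume")
  reg <- regional_summary(con, obs, regions, groups)
  glo <- global_summary(con, obs, groups)
  for (grp in c("cereal", "legume", "all")) {
    parts <- reg[reg$region != "Global" & reg$crop_group == grp, ]
    total <- reg[reg$region == "Global" & reg$crop_group == grp, ]
    expect_identical(sum(parts$contribution_t), total$contribution_t)
    expect_equal(glo[glo$crop_group == grp, "contribution_t"],
                 total$contribution_t)
  }
  # permuting region labels permutes rows, not values
  perm <- c(2L, 3L, 1L)
  regions_p <- region_map(category_grid(
    matrix(perm[codes], 6, 6), levels = c("R1", "R2", "R3")[order(perm)],
    factor_name = "region"))
  reg_p <- regional_summary(con, obs, regions_p, groups)
  for (r in c("R1", "R2", "R3")) {
    expect_equal(
      reg_p[reg_p$region == r & reg_p$crop_group == "all", "contribution_t"],
      reg[reg$region == r & reg$crop_group == "all", "contribution_t"])
  }
})
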