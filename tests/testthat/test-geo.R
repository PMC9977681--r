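flat <- function(v, nr = 4, nc = 5) matrix(v, nr, nc)

test_that("mean annual rainfall averages annual layers", {
  expect_equal(mean_annual_rainfall(list(flat(300), flat(300), flat(300))),
               flat(300))
  expect_equal(mean_annual_rainfall(list(flat(100), flat(300))), flat(200))
})

test_that("monthly stacks are summed per year before averaging", {
  months <- replicate(12, flat(10), simplify = FALSE)
  expect_equal(mean_annual_rainfall(months, frequency = "monthly"),
               flat(120))
  expect_error(mean_annual_rainfall(months[1:10], frequency = "monthly"),
               "2 months missing")
  # nodata propagates
  m2 <- months; m2[[3]][1, 1] <- -9999
  out <- mean_annual_rainfall(m2, frequency = "monthly")
  expect_equal(out[1, 1], -9999)
  expect_equal(out[2, 2], 120)
})

test_that("bilinear extraction honours cell centres, midpoints and bounds", {
  f <- rainfall_field(matrix(c(100, 300), 1, 2), cell_size = 10)
  # cell centres at x = 5 and 15
  expect_equal(extract_rainfall(f, 5, 5), 100)
  expect_equal(extract_rainfall(f, 15, 5), 300)
  expect_equal(extract_rainfall(f, 10, 5), 200)  # midpoint of two cells
  expect_equal(extract_rainfall(f, 12.5, 5), 250)
  expect_true(is.na(extract_rainfall(f, 25, 5)))  # outside bounds
  # nodata neighbour poisons the interpolation
  fn <- rainfall_field(matrix(c(100, -9999), 1, 2), cell_size = 10)
  expect_true(is.na(extract_rainfall(fn, 10, 5)))
})

test_that("extraction is linear along a gradient field", {
  land <- gen_landscape(landscape_config(extent = c(0, 4000, 0, 400),
                                         seed = 1))
  xs <- seq(500, 3500, by = 250)
  got <- extract_rainfall(land$field, xs, rep(200, length(xs)))
  expect_equal(got, 1000 * xs / 4000, tolerance = 1e-9)
})

test_that("zone classification uses half-open intervals with a closed top", {
  p <- c(0, 100, 149.999, 150, 299.999, 300, 600, 1000, 1000.001, 1200)
  want <- c("hyper-arid", "hyper-arid", "hyper-arid", "arid", "arid",
            "semi-arid", "sub-humid", "sub-humid", NA, NA)
  expect_equal(as.character(classify_zone(p)), want)
  expect_error(classify_zone(-5), "non-negative")
})

test_that("zone classification is invariant to whole-cell raster shifts", {
  land <- gen_landscape(landscape_config(extent = c(0, 3000, 0, 300),
                                         seed = 2))
  f <- land$field
  shifted <- rainfall_field(f$values, xmin = f$xmin + 2 * f$cell_size,
                            ymin = f$ymin, cell_size = f$cell_size)
  pts_x <- seq(600, 2400, by = 100)
  z1 <- classify_zone(extract_rainfall(f, pts_x, rep(150, length(pts_x))))
  z2 <- classify_zone(extract_rainfall(shifted, pts_x + 2 * f$cell_size,
                                       rep(150, length(pts_x))))
  expect_identical(z1, z2)
})

test_that("carbon density converts kg per cell to Mg per hectare", {
  one <- data.frame(id = 1, x = 50, y = 50, carbon_kg = 47)
  g <- carbon_density_grid(one, extent = c(0, 100, 0, 100))
  expect_equal(g$values[1, 1], 0.047)
  empty <- data.frame(id = integer(), x = numeric(), y = numeric(),
                      carbon_kg = numeric())
  g0 <- carbon_density_grid(empty, extent = c(0, 300, 0, 300))
  expect_true(all(g0$values == 0))
  expect_error(carbon_density_grid(
    data.frame(id = 7, x = 1, y = 1, carbon_kg = NA), c(0, 100, 0, 100)),
    "7")
})

test_that("density grids conserve total carbon", {
  set.seed(33)
  crowns <- data.frame(id = 1:500, x = runif(500, 0, 950),
                       y = runif(500, 0, 450),
                       carbon_kg = rexp(500, 1 / 50))
  g <- carbon_density_grid(crowns, extent = c(0, 950, 0, 450))
  expect_equal(sum(g$values) * 1000 * g$cell_ha, sum(crowns$carbon_kg),
               tolerance = 1e-9)
  # re-aggregating two adjacent cells equals pooling their trees
  g2 <- carbon_density_grid(crowns, extent = c(0, 950, 0, 450),
                            cell_size = 200)
  expect_equal(sum(g2$values) * 1000 * g2$cell_ha, sum(crowns$carbon_kg),
               tolerance = 1e-9)
})

test_that("zonal summaries report means, shares and oracle percentiles", {
  crowns <- data.frame(zone = "semi-arid", carbon_kg = c(10, 30),
                       crown_area_m2 = c(10, 20))
  zs <- zonal_summary(crowns, c("semi-arid" = 2))
  row <- zs[zs$zone == "semi-arid", ]
  expect_equal(row$mean_carbon_kg, 20)
  expect_equal(row$carbon_density_mg_ha, 40 / 1000 / 2)
  expect_equal(row$carbon_share_pct, 100)
  expect_equal(zs$n_trees[zs$zone == "arid"], 0L)
  # percentile definition against the hand-rolled oracle
  big <- data.frame(zone = "arid", carbon_kg = 1:100,
                    crown_area_m2 = rep(10, 100))
  zb <- zonal_summary(big, c("arid" = 1))
  expect_equal(zb$p25[zb$zone == "arid"], 25.75)
  expect_equal(zb$p25[zb$zone == "arid"], oracle_percentile(1:100, 0.25))
  expect_equal(zb$p95[zb$zone == "arid"], oracle_percentile(1:100, 0.95))
})

test_that("zone carbon shares sum to 100% across populated zones", {
  land <- gen_landscape(landscape_config(extent = c(0, 4000, 0, 400),
                                         seed = 13))
  est <- estimate_tree_carbon(land$crowns$crown_area_m2)
  crowns <- cbind(land$crowns, carbon_kg = est$carbon_kg)
  zs <- zonal_summary(crowns, c())
  expect_equal(sum(zs$carbon_share_pct, na.rm = TRUE), 100,
               tolerance = 0.01)
})

test_that("rainfall profiles bin trees along the gradient", {
  crowns <- data.frame(rainfall_mm = c(10, 20, 40, 260, 270),
                       carbon_kg = c(1, 2, 3, 10, 20))
  prof <- rainfall_profile(crowns, bin_width = 25)
  m0 <- prof[prof$bin_centre_mm == 12.5 & prof$statistic == "mean", ]
  expect_equal(m0$carbon_kg, 1.5)
  expect_equal(unique(prof$bin_centre_mm), c(12.5, 37.5, 262.5))
})

test_that("ASCII grid round trip preserves the field", {
  land <- gen_landscape(landscape_config(extent = c(0, 2000, 0, 400),
                                         seed = 3))
  path <- tempfile(fileext = ".asc")
  write_asc(land$field, path)
  back <- read_asc(path)
  expect_equal(back$values, land$field$values, tolerance = 1e-9)
  expect_equal(back$cell_size, land$field$cell_size)
  expect_equal(back$xmin, land$field$xmin)
})
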