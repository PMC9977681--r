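test_that("power laws return the coefficient at unit crown area", {
  m <- default_allometric_models()
  expect_equal(predict_component_mass(m$wood, 1), 3.9448)
  expect_equal(predict_component_mass(m$foliage, 1), 0.2693)
  expect_equal(predict_component_mass(m$root, 1), 0.8339)
})

test_that("component masses match high-precision evaluations", {
  m <- default_allometric_models()
  expect_equal(predict_component_mass(m$wood, 100), 645.096951420203,
               tolerance = 1e-12)
  expect_equal(predict_component_mass(m$foliage, 100), 20.8178729342585,
               tolerance = 1e-12)
  expect_error(predict_component_mass(m$wood, -1), "positive")
  expect_error(predict_component_mass(m$wood, 0), "positive")
})

test_that("split rule yields 100 m^2 pieces plus remainder, conserving area", {
  expect_equal(split_crown(250), c(100, 100, 50))
  expect_equal(split_crown(200), 200)          # rule applies only above 200
  expect_equal(split_crown(300), c(100, 100, 100))  # no zero remainder piece
  expect_equal(split_crown(150), 150)
  expect_equal(split_crown(200.5), c(100, 100, 0.5))
  for (a in c(3.7, 42, 199.99, 200.01, 250, 300, 512.25, 1000.4)) {
    expect_equal(sum(split_crown(a)), a, tolerance = 1e-12)
  }
})

test_that("tree carbon estimates follow the split-and-sum oracle", {
  est <- estimate_tree_carbon(100)
  expect_equal(est$mass_total_kg, 850.890223801602, tolerance = 1e-12)
  expect_equal(est$carbon_kg, 399.918405186753, tolerance = 1e-12)
  est250 <- estimate_tree_carbon(250)
  expect_equal(est250$mass_total_kg, 2094.17007842603, tolerance = 1e-12)
  # pipeline vs independently coded brute force on a dense area grid
  areas <- seq(3.01, 1000, by = 0.5)
  got <- estimate_tree_carbon(areas)$carbon_kg
  want <- vapply(areas, oracle_carbon, 1)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("carbon is exactly the fixed fraction of total dry mass", {
  areas <- exp(runif(500, log(3.1), log(900)))
  est <- estimate_tree_carbon(areas)
  expect_equal(est$carbon_kg / est$mass_total_kg, rep(0.47, 500),
               tolerance = 1e-15)
  est2 <- estimate_tree_carbon(areas, carbon_fraction = 0.5)
  expect_equal(est2$carbon_kg / est2$mass_total_kg, rep(0.5, 500),
               tolerance = 1e-15)
})

test_that("sub-threshold crowns are filtered, not errors", {
  est <- estimate_tree_carbon(c(2, 3, 3.5))
  expect_equal(est$retained, c(FALSE, FALSE, TRUE))
  expect_true(is.na(est$carbon_kg[1]) && is.na(est$carbon_kg[2]))
  expect_false(is.na(est$carbon_kg[3]))
  expect_error(estimate_tree_carbon(c(5, -1)), "positive")
})

test_that("carbon is monotone in area within each splitting regime", {
  g1 <- seq(3.01, 200, by = 0.25)
  c1 <- estimate_tree_carbon(g1)$carbon_kg
  expect_true(all(diff(c1) > 0))
  for (lo in c(200.01, 300.01, 500.01)) {
    g <- seq(lo, lo + 99.9, by = 0.25)
    cc <- estimate_tree_carbon(g)$carbon_kg
    expect_true(all(diff(cc) > 0))
  }
})

test_that("splitting caps the superlinear extrapolation above 200 m^2", {
  m <- default_allometric_models()
  eps_areas <- c(200.5, 210, 250)
  for (a in eps_areas) {
    split_mass <- sum(predict_component_mass(m$wood, split_crown(a)))
    expect_lt(split_mass, predict_component_mass(m$wood, a))  # b > 1
    split_root <- sum(predict_component_mass(m$root, split_crown(a)))
    expect_lt(split_root, predict_component_mass(m$root, a))
  }
})

test_that("split bookkeeping is exposed for single crowns", {
  ce <- carbon_estimate(250)
  expect_equal(ce$split_areas, c(100, 100, 50))
  expect_equal(ce$mass_total, ce$mass_w + ce$mass_f + ce$mass_r)
  expect_equal(ce$carbon, 0.47 * ce$mass_total)
})

test_that("log-log OLS fit recovers models exactly on noiseless data", {
  for (m in default_allometric_models()) {
    A <- exp(seq(log(1), log(200), length.out = 50))
    s <- data.frame(crown_area_m2 = A,
                    mass_kg = predict_component_mass(m, A),
                    component = m$component)
    fit <- fit_component_model(s)
    expect_equal(fit$a, m$a, tolerance = 1e-9)
    expect_equal(fit$b, m$b, tolerance = 1e-9)
    expect_identical(fit$component, m$component)
  }
  # exact line in log space through two points
  two <- data.frame(crown_area_m2 = c(1, 10), mass_kg = c(2, 20))
  fit <- fit_component_model(two, component = "wood")
  expect_equal(fit$a, 2, tolerance = 1e-12)
  expect_equal(fit$b, 1, tolerance = 1e-12)
})

test_that("fit rejects degenerate or out-of-domain samples", {
  expect_error(fit_component_model(
    data.frame(crown_area_m2 = c(5, 5, 5), mass_kg = c(1, 2, 3))),
    "degenerate")
  expect_error(fit_component_model(
    data.frame(crown_area_m2 = c(1, -2), mass_kg = c(1, 2))), "positive")
  expect_error(fit_component_model(
    data.frame(crown_area_m2 = 1, mass_kg = 1)), "at least 2")
})

test_that("exponent is recovered within 0.05 under realistic noise", {
  hits <- vapply(1:20, function(s) {
    cfg <- field_sample_config(noise_sigma = 0.4, seed = s)
    smp <- gen_field_samples(cfg)
    fit <- fit_component_model(smp$wood)
    abs(fit$b - 1.1068) <= 0.05
  }, TRUE)
  expect_gte(sum(hits), 19)
})
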