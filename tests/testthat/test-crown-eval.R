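test_that("identical crown sets match perfectly", {
  crowns <- make_circle_df(1:5, c(0, 20, 40, 60, 80), rep(0, 5),
                           c(10, 20, 30, 15, 50))
  m <- match_crowns(crowns, crowns)
  expect_equal(m$n_matched, 5L)
  expect_length(m$omissions, 0)
  expect_length(m$commissions, 0)
  expect_equal(m$pairs$overlap_m2, crowns$crown_area_m2[
    match(m$pairs$labelled_id, crowns$id)], tolerance = 1e-9)
})

test_that("unmatched crowns become omissions and commissions", {
  lab <- make_circle_df(1, 0, 0, 10)
  none <- make_circle_df(integer(), numeric(), numeric(), numeric())
  m <- match_crowns(lab, none)
  expect_equal(m$omissions, 1)
  expect_equal(m$n_matched, 0L)
  m2 <- match_crowns(none, lab)
  expect_equal(m2$commissions, 1)
  expect_error(match_crowns(make_circle_df(1, 0, 0, -5), lab), "positive")
})

test_that("greedy matching equals exhaustive assignment on a crossing pattern", {
  # three labels and three predictions with interleaved overlaps
  lab <- make_circle_df(1:3, c(0, 6, 12), c(0, 0, 0), c(30, 30, 30))
  pred <- make_circle_df(11:13, c(2, 8, 13), c(1, -1, 0.5), c(28, 32, 25))
  m <- match_crowns(lab, pred)
  rl <- sqrt(lab$crown_area_m2 / pi); rp <- sqrt(pred$crown_area_m2 / pi)
  ov <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    d <- sqrt((lab$x[i] - pred$x[j])^2 + (lab$y[i] - pred$y[j])^2)
    ov[i, j] <- drylandtrees:::circle_overlap_area(d, rl[i], rp[j])
  }
  best <- oracle_best_assignment(ov)
  got <- sum(m$pairs$overlap_m2)
  expect_equal(got, best$total, tolerance = 1e-9)
  want_pairs <- sort(vapply(best$pairs, function(p)
    paste(lab$id[p[1]], pred$id[p[2]]), ""))
  expect_equal(sort(paste(m$pairs$labelled_id, m$pairs$predicted_id)),
               want_pairs)
})

test_that("matching counts are conserved and symmetric", {
  fx <- gen_eval_fixture(300, 0.1, 0.05, seed = 12)
  for (p in fx) {
    m <- match_crowns(p$labelled, p$predicted)
    expect_equal(m$n_matched + length(m$omissions), m$n_labelled)
    expect_equal(m$n_matched + length(m$commissions), m$n_predicted)
    # swapping roles swaps omissions and commissions
    ms <- match_crowns(p$predicted, p$labelled)
    expect_equal(length(ms$omissions), length(m$commissions))
    expect_equal(length(ms$commissions), length(m$omissions))
  }
})

test_that("pooled error rates recover planted fixture rates exactly", {
  for (rates in list(c(0, 0), c(0.049, 0.027), c(0.2, 0.027), c(0.049, 0.2))) {
    fx <- gen_eval_fixture(1000, rates[1], rates[2], seed = 21)
    got <- error_rates(lapply(fx, function(p)
      match_crowns(p$labelled, p$predicted)))
    expect_equal(got$commission_rate, rates[1])
    expect_equal(got$omission_rate, rates[2])
    expect_equal(got$net_rate, rates[1] - rates[2])
  }
})

test_that("rates are invariant to plot order and defined per convention", {
  fx <- gen_eval_fixture(500, 0.049, 0.027, seed = 23)
  ms <- lapply(fx, function(p) match_crowns(p$labelled, p$predicted))
  expect_equal(error_rates(ms)[1:8], error_rates(rev(ms))[1:8])
  # single plot: 1 commission among 10 predictions, no omissions
  lab <- make_circle_df(1:9, seq(0, 160, by = 20), rep(0, 9), rep(12, 9))
  pred <- rbind(lab, make_circle_df(99, 500, 500, 12))
  r <- error_rates(match_crowns(lab, pred))
  expect_equal(r$commission_rate_predicted, 0.1)
  expect_equal(r$omission_rate, 0)
})

test_that("per-class counts partition the crowns by area class", {
  fx <- gen_eval_fixture(400, 0.1, 0.05, seed = 31)
  r <- error_rates(lapply(fx, function(p)
    match_crowns(p$labelled, p$predicted)))
  pc <- r$per_class
  expect_equal(sum(pc$n_labelled), r$n_labelled)
  expect_equal(sum(pc$n_commission), r$n_commissions)
  expect_equal(sum(pc$n_omission), r$n_omissions)
  expect_identical(pc$class, c("0-15", "15-50", "50-200", ">200"))
})

test_that("area RMSE counts missed trees at their full area", {
  lab <- make_circle_df(1:2, c(0, 100), c(0, 0), c(10, 20))
  perfect <- match_crowns(lab, lab)
  expect_equal(area_rmse(perfect), 0)
  # one labelled 10 m^2 tree missed entirely
  one <- make_circle_df(1, 0, 0, 10)
  m <- match_crowns(one, make_circle_df(integer(), numeric(), numeric(),
                                        numeric()))
  expect_equal(area_rmse(m), 10)
  # hand arithmetic: errors (2, 0) over two trees
  pred <- make_circle_df(11:12, c(0, 100), c(0, 0), c(12, 20))
  expect_equal(area_rmse(match_crowns(lab, pred)), sqrt(4 / 2))
})

test_that("evaluation plots are sampled with the configured wet bias", {
  land <- gen_landscape(landscape_config(extent = c(0, 8000, 0, 600),
                                         seed = 41))
  all_wet <- sample_eval_plots(land, 50, wet_bias = 1, seed = 1)
  expect_true(all(vapply(all_wet, `[[`, 1, "rainfall_mm") > 200))
  plots <- sample_eval_plots(land, 400, wet_bias = 0.8, seed = 2)
  expect_true(all(vapply(plots, function(p) nrow(p$labelled), 1L) > 0))
  wet_frac <- mean(vapply(plots, `[[`, 1, "rainfall_mm") > 200)
  # dry plots are often empty and get filtered, so the realised wet share
  # can only exceed the sampling bias
  expect_gt(wet_frac, 0.7)
})

test_that("plot sampling degrades gracefully on one-sided landscapes", {
  dry <- gen_landscape(landscape_config(
    extent = c(0, 2000, 0, 500), rainfall_west = 50, rainfall_east = 120,
    zone_density = c("hyper-arid" = 10), seed = 5))
  expect_warning(plots <- sample_eval_plots(dry, 20, seed = 3),
                 "does not span")
  expect_true(all(vapply(plots, `[[`, 1, "rainfall_mm") < 200))
})
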