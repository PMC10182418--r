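test_that("growth-rate fits are exact on noiseless exponentials", {
  t <- seq(0, 3, by = 0.5)
  for (mu in c(0, 0.05, 0.2, 0.31)) {
    f <- fit_growth_rate(t, 0.30 * exp(mu * t))
    expect_equal(f$mu, mu, tolerance = 1e-12)
    expect_equal(f$od0_hat, 0.30, tolerance = 1e-12)
    expect_equal(f$r2, 1, tolerance = 1e-9)
  }
  expect_error(fit_growth_rate(c(0, 1), c(1, 2)), "at least 3")
  expect_error(fit_growth_rate(c(0, 1, 2), c(1, -1, 2)), "positive")
  expect_error(fit_growth_rate(c(0, 1, 1), c(1, 2, 3)), "increasing")
})

test_that("noisy growth-rate fits are unbiased (simulation oracle)", {
  set.seed(31)
  t <- seq(0, 3, by = 0.5)
  mus <- replicate(200, {
    od <- 0.30 * exp(0.20 * t) * exp(rnorm(7, 0, 0.02))
    fit_growth_rate(t, od)$mu
  })
  expect_lt(abs(mean(mus) - 0.20), 2 * sd(mus) / sqrt(200))
})

test_that("culture summaries average per-cell geometry", {
  one <- data.frame(culture_id = "c", modulation = "base",
                    dose_label = "EMM2", growth_rate = 0.2,
                    length_um = 10, width_um = 4, surface_um2 = 120,
                    volume_um3 = 100, sv_ratio_per_um = 1.2)
  s1 <- summarize_culture(one)
  expect_equal(s1$mean_volume, 100)
  expect_equal(s1$sem_volume, 0)
  two <- rbind(one, within(one, volume_um3 <- 200))
  s2 <- summarize_culture(two)
  expect_equal(s2$mean_volume, 150)
  expect_equal(s2$sem_volume, 50)
  # mean of per-cell ratios, not ratio of means
  two$sv_ratio_per_um <- c(1, 2)
  s3 <- summarize_culture(two)
  expect_equal(s3$mean_sv, 1.5)
  expect_equal(s3$sv_of_means, 120 / 150)
  expect_error(summarize_culture(one[0, ]), "empty")
})

test_that("size-law fits recover noiseless lines exactly", {
  law <- size_law_spec(cell_cv = 0, od_noise = 0)
  st <- suppressWarnings(simulate_study(titration_panel(1, n_cells = 5),
                                        law))
  f <- fit_size_law(st$summaries)
  expect_equal(f$slope, 300, tolerance = 1e-9)
  expect_equal(f$intercept, 30, tolerance = 1e-9)
  expect_lt(sum(stats::residuals(f$fit)^2), 1e-18)
  expect_true(f$ci95_slope[1] <= f$slope && f$slope <= f$ci95_slope[2])
  expect_error(fit_size_law(st$summaries[1:2, ]), "at least 3")
})

test_that("size-law fits are affine-equivariant in the metric", {
  st <- simulate_study(titration_panel(7))
  f1 <- fit_size_law(st$summaries)
  sc <- st$summaries
  sc$mean_volume <- sc$mean_volume * 3.5
  f2 <- fit_size_law(sc)
  expect_equal(f2$slope, 3.5 * f1$slope, tolerance = 1e-9)
  expect_equal(f2$intercept, 3.5 * f1$intercept, tolerance = 1e-9)
  expect_equal(f2$ci95_slope, 3.5 * f1$ci95_slope, tolerance = 1e-9)
})

test_that("collapse test: zero F for collinear classes, detects offsets", {
  law0 <- size_law_spec(cell_cv = 0, od_noise = 0)
  st0 <- suppressWarnings(simulate_study(titration_panel(2, n_cells = 5),
                                         law0))
  ct0 <- test_collapse(st0$summaries)
  expect_equal(ct0$f_stat, 0)
  expect_equal(ct0$p_value, 1)

  # a 2.5x offset class at matched growth rates is firmly rejected
  st <- simulate_study(titration_panel(3))
  off <- st$summaries
  sel <- off$modulation == "glucose_titration"
  off$mean_volume[sel] <- off$mean_volume[sel] * 2.5
  ct1 <- test_collapse(off)
  expect_lt(ct1$p_value, 0.01)
  expect_error(test_collapse(st$summaries[1:4, ]), "at least 3")
})

test_that("surface-to-volume trends are classified by CI sign", {
  st <- simulate_study(default_panel(seed = 12))
  tr <- classify_sv_trends(st$summaries)
  lab <- setNames(tr$table$label, tr$table$class)
  expect_equal(lab[["ammonium_titration"]], "negative")
  expect_equal(lab[["glucose_titration"]], "negative")
  expect_equal(lab[["cycloheximide"]], "positive")
  expect_equal(lab[["nitrogen_source"]], "none")
  # ammonium steeper than glucose
  expect_lt(tr$table$slope[tr$table$class == "ammonium_titration"],
            tr$table$slope[tr$table$class == "glucose_titration"])
})
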