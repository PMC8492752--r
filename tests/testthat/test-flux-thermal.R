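make_records <- function(temp, flux, lake = "L", zone = "edge") {
  data.frame(trap_id = "t", lake = lake, zone = zone,
             date = as.Date("2012-07-01"), temp_C = temp,
             flux_mg_m2_d = flux)
}

test_that("bins are integer-anchored half-open intervals with t-based CIs", {
  rec <- make_records(c(4.2, 4.9, 5.0), c(2, 4, 6))
  b <- bin_flux(rec)
  expect_equal(b$bin_center_C, c(4.5, 5.5))
  expect_equal(b$n, c(2L, 1L))
  expect_true(b$degenerate[2])
  expect_true(is.na(b$ci_lo[2]))

  # hand t-interval: {2,4,6} -> mean 4 +- qt(.975, 2) * 2/sqrt(3)
  b3 <- bin_flux(make_records(c(4.1, 4.5, 4.9), c(2, 4, 6)))
  expect_equal(b3$mean_flux, 4)
  half <- qt(0.975, 2) * sd(c(2, 4, 6)) / sqrt(3)  # 4.96828
  expect_equal(b3$ci_lo, 4 - half, tolerance = 1e-12)
  expect_equal(b3$ci_hi, 4 + half, tolerance = 1e-12)
  expect_equal(half, 4.96828, tolerance = 1e-6)
  expect_true(b3$ci_lo < b3$mean_flux && b3$mean_flux < b3$ci_hi)

  expect_error(bin_flux(rec, width_C = 0), "positive")
  expect_error(bin_flux(rec[0, ]), "records")
})

test_that("binning conserves the record count within each group", {
  fx <- generate_flux_records(small_config(seed = 4))
  b <- bin_flux(fx)
  n_bins <- tapply(b$n, paste(b$lake, b$zone), sum)
  n_rec <- table(paste(fx$lake, fx$zone))
  expect_equal(as.numeric(n_bins[names(n_rec)]), as.numeric(n_rec))
})

test_that("polynomial fit recovers an exact parabola and interpolates 3 bins", {
  centers <- c(4.5, 8.5, 12.5, 16.5, 20.5)
  b <- data.frame(lake = "L", zone = "edge", bin_center_C = centers,
                  n = 5, mean_flux = 2 - 0.3 * centers + 0.05 * centers^2,
                  ci_lo = NA, ci_hi = NA, degenerate = FALSE)
  fit <- fit_polynomial(b)
  expect_equal(unlist(fit[c("c0", "c1", "c2")]),
               c(c0 = 2, c1 = -0.3, c2 = 0.05), tolerance = 1e-10)
  expect_equal(fit$r2, 1)
  fit3 <- fit_polynomial(b[1:3, ])
  expect_equal(fit3$r2, 1)
  expect_error(fit_polynomial(b[1:2, ]), "fewer bins")
})

test_that("Arrhenius fit matches hand OLS and handles bad bins", {
  inv_t <- c(0.00340, 0.00345, 0.00350)
  b <- data.frame(lake = "L", zone = "edge",
                  bin_center_C = 1 / inv_t - 273.15, n = 10,
                  mean_flux = exp(c(1.0, 0.5, 0.0)),
                  ci_lo = NA, ci_hi = NA, degenerate = FALSE)
  fit <- fit_arrhenius(b)
  expect_equal(fit$slope_K, -10000, tolerance = 1e-6)
  expect_equal(fit$intercept, 35, tolerance = 1e-6)
  expect_equal(fit$apparent_Ea_kJ_mol, 10000 * 8.314 / 1000,
               tolerance = 1e-6)

  # a non-positive bin mean is dropped with a warning; < 3 bins errors
  b_bad <- rbind(b, within(b[1, ], {
    bin_center_C <- 30
    mean_flux <- 0
  }))
  expect_warning(fit2 <- fit_arrhenius(b_bad), "non-positive")
  expect_equal(fit2$slope_K, fit$slope_K)
  expect_error(suppressWarnings(fit_arrhenius(b_bad[3:4, ])), "fewer than 3")
})

test_that("Arrhenius slope is invariant to flux unit rescaling", {
  cfg <- small_config(seed = 5)
  b <- bin_flux(generate_flux_records(cfg))
  f1 <- fit_arrhenius(b)
  b2 <- b
  b2$mean_flux <- b2$mean_flux * 1000  # mg -> ug
  f2 <- fit_arrhenius(b2)
  expect_equal(f2$slope_K, f1$slope_K, tolerance = 1e-10)
  expect_equal(f2$intercept, f1$intercept + log(1000), tolerance = 1e-10)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-10)
})

test_that("noise-free generator output returns the configured slopes", {
  cfg <- small_config(flux_noise_sdlog = 0)
  fx <- generate_flux_records(cfg)
  # record-level regression is exact: every point sits on the line
  for (z in c("edge", "middle")) {
    rec <- fx[fx$zone == z & fx$lake == "MH", ]
    sl <- unname(coef(lm(log(rec$flux_mg_m2_d) ~
                           I(1 / (rec$temp_C + 273.15))))[2])
    expect_equal(sl, cfg$arrhenius_slope_K[[z]], tolerance = 1e-9)
  }
  # binned means average a convex curve within each 1-degree interval, so
  # the binned fit agrees closely but not to machine precision
  fit <- fit_arrhenius(bin_flux(fx))
  for (i in seq_len(nrow(fit))) {
    true_slope <- cfg$arrhenius_slope_K[[fit$zone[i]]]
    expect_equal(fit$slope_K[i], true_slope, tolerance = 0.02)
    expect_gt(fit$r2[i], 0.999)
  }
})

test_that("slope comparison is symmetric and honors robustness subsets", {
  cfg <- synthetic_config(seed = 11, lakes = "L")
  b <- bin_flux(generate_flux_records(cfg))
  cmp <- compare_slopes(b)
  b_rev <- b[rev(seq_len(nrow(b))), ]
  expect_equal(compare_slopes(b_rev)$interaction_p, cmp$interaction_p,
               tolerance = 1e-12)

  trimmed <- compare_slopes(b, subset = "edge_trimmed")
  expect_false(trimmed$skipped)
  max_mid <- max(b$bin_center_C[b$zone == "middle"])
  expect_true(any(b$bin_center_C[b$zone == "edge"] > max_mid))

  top <- compare_slopes(b, subset = "drop_top_middle_bin")
  bot <- compare_slopes(b, subset = "drop_bottom_middle_bin")
  expect_false(any(c(top$skipped, bot$skipped)))
  # a subsetted group reduced below 3 bins is skipped with a warning
  b_small <- b[b$zone == "middle" | b$bin_center_C <= 6, ]
  b_small <- b_small[b_small$zone == "edge" | b_small$bin_center_C <= 6.5, ]
  expect_warning(sk <- compare_slopes(b_small, subset = "drop_top_middle_bin"),
                 "skipped")
  expect_true(sk$skipped)
})

test_that("raw-record mode fits the interaction model on log fluxes", {
  cfg <- synthetic_config(seed = 12, lakes = "L", traps_per_zone = 2,
                          n_flux_obs = 150)
  fx <- generate_flux_records(cfg)
  cmp <- compare_slopes(fx)
  expect_false(cmp$skipped)
  expect_true(cmp$interaction_p >= 0 && cmp$interaction_p <= 1)
  # 3.5-fold slope contrast at this n is overwhelmingly significant
  expect_lt(cmp$interaction_p, 0.001)
})

test_that("incubation rates follow the headspace slope over dry mass", {
  expect_equal(incubation_rate(0:5, c(0, 1, 2, 3, 4, 5), 2)$rate, 0.5)
  expect_equal(incubation_rate(0:4, rep(3, 5), 1.5)$rate, 0)
  neg <- incubation_rate(0:4, c(5, 4, 3, 2, 1), 1)
  expect_true(neg$negative)
  expect_equal(neg$rate, -1)
  expect_error(incubation_rate(0:4, 1:5, 0), "dry mass")
  expect_error(incubation_rate(c(0, 0, 1), 1:3, 1), "increasing")
})

test_that("middle-parameterized incubations exceed edges under one-way ANOVA", {
  set.seed(42)
  rates <- c(rnorm(12, 0.2, 0.05), rnorm(12, 0.6, 0.1))
  zone <- rep(c("edge", "middle"), each = 12)
  p <- summary(aov(rates ~ zone))[[1]][["Pr(>F)"]][1]
  expect_lt(p, 0.05)
  # the package-side computation feeding that ANOVA
  series <- lapply(rates, function(r) incubation_rate(0:5, r * 2 * (0:5), 2))
  expect_equal(vapply(series, `[[`, numeric(1), "rate"), rates)
})
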