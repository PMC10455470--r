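test_that("area linearization is the square root in mm", {
  expect_equal(linearize_area(4), 2)
  expect_equal(linearize_area(0), 0)
  expect_error(linearize_area(-1), "nonnegative")
  # generator round trip: noise-free cohort linearizes to the exact
  # linear predictor
  coh <- make_allometric_cohort(n = 8, slope = 0.8, intercept = -1.2,
                                noise_sd = 0, seed = 6)
  expect_equal(log(linearize_area(coh$dra_area_mm2)),
               -1.2 + 0.8 * log(coh$itd_mm))
})

test_that("allometric fits behave on exact, noisy and degenerate inputs", {
  coh <- make_allometric_cohort(n = 15, slope = 0.8, noise_sd = 0, seed = 2)
  f <- fit_allometry(coh$itd_mm, coh$dra_area_mm2)
  expect_equal(f$slope, 0.8, tolerance = 1e-12)
  expect_equal(f$df, 13L)
  expect_equal(f$t_stat * f$slope_se, f$slope, tolerance = 1e-6)

  fn <- fit_allometry(make_allometric_cohort(n = 20, noise_sd = 0.05, seed = 9)$itd_mm,
                      make_allometric_cohort(n = 20, noise_sd = 0.05, seed = 9)$dra_area_mm2)
  expect_lt(abs(fn$slope - 0.8), 2 * fn$slope_se)

  # constant area: flat response
  fc <- fit_allometry(c(3, 4, 5, 6), rep(2, 4))
  expect_equal(fc$slope, 0)
  expect_equal(fc$t_stat, 0)

  # slope invariant to rescaling ITD (intercept shifts only)
  f2 <- fit_allometry(coh$itd_mm * 3, coh$dra_area_mm2)
  expect_equal(f2$slope, f$slope, tolerance = 1e-12)
  expect_equal(f2$intercept, f$intercept - f$slope * log(3), tolerance = 1e-10)

  expect_error(fit_allometry(c(1, 2), c(1, 2)), "insufficient|at least 3")
  expect_error(fit_allometry(c(1, 2, -3), c(1, 2, 3)), "positive")

  td <- tidy(f)
  expect_equal(td$term, c("intercept", "slope"))
  expect_equal(glance(f)$slope, f$slope)
})

test_that("signed-rank test handles zeros, ties and exact enumeration", {
  expect_equal(paired_signed_rank(1:5, 1:5)$p_value, 1)
  expect_equal(paired_signed_rank(1:5, 1:5)$statistic, 0)
  r <- paired_signed_rank(c(1, 2, 3, 4), c(1, 5, 1, 2))
  expect_equal(r$n_zero, 1L)
  expect_equal(r$n_used, 3L)

  # n = 6, all positive differences: exact two-sided p = 2/2^6
  expect_equal(paired_signed_rank(2:7, 1:6)$p_value, 2 / 64)

  # agrees with the classical exact test on tie-free data
  for (r in 1:25) {
    n <- 3 + (r %% 8)
    a <- dramorph:::with_seed(100 + r, rnorm(n))
    b <- dramorph:::with_seed(200 + r, rnorm(n))
    expect_equal(paired_signed_rank(a, b)$p_value,
                 suppressWarnings(wilcox.test(a, b, paired = TRUE))$p.value,
                 tolerance = 1e-12)
  }

  # normal approximation above the exact limit
  big <- paired_signed_rank(rnorm(30, 0.5), rnorm(30), exact_max_n = 15)
  expect_equal(big$method, "normal")
  expect_true(big$p_value >= 0 && big$p_value <= 1)
})

test_that("region comparison reproduces the rank formula and letters", {
  mm <- tibble::tibble(
    specimen_id = rep(c("a", "b"), 3),
    slice_id = "s", structure = "cone", dimension = "thickness",
    region = rep(c("DRA", "proximate", "non_DRA"), each = 2),
    value_um = c(1, 2, 3, 4, 5, 6)
  )
  rc <- region_comparison(mm, "cone", pool_specimens = FALSE)
  expect_equal(rc$kw$statistic, 32 / 7, tolerance = 1e-12)

  # identical groups: no rank separation
  mm0 <- mm
  mm0$value_um <- rep(c(1, 2), 3)
  rc0 <- region_comparison(mm0, "cone", pool_specimens = FALSE)
  expect_equal(rc0$kw$statistic, 0, tolerance = 1e-12)
  expect_true(all(rc0$letters$letters == rc0$letters$letters[1]))

  # a region with < 2 values is skipped with a warning
  mm1 <- mm[-(1:1), ]
  expect_warning(rc1 <- region_comparison(mm1, "cone", pool_specimens = FALSE),
                 "skipped")
  expect_equal(nrow(rc1$pairwise), 1L)

  # Holm adjustment matches p.adjust; "none" leaves raw p-values
  m2 <- simulate_ommatidial_measurements(
    region_means_um = c(DRA = 40, proximate = 60, non_DRA = 62), seed = 3)
  rc2 <- region_comparison(m2, "cone")
  expect_equal(rc2$pairwise$p_adj, p.adjust(rc2$pairwise$p_raw, "holm"))
  rc3 <- region_comparison(m2, "cone", adjust = "none")
  expect_equal(rc3$pairwise$p_adj, rc3$pairwise$p_raw)

  expect_error(region_comparison(mm, "rhabdom"), "no measurements")
})

test_that("a strong DRA cone contrast is flagged with separating letters", {
  m <- simulate_ommatidial_measurements(
    region_means_um = c(DRA = 48, proximate = 60, non_DRA = 60),
    specimen_sd_um = 1, measurement_sd_um = 1, seed = 12)
  rc <- region_comparison(m, "cone", "thickness")
  expect_lt(rc$kw$p_value, 0.05)
  lt <- setNames(rc$letters$letters, rc$letters$region)
  expect_false(grepl(lt[["DRA"]], lt[["proximate"]], fixed = TRUE))
  expect_equal(lt[["proximate"]], lt[["non_DRA"]])
})
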