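make_record <- function(reference, delta, flow = 400, subflow = 233) {
  tibble::tibble(reference_co2_ppm = reference, delta_co2_ppm = delta,
                 flow_umol_s = flow, subsample_flow_umol_s = subflow)
}

test_that("headspace correction applies the subsample-loop scaling and clamps at zero", {
  # no drawdown: headspace equals the (reference = sample) chamber value
  expect_identical(headspace_co2(make_record(400, 0))$headspace_co2_ppm, 400)
  r <- headspace_co2(make_record(400, 20))
  expect_rel_equal(r$headspace_co2_ppm, 380 - 400 / 233 * 20, 1e-12)
  expect_rel_equal(r$headspace_co2_ppm, 345.67, 1e-4)
  expect_false(r$headspace_clamped)
  clamped <- headspace_co2(make_record(55, 25))
  expect_identical(clamped$headspace_co2_ppm, 0)
  expect_true(clamped$headspace_clamped)
  expect_identical(attr(clamped, "n_clamped"), 1L)
  expect_error(headspace_co2(make_record(400, 10, flow = 0)), "Flow rates")
  expect_error(headspace_co2(make_record(400, 10)[, -2]), "missing column")
})

test_that("headspace correction never returns negatives on fuzzed records", {
  set.seed(42)
  n <- 1e4
  rec <- tibble::tibble(
    reference_co2_ppm = stats::runif(n, 0, 2000),
    delta_co2_ppm = stats::runif(n, -100, 500),
    flow_umol_s = stats::runif(n, 50, 800),
    subsample_flow_umol_s = stats::runif(n, 50, 400)
  )
  out <- headspace_co2(rec)
  expect_true(all(out$headspace_co2_ppm >= 0))
  expect_identical(attr(out, "n_clamped"), sum(out$headspace_clamped))
  expect_gt(attr(out, "n_clamped"), 0)  # the fuzz does hit the clamp
})

test_that("headspace-to-dissolved conversion is a strictly increasing Henry mapping", {
  curve <- tibble::tibble(driver = c(0, 100, 400, 1000))
  out <- to_dissolved(curve, temperature_c = 40)
  expect_identical(out$dissolved_co2_uM[1], 0)
  expect_rel_equal(out$dissolved_co2_uM[3], 9.6, 0.01)
  expect_true(all(diff(out$dissolved_co2_uM) > 0))
  # temperature can come from a column
  curve$temperature_c <- 40
  expect_identical(to_dissolved(curve)$dissolved_co2_uM, out$dissolved_co2_uM)
  expect_error(to_dissolved(tibble::tibble(driver = 1)), "temperature_c")
})

test_that("the Michaelis-Menten fit recovers noise-free parameters exactly", {
  grid <- c(25, 50, 100, 200, 400, 800)
  curve <- tibble::tibble(driver = grid, assimilation = 35 * grid / (150 + grid))
  f <- fit_michaelis_menten(curve)
  expect_rel_equal(f$km, 150, 1e-6)
  expect_rel_equal(f$amax, 35, 1e-6)
  expect_identical(f$n_points_used, 6L)
  # strict cutoff drops the 800 point and stays exact
  f700 <- fit_michaelis_menten(curve, max_driver = 700)
  expect_identical(f700$n_points_used, 5L)
  expect_rel_equal(f700$km, 150, 1e-6)
  # invariant to point order
  f_rev <- fit_michaelis_menten(curve[rev(seq_len(nrow(curve))), ])
  expect_rel_equal(f_rev$km, f$km, 1e-9)
  expect_error(fit_michaelis_menten(curve[1:2, ]), "at least 3")
  expect_error(fit_michaelis_menten(curve, max_driver = 60), "max_driver")
  td <- tidy(f)
  expect_identical(td$term, c("amax", "km"))
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
  expect_identical(glance(f)$n_points_used, 6L)
})

test_that("the compensation-point fit uses only the low-CO2 window", {
  df <- tibble::tibble(driver = c(20, 60, 100), assimilation = c(-2, 2, 6))
  f <- fit_compensation_point(df)
  expect_rel_equal(f$gamma, 40, 1e-12)
  expect_rel_equal(f$slope, 0.1, 1e-12)
  # points above the threshold leave the fit unchanged
  df_hi <- dplyr::bind_rows(df, tibble::tibble(driver = c(300, 900),
                                               assimilation = c(25, 31)))
  f2 <- fit_compensation_point(df_hi)
  expect_rel_equal(f2$gamma, f$gamma, 1e-12)
  expect_identical(f2$n_points_used, 3L)
  expect_error(fit_compensation_point(df, threshold = 30), "distinct points")
  down <- tibble::tibble(driver = c(20, 60, 100), assimilation = c(6, 2, -2))
  expect_error(fit_compensation_point(down), "Degenerate")
  expect_identical(glance(f)$threshold, 100)
})

test_that("the compensation point of offset saturation curves is recovered to 2%", {
  # noise-free offset model: gamma_true = km rl / amax = 15 ppm; the <=100 ppm
  # window brackets it, and its mild curvature keeps the linear fit within 2%
  grid <- c(5, 20, 50, 100, 300, 800)
  truth <- list(km = 150, amax = 35, rl = 3.5)
  a <- (truth$amax + truth$rl) * grid / (truth$km + grid) - truth$rl
  f <- fit_compensation_point(tibble::tibble(driver = grid, assimilation = a))
  gamma_true <- truth$km * truth$rl / truth$amax
  expect_rel_equal(f$gamma, gamma_true, 0.02)
})

test_that("gamma fitting commutes with the dissolved-unit bridge to 0.5%", {
  grid <- c(5, 20, 50, 100, 300, 800)
  a <- 38.5 * grid / (150 + grid) - 3.5
  curve <- tibble::tibble(driver = grid, assimilation = a)
  gamma_ppm <- fit_compensation_point(curve)$gamma
  gamma_ppm_converted <- dissolved_concentration("CO2", gamma_ppm * 1e-6, 40)
  curve_uM <- to_dissolved(curve, 40)
  thr_uM <- dissolved_concentration("CO2", 100e-6, 40)
  gamma_uM <- fit_compensation_point(curve_uM, driver = dissolved_co2_uM,
                                     threshold = thr_uM)$gamma
  expect_rel_equal(gamma_uM, gamma_ppm_converted, 0.005)
})

test_that("the Kok fit extrapolates the low-light window to zero light", {
  df <- tibble::tibble(driver = c(10, 20, 30), assimilation = 0.05 * driver - 3)
  f <- fit_kok(df)
  expect_rel_equal(f$rl, 3, 1e-12)
  expect_rel_equal(f$slope, 0.05, 1e-12)
  # saturated points outside the window are ignored
  df_hi <- dplyr::bind_rows(df, tibble::tibble(driver = c(500, 2000),
                                               assimilation = c(30, 34)))
  expect_rel_equal(fit_kok(df_hi)$rl, 3, 1e-12)
  expect_identical(fit_kok(df_hi)$n_points_used, 3L)
  expect_error(fit_kok(df[1, ]), "at least 2")
  expect_identical(glance(f)$rl, f$rl)
})

test_that("replicate oxygen-response analysis aggregates per-replicate slopes", {
  exact <- tidyr::expand_grid(replicate = 1:3, o_uM = c(20, 209, 398)) |>
    dplyr::mutate(gamma_uM = 0.005 * o_uM + 0.4)
  res <- oxygen_response_analysis(exact)
  expect_rel_equal(res$mean_slope_pM_per_uM, 5000, 1e-9)
  expect_lt(res$se_pM_per_uM, 1e-6)
  expect_identical(res$n_replicates, 3L)
  single <- dplyr::filter(exact, replicate == 1)
  res1 <- oxygen_response_analysis(single)
  expect_true(is.na(res1$se_pM_per_uM))
  expect_identical(res1$n_replicates, 1L)
  unbal <- exact[-1, ]
  expect_warning(oxygen_response_analysis(unbal), "Unbalanced")
  expect_error(oxygen_response_analysis(dplyr::filter(exact, o_uM == 20)),
               "two distinct O2")
})

test_that("replicate-mean slope stays within 2 SE of truth at the t-theory rate", {
  # 6 replicate slopes: the +/- 2 SE band has P(|t_5| < 2) = 0.898 coverage
  hits <- 0
  n_sims <- 1000
  for (s in seq_len(n_sims)) {
    sim <- simulate_oxygen_response(slope_true = 5000, noise_sd = 0.1,
                                    n_replicates = 6, seed = s)
    res <- oxygen_response_analysis(sim)
    if (abs(res$mean_slope_pM_per_uM - 5000) <= res$ci2_pM_per_uM) hits <- hits + 1
  }
  expect_gte(hits / n_sims, 0.86)
})

test_that("the directional pH tests behave like their closed forms", {
  out <- ph_comparison_tests(c(200, 210, 220), c(100, 105, 110))
  half <- out[out$test == "half_mean", ]
  # means exactly in 2:1 ratio: statistic 0, one-sided p = 0.5
  expect_lt(abs(half$statistic), 1e-9)
  expect_rel_equal(half$p_value, 0.5, 1e-6)
  # oracle: Welch t of ph6 against 0.5 * ph2 computed directly
  oracle <- stats::t.test(c(100, 105, 110), 0.5 * c(200, 210, 220),
                          alternative = "less")
  expect_rel_equal(half$p_value, oracle$p.value, 1e-12)
  ident <- ph_comparison_tests(c(5, 6, 7), c(5, 6, 7))
  expect_rel_equal(ident$p_value[ident$test == "ph2_greater"], 0.5, 1e-6)
  # pH 6 equal to pH 2 strongly contradicts the "pH 6 is half" direction
  same <- ph_comparison_tests(c(200, 210, 220), c(200, 210, 220))
  expect_gt(same$p_value[same$test == "half_mean"], 0.95)
  expect_error(ph_comparison_tests(1, c(1, 2)), "2 replicates")
})
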