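test_that("the compensation-point equation evaluates its closed forms", {
  expect_identical(gamma_co2(100, 5, 500, 0, 0)$gamma_uM, 0)
  # r = 0: gamma reduces to 0.5 O / Sc_o
  expect_rel_equal(gamma_co2(100, 5, 500, 0, 200)$gamma_uM, 1.0, 1e-12)
  res <- gamma_co2(112.5, 7.49, 589, 0.13, 209)
  expect_rel_equal(res$gamma_uM,
                   res$slope_term * 209 + res$intercept_term, 1e-12)
  expect_error(gamma_co2(100, 5, 500, 1, 200), "singular")
  expect_error(gamma_co2(100, 5, 500, -0.1, 200), "rl_ratio")
  expect_error(gamma_co2(-1, 5, 500, 0.1, 200), "> 0")
})

test_that("gamma is monotone in each argument with the expected signs", {
  base <- list(sco = 112, kc = 7.5, ko = 589, r = 0.13, o = 209)
  g0 <- gamma_co2(base$sco, base$kc, base$ko, base$r, base$o)$gamma_uM
  eps <- 1e-3
  for (lat in list(c(1, 1, 1, 1, 1), c(2, 0.5, 3, 0.5, 0.2))) {
    sco <- base$sco * lat[1]; kc <- base$kc * lat[2]; ko <- base$ko * lat[3]
    r <- base$r * lat[4]; o <- base$o * lat[5]
    g <- function(...) gamma_co2(...)$gamma_uM
    ref <- g(sco, kc, ko, r, o)
    expect_gt(g(sco, kc, ko, r, o + eps), ref)        # increasing in O
    expect_gt(g(sco, kc + eps, ko, r, o), ref)        # increasing in Kc
    expect_gt(g(sco, kc, ko, r + eps, o), ref)        # increasing in r
    expect_lt(g(sco + eps, kc, ko, r, o), ref)        # decreasing in Sc/o
    expect_lt(g(sco, kc, ko + eps * ko, r, o), ref)   # decreasing in Ko
  }
  expect_true(is.finite(g0))
})

test_that("gamma is exactly linear in O2, so interpolation and OLS agree with the analytic slope", {
  res <- gamma_co2(112.5, 7.49, 589, 0.13, c(20, 209, 398))
  mid <- gamma_co2(112.5, 7.49, 589, 0.13, 209)$gamma_uM
  interp <- stats::approx(res$o_uM[c(1, 3)], res$gamma_uM[c(1, 3)], xout = 209)$y
  expect_rel_equal(interp, mid, 1e-12)
  sl <- oxygen_slope(res)
  expect_rel_equal(sl$slope_pM_per_uM, res$slope_term[1] * 1e6, 1e-9)
})

test_that("the grid crosses all specificity and Kc sources with the shared Ko", {
  g <- gamma_grid()
  expect_identical(nrow(g$slopes), 9L)
  expect_identical(nrow(g$rows), 27L)
  expect_true(all(g$rows$Ko_uM_T == g$rows$Ko_uM_T[1]))
  # OLS slope equals the analytic coefficient for every combination
  expect_rel_equal(g$slopes$slope_pM_per_uM,
                   g$slopes$analytic_slope_pM_per_uM, 1e-9)
  # brute-force extrema: max slope at (min Sc/o, max Kc), min at (max, min)
  adj <- adjust_kinetics(rubisco_cyanidiales(), 40)
  brute <- sapply(adj$Sc_o_T, function(s) sapply(adj$Kc_uM_T, function(k) {
    gamma_co2(s, k, adj$Ko_uM_T[1], 0.13, 1)$slope_term * 1e6
  }))
  expect_rel_equal(g$slope_min, min(brute), 1e-12)
  expect_rel_equal(g$slope_max, max(brute), 1e-12)
  lo <- g$slopes[which.min(g$slopes$slope_pM_per_uM), ]
  hi <- g$slopes[which.max(g$slopes$slope_pM_per_uM), ]
  expect_identical(lo$sco_source, adj$species[which.max(adj$Sc_o_T)])
  expect_identical(lo$kc_source, adj$species[which.min(adj$Kc_uM_T)])
  expect_identical(hi$sco_source, adj$species[which.min(adj$Sc_o_T)])
  expect_identical(hi$kc_source, adj$species[which.max(adj$Kc_uM_T)])
  # per-O2 gamma envelope is ordered
  expect_true(all(g$gamma_range$gamma_min <= g$gamma_range$gamma_max))
})

test_that("a degenerate single-set single-O grid reduces to a direct evaluation", {
  kin <- rubisco_cyanidiales()[1, ]
  g <- gamma_grid(kin, 40, o_levels = 209, rl_ratio = 0.13)
  adj <- adjust_kinetics(kin, 40)
  direct <- gamma_co2(adj$Sc_o_T, adj$Kc_uM_T, adj$Ko_uM_T, 0.13, 209)
  expect_identical(nrow(g$rows), 1L)
  expect_rel_equal(g$rows$gamma_uM, direct$gamma_uM, 1e-12)
})

test_that("hypothetical kinetics select post-adjustment extrema and apply multipliers", {
  g <- gamma_grid()
  ident <- hypothetical_gamma(sco_multiplier = 1, kc_multiplier = 1)
  adj <- adjust_kinetics(rubisco_cyanidiales(), 40)
  cell <- g$rows[g$rows$Sc_o_T == max(adj$Sc_o_T) &
                   g$rows$Kc_uM_T == min(adj$Kc_uM_T) &
                   g$rows$o_uM == 209, ]
  expect_rel_equal(ident$gamma_uM, cell$gamma_uM, 1e-12)
  # unbounded specificity leaves only the Kc r O / Ko and intercept terms
  lim <- hypothetical_gamma(sco_multiplier = 1e12)
  kc_h <- 0.5 * min(adj$Kc_uM_T)
  expected_lim <- (kc_h * 0.13 / adj$Ko_uM_T[1]) / 0.87 * 209 +
    kc_h * 0.13 / 0.87
  expect_rel_equal(lim$gamma_uM, expected_lim, 1e-6)
})

test_that("oxygen_slope recovers exact lines and demands two O2 levels", {
  df <- tibble::tibble(o_uM = c(20, 209, 398), gamma_uM = 0.007 * o_uM + 0.5)
  sl <- oxygen_slope(df)
  expect_rel_equal(sl$slope_pM_per_uM, 7000, 1e-9)
  expect_lt(sl$se_pM_per_uM, 1e-6)
  expect_error(oxygen_slope(df[c(1, 1), ]), "two distinct O2 levels")
})

test_that("noisy slope recovery stays within its fitted uncertainty at the t-theory rate", {
  # 3 replicate triplets, noise sd 0.05 uM; pooled OLS on 9 points has
  # P(|t_7| < 2) = 0.914 coverage for the +/- 2 SE band
  truth <- 0.007
  hits <- 0
  n_sims <- 1000
  for (s in seq_len(n_sims)) {
    set.seed(s)
    o <- rep(c(20, 209, 398), 3)
    g <- truth * o + 0.5 + stats::rnorm(9, 0, 0.05)
    est <- oxygen_slope(tibble::tibble(o_uM = o, gamma_uM = g))
    if (abs(est$slope_pM_per_uM - truth * 1e6) <= 2 * est$se_pM_per_uM) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / n_sims, 0.88)
})

test_that("measurements are classified against calculated ranges by interval arithmetic", {
  expect_identical(as.character(classify_measurement(1.1, 0, 1.4, 3.0)$verdict), "below")
  expect_identical(as.character(classify_measurement(2.0, 0.7, 1.4, 3.0)$verdict), "within")
  expect_identical(as.character(classify_measurement(5425, 1396, 7046, 11153)$verdict), "below")
  expect_identical(as.character(classify_measurement(12, 1, 1.4, 3.0)$verdict), "above")
  # boundary contact counts as within
  expect_identical(as.character(classify_measurement(1.0, 0.4, 1.4, 3.0)$verdict), "within")
  expect_error(classify_measurement(1, 0, 3, 2), "range_min")
})
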