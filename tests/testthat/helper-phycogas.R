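# Shared fixtures and small oracles for the suite.

# A noise-free response curve that is exactly linear below `threshold` and
# Michaelis-Menten-shaped above it; compensation point = gamma.
linear_low_co2_curve <- function(gamma = 40, slope = 0.1, threshold = 100,
                                 high = c(200, 400, 800)) {
  low <- c(20, 60, 100)
  tibble::tibble(
    driver = c(low, high),
    assimilation = c(slope * (low - gamma), 35 * high / (150 + high))
  )
}

# Direct scalar evaluation of the van 't Hoff Henry adjustment, kept separate
# from the package path as the oracle for derived solubility values.
henry_oracle <- function(H298, B, t_K) H298 * exp(B * (1 / t_K - 1 / 298.15))

expect_rel_equal <- function(object, expected, rel_tol) {
  expect_true(all(abs(object - expected) <= rel_tol * abs(expected)),
              label = sprintf("%s vs %s (rel tol %g)",
                              paste(signif(object, 8), collapse = ","),
                              paste(signif(expected, 8), collapse = ","),
                              rel_tol))
}
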