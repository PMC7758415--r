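test_that("Kovats RI matches the closed forms on a two-rung ladder", {
  ladder <- two_rung_ladder()
  expect_equal(kovats_ri(11, ladder, mode = "linear"), 1050)
  # direct evaluation of the log form as the oracle
  expect_equal(
    kovats_ri(11, ladder, mode = "log"),
    100 * 10 + 100 * (log(11) - log(10)) / (log(12) - log(10))
  )
  # geometric-mean query sits exactly mid-bracket in log mode
  expect_equal(kovats_ri(sqrt(10 * 12), ladder, mode = "log"), 1050)
})

test_that("every ladder alkane indexes to exactly 100 x carbon in both modes", {
  ladder <- generate_alkane_ladder(4, 26)
  for (mode in c("log", "linear")) {
    expect_identical(kovats_ri(ladder$rt, ladder, mode = mode), 100 * ladder$carbon)
  }
})

test_that("RI is strictly monotone within a bracket and refuses to extrapolate", {
  ladder <- generate_alkane_ladder(4, 26, rt_model = function(z) 0.05 * z^2 + z)
  set.seed(42)
  rts <- sort(runif(200, min(ladder$rt), max(ladder$rt)))
  for (mode in c("log", "linear")) {
    ri <- kovats_ri(rts, ladder, mode = mode)
    expect_true(all(diff(ri) > 0))
    expect_true(all(ri > 100 * min(ladder$carbon) & ri < 100 * max(ladder$carbon)))
  }
  expect_warning(out <- kovats_ri(max(ladder$rt) + 1, ladder), "outside")
  expect_true(is.na(out))
  expect_error(kovats_ri(5, tibble::tibble(carbon = c(5, 5), rt = c(1, 2))),
               "strictly increasing")
  expect_error(kovats_ri(5, tibble::tibble(carbon = 5:6, rt = c(2, 1))),
               "strictly increasing")
})

test_that("identification filtering requires both matches strictly above the cutoff", {
  peaks <- tibble::tibble(
    compound_id = c("a", "b", "c", "d"),
    match_forward = c(850, 800, 1000, NA),
    match_reverse = c(805, 900, 1000, 900)
  )
  kept <- filter_identifications(peaks)
  expect_identical(kept$compound_id, c("a", "c"))
  rej <- rejected_peaks(kept)
  expect_identical(rej$compound_id, c("b", "d"))
  expect_match(rej$reason[rej$compound_id == "b"], "forward")
  expect_match(rej$reason[rej$compound_id == "d"], "missing")
  # never grows, and the retained set ignores input order
  expect_lte(nrow(kept), nrow(peaks))
  shuffled <- filter_identifications(peaks[c(3, 1, 4, 2), ])
  expect_setequal(shuffled$compound_id, kept$compound_id)
  expect_error(filter_identifications(tibble::tibble(match_forward = 1200,
                                                     match_reverse = 10)),
               "\\[0, 1000\\]")
})

test_that("relative concentration follows the internal-standard ratio", {
  expect_equal(relative_concentration(1e6, 1e6, 65.68, 1), 65.68)
  expect_equal(relative_concentration(2e5, 1e5, 10), 2 * relative_concentration(1e5, 1e5, 10))
  expect_equal(relative_concentration(2.5e6, 1e6, 65.68, 1), 164.2)
  expect_error(relative_concentration(1, 0, 65.68), "internal-standard")
  expect_error(relative_concentration(1, 1e6, 65.68, sample_mass = 0), "positive")
})

test_that("calibration correction inverts the fitted line and floors negatives", {
  # forward-evaluate the hexanal curve, then invert
  y <- 2.433 * 100 - 0.561
  expect_equal(as.numeric(apply_calibration(y, 2.433, -0.561)), 100)
  expect_equal(as.numeric(apply_calibration(7.3, 1, 0)), 7.3)
  expect_equal(as.numeric(apply_calibration(-0.561, 2.433, -0.561)), 0)
  expect_warning(out <- apply_calibration(c(0.5, -2), slope = 1, intercept = 0),
                 "floored")
  expect_equal(as.numeric(out), c(0.5, 0))
  expect_identical(attr(out, "n_floored"), 1L)
  expect_error(apply_calibration(1, slope = 0), "nonzero")
})

test_that("calibration fitting recovers known lines and flags poor fits", {
  conc <- seq(0, 300, by = 50)
  exact <- fit_calibration(conc, 2.433 * conc - 0.561)
  expect_equal(exact$slope, 2.433, tolerance = 1e-12)
  expect_equal(exact$intercept, -0.561, tolerance = 1e-12)
  expect_equal(exact$r_squared, 1)
  expect_false(exact$flagged)

  set.seed(11)
  noisy <- fit_calibration(conc, (2.433 * conc - 0.561) * exp(rnorm(7, 0, 0.01)))
  expect_gte(noisy$r_squared, 0.99)

  expect_error(fit_calibration(rep(1, 5), rnorm(5)), "identical")
  expect_error(fit_calibration(c(0, 1), c(0, 1)), "3 distinct")
})

test_that("the quantification pipeline inverts a zero-noise forward simulation", {
  cfg <- small_config(area_noise_cv = 0, seed = 3)
  panel <- quiet_panel(cfg)
  conc <- quantify_peaks(panel$peaks, panel$ref, panel$ladder)
  joined <- dplyr::inner_join(
    dplyr::rename(conc, accession = sample_id),
    panel$ground_truth$concentrations,
    by = c("accession", "compound_id"), suffix = c("", "_true")
  )
  expect_equal(nrow(joined), nrow(panel$peaks))
  expect_lt(max(abs(joined$concentration / joined$concentration_true - 1)), 1e-9)
  expect_true(all(is.finite(joined$ri)))
})
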