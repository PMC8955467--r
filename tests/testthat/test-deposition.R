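conc_from_counts <- function(grid, counts, phase = "inhalation",
                             duration = 6) {
  concentration(binned_spectrum(grid, counts, phase = phase,
                                duration = duration))
}

test_that("phase averaging is the bin-wise mean over selected runs", {
  g <- build_grid(1, 10, 2)
  a <- conc_from_counts(g, c(2, 2) * 500)
  b <- conc_from_counts(g, c(4, 4) * 500)
  ex <- conc_from_counts(g, c(1, 1) * 500, phase = "exhalation")
  expect_equal(phase_average(list(a))$dCn, a$dCn)
  expect_equal(phase_average(list(a, b, ex), phase = "inhalation")$dCn,
               (a$dCn + b$dCn) / 2)
  expect_error(phase_average(list(a, b), phase = "background"), "no spectra")
  g2 <- build_grid(1, 10, 3)
  expect_error(phase_average(list(a, conc_from_counts(g2, c(1, 1, 1) * 500))),
               "incompatible")
})

test_that("deposition and exhaled fraction are exact complements", {
  g <- build_grid()
  set.seed(31)
  inh <- conc_from_counts(g, rpois(n_bins(g), 40))
  exh <- conc_from_counts(g, rpois(n_bins(g), 4), phase = "exhalation")
  d <- deposition(inh, exh)
  expect_equal(d$overall_deposition + d$exhaled_fraction, 100,
               tolerance = 1e-9)
  expect_true(d$exhaled_fraction >= 0 && d$exhaled_fraction <= 100)
  ok <- !is.na(d$per_bin_deposition)
  expect_true(all(d$per_bin_deposition[ok] >= 0 &
                    d$per_bin_deposition[ok] <= 100))
  expect_true(all(is.na(d$per_bin_deposition[inh$dCn == 0])))
})

test_that("deposition handles the limiting exhaled spectra", {
  g <- build_grid(1, 10, 4)
  inh <- conc_from_counts(g, c(100, 200, 300, 400))
  expect_equal(deposition(inh, inh)$overall_deposition, 0)
  expect_equal(deposition(inh, inh)$exhaled_fraction, 100)
  none <- conc_from_counts(g, c(0, 0, 0, 0), phase = "exhalation")
  expect_equal(deposition(inh, none)$overall_deposition, 100)
  expect_error(deposition(none, inh), "zero")
  # a constructed 2.13% exhaled ratio comes back exactly
  exh <- inh
  exh$dCn <- inh$dCn * 0.0213
  expect_equal(deposition(inh, exh)$exhaled_fraction, 2.13, tolerance = 1e-9)
})

test_that("scaling down the exhaled spectrum strictly increases deposition", {
  g <- build_grid()
  set.seed(32)
  inh <- conc_from_counts(g, rpois(n_bins(g), 30))
  exh <- conc_from_counts(g, rpois(n_bins(g), 6), phase = "exhalation")
  dep <- vapply(c(1, 0.7, 0.4, 0.1), function(s) {
    scaled <- exh
    scaled$dCn <- exh$dCn * s
    deposition(inh, scaled)$overall_deposition
  }, 0)
  expect_true(all(diff(dep) > 0))
})

test_that("device summaries are order-invariant and carry run dispersion", {
  g <- build_grid(1, 10, 4)
  mk <- function(sc) deposition(
    conc_from_counts(g, c(100, 200, 300, 400)),
    conc_from_counts(g, sc * c(100, 200, 300, 400), phase = "exhalation"))
  res <- list(a = mk(0.05), b = mk(0.10))
  per_run <- data.frame(device = c("a", "a", "b", "b"),
                        exhaled_fraction = c(4, 6, 9, 11),
                        mean_diameter_in = 1, mean_diameter_ex = 0.5)
  s1 <- summarize_devices(res, per_run)
  s2 <- summarize_devices(rev(res), per_run[c(3, 4, 1, 2), ])
  expect_identical(s1, s2)
  expect_equal(s1$exhaled_fraction_median, c(5, 10))
  expect_equal(s1$overall_deposition, c(95, 90))
})
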