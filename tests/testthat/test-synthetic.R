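test_that("simulated traces hit the resistance-limited peak flow deterministically", {
  d <- default_study_design()
  hh <- d$devices$handihaler
  man <- d$maneuver
  tr <- simulate_flow(hh, man, lung = "bag", seed = 5)
  expect_equal(max(tr$flow[seq_len(tr$phase_marks[1L])]),
               sqrt(4) / 0.0504, tolerance = 0.08)   # flutter overlay allowed
  f <- extract_features(tr)
  expect_equal(f$t_inh, 1.4, tolerance = 1e-6)
  expect_equal(f$resistance, 0.0504, tolerance = 1e-9)

  # determinism under a fixed seed, for a flutter device
  tr2 <- simulate_flow(hh, man, lung = "bag", seed = 5)
  expect_identical(tr, tr2)

  # porcine mode adds resistance, strictly lowering the peak
  trp <- simulate_flow(hh, man, lung = "porcine", seed = 5,
                       resistance_increment = 0.003)
  expect_lt(max(trp$flow[seq_len(trp$phase_marks[1L])]), sqrt(4) / 0.0504)
  expect_equal(extract_features(trp)$resistance, 0.0534, tolerance = 1e-9)
})

test_that("emitted spectra are lognormal in the grid with the calibrated mean", {
  g <- build_grid()
  d <- default_study_design()
  # degenerate distribution: gsd -> 1 puts all mass at the median bin
  narrow <- inhaler_preset("n", 0.03, cmd = 2.9, gsd = 1.0001)
  e <- emitted_spectrum(narrow, g)
  expect_equal(sum(e), narrow$emission_concentration, tolerance = 1e-9)
  expect_gt(max(e) / sum(e), 0.99)
  expect_lt(abs(g$centers[which.max(e)] - 2.9), 0.06)

  # linearity in the emission concentration
  p1 <- d$devices$ellipta
  p2 <- p1; p2$emission_concentration <- 2 * p1$emission_concentration
  expect_equal(emitted_spectrum(p2, g), 2 * emitted_spectrum(p1, g))

  # calibrated targets: expected M1 on the grid
  m1 <- function(p) sum(g$centers * emitted_spectrum(p, g)) /
    sum(emitted_spectrum(p, g))
  expect_equal(m1(d$devices$handihaler), 2.90, tolerance = 1e-3)
  expect_equal(m1(d$devices$turbohaler), 0.95, tolerance = 1e-3)

  # a median outside the measured range warns and renormalizes in-range
  narrow_grid <- build_grid(1, 10, 16)
  expect_warning(
    e_out <- emitted_spectrum(inhaler_preset("w", 0.03, cmd = 0.5, gsd = 2),
                              narrow_grid),
    "renormalized")
  expect_equal(sum(e_out), 2000, tolerance = 1e-9)
})

test_that("airway filters keep survival in [0, 1] and never amplify", {
  g <- build_grid()
  filt <- filter_model(lung_min_survival = 0.3)
  su <- uam_survival(g$centers, flow = 60, filt)
  sl <- lung_survival(g$centers, filt)
  expect_true(all(su >= 0 & su <= 1))
  expect_true(all(sl >= 0 & sl <= 1))
  # impaction removes essentially everything far above the cutoff
  expect_lt(uam_survival(10, 60, filt), 0.01)
  # lung survival is maximal, and equals the calibrated peak, at the minimum
  expect_equal(lung_survival(filt$lung_min_diameter, filt), 0.3)
  expect_true(all(sl <= 0.3 + 1e-12))

  e <- emitted_spectrum(default_study_design()$devices$breezhaler, g)
  out <- apply_filters(e, filt, flow = 60, grid = g)
  expect_true(all(out$post_uam <= e + 1e-12))
  expect_true(all(out$post_lung <= out$post_uam + 1e-12))
  expect_true(all(out$post_lung >= 0))
})

test_that("counts are Poisson draws of expected concentration x volume", {
  g <- build_grid(1, 10, 1)
  # expectation 2 P/cm3 in one bin, Vm = 500 cm3 -> mean 1000 counts
  means <- vapply(1:12, function(s) {
    sum(sample_counts(2, g, sample_flow = 5, duration = 6, seed = s)$counts)
  }, 0)
  expect_lt(abs(mean(means) - 1000), 3 * sqrt(1000 / 12))
  expect_identical(sample_counts(2, g, duration = 6, seed = 3)$counts,
                   sample_counts(2, g, duration = 6, seed = 3)$counts)
  expect_equal(sample_counts(0, g, duration = 6, seed = 1)$counts, 0)
  expect_error(sample_counts(-1, g, duration = 6), "non-negative")
})

test_that("a generated study tree is complete and byte-deterministic", {
  d <- small_design(seed = 99, n_runs = 2)
  td1 <- withr::local_tempdir()
  td2 <- withr::local_tempdir()
  m1 <- generate_study(d, td1)
  m2 <- generate_study(d, td2)
  # 2 devices x 2 runs x 5 files + 2 background spectra
  expect_equal(nrow(m1), 2 * 2 * 5 + 2)
  expect_identical(m1[setdiff(names(m1), "path")],
                   m2[setdiff(names(m2), "path")])
  rel <- sub(td1, "", m1$path, fixed = TRUE)
  for (i in seq_along(rel)) {
    expect_identical(readLines(file.path(td1, rel[i])),
                     readLines(file.path(td2, rel[i])),
                     label = rel[i])
  }
})

test_that("characterizing generated traces recovers the configured resistances", {
  d <- small_design(seed = 3, n_runs = 2)
  td <- withr::local_tempdir()
  generate_study(d, td)
  ch <- characterize_study(td, "characterization")
  expect_equal(round(ch$summary$resistance, 4),
               unname(vapply(d$devices[ch$summary$device], `[[`, 0,
                             "resistance")))
  rs <- characterize_study(td, "respiration")
  expect_equal(round(rs$summary$resistance, 4),
               round(vapply(d$devices[rs$summary$device], `[[`, 0,
                            "resistance") + d$lung_resistance_increment, 4),
               ignore_attr = TRUE)
  # porcine-mode resistance exceeds bag-mode resistance for every device
  expect_true(all(rs$summary$resistance > ch$summary$resistance))
})
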