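test_that("q0 follows the differential-distribution definition", {
  g <- build_grid(1, 10, 1)          # single bin of width 9
  g2 <- structure(list(lower = c(0, 1), upper = c(1, 2), centers = c(0.5, 1.5),
                       widths = c(1, 1), intervals_per_decade = NA_integer_),
                  class = "size_grid")
  # all mass in one bin of width 0.5
  g05 <- structure(list(lower = c(1, 1.5), upper = c(1.5, 2),
                        centers = c(1.25, 1.75), widths = c(0.5, 0.5),
                        intervals_per_decade = NA_integer_),
                   class = "size_grid")
  q <- number_distribution(binned_spectrum(g05, c(1000, 0), duration = 1))
  expect_equal(q$q0, c(2, 0))

  q2 <- number_distribution(binned_spectrum(g2, c(3, 1), duration = 1))
  expect_equal(q2$q0, c(0.75, 0.25))
})

test_that("q0 integrates to one for random spectra and zero counts are flagged", {
  set.seed(11)
  g <- build_grid()
  for (i in 1:100) {
    q <- number_distribution(random_spectrum(g, lambda = runif(1, 0.5, 200)))
    if (q$total_count > 0) {
      expect_equal(sum(q$q0 * g$widths), 1, tolerance = 1e-9)
    }
  }
  empty <- number_distribution(binned_spectrum(g, numeric(n_bins(g)),
                                               duration = 1))
  expect_true(empty$empty)
  expect_identical(empty$q0, numeric(n_bins(g)))
  expect_error(mean_diameter(empty), "undefined")
})

test_that("mean diameter equals the count-weighted mean of bin centers", {
  g <- build_grid()
  set.seed(12)
  for (i in 1:1000) {
    s <- random_spectrum(g, lambda = runif(1, 0.2, 100))
    if (sum(s$counts) == 0) next
    oracle <- sum(s$counts * g$centers) / sum(s$counts)
    expect_equal(mean_diameter(s), oracle, tolerance = 1e-9)
  }
  # degenerate: all counts in one bin -> M1 is that bin's center
  counts <- numeric(n_bins(g))
  k <- which.min(abs(g$centers - 2.9))
  counts[k] <- 5000
  expect_equal(mean_diameter(binned_spectrum(g, counts, duration = 1)),
               g$centers[k])
})

test_that("measured volume converts L/min x s to cm3", {
  expect_equal(measured_volume(5, 6), 500)
  expect_equal(measured_volume(5, 60), 5000)
  expect_equal(measured_volume(30, 6), 3000)
  expect_error(measured_volume(0, 5), "positive")
  expect_error(measured_volume(5, -1), "positive")
})

test_that("concentration and counts round-trip through the measured volume", {
  g <- build_grid()
  set.seed(13)
  s <- random_spectrum(g, lambda = 20, duration = 6, sample_flow = 5)
  cs <- concentration(s)
  expect_equal(cs$measured_volume, 500)
  expect_equal(sum(cs$dCn) * cs$measured_volume, sum(s$counts),
               tolerance = 1e-9)
  expect_equal(cs$dCn * cs$measured_volume, s$counts, tolerance = 1e-9)
  # 1000 particles in 500 cm3 -> 2 P/cm3
  counts <- numeric(n_bins(g)); counts[10] <- 1000
  expect_equal(sum(concentration(binned_spectrum(g, counts, duration = 6))$dCn),
               2)
})

test_that("background subtraction is bin-wise and clipped at zero", {
  g <- build_grid(1, 10, 4)
  mk <- function(counts) concentration(binned_spectrum(g, counts, duration = 6))
  a <- mk(c(10, 5, 0, 7))
  b <- mk(c(3, 9, 1, 7))
  out <- subtract_background(a, b)
  expect_equal(out$dCn, pmax(a$dCn - b$dCn, 0))
  expect_true(all(out$dCn >= 0))
  expect_equal(subtract_background(a, a)$dCn, numeric(4))
  zero <- mk(c(0, 0, 0, 0))
  expect_equal(subtract_background(a, zero)$dCn, a$dCn)
  other <- concentration(binned_spectrum(build_grid(1, 10, 5),
                                         numeric(5), duration = 1))
  expect_error(subtract_background(a, other), "incompatible")
})
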