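test_that("intervals and rhythm ratios follow their defining formulas", {
  expect_equal(intervals(c(0, 250, 500)), c(250, 250))
  s <- generate_poisson(5, 50, seed = 2)
  iv <- intervals(s)
  expect_length(iv, length(s) - 1)
  expect_equal(sum(iv), as.numeric(s[length(s)] - s[1]))
  expect_error(intervals(c(0, 0, 1)), "strictly increasing")
  expect_error(intervals(5), "at least 2")

  expect_equal(rhythm_ratios(c(200, 100)), 2 / 3)   # a 2:1 long-short pair
  expect_true(all(rhythm_ratios(rep(7, 10)) == 0.5))
  expect_error(rhythm_ratios(100), "at least 2")
  expect_error(rhythm_ratios(c(1, -1)), "positive")
})

test_that("ratios of a reversed interval sequence are 1 - r, reversed", {
  set.seed(9)
  for (i in 1:20) {
    iv <- rexp(sample(5:50, 1)) + 0.01
    expect_equal(rhythm_ratios(rev(iv)), rev(1 - rhythm_ratios(iv)),
                 tolerance = 1e-12)
  }
})

test_that("KDE recovers uniform and bimodal shapes and integrates to 1", {
  set.seed(4)
  u <- runif(2e4)
  d <- kde_density(u)
  inner <- d$density[d$ratio > 0.1 & d$ratio < 0.9]
  expect_true(all(abs(inner - 1) < 0.1))
  wide <- kde_density(u, grid = seq(-0.5, 1.5, length.out = 2001))
  expect_equal(sum(wide$density) * (2 / 2000), 1, tolerance = 0.02)

  bi <- c(rnorm(4000, 1 / 3, 0.02), rnorm(4000, 2 / 3, 0.02))
  db <- kde_density(bi)
  lower <- db[db$ratio < 0.5, ]; upper <- db[db$ratio >= 0.5, ]
  expect_lt(abs(lower$ratio[which.max(lower$density)] - 1 / 3), 0.02)
  expect_lt(abs(upper$ratio[which.max(upper$density)] - 2 / 3), 0.02)

  expect_error(kde_density(rep(0.5, 100)), "degenerate")
})

test_that("bin construction follows the midpoint / central-half rule", {
  b <- build_bins(c(0.5, 0.6))
  expect_equal(b$hi[1], 0.55)          # midpoint boundary
  expect_equal(b$on_hi[1], 0.525)      # on-bin extends half-way to it
  expect_equal(b$on_lo[1], 0.475)      # outermost side mirrors it
  expect_equal(b$lo[1], 0.45)

  full <- build_bins()
  expect_equal(nrow(full), 7)
  expect_equal(full$target, c(1/4, 1/3, 2/5, 1/2, 3/5, 2/3, 3/4))
  # inverse categories (1:2 vs 2:1 etc.) are distinct bins
  expect_true(all(c("1:2", "2:1", "1:3", "3:1") %in% full$label))
  # segments tile without overlap, on-bins sit inside their segment
  expect_true(all(full$hi[-7] == full$lo[-1]))
  expect_true(all(full$lo < full$on_lo & full$on_lo < full$target &
                  full$target < full$on_hi & full$on_hi < full$hi))
  # on-width equals the combined off-width per segment (uniform scores 0.5)
  expect_equal(full$on_hi - full$on_lo,
               (full$on_lo - full$lo) + (full$hi - full$on_hi))
  expect_error(build_bins(0.5), "at least 2")
})

test_that("on-integer fraction measures concentration at a category", {
  bins <- build_bins()
  expect_equal(on_integer_fraction(rep(0.5, 50), "1:1", bins), 1)
  expect_equal(on_integer_fraction(rep(2 / 3, 50), "2:1", bins), 1)
  set.seed(6)
  expect_lt(abs(on_integer_fraction(runif(2e5), "1:1", bins) - 0.5), 0.05)
  expect_lt(abs(on_integer_fraction(runif(2e5), "1:3", bins) - 0.5), 0.05)
  # isochronous event sequence scores 1 on the 1:1 category
  r <- event_ratios(generate_isochronous(4, 120))
  expect_equal(on_integer_fraction(r, "1:1", bins), 1)
  # no mass anywhere near the category -> undefined
  expect_true(is.na(on_integer_fraction(c(0.05, 0.95), "1:1", bins)))
  expect_error(on_integer_fraction(r, "5:4", bins), "unknown")
})

test_that("spacing entropy estimator is calibrated against closed forms", {
  set.seed(13)
  e_unif <- replicate(5, differential_entropy(runif(1e4)))
  expect_true(all(abs(e_unif - 0) < 0.05))
  e_half <- replicate(5, differential_entropy(runif(1e4, 0, 0.5)))
  expect_true(all(abs(e_half - log(0.5)) < 0.05))
  e_norm <- differential_entropy(rnorm(1e4, sd = 2))
  expect_lt(abs(e_norm - 0.5 * log(2 * pi * exp(1) * 4)), 0.1)
  expect_identical(differential_entropy(rep(0.5, 100)), -Inf)
  expect_error(differential_entropy(runif(5)), "at least 10")
})

test_that("entropy decreases under concentration, uniform is maximal on (0,1)", {
  set.seed(14)
  for (spread in c(0.3, 0.1, 0.03)) {
    lo <- differential_entropy(runif(2000, 0.5 - spread, 0.5 + spread))
    hi <- differential_entropy(runif(2000, 0.5 - spread * 3, 0.5 + spread * 3))
    expect_lt(lo, hi)
  }
  # no sample supported on (0,1) beats the uniform by more than estimator noise
  for (i in 1:10) {
    x <- rbeta(2000, sample(1:5, 1), sample(1:5, 1))
    expect_lt(differential_entropy(x), 0 + 3 * 0.05)
  }
})

test_that("sequence_metrics emits the documented one-row layout", {
  m <- sequence_metrics(generate_isochronous(4, 120))
  expect_equal(names(m), c("n_intervals", "entropy", "frac_1_3", "frac_1_2",
                           "frac_2_3", "frac_1_1", "frac_3_2", "frac_2_1",
                           "frac_3_1"))
  expect_equal(m$n_intervals, 119)
  expect_identical(m$entropy, -Inf)
  expect_equal(m$frac_1_1, 1)
})
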