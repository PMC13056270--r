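test_that("alpha current kernel is normalised to its peak", {
  expect_equal(alpha_current(2, w = 500, tau_syn = 2), 500)   # peak at tau_syn
  expect_equal(alpha_current(0, 500, 2), 0)
  expect_equal(alpha_current(-1, 500, 2), 0)                  # before the event
  expect_equal(alpha_current(200, 500, 2), 0, tolerance = 1e-6)
  expect_equal(alpha_current(4, w = 1, tau_syn = 2), 2 * exp(1) * exp(-2))
})

test_that("closed-form intrinsic period behaves like a Type I oscillator", {
  nrn <- lif_neuron(rate = 40)
  expect_equal(intrinsic_period(nrn), 25)
  # period diverges toward rheobase (logarithmically) and shrinks with drive
  rheo <- (nrn$V_th - nrn$E_L) * nrn$C_m / nrn$tau_m
  periods <- sapply(rheo * c(1.0000001, 1.001, 1.1, 1.5, 3),
                    function(I) intrinsic_period(lif_neuron(I_e = I)))
  expect_true(all(diff(periods) < 0))
  expect_gt(periods[1], 150)  # near-rheobase firing is slow
  expect_error(intrinsic_period(lif_neuron(I_e = rheo * 0.99)), "rheobase")
})

test_that("current_for_rate inverts the period formula", {
  nrn <- lif_neuron(I_e = 400)
  for (rate in c(10, 20, 40, 77, 100)) {
    I <- current_for_rate(rate, nrn)
    expect_lt(abs(intrinsic_period(lif_neuron(I_e = I)) - 1000 / rate), 1e-9)
  }
  Is <- sapply(seq(5, 100, by = 5), current_for_rate, object = nrn)
  expect_true(all(diff(Is) > 0))  # faster firing needs more current
  expect_error(current_for_rate(600, nrn), "refractory")
  expect_error(current_for_rate(0.01, nrn), "too slow")
})

test_that("simulated free run matches the closed-form period within 2 dt", {
  set.seed(42)
  for (i in 1:50) {
    nrn <- lif_neuron(rate = runif(1, 15, 80), tau_m = runif(1, 5, 25),
                      t_ref = runif(1, 1, 4), V_th = runif(1, -60, -50),
                      dt = 0.01)
    isi <- diff(simulate(nrn, nsim = 5))
    expect_lt(max(abs(isi - intrinsic_period(nrn))), 2 * nrn$dt)
  }
})

test_that("unforced output is isochronous with all rhythm ratios 0.5", {
  sp <- simulate(lif_neuron(rate = 40), nsim = 120)
  expect_true(all(event_ratios(sp) == 0.5))
  expect_equal(unique(diff(sp)), 25, tolerance = 2 * 0.1)
})

test_that("refining the step converges: free run exactly, forced run in median", {
  # free run: every inter-spike interval agrees to within one coarse step
  # (absolute spike times can drift linearly when the continuous-time
  # crossing falls exactly on a grid boundary)
  for (dt in c(0.1, 0.05)) {
    a <- simulate(lif_neuron(rate = 40, dt = dt), nsim = 50)
    b <- simulate(lif_neuron(rate = 40, dt = dt / 2), nsim = 50)
    expect_lt(max(abs(diff(a) - diff(b))), dt + 1e-12)
    expect_lte(abs(a[1] - b[1]), dt)
  }
  # forced run: input snapping makes near-tangent crossings slip by whole
  # steps, and such slips accumulate over the run; convergence shows up as a
  # small typical (median) displacement and an accurate first spike
  t <- unique(round(as.numeric(generate_poisson(60, 300, seed = 8)) / 0.2) * 0.2 + 0.2)
  inp <- event_seq(t)  # grid-aligned for both step sizes
  for (dt in c(0.1, 0.05)) {
    a <- simulate(lif_neuron(rate = 40, dt = dt), nsim = 20, input = inp)
    b <- simulate(lif_neuron(rate = 40, dt = dt / 2), nsim = 20, input = inp)
    expect_lte(abs(a[1] - b[1]), 2 * dt)
    expect_lt(stats::median(abs(as.numeric(a) - as.numeric(b))), 5 * dt)
  }
})

test_that("an excitatory input spike can only advance the next firing", {
  base <- simulate(lif_neuron(rate = 20), nsim = 3)
  first <- base[2]
  for (t_in in seq(2, 48, by = 2.5)) {
    sp <- simulate(lif_neuron(rate = 20), nsim = 3, input = event_seq(t_in))
    expect_lte(sp[2], first + 1e-9)
  }
})

test_that("a strong input spike fires a sub-rheobase neuron exactly once", {
  nrn <- lif_neuron(I_e = 0, weight = 3200)  # silent without input
  sp <- simulate(nrn, nsim = 1, input = event_seq(50),
                 max_duration = 5000)
  expect_gt(sp[1], 50)        # causal
  expect_lt(sp[1], 60)        # and prompt
  # and no second output interval materialises afterwards
  expect_error(simulate(nrn, nsim = 2, input = event_seq(50),
                        max_duration = 5000), "silent")
})

test_that("the forced simulation is deterministic given its input", {
  inp <- generate_poisson(30, 300, seed = 99)
  a <- simulate(lif_neuron(rate = 40), nsim = 100, input = inp)
  b <- simulate(lif_neuron(rate = 40), nsim = 100, input = inp)
  expect_identical(as.numeric(a), as.numeric(b))
})

test_that("parameter invariants are enforced", {
  expect_error(lif_neuron(rate = 40, dt = 3), "t_ref")
  expect_error(lif_neuron(rate = 40, V_th = -75), "V_reset")
  expect_error(lif_neuron(), "required")
  expect_error(lif_neuron(rate = 40, I_e = 100), "not both")
  expect_error(lif_neuron(rate = 40, tau_syn = 0), "positive")
})
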