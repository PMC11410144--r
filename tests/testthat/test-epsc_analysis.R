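test_that("baseline is the mean of the 1 ms pre-stimulus window", {
  sw <- sweep_trace(rep(-10, 20000), 5e-5, 0.5)
  expect_equal(measure_baseline(sw), -10)
  # linear ramp 0 -> -2 pA across the 1 ms window: mean -1 within half a step
  n <- 20000; dt <- 5e-5
  y <- rep(0, n)
  idx <- (10000 - 19):10000
  y[idx] <- seq(0, -2, length.out = 20)
  sw <- sweep_trace(y, dt, 0.5)
  expect_lt(abs(measure_baseline(sw) - (-1)), 2 / 20 / 2 + 1e-9)
  expect_error(measure_baseline(sweep_trace(rep(0, 100), 5e-5, 0)),
               "pre-stimulus")
})

test_that("EPSC amplitude and peak are recovered from constructions", {
  sw <- biexp_epsc_sweep(A1 = 490, A2 = 210)
  bl <- measure_baseline(sw)
  pk <- measure_epsc(sw, bl)
  expect_lt(abs(pk$amplitude - 700), 1)
  expect_false(pk$flagged)
  # flat trace: ~0 amplitude, flagged
  flat <- sweep_trace(rep(-5, 30000), 5e-5, 0.5)
  pf <- measure_epsc(flat, measure_baseline(flat))
  expect_equal(pf$amplitude, 0)
  expect_true(pf$flagged)
  # a 30 pA quantal event at +50 ms does not contaminate the peak search
  syn <- synapse_sim_preset("parallel_fiber_MLI"); syn$noise_rms <- 0
  gen <- genotype_preset("WT", "parallel_fiber_MLI")
  sim <- generate_sweep(syn, gen, post = 1.5,
                        events = data.frame(t = 0.05, amp = 30))
  pk2 <- measure_epsc(sim$sweep, measure_baseline(sim$sweep))
  expect_lt(abs(pk2$amplitude - 700), 1)
  # invariance to a constant offset
  off <- sim$sweep; off$samples <- off$samples + 37
  pk3 <- measure_epsc(off, measure_baseline(off))
  expect_equal(pk3$amplitude, pk2$amplitude, tolerance = 1e-10)
})

test_that("bi-exponential decay fits recover amplitudes and weighted tau", {
  sw <- biexp_epsc_sweep(A1 = 500, tau1 = 2, A2 = 200, tau2 = 20)
  bl <- measure_baseline(sw)
  pk <- measure_epsc(sw, bl)
  fit <- fit_epsc_decay(sw, pk, bl)
  expect_lt(abs(fit$weighted_tau - 500 * 2 / 700 - 200 * 20 / 700) /
              (500 * 2 / 700 + 200 * 20 / 700), 0.02)
  expect_gte(fit$fit_start_time, fit$peak_time)
  expect_true(fit$weighted_tau >= min(fit$tau1, fit$tau2) &&
                fit$weighted_tau <= max(fit$tau1, fit$tau2))
  # degenerate single exponential: weighted tau collapses to that tau
  sw1 <- biexp_epsc_sweep(A1 = 700, tau1 = 3, A2 = 0, tau2 = 30)
  pk1 <- measure_epsc(sw1, 0)
  fit1 <- fit_epsc_decay(sw1, pk1, 0)
  expect_lt(abs(fit1$weighted_tau - 3), 0.05)
  # pure noise: degenerate fit reported as error
  set.seed(5)
  noise <- sweep_trace(rnorm(30000, sd = 0.001), 5e-5, 0.5)
  pkn <- measure_epsc(noise, measure_baseline(noise))
  expect_error(fit_epsc_decay(noise, pkn, measure_baseline(noise)))
})

test_that("weighted tau recovery stays within 2% across a tau grid", {
  for (tau2 in c(10, 30, 100)) {
    for (frac in c(0.5, 0.8)) {
      A <- 700
      sw <- biexp_epsc_sweep(A1 = frac * A, tau1 = 2, A2 = (1 - frac) * A,
                             tau2 = tau2)
      pk <- measure_epsc(sw, 0)
      fit <- fit_epsc_decay(sw, pk, 0, fit_window_ms = 400)
      truth <- (frac * A * 2 + (1 - frac) * A * tau2) / A
      expect_lt(abs(fit$weighted_tau - truth) / truth, 0.02)
    }
  }
})

test_that("subtracting the fitted EPSC leaves only the quantal events", {
  # sweep built exactly from its own fit: residual ~ 0
  sw <- biexp_epsc_sweep(A1 = 500, tau1 = 2, A2 = 200, tau2 = 20,
                         baseline = -12)
  bl <- measure_baseline(sw)
  pk <- measure_epsc(sw, bl)
  fit <- fit_epsc_decay(sw, pk, bl, fit_window_ms = 1400)
  res <- subtract_epsc_fit(sw, fit)
  i_fit <- round((fit$fit_start_time + sw$stim_time) / sw$dt) + 1L
  expect_lt(max(abs(res$samples[i_fit:length(res$samples)])), 0.5)
  expect_length(res$samples, length(sw$samples))
  expect_equal(res$dt, sw$dt)
  # EPSC + one event: residual shows the event and little else
  syn <- synapse_sim_preset("parallel_fiber_MLI"); syn$noise_rms <- 0
  gen <- genotype_preset("WT", "parallel_fiber_MLI")
  sim <- generate_sweep(syn, gen, post = 1.5,
                        events = data.frame(t = 0.05, amp = 30))
  sw2 <- sim$sweep
  bl2 <- measure_baseline(sw2)
  pk2 <- measure_epsc(sw2, bl2)
  res2 <- subtract_epsc_fit(sw2, fit_epsc_decay(sw2, pk2, bl2))
  t_rel <- sweep_times(res2)
  late <- res2$samples[t_rel > 0.03]
  expect_lt(abs(min(late) + 30), 3)
  expect_lt(abs(t_rel[t_rel > 0.03][which.min(late)] - 0.05), 1.5e-3)
  quiet <- res2$samples[t_rel > 0.1 & t_rel < 1.4]
  expect_lt(max(abs(quiet)), 2)
})

test_that("peak-aligned averaging preserves amplitude and reports dispersion", {
  sw <- biexp_epsc_sweep()
  avg <- average_peak_aligned(list(sw, sw, sw), rep(0, 3))
  i <- which.min(abs(avg$time - 0.001))
  expect_equal(avg$mean[i], sw$samples[round(0.501 / 5e-5) + 1L])
  expect_true(all(avg$sd == 0))
  # one-sample offset peaks still align to the common peak amplitude
  sw_shift <- sw
  sw_shift$samples <- c(sw$samples[-1L], sw$samples[length(sw$samples)])
  avg2 <- average_peak_aligned(list(sw, sw_shift), c(0, -5e-5))
  expect_equal(min(avg2$mean), min(sw$samples), tolerance = 1e-6)
  expect_error(average_peak_aligned(list(sw), 0), "at least 2")
})
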