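test_that("quantal kernel peak time and normalization match the closed form", {
  k <- make_quantal_kernel(0.2, 2.0, dt = 5e-5)
  # t* = ln(tau_d/tau_r) * tau_r tau_d / (tau_d - tau_r) = ln(10)*0.4/1.8 ms
  t_star <- log(10) * 0.2 * 2.0 / 1.8 / 1000
  expect_lt(abs(k$peak_time - t_star), 1e-9)
  expect_equal(which.max(k$waveform),
               round(t_star / 5e-5) + 1L, tolerance = 1)
  expect_equal(max(k$waveform), 1.0)
  expect_lt(k$waveform[length(k$waveform)], 2e-2)
  expect_error(make_quantal_kernel(2, 2, 5e-5), "tau")
  # near-degenerate time constants stay finite (alpha-function limit)
  k2 <- make_quantal_kernel(1, 1.0001, dt = 1e-5)
  expect_true(all(is.finite(k2$waveform)))
  expect_equal(max(k2$waveform), 1.0)
})

test_that("event-time sampler reproduces homogeneous Poisson statistics", {
  expect_identical(sample_event_times(0, 50, 0, c(0, 1), seed = 1),
                   numeric(0))
  set.seed(21)
  n_draws <- 5000
  counts <- vapply(seq_len(n_draws), function(i) {
    length(sample_event_times(0, 50, 10, c(1, 5)))
  }, numeric(1L))
  # mean = rate x duration = 40, within 3 SE
  expect_lt(abs(mean(counts) - 40), 3 * sd(counts) / sqrt(n_draws))
})

test_that("event-time sampler integrates the AR transient correctly", {
  set.seed(22)
  n_draws <- 5000
  counts <- vapply(seq_len(n_draws), function(i) {
    length(sample_event_times(2, 50, 0, c(0, 1)))
  }, numeric(1L))
  expected <- 2 * (1 - exp(-1000 / 50))
  expect_lt(abs(mean(counts) - expected), 3 * sd(counts) / sqrt(n_draws))
  expect_error(sample_event_times(-1, 50, 0, c(0, 1)), "non-negative")
  expect_error(sample_event_times(1, 50, 0, c(1, 0)), "window")
  expect_error(sample_event_times(1, 50, 5, c(0, 1), envelope = 1),
               "envelope")
})

test_that("sampler PSTH matches the rate model bin by bin", {
  set.seed(23)
  n_sweeps <- 5000
  n_ar <- 2; tau <- 50; spont <- 2
  times <- unlist(lapply(seq_len(n_sweeps), function(i) {
    sample_event_times(n_ar, tau, spont, c(0, 0.3))
  }))
  breaks <- seq(0, 0.3, by = 0.01)
  obs <- tabulate(findInterval(times, breaks, rightmost.closed = TRUE),
                  nbins = length(breaks) - 1L)
  lo <- breaks[-length(breaks)] * 1000; hi <- breaks[-1L] * 1000
  expected <- n_sweeps * (spont * 0.01 +
                            n_ar * (exp(-lo / tau) - exp(-hi / tau)))
  gof <- suppressWarnings(stats::chisq.test(obs, p = expected / sum(expected)))
  expect_gt(gof$p.value, 0.01)
})

test_that("generated sweeps embed events and EPSC as constructed", {
  syn <- synapse_sim_preset("parallel_fiber_MLI")
  syn$noise_rms <- 0
  gen <- genotype_preset("WT", "parallel_fiber_MLI")
  # no events, no noise: sweep is exactly the EPSC template
  sim <- generate_sweep(syn, gen, seed = 1, post = 1.5,
                        events = data.frame(t = numeric(0),
                                            amp = numeric(0)))
  expect_equal(min(sim$sweep$samples), -syn$epsc_amplitude, tolerance = 1e-6)
  expect_equal(sim$sweep$samples[1L], 0)
  # one forced 30 pA event on a flat background
  sw <- quantal_sweep(0.2, 30)
  i_min <- which.min(sw$samples)
  expect_lt(abs(sweep_times(sw)[i_min] - 0.2), 1.5e-3)
  expect_equal(min(sw$samples), -30, tolerance = 1e-6)
  # determinism
  s1 <- generate_sweep(syn, gen, seed = 99, post = 1.5)
  s2 <- generate_sweep(syn, gen, seed = 99, post = 1.5)
  expect_identical(s1$sweep$samples, s2$sweep$samples)
  expect_identical(s1$truth$event_times, s2$truth$event_times)
})

test_that("cohorts have the requested shape and are seed-reproducible", {
  co <- generate_cohort("parallel_fiber_MLI", "WT", n_cells = 2,
                        n_sweeps = 3, seed = 4, post = 1.0)
  expect_length(co, 2L)
  expect_length(co[[1L]]$recording$sweeps, 3L)
  co2 <- generate_cohort("parallel_fiber_MLI", "WT", n_cells = 2,
                         n_sweeps = 3, seed = 4, post = 1.0)
  expect_identical(co[[2L]]$recording$sweeps[[3L]]$samples,
                   co2[[2L]]$recording$sweeps[[3L]]$samples)
})

test_that("cohort-level injected AR counts are Poisson-consistent", {
  co <- generate_cohort("parallel_fiber_MLI", "WT", n_cells = 8,
                        n_sweeps = 25, seed = 7, post = 1.5)
  ar_counts <- unlist(lapply(co, function(cell) {
    vapply(cell$truth[seq_len(25)], function(tr) {
      # spontaneous floor removed by expectation: count events at t >= 0
      # minus the expected spontaneous contribution
      sum(tr$event_times >= 0)
    }, numeric(1L))
  }))
  spont <- synapse_sim_preset("parallel_fiber_MLI")$spont_rate
  expected <- 0.5 * (1 - exp(-1500 / 40)) + spont * 1.5
  n <- length(ar_counts)
  expect_lt(abs(mean(ar_counts) - expected), 3 * sqrt(expected / n))
})

test_that("paired genotypes from one seed share spontaneous candidates", {
  wt <- generate_cohort("parallel_fiber_MLI", "WT", 1, 2, seed = 31,
                        post = 1.5)
  ko <- generate_cohort("parallel_fiber_MLI", "DKO", 1, 2, seed = 31,
                        post = 1.5)
  # pre-stimulus (spontaneous) events are identical under the coupling
  wt_pre <- wt[[1L]]$truth[[1L]]$event_times
  ko_pre <- ko[[1L]]$truth[[1L]]$event_times
  expect_identical(wt_pre[wt_pre < 0], ko_pre[ko_pre < 0])
  # where the DKO rate is below the WT rate (early transient), DKO events
  # are a strict subset of WT events
  expect_true(all(ko_pre[ko_pre >= 0 & ko_pre < 0.15] %in%
                    wt_pre[wt_pre >= 0]))
})

test_that("nucleus generator matches binomial detection closed forms", {
  nuc <- generate_nuclei(100, 0, 0, co_express_fraction = 1, seed = 1)
  expect_true(all(nuc$count_a == 0) && all(nuc$count_b == 0))
  nuc <- generate_nuclei(10000, 1e-4, 1e-4, co_express_fraction = 1,
                         depth = function(n) rep(20000L, n), seed = 2)
  p_expect <- 1 - (1 - 1e-4)^20000  # ~0.8647
  expect_lt(abs(mean(nuc$count_a >= 1) - p_expect),
            3 * sqrt(p_expect * (1 - p_expect) / 10000))
  n1 <- generate_nuclei(50, 1e-4, 2e-4, 0.5, seed = 3)
  n2 <- generate_nuclei(50, 1e-4, 2e-4, 0.5, seed = 3)
  expect_identical(n1, n2)
  expect_error(generate_nuclei(10, -0.1, 0.5), "must lie")
})
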