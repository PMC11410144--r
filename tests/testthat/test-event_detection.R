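test_that("low-pass filter has unit DC gain and the expected rolloff", {
  dc <- sweep_trace(rep(7, 20000), 5e-5, 0.5)
  expect_lt(max(abs(lowpass(dc, 800)$samples - 7)), 1e-6)
  t <- (0:19999) * 5e-5
  pass <- sweep_trace(sin(2 * pi * 100 * t), 5e-5, 0.5)
  out <- lowpass(pass, 800)$samples[2000:18000]
  expect_gt(max(abs(out)), 0.99)
  stopband <- sweep_trace(sin(2 * pi * 5000 * t), 5e-5, 0.5)
  out2 <- lowpass(stopband, 800)$samples[2000:18000]
  expect_lt(max(abs(out2)), 0.1)
  expect_error(lowpass(dc, 11000), "Nyquist")
})

test_that("differentiation is exact on ramps and scaled to pA/ms", {
  flat <- sweep_trace(rep(3, 1000), 5e-5, 0.01)
  expect_true(all(differentiate(flat)$samples == 0))
  # -1 pA per ms ramp
  ramp <- sweep_trace(-(0:999) * 5e-5 * 1000, 5e-5, 0.01)
  d <- differentiate(ramp)$samples
  expect_lt(max(abs(d - (-1))), 1e-9)
  # quantal kernel max slope comfortably exceeds the 20 pA/ms floor
  k <- make_quantal_kernel(0.2, 2, 5e-5)
  ksw <- sweep_trace(-30 * k$waveform, 5e-5, 0)
  expect_gt(max(-differentiate(ksw)$samples), 20)
})

test_that("detection thresholds follow the RMS rule and fixed presets", {
  # deriv trace with known RMS over the 1-5 s window
  t <- (0:119999) * 5e-5
  make_deriv <- function(rms) {
    sweep_trace(rms * sqrt(2) * sin(2 * pi * 200 * t), 5e-5, 0.5)
  }
  mli <- detection_preset("MLI")
  expect_equal(detection_threshold(make_deriv(15), mli), 30,
               tolerance = 1e-3)
  expect_equal(detection_threshold(make_deriv(6), mli), 20)
  pc <- detection_preset("PC")
  expect_equal(detection_threshold(make_deriv(6), pc), 35)
  expect_equal(detection_threshold(make_deriv(50), pc), 35)
  olm <- detection_preset("CA1_OLM")
  expect_identical(olm$name, "OLM")
  expect_equal(olm$exclusion_window, 10)
  short <- sweep_trace(rnorm(50000), 5e-5, 0.5)
  expect_warning(detection_threshold(short, mli), "clipped")
  too_short <- sweep_trace(rnorm(20000), 5e-5, 0.5)
  expect_error(suppressWarnings(detection_threshold(too_short, mli)),
               "RMS window")
})

test_that("single events are localized and measured accurately", {
  sw <- quantal_sweep(0.2, 30, noise_rms = 3, seed = 42)
  ev <- suppressWarnings(detect_events(sw, detection_preset("MLI")))
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$time - 0.2), 5e-4)
  expect_lt(abs(ev$amplitude - 30), 5)
  # below the 20 pA floor: nothing
  sw12 <- quantal_sweep(0.2, 12, noise_rms = 3, seed = 42)
  expect_equal(nrow(suppressWarnings(
    detect_events(sw12, detection_preset("MLI")))), 0L)
  # flat noiseless trace: nothing
  flat <- sweep_trace(rep(0, 60000), 5e-5, 0.5)
  expect_equal(nrow(detect_events(flat, detection_preset("MLI"),
                                  threshold = 20)), 0L)
})

test_that("refractory and exclusion rules drop the expected events", {
  # two 30 pA events 0.6 ms apart: keep the earlier only
  sw <- quantal_sweep(c(0.2, 0.2006), c(30, 30), noise_rms = 0)
  ev <- suppressWarnings(detect_events(sw, detection_preset("MLI"),
                                       threshold = 20))
  expect_equal(nrow(ev), 1L)
  # a fused pair reads as one event localized at the summed-current peak
  expect_gte(ev$time, 0.2)
  expect_lt(ev$time, 0.2025)
  expect_gt(ev$amplitude, 30)
  # two events 5 ms apart: both kept
  sw2 <- quantal_sweep(c(0.2, 0.205), c(30, 30), noise_rms = 0)
  ev2 <- suppressWarnings(detect_events(sw2, detection_preset("MLI"),
                                        threshold = 20))
  expect_equal(nrow(ev2), 2L)
  expect_true(!is.unsorted(ev2$time))
  # event 3 ms after the EPSC peak with a 5 ms exclusion window: dropped
  sw3 <- quantal_sweep(0.003, 30, noise_rms = 0)
  ev3 <- suppressWarnings(detect_events(sw3, detection_preset("MLI"),
                                        threshold = 20,
                                        epsc_peak_time = 0))
  expect_equal(nrow(ev3), 0L)
  # same event without an exclusion window: kept
  ev4 <- suppressWarnings(detect_events(sw3, detection_preset("MLI"),
                                        threshold = 20))
  expect_equal(nrow(ev4), 1L)
})

test_that("detection is idempotent and strictly inward-selective", {
  sw <- quantal_sweep(c(0.1, 0.4, 1.2), c(35, 50, 28), noise_rms = 3,
                      seed = 9)
  p <- detection_preset("MLI")
  ev1 <- suppressWarnings(detect_events(sw, p))
  ev2 <- suppressWarnings(detect_events(sw, p))
  expect_identical(ev1, ev2)
  expect_equal(nrow(ev1), 3L)
  flipped <- sw
  flipped$samples <- -sw$samples
  expect_equal(nrow(suppressWarnings(detect_events(flipped, p))), 0L)
})

test_that("recall and precision exceed 0.90 at the default SNR", {
  syn <- synapse_sim_preset("parallel_fiber_MLI")
  gen <- genotype_preset("WT", "parallel_fiber_MLI")
  pre <- detection_preset("MLI")
  tot <- c(tp = 0L, fp = 0L, fn = 0L)
  for (i in 1:25) {
    sim <- generate_sweep(syn, gen, seed = 500 + i)
    sw <- sim$sweep
    bl <- measure_baseline(sw)
    pk <- measure_epsc(sw, bl)
    res <- subtract_epsc_fit(sw, fit_epsc_decay(sw, pk, bl))
    ev <- suppressWarnings(detect_events(res, pre,
                                         epsc_peak_time = pk$peak_time))
    keep <- sim$truth$event_amps >= 20 &
      (sim$truth$event_times < pk$peak_time |
         sim$truth$event_times > pk$peak_time + 0.0055)
    tot <- tot + match_events(ev$time, sim$truth$event_times[keep])
  }
  recall <- tot[["tp"]] / (tot[["tp"]] + tot[["fn"]])
  precision <- tot[["tp"]] / (tot[["tp"]] + tot[["fp"]])
  expect_gte(recall, 0.90)
  expect_gte(precision, 0.90)
})

test_that("pure-noise sweeps almost never produce false positives", {
  syn <- synapse_sim_preset("parallel_fiber_MLI")
  pre <- detection_preset("MLI")
  n_seeds <- 150
  clean <- 0L
  for (i in seq_len(n_seeds)) {
    set.seed(3000 + i)
    noise <- arquant:::.shaped_noise(80000, 5e-5, 3, 2900)
    sw <- sweep_trace(noise, 5e-5, 0.5)
    ev <- suppressWarnings(detect_events(sw, pre))
    if (nrow(ev) == 0L) clean <- clean + 1L
  }
  expect_gte(clean / n_seeds, 0.95)
})
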