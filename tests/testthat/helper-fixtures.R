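# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# noiseless sweep holding a pure bi-exponential EPSC whose decay the
# fitter should recover exactly; the abrupt onset sits 1 ms after the
# stimulus so the peak falls outside the artifact-blanking interval
biexp_epsc_sweep <- function(A1 = 500, tau1 = 2, A2 = 200, tau2 = 20,
                             baseline = 0, pre = 0.5, post = 1.5,
                             dt = 5e-5, onset_ms = 1) {
  n <- round((pre + post) / dt)
  t_ms <- ((seq_len(n) - 1L) * dt - pre) * 1000 - onset_ms
  y <- rep(baseline, n)
  pos <- t_ms >= 0
  y[pos] <- baseline - (A1 * exp(-t_ms[pos] / tau1) +
                          A2 * exp(-t_ms[pos] / tau2))
  sweep_trace(y, dt, pre, "biexp")
}

# flat sweep with injected difference-of-exponential quantal events
quantal_sweep <- function(event_times, event_amps, noise_rms = 0,
                          pre = 0.5, post = 2.5, dt = 5e-5, seed = NULL) {
  syn <- synapse_sim_preset("parallel_fiber_MLI")
  syn$noise_rms <- noise_rms
  syn$epsc_amplitude <- 1e-9  # effectively no synchronous EPSC
  gen <- genotype_preset("WT", "parallel_fiber_MLI")
  sim <- generate_sweep(syn, gen, seed = seed, pre = pre, post = post,
                        dt = dt,
                        events = data.frame(t = event_times,
                                            amp = event_amps))
  sim$sweep
}

# greedy matching of detected to true event times within a tolerance
match_events <- function(detected, truth, tol = 1.5e-3) {
  used <- rep(FALSE, length(truth))
  tp <- 0L
  for (t in detected) {
    j <- which(!used & abs(truth - t) < tol)
    if (length(j)) {
      used[j[1L]] <- TRUE
      tp <- tp + 1L
    }
  }
  c(tp = tp, fp = length(detected) - tp, fn = length(truth) - tp)
}

# small deterministic recording for I/O tests
tiny_recording <- function(n_sweeps = 2, seed = 11) {
  set.seed(seed)
  sweeps <- lapply(seq_len(n_sweeps), function(i) {
    sweep_trace(round(stats::rnorm(30000, sd = 5), 4), dt = 5e-5,
                stim_time = 0.5, sweep_id = paste0("s", i))
  })
  recording(sweeps, synapse = "parallel_fiber_MLI", genotype = "WT",
            cell_id = "cellA", isi = 8)
}
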