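#' Synapse simulation presets
#'
#' Each preset bundles the scales needed to emulate stimulus-evoked
#' recordings at one synapse type: the synchronous EPSC (amplitude and
#' kinetics), the expected number of asynchronous-release (AR) events per
#' stimulus for wild type, the spontaneous event rate, the quantal
#' amplitude distribution, and the recording noise. The parallel-fiber
#' EPSC amplitude (700 pA) matches the reported scale of parallel
#' fiber-to-interneuron responses; the remaining scales are package
#' defaults chosen to be realistic for these synapses (see the methods
#' vignette) and are freely overridable by editing the returned list.
#'
#' @param name One of `"climbing_fiber"`, `"parallel_fiber_MLI"`,
#'   `"CA1_OLM"`.
#' @return A list with fields `name`, `epsc_amplitude` (pA), `epsc_rise`,
#'   `epsc_tau1`, `epsc_tau2` (ms), `epsc_frac1` (fraction of decay
#'   amplitude in the fast component), `wt_ar_per_stim`, `spont_rate`
#'   (Hz), `quantal_mean` (pA), `quantal_cv`, `kernel_tau_rise`,
#'   `kernel_tau_decay` (ms), `noise_rms` (pA), and
#'   `acquisition_cutoff` (Hz) shaping the simulated noise.
#' @export
synapse_sim_preset <- function(name = c("climbing_fiber", "parallel_fiber_MLI",
                                        "CA1_OLM")) {
  name <- match.arg(name)
  base <- list(
    name = name,
    quantal_mean = 40, quantal_cv = 0.3,
    kernel_tau_rise = 0.2, kernel_tau_decay = 2,
    noise_rms = 3, acquisition_cutoff = 2900,
    cell_amp_cv = 0.1,
    # reference AR decay constant (ms) defining the synapse-level thinning
    # envelope shared by all genotypes of the synapse (see
    # sample_event_times); equals the WT AR time constant
    ar_env_tau = 40
  )
  specific <- switch(name,
    climbing_fiber = list(epsc_amplitude = 2000, epsc_rise = 0.3,
                          epsc_tau1 = 3, epsc_tau2 = 20, epsc_frac1 = 0.7,
                          wt_ar_per_stim = 1.5, spont_rate = 0.5),
    parallel_fiber_MLI = list(epsc_amplitude = 700, epsc_rise = 0.3,
                              epsc_tau1 = 2, epsc_tau2 = 15, epsc_frac1 = 0.7,
                              wt_ar_per_stim = 0.5, spont_rate = 0.5),
    CA1_OLM = list(epsc_amplitude = 700, epsc_rise = 0.4,
                   epsc_tau1 = 3, epsc_tau2 = 25, epsc_frac1 = 0.7,
                   wt_ar_per_stim = 0.5, spont_rate = 0.3)
  )
  c(base, specific)
}

#' Genotype presets for the AR generator
#'
#' The AR expectation of a simulated genotype is
#' `wt_ar_per_stim * ar_multiplier`. Multipliers encode the reported
#' percent reductions in AR relative to wild type at each synapse
#' (climbing fiber: 80% loss in Syt3 knockouts; parallel fiber: 23%, 49%
#' and 71% loss in Syt3, Syt7 and double knockouts; hippocampal CA1 to
#' O-LM: 49%, 61% and 92%). The AR decay constants follow the reported
#' ordering (slower in Syt3 knockouts, faster in Syt7 knockouts, slowest
#' remaining component in double knockouts); their magnitudes are package
#' defaults since no values are reported.
#'
#' @param genotype `"WT"`, `"Syt3KO"`, `"Syt7KO"` or `"DKO"`.
#' @param synapse Synapse preset name (multipliers are synapse-specific).
#' @return A list with `name`, `ar_multiplier` and `tau_ar` (ms).
#' @export
genotype_preset <- function(genotype = c("WT", "Syt3KO", "Syt7KO", "DKO"),
                            synapse = c("climbing_fiber", "parallel_fiber_MLI",
                                        "CA1_OLM")) {
  genotype <- match.arg(genotype)
  synapse <- match.arg(synapse)
  multipliers <- list(
    climbing_fiber     = c(WT = 1, Syt3KO = 0.20, Syt7KO = NA, DKO = NA),
    parallel_fiber_MLI = c(WT = 1, Syt3KO = 0.77, Syt7KO = 0.51, DKO = 0.29),
    CA1_OLM            = c(WT = 1, Syt3KO = 0.51, Syt7KO = 0.39, DKO = 0.08)
  )
  m <- multipliers[[synapse]][[genotype]]
  if (is.na(m)) {
    stop(sprintf("no %s preset for synapse %s", genotype, synapse))
  }
  taus <- c(WT = 40, Syt3KO = 60, Syt7KO = 25, DKO = 70)
  list(name = genotype, ar_multiplier = unname(m),
       tau_ar = unname(taus[[genotype]]))
}

#' Build a normalized quantal-event template
#'
#' Difference-of-exponentials waveform
#' `w(t) = exp(-t/tau_decay) - exp(-t/tau_rise)` rescaled to unit peak,
#' evaluated on the sweep grid. The continuous-time peak sits at
#' `t* = log(tau_decay/tau_rise) * tau_rise * tau_decay /
#' (tau_decay - tau_rise)`.
#'
#' @param tau_rise,tau_decay Rise and decay time constants (ms),
#'   `tau_decay > tau_rise > 0`.
#' @param dt Sampling interval (s).
#' @return A list of class `"QuantalKernel"` with `waveform` (unit peak,
#'   positive), `peak_time` (s, from kernel onset), `tau_rise`,
#'   `tau_decay`, `dt`.
#' @export
make_quantal_kernel <- function(tau_rise, tau_decay, dt) {
  if (!(tau_rise > 0) || !(tau_decay > tau_rise)) {
    stop("require tau_decay > tau_rise > 0")
  }
  span_ms <- 8 * tau_decay + 5 * tau_rise
  t_ms <- seq(0, span_ms, by = dt * 1000)
  w <- exp(-t_ms / tau_decay) - exp(-t_ms / tau_rise)
  peak_ms <- log(tau_decay / tau_rise) * tau_rise * tau_decay /
    (tau_decay - tau_rise)
  w <- w / max(w)
  structure(list(waveform = w, peak_time = peak_ms / 1000,
                 tau_rise = tau_rise, tau_decay = tau_decay, dt = dt),
            class = "QuantalKernel")
}

#' Sample event times from the AR + spontaneous release model
#'
#' Event times are drawn from an inhomogeneous Poisson process whose rate
#' is a stimulus-triggered exponential transient over a constant
#' spontaneous floor:
#' `lambda(t) = spont_rate + (n_ar / tau_ar) * exp(-t / tau_ar)` for
#' `t >= 0` and `lambda(t) = spont_rate` before the stimulus, so that the
#' transient integrates to `n_ar` expected AR events per stimulus.
#' Sampling uses thinning with the exact envelope
#' `lambda_max = spont_rate + n_ar / tau_ar`.
#'
#' @param n_ar Expected AR events per stimulus (integral of the
#'   transient).
#' @param tau_ar AR decay constant (ms).
#' @param spont_rate Spontaneous rate (Hz).
#' @param window Length-2 numeric, stimulus-relative sampling window (s).
#' @param seed Optional integer seed; when `NULL`, the current RNG stream
#'   is used (so cohort generation stays reproducible from one master
#'   seed).
#' @param envelope Optional thinning envelope rate (Hz) overriding the
#'   default `spont_rate + n_ar/tau_ar`. Any envelope at least as large
#'   as the peak rate yields an exact sampler; passing the same envelope
#'   for every genotype of a synapse couples their candidate streams
#'   under a shared seed, so paired cohorts differ only in which AR
#'   candidates are accepted (common-random-number pairing).
#' @return Sorted numeric vector of stimulus-relative event times (s).
#' @export
sample_event_times <- function(n_ar, tau_ar, spont_rate, window,
                               seed = NULL, envelope = NULL) {
  if (n_ar < 0 || spont_rate < 0) stop("rates must be non-negative")
  if (!(tau_ar > 0)) stop("tau_ar must be positive")
  if (length(window) != 2L || window[1L] >= window[2L]) {
    stop("window must be (t0, t1) with t0 < t1")
  }
  if (!is.null(seed)) set.seed(seed)
  tau_s <- tau_ar / 1000
  peak_rate <- spont_rate + n_ar / tau_s
  lambda_max <- envelope %||% peak_rate
  if (lambda_max < peak_rate) {
    stop("envelope must be at least the peak rate spont_rate + n_ar/tau_ar")
  }
  if (lambda_max == 0) return(numeric(0L))
  n_cand <- stats::rpois(1L, lambda_max * (window[2L] - window[1L]))
  if (n_cand == 0L) return(numeric(0L))
  t_cand <- stats::runif(n_cand, window[1L], window[2L])
  rate <- spont_rate + ifelse(t_cand >= 0,
                              (n_ar / tau_s) * exp(-t_cand / tau_s), 0)
  keep <- stats::runif(n_cand) < rate / lambda_max
  sort(t_cand[keep])
}

# unit-peak synchronous EPSC shape on a stimulus-relative ms grid:
# bi-exponential decay multiplied by an exponential rise
.epsc_shape <- function(t_ms, preset) {
  shape <- numeric(length(t_ms))
  pos <- t_ms >= 0
  tp <- t_ms[pos]
  raw <- (1 - exp(-tp / preset$epsc_rise)) *
    (preset$epsc_frac1 * exp(-tp / preset$epsc_tau1) +
       (1 - preset$epsc_frac1) * exp(-tp / preset$epsc_tau2))
  shape[pos] <- raw / max(raw)
  shape
}

# band-limited Gaussian noise emulating the acquisition low-pass filter,
# rescaled to the requested RMS
.shaped_noise <- function(n, dt, rms, cutoff) {
  if (rms <= 0) return(numeric(n))
  white <- stats::rnorm(n)
  nyq <- 1 / (2 * dt)
  if (cutoff < nyq) {
    bf <- signal::butter(2, cutoff / nyq, type = "low")
    shaped <- .filtfilt_fast(bf$b, bf$a, white)
  } else {
    shaped <- white
  }
  shaped * rms / stats::sd(shaped)
}

.draw_quantal_amps <- function(n, mean_pA, cv) {
  if (n == 0L) return(numeric(0L))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean_pA) - sdlog^2 / 2, sdlog = sdlog)
}

# add -amp * kernel at each event time (times stimulus-relative, s)
.add_events <- function(samples, times, amps, kernel, stim_time, dt) {
  klen <- length(kernel$waveform)
  n <- length(samples)
  for (i in seq_along(times)) {
    i0 <- round((times[i] + stim_time) / dt) + 1L
    if (i0 > n) next
    idx <- i0:min(n, i0 + klen - 1L)
    samples[idx] <- samples[idx] - amps[i] * kernel$waveform[seq_along(idx)]
  }
  samples
}

#' Generate one synthetic stimulus-evoked sweep with ground truth
#'
#' The sweep is the sum of (i) a synchronous EPSC at t = 0 (bi-exponential
#' decay, inward/negative), (ii) quantal events at times drawn from the AR
#' + spontaneous Poisson model with amplitudes from the preset lognormal
#' distribution, and (iii) band-limited Gaussian noise emulating the
#' acquisition filter. The returned ground truth lists every injected
#' event, so detection and quantification can be validated by parameter
#' recovery.
#'
#' @param synapse A [synapse_sim_preset()] list (possibly modified).
#' @param genotype A [genotype_preset()] list.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @param pre,post Pre-/post-stimulus durations (s).
#' @param dt Sampling interval (s), default 20 kHz.
#' @param epsc_amplitude Optional override of the preset EPSC amplitude
#'   (pA), e.g. a jittered per-cell value.
#' @param events Optional data frame with columns `t` (s) and `amp` (pA)
#'   forcing the injected events instead of sampling them.
#' @param sweep_id Identifier for the generated sweep.
#' @return A list with `sweep` (a `Sweep`) and `truth` (event times and
#'   amplitudes, the AR expectation `ar_per_stim`, `tau_ar`,
#'   `spont_rate`, and the injected `epsc_amplitude`).
#' @export
generate_sweep <- function(synapse, genotype, seed = NULL,
                           pre = 0.5, post = 2.5, dt = 5e-5,
                           epsc_amplitude = NULL, events = NULL,
                           sweep_id = "sweep1") {
  if (!is.null(seed)) set.seed(seed)
  if (post < 0.5) stop("post-stimulus window too short for AR analysis")
  amp <- epsc_amplitude %||% synapse$epsc_amplitude
  n <- round((pre + post) / dt)
  t_ms <- ((seq_len(n) - 1L) * dt - pre) * 1000
  samples <- -amp * .epsc_shape(t_ms, synapse)

  ar_expect <- synapse$wt_ar_per_stim * genotype$ar_multiplier
  if (is.null(events)) {
    # candidate times, per-candidate amplitudes, then thinning acceptance,
    # in that order against a synapse-level envelope: genotypes simulated
    # from the same seed share candidates, amplitudes and noise, and
    # differ only in which AR candidates are accepted
    env_tau <- synapse$ar_env_tau %||% genotype$tau_ar
    envelope <- synapse$spont_rate +
      max(synapse$wt_ar_per_stim / (env_tau / 1000),
          ar_expect / (genotype$tau_ar / 1000))
    tau_s <- genotype$tau_ar / 1000
    n_cand <- stats::rpois(1L, envelope * (pre + post))
    t_cand <- stats::runif(n_cand, -pre, post)
    amp_cand <- .draw_quantal_amps(n_cand, synapse$quantal_mean,
                                   synapse$quantal_cv)
    rate <- synapse$spont_rate + ifelse(
      t_cand >= 0, (ar_expect / tau_s) * exp(-t_cand / tau_s), 0)
    keep <- stats::runif(n_cand) < rate / envelope
    ord <- order(t_cand[keep])
    times <- t_cand[keep][ord]
    amps <- amp_cand[keep][ord]
  } else {
    times <- events$t
    amps <- events$amp
  }
  kernel <- make_quantal_kernel(synapse$kernel_tau_rise,
                                synapse$kernel_tau_decay, dt)
  samples <- .add_events(samples, times, amps, kernel, pre, dt)
  samples <- samples + .shaped_noise(n, dt, synapse$noise_rms,
                                     synapse$acquisition_cutoff)
  list(
    sweep = sweep_trace(samples, dt, pre, sweep_id),
    truth = list(event_times = times, event_amps = amps,
                 ar_per_stim = ar_expect, tau_ar = genotype$tau_ar,
                 spont_rate = synapse$spont_rate, epsc_amplitude = amp)
  )
}

#' Generate a cohort of synthetic recordings with ground truth
#'
#' Cells receive seeds derived deterministically from the master seed, and
#' per-cell synchronous EPSC amplitudes are jittered (lognormal, CV from
#' the preset) around the preset mean to emulate cell-to-cell variability
#' in the number of stimulated fibers.
#'
#' @param synapse A [synapse_sim_preset()] list or preset name.
#' @param genotype A [genotype_preset()] list or genotype name.
#' @param n_cells,n_sweeps Cohort dimensions.
#' @param seed Master integer seed.
#' @inheritParams generate_sweep
#' @return A list with one element per cell, each a list of `recording`
#'   (a `Recording`) and `truth` (per-sweep ground-truth lists plus the
#'   cell's true EPSC amplitude).
#' @export
generate_cohort <- function(synapse, genotype, n_cells, n_sweeps, seed,
                            pre = 0.5, post = 2.5, dt = 5e-5) {
  if (is.character(synapse)) synapse <- synapse_sim_preset(synapse)
  if (is.character(genotype)) genotype <- genotype_preset(genotype, synapse$name)
  if (n_cells < 1L || n_sweeps < 1L) stop("n_cells and n_sweeps must be >= 1")
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, n_cells)
  cv <- synapse$cell_amp_cv %||% 0.1
  sdlog <- sqrt(log(1 + cv^2))
  lapply(seq_len(n_cells), function(ci) {
    set.seed(cell_seeds[ci])
    cell_amp <- stats::rlnorm(1L, log(synapse$epsc_amplitude) - sdlog^2 / 2,
                              sdlog)
    # per-sweep seeds keep paired genotype cohorts aligned sweep-by-sweep
    sweep_seeds <- sample.int(.Machine$integer.max - 1L, n_sweeps)
    sims <- lapply(seq_len(n_sweeps), function(si) {
      generate_sweep(synapse, genotype, seed = sweep_seeds[si], pre = pre,
                     post = post, dt = dt, epsc_amplitude = cell_amp,
                     sweep_id = sprintf("c%02d_s%03d", ci, si))
    })
    rec <- recording(lapply(sims, `[[`, "sweep"), synapse = synapse$name,
                     genotype = genotype$name,
                     cell_id = sprintf("cell%02d", ci))
    list(recording = rec,
         truth = c(lapply(sims, `[[`, "truth"),
                   list(cell_epsc_amplitude = cell_amp)))
  })
}

#' Generate synthetic single-nucleus transcript count records
#'
#' Stands in for a droplet-based single-nucleus RNA-seq dataset: each
#' nucleus draws a total transcript depth from a lognormal depth
#' distribution; a fraction `co_express_fraction` of nuclei express both
#' genes, the remainder split evenly between single-gene expressers.
#' Expressed genes contribute counts `Binomial(total, f)` (independent
#' per-transcript capture at relative abundance `f`); unexpressed genes
#' always yield zero.
#'
#' @param n Number of nuclei.
#' @param f_a,f_b Relative transcript abundances of the two genes in
#'   expressing nuclei (probability per captured transcript).
#' @param co_express_fraction Fraction of nuclei expressing both genes.
#' @param depth Either a function `n -> integer depths` or a length-2
#'   numeric `c(meanlog, sdlog)` of a lognormal depth distribution
#'   (default centered near 20000 transcripts).
#' @param seed Optional integer seed.
#' @return A data frame with columns `total_counts`, `count_a`,
#'   `count_b`, and the latent `expresses_a`, `expresses_b` flags
#'   (ground truth).
#' @export
generate_nuclei <- function(n, f_a, f_b, co_express_fraction = 1,
                            depth = c(log(20000), 0.6), seed = NULL) {
  if (any(c(f_a, f_b, co_express_fraction) < 0) ||
      any(c(f_a, f_b, co_express_fraction) > 1)) {
    stop("f_a, f_b and co_express_fraction must lie in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  depths <- if (is.function(depth)) {
    as.integer(depth(n))
  } else {
    pmax(500L, as.integer(round(stats::rlnorm(n, depth[1L], depth[2L]))))
  }
  co <- stats::runif(n) < co_express_fraction
  a_only <- !co & stats::runif(n) < 0.5
  expresses_a <- co | a_only
  expresses_b <- co | (!co & !a_only)
  count_a <- ifelse(expresses_a, stats::rbinom(n, depths, f_a), 0L)
  count_b <- ifelse(expresses_b, stats::rbinom(n, depths, f_b), 0L)
  data.frame(total_counts = depths, count_a = count_a, count_b = count_b,
             expresses_a = expresses_a, expresses_b = expresses_b)
}
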