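#' Spontaneous event rate from baseline windows
#'
#' The spontaneous rate is estimated from windows far from the
#' stimulus-evoked transient: 500 ms immediately before the stimulus and
#' from 1 s after the stimulus to the end of the analyzed span. It is
#' subtracted from all evoked-release metrics.
#'
#' @param events `DetectedEvents` (pooled over sweeps of one cell);
#'   times stimulus-relative (s).
#' @param n_sweeps Number of sweeps the events were pooled from.
#' @param post_end End of the post-stimulus baseline window (s); clip to
#'   the sweep's post-stimulus span.
#' @param pre_window Pre-stimulus baseline window (s), default
#'   `c(-0.5, 0)`.
#' @param post_start Start of the post-stimulus baseline window (s).
#' @return Spontaneous rate (Hz).
#' @export
spontaneous_rate <- function(events, n_sweeps, post_end,
                             pre_window = c(-0.5, 0), post_start = 1) {
  dur <- (pre_window[2L] - pre_window[1L]) + (post_end - post_start)
  if (dur <= 0) stop("zero-duration spontaneous window")
  n_evt <- sum(events$time >= pre_window[1L] & events$time < pre_window[2L]) +
    sum(events$time >= post_start & events$time <= post_end)
  n_evt / (dur * n_sweeps)
}

#' Spontaneous-corrected AR events per stimulus
#'
#' Counts detected events in the AR window (from the end of the
#' exclusion window to the end of the counting span) per stimulus and
#' subtracts the expected spontaneous contribution.
#'
#' @param events `DetectedEvents` pooled over sweeps.
#' @param spont_rate Spontaneous rate (Hz) from [spontaneous_rate()].
#' @param ar_window Length-2 numeric, the AR counting window (s,
#'   stimulus-relative).
#' @param n_sweeps Number of sweeps pooled.
#' @return Corrected events per stimulus (may be slightly negative
#'   within sampling noise of the correction).
#' @export
events_per_stimulus <- function(events, spont_rate, ar_window, n_sweeps) {
  n_evt <- sum(events$time >= ar_window[1L] & events$time <= ar_window[2L])
  n_evt / n_sweeps - spont_rate * (ar_window[2L] - ar_window[1L])
}

#' Normalize AR events per stimulus by the synchronous EPSC
#'
#' At synapses pooling many fibers, the synchronous EPSC amplitude is a
#' proxy for the number of stimulated synapses, so AR rates are reported
#' per nA of synchronous EPSC.
#'
#' @param events_per_stim Spontaneous-corrected events per stimulus.
#' @param epsc_amplitude Synchronous EPSC amplitude (pA, positive).
#' @return Events per stimulus per nA.
#' @export
normalize_ar <- function(events_per_stim, epsc_amplitude) {
  if (!(epsc_amplitude > 0)) stop("epsc_amplitude must be positive")
  events_per_stim / (epsc_amplitude / 1000)
}

#' Peristimulus time histogram of detected events
#'
#' Per-bin event rate (Hz) across sweeps, with the spontaneous rate
#' subtracted.
#'
#' @param events `DetectedEvents` pooled over sweeps.
#' @param n_sweeps Number of sweeps pooled.
#' @param ar_window Length-2 numeric window to histogram (s).
#' @param bin_ms Bin width (ms).
#' @param spont_rate Spontaneous rate (Hz) to subtract.
#' @return A list with `breaks` (s), `mid` (s), `rate` (Hz,
#'   spontaneous-subtracted) and `count` (raw counts).
#' @export
build_psth <- function(events, n_sweeps, ar_window, bin_ms = 10,
                       spont_rate = 0) {
  if (!(bin_ms > 0)) stop("bin_ms must be positive")
  w <- bin_ms / 1000
  breaks <- seq(ar_window[1L], ar_window[2L] + w - 1e-12, by = w)
  t <- events$time[events$time >= ar_window[1L] & events$time < max(breaks)]
  count <- if (length(t)) {
    tabulate(findInterval(t, breaks), nbins = length(breaks) - 1L)
  } else {
    integer(length(breaks) - 1L)
  }
  list(breaks = breaks, mid = (breaks[-1L] + breaks[-length(breaks)]) / 2,
       rate = count / (n_sweeps * w) - spont_rate, count = count)
}

#' Fit the AR time course with exponentials
#'
#' Least-squares fit of `r(t) = sum_i A_i exp(-t/tau_i)` to the
#' spontaneous-subtracted PSTH at bin centers. With two components the
#' reported time constant is amplitude-weighted,
#' `(A1 tau1 + A2 tau2)/(A1 + A2)`.
#'
#' @param psth Result of [build_psth()].
#' @param n_components 1 (default) or 2.
#' @return A list with `A` (Hz), `tau` (ms), per component, plus
#'   `weighted_tau` (ms) and `rss`.
#' @export
fit_ar_decay <- function(psth, n_components = 1) {
  stopifnot(n_components %in% c(1, 2))
  use <- is.finite(psth$rate)
  if (sum(psth$count[use] > 0) < 5L) {
    stop("need at least 5 non-empty PSTH bins to fit the AR time course")
  }
  t_ms <- psth$mid[use] * 1000
  y <- psth$rate[use]
  if (max(y) <= 0) stop("flat or non-positive PSTH: AR time course unresolved")
  a0 <- max(y)
  t0 <- t_ms - min(t_ms)
  fit <- tryCatch(
    if (n_components == 1L) {
      minpack.lm::nlsLM(y ~ A1 * exp(-t0 / tau1),
                        start = list(A1 = a0, tau1 = 40),
                        lower = c(0, 1e-2),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(y ~ A1 * exp(-t0 / tau1) + A2 * exp(-t0 / tau2),
                        start = list(A1 = 0.7 * a0, tau1 = 20,
                                     A2 = 0.3 * a0, tau2 = 150),
                        lower = c(0, 1e-2, 0, 1e-2),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    },
    error = function(e) stop("AR time-course fit failed to converge: ",
                             conditionMessage(e))
  )
  cf <- stats::coef(fit)
  if (n_components == 1L) {
    out <- list(A = unname(cf["A1"] * exp(min(t_ms) / cf["tau1"])),
                tau = unname(cf["tau1"]),
                weighted_tau = unname(cf["tau1"]))
  } else {
    tau <- cf[c("tau1", "tau2")]
    # reference amplitudes back to the stimulus (t = 0) before weighting
    a <- abs(cf[c("A1", "A2")]) * exp(min(t_ms) / tau)
    out <- list(A = unname(a), tau = unname(tau),
                weighted_tau = unname(sum(a * tau) / sum(a)))
  }
  out$rss <- sum(stats::resid(fit)^2)
  out
}

#' Percent reduction of an AR metric relative to a reference condition
#'
#' @param ref Numeric vector of per-cell metric values in the reference
#'   condition (e.g. WT).
#' @param test Numeric vector of per-cell metric values in the test
#'   condition.
#' @return `100 * (1 - mean(test)/mean(ref))`.
#' @export
percent_reduction <- function(ref, test) {
  m_ref <- mean(ref)
  if (!(m_ref > 0)) stop("reference metric must be positive")
  100 * (1 - mean(test) / m_ref)
}
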