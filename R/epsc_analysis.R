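#' Measure the pre-stimulus baseline current
#'
#' The baseline is the mean current over the 1 ms immediately preceding
#' the stimulation artifact; all EPSC amplitudes are measured relative to
#' it.
#'
#' @param sweep A `Sweep`.
#' @param window_ms Width of the pre-stimulus baseline window (ms).
#' @return Baseline current (pA).
#' @export
measure_baseline <- function(sweep, window_ms = 1) {
  n_win <- round(window_ms / 1000 / sweep$dt)
  i_stim <- round(sweep$stim_time / sweep$dt) + 1L
  if (i_stim - n_win < 1L || n_win < 1L) {
    stop("insufficient pre-stimulus samples for the baseline window")
  }
  mean(sweep$samples[(i_stim - n_win):(i_stim - 1L)])
}

#' Measure the synchronous EPSC peak
#'
#' Searches for the most negative (inward) current in a short window
#' after the stimulus, skipping an initial artifact-blanking interval,
#' and reports the amplitude as a positive magnitude relative to the
#' baseline. Amplitudes below the detectability floor are flagged, not
#' errored, so flat traces can flow through batch analysis.
#'
#' @param sweep A `Sweep`.
#' @param baseline Baseline current from [measure_baseline()] (pA).
#' @param search_ms Peak search window after the stimulus (ms).
#' @param blank_ms Stimulus-artifact blanking interval excluded from the
#'   search (ms).
#' @param floor Detectability floor (pA); amplitudes below it set
#'   `flagged = TRUE`.
#' @return A list with `amplitude` (pA, positive), `peak_time`
#'   (s, stimulus-relative), and `flagged`.
#' @export
measure_epsc <- function(sweep, baseline, search_ms = 10, blank_ms = 0.5,
                         floor = 20) {
  i_stim <- round(sweep$stim_time / sweep$dt) + 1L
  i_from <- i_stim + max(1L, round(blank_ms / 1000 / sweep$dt))
  i_to <- min(length(sweep$samples), i_stim + round(search_ms / 1000 / sweep$dt))
  if (i_from >= i_to) stop("peak search window does not fit in the sweep")
  seg <- sweep$samples[i_from:i_to]
  i_min <- which.min(seg)
  amplitude <- abs(seg[i_min] - baseline)
  list(amplitude = amplitude,
       peak_time = (i_from + i_min - 2L) * sweep$dt - sweep$stim_time,
       flagged = amplitude < floor)
}

#' Fit a bi-exponential to the EPSC decay
#'
#' Fits `I(t) = A1 exp(-(t - t0)/tau1) + A2 exp(-(t - t0)/tau2)` (as a
#' positive magnitude relative to baseline) from the first post-peak
#' sample where the current has decayed to 90% of the peak, out to the
#' end of the fit window. The weighted decay time constant is the
#' amplitude-weighted mean `(A1 tau1 + A2 tau2) / (A1 + A2)`.
#'
#' @param sweep A `Sweep`.
#' @param peak Result of [measure_epsc()].
#' @param baseline Baseline current (pA).
#' @param fit_window_ms Length of the fit window after the peak (ms).
#' @return A list of class `"EpscFit"` with `baseline`, `amplitude`,
#'   `peak_time`, `A1`, `tau1`, `A2`, `tau2` (pA / ms), `weighted_tau`
#'   (ms), `fit_start_time` (s) and `truncated` (logical, fit window
#'   clipped by sweep end).
#' @export
fit_epsc_decay <- function(sweep, peak, baseline, fit_window_ms = 200) {
  dt <- sweep$dt
  i_stim <- round(sweep$stim_time / dt) + 1L
  i_peak <- i_stim + round(peak$peak_time / dt)
  mag <- abs(sweep$samples - baseline)
  # first post-peak sample at or below 90% of the peak magnitude
  post <- which(mag[(i_peak + 1L):length(mag)] <= 0.9 * peak$amplitude)
  if (length(post) == 0L) {
    stop("decay never crosses 90% of the peak within the sweep")
  }
  i_start <- i_peak + post[1L]
  i_end <- i_peak + round(fit_window_ms / 1000 / dt)
  truncated <- i_end > length(mag)
  if (truncated) {
    warning("fit window truncated by sweep end")
    i_end <- length(mag)
  }
  idx <- i_start:i_end
  # decimate the fit grid to <= 1000 points: the decay is smooth at these
  # time scales, and the stride is well below tau1
  stride <- max(1L, length(idx) %/% 1000L)
  idx <- idx[seq(1L, length(idx), by = stride)]
  t_ms <- (idx - i_start) * dt * 1000
  y <- -(sweep$samples[idx] - baseline)  # positive magnitude for an EPSC
  if (max(y) < .Machine$double.eps^0.5 || stats::sd(y) == 0) {
    stop("degenerate decay segment: no EPSC to fit")
  }
  a0 <- max(y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A1 * exp(-t_ms / tau1) + A2 * exp(-t_ms / tau2),
      start = list(A1 = 0.7 * a0, tau1 = 3, A2 = 0.3 * a0, tau2 = 30),
      lower = c(0, 1e-3, 0, 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    # exactly single-exponential decays drive one component to zero
    # amplitude, where the bi-exponential Jacobian is singular; refit the
    # degenerate one-component model instead
    single <- tryCatch(
      minpack.lm::nlsLM(y ~ A1 * exp(-t_ms / tau1),
                        start = list(A1 = a0, tau1 = 5),
                        lower = c(0, 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e2) stop("EPSC decay fit failed to converge: ",
                                conditionMessage(fit))
    )
    cs <- stats::coef(single)
    cf <- c(A1 = unname(cs[["A1"]]), tau1 = unname(cs[["tau1"]]),
            A2 = 0, tau2 = unname(cs[["tau1"]]))
    rss <- sum(stats::resid(single)^2)
  } else {
    cf <- stats::coef(fit)
    rss <- sum(stats::resid(fit)^2)
  }
  if (!all(is.finite(cf)) || (cf[["A1"]] + cf[["A2"]]) <= 0) {
    stop(sprintf("degenerate EPSC decay fit (A1=%.3g, A2=%.3g, rss=%.3g)",
                 cf[["A1"]], cf[["A2"]], rss))
  }
  # reference component amplitudes back to the peak: the fit parameterizes
  # them at the 90% crossing, which would skew the amplitude weighting of
  # the slow component
  lag_ms <- ((i_start - i_peak) * dt) * 1000
  A1p <- cf[["A1"]] * exp(lag_ms / cf[["tau1"]])
  A2p <- cf[["A2"]] * exp(lag_ms / cf[["tau2"]])
  wt <- (A1p * cf[["tau1"]] + A2p * cf[["tau2"]]) / (A1p + A2p)
  structure(list(
    baseline = baseline, amplitude = peak$amplitude,
    peak_time = peak$peak_time,
    A1 = A1p, tau1 = cf[["tau1"]],
    A2 = A2p, tau2 = cf[["tau2"]],
    weighted_tau = wt,
    fit_start_time = (i_start - 1L) * dt - sweep$stim_time,
    truncated = truncated, rss = rss
  ), class = "EpscFit")
}

#' @export
print.EpscFit <- function(x, ...) {
  cat(sprintf(paste0("<EpscFit: amp %.1f pA at %.3f ms; A1=%.1f tau1=%.2f ms,",
                     " A2=%.1f tau2=%.2f ms, weighted tau %.2f ms>\n"),
              x$amplitude, x$peak_time * 1000, x$A1, x$tau1, x$A2, x$tau2,
              x$weighted_tau))
  invisible(x)
}

#' Subtract the fitted synchronous EPSC from a sweep
#'
#' Returns the residual trace on which delayed quantal events are
#' detected: from the start of the decay fit onward the fitted
#' bi-exponential (plus baseline) is subtracted; earlier samples are
#' simply baseline-subtracted. Where the sweep equals its fit the
#' residual is ~0.
#'
#' @param sweep A `Sweep`.
#' @param fit An `EpscFit` for that sweep.
#' @return A residual `Sweep` (same grid, same id).
#' @export
subtract_epsc_fit <- function(sweep, fit) {
  dt <- sweep$dt
  res <- sweep$samples - fit$baseline
  i_start <- round((fit$fit_start_time + sweep$stim_time) / dt) + 1L
  i_peak <- round((fit$peak_time + sweep$stim_time) / dt) + 1L
  idx <- i_start:length(res)
  t_ms <- (idx - i_peak) * dt * 1000  # amplitudes are peak-referenced
  model <- -(fit$A1 * exp(-t_ms / fit$tau1) + fit$A2 * exp(-t_ms / fit$tau2))
  res[idx] <- res[idx] - model
  out <- sweep
  out$samples <- res
  out
}

#' Average sweeps after aligning their EPSC peaks
#'
#' Sweeps are shifted by whole samples so their measured peak times
#' coincide (at the median peak index), then averaged pointwise; the
#' per-timepoint standard deviation quantifies dispersion around the
#' average decay.
#'
#' @param sweeps List of `Sweep` objects (>= 2).
#' @param peak_times Numeric vector of stimulus-relative peak times (s),
#'   one per sweep (from [measure_epsc()]).
#' @return A list with `time` (s, stimulus-relative grid), `mean` and
#'   `sd` (pA), over the overlap region common to all shifted sweeps.
#' @export
average_peak_aligned <- function(sweeps, peak_times) {
  if (length(sweeps) < 2L) stop("need at least 2 sweeps to average")
  if (length(peak_times) != length(sweeps)) {
    stop("one peak time per sweep required")
  }
  dt <- sweeps[[1L]]$dt
  peak_idx <- round(peak_times / dt)
  ref <- round(stats::median(peak_idx))
  shifts <- peak_idx - ref
  n <- min(vapply(sweeps, function(s) length(s$samples), integer(1L)))
  lo <- 1L + max(0L, -min(shifts))
  hi <- n - max(0L, max(shifts))
  mat <- vapply(seq_along(sweeps), function(i) {
    sweeps[[i]]$samples[(lo:hi) + shifts[i]]
  }, numeric(hi - lo + 1L))
  list(
    time = ((lo:hi) - 1L) * dt - sweeps[[1L]]$stim_time,
    mean = rowMeans(mat),
    sd = apply(mat, 1L, stats::sd)
  )
}
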