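#' Detection presets for the three recorded synapse types
#'
#' Constants of the filtered-derivative quantal-event detector. For
#' interneuron recordings (`"MLI"`, molecular-layer interneurons;
#' `"OLM"`, hippocampal O-LM interneurons) the derivative threshold is
#' `max(2 x RMS, 20 pA/ms)` with the RMS taken over the differentiated
#' trace 1-5 s after the stimulus; for Purkinje-cell climbing-fiber
#' recordings (`"PC"`) the thresholds are fixed at 35 pA/ms and 35 pA.
#' Events within an exclusion window after the synchronous EPSC peak
#' (5, 10 and 20 ms for MLI, OLM and PC respectively) cannot be resolved
#' on the decaying EPSC and are omitted.
#'
#' @param name `"MLI"`, `"OLM"` or `"PC"`, or a synapse-simulation preset
#'   name (`"parallel_fiber_MLI"`, `"CA1_OLM"`, `"climbing_fiber"`).
#' @return A list of class `"SynapsePreset"`: `lowpass_cutoff` (Hz),
#'   `rms_rule` (logical), `rms_multiplier`, `deriv_floor` (pA/ms),
#'   `amp_floor` (pA), `rms_window` (s, stimulus-relative),
#'   `exclusion_window` (ms after the EPSC peak), `refractory` (ms),
#'   `peak_search` (ms).
#' @export
detection_preset <- function(name = c("MLI", "OLM", "PC",
                                      "parallel_fiber_MLI", "CA1_OLM",
                                      "climbing_fiber")) {
  name <- match.arg(name)
  name <- switch(name, parallel_fiber_MLI = "MLI", CA1_OLM = "OLM",
                 climbing_fiber = "PC", name)
  base <- list(name = name, lowpass_cutoff = 800, rms_multiplier = 2,
               rms_window = c(1, 5), refractory = 1, peak_search = 1,
               merge_gap = 0.2, refractory_drop_both = FALSE)
  specific <- switch(name,
    MLI = list(rms_rule = TRUE, deriv_floor = 20, amp_floor = 20,
               exclusion_window = 5),
    OLM = list(rms_rule = TRUE, deriv_floor = 20, amp_floor = 20,
               exclusion_window = 10),
    PC  = list(rms_rule = FALSE, deriv_floor = 35, amp_floor = 35,
               exclusion_window = 20)
  )
  structure(c(base, specific), class = "SynapsePreset")
}

#' Zero-phase low-pass filter a trace
#'
#' Second-order Butterworth applied forward and backward
#' (zero net phase), used to condition residual traces before
#' differentiation. Analysis default is 0.8 kHz.
#'
#' @param sweep A `Sweep`.
#' @param cutoff Cutoff frequency (Hz); must be below Nyquist.
#' @return The filtered `Sweep` (same grid).
#' @export
lowpass <- function(sweep, cutoff = 800) {
  nyq <- 1 / (2 * sweep$dt)
  if (cutoff >= nyq) {
    stop(sprintf("cutoff (%g Hz) must be below Nyquist (%g Hz)", cutoff, nyq))
  }
  bf <- signal::butter(2, cutoff / nyq, type = "low")
  out <- sweep
  out$samples <- .filtfilt_fast(bf$b, bf$a, sweep$samples)
  out
}

#' First derivative of a trace in pA/ms
#'
#' Central differences in the interior, one-sided at the endpoints;
#' differentiating the low-passed residual improves the signal-to-noise
#' ratio of fast quantal rise phases over slow baseline drift.
#'
#' @param sweep A `Sweep` (>= 3 samples).
#' @return A `Sweep` whose samples are the derivative in pA/ms.
#' @export
differentiate <- function(sweep) {
  x <- sweep$samples
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples to differentiate")
  dt_ms <- sweep$dt * 1000
  d <- numeric(n)
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt_ms)
  d[1L] <- (x[2L] - x[1L]) / dt_ms
  d[n] <- (x[n] - x[n - 1L]) / dt_ms
  out <- sweep
  out$samples <- d
  out
}

#' Derivative detection threshold for a sweep
#'
#' For RMS-rule presets the threshold is
#' `max(rms_multiplier x RMS, deriv_floor)` with the RMS of the
#' differentiated trace measured over the preset's post-stimulus window
#' (1-5 s; clipped to the sweep end with a warning when the sweep is
#' shorter). Fixed presets (Purkinje) return `deriv_floor` regardless of
#' the noise.
#'
#' @param deriv Differentiated `Sweep` (pA/ms), stimulus-aligned.
#' @param preset A [detection_preset()].
#' @return Threshold magnitude (pA/ms).
#' @export
detection_threshold <- function(deriv, preset) {
  if (!isTRUE(preset$rms_rule)) return(preset$deriv_floor)
  dt <- deriv$dt
  n <- length(deriv$samples)
  i0 <- round((preset$rms_window[1L] + deriv$stim_time) / dt) + 1L
  i1 <- round((preset$rms_window[2L] + deriv$stim_time) / dt)
  if (i1 > n) {
    warning("RMS window clipped to sweep end")
    i1 <- n
  }
  if (i0 >= i1 || i0 < 1L) stop("empty RMS window: sweep too short")
  rms <- sqrt(mean(deriv$samples[i0:i1]^2))
  max(preset$rms_multiplier * rms, preset$deriv_floor)
}

#' Detect quantal events on a residual trace
#'
#' Implements the filtered-derivative threshold detector: the residual
#' (EPSC-subtracted) trace is low-pass filtered at the preset cutoff and
#' differentiated; every contiguous segment where the derivative drops
#' below minus the threshold (segments separated by less than
#' `merge_gap` ms are merged) nominates a candidate, localized at the
#' segment's derivative minimum. The event peak is the most negative
#' residual sample within `peak_search` ms after that minimum; the
#' amplitude is measured against the median of the 1 ms of residual
#' preceding the threshold crossing. Candidates below the amplitude
#' floor are dropped; of events closer than the refractory interval the
#' earlier is kept; events inside the exclusion window after the EPSC
#' peak are omitted.
#'
#' @param residual A residual `Sweep` from [subtract_epsc_fit()], or a
#'   baseline trace without a stimulus (then leave `epsc_peak_time`
#'   `NULL` to skip the exclusion window).
#' @param preset A [detection_preset()].
#' @param epsc_peak_time Stimulus-relative EPSC peak time (s), or `NULL`.
#' @param threshold Optional fixed derivative threshold (pA/ms)
#'   overriding [detection_threshold()].
#' @return A data frame of class `"DetectedEvents"` with columns `time`
#'   (s, stimulus-relative, at the event current peak), `amplitude`
#'   (pA, positive), `deriv_extreme` (pA/ms, magnitude), `sweep_id`;
#'   sorted by time. Empty when nothing is detected.
#' @export
detect_events <- function(residual, preset, epsc_peak_time = NULL,
                          threshold = NULL) {
  dt <- residual$dt
  filt <- lowpass(residual, preset$lowpass_cutoff)
  deriv <- differentiate(filt)
  thr <- threshold %||% detection_threshold(deriv, preset)
  d <- deriv$samples
  below <- d < -thr
  empty <- data.frame(time = numeric(0L), amplitude = numeric(0L),
                      deriv_extreme = numeric(0L),
                      sweep_id = character(0L), stringsAsFactors = FALSE)
  class(empty) <- c("DetectedEvents", "data.frame")
  if (!any(below)) return(empty)

  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge segments separated by a sub-resolution gap (noisy shoulders)
  gap_n <- max(1L, round(preset$merge_gap / 1000 / dt))
  if (nrow(seg) > 1L) {
    keep <- rep(TRUE, nrow(seg))
    for (i in 2:nrow(seg)) {
      j <- max(which(keep[1:(i - 1L)]))
      if (seg$start[i] - seg$end[j] <= gap_n) {
        seg$end[j] <- seg$end[i]
        keep[i] <- FALSE
      }
    }
    seg <- seg[keep, , drop = FALSE]
  }

  n <- length(d)
  search_n <- max(1L, round(preset$peak_search / 1000 / dt))
  base_n <- max(1L, round(1e-3 / dt))
  res <- residual$samples
  cand <- lapply(seq_len(nrow(seg)), function(i) {
    idx <- seg$start[i]:seg$end[i]
    i_min <- idx[which.min(d[idx])]
    win <- i_min:min(n, i_min + search_n)
    i_peak <- win[which.min(res[win])]
    pre_idx <- max(1L, seg$start[i] - base_n):max(1L, seg$start[i] - 1L)
    local_base <- stats::median(res[pre_idx])
    # signed inward deflection: positive for true (negative-going) events,
    # so outward transients are dropped by the amplitude floor
    c(i_peak = i_peak, amplitude = local_base - res[i_peak],
      deriv_extreme = abs(d[i_min]))
  })
  cand <- do.call(rbind, cand)
  # amplitude floor, and the peak itself must be a negative (inward)
  # excursion of the baseline-subtracted residual — outward transients
  # whose decay crosses the derivative threshold are not events
  cand <- cand[cand[, "amplitude"] >= preset$amp_floor &
                 res[cand[, "i_peak"]] < 0, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[order(cand[, "i_peak"]), , drop = FALSE]

  # refractory: drop events within `refractory` ms of an earlier kept event
  refr_n <- round(preset$refractory / 1000 / dt)
  keep <- logical(nrow(cand))
  last_kept <- NA_integer_
  for (i in seq_len(nrow(cand))) {
    if (is.na(last_kept) || cand[i, "i_peak"] - cand[last_kept, "i_peak"] >= refr_n) {
      keep[i] <- TRUE
      last_kept <- i
    } else if (isTRUE(preset$refractory_drop_both)) {
      # strict reading: a too-close pair invalidates both events
      keep[last_kept] <- FALSE
      last_kept <- NA_integer_
    }
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)

  times <- (cand[, "i_peak"] - 1L) * dt - residual$stim_time
  out <- data.frame(time = times, amplitude = cand[, "amplitude"],
                    deriv_extreme = cand[, "deriv_extreme"],
                    sweep_id = residual$sweep_id, stringsAsFactors = FALSE)
  if (!is.null(epsc_peak_time)) {
    excl_end <- epsc_peak_time + preset$exclusion_window / 1000
    out <- out[out$time < epsc_peak_time - 1e-9 | out$time > excl_end + 1e-9, ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("DetectedEvents", "data.frame")
  out
}
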