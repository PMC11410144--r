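#' Analyze one cell's recording into an AR profile
#'
#' Runs the full single-cell analysis: per sweep, measure the baseline
#' and synchronous EPSC, fit and subtract the bi-exponential EPSC decay,
#' and detect quantal events on the residual; then pool events across
#' sweeps into the cell's AR metrics — spontaneous rate, spontaneous-
#' corrected AR events per stimulus (raw and EPSC-normalized), and the
#' PSTH of the AR window.
#'
#' @param rec A `Recording`.
#' @param preset A [detection_preset()]; defaults to the preset matching
#'   `rec$synapse`.
#' @param ar_end End of the AR counting window (s post-stimulus). The
#'   window starts at the end of the exclusion window after the mean
#'   EPSC peak.
#' @param bin_ms PSTH bin width (ms).
#' @param fit_window_ms EPSC decay fit window (ms).
#' @return A list of class `"ARProfile"`: `cell_id`, `genotype`,
#'   `n_sweeps`, `events` (pooled `DetectedEvents`), `spont_rate` (Hz),
#'   `ar_window` (s), `events_per_stim`, `norm_events_per_stim`
#'   (per nA), `epsc_amplitude` (pA, cell mean), `epsc_peak_time` (s),
#'   `epsc_weighted_tau` (ms, cell mean), `psth`, `flagged` (negative
#'   corrected count beyond sampling noise).
#' @export
analyze_recording <- function(rec, preset = NULL, ar_end = 0.5, bin_ms = 10,
                              fit_window_ms = 200) {
  preset <- preset %||% detection_preset(rec$synapse)
  n_sweeps <- length(rec$sweeps)
  span <- post_stim_span(rec$sweeps[[1L]])
  ev_list <- vector("list", n_sweeps)
  amps <- peaks <- taus <- numeric(n_sweeps)
  for (i in seq_len(n_sweeps)) {
    sw <- rec$sweeps[[i]]
    res <- tryCatch({
      bl <- measure_baseline(sw)
      pk <- measure_epsc(sw, bl)
      fit <- fit_epsc_decay(sw, pk, bl, fit_window_ms = fit_window_ms)
      resid <- subtract_epsc_fit(sw, fit)
      ev <- suppressWarnings(
        detect_events(resid, preset, epsc_peak_time = pk$peak_time)
      )
      list(ev = ev, amp = pk$amplitude, peak = pk$peak_time,
           tau = fit$weighted_tau)
    }, error = function(e) {
      stop(sprintf("cell %s sweep %s: %s", rec$cell_id, sw$sweep_id,
                   conditionMessage(e)), call. = FALSE)
    })
    ev_list[[i]] <- res$ev
    amps[i] <- res$amp
    peaks[i] <- res$peak
    taus[i] <- res$tau
  }
  events <- do.call(rbind, ev_list)
  class(events) <- c("DetectedEvents", "data.frame")
  mean_peak <- mean(peaks)
  ar_window <- c(mean_peak + preset$exclusion_window / 1000, ar_end)
  spont <- spontaneous_rate(events, n_sweeps, post_end = span)
  eps <- events_per_stimulus(events, spont, ar_window, n_sweeps)
  amp_cell <- mean(amps)
  psth <- build_psth(events, n_sweeps, ar_window, bin_ms = bin_ms,
                     spont_rate = spont)
  se_floor <- 3 * sqrt(max(spont, 0.1) * diff(ar_window) / n_sweeps)
  structure(list(
    cell_id = rec$cell_id, genotype = rec$genotype, synapse = rec$synapse,
    n_sweeps = n_sweeps, events = events, spont_rate = spont,
    ar_window = ar_window, events_per_stim = eps,
    norm_events_per_stim = normalize_ar(eps, amp_cell),
    epsc_amplitude = amp_cell, epsc_peak_time = mean_peak,
    epsc_weighted_tau = mean(taus), psth = psth,
    flagged = eps < -se_floor
  ), class = "ARProfile")
}

#' @export
print.ARProfile <- function(x, ...) {
  cat(sprintf(paste0("<ARProfile %s (%s, %s): %d sweeps, spont %.2f Hz, ",
                     "%.3f AR events/stim (%.3f per nA), EPSC %.0f pA>\n"),
              x$cell_id, x$synapse, x$genotype, x$n_sweeps, x$spont_rate,
              x$events_per_stim, x$norm_events_per_stim, x$epsc_amplitude))
  invisible(x)
}

#' Analyze every cell of a cohort and pool the AR time course
#'
#' @param cohort Output of [generate_cohort()], or a list of
#'   `Recording` objects.
#' @param ... Passed to [analyze_recording()].
#' @return A list with `profiles` (per-cell `ARProfile`s), `cells`
#'   (per-cell metric data frame), `pooled_psth` and `pooled_fit`
#'   (single-exponential AR time-course fit over all cells' events).
#' @export
analyze_cohort <- function(cohort, ...) {
  recs <- lapply(cohort, function(el) {
    if (inherits(el, "Recording")) el else el$recording
  })
  profiles <- lapply(recs, analyze_recording, ...)
  cells <- data.frame(
    cell_id = vapply(profiles, `[[`, character(1L), "cell_id"),
    genotype = vapply(profiles, `[[`, character(1L), "genotype"),
    events_per_stim = vapply(profiles, `[[`, numeric(1L), "events_per_stim"),
    norm_events_per_stim = vapply(profiles, `[[`, numeric(1L),
                                  "norm_events_per_stim"),
    epsc_amplitude = vapply(profiles, `[[`, numeric(1L), "epsc_amplitude"),
    epsc_weighted_tau = vapply(profiles, `[[`, numeric(1L),
                               "epsc_weighted_tau"),
    spont_rate = vapply(profiles, `[[`, numeric(1L), "spont_rate"),
    stringsAsFactors = FALSE
  )
  pooled_events <- do.call(rbind, lapply(profiles, `[[`, "events"))
  n_total <- sum(cells$events_per_stim * 0 + vapply(profiles, `[[`,
                                                    numeric(1L), "n_sweeps"))
  ar_window <- profiles[[1L]]$ar_window
  spont_pool <- mean(cells$spont_rate)
  pooled_psth <- build_psth(pooled_events, n_total, ar_window,
                            spont_rate = spont_pool)
  pooled_fit <- tryCatch(fit_ar_decay(pooled_psth, n_components = 1),
                         error = function(e) NULL)
  list(profiles = profiles, cells = cells, pooled_psth = pooled_psth,
       pooled_fit = pooled_fit)
}

#' Percent reduction between two analyzed cohorts
#'
#' @param ref,test Results of [analyze_cohort()] (reference, e.g. WT,
#'   and test condition).
#' @param metric `"normalized"` (events per stimulus per nA of
#'   synchronous EPSC; appropriate where many fibers are stimulated) or
#'   `"raw"` (events per stimulus; appropriate for all-or-none
#'   single-fiber inputs such as climbing fibers).
#' @return A list with `metric`, `percent_reduction`, per-cell values
#'   `ref_values` / `test_values`, and their means.
#' @export
compare_cohorts <- function(ref, test, metric = c("normalized", "raw")) {
  metric <- match.arg(metric)
  col <- if (metric == "normalized") "norm_events_per_stim" else
    "events_per_stim"
  rv <- ref$cells[[col]]
  tv <- test$cells[[col]]
  list(metric = metric, percent_reduction = percent_reduction(rv, tv),
       ref_values = rv, test_values = tv,
       ref_mean = mean(rv), test_mean = mean(tv))
}

#' Default metric for a synapse preset
#'
#' Climbing fibers are all-or-none single inputs, so AR is compared on
#' raw events per stimulus; parallel-fiber and hippocampal presets pool
#' many fibers and use EPSC-normalized rates.
#'
#' @param synapse Synapse preset name.
#' @return `"raw"` or `"normalized"`.
#' @export
default_ar_metric <- function(synapse) {
  if (identical(synapse, "climbing_fiber")) "raw" else "normalized"
}

#' Run the end-to-end simulation + analysis pipeline
#'
#' Generates a synthetic cohort for every requested genotype (all from
#' the same master seed, so conditions share cell seeds and differ only
#' in release parameters), analyzes each cohort, compares every
#' knockout against the first genotype (the reference, normally WT),
#' and runs the group-level statistics on the per-cell AR metric.
#'
#' @param config A list with fields `synapse` (preset name), `genotypes`
#'   (character; first entry is the reference), `n_cells`, `n_sweeps`,
#'   `seed`, and optionally `ar_end` (s, default 0.5), `bin_ms`
#'   (default 10), `pre`/`post` (s), `dt` (s), `family_alpha`
#'   (default 0.05), `correction` (`"per_comparison"` or `"sidak"`).
#' @return A list of class `"ARPipelineResult"`: `config`, `cohorts`
#'   (per genotype, the [analyze_cohort()] result), `comparisons`
#'   (data frame of percent reductions vs the reference), `stats`
#'   (a `GroupComparison` when more than one genotype), `log`.
#' @export
run_ar_pipeline <- function(config) {
  required <- c("synapse", "genotypes", "n_cells", "n_sweeps", "seed")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop("config missing field(s): ", paste(missing, collapse = ", "))
  }
  ar_end <- config$ar_end %||% 0.5
  bin_ms <- config$bin_ms %||% 10
  pre <- config$pre %||% 0.5
  post <- config$post %||% 2.5
  dt <- config$dt %||% 5e-5
  metric <- config$metric %||% default_ar_metric(config$synapse)
  log <- character(0L)
  note <- function(fmt, ...) sprintf(fmt, ...)

  cohorts <- list()
  for (g in config$genotypes) {
    log <- c(log, note("simulate: %s %s, %d cells x %d sweeps, seed %d",
                       config$synapse, g, config$n_cells, config$n_sweeps,
                       config$seed))
    cohort <- generate_cohort(config$synapse, g, config$n_cells,
                              config$n_sweeps, seed = config$seed,
                              pre = pre, post = post, dt = dt)
    cohorts[[g]] <- analyze_cohort(cohort, ar_end = ar_end, bin_ms = bin_ms)
    log <- c(log, note("analyze: %s mean %s = %.4f", g, metric,
                       mean(cohorts[[g]]$cells[[
                         if (metric == "normalized") "norm_events_per_stim"
                         else "events_per_stim"]])))
  }

  ref_name <- config$genotypes[1L]
  comparisons <- NULL
  if (length(config$genotypes) > 1L) {
    rows <- lapply(config$genotypes[-1L], function(g) {
      cmp <- compare_cohorts(cohorts[[ref_name]], cohorts[[g]], metric)
      data.frame(reference = ref_name, test = g, metric = metric,
                 percent_reduction = cmp$percent_reduction,
                 ref_mean = cmp$ref_mean, test_mean = cmp$test_mean,
                 stringsAsFactors = FALSE)
    })
    comparisons <- do.call(rbind, rows)
    log <- c(log, vapply(seq_len(nrow(comparisons)), function(i) {
      note("compare: %s vs %s -> %.1f%% reduction",
           comparisons$test[i], ref_name, comparisons$percent_reduction[i])
    }, character(1L)))
  }

  stats_out <- NULL
  if (length(config$genotypes) > 1L) {
    col <- if (metric == "normalized") "norm_events_per_stim" else
      "events_per_stim"
    groups <- lapply(cohorts, function(co) co$cells[[col]])
    stats_out <- tryCatch(
      compare_groups(groups, family_alpha = config$family_alpha %||% 0.05,
                     method = config$correction %||% "per_comparison"),
      error = function(e) NULL
    )
  }

  structure(list(config = config, cohorts = cohorts,
                 comparisons = comparisons, stats = stats_out, log = log),
            class = "ARPipelineResult")
}

#' Deterministic text summary of a pipeline result
#'
#' Every number in the summary is reproducible from the configuration
#' and seed alone; no timestamps are included.
#'
#' @param result An `ARPipelineResult`.
#' @return Character vector of summary lines.
#' @export
pipeline_summary <- function(result) {
  lines <- c(sprintf("synapse: %s", result$config$synapse),
             sprintf("seed: %d", result$config$seed),
             sprintf("cohort: %d cells x %d sweeps",
                     result$config$n_cells, result$config$n_sweeps))
  for (g in names(result$cohorts)) {
    cells <- result$cohorts[[g]]$cells
    fit <- result$cohorts[[g]]$pooled_fit
    lines <- c(lines, sprintf(
      "%s: events/stim %.4f, per nA %.4f, spont %.3f Hz, AR tau %s ms",
      g, mean(cells$events_per_stim), mean(cells$norm_events_per_stim),
      mean(cells$spont_rate),
      if (is.null(fit)) "NA" else sprintf("%.1f", fit$weighted_tau)))
  }
  if (!is.null(result$comparisons)) {
    lines <- c(lines, apply(result$comparisons, 1L, function(r) {
      sprintf("reduction %s vs %s (%s): %.2f%%",
              r[["test"]], r[["reference"]], r[["metric"]],
              as.numeric(r[["percent_reduction"]]))
    }))
  }
  lines
}

#' @export
print.ARPipelineResult <- function(x, ...) {
  cat(pipeline_summary(x), sep = "\n")
  invisible(x)
}
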