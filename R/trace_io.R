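#' Construct a stimulus-aligned voltage-clamp sweep
#'
#' A sweep is one current trace recorded around a single presynaptic
#' stimulus. Currents follow the recording convention at -70 mV: inward
#' (excitatory) currents are negative. All analysis windows downstream are
#' expressed relative to the stimulus, so every sweep carries `stim_time`
#' to map stimulus-relative times onto sample indices.
#'
#' @param samples Numeric vector of membrane current (pA, inward negative).
#' @param dt Sampling interval in seconds (e.g. `5e-5` for 20 kHz).
#' @param stim_time Stimulus onset relative to sweep start (s). Must leave
#'   at least 0.5 s of pre-stimulus baseline.
#' @param sweep_id Opaque identifier (character or integer).
#' @return An object of class `"Sweep"`.
#' @export
sweep_trace <- function(samples, dt, stim_time, sweep_id = "sweep1") {
  if (!is.numeric(samples) || length(samples) < 3L) {
    stop("samples must be a numeric vector with at least 3 values")
  }
  if (!all(is.finite(samples))) stop("all samples must be finite")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("dt must be a single positive number (sampling interval in s)")
  }
  if (!is.numeric(stim_time) || length(stim_time) != 1L || stim_time < 0) {
    stop("stim_time must be a single non-negative number (s)")
  }
  if (stim_time > (length(samples) - 1L) * dt) {
    stop("stim_time lies beyond the end of the sweep")
  }
  structure(
    list(samples = as.numeric(samples), dt = dt, stim_time = stim_time,
         sweep_id = as.character(sweep_id)),
    class = "Sweep"
  )
}

#' @export
print.Sweep <- function(x, ...) {
  cat(sprintf("<Sweep %s: %d samples @ %.6g s, stim at %.4g s, %.3g s total>\n",
              x$sweep_id, length(x$samples), x$dt, x$stim_time,
              length(x$samples) * x$dt))
  invisible(x)
}

#' Duration of a sweep after the stimulus (s)
#' @param sweep A `Sweep`.
#' @return Post-stimulus duration in seconds.
#' @export
post_stim_span <- function(sweep) {
  length(sweep$samples) * sweep$dt - sweep$stim_time
}

#' Time axis of a sweep relative to the stimulus
#' @param sweep A `Sweep`.
#' @return Numeric vector of stimulus-relative times (s), one per sample.
#' @export
sweep_times <- function(sweep) {
  (seq_along(sweep$samples) - 1L) * sweep$dt - sweep$stim_time
}

#' Construct a recording (a cell's collection of sweeps)
#'
#' All sweeps of a recording must share sampling interval and stimulus
#' time; the recording carries the synapse preset name, genotype label and
#' the inter-stimulus interval used during acquisition.
#'
#' @param sweeps List of `Sweep` objects (at least one).
#' @param synapse Synapse preset name (e.g. `"parallel_fiber_MLI"`).
#' @param genotype Genotype label (`"WT"`, `"Syt3KO"`, `"Syt7KO"`, `"DKO"`
#'   or a custom label).
#' @param cell_id Cell identifier.
#' @param isi Inter-stimulus interval (s); 8 s in the experiments this
#'   package models.
#' @return An object of class `"Recording"`.
#' @export
recording <- function(sweeps, synapse, genotype, cell_id = "cell1", isi = 8) {
  if (!is.list(sweeps) || length(sweeps) == 0L) {
    stop("recording has no sweeps")
  }
  if (!all(vapply(sweeps, inherits, logical(1L), "Sweep"))) {
    stop("sweeps must all be Sweep objects")
  }
  dts <- vapply(sweeps, function(s) s$dt, numeric(1L))
  if (max(dts) - min(dts) > .Machine$double.eps * 4) {
    stop("inconsistent dt across sweeps")
  }
  stims <- vapply(sweeps, function(s) s$stim_time, numeric(1L))
  if (max(stims) - min(stims) > .Machine$double.eps * 4) {
    stop("inconsistent stim_time across sweeps")
  }
  if (!is.numeric(isi) || isi <= 0) stop("isi must be positive (s)")
  span <- post_stim_span(sweeps[[1L]])
  if (isi < span) {
    stop("isi shorter than the stimulus-aligned analysis span of the sweeps")
  }
  structure(
    list(sweeps = sweeps, synapse = as.character(synapse),
         genotype = as.character(genotype), cell_id = as.character(cell_id),
         isi = isi),
    class = "Recording"
  )
}

#' @export
print.Recording <- function(x, ...) {
  cat(sprintf("<Recording %s: %d sweeps, synapse %s, genotype %s, isi %g s>\n",
              x$cell_id, length(x$sweeps), x$synapse, x$genotype, x$isi))
  invisible(x)
}

# text dialect: `# key = value` header, then `# sweep <id>` blocks with one
# column of pA values. Written to 1e-6 pA absolute precision.
.write_recording_text <- function(rec, path) {
  s1 <- rec$sweeps[[1L]]
  con <- file(path, open = "wt")
  on.exit(close(con))
  header <- c(
    sprintf("# dt_s = %.17g", s1$dt),
    sprintf("# stim_time_s = %.17g", s1$stim_time),
    sprintf("# genotype = %s", rec$genotype),
    sprintf("# synapse = %s", rec$synapse),
    sprintf("# cell_id = %s", rec$cell_id),
    sprintf("# isi_s = %.17g", rec$isi)
  )
  writeLines(header, con)
  for (sw in rec$sweeps) {
    writeLines(sprintf("# sweep %s", sw$sweep_id), con)
    writeLines(sprintf("%.6f", sw$samples), con)
  }
  invisible(NULL)
}

.read_recording_text <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#\\s*\\w+\\s*=", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    kv <- sub("^#\\s*", "", ln)
    key <- trimws(sub("=.*$", "", kv))
    val <- trimws(sub("^[^=]*=", "", kv))
    meta[[key]] <- val
  }
  required <- c(dt_s = "sampling interval", stim_time_s = "stimulus time",
                genotype = "genotype", synapse = "synapse preset",
                cell_id = "cell id", isi_s = "inter-stimulus interval")
  for (key in names(required)) {
    if (is.null(meta[[key]])) {
      stop(sprintf("missing %s (header field '%s') in %s",
                   required[[key]], key, path))
    }
  }
  dt <- as.numeric(meta$dt_s)
  stim_time <- as.numeric(meta$stim_time_s)
  sweep_starts <- grep("^#\\s*sweep\\b", lines)
  if (length(sweep_starts) == 0L) stop("no sweep blocks found in ", path)
  ids <- trimws(sub("^#\\s*sweep\\s*", "", lines[sweep_starts]))
  bounds <- c(sweep_starts, length(lines) + 1L)
  sweeps <- vector("list", length(sweep_starts))
  for (i in seq_along(sweep_starts)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    block <- block[!grepl("^#", block) & nzchar(trimws(block))]
    sweeps[[i]] <- sweep_trace(as.numeric(block), dt, stim_time, ids[i])
  }
  recording(sweeps, synapse = meta$synapse, genotype = meta$genotype,
            cell_id = meta$cell_id, isi = as.numeric(meta$isi_s))
}

#' Write a recording to a sweep bundle
#'
#' Two dialects are supported: `"text"`, a human-readable columnar bundle
#' (header lines `# key = value`, then one column of pA values per sweep
#' under `# sweep <id>` markers; numeric round-trip exact to 1e-6 pA), and
#' `"binary"`, the package's binary container (exact numeric round-trip),
#' intended for cohort-scale storage.
#'
#' @param rec A `Recording`.
#' @param path Output file path.
#' @param format `"text"` or `"binary"`.
#' @return Invisibly, `path`.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, path, format = c("text", "binary")) {
  format <- match.arg(format)
  if (!inherits(rec, "Recording")) {
    if (is.list(rec) && length(rec$sweeps %||% list()) == 0L) {
      stop("recording has no sweeps")
    }
    stop("rec must be a Recording")
  }
  if (format == "text") {
    .write_recording_text(rec, path)
  } else {
    saveRDS(rec, path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a recording from a sweep bundle
#'
#' @param path File written by [write_recording()].
#' @param format `"text"` or `"binary"`; `"auto"` (default) sniffs the
#'   dialect.
#' @return A `Recording`. Units are pA and seconds as stored; loading never
#'   changes sample order or sign convention.
#' @export
read_recording <- function(path, format = c("auto", "text", "binary")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readBin(path, "raw", n = 2L)
    # text dialect always starts with '# '
    format <- if (identical(first, charToRaw("# "))) "text" else "binary"
  }
  if (format == "text") {
    .read_recording_text(path)
  } else {
    rec <- readRDS(path)
    if (!inherits(rec, "Recording")) stop("not a recording bundle: ", path)
    rec
  }
}
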