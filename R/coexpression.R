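#' Bin nuclei by sequencing depth
#'
#' Nuclei are sorted by total detected transcripts and partitioned into
#' contiguous half-open depth intervals `[k*w, (k+1)*w)`; empty bins are
#' omitted. Binning by depth separates true absence of a transcript from
#' dropout at shallow sequencing.
#'
#' @param nuclei Data frame with columns `total_counts`, `count_a`,
#'   `count_b` (one row per nucleus).
#' @param bin_width Bin width in transcripts (e.g. 20000 for granule
#'   cells, 10000 for CA1 pyramidal and Purkinje neurons).
#' @return A list of bins, each a list with `lower`, `upper` (depth
#'   range), `mid`, and `nuclei` (the rows falling in the bin).
#' @export
bin_by_depth <- function(nuclei, bin_width) {
  if (!(bin_width > 0)) stop("bin_width must be positive")
  k <- nuclei$total_counts %/% bin_width
  levels_k <- sort(unique(k))
  lapply(levels_k, function(kk) {
    list(lower = kk * bin_width, upper = (kk + 1) * bin_width,
         mid = (kk + 0.5) * bin_width,
         nuclei = nuclei[k == kk, , drop = FALSE])
  })
}

#' Per-bin detection fractions for two genes
#'
#' @param bin One bin from [bin_by_depth()].
#' @return A list of class `"BinSummary"`: `lower`, `upper`, `mid`,
#'   `n_nuclei`, and the fractions of nuclei with at least one count of
#'   gene A, gene B, both, and either (`frac_a`, `frac_b`, `frac_both`,
#'   `frac_either`); `frac_single = frac_either - frac_both`.
#' @export
detection_fractions <- function(bin) {
  nuc <- bin$nuclei
  if (is.null(nuc) || nrow(nuc) < 1L) stop("empty bin")
  pos_a <- nuc$count_a >= 1L
  pos_b <- nuc$count_b >= 1L
  frac_a <- mean(pos_a)
  frac_b <- mean(pos_b)
  frac_both <- mean(pos_a & pos_b)
  structure(list(lower = bin$lower, upper = bin$upper, mid = bin$mid,
                 n_nuclei = nrow(nuc),
                 frac_a = frac_a, frac_b = frac_b, frac_both = frac_both,
                 frac_either = frac_a + frac_b - frac_both,
                 frac_single = frac_a + frac_b - 2 * frac_both),
            class = "BinSummary")
}

#' Expected detection fractions under universal co-expression
#'
#' Under the transcript-dropout null every nucleus expresses both genes
#' and each captured transcript is gene g with probability `f_g`
#' independently, so a nucleus of depth `T` detects gene g with
#' probability `p_g(T) = 1 - (1 - f_g)^T`. With independent capture of
#' the two genes, the expected double-positive fraction is `p_a * p_b`
#' and the single-positive fraction `p_a (1 - p_b) + p_b (1 - p_a)` —
#' i.e. single-positive nuclei arise from dropout alone.
#'
#' @param f_a,f_b Relative transcript abundances, between 0 and 1.
#' @param depth Total transcripts `T` (may be a vector).
#' @return A data frame with `depth`, `frac_a`, `frac_b`, `frac_both`,
#'   `frac_single`.
#' @export
dropout_expected_fractions <- function(f_a, f_b, depth) {
  if (any(c(f_a, f_b) < 0) || any(c(f_a, f_b) > 1)) {
    stop("abundances must lie in [0, 1]")
  }
  if (any(depth < 0)) stop("depth must be non-negative")
  p_a <- 1 - (1 - f_a)^depth
  p_b <- 1 - (1 - f_b)^depth
  data.frame(depth = depth, frac_a = p_a, frac_b = p_b,
             frac_both = p_a * p_b,
             frac_single = p_a * (1 - p_b) + p_b * (1 - p_a))
}

# ML estimate of f from per-nucleus detection indicators at the actual
# nucleus depths: positive_i ~ Bernoulli(1 - (1 - f)^T_i). Evaluating the
# likelihood at true depths (rather than a bin-center approximation)
# matters: p(T) is strongly nonlinear across a wide bin.
.fit_abundance <- function(positive, depth) {
  nll <- function(log10f) {
    f <- 10^log10f
    p <- pmin(pmax(1 - (1 - f)^depth, 1e-12), 1 - 1e-12)
    -sum(ifelse(positive, log(p), log1p(-p)))
  }
  opt <- stats::optimize(nll, interval = c(-12, -0.5))
  10^opt$minimum
}

#' Test whether single-positive nuclei are explained by dropout
#'
#' Fits the universal co-expression dropout null to binned detection
#' fractions: the two abundances are estimated by maximum likelihood
#' from per-nucleus marginal detection at the actual nucleus depths,
#' then the observed single-positive counts per bin are compared with
#' the null expectation (also evaluated at per-nucleus depths, since
#' detection probability is strongly nonlinear across a bin) via a
#' chi-square statistic summed over bins (df = number of bins - 2
#' estimated abundances). A small p-value means single-positive nuclei
#' are more (or fewer) than transcript dropout can explain, i.e.
#' genuine single-expressers exist.
#'
#' @param bins List of bins from [bin_by_depth()] (>= 2 usable bins).
#' @param min_nuclei Bins with fewer nuclei are excluded (with a
#'   warning) to keep the normal approximation honest.
#' @return A list with `f_a`, `f_b` (ML abundance estimates), `table`
#'   (per-bin observed vs expected fractions), `chisq`, `df`, `p_value`.
#' @export
fit_dropout_null <- function(bins, min_nuclei = 20) {
  summaries <- lapply(bins, detection_fractions)
  n <- vapply(summaries, `[[`, numeric(1L), "n_nuclei")
  degenerate <- vapply(summaries, function(s) {
    s$frac_a + s$frac_b == 0
  }, logical(1L)) | n < min_nuclei
  if (any(degenerate)) {
    warning(sum(degenerate), " degenerate or underpopulated bin(s) excluded")
    summaries <- summaries[!degenerate]
    n <- n[!degenerate]
  }
  if (length(summaries) < 2L) {
    stop("need at least 2 usable depth bins to fit the dropout null")
  }
  keep_bins <- bins[!degenerate]
  nuc_all <- do.call(rbind, lapply(keep_bins, `[[`, "nuclei"))
  f_a <- .fit_abundance(nuc_all$count_a >= 1L, nuc_all$total_counts)
  f_b <- .fit_abundance(nuc_all$count_b >= 1L, nuc_all$total_counts)

  per_bin <- lapply(keep_bins, function(b) {
    T_i <- b$nuclei$total_counts
    e <- dropout_expected_fractions(f_a, f_b, T_i)
    p_i <- pmin(pmax(e$frac_single, 1e-12), 1 - 1e-12)
    obs <- sum((b$nuclei$count_a >= 1L) != (b$nuclei$count_b >= 1L))
    c(exp_count = sum(p_i), var_count = sum(p_i * (1 - p_i)), obs = obs,
      exp_both = mean(e$frac_both))
  })
  pb <- do.call(rbind, per_bin)
  chisq <- sum((pb[, "obs"] - pb[, "exp_count"])^2 /
                 pmax(pb[, "var_count"], 1e-12))
  df <- max(1L, nrow(pb) - 2L)
  tab <- data.frame(
    depth = vapply(summaries, `[[`, numeric(1L), "mid"),
    n_nuclei = n,
    obs_frac_a = vapply(summaries, `[[`, numeric(1L), "frac_a"),
    obs_frac_b = vapply(summaries, `[[`, numeric(1L), "frac_b"),
    obs_frac_single = pb[, "obs"] / n,
    exp_frac_single = pb[, "exp_count"] / n,
    exp_frac_both = pb[, "exp_both"]
  )
  list(f_a = f_a, f_b = f_b, table = tab, chisq = chisq, df = df,
       p_value = stats::pchisq(chisq, df, lower.tail = FALSE))
}
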