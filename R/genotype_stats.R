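#' Multiple-comparison corrected critical alpha
#'
#' The default `"per_comparison"` method divides the family alpha by the
#' number of comparisons (alpha/m, the Bonferroni critical level, which
#' reproduces the printed critical alphas 0.0167 for m = 3 and 0.025 for
#' m = 2 at family alpha 0.05); `"sidak"` applies the exact
#' Sidak formula `1 - (1 - alpha)^(1/m)`. The two agree to three
#' decimals at small m; both are provided because published critical
#' levels are sometimes labeled with one and computed with the other.
#'
#' @param alpha Family-wise significance level, in (0, 1).
#' @param m Number of pairwise comparisons (>= 1).
#' @param method `"per_comparison"` (default) or `"sidak"`.
#' @return The critical per-comparison alpha.
#' @export
corrected_alpha <- function(alpha, m, method = c("per_comparison", "sidak")) {
  method <- match.arg(method)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (m < 1 || m != round(m)) stop("m must be a positive integer")
  switch(method,
         per_comparison = alpha / m,
         sidak = 1 - (1 - alpha)^(1 / m))
}

#' Compare per-cell metrics across genotype groups
#'
#' The statistical procedure used throughout for per-cell metrics:
#' normality is assessed per group with Shapiro-Wilk tests; two groups
#' are compared with a two-tailed pooled-variance (Student's) t-test;
#' more than two groups with a one-way ANOVA followed by all pairwise
#' two-tailed Student's t-tests judged against a multiple-comparison
#' corrected critical alpha. Kolmogorov-Smirnov tests of the full
#' distributions are available on request.
#'
#' @param groups Named list of numeric vectors (one per group, each
#'   n >= 3).
#' @param family_alpha Family-wise significance level.
#' @param method Correction method passed to [corrected_alpha()].
#' @param ks Also run pairwise Kolmogorov-Smirnov tests.
#' @return A list of class `"GroupComparison"`: `groups`, `normality_p`
#'   (per group), `omnibus` (`statistic`, `p`, `method`), `pairwise`
#'   (data frame: `group1`, `group2`, `p`, `significant`, optionally
#'   `ks_p`), `critical_alpha`, `correction_method`.
#' @export
compare_groups <- function(groups, family_alpha = 0.05,
                           method = c("per_comparison", "sidak"),
                           ks = FALSE) {
  method <- match.arg(method)
  if (!is.list(groups) || length(groups) < 2L) stop("need at least 2 groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  ns <- lengths(groups)
  if (any(ns < 3L)) {
    stop("every group needs n >= 3 (got ",
         paste(ns, collapse = ", "), ")")
  }
  normality_p <- vapply(groups, function(x) {
    if (stats::sd(x) == 0) NA_real_ else stats::shapiro.test(x)$p.value
  }, numeric(1L))

  k <- length(groups)
  if (k == 2L) {
    tt <- stats::t.test(groups[[1L]], groups[[2L]], var.equal = TRUE)
    omnibus <- list(statistic = unname(tt$statistic), p = tt$p.value,
                    method = "Student t-test")
  } else {
    df <- data.frame(
      value = unlist(groups, use.names = FALSE),
      group = factor(rep(names(groups), ns))
    )
    av <- stats::aov(value ~ group, data = df)
    s <- summary(av)[[1L]]
    omnibus <- list(statistic = s[["F value"]][1L], p = s[["Pr(>F)"]][1L],
                    method = "one-way ANOVA")
  }

  pairs <- utils::combn(names(groups), 2L)
  m <- ncol(pairs)
  crit <- corrected_alpha(family_alpha, m, method)
  pw <- data.frame(
    group1 = pairs[1L, ], group2 = pairs[2L, ],
    p = vapply(seq_len(m), function(i) {
      stats::t.test(groups[[pairs[1L, i]]], groups[[pairs[2L, i]]],
                    var.equal = TRUE)$p.value
    }, numeric(1L)),
    stringsAsFactors = FALSE
  )
  pw$significant <- pw$p < crit
  if (isTRUE(ks)) {
    pw$ks_p <- vapply(seq_len(m), function(i) {
      suppressWarnings(stats::ks.test(groups[[pairs[1L, i]]],
                                      groups[[pairs[2L, i]]])$p.value)
    }, numeric(1L))
  }
  structure(list(groups = groups, normality_p = normality_p,
                 omnibus = omnibus, pairwise = pw, critical_alpha = crit,
                 correction_method = method),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("<GroupComparison: %d groups; %s p = %.3g; critical alpha %.4f (%s)>\n",
              length(x$groups), x$omnibus$method, x$omnibus$p,
              x$critical_alpha, x$correction_method))
  print(x$pairwise)
  invisible(x)
}

#' Relative expression by the 2^-dCt method
#'
#' Converts qPCR threshold cycles into expression relative to a
#' reference gene: `2^-(ct_target - ct_reference)`.
#'
#' @param ct_target Threshold cycle(s) of the gene of interest.
#' @param ct_reference Threshold cycle(s) of the housekeeping reference
#'   (e.g. GAPDH).
#' @return Relative expression, elementwise.
#' @export
rel_expression_2dct <- function(ct_target, ct_reference) {
  if (!all(is.finite(ct_target)) || !all(is.finite(ct_reference))) {
    stop("Ct values must be finite")
  }
  2^(-(ct_target - ct_reference))
}
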