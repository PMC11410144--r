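# Zero-phase IIR filtering (forward-backward application of b/a), with
# reflected end-padding to suppress edge transients. Equivalent to the
# usual filtfilt construction; implemented over stats::filter for speed
# on long sweeps.
.filter_ba <- function(b, a, x) {
  v <- stats::filter(x, b, method = "convolution", sides = 1L)
  v[seq_len(length(b) - 1L)] <- v[length(b)]
  as.numeric(stats::filter(v, -a[-1L], method = "recursive"))
}

.filtfilt_fast <- function(b, a, x) {
  n <- length(x)
  nf <- min(n - 1L, 200L)
  xx <- c(2 * x[1L] - x[(nf + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - nf)])
  y <- .filter_ba(b, a, xx)
  y <- rev(.filter_ba(b, a, rev(y)))
  y[(nf + 1L):(nf + n)]
}
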