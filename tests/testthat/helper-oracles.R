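# Independent brute-force oracles used to check the package implementations.
# These deliberately use different computational routes than the package code.

# two-way crossed ANOVA mean squares via explicit cell-wise residuals
# (the package computes SSE by subtraction from the total SS)
oracle_two_way <- function(tab) {
  tab <- as.matrix(tab)
  n <- nrow(tab); k <- ncol(tab)
  grand <- mean(tab)
  rm_ <- rowMeans(tab); cm_ <- colMeans(tab)
  ssr <- 0; ssc <- 0; sse <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      sse <- sse + (tab[i, j] - rm_[i] - cm_[j] + grand)^2
    }
  }
  for (i in seq_len(n)) ssr <- ssr + k * (rm_[i] - grand)^2
  for (j in seq_len(k)) ssc <- ssc + n * (cm_[j] - grand)^2
  list(MSR = ssr / (n - 1), MSC = ssc / (k - 1),
       MSE = sse / ((n - 1) * (k - 1)), n = n, k = k)
}

# brute-force lag search: plain loop, cor() on the overlap
oracle_lag <- function(ref, query, max_lag) {
  rs <- vapply(0:max_lag, function(L) {
    n <- min(length(ref), length(query) - L)
    stats::cor(ref[seq_len(n)], query[L + seq_len(n)])
  }, numeric(1))
  which.max(rs) - 1L
}

# analytic two-pass Butterworth magnitude response at frequency f (Hz)
oracle_butter2_filtfilt_gain <- function(f, cutoff) {
  1 / (1 + (f / cutoff)^4)   # |H|^2 of a 2nd-order lowpass, squared phases cancel
}
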