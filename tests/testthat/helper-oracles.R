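# Independent brute-force oracles kept deliberately naive: they enumerate
# definitions directly and share no code with the implementation paths
# they check.

# permutation entropy by explicit pattern enumeration
naive_pe <- function(x, m, lam) {
  n_vec <- length(x) - (m - 1) * lam
  pats <- vapply(seq_len(n_vec), function(i) {
    v <- x[seq(i, by = lam, length.out = m)]
    paste(order(v), collapse = ",")
  }, "")
  p <- as.numeric(table(pats)) / n_vec
  -sum(p * log(p)) / log(factorial(m))
}

# two-step firing power on exactly one long window of `shorts` short
# windows with `m` labels each: does it alarm?
naive_long_window_alarm <- function(tg, m, p, k, shorts = 3) {
  counts <- vapply(seq_len(shorts), function(t)
    sum(tg[((t - 1) * m + 1):(t * m)]), 1)
  sum(counts >= p) >= k
}

# fabricate a FeatureSeries without running entropy extraction
fake_feature_series <- function(values, starts, window_len = 5, fs = 256) {
  values <- if (is.matrix(values)) values else matrix(values, nrow = 1)
  structure(list(values = values, window_starts = starts,
                 channel_ids = rownames(values), fs = fs,
                 config = entropy_config(window_len = window_len)),
            class = "FeatureSeries")
}

# two-cluster toy dataset for classifier tests
blob_dataset <- function(n_per_class = 30, sep = 6, seed = 42) {
  withr::with_seed(seed, {
    f <- rbind(matrix(rnorm(n_per_class * 2), ncol = 2),
               matrix(rnorm(n_per_class * 2, mean = sep), ncol = 2))
  })
  labeled_dataset(f, rep(c(0L, 1L), each = n_per_class),
                  seq_len(2 * n_per_class),
                  data.frame(recording_id = "blob",
                             seizure_id = NA_real_))
}
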