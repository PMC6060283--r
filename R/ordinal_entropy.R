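# Ordinal-pattern distributions and permutation-entropy measures.
#
# A scalar series x(1..N) is embedded as vectors
#   X(i) = (x(i), x(i+lam), ..., x(i+(m-1)lam)),  i = 1..N-(m-1)lam,
# each mapped to the permutation that sorts it ascending (ties broken by
# original position). Permutation entropy is the Shannon entropy of the
# pattern distribution normalised by ln(m!), so 0 = fully regular and
# 1 = all m! patterns equally likely.

#' Entropy extraction configuration
#'
#' @param m Embedding dimension (pattern length), 2..7. Default 4.
#' @param lam Embedding delay in samples (>= 1). Default 1.
#' @param measure One of `"PE"` (Shannon), `"TPE"` (Tsallis), `"RPE"`
#'   (Renyi), `"MPE"` (min-entropy).
#' @param q Entropic order for TPE/RPE (`q != 1`). Default 2.
#' @param window_len Sliding-window length in seconds. Default 5.
#' @param overlap Fraction of window overlap in `[0, 1)`. Default 0
#'   (non-overlapping windows).
#' @return An object of class `EntropyConfig`.
#' @export
entropy_config <- function(m = 4, lam = 1, measure = c("PE", "TPE", "RPE", "MPE"),
                           q = 2, window_len = 5, overlap = 0) {
  measure <- match.arg(measure)
  .check_scalar_num(m, "m", lower = 2, upper = 7)
  .check_scalar_num(lam, "lam", lower = 1)
  .check_scalar_num(window_len, "window_len", lower = .Machine$double.eps)
  .check_scalar_num(overlap, "overlap", lower = 0)
  if (overlap >= 1) .stopf("'overlap' must be < 1")
  if (m != round(m) || lam != round(lam))
    .stopf("'m' and 'lam' must be integers")
  if (measure %in% c("TPE", "RPE") && isTRUE(all.equal(q, 1)))
    .stopf("q = 1 is not admissible for %s (use PE for the q -> 1 limit)",
           measure)
  structure(list(m = as.integer(m), lam = as.integer(lam), measure = measure,
                 q = q, window_len = window_len, overlap = overlap),
            class = "EntropyConfig")
}

#' Ordinal pattern of a single embedding vector
#'
#' Returns the index sequence `(j1, ..., jm)` with
#' `v[j1] <= v[j2] <= ... <= v[jm]`; equal elements keep ascending index
#' order (stable sort), so e.g. `c(5, 5, 5)` maps to `1 2 3`.
#'
#' @param v Numeric vector of length `m`, all finite.
#' @return Integer permutation of `1..length(v)`.
#' @export
ordinal_pattern <- function(v) {
  if (!is.numeric(v) || length(v) < 2L)
    .stopf("'v' must be a numeric vector of length >= 2")
  if (any(!is.finite(v))) .stopf("'v' contains non-finite values")
  order(v)   # order() is stable: ties resolved by original index
}

# Stable ranks of every embedding vector, fully vectorised. Row i holds the
# ranks of (x[i], x[i+lam], ..., x[i+(m-1)lam]); the rank vector determines
# the ordinal pattern (its inverse permutation).
.embedding_ranks <- function(x, m, lam) {
  n_vec <- length(x) - (m - 1L) * lam
  if (n_vec < 1L)
    .stopf("series too short: need at least (m-1)*lam + 1 = %d samples",
           (m - 1L) * lam + 1L)
  idx <- seq_len(n_vec)
  E <- matrix(0, n_vec, m)
  for (j in seq_len(m)) E[, j] <- x[idx + (j - 1L) * lam]
  R <- matrix(1L, n_vec, m)
  for (a in seq_len(m)) for (b in seq_len(m)) {
    if (a == b) next
    if (a < b) R[, b] <- R[, b] + (E[, a] <= E[, b])
    else       R[, b] <- R[, b] + (E[, a] <  E[, b])
  }
  R
}

# Integer code in 1..m^m, unique per rank vector (digits base m).
.pattern_codes <- function(x, m, lam) {
  R <- .embedding_ranks(x, m, lam)
  drop((R - 1L) %*% m^(seq_len(m) - 1L)) + 1L
}

.decode_pattern <- function(code, m) {
  r <- ((code - 1L) %/% m^(seq_len(m) - 1L)) %% m + 1L
  order(r)   # inverse of the rank vector = ascending index sequence
}

#' Ordinal-pattern distribution of a series
#'
#' Counts the ordinal pattern of every embedding vector of the series.
#' The number of vectors is `N - (m-1)*lam`.
#'
#' @param series Numeric vector (finite values).
#' @param cfg An [entropy_config()]; `m` and `lam` are used.
#' @return Object of class `PatternDistribution`: a list with `counts`
#'   (named integer vector; names are patterns as comma-separated 1-based
#'   index sequences such as `"3,1,2"`), `n_vectors`, and `m`.
#' @export
pattern_distribution <- function(series, cfg = entropy_config()) {
  if (any(!is.finite(series))) .stopf("'series' contains non-finite values")
  codes <- .pattern_codes(series, cfg$m, cfg$lam)
  tab <- table(codes)
  u <- as.integer(names(tab))
  pat_names <- vapply(u, function(cd)
    paste(.decode_pattern(cd, cfg$m), collapse = ","), "")
  counts <- as.integer(tab)
  names(counts) <- pat_names
  structure(list(counts = counts, n_vectors = length(codes), m = cfg$m),
            class = "PatternDistribution")
}

#' @export
print.PatternDistribution <- function(x, ...) {
  cat(sprintf("PatternDistribution: m = %d, %d vectors, %d/%d patterns seen\n",
              x$m, x$n_vectors, length(x$counts), factorial(x$m)))
  print(x$counts)
  invisible(x)
}

# Entropy measures from a raw count vector (zeros allowed / ignored).
.entropy_from_counts <- function(counts, m, measure = "PE", q = 2) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 1) .stopf("empty pattern distribution")
  p <- counts / n
  lmax <- log(factorial(m))
  h <- switch(measure,
    PE  = -sum(p * log(p)) / lmax,
    MPE = -log(max(p)) / lmax,
    RPE = log(sum(p^q)) / (1 - q) / lmax,
    TPE = ((1 - sum(p^q)) / (q - 1)) /
          ((1 - factorial(m)^(1 - q)) / (q - 1)),
    .stopf("unknown measure '%s'", measure))
  min(max(h, 0), 1)
}

#' Normalised permutation entropy of a pattern distribution
#'
#' `H = -sum(P_g log P_g) / log(m!)` with `P_g = count_g / n_vectors`;
#' natural logarithm. Lies in `[0, 1]`: 0 for a single pattern (monotone
#' series), 1 for the uniform distribution over all `m!` patterns.
#'
#' @param dist A [pattern_distribution()].
#' @param m Embedding dimension; defaults to `dist$m`.
#' @return Normalised entropy in `[0, 1]`.
#' @export
permutation_entropy <- function(dist, m = dist$m) {
  .entropy_from_counts(dist$counts, m, "PE")
}

#' Generalised permutation-entropy variants
#'
#' Renyi (`RPE`): `log(sum P_g^q) / (1-q)`, normalised by `log(m!)`.
#' Tsallis (`TPE`): `(1 - sum P_g^q) / (q-1)`, normalised by its maximum
#' `(1 - (m!)^(1-q)) / (q-1)` so the uniform distribution maps to 1.
#' Min-entropy (`MPE`): `-log(max P_g) / log(m!)`.
#'
#' @param dist A [pattern_distribution()].
#' @param m Embedding dimension; defaults to `dist$m`.
#' @param measure `"TPE"`, `"RPE"` or `"MPE"`.
#' @param q Entropic order for TPE/RPE (`q != 1`); ignored for MPE.
#' @return Normalised entropy in `[0, 1]`.
#' @export
entropy_variant <- function(dist, m = dist$m,
                            measure = c("TPE", "RPE", "MPE"), q = 2) {
  measure <- match.arg(measure)
  if (measure %in% c("TPE", "RPE") && isTRUE(all.equal(q, 1)))
    .stopf("q = 1 is not admissible for %s", measure)
  .entropy_from_counts(dist$counts, m, measure, q)
}

#' Number of complete sliding windows in a series
#'
#' `floor(L / (window_len * fs))`: trailing samples that do not fill a
#' window are discarded.
#'
#' @param L Series length in samples.
#' @param fs Sampling rate, Hz.
#' @param window_len Window length, seconds.
#' @return Integer window count.
#' @export
n_windows <- function(L, fs, window_len = 5) {
  .check_scalar_num(L, "L", lower = 0)
  as.integer(floor(L / (window_len * fs)))
}

#' Per-channel sliding-window entropy features
#'
#' Computes the configured entropy measure independently for each channel on
#' each complete window of `window_len` seconds (default non-overlapping;
#' the trailing partial window is discarded). This is the feature matrix
#' `H[a, b]` (channel a, window b) consumed by the classifier.
#'
#' @param rec A [recording()].
#' @param cfg An [entropy_config()].
#' @return Object of class `FeatureSeries`: list with `values`
#'   (`n_channels x n_windows` matrix), `window_starts` (seconds),
#'   `channel_ids`, `fs`, and `config`.
#' @export
sliding_feature_matrix <- function(rec, cfg = entropy_config()) {
  W <- as.integer(round(cfg$window_len * rec$fs))
  N <- ncol(rec$signal)
  if (N < W)
    .stopf("recording (%.2f s) shorter than one %g-s window",
           rec_duration(rec), cfg$window_len)
  step <- max(1L, as.integer(round(W * (1 - cfg$overlap))))
  x <- as.integer(floor((N - W) / step) + 1L)
  starts <- (seq_len(x) - 1L) * step + 1L
  span <- (cfg$m - 1L) * cfg$lam
  if (W <= span)
    .stopf("window of %d samples too short for m = %d, lam = %d",
           W, cfg$m, cfg$lam)

  nbins <- cfg$m^cfg$m
  vals <- matrix(NA_real_, nrow(rec$signal), x,
                 dimnames = list(rec$channel_ids, NULL))
  for (ch in seq_len(nrow(rec$signal))) {
    codes <- .pattern_codes(rec$signal[ch, ], cfg$m, cfg$lam)
    for (b in seq_len(x)) {
      # vectors fully inside window b: starts[b] .. starts[b] + W - 1 - span
      sl <- codes[starts[b]:(starts[b] + W - 1L - span)]
      counts <- tabulate(sl, nbins)
      vals[ch, b] <- if (cfg$measure == "PE")
        .entropy_from_counts(counts, cfg$m, "PE")
      else .entropy_from_counts(counts, cfg$m, cfg$measure, cfg$q)
    }
  }
  structure(list(values = vals, window_starts = (starts - 1L) / rec$fs,
                 channel_ids = rec$channel_ids, fs = rec$fs, config = cfg),
            class = "FeatureSeries")
}

#' @export
print.FeatureSeries <- function(x, ...) {
  cat(sprintf("FeatureSeries: %d channel(s) x %d windows (%s, m=%d, lam=%d, %gs windows)\n",
              nrow(x$values), ncol(x$values), x$config$measure, x$config$m,
              x$config$lam, x$config$window_len))
  invisible(x)
}

#' Write / read a feature matrix as a delimited table
#'
#' One row per window: `window_start_s` followed by one column per channel.
#' The entropy configuration is echoed in `#`-prefixed header comments and
#' restored on read.
#'
#' @param fs A `FeatureSeries`.
#' @param path Output (input) file path.
#' @return `write_features()`: `path`, invisibly. `read_features()`: a
#'   `FeatureSeries`.
#' @export
write_features <- function(fs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- fs$config
  writeLines(sprintf("# m=%d lam=%d measure=%s q=%g window_len=%g overlap=%g fs=%g",
                     cfg$m, cfg$lam, cfg$measure, cfg$q, cfg$window_len,
                     cfg$overlap, fs$fs), con)
  tab <- data.frame(window_start_s = fs$window_starts, t(fs$values),
                    check.names = FALSE)
  colnames(tab) <- c("window_start_s", fs$channel_ids)
  suppressWarnings(write.table(tab, con, row.names = FALSE, quote = FALSE,
                               sep = "\t"))
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) .stopf("cannot read '%s': no such file", path)
  hdr <- readLines(path, n = 1L)
  kv <- strsplit(strsplit(sub("^#\\s*", "", hdr), "\\s+")[[1]], "=")
  opts <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  cfg <- entropy_config(m = as.numeric(opts[["m"]]),
                        lam = as.numeric(opts[["lam"]]),
                        measure = opts[["measure"]],
                        q = as.numeric(opts[["q"]]),
                        window_len = as.numeric(opts[["window_len"]]),
                        overlap = as.numeric(opts[["overlap"]]))
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE)
  vals <- t(as.matrix(tab[, -1, drop = FALSE]))
  structure(list(values = vals, window_starts = tab[[1]],
                 channel_ids = rownames(vals),
                 fs = as.numeric(opts[["fs"]]), config = cfg),
            class = "FeatureSeries")
}
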