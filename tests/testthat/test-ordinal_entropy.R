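test_that("ordinal patterns sort ascending with ties broken by position", {
  expect_equal(ordinal_pattern(c(1, 2, 3, 4)), 1:4)
  expect_equal(ordinal_pattern(c(5, 5, 5)), 1:3)
  expect_equal(ordinal_pattern(c(9, 10, 6)), c(3L, 1L, 2L))
  expect_equal(ordinal_pattern(c(2, 1, 2)), c(2L, 1L, 3L))
  expect_error(ordinal_pattern(c(1, NA, 3)), "non-finite")
})

test_that("pattern distribution enumerates all embedding vectors", {
  cfg <- entropy_config(m = 3, lam = 1)
  d <- pattern_distribution(c(4, 7, 9, 10, 6, 11, 3), cfg)
  expect_equal(d$n_vectors, 5L)
  expect_equal(sum(d$counts), d$n_vectors)
  expect_equal(d$counts[["1,2,3"]], 2L)
  expect_equal(d$counts[["3,1,2"]], 2L)
  expect_equal(d$counts[["2,1,3"]], 1L)

  # monotone series: a single pattern with count N - (m-1)*lam
  for (m in 2:5) {
    dm <- pattern_distribution(1:20, entropy_config(m = m))
    expect_equal(length(dm$counts), 1L)
    expect_equal(names(dm$counts), paste(1:m, collapse = ","))
    expect_equal(unname(dm$counts[1]), 20L - (m - 1L))
  }

  # boundary: exactly one vector
  d1 <- pattern_distribution(c(3, 1, 2), cfg)
  expect_equal(d1$n_vectors, 1L)
  expect_error(pattern_distribution(c(1, 2), cfg), "too short")
})

test_that("permutation entropy matches hand-computed and limiting values", {
  cfg <- entropy_config(m = 3, lam = 1)
  d <- pattern_distribution(c(4, 7, 9, 10, 6, 11, 3), cfg)
  # -(2*0.4*ln 0.4 + 0.2*ln 0.2) / ln 6
  expect_equal(permutation_entropy(d),
               -(2 * 0.4 * log(0.4) + 0.2 * log(0.2)) / log(6),
               tolerance = 1e-12)
  expect_equal(round(permutation_entropy(d), 3), 0.589)

  expect_equal(permutation_entropy(pattern_distribution(1:50, cfg)), 0)

  uniform <- structure(list(counts = stats::setNames(rep(1L, 6),
                              c("1,2,3", "1,3,2", "2,1,3",
                                "2,3,1", "3,1,2", "3,2,1")),
                            n_vectors = 6L, m = 3L),
                       class = "PatternDistribution")
  expect_equal(permutation_entropy(uniform), 1)
})

test_that("entropy variants are normalised to [0,1] with correct limits", {
  cfg <- entropy_config(m = 3, lam = 1)
  mono <- pattern_distribution(1:30, cfg)
  for (meas in c("TPE", "RPE", "MPE"))
    expect_equal(entropy_variant(mono, measure = meas), 0)

  uniform <- structure(list(counts = stats::setNames(rep(5L, 6),
                              c("1,2,3", "1,3,2", "2,1,3",
                                "2,3,1", "3,1,2", "3,2,1")),
                            n_vectors = 30L, m = 3L),
                       class = "PatternDistribution")
  expect_equal(entropy_variant(uniform, measure = "MPE"), 1)
  expect_equal(entropy_variant(uniform, measure = "TPE", q = 2), 1)
  expect_equal(entropy_variant(uniform, measure = "RPE", q = 2), 1)

  # Renyi entropy approaches Shannon PE as q -> 1
  d <- pattern_distribution(c(4, 7, 9, 10, 6, 11, 3), cfg)
  pe <- permutation_entropy(d)
  expect_equal(entropy_variant(d, measure = "RPE", q = 1 + 1e-6), pe,
               tolerance = 1e-4)
  expect_equal(entropy_variant(d, measure = "RPE", q = 1 - 1e-6), pe,
               tolerance = 1e-4)
  expect_error(entropy_variant(d, measure = "RPE", q = 1), "q = 1")
  expect_error(entropy_config(measure = "TPE", q = 1), "q = 1")
})

test_that("window counting discards trailing partial windows", {
  expect_equal(n_windows(1280, 256, 5), 1L)
  expect_equal(n_windows(1279, 256, 5), 0L)
  expect_equal(n_windows(921600, 256, 5), 720L)
  expect_equal(n_windows(2 * 3600 * 256, 256, 5), 1440L)
})

test_that("sliding feature matrix computes per-channel window entropies", {
  withr::local_seed(1)
  rec <- recording(matrix(rnorm(6 * 2816), nrow = 6), fs = 256)
  fs <- sliding_feature_matrix(rec, entropy_config())   # 11 s -> 2 windows
  expect_equal(dim(fs$values), c(6L, 2L))
  expect_equal(fs$window_starts, c(0, 5))
  expect_true(all(fs$values >= 0 & fs$values <= 1))

  # each cell equals the naive oracle on exactly that window's samples
  expect_equal(unname(fs$values[3, 2]),
               naive_pe(rec$signal[3, 1281:2560], 4, 1), tolerance = 1e-12)

  # duration exactly one window
  one <- sliding_feature_matrix(
    recording(matrix(rnorm(1280), 1), fs = 256), entropy_config())
  expect_equal(ncol(one$values), 1L)
  expect_error(sliding_feature_matrix(
    recording(matrix(rnorm(1279), 1), fs = 256), entropy_config()),
    "shorter")
})

test_that("feature tables round-trip through the delimited writer", {
  withr::local_seed(2)
  rec <- recording(matrix(rnorm(2 * 2560), nrow = 2), fs = 256,
                   channel_ids = c("HL1", "HR2"))
  fs <- sliding_feature_matrix(rec, entropy_config(m = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_features(fs, path)
  back <- read_features(path)
  expect_equal(back$values, fs$values, tolerance = 1e-10)
  expect_equal(back$window_starts, fs$window_starts)
  expect_equal(back$config$m, 3L)
  expect_equal(back$channel_ids, c("HL1", "HR2"))
})

test_that("PE is invariant under monotone transforms and rescaling", {
  withr::local_seed(3)
  x <- rnorm(400)
  for (m in c(3, 4)) {
    cfg <- entropy_config(m = m)
    ref <- permutation_entropy(pattern_distribution(x, cfg))
    expect_equal(permutation_entropy(pattern_distribution(exp(x), cfg)), ref)
    expect_equal(permutation_entropy(pattern_distribution(3 * x + 7, cfg)),
                 ref)
  }
})

test_that("pipeline PE equals brute-force enumeration on random series", {
  withr::local_seed(4)
  for (i in 1:60) {
    m <- sample(2:5, 1)
    lam <- sample(1:3, 1)
    len <- sample(((m - 1) * lam + 2):50, 1)
    x <- rnorm(len)
    cfg <- entropy_config(m = m, lam = lam)
    expect_equal(permutation_entropy(pattern_distribution(x, cfg)),
                 naive_pe(x, m, lam), tolerance = 1e-12)
  }
  # repeated values exercise the tie rule
  y <- sample(1:4, 40, replace = TRUE)
  expect_equal(permutation_entropy(pattern_distribution(y, entropy_config())),
               naive_pe(y, 4, 1), tolerance = 1e-12)
})
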