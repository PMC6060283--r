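test_that("window labelling follows the horizon / exclusion rules", {
  starts <- seq(0, 4995, by = 5)
  fs <- fake_feature_series(matrix(runif(length(starts)), 1), starts)
  ann <- data.frame(onset = 3600, offset = 3660)
  spec <- split_spec(preictal_horizon_min = 50, exclusion_margin_min = 5)
  ds <- label_windows(fs, ann, spec)

  lab_at <- function(t) ds$labels[match(t, ds$window_times)]
  expect_equal(lab_at(600), 1L)      # inside [600, 3600)
  expect_equal(lab_at(100), 0L)      # before the horizon
  expect_equal(lab_at(595), 0L)      # [595,600) ends where the horizon opens
  expect_equal(lab_at(3595), 1L)     # last pre-onset window
  # ictal and post-ictal-margin windows are excluded entirely
  expect_false(any(ds$window_times >= 3600 & ds$window_times < 3660 + 300))
  expect_equal(lab_at(3960), 0L)     # first window past the margin
  expect_true(4995 %in% ds$window_times)   # after the exclusion margin
  expect_equal(unique(ds$provenance$seizure_id[ds$labels == 1L]), 1)

  expect_error(
    label_windows(fs, data.frame(onset = c(100, 150), offset = c(200, 250)),
                  spec),
    "overlapping")
})

test_that("labelling is a pure function of window interval and annotations", {
  starts <- seq(0, 4995, by = 5)
  vals <- matrix(runif(length(starts)), 1)
  ann <- data.frame(onset = 3600, offset = 3660)
  spec <- split_spec()
  ds <- label_windows(fake_feature_series(vals, starts), ann, spec)
  perm <- withr::with_seed(1, sample(length(starts)))
  ds_p <- label_windows(fake_feature_series(vals[, perm, drop = FALSE],
                                            starts[perm]), ann, spec)
  expect_equal(ds_p$labels[order(ds_p$window_times)],
               ds$labels[order(ds$window_times)])
})

toy_seizure_ds <- function(id, n_pre = 5, n_inter = 5) {
  n <- n_pre + n_inter
  labeled_dataset(matrix(seq_len(n * 2), ncol = 2),
                  rep(c(1L, 0L), c(n_pre, n_inter)), seq_len(n),
                  data.frame(recording_id = id,
                             seizure_id = c(rep(id, n_pre), rep(NA, n_inter))))
}

test_that("leave-one-seizure-out keeps train and test disjoint", {
  szs <- stats::setNames(lapply(paste0("s", 1:4), toy_seizure_ds),
                         paste0("s", 1:4))
  pool <- toy_seizure_ds("ipool", n_pre = 0, n_inter = 20)
  sp <- leave_one_seizure_split(szs, pool, "s2")
  expect_equal(n_samples(sp$test), 10L)
  # training preictal windows come from the other three seizures only
  pre_src <- unique(sp$train$provenance$seizure_id[sp$train$labels == 1L])
  expect_setequal(pre_src, c("s1", "s3", "s4"))
  expect_false("s2" %in% sp$train$provenance$recording_id)
  # interictal training windows come from the pool
  expect_true(all(sp$train$provenance$recording_id[sp$train$labels == 0L] ==
                  "ipool"))

  expect_error(leave_one_seizure_split(szs[1:2], pool, "s1"),
               "at least 3 seizures")
})

test_that("undersampling balances to the minority count, deterministically", {
  ds <- labeled_dataset(matrix(rnorm(1240 * 2), ncol = 2),
                        rep(c(0L, 1L), c(1000, 240)), seq_len(1240),
                        data.frame(recording_id = "r",
                                   seizure_id = NA_real_))
  bal <- balance_undersample(ds, seed = 9)
  expect_equal(sum(bal$labels == 0L), 240L)
  expect_equal(sum(bal$labels == 1L), 240L)
  # every minority row survives
  expect_true(all(ds$window_times[ds$labels == 1L] %in% bal$window_times))

  bal2 <- balance_undersample(ds, seed = 9)
  expect_identical(bal$window_times, bal2$window_times)
  bal3 <- balance_undersample(ds, seed = 10)
  expect_false(identical(bal$window_times, bal3$window_times))

  even <- subset_dataset(ds, c(1:240, 1001:1240))
  expect_equal(n_samples(balance_undersample(even, 1)), 480L)
  only1 <- subset_dataset(ds, ds$labels == 1L)
  expect_error(balance_undersample(only1, 1), "both classes")
})
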