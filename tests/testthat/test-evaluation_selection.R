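test_that("sensitivity and false prediction rate are simple ratios", {
  expect_equal(sensitivity(4, 4), 1)
  expect_equal(sensitivity(3, 4), 0.75)
  expect_equal(sensitivity(0, 4), 0)
  expect_error(sensitivity(5, 4), "upper|in \\[")
  expect_equal(false_prediction_rate(0, 24), 0)
  expect_equal(false_prediction_rate(2, 24), 2 / 24)
  expect_error(false_prediction_rate(1, 0), "NT_hours")
})

test_that("alarm scoring counts hits, false alarms and SPH correctly", {
  ann <- data.frame(onset = 3600, offset = 3660)
  # alarm 6 min before onset, within the 50-min horizon
  rep1 <- score_alarms(3600 - 360, ann, horizon_min = 50, total_hours = 1)
  expect_equal(rep1$Nc, 1L)
  expect_equal(rep1$SS, 1)
  expect_equal(rep1$Nf, 0L)
  expect_equal(rep1$SPH_min, 6)

  # no alarms at all
  rep0 <- score_alarms(numeric(0), ann, 50, 1)
  expect_equal(rep0$SS, 0)
  expect_equal(rep0$Nf, 0L)

  # three false alarms over a 24-h record
  rep3 <- score_alarms(c(10, 5000, 20000),
                       data.frame(onset = 86000, offset = 86060),
                       50, 24)
  expect_equal(rep3$Nf, 3L)
  expect_equal(rep3$FPR, 0.125)
  expect_true(rep3$below_chance)

  # only the FIRST in-horizon alarm defines SPH; later ones are neither
  # hits nor false alarms; ordering of the input does not matter
  two <- score_alarms(c(3500, 3300), ann, 50, 1)
  expect_equal(two$Nc, 1L)
  expect_equal(two$Nf, 0L)
  expect_equal(two$SPH_min, (3600 - 3300) / 60)
  expect_equal(score_alarms(c(3300, 3500), ann, 50, 1)$SPH_min, two$SPH_min)

  # an early alarm before the horizon opens is false
  early <- score_alarms(3600 - 3001, ann, 50, 1)
  expect_equal(early$Nc, 0L)
  expect_equal(early$Nf, 1L)
})

test_that("pooling reports recomputes SS and FPR over the union", {
  r1 <- score_alarms(3240, data.frame(onset = 3300, offset = 3360), 50, 1)
  r2 <- score_alarms(numeric(0), data.frame(onset = 3300, offset = 3360),
                     50, 1)
  pooled <- pool_reports(list(r1, r2))
  expect_equal(pooled$Nc, 1L)
  expect_equal(pooled$Nt, 2L)
  expect_equal(pooled$SS, 0.5)
  expect_equal(pooled$NT_hours, 2)
})

test_that("FPR normalisation scales by the candidate-set maximum", {
  expect_equal(normalized_fpr(c(0.1, 0.2, 0.4)), c(25, 50, 100))
  expect_equal(normalized_fpr(c(0, 0)), c(0, 0))
  expect_equal(normalized_fpr(0.3), 100)
  expect_error(normalized_fpr(c(0.1, -0.2)), "non-negative")
})

test_that("Euclidean distance to the ideal point matches its definition", {
  expect_equal(euclidean_distance(100, 0), 0)
  expect_equal(euclidean_distance(100, 26.67), 26.67)
  expect_equal(euclidean_distance(0, 0), 100)
  expect_equal(euclidean_distance(80, 30), sqrt(20^2 + 30^2))
})

test_that("model selection minimises distance with the stated tie-breaks", {
  sc <- model_scores(ss = c(0.9, 0.95, 0.8), fpr = c(0.2, 0.1, 0.4))
  expect_equal(select_best_model(sc), order(sc$ed)[1])
  expect_equal(select_best_model(model_scores(1, 0.3)), 1L)

  # equal distance: prefer higher sensitivity
  tie <- data.frame(ss_pct = c(90, 95), fpr = c(0.1, 0.2), ed = c(12, 12))
  expect_equal(select_best_model(tie), 2L)
  # equal distance and sensitivity: prefer lower raw FPR
  tie2 <- data.frame(ss_pct = c(95, 95), fpr = c(0.3, 0.2), ed = c(12, 12))
  expect_equal(select_best_model(tie2), 2L)
  expect_error(select_best_model(data.frame()), "empty")
})

test_that("benchmark table aggregation reproduces the published averages", {
  tbl <- freiburg_benchmark()
  expect_equal(nrow(tbl), 19L)
  agg <- aggregate_report(tbl)
  avg <- agg[agg$patient == "Avg.", ]
  expect_equal(round(avg$ss_two, 3), 0.940)
  expect_equal(round(avg$fpr_two, 3), 0.111)
  expect_equal(round(avg$sph_two, 2), 61.93)
  expect_equal(round(avg$dist_two, 2), 11.46)

  # identical rows aggregate to themselves
  same <- data.frame(patient = 1:3, ss = 0.9, fpr = 0.1)
  agg2 <- aggregate_report(same)
  expect_equal(agg2$ss[4], 0.9)
  expect_equal(agg2$fpr[4], 0.1)
})
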