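# Firing-power alarm generation.
#
# The classifier emits one binary label per 5-s window. Two-step firing
# power: (1) sum labels over non-overlapping 2-min short windows (24
# labels) and call a short window preictal when the count reaches the
# threshold p; (2) partition short windows into non-overlapping triples
# (6-min long windows) and raise one alarm, timestamped at the long
# window's start, when at least k of its 3 short windows are preictal.
# One-step firing power thresholds the label count of a single 6-min
# window directly. An optional refractory period suppresses alarms too
# close to a previous one.

#' Firing-power configuration
#'
#' @param mode `"two_step"` (short + long window) or `"one_step"` (single
#'   long window).
#' @param short_window_labels Labels per short window (default 24 = 2 min of
#'   5-s windows).
#' @param long_window_shorts Short windows per long window (default 3 =
#'   6 min).
#' @param p Short-window preictal-count threshold, in `1..short/2`
#'   (the canonical candidate set is `{1, ..., 12}`); two-step only.
#' @param k Preictal short windows required per long window, `1..3`;
#'   two-step only.
#' @param one_step_threshold Label-count threshold on the 6-min window;
#'   one-step only.
#' @param one_step_window_labels Labels per one-step window (default 72 =
#'   6 min).
#' @param refractory_min Minimum spacing between alarms, minutes; `NULL` or
#'   `0` disables suppression. Default 50 (the preictal horizon).
#' @return An object of class `FPConfig`.
#' @export
fp_config <- function(mode = c("two_step", "one_step"),
                      short_window_labels = 24L, long_window_shorts = 3L,
                      p = 7L, k = 2L, one_step_threshold = 21L,
                      one_step_window_labels = 72L, refractory_min = 50) {
  mode <- match.arg(mode)
  .check_scalar_num(short_window_labels, "short_window_labels", lower = 2)
  .check_scalar_num(long_window_shorts, "long_window_shorts", lower = 1)
  if (mode == "two_step") {
    .check_scalar_num(p, "p", lower = 1, upper = short_window_labels / 2)
    .check_scalar_num(k, "k", lower = 1, upper = long_window_shorts)
  } else {
    .check_scalar_num(one_step_threshold, "one_step_threshold", lower = 1,
                      upper = one_step_window_labels)
  }
  if (!is.null(refractory_min))
    .check_scalar_num(refractory_min, "refractory_min", lower = 0)
  structure(list(mode = mode,
                 short_window_labels = as.integer(short_window_labels),
                 long_window_shorts = as.integer(long_window_shorts),
                 p = as.integer(p), k = as.integer(k),
                 one_step_threshold = as.integer(one_step_threshold),
                 one_step_window_labels = as.integer(one_step_window_labels),
                 refractory_min = refractory_min),
            class = "FPConfig")
}

.check_binary <- function(tg) {
  if (length(tg) == 0L || !all(tg %in% c(0, 1)))
    .stopf("label sequence must be non-empty and binary (0/1)")
  as.integer(tg)
}

#' Preictal-label counts per short window
#'
#' Sums the binary label sequence over consecutive non-overlapping blocks
#' of `m` labels; a trailing partial block is discarded.
#'
#' @param tg Binary label sequence (one value per 5-s window).
#' @param m Labels per short window (default 24).
#' @return Integer vector `num_pre[t]`, each in `0..m`.
#' @export
short_window_counts <- function(tg, m = 24L) {
  tg <- .check_binary(tg)
  .check_scalar_num(m, "m", lower = 1)
  n_short <- floor(length(tg) / m)
  if (n_short == 0L) return(integer(0))
  colSums(matrix(tg[seq_len(n_short * m)], nrow = m))
}

#' Threshold short-window counts into states
#'
#' A short window is preictal when its preictal-label count reaches the
#' threshold `p`, interictal otherwise.
#'
#' @param num_pre Integer counts from [short_window_counts()].
#' @param p Threshold (>= 1).
#' @return Character vector of `"preictal"` / `"interictal"` states.
#' @export
classify_short_windows <- function(num_pre, p) {
  .check_scalar_num(p, "p", lower = 1)
  ifelse(num_pre >= p, "preictal", "interictal")
}

.apply_refractory <- function(times, refractory_min) {
  if (is.null(refractory_min) || refractory_min <= 0 || length(times) == 0L)
    return(times)
  refr_s <- refractory_min * 60
  kept <- times[1]
  for (t in times[-1]) if (t - kept[length(kept)] >= refr_s) kept <- c(kept, t)
  kept
}

.alarm_sequence <- function(times, config) {
  structure(list(alarm_times = times, config = config),
            class = "AlarmSequence")
}

#' @export
print.AlarmSequence <- function(x, ...) {
  cat(sprintf("AlarmSequence (%s): %d alarm(s)\n", x$config$mode,
              length(x$alarm_times)))
  if (length(x$alarm_times) > 0L)
    cat("  at (s):", paste(signif(x$alarm_times, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Two-step firing-power alarms (k-of-3 rule)
#'
#' Partitions the short-window state sequence into consecutive
#' non-overlapping groups of `long_window_shorts` (default 3; a trailing
#' partial group is ignored). A long window with at least `k` preictal
#' short windows raises one alarm at the long window's start time;
#' subsequent alarms within the refractory period are suppressed.
#'
#' @param states Character states from [classify_short_windows()] (or a
#'   binary vector, 1 = preictal).
#' @param k Required preictal short windows per long window.
#' @param refractory_min Alarm suppression interval, minutes (`NULL`/0 =
#'   off).
#' @param short_window_s Short-window duration in seconds (default 120).
#' @param long_window_shorts Short windows per long window (default 3).
#' @param t0 Time of the first short window's start, seconds.
#' @return An `AlarmSequence`.
#' @export
two_step_alarms <- function(states, k, refractory_min = 50,
                            short_window_s = 120, long_window_shorts = 3L,
                            t0 = 0) {
  if (is.numeric(states)) states <- ifelse(states > 0, "preictal", "interictal")
  .check_scalar_num(k, "k", lower = 1, upper = long_window_shorts)
  pre <- as.integer(states == "preictal")
  n_long <- floor(length(pre) / long_window_shorts)
  cfg <- fp_config("two_step", k = k, p = 1L, refractory_min = refractory_min,
                   long_window_shorts = long_window_shorts)
  if (n_long == 0L) return(.alarm_sequence(numeric(0), cfg))
  per_long <- colSums(matrix(pre[seq_len(n_long * long_window_shorts)],
                             nrow = long_window_shorts))
  hits <- which(per_long >= k)
  times <- t0 + (hits - 1L) * long_window_shorts * short_window_s
  .alarm_sequence(.apply_refractory(times, refractory_min), cfg)
}

#' Run both firing-power steps on a label sequence
#'
#' Convenience wrapper: [short_window_counts()] then
#' [classify_short_windows()] then [two_step_alarms()], with all sizes taken
#' from the configuration.
#'
#' @param tg Binary label sequence (one value per `label_s` seconds).
#' @param cfg An [fp_config()] with `mode = "two_step"`.
#' @param label_s Seconds per label (default 5).
#' @param t0 Time of the first label's window start, seconds.
#' @return An `AlarmSequence`.
#' @export
firing_power_alarms <- function(tg, cfg, label_s = 5, t0 = 0) {
  if (cfg$mode == "one_step")
    return(one_step_alarms(tg, cfg$one_step_window_labels,
                           cfg$one_step_threshold, cfg$refractory_min,
                           label_s = label_s, t0 = t0))
  counts <- short_window_counts(tg, cfg$short_window_labels)
  states <- classify_short_windows(counts, cfg$p)
  al <- two_step_alarms(states, cfg$k, cfg$refractory_min,
                        short_window_s = cfg$short_window_labels * label_s,
                        long_window_shorts = cfg$long_window_shorts, t0 = t0)
  al$config <- cfg   # record the full configuration including p
  al
}

#' One-step firing-power alarms
#'
#' Groups the label sequence into non-overlapping blocks (default 72 labels
#' = 6 min) and raises an alarm at the start of every block whose label sum
#' reaches the threshold, subject to refractory suppression.
#'
#' @param tg Binary label sequence.
#' @param window_labels Labels per block (default 72).
#' @param threshold Label-count threshold (>= 1).
#' @param refractory_min Alarm suppression interval, minutes (`NULL`/0 =
#'   off).
#' @param label_s Seconds per label (default 5).
#' @param t0 Time of the first label's window start, seconds.
#' @return An `AlarmSequence`.
#' @export
one_step_alarms <- function(tg, window_labels = 72L, threshold,
                            refractory_min = 50, label_s = 5, t0 = 0) {
  tg <- .check_binary(tg)
  .check_scalar_num(threshold, "threshold", lower = 1)
  .check_scalar_num(window_labels, "window_labels", lower = 1)
  cfg <- fp_config("one_step", one_step_threshold = threshold,
                   one_step_window_labels = window_labels,
                   refractory_min = refractory_min)
  n_block <- floor(length(tg) / window_labels)
  if (n_block == 0L) return(.alarm_sequence(numeric(0), cfg))
  sums <- colSums(matrix(tg[seq_len(n_block * window_labels)],
                         nrow = window_labels))
  hits <- which(sums >= threshold)
  times <- t0 + (hits - 1L) * window_labels * label_s
  .alarm_sequence(.apply_refractory(times, refractory_min), cfg)
}

#' Write an alarm sequence as a delimited table
#'
#' @param alarms An `AlarmSequence`.
#' @param path Output path; alarm times in seconds, one per line, with the
#'   generating configuration in a `#` header comment.
#' @return `path`, invisibly.
#' @export
write_alarms <- function(alarms, path) {
  cfg <- alarms$config
  digest <- if (cfg$mode == "two_step")
    sprintf("mode=two_step p=%d k=%d refractory_min=%s", cfg$p, cfg$k,
            format(cfg$refractory_min))
  else sprintf("mode=one_step threshold=%d refractory_min=%s",
               cfg$one_step_threshold, format(cfg$refractory_min))
  writeLines(c(paste("#", digest), "alarm_time_s",
               format(alarms$alarm_times, trim = TRUE)), path)
  invisible(path)
}
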