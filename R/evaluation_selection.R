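# Scoring alarm sequences against seizure annotations, and selecting the
# best candidate model by normalized-FPR Euclidean distance.
#
# A seizure counts as predicted when at least one alarm falls inside its
# preictal horizon [onset - horizon, onset); the seizure prediction horizon
# (SPH) is the gap between the FIRST such alarm and the onset. Alarms
# outside every seizure's preictal interval are false; later in-horizon
# alarms for an already-predicted seizure are neither hits nor false.
# FPR divides false alarms by TOTAL record time (interictal + preictal),
# not interictal-only time.

#' Sensitivity of seizure prediction
#'
#' `SS = Nc / Nt`: the fraction of seizures preceded by at least one
#' in-horizon alarm.
#'
#' @param Nc Correctly predicted seizures.
#' @param Nt Total seizures (>= 1).
#' @return Sensitivity in `[0, 1]`.
#' @export
sensitivity <- function(Nc, Nt) {
  .check_scalar_num(Nt, "Nt", lower = 1)
  .check_scalar_num(Nc, "Nc", lower = 0, upper = Nt)
  Nc / Nt
}

#' False prediction rate
#'
#' `FPR = Nf / NT`: false alarms per hour of recording.
#'
#' @param Nf Number of false alarms.
#' @param NT_hours Total recording time in hours (> 0).
#' @return Rate in alarms per hour.
#' @export
false_prediction_rate <- function(Nf, NT_hours) {
  .check_scalar_num(Nf, "Nf", lower = 0)
  .check_scalar_num(NT_hours, "NT_hours", lower = .Machine$double.eps)
  Nf / NT_hours
}

#' Score an alarm sequence against seizure annotations
#'
#' @param alarms An `AlarmSequence` (or numeric vector of alarm times in
#'   seconds).
#' @param annotations Data frame of seizures (`onset`, `offset`, seconds).
#' @param horizon_min Preictal horizon, minutes (default 50).
#' @param total_hours Total duration of the scored recording(s), hours.
#' @param chance_fpr Literature chance level used for the `below_chance`
#'   flag (default 0.15 alarms/h).
#' @return Object of class `EvaluationReport`: list with `Nc`, `Nt`, `Nf`,
#'   `NT_hours`, `SS`, `FPR`, `SPH_min` (one entry per predicted seizure),
#'   `mean_SPH_min`, and `below_chance`.
#' @export
score_alarms <- function(alarms, annotations, horizon_min = 50, total_hours,
                         chance_fpr = 0.15) {
  times <- if (inherits(alarms, "AlarmSequence")) alarms$alarm_times
           else as.numeric(alarms)
  times <- sort(times)
  .check_scalar_num(total_hours, "total_hours",
                    lower = .Machine$double.eps)
  ann <- as.data.frame(annotations)
  horizon_s <- horizon_min * 60
  Nt <- NROW(ann)
  sph <- numeric(0)
  in_any_horizon <- rep(FALSE, length(times))
  Nc <- 0L
  for (i in seq_len(Nt)) {
    lo <- ann$onset[i] - horizon_s
    hit <- times >= lo & times < ann$onset[i]
    in_any_horizon <- in_any_horizon | hit
    if (any(hit)) {
      Nc <- Nc + 1L
      sph <- c(sph, (ann$onset[i] - times[which(hit)[1]]) / 60)
    }
  }
  Nf <- sum(!in_any_horizon)
  fpr <- false_prediction_rate(Nf, total_hours)
  structure(list(Nc = Nc, Nt = Nt, Nf = Nf, NT_hours = total_hours,
                 SS = if (Nt > 0) Nc / Nt else NA_real_,
                 FPR = fpr, SPH_min = sph,
                 mean_SPH_min = if (length(sph)) mean(sph) else NA_real_,
                 below_chance = fpr < chance_fpr),
            class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf("EvaluationReport: SS = %d/%d = %.3f, FPR = %.3f /h over %.2f h%s\n",
              x$Nc, x$Nt, x$SS, x$FPR, x$NT_hours,
              if (isTRUE(x$below_chance)) " (below 0.15/h chance level)" else ""))
  if (length(x$SPH_min))
    cat(sprintf("  SPH (min): %s (mean %.2f)\n",
                paste(signif(x$SPH_min, 4), collapse = ", "), x$mean_SPH_min))
  invisible(x)
}

#' Combine evaluation reports from several recordings
#'
#' Pools counts and durations (`Nc`, `Nt`, `Nf`, `NT_hours`, SPH lists) so
#' SS and FPR are recomputed over the union, e.g. across the folds of a
#' leave-one-seizure-out evaluation.
#'
#' @param reports List of `EvaluationReport`s.
#' @return A pooled `EvaluationReport`.
#' @export
pool_reports <- function(reports) {
  Nc <- sum(vapply(reports, `[[`, 1L, "Nc"))
  Nt <- sum(vapply(reports, `[[`, 1L, "Nt"))
  Nf <- sum(vapply(reports, `[[`, 1L, "Nf"))
  NT <- sum(vapply(reports, `[[`, 1, "NT_hours"))
  sph <- unlist(lapply(reports, `[[`, "SPH_min"))
  structure(list(Nc = Nc, Nt = Nt, Nf = Nf, NT_hours = NT,
                 SS = if (Nt > 0) Nc / Nt else NA_real_, FPR = Nf / NT,
                 SPH_min = sph,
                 mean_SPH_min = if (length(sph)) mean(sph) else NA_real_,
                 below_chance = Nf / NT < 0.15),
            class = "EvaluationReport")
}

#' Normalise false prediction rates over a candidate set
#'
#' `fprn(u) = fpr(u) / max(fpr) * 100`. When every candidate has zero FPR
#' the normalised values are all zero by convention.
#'
#' @param fprs Non-negative FPR values, one per candidate model.
#' @return Normalised FPRs in `[0, 100]`.
#' @export
normalized_fpr <- function(fprs) {
  if (any(!is.finite(fprs)) || any(fprs < 0))
    .stopf("FPR values must be finite and non-negative")
  mx <- max(fprs)
  if (mx == 0) return(rep(0, length(fprs)))
  fprs / mx * 100
}

#' Euclidean distance to the ideal operating point
#'
#' `ed = sqrt((ss_pct - 100)^2 + fprn^2)`: distance from a candidate's
#' (sensitivity %, normalised FPR) to the ideal (100, 0). Zero iff the
#' candidate predicts every seizure with the candidate set's minimum FPR
#' of zero.
#'
#' @param ss_pct Sensitivity in percent (`0..100`); vectorised.
#' @param fprn Normalised FPR from [normalized_fpr()] (`>= 0`); vectorised.
#' @return Euclidean distance(s) in `[0, sqrt(2) * 100]`.
#' @export
euclidean_distance <- function(ss_pct, fprn) {
  if (any(!is.finite(ss_pct)) || any(ss_pct < 0) || any(ss_pct > 100))
    .stopf("ss_pct must lie in [0, 100]")
  if (any(!is.finite(fprn)) || any(fprn < 0))
    .stopf("fprn must be non-negative")
  sqrt((ss_pct - 100)^2 + fprn^2)
}

#' Score a set of candidate models
#'
#' Computes normalised FPR and Euclidean distance for each candidate from
#' its sensitivity and raw FPR.
#'
#' @param ss Sensitivities in `[0, 1]`, one per candidate.
#' @param fpr Raw FPRs (per hour), one per candidate.
#' @return Data frame with columns `ss_pct`, `fpr`, `fprn`, `ed`.
#' @export
model_scores <- function(ss, fpr) {
  if (length(ss) != length(fpr)) .stopf("ss and fpr must align")
  fprn <- normalized_fpr(fpr)
  data.frame(ss_pct = ss * 100, fpr = fpr, fprn = fprn,
             ed = euclidean_distance(ss * 100, fprn))
}

#' Select the best candidate model
#'
#' Minimum Euclidean distance; ties broken towards higher sensitivity,
#' then lower raw FPR, then earlier position.
#'
#' @param scores Data frame from [model_scores()] (columns `ed`, `ss_pct`,
#'   `fpr`).
#' @return Index of the winning candidate.
#' @export
select_best_model <- function(scores) {
  if (NROW(scores) == 0L) .stopf("empty candidate list")
  order(scores$ed, -scores$ss_pct, scores$fpr)[1]
}

#' Aggregate per-patient results into a summary table
#'
#' Appends an unweighted arithmetic-mean (`Avg.`) row to a per-patient
#' results table, mirroring the standard reporting layout (sensitivity,
#' FPR, mean SPH and selected-model distance per post-processing mode).
#'
#' @param per_patient Data frame with one row per patient; all numeric
#'   columns are averaged.
#' @param id_col Name of the patient-identifier column (default
#'   `"patient"`).
#' @return The table with an `Avg.` row appended.
#' @export
aggregate_report <- function(per_patient, id_col = "patient") {
  if (NROW(per_patient) == 0L) .stopf("empty results table")
  num <- vapply(per_patient, is.numeric, TRUE)
  num[names(num) == id_col] <- FALSE
  avg <- per_patient[1, , drop = FALSE]
  avg[, ] <- NA
  if (id_col %in% names(avg)) avg[[id_col]] <- "Avg."
  avg[num] <- lapply(per_patient[num], mean)
  out <- rbind(per_patient, avg)
  rownames(out) <- NULL
  out
}
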