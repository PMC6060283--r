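#' Published per-patient benchmark results on the Freiburg iEEG database
#'
#' Per-patient sensitivity (`ss`), false prediction rate (`fpr`, per hour),
#' mean seizure prediction horizon (`sph`, minutes) and selected-model
#' Euclidean distance (`dist`) reported for the 19 analysable Freiburg
#' patients under the two-step (`_two`) and one-step (`_one`) firing-power
#' post-processing modes. Used to validate the aggregation utilities: the
#' unweighted column means reproduce the published averages
#' (two-step 0.940 / 0.111 / 61.93 / 11.46; one-step 0.938 / 0.423 /
#' 65.40 / 22.89).
#'
#' @return Data frame with one row per patient and the columns above.
#' @export
freiburg_benchmark <- function() {
  path <- system.file("extdata", "freiburg_benchmark.tsv",
                      package = "peseizr", mustWork = TRUE)
  read.table(path, header = TRUE, sep = "\t")
}
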