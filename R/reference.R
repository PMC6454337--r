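# Shipped reference benchmark tables: published precision/recall of the
# original CRF tagger on its private clinical corpus. Used to exercise
# the package's averaging arithmetic against known-good published cells;
# they are inputs, never reproduction targets for models trained here.

#' Reference test-set precision/recall benchmark
#'
#' Per-construct and microaverage precision/recall of the best published
#' model at the four evaluation levels, on the original (private)
#' clinical corpus. F1 and macroaverage cells are intentionally absent:
#' they are recomputed with [summarize_pr()].
#'
#' @return data.frame: `construct`, `level`, `precision`, `recall`.
#' @export
reference_test_metrics <- function() {
  utils::read.delim(gstag_extdata("reference_test_metrics.tsv"),
                    stringsAsFactors = FALSE, comment.char = "#")
}

#' Reference feature-ablation benchmark (phrase-partial, validation)
#'
#' Published macro/micro precision, recall and F1 for the basic feature
#' set, each single added feature family, the best combination, and the
#' ICD9-only rule baseline.
#'
#' @return data.frame with one row per configuration.
#' @export
reference_ablation_metrics <- function() {
  utils::read.delim(gstag_extdata("reference_ablation_metrics.tsv"),
                    stringsAsFactors = FALSE, comment.char = "#")
}
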