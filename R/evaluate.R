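# Four-level evaluation of predicted construct spans against gold
# annotations: phrase-exact, phrase-partial (>= 1 overlapping character,
# same construct), note-level and patient-level set comparison; per
# construct and micro/macro averaged; McNemar's test between two systems.
#
# Averaging conventions: microaveraging pools TP/FP/FN over constructs
# before computing P/R/F1; macroaveraging takes the arithmetic mean of the
# per-construct precisions and of the per-construct recalls, and macro-F1
# is the harmonic mean of macro-P and macro-R (not the mean of
# per-construct F1s).

.prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f)
}

.empty_counts <- function() {
  data.frame(construct = construct_codes(),
             tp = 0L, fp = 0L, fn = 0L, stringsAsFactors = FALSE)
}

# Greedy one-to-one phrase matching within one note for one construct.
# Predictions are taken left-to-right; each chooses the leftmost unmatched
# gold span satisfying the criterion. Returns logical vectors
# (gold matched, pred matched).
.match_one <- function(gold, pred, mode) {
  gold <- gold[order(gold$start, gold$end), , drop = FALSE]
  pred <- pred[order(pred$start, pred$end), , drop = FALSE]
  gm <- rep(FALSE, nrow(gold))
  pm <- rep(FALSE, nrow(pred))
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(nrow(gold))) {
      if (gm[j]) next
      ok <- if (mode == "exact") {
        pred$start[i] == gold$start[j] && pred$end[i] == gold$end[j]
      } else {
        pred$start[i] < gold$end[j] && gold$start[j] < pred$end[i]
      }
      if (ok) { gm[j] <- TRUE; pm[i] <- TRUE; break }
    }
  }
  list(gold = gm, pred = pm,
       gold_order = gold, pred_order = pred)
}

#' Phrase-level matching counts
#'
#' Pairs predicted and gold spans one-to-one within each note: `exact`
#' requires identical `(construct, start, end)`; `partial` requires the
#' same construct and at least one overlapping character. Matching is
#' greedy in left-to-right order of predictions, each prediction claiming
#' the leftmost unmatched overlapping gold span. Unmatched predictions
#' count as FP, unmatched gold spans as FN.
#'
#' @param gold,pred data.frames of spans (`note_id`, `construct`, `start`,
#'   `end`).
#' @param mode `"exact"` or `"partial"`.
#' @return data.frame with columns `construct`, `tp`, `fp`, `fn`.
#' @export
match_phrase <- function(gold, pred, mode = c("partial", "exact")) {
  mode <- match.arg(mode)
  counts <- .empty_counts()
  notes <- union(unique(gold$note_id), unique(pred$note_id))
  for (nid in notes) {
    for (cc in construct_codes()) {
      g <- gold[gold$note_id == nid & gold$construct == cc, , drop = FALSE]
      p <- pred[pred$note_id == nid & pred$construct == cc, , drop = FALSE]
      if (nrow(g) == 0L && nrow(p) == 0L) next
      m <- .match_one(g, p, mode)
      k <- counts$construct == cc
      counts$tp[k] <- counts$tp[k] + sum(m$pred)
      counts$fp[k] <- counts$fp[k] + sum(!m$pred)
      counts$fn[k] <- counts$fn[k] + sum(!m$gold)
    }
  }
  counts
}

# Set comparison of constructs per grouping unit (note or patient).
.match_sets <- function(gold_units, pred_units) {
  counts <- .empty_counts()
  units <- union(names(gold_units), names(pred_units))
  for (u in units) {
    g <- gold_units[[u]] %||% character(0)
    p <- pred_units[[u]] %||% character(0)
    for (cc in construct_codes()) {
      k <- counts$construct == cc
      if (cc %in% g && cc %in% p) counts$tp[k] <- counts$tp[k] + 1L
      else if (cc %in% p) counts$fp[k] <- counts$fp[k] + 1L
      else if (cc %in% g) counts$fn[k] <- counts$fn[k] + 1L
    }
  }
  counts
}

.units_by <- function(spans, key) {
  if (nrow(spans) == 0L) return(stats::setNames(list(), character(0)))
  lapply(split(spans$construct, spans[[key]]), unique)
}

#' Note-level matching counts
#'
#' Compares the set of constructs predicted anywhere in each note against
#' the gold set for that note: TP where both contain the construct, FP
#' where only predicted, FN where only gold.
#'
#' @inheritParams match_phrase
#' @return data.frame with columns `construct`, `tp`, `fp`, `fn`.
#' @export
match_note <- function(gold, pred) {
  .match_sets(.units_by(gold, "note_id"), .units_by(pred, "note_id"))
}

#' Patient-level matching counts
#'
#' As [match_note()], with construct sets unioned over each patient's
#' notes: a patient has a construct if it appears in any of their notes.
#' Span tables must carry a `patient_id` column.
#'
#' @inheritParams match_phrase
#' @return data.frame with columns `construct`, `tp`, `fp`, `fn`.
#' @export
match_patient <- function(gold, pred) {
  stopifnot("patient_id" %in% names(gold), "patient_id" %in% names(pred))
  .match_sets(.units_by(gold, "patient_id"), .units_by(pred, "patient_id"))
}

#' Aggregate per-construct counts into a metrics table
#'
#' Adds precision, recall and F1 per construct, a microaverage row
#' (counts pooled over constructs, then P/R/F1) and a macroaverage row
#' (mean of per-construct P and of per-construct R; macro-F1 = harmonic
#' mean of macro-P and macro-R). Zero denominators give 0.
#'
#' @param counts data.frame `construct`/`tp`/`fp`/`fn` (one of the
#'   `match_*` outputs).
#' @return data.frame with columns `construct`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`; the last two rows are `Macroaverage`
#'   and `Microaverage`.
#' @export
aggregate_counts <- function(counts) {
  per <- t(mapply(.prf, counts$tp, counts$fp, counts$fn))
  out <- cbind(counts, as.data.frame(per))
  macro_p <- mean(out$precision)
  macro_r <- mean(out$recall)
  macro_f <- if (macro_p + macro_r > 0) {
    2 * macro_p * macro_r / (macro_p + macro_r)
  } else 0
  micro <- .prf(sum(counts$tp), sum(counts$fp), sum(counts$fn))
  rbind(out,
        data.frame(construct = "Macroaverage", tp = NA, fp = NA, fn = NA,
                   precision = macro_p, recall = macro_r, f1 = macro_f),
        data.frame(construct = "Microaverage",
                   tp = sum(counts$tp), fp = sum(counts$fp),
                   fn = sum(counts$fn),
                   precision = micro[["precision"]],
                   recall = micro[["recall"]], f1 = micro[["f1"]]))
}

#' Macro/micro summary from precision/recall columns
#'
#' Applies the package's averaging arithmetic directly to a table of
#' per-construct precision and recall values (e.g. a published benchmark
#' table): per-row F1 as the harmonic mean, macro-P/R as column means,
#' macro-F1 as the harmonic mean of macro-P and macro-R.
#'
#' @param precision,recall numeric vectors, one value per construct.
#' @return list with `f1` (per construct), `macro_precision`,
#'   `macro_recall`, `macro_f1`.
#' @export
summarize_pr <- function(precision, recall) {
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  mp <- mean(precision); mr <- mean(recall)
  list(f1 = f1, macro_precision = mp, macro_recall = mr,
       macro_f1 = if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0)
}

#' Full four-level metrics report
#'
#' Runs all four evaluation levels and aggregates each.
#'
#' @param gold,pred span tables with `note_id`, `patient_id`, `construct`,
#'   `start`, `end`.
#' @return named list of [aggregate_counts()] tables:
#'   `exact`, `partial`, `note`, `patient`.
#' @export
metrics_report <- function(gold, pred) {
  list(exact = aggregate_counts(match_phrase(gold, pred, "exact")),
       partial = aggregate_counts(match_phrase(gold, pred, "partial")),
       note = aggregate_counts(match_note(gold, pred)),
       patient = aggregate_counts(match_patient(gold, pred)))
}

#' Extract a summary cell from a metrics report
#' @param report a [metrics_report()] or single [aggregate_counts()] table.
#' @param level one of `exact`, `partial`, `note`, `patient` (ignored if
#'   `report` is already a table).
#' @param average `"Microaverage"` or `"Macroaverage"`.
#' @param metric `"precision"`, `"recall"` or `"f1"`.
#' @return numeric scalar.
#' @export
metric_cell <- function(report, level = "partial", average = "Microaverage",
                        metric = "f1") {
  tab <- if (is.data.frame(report)) report else report[[level]]
  tab[tab$construct == average, metric][[1]]
}

#' Per-item phrase-partial correctness for McNemar pairing
#'
#' Items are the gold mentions; a gold mention is correct for a system iff
#' it is matched under the greedy phrase matching. Returns a logical
#' vector aligned to the row order of `gold` sorted by
#' (note_id, construct, start).
#'
#' @inheritParams match_phrase
#' @return logical vector, one element per gold span.
#' @export
gold_decisions <- function(gold, pred, mode = "partial") {
  gold <- gold[order(gold$note_id, gold$construct, gold$start), , drop = FALSE]
  out <- logical(nrow(gold))
  for (nid in unique(gold$note_id)) {
    for (cc in construct_codes()) {
      k <- which(gold$note_id == nid & gold$construct == cc)
      if (length(k) == 0L) next
      p <- pred[pred$note_id == nid & pred$construct == cc, , drop = FALSE]
      m <- .match_one(gold[k, , drop = FALSE], p, mode)
      # .match_one sorts by start; k is already in start order
      out[k] <- m$gold
    }
  }
  out
}

#' McNemar's test for paired system comparison
#'
#' Continuity-corrected statistic `(|b - c| - 1)^2 / (b + c)` on the
#' discordant counts (`b`: correct for A only, `c`: correct for B only),
#' with p from the chi-square distribution (1 df). When `b + c < 25` the
#' exact binomial two-sided p-value is used instead. `b + c = 0` gives
#' p = 1 by convention.
#'
#' @param a,b logical vectors of per-item correctness for the two systems,
#'   same length and item order.
#' @return list with `statistic`, `p_value`, `b`, `c`, `method`.
#' @export
mcnemar_paired <- function(a, b) {
  stopifnot(length(a) == length(b))
  n10 <- sum(a & !b)
  n01 <- sum(!a & b)
  if (n10 + n01 == 0L) {
    return(list(statistic = 0, p_value = 1, b = n10, c = n01,
                method = "degenerate"))
  }
  if (n10 + n01 < 25L) {
    p <- stats::binom.test(n10, n10 + n01, 0.5)$p.value
    stat <- (abs(n10 - n01) - 1)^2 / (n10 + n01)
    return(list(statistic = stat, p_value = p, b = n10, c = n01,
                method = "exact-binomial"))
  }
  stat <- (abs(n10 - n01) - 1)^2 / (n10 + n01)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       b = n10, c = n01, method = "chi-square")
}

#' Render a metrics report as a delimited table
#'
#' One row per construct plus the macro/micro rows, level-metric columns
#' (`exact_precision`, ..., `patient_f1`).
#'
#' @param report a [metrics_report()].
#' @param path optional output TSV path.
#' @return the wide data.frame, invisibly written to `path` if given.
#' @export
render_metrics <- function(report, path = NULL) {
  wide <- data.frame(construct = report$exact$construct,
                     stringsAsFactors = FALSE)
  for (lv in c("exact", "partial", "note", "patient")) {
    for (m in c("precision", "recall", "f1")) {
      wide[[paste(lv, m, sep = "_")]] <- report[[lv]][[m]]
    }
  }
  if (!is.null(path)) {
    utils::write.table(wide, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(wide)
}
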