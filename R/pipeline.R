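# End-to-end orchestration: building training sequences from annotated
# patients, hyperparameter grid search on validation data, prediction
# with optional ICD9 label post-processing, the rule-based ICD9-only
# baseline, the feature-ablation runner, and the scaled synthetic
# recovery benchmark.

#' Build CRF training sequences from patients
#'
#' Preprocesses every note (sections, sentences, tokens, POS, entity
#' attributes), extracts features under the given configuration and
#' BIO-encodes the gold spans.
#'
#' @param patients list of `gstag_patient`.
#' @param config a [feature_config()].
#' @param lexicons [default_lexicons()]-style list.
#' @return list of `list(features, tags)` sequences, one per sentence.
#' @export
build_sequences <- function(patients, config = feature_config(),
                            lexicons = default_lexicons()) {
  out <- list()
  for (p in patients) {
    for (nt in p$notes) {
      ann <- annotate_note(nt)
      fz <- featurize(ann, config, lexicons)
      bio <- to_bio(ann)
      for (k in seq_along(fz)) {
        out[[length(out) + 1L]] <- list(features = fz[[k]]$features,
                                        tags = bio[[k]]$tag)
      }
    }
  }
  out
}

#' ICD9-Annotation label post-processing
#'
#' For every token whose normalized form is a code in the construct map,
#' the predicted label is overwritten with that construct: `I-c` if the
#' previous token already carries construct `c`, else `B-c`. All other
#' labels are unchanged. Idempotent.
#'
#' @param tags character vector of predicted BIO tags.
#' @param tokens aligned token table (column `text`).
#' @param icd9_map an [load_icd9_map()].
#' @return corrected tag vector.
#' @export
icd9_annotation_post <- function(tags, tokens, icd9_map) {
  lookup <- attr(icd9_map, "lookup")
  for (i in seq_along(tags)) {
    cc <- lookup[normalize_icd9_token(tokens$text[i])]
    if (is.na(cc)) next
    prev_cc <- if (i > 1L && tags[i - 1L] != "O") {
      sub("^[BI]-", "", tags[i - 1L])
    } else NA_character_
    tags[i] <- if (!is.na(prev_cc) && prev_cc == cc) paste0("I-", cc)
               else paste0("B-", cc)
  }
  tags
}

#' Predict construct spans for patients
#'
#' Viterbi-decodes every sentence and converts the BIO tags to character
#' spans. With `post = TRUE` the ICD9 label post-processing
#' ([icd9_annotation_post()]) is applied to the tag sequences before span
#' extraction.
#'
#' @param model a trained `crf_model`.
#' @param patients list of `gstag_patient`.
#' @param config the [feature_config()] the model was trained with.
#' @param lexicons lexicon bundle.
#' @param post apply ICD9 label post-processing.
#' @return data.frame of predicted spans with `note_id`, `patient_id`,
#'   `construct`, `start`, `end`, `text`.
#' @export
predict_spans <- function(model, patients, config = feature_config(),
                          lexicons = default_lexicons(),
                          post = isTRUE(config$icd9_annotation_post)) {
  out <- list()
  for (p in patients) {
    for (nt in p$notes) {
      ann <- annotate_note(nt)
      fz <- featurize(ann, config, lexicons)
      for (sent in fz) {
        tags <- viterbi(model, sent$features)
        if (post) tags <- icd9_annotation_post(tags, sent$tokens,
                                               lexicons$icd9_map)
        sp <- spans_from_bio(tags, sent$tokens, nt$note_id, nt$text)
        if (nrow(sp) > 0L) {
          sp$patient_id <- p$patient_id
          out[[length(out) + 1L]] <- as.data.frame(sp)
        }
      }
    }
  }
  if (length(out) == 0L) {
    df <- as.data.frame(empty_spans())
    df$patient_id <- character(0)
    return(df)
  }
  do.call(rbind, out)
}

#' Rule-based ICD9-only baseline
#'
#' Predicts a single-token span of construct `c` for every note token
#' whose normalized form is a mapped ICD9 code; no CRF involved. On text
#' where constructs are expressed lexically rather than as codes this
#' baseline has very low recall.
#'
#' @param patients list of `gstag_patient`.
#' @param icd9_map an [load_icd9_map()].
#' @return predicted span data.frame as in [predict_spans()].
#' @export
icd9_rule_baseline <- function(patients, icd9_map = load_icd9_map()) {
  lookup <- attr(icd9_map, "lookup")
  out <- list()
  for (p in patients) {
    for (nt in p$notes) {
      toks <- tokenize(nt$text)
      if (nrow(toks) == 0L) next
      cc <- lookup[normalize_icd9_token(toks$text)]
      hit <- which(!is.na(cc))
      for (i in hit) {
        out[[length(out) + 1L]] <- data.frame(
          note_id = nt$note_id, construct = unname(cc[i]),
          start = toks$start[i], end = toks$end[i], text = toks$text[i],
          patient_id = p$patient_id, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    df <- as.data.frame(empty_spans())
    df$patient_id <- character(0)
    return(df)
  }
  do.call(rbind, out)
}

#' The default hyperparameter grid
#'
#' L2 strengths crossed with maximum epoch counts; includes the
#' historically best-performing point (l2 = 0.2, 100 iterations).
#' @return data.frame with columns `l2`, `max_iterations`.
#' @export
default_grid <- function() {
  expand.grid(l2 = c(0.01, 0.05, 0.1, 0.2, 0.5, 1.0),
              max_iterations = c(50L, 100L))
}

#' Grid-search hyperparameter tuning
#'
#' Trains one SGD model per grid point on the training patients and
#' selects by microaveraged phrase-partial F1 on the validation patients
#' (the fixed selection metric; the API never sees a test split). Ties
#' are broken by smaller l2, then fewer iterations.
#'
#' @param train,validation lists of `gstag_patient`.
#' @param config a [feature_config()].
#' @param grid data.frame with columns `l2`, `max_iterations`.
#' @param lexicons lexicon bundle.
#' @param seed integer seed (training shuffles).
#' @param verbose log progress.
#' @return list: `model` (best), `grid_report` (data.frame of grid point
#'   scores), `best` (row of the winning point).
#' @export
tune <- function(train, validation, config = feature_config(),
                 grid = default_grid(), lexicons = default_lexicons(),
                 seed = 1L, verbose = FALSE) {
  stopifnot(nrow(grid) >= 1L)
  train_seqs <- build_sequences(train, config, lexicons)
  gold_valid <- gold_spans(validation)
  report <- grid
  report$f1 <- NA_real_
  models <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    m <- crf_train_sgd(train_seqs, l2 = grid$l2[g],
                       max_iterations = grid$max_iterations[g],
                       seed = seed, track_objective = FALSE)
    pred <- predict_spans(m, validation, config, lexicons)
    rep_ <- aggregate_counts(match_phrase(gold_valid, pred, "partial"))
    report$f1[g] <- metric_cell(rep_, metric = "f1")
    models[[g]] <- m
    if (verbose) {
      gstag_log(sprintf("grid l2=%g iters=%d: partial micro-F1 %.3f",
                        grid$l2[g], grid$max_iterations[g], report$f1[g]),
                level = "INFO")
    }
  }
  ord <- order(-report$f1, report$l2, report$max_iterations)
  best <- ord[1]
  list(model = models[[best]], grid_report = report, best = report[best, ])
}

#' Feature-ablation experiment
#'
#' Runs basic features alone, basic plus each named single feature
#' family, and any explicitly listed combinations; each run is tuned
#' independently on the validation set, and McNemar's test compares every
#' run against the basic-features run on paired per-gold-mention
#' phrase-partial correctness.
#'
#' @param train,validation lists of `gstag_patient`.
#' @param families character vector of single feature flags to ablate
#'   (names of [feature_config()] arguments).
#' @param combinations named list of [feature_config()] objects for
#'   multi-family rows.
#' @param grid hyperparameter grid per run.
#' @param lexicons lexicon bundle.
#' @param seed integer seed.
#' @return data.frame: one row per configuration with macro/micro P, R,
#'   F1 (phrase-partial, validation) and the McNemar p-value vs basic.
#' @export
ablate <- function(train, validation, families = character(0),
                   combinations = list(), grid = default_grid(),
                   lexicons = default_lexicons(), seed = 1L) {
  configs <- list(basic = feature_config())
  for (fam in families) {
    args <- stats::setNames(list(TRUE), fam)
    configs[[paste0("basic+", fam)]] <- do.call(feature_config, args)
  }
  for (nm in names(combinations)) configs[[nm]] <- combinations[[nm]]
  gold_valid <- gold_spans(validation)
  rows <- list()
  basic_decisions <- NULL
  for (nm in names(configs)) {
    cfg <- configs[[nm]]
    tuned <- tune(train, validation, cfg, grid, lexicons, seed)
    pred <- predict_spans(tuned$model, validation, cfg, lexicons)
    rep_ <- aggregate_counts(match_phrase(gold_valid, pred, "partial"))
    decisions <- gold_decisions(gold_valid, pred)
    p_val <- NA_real_
    if (nm == "basic") basic_decisions <- decisions
    else p_val <- mcnemar_paired(basic_decisions, decisions)$p_value
    rows[[nm]] <- data.frame(
      configuration = nm,
      l2 = tuned$best$l2, max_iterations = tuned$best$max_iterations,
      macro_precision = metric_cell(rep_, average = "Macroaverage",
                                    metric = "precision"),
      macro_recall = metric_cell(rep_, average = "Macroaverage",
                                 metric = "recall"),
      macro_f1 = metric_cell(rep_, average = "Macroaverage", metric = "f1"),
      micro_precision = metric_cell(rep_, metric = "precision"),
      micro_recall = metric_cell(rep_, metric = "recall"),
      micro_f1 = metric_cell(rep_, metric = "f1"),
      mcnemar_p = p_val,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "configs") <- configs
  out
}

#' Scaled synthetic recovery benchmark
#'
#' Generates a lexically separable synthetic corpus, splits it by patient
#' (60/20/20 by default), tunes a full-feature CRF on train/validation
#' and evaluates it on the held-out test patients. With `holdout > 0`, a
#' vocabulary shift is applied to the designated constructs' test
#' lexicons (the train corpus is unchanged), reproducing the
#' out-of-vocabulary recall loss seen on real clinical text. Corpus and
#' training sizes are deliberately desk-scale; see the package vignette.
#'
#' @param seed integer master seed for corpus generation, splitting and
#'   training.
#' @param sizes patients per split.
#' @param holdout vocabulary-shift holdout fraction for `shift_constructs`.
#' @param shift_constructs constructs whose test lexicon is shifted.
#' @param grid hyperparameter grid (small by design).
#' @param config optional `synth_config` override for the corpus scale.
#' @param lexicons lexicon bundle.
#' @param tuned optional [tune()] result to reuse: a vocabulary shift
#'   only alters the test lexicons, so the paired no-shift model can be
#'   evaluated on the shifted test corpus without retraining.
#' @param verbose log progress.
#' @return list: `report` ([metrics_report()] on test), `tuned` (the
#'   [tune()] result), `test_patients`, `train_patients`,
#'   `validation_patients`, `pred` (test predictions).
#' @export
synthetic_benchmark <- function(seed = 1L, sizes = c(60L, 20L, 20L),
                                holdout = 0,
                                shift_constructs = c("ML", "UC"),
                                grid = data.frame(l2 = c(0.1, 0.2),
                                                  max_iterations = 20L),
                                config = NULL,
                                lexicons = default_lexicons(),
                                tuned = NULL, verbose = FALSE) {
  if (is.null(config)) {
    base_mentions <- eval(formals(synth_config)$mentions_per_patient)
    config <- synth_config(
      n_patients = sum(sizes),
      notes_per_patient_mean = 3,
      filler_sentences_per_note = 5,
      mentions_per_patient = pmin(base_mentions, 6),
      seed = derive_seed(seed, "benchmark-corpus"))
  }
  shifted <- vocabulary_shift(config, holdout, shift_constructs)
  cfg_train <- shifted$train
  cfg_train$n_patients <- sizes[1] + sizes[2]
  cfg_test <- shifted$test
  cfg_test$n_patients <- sizes[3]
  cfg_test$seed <- derive_seed(config$seed, "test-part")
  pats_tv <- generate(cfg_train, lexicons$icd9_map)
  split_tv <- split_by_patient(pats_tv, c(sizes[1], sizes[2], 0L),
                               seed = derive_seed(seed, "split"))
  test_pats <- generate(cfg_test, lexicons$icd9_map)
  fcfg <- full_feature_config()
  if (is.null(tuned)) {
    tuned <- tune(split_tv$train, split_tv$validation, fcfg, grid, lexicons,
                  seed = derive_seed(seed, "train"), verbose = verbose)
  }
  pred <- predict_spans(tuned$model, test_pats, fcfg, lexicons)
  gold <- gold_spans(test_pats)
  list(report = metrics_report(gold, pred), tuned = tuned,
       train_patients = split_tv$train,
       validation_patients = split_tv$validation,
       test_patients = test_pats, pred = pred, config = config)
}
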