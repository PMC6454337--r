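# Shared fixtures and independent oracles used across the suite.

# A small random CRF instance: L labels, F feature types, T positions
# with random feature activations and standard-normal weights.
random_toy_crf <- function(T_, L, F_, seed) {
  withr::local_seed(seed)
  labels <- paste0("y", seq_len(L))
  fnames <- paste0("f", seq_len(F_))
  m <- crf_model(labels, fnames, l2 = 0)
  m$state[] <- rnorm(F_ * L)
  m$trans[] <- rnorm(L * L)
  feats <- lapply(seq_len(T_), function(t) {
    k <- sample(fnames, sample.int(F_, 1L))
    k
  })
  list(model = m, feats = feats)
}

# Exhaustive path enumeration: every label sequence with its score.
enum_paths <- function(model, feats) {
  L <- length(model$labels)
  T_ <- length(feats)
  grid <- do.call(expand.grid, rep(list(seq_len(L)), T_))
  scores <- apply(grid, 1L, function(idx) {
    score_path(model, feats, model$labels[as.integer(idx)])
  })
  list(grid = grid, scores = scores)
}

enum_logZ <- function(model, feats) {
  sc <- enum_paths(model, feats)$scores
  m <- max(sc)
  m + log(sum(exp(sc - m)))
}

enum_best <- function(model, feats) {
  ep <- enum_paths(model, feats)
  best <- which.max(ep$scores)
  sorted <- sort(ep$scores, decreasing = TRUE)
  list(score = ep$scores[best],
       path = model$labels[as.integer(ep$grid[best, ])],
       unique = length(sorted) == 1L || (sorted[1] - sorted[2]) > 1e-9)
}

# Brute-force optimal one-to-one span matching (single note, single
# construct): maximum number of gold/pred pairs under the criterion.
opt_match_count <- function(gold, pred, mode) {
  ok <- function(i, j) {
    if (mode == "exact") {
      pred$start[i] == gold$start[j] && pred$end[i] == gold$end[j]
    } else {
      pred$start[i] < gold$end[j] && gold$start[j] < pred$end[i]
    }
  }
  recurse <- function(i, used) {
    if (i > nrow(pred)) return(0L)
    best <- recurse(i + 1L, used)  # leave prediction i unmatched
    for (j in seq_len(nrow(gold))) {
      if (!used[j] && ok(i, j)) {
        used2 <- used; used2[j] <- TRUE
        best <- max(best, 1L + recurse(i + 1L, used2))
      }
    }
    best
  }
  recurse(1L, rep(FALSE, nrow(gold)))
}

# Random span set for one note: gold spans non-overlapping (the gold
# contract); predictions unconstrained.
random_span_instance <- function(seed, max_spans = 6L) {
  withr::local_seed(seed)
  n_gold <- sample.int(max_spans + 1L, 1L) - 1L
  n_pred <- sample.int(max_spans + 1L, 1L) - 1L
  codes <- sample(construct_codes(), 2L)
  mk_gold <- function(n) {
    if (n == 0L) return(as.data.frame(gstag:::empty_spans()))
    starts <- sort(sample.int(60L, n))
    lens <- sample.int(3L, n, replace = TRUE)
    starts <- starts + cumsum(c(0L, lens[-n] + 1L))  # enforce gaps
    data.frame(note_id = "n1", construct = sample(codes, n, replace = TRUE),
               start = starts, end = starts + lens,
               text = strrep("x", lens), stringsAsFactors = FALSE)
  }
  mk_pred <- function(n) {
    if (n == 0L) return(as.data.frame(gstag:::empty_spans()))
    starts <- sample.int(80L, n, replace = TRUE)
    lens <- sample.int(4L, n, replace = TRUE)
    data.frame(note_id = "n1", construct = sample(codes, n, replace = TRUE),
               start = starts, end = starts + lens,
               text = strrep("x", lens), stringsAsFactors = FALSE)
  }
  list(gold = mk_gold(n_gold), pred = mk_pred(n_pred))
}

# A tiny deterministic annotated note with two gold spans.
fixture_note <- function() {
  txt <- paste0("Assessment:\nPatient has dementia and reports worse memory",
                " today . She suffered a fall this past Tuesday .")
  fall_at <- as.integer(regexpr("a fall", txt)) - 1L
  make_note("n1", "p1", txt,
            make_span("n1", c("DE", "FL"), c(20L, fall_at),
                      c(32L, fall_at + 6L), c("has dementia", "a fall")))
}

# Small separable training corpus where each construct is cued by a
# unique token.
toy_corpus <- function(n_patients = 8L, seed = 11L) {
  cfg <- synth_config(n_patients = n_patients, notes_per_patient_mean = 2,
                      filler_sentences_per_note = 3,
                      mentions_per_patient = stats::setNames(
                        rep(3, 10), construct_codes()),
                      seed = seed)
  generate(cfg)
}
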