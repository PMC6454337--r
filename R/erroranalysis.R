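# Error analysis: construct-specific bigram language models with add-k
# smoothing and perplexity, out-of-vocabulary rates of test mentions
# relative to training mentions, and a gold-error confusion breakdown
# (missed vs confused-with-another-construct).

.BOS <- "<s>"
.EOS <- "</s>"
.UNK <- "<unk>"

#' Fit a construct-specific bigram language model
#'
#' Trains on the token sequences of a construct's mentions. Sequences are
#' padded with a start symbol and an end symbol; unigram and bigram counts
#' are add-k smoothed: `P(w|h) = (c(h,w) + k) / (c(h) + k*V)` where the
#' event vocabulary (size `V`) is the training types plus the unknown and
#' end symbols. Conditional probabilities sum to 1 over that vocabulary
#' for every history.
#'
#' @param mentions list of character vectors (token sequences of mentions).
#' @param k add-k smoothing parameter (> 0 for finite held-out perplexity).
#' @return a `bigram_lm`.
#' @export
fit_bigram <- function(mentions, k = 1) {
  if (length(mentions) == 0L) stop("empty training mentions")
  mentions <- lapply(mentions, tolower)
  vocab <- sort(unique(unlist(mentions)))
  events <- c(vocab, .UNK, .EOS)        # what can follow a history
  histories <- c(vocab, .UNK, .BOS)
  big <- matrix(0L, length(histories), length(events),
                dimnames = list(histories, events))
  hist_count <- stats::setNames(rep(0L, length(histories)), histories)
  for (m in mentions) {
    seq_ <- c(.BOS, m, .EOS)
    for (i in seq_len(length(seq_) - 1L)) {
      h <- seq_[i]; w <- seq_[i + 1L]
      big[h, w] <- big[h, w] + 1L
      hist_count[h] <- hist_count[h] + 1L
    }
  }
  structure(list(vocab = vocab, events = events, histories = histories,
                 bigram = big, hist_count = hist_count, k = k),
            class = "bigram_lm")
}

#' Conditional probability table of a bigram LM
#' @param lm a `bigram_lm`.
#' @param history history token (mapped to the unknown symbol if unseen).
#' @return named numeric vector over the event vocabulary, summing to 1.
#' @export
bigram_cond <- function(lm, history) {
  history <- tolower(history)
  if (!history %in% lm$histories) history <- .UNK
  V <- length(lm$events)
  (lm$bigram[history, ] + lm$k) / (lm$hist_count[[history]] + lm$k * V)
}

#' Perplexity of a bigram LM on mention token sequences
#'
#' `PP = 2^(-(1/N) * sum log2 P(w_i | w_{i-1}))` over all transitions of
#' all mentions, including the transition into the end symbol (`N` = total
#' transitions). Tokens outside the training vocabulary are mapped to the
#' unknown symbol. Any log base gives the same PP; base 2 is used.
#'
#' @param lm a `bigram_lm`.
#' @param mentions list of character vectors.
#' @return positive real; always >= 1 for a proper model.
#' @export
perplexity <- function(lm, mentions) {
  total <- 0; n <- 0L
  for (m in mentions) {
    m <- tolower(m)
    m[!m %in% lm$vocab] <- .UNK
    seq_ <- c(.BOS, m, .EOS)
    for (i in seq_len(length(seq_) - 1L)) {
      p <- bigram_cond(lm, seq_[i])[[seq_[i + 1L]]]
      total <- total + log2(p)
      n <- n + 1L
    }
  }
  if (n == 0L) stop("no transitions to evaluate")
  2^(-total / n)
}

#' Out-of-vocabulary rate of test mentions
#'
#' Fraction of test-mention token instances whose type never occurs in the
#' training mentions (of the same construct). Case-insensitive.
#'
#' @param train_mentions,test_mentions lists of character vectors.
#' @return fraction in \[0, 1\].
#' @export
oov_rate <- function(train_mentions, test_mentions) {
  train_vocab <- unique(tolower(unlist(train_mentions)))
  test_tokens <- tolower(unlist(test_mentions))
  if (length(test_tokens) == 0L) return(0)
  mean(!test_tokens %in% train_vocab)
}

#' Mention texts per construct from a patient list
#'
#' Tokenizes every gold span's surface text; grouped by construct.
#'
#' @param patients list of `gstag_patient`.
#' @return named list (construct code -> list of token vectors).
#' @export
construct_mentions <- function(patients) {
  gs <- gold_spans(patients)
  out <- stats::setNames(vector("list", 10L), construct_codes())
  for (cc in construct_codes()) {
    texts <- gs$text[gs$construct == cc]
    out[[cc]] <- lapply(texts, function(tx) tokenize(tx)$text)
  }
  out
}

#' Per-construct perplexity and OOV report
#'
#' Fits one bigram LM per construct on training mentions and evaluates
#' perplexity on that construct's test mentions, alongside the OOV rate.
#' Constructs with no training or no test mentions get NA.
#'
#' @param train_patients,test_patients patient lists.
#' @param k smoothing parameter.
#' @return data.frame: `construct`, `n_train`, `n_test`, `oov_rate`,
#'   `perplexity`.
#' @export
perplexity_report <- function(train_patients, test_patients, k = 1) {
  tr <- construct_mentions(train_patients)
  te <- construct_mentions(test_patients)
  rows <- lapply(construct_codes(), function(cc) {
    pp <- NA_real_; ov <- NA_real_
    if (length(tr[[cc]]) > 0L && length(te[[cc]]) > 0L) {
      pp <- perplexity(fit_bigram(tr[[cc]], k), te[[cc]])
      ov <- oov_rate(tr[[cc]], te[[cc]])
    }
    data.frame(construct = cc, n_train = length(tr[[cc]]),
               n_test = length(te[[cc]]), oov_rate = ov, perplexity = pp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cross-construct confusion breakdown of gold-span errors
#'
#' Classifies every unmatched gold span (an error) as `missed` (no
#' overlapping prediction at all) or `confused` (overlapped by a
#' prediction of a different construct); spurious predictions (overlapping
#' no gold span) are counted once each. Reports the confusion matrix
#' over (gold construct, predicted construct) for confused errors and the
#' missed fraction `missed / (missed + confused)`.
#'
#' @param gold,pred span tables (`note_id`, `construct`, `start`, `end`).
#' @return list: `table` (10 x 10 matrix gold x predicted), `missed`
#'   (named count per gold construct), `spurious` (count), `n_missed`,
#'   `n_confused`, `missed_fraction`.
#' @export
confusion <- function(gold, pred) {
  codes <- construct_codes()
  tab <- matrix(0L, 10L, 10L, dimnames = list(gold = codes, pred = codes))
  missed <- stats::setNames(rep(0L, 10L), codes)
  pred_used <- rep(FALSE, nrow(pred))
  for (i in seq_len(nrow(gold))) {
    same_note <- pred$note_id == gold$note_id[i]
    ov <- same_note & pred$start < gold$end[i] & gold$start[i] < pred$end
    correct <- ov & pred$construct == gold$construct[i]
    if (any(correct)) { pred_used[correct] <- TRUE; next }  # not an error
    if (any(ov)) {
      pc <- pred$construct[which(ov)[1]]
      tab[gold$construct[i], pc] <- tab[gold$construct[i], pc] + 1L
      pred_used[ov] <- TRUE
    } else {
      missed[gold$construct[i]] <- missed[gold$construct[i]] + 1L
    }
  }
  n_missed <- sum(missed)
  n_confused <- sum(tab)
  frac <- if (n_missed + n_confused > 0) n_missed / (n_missed + n_confused)
          else NA_real_
  list(table = tab, missed = missed, spurious = sum(!pred_used),
       n_missed = n_missed, n_confused = n_confused,
       missed_fraction = frac)
}
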