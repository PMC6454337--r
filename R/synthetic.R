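# Seeded generator of synthetic annotated clinical corpora with the
# statistical structure of a geriatric primary-care note corpus: skewed
# per-construct patient prevalence, construct-specific mention
# frequencies and mention lengths, sparse construct tokens (< 1% of all
# tokens), embedded ICD9 code tokens, section headers, and
# negated/family-subject decoy sentences that must not be annotated.
# Notes are templated filler text (not a language model) so that
# generation is fully deterministic under a seed.

# Construct-specific phrase word pools, 12 words each. Pools are
# disjoint from each other and from the filler/template vocabulary, so
# corpora built from them are lexically separable by construct;
# ambiguity is injected explicitly (weight-loss decoys) rather than
# accidentally. The first 6 words of each pool feed the main phrase
# lexicon, the last 6 the held-out lexicon; the halves have disjoint
# Porter stems, so a vocabulary shift produces genuine word-level OOV
# that neither the word-identity nor the stem feature can bridge.
.phrase_pools <- list(
  BC = c("fecal", "soiling", "bowel", "accidents", "encopresis", "stool",
         "seepage", "smearing", "involuntary", "defecation", "messes",
         "diarrheal"),
  DE = c("dementia", "memory", "cognitive", "confusion", "forgetful",
         "disoriented",
         "alzheimers", "senile", "amnestic", "bewildered", "muddled",
         "lapses"),
  FL = c("fall", "fell", "tripped", "slipped", "stumbled", "balance",
         "tumbled", "toppled", "collapsed", "spill", "lightheaded",
         "wobbled"),
  WL = c("weight", "loss", "losing", "pounds", "unintentional", "dropped",
         "thinner", "shrinking", "kilograms", "wasting", "slimmer",
         "gaunt"),
  ML = c("malnutrition", "intake", "undernourished", "appetite",
         "inadequate", "nutrition",
         "cachexia", "emaciated", "anorexia", "malnourished", "deficient",
         "underweight"),
  PU = c("decubitus", "ulcer", "pressure", "sore", "sacral", "wound",
         "bedsore", "eschar", "necrotic", "blistered", "heel",
         "breakdown"),
  SS = c("alone", "isolated", "widowed", "unsupported", "companionless",
         "estranged",
         "lonely", "solitary", "abandoned", "friendless", "secluded",
         "reclusive"),
  UC = c("urinary", "catheter", "bladder", "incontinence", "urgency",
         "leakage",
         "enuresis", "dribbling", "foley", "nocturia", "voiding",
         "wetting"),
  VI = c("vision", "blind", "visual", "impaired", "cataracts", "blurry",
         "glaucoma", "macular", "degeneration", "eyesight", "sightless",
         "dimming"),
  WD = c("walking", "walker", "ambulates", "gait", "unsteady", "cane",
         "shuffling", "limping", "mobility", "hobbling", "wheelchair",
         "imbalance")
)

.pool_main <- function(cc) .phrase_pools[[cc]][1:6]
.pool_held <- function(cc) .phrase_pools[[cc]][7:12]

# Mention sentence templates: prefix/suffix around the annotated phrase.
# Free of trigger words and of all phrase-pool tokens.
.mention_templates <- list(
  c("Patient reports ", " since the last visit ."),
  c("She has been experiencing ", " over the past month ."),
  c("He describes ", " at home recently ."),
  c("Exam today notable for ", " again ."),
  c("Ongoing ", " was discussed at length ."),
  c("Chart documents ", " this year ."),
  c("Visit prompted by ", " per intake form .")
)

# Neutral filler sentences; share no tokens with the phrase pools.
.filler_templates <- c(
  "Medication refill requested by phone today .",
  "Lab results reviewed and within normal limits .",
  "Follow up visit scheduled in two weeks .",
  "Patient seen in office for routine evaluation .",
  "Plan reviewed and questions answered in detail .",
  "Vitals obtained and recorded by nursing staff .",
  "Continue current medications as prescribed .",
  "Phone call returned regarding appointment request .",
  "Chronic conditions remain stable on current regimen .",
  "Influenza vaccine administered without complication .",
  "Records requested from outside facility .",
  "Reviewed allergies and updated the problem list .",
  "Letter sent to patient summarizing recommendations .",
  "Telephone encounter documented for the record .",
  "Routine screening discussed and declined for now ."
)

.decoy_neg_templates <- list(
  c("Denies any ", " at this time ."),
  c("No ", " reported today .")
)

.decoy_family_templates <- list(
  c("Daughter mentions her own ", " during the visit ."),
  c("Husband reports ", " himself this year .")
)

.wl_decoy_sentences <- c(
  "Patient is overweight and actively trying to lose weight .",
  "Discussed intentional weight loss program and diet goals .",
  "She is pleased about losing weight on her exercise plan ."
)

.section_header_pool <- c("Assessment", "Plan", "Patient Medical History",
                          "History of Present Illness", "Review of Systems")

.encounter_mix <- c(phone_call = 0.378, office_visit = 0.302, refill = 0.116,
                    letter = 0.032, notation = 0.026, other = 0.146)

# Sample a phrase lexicon for one construct: `n` variants whose token
# lengths follow a shifted Poisson with the given mean. Duplicates are
# kept so that every lexicon has exactly `n` entries (main and held-out
# lexicons of equal length keep paired generator runs on identical
# random streams).
.make_lexicon <- function(pool, n, mean_len) {
  vapply(seq_len(n), function(i) {
    L <- 1L + stats::rpois(1L, max(mean_len - 1, 0.01))
    L <- min(max(L, 1L), 8L)
    paste(sample(pool, L, replace = L > length(pool)), collapse = " ")
  }, character(1))
}

#' Configuration for the synthetic corpus generator
#'
#' Defaults are the study conditions of the corpus the generator
#' emulates: 185 patients; per-construct patient prevalence from the
#' annotated training-set distribution (e.g. walking difficulty 0.66,
#' malnutrition 0.09); per-construct mean mentions per positive patient
#' (e.g. lack of social support 15.23) and mean mention length in tokens
#' (2.04-4.03); about 46 notes per patient with enough filler text that
#' construct tokens are roughly 0.76% of all tokens; encounter-type mix
#' of a primary-care population (phone calls 37.8%, office visits 30.2%,
#' refills 11.6%, ...). Two phrase-variant pools are drawn per construct
#' (main + held-out) so [vocabulary_shift()] can induce controlled
#' out-of-vocabulary rates.
#'
#' @param n_patients number of patients.
#' @param notes_per_patient_mean mean notes per patient (shifted Poisson).
#' @param filler_sentences_per_note mean filler sentences per note.
#' @param prevalence named per-construct patient prevalence in \[0, 1\].
#' @param mentions_per_patient named per-construct mean mention count per
#'   positive patient.
#' @param mention_length named per-construct mean mention length (tokens).
#' @param lexicon_variants phrase variants per construct per pool.
#' @param icd9_rate probability a positive (patient, construct) also gets
#'   an embedded, annotated ICD9 code token.
#' @param negation_rate,family_rate probability of an unannotated
#'   negated / family-subject decoy sentence per positive construct.
#' @param wl_decoy_rate probability per note of an unannotated
#'   intentional-weight-loss decoy sentence (see
#'   [weight_loss_ambiguity()]).
#' @param header_prob probability a note starts with a section header.
#' @param seed integer seed; drives lexicon sampling and generation.
#' @return a `synth_config` list (includes sampled `lexicons` and
#'   `holdout_lexicons`).
#' @export
synth_config <- function(n_patients = 185L,
                         notes_per_patient_mean = 45.6,
                         filler_sentences_per_note = 44,
                         prevalence = c(BC = 0.14, DE = 0.18, FL = 0.44,
                                        WL = 0.25, ML = 0.09, PU = 0.11,
                                        SS = 0.62, UC = 0.19, VI = 0.19,
                                        WD = 0.66),
                         mentions_per_patient = c(BC = 2.67, DE = 13.00,
                                                  FL = 9.04, WL = 13.53,
                                                  ML = 13.92, PU = 5.67,
                                                  SS = 15.23, UC = 13.71,
                                                  VI = 9.31, WD = 12.59),
                         mention_length = c(BC = 2.98, DE = 2.76, FL = 3.37,
                                            WL = 3.01, ML = 2.04, PU = 3.48,
                                            SS = 4.03, UC = 2.94, VI = 3.62,
                                            WD = 3.43),
                         lexicon_variants = 24L,
                         icd9_rate = 0.3,
                         negation_rate = 0.15,
                         family_rate = 0.10,
                         wl_decoy_rate = 0,
                         header_prob = 0.6,
                         seed = 1L) {
  codes <- construct_codes()
  stopifnot(all(codes %in% names(prevalence)),
            all(prevalence >= 0 & prevalence <= 1),
            all(codes %in% names(mentions_per_patient)),
            all(codes %in% names(mention_length)))
  if (any(mention_length > 8)) {
    stop("mention_length means above 8 tokens exceed the sentence templates")
  }
  lex <- with_seed(derive_seed(seed, "lexicons"), {
    main <- lapply(codes, function(cc) {
      .make_lexicon(.pool_main(cc), lexicon_variants, mention_length[[cc]])
    })
    held <- lapply(codes, function(cc) {
      .make_lexicon(.pool_held(cc), lexicon_variants, mention_length[[cc]])
    })
    list(main = stats::setNames(main, codes),
         held = stats::setNames(held, codes))
  })
  if (any(!vapply(lex$main, length, 1L))) stop("empty construct lexicon")
  structure(list(n_patients = as.integer(n_patients),
                 notes_per_patient_mean = notes_per_patient_mean,
                 filler_sentences_per_note = filler_sentences_per_note,
                 prevalence = prevalence[codes],
                 mentions_per_patient = mentions_per_patient[codes],
                 mention_length = mention_length[codes],
                 lexicons = lex$main, holdout_lexicons = lex$held,
                 icd9_rate = icd9_rate, negation_rate = negation_rate,
                 family_rate = family_rate, wl_decoy_rate = wl_decoy_rate,
                 header_prob = header_prob, seed = as.integer(seed)),
            class = "synth_config")
}

# One sentence destined for a note: text plus (optionally) the relative
# offsets of an annotated phrase inside it.
.mention_sentence <- function(phrase, construct, templates = .mention_templates) {
  tpl <- templates[[sample.int(length(templates), 1L)]]
  list(text = paste0(tpl[1], phrase, tpl[2]),
       rel_start = nchar(tpl[1]), rel_end = nchar(tpl[1]) + nchar(phrase),
       construct = construct)
}

.plain_sentence <- function(text) {
  list(text = text, rel_start = NA_integer_, rel_end = NA_integer_,
       construct = NA_character_)
}

# Generate one patient: sample incidence, mentions, decoys, codes; spread
# sentences over notes; build note text and exact gold offsets.
.generate_patient <- function(pid, config, icd9_by_construct) {
  codes <- construct_codes()
  present <- stats::runif(10L) < config$prevalence
  special <- list()
  for (ci in which(present)) {
    cc <- codes[ci]
    n_m <- 1L + stats::rpois(1L, max(config$mentions_per_patient[[cc]] - 1, 0))
    lex <- config$lexicons[[cc]]
    for (j in seq_len(n_m)) {
      special[[length(special) + 1L]] <-
        .mention_sentence(lex[[sample.int(length(lex), 1L)]], cc)
    }
    if (stats::runif(1L) < config$icd9_rate &&
        length(icd9_by_construct[[cc]]) > 0L) {
      code <- sample(icd9_by_construct[[cc]], 1L)
      s <- list(text = paste0("Dx code ", code, " on problem list ."),
                rel_start = 8L, rel_end = 8L + nchar(code), construct = cc)
      special[[length(special) + 1L]] <- s
    }
    if (stats::runif(1L) < config$negation_rate) {
      tpl <- .decoy_neg_templates[[sample.int(2L, 1L)]]
      word <- sample(.pool_main(cc), 1L)
      special[[length(special) + 1L]] <-
        .plain_sentence(paste0(tpl[1], word, tpl[2]))
    }
    if (stats::runif(1L) < config$family_rate) {
      tpl <- .decoy_family_templates[[sample.int(2L, 1L)]]
      word <- sample(.pool_main(cc), 1L)
      special[[length(special) + 1L]] <-
        .plain_sentence(paste0(tpl[1], word, tpl[2]))
    }
  }
  n_notes <- 1L + stats::rpois(1L, max(config$notes_per_patient_mean - 1, 0))
  assignment <- if (length(special)) sample.int(n_notes, length(special),
                                                replace = TRUE) else integer(0)
  notes <- vector("list", n_notes)
  for (k in seq_len(n_notes)) {
    nid <- sprintf("%s-N%03d", pid, k)
    n_fill <- 1L + stats::rpois(1L, max(config$filler_sentences_per_note - 1, 0))
    fill <- .filler_templates[sample.int(length(.filler_templates), n_fill,
                                         replace = TRUE)]
    sents <- lapply(fill, .plain_sentence)
    if (stats::runif(1L) < config$wl_decoy_rate) {
      sents[[length(sents) + 1L]] <- .plain_sentence(
        .wl_decoy_sentences[sample.int(length(.wl_decoy_sentences), 1L)])
    }
    for (si in which(assignment == k)) {
      sents[[length(sents) + 1L]] <- special[[si]]
    }
    sents <- sents[sample.int(length(sents))]
    header <- if (stats::runif(1L) < config$header_prob) {
      paste0(.section_header_pool[sample.int(length(.section_header_pool), 1L)],
             ":")
    } else NULL
    texts <- vapply(sents, `[[`, "", "text")
    body_starts <- cumsum(c(0L, nchar(texts) + 1L))[seq_along(texts)]
    offset <- if (is.null(header)) 0L else nchar(header) + 1L
    note_text <- paste(c(header, paste(texts, collapse = " ")),
                       collapse = "\n")
    spans <- list()
    for (si in seq_along(sents)) {
      s <- sents[[si]]
      if (!is.na(s$construct)) {
        st <- offset + body_starts[si] + s$rel_start
        en <- offset + body_starts[si] + s$rel_end
        spans[[length(spans) + 1L]] <- data.frame(
          note_id = nid, construct = s$construct,
          start = st, end = en,
          text = substring(note_text, st + 1L, en),
          stringsAsFactors = FALSE)
      }
    }
    sp <- if (length(spans)) {
      df <- do.call(rbind, spans)
      class(df) <- c("gstag_spans", "data.frame")
      df
    } else empty_spans()
    etype <- sample(names(.encounter_mix), 1L, prob = .encounter_mix)
    notes[[k]] <- make_note(nid, pid, note_text, sp, etype)
  }
  make_patient(pid, notes)
}

#' Generate a synthetic annotated corpus
#'
#' Per patient: construct incidence is sampled from the configured
#' prevalences; each positive construct contributes a shifted-Poisson
#' number of mention sentences (phrases from the construct's lexicon,
#' with exact gold offsets recorded), optionally an annotated embedded
#' ICD9 code token, and optionally unannotated negated and family-subject
#' decoy sentences; notes are padded with neutral filler sentences and
#' optionally opened by a section header. Deterministic for a fixed
#' config seed.
#'
#' @param config a [synth_config()].
#' @param icd9_map construct map used for embedded codes (default:
#'   shipped map).
#' @return list of `gstag_patient` with validated gold spans.
#' @export
generate <- function(config, icd9_map = load_icd9_map()) {
  stopifnot(inherits(config, "synth_config"))
  icd9_by_construct <- split(icd9_map$code, icd9_map$construct)
  with_seed(derive_seed(config$seed, "generate"), {
    lapply(seq_len(config$n_patients), function(i) {
      .generate_patient(sprintf("P%04d", i), config, icd9_by_construct)
    })
  })
}

#' Split lexicons to induce a controlled out-of-vocabulary rate
#'
#' Returns a train config and a test config. For each designated
#' construct, the test config's lexicon replaces a fraction `holdout` of
#' its phrase variants with variants from the held-out pool, which the
#' train config never uses: `holdout = 0` leaves the configs identical,
#' `holdout = 1` makes the test variants disjoint from training,
#' intermediate values give intermediate measured OOV rates.
#'
#' @param config a [synth_config()].
#' @param holdout fraction in \[0, 1\].
#' @param constructs construct codes to shift (default: all 10).
#' @return list with elements `train` and `test` (both `synth_config`).
#' @export
vocabulary_shift <- function(config, holdout,
                             constructs = construct_codes()) {
  stopifnot(holdout >= 0, holdout <= 1)
  train <- config
  test <- config
  if (holdout == 0) return(list(train = train, test = test))
  for (cc in constructs) {
    main <- config$lexicons[[cc]]
    held <- config$holdout_lexicons[[cc]]
    n <- length(main)
    n_held <- max(1L, round(holdout * n))
    n_keep <- n - n_held
    kept <- if (n_keep > 0L) main[seq_len(n_keep)] else character(0)
    test$lexicons[[cc]] <- c(kept, held[seq_len(min(n_held, length(held)))])
  }
  list(train = train, test = test)
}

#' Inject intentional-weight-loss ambiguity
#'
#' Returns a config whose generated notes contain unannotated sentences
#' about intentional weight loss ("trying to lose weight") at the given
#' per-note rate. These decoys share surface tokens with annotated
#' weight-loss mentions, reproducing the hardest confusion of the task as
#' a controllable stressor: they carry no gold spans by construction.
#'
#' @param config a [synth_config()].
#' @param intentional_fraction per-note decoy probability in \[0, 1\].
#' @return modified `synth_config`.
#' @export
weight_loss_ambiguity <- function(config, intentional_fraction) {
  stopifnot(intentional_fraction >= 0, intentional_fraction <= 1)
  config$wl_decoy_rate <- intentional_fraction
  config
}

#' Corpus-level token statistics of a patient list
#'
#' Tokenizes every note and counts the fraction of tokens covered by gold
#' construct spans.
#'
#' @param patients list of `gstag_patient`.
#' @return list with `n_tokens`, `n_construct_tokens`, `construct_token_rate`.
#' @export
corpus_token_stats <- function(patients) {
  total <- 0L
  inside <- 0L
  for (p in patients) {
    for (nt in p$notes) {
      toks <- tokenize(nt$text)
      total <- total + nrow(toks)
      if (nrow(nt$spans) > 0L) {
        for (i in seq_len(nrow(nt$spans))) {
          inside <- inside +
            sum(toks$end > nt$spans$start[i] & toks$start < nt$spans$end[i])
        }
      }
    }
  }
  list(n_tokens = total, n_construct_tokens = inside,
       construct_token_rate = inside / total)
}
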