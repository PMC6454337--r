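# Rule-based clinical text preprocessing: section segmentation, sentence
# segmentation, tokenization, coarse POS tagging, and detection of
# negation / uncertainty / subject attributes. These are deterministic
# stand-ins with the same output contracts as the clinical pipeline tools
# (cTAKES-class systems) typically used for these steps, so the package has
# no external tool dependency; the tagger and attribute detector are
# pluggable via arguments.

# -- sections -----------------------------------------------------------

#' Default section header lexicon
#'
#' Maps normalized header strings (lowercase, no trailing colon) to
#' canonical section keys. Shipped as an editable plain-text config
#' (`inst/extdata/section_headers.tsv`).
#'
#' @return data.frame with columns `header`, `name`.
#' @export
default_section_headers <- function() {
  utils::read.delim(gstag_extdata("section_headers.tsv"),
                    stringsAsFactors = FALSE, comment.char = "#")
}

#' Segment a clinical note into sections
#'
#' Scans for line-anchored, case-insensitive header lines (optionally
#' colon-terminated) from a header lexicon. Each match opens a section that
#' extends to the next match or the end of the note. Text before the first
#' header, or a note with no recognized header, is a section named
#' `"other"`. Sections tile the note: `[start, end)` character offsets,
#' 0-based.
#'
#' @param text note text.
#' @param header_lexicon data.frame with columns `header`, `name`
#'   (default: shipped lexicon).
#' @return data.frame with columns `name`, `header`, `start`, `end`.
#' @export
segment_sections <- function(text, header_lexicon = default_section_headers()) {
  cols <- c("name", "header", "start", "end")
  empty <- data.frame(name = character(), header = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (!nzchar(text)) return(empty)
  n <- nchar(text)
  hits <- data.frame(start = integer(), name = character(),
                     header = character(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(header_lexicon))) {
    h <- header_lexicon$header[i]
    pat <- paste0("(?mi)^[ \\t]*", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", h),
                  "[ \\t]*:?[ \\t]*$")
    m <- gregexpr(pat, text, perl = TRUE)[[1]]
    if (m[1] != -1L) {
      hits <- rbind(hits, data.frame(
        start = as.integer(m) - 1L, name = header_lexicon$name[i],
        header = h, stringsAsFactors = FALSE))
    }
  }
  hits <- hits[order(hits$start), , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(data.frame(name = "other", header = NA_character_,
                      start = 0L, end = n, stringsAsFactors = FALSE))
  }
  out <- empty
  if (hits$start[1] > 0L) {
    out <- rbind(out, data.frame(name = "other", header = NA_character_,
                                 start = 0L, end = hits$start[1],
                                 stringsAsFactors = FALSE))
  }
  ends <- c(hits$start[-1], n)
  out <- rbind(out, data.frame(name = hits$name, header = hits$header,
                               start = hits$start, end = ends,
                               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out[, cols]
}

# -- sentences ----------------------------------------------------------

# Abbreviations that never end a sentence when followed by a period.
.abbrevs <- c("dr", "mr", "mrs", "ms", "pt", "pts", "vs", "eg", "ie", "etc",
              "approx", "dx", "hx", "fx", "tx", "rx", "prn", "qd", "bid",
              "tid", "wk", "mo", "yr", "no")

#' Split text into sentences
#'
#' Rule-based segmentation on `.`, `!`, `?` and newlines, with guards: a
#' period inside a decimal number or ICD9-shaped code (e.g. `250.00`) and a
#' period after a known clinical abbreviation (`Dr.`, `pt.`, `Dx.`) never
#' split. Returned ranges are 0-based half-open character offsets covering
#' the non-whitespace content of each sentence.
#'
#' @param text input text (typically one section of a note).
#' @param offset integer added to all returned offsets (so sentences of a
#'   section carry note-level offsets).
#' @return data.frame with columns `start`, `end`.
#' @export
split_sentences <- function(text, offset = 0L) {
  empty <- data.frame(start = integer(), end = integer())
  if (!nzchar(text) || !grepl("[^[:space:]]", text)) return(empty)
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  is_digit <- function(ch) grepl("[0-9]", ch)
  boundaries <- integer(0)  # index AFTER which a sentence ends (1-based)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("!", "?", "\n")) {
      boundaries <- c(boundaries, i)
    } else if (ch == ".") {
      prev <- if (i > 1L) chars[i - 1L] else ""
      nxt <- if (i < n) chars[i + 1L] else ""
      split_here <- TRUE
      # decimal / ICD9-shaped: digit.digit never splits
      if (is_digit(prev) && is_digit(nxt)) split_here <- FALSE
      if (split_here) {
        # word before the period
        j <- i - 1L
        while (j >= 1L && grepl("[A-Za-z]", chars[j])) j <- j - 1L
        word <- tolower(paste0(chars[seq.int(j + 1L, length.out = i - 1L - j)],
                               collapse = ""))
        if (word %in% .abbrevs) split_here <- FALSE
      }
      if (split_here) boundaries <- c(boundaries, i)
    }
    i <- i + 1L
  }
  boundaries <- unique(c(boundaries, n))
  out <- empty
  seg_start <- 1L
  for (b in boundaries) {
    seg <- substr(text, seg_start, b)
    if (grepl("[^[:space:]]", seg)) {
      # trim to non-whitespace extent
      lead <- regexpr("[^[:space:]]", seg)
      trail <- regexpr("[^[:space:]][[:space:]]*$", seg)
      out <- rbind(out, data.frame(start = seg_start - 1L + lead - 1L,
                                   end = seg_start - 1L + trail))
    }
    seg_start <- b + 1L
  }
  out$start <- as.integer(out$start + offset)
  out$end <- as.integer(out$end + offset)
  rownames(out) <- NULL
  out
}

# -- tokenization -------------------------------------------------------

# Token pattern: ICD9-shaped / decimal numbers with an internal period stay
# single tokens; then alphanumeric runs; then single punctuation marks.
.token_pattern <- "[VE]?[0-9]+\\.[0-9]+|[A-Za-z0-9]+(?:/[A-Za-z0-9]+)*|[^A-Za-z0-9[:space:]]"

#' Tokenize a sentence
#'
#' Splits on whitespace and punctuation. Numbers with an internal period
#' (decimals and ICD9-shaped codes such as `707.0` or `V60.4`) and
#' slash-joined alphanumerics (`r/o`) are kept as single tokens;
#' punctuation is emitted as separate tokens.
#'
#' @param text sentence text.
#' @param offset integer added to all returned offsets.
#' @return data.frame with columns `text`, `start`, `end` (0-based
#'   half-open, relative to `text` plus `offset`).
#' @export
tokenize <- function(text, offset = 0L) {
  if (!nzchar(text)) {
    return(data.frame(text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  m <- gregexpr(.token_pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  data.frame(text = substring(text, starts, starts + lens - 1L),
             start = as.integer(starts - 1L + offset),
             end = as.integer(starts - 1L + lens + offset),
             stringsAsFactors = FALSE)
}

# -- POS tagging --------------------------------------------------------

.pos_lexicon <- c(
  she = "PRON", he = "PRON", it = "PRON", they = "PRON", i = "PRON",
  patient = "NOUN", pt = "NOUN", daughter = "NOUN", husband = "NOUN",
  wife = "NOUN", son = "NOUN", family = "NOUN", home = "NOUN",
  the = "DET", a = "DET", an = "DET", this = "DET", that = "DET",
  and = "CONJ", or = "CONJ", but = "CONJ",
  of = "ADP", `in` = "ADP", on = "ADP", with = "ADP", at = "ADP",
  to = "PRT", not = "ADV", no = "ADV", very = "ADV", slowly = "ADV",
  is = "VERB", was = "VERB", has = "VERB", had = "VERB", have = "VERB",
  be = "VERB", been = "VERB", are = "VERB", fell = "VERB", feels = "VERB",
  denies = "VERB", reports = "VERB", uses = "VERB", walks = "VERB"
)

#' Coarse part-of-speech tagging
#'
#' Deterministic lexicon + suffix rule tagger over the universal coarse
#' tagset (NOUN, VERB, ADJ, ADV, PRON, DET, ADP, NUM, CONJ, PRT, PUNCT, X).
#' The contract required downstream is determinism and alignment with the
#' token sequence, not linguistic accuracy; a different tagger can be
#' plugged into [annotate_note()].
#'
#' @param tokens character vector of token texts (one sentence).
#' @return character vector of tags, same length.
#' @export
pos_tag <- function(tokens) {
  if (length(tokens) == 0L) return(character(0))
  vapply(tokens, function(tok) {
    low <- tolower(tok)
    if (grepl("^[^A-Za-z0-9]+$", tok)) return("PUNCT")
    if (grepl("^[VE]?[0-9]+(\\.[0-9]+)?$", tok)) return("NUM")
    if (!is.na(.pos_lexicon[low])) return(unname(.pos_lexicon[low]))
    if (grepl("(ing|ed|ates|izes)$", low)) return("VERB")
    if (grepl("(ly)$", low)) return("ADV")
    if (grepl("(ous|ful|ible|able|al|ive)$", low)) return("ADJ")
    if (grepl("^[a-z]", tok) || grepl("^[A-Z]", tok)) return("NOUN")
    "X"
  }, character(1), USE.NAMES = FALSE)
}

# -- entity attributes --------------------------------------------------

#' Default negation/uncertainty/subject trigger lexicons
#' @return named list of character vectors `negation`, `uncertainty`,
#'   `subject`, read from the shipped editable YAML config.
#' @export
default_triggers <- function() {
  yaml::read_yaml(gstag_extdata("triggers.yaml"))
}

#' Detect negation, uncertainty and subject attributes per token
#'
#' Forward-scope rule in the NegEx tradition: a trigger token (or bigram)
#' marks the following tokens of the same sentence, up to `window` tokens
#' or a scope terminator (`but`, `.` or `,`). Negation triggers set
#' `negated`, uncertainty triggers set `uncertain`, subject triggers set
#' `subject = "family_member"`. Defaults are `(FALSE, FALSE, "patient")`.
#' Scopes never cross sentence boundaries because the function is applied
#' per sentence.
#'
#' @param tokens character vector of one sentence's token texts.
#' @param triggers named list as from [default_triggers()].
#' @param window scope window in tokens (default 5).
#' @return data.frame with columns `negated`, `uncertain`, `subject`.
#' @export
entity_attributes <- function(tokens, triggers = default_triggers(),
                              window = 5L) {
  n <- length(tokens)
  out <- data.frame(negated = rep(FALSE, n), uncertain = rep(FALSE, n),
                    subject = rep("patient", n), stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  low <- tolower(tokens)
  terminators <- c("but", ".", ",")
  mark <- function(from, col, value) {
    i <- from
    while (i <= n && i < from + window) {
      if (low[i] %in% terminators) break
      out[i, col] <<- value
      i <- i + 1L
    }
  }
  trig <- function(set) {
    set <- tolower(set)
    singles <- set[!grepl(" ", set)]
    bigrams <- strsplit(set[grepl(" ", set)], " ", fixed = TRUE)
    hits <- which(low %in% singles)
    for (bg in bigrams) {
      for (i in seq_len(max(0L, n - 1L))) {
        if (low[i] == bg[1] && low[i + 1L] == bg[2]) hits <- c(hits, i + 1L)
      }
    }
    sort(unique(hits))
  }
  for (i in trig(triggers$negation)) mark(i + 1L, "negated", TRUE)
  for (i in trig(triggers$uncertainty)) mark(i + 1L, "uncertain", TRUE)
  for (i in trig(triggers$subject)) mark(i + 1L, "subject", "family_member")
  out
}

# -- full annotation ----------------------------------------------------

#' Run the full preprocessing pipeline on a note
#'
#' Segments sections and sentences, tokenizes, POS-tags and attaches
#' entity attributes. The result is the note with `$sections` and
#' `$sentences` filled in; each sentence carries a token table with
#' offsets, POS tags, section name, and attribute columns.
#'
#' @param note an `gstag_note` (see [make_note()]).
#' @param header_lexicon section header lexicon.
#' @param triggers attribute trigger lexicons.
#' @param tagger POS tagging function `tokens -> tags` (pluggable).
#' @param attribute_fun attribute function `(tokens, triggers) -> data.frame`.
#' @return the note, annotated.
#' @export
annotate_note <- function(note, header_lexicon = default_section_headers(),
                          triggers = default_triggers(),
                          tagger = pos_tag,
                          attribute_fun = entity_attributes) {
  secs <- segment_sections(note$text, header_lexicon)
  sentences <- list()
  for (si in seq_len(max(1L, nrow(secs)))) {
    if (nrow(secs) == 0L) break
    sec <- secs[si, ]
    sec_text <- substr(note$text, sec$start + 1L, sec$end)
    sents <- split_sentences(sec_text, offset = sec$start)
    for (k in seq_len(nrow(sents))) {
      stext <- substr(note$text, sents$start[k] + 1L, sents$end[k])
      toks <- tokenize(stext, offset = sents$start[k])
      if (nrow(toks) == 0L) next
      toks$pos <- tagger(toks$text)
      attrs <- attribute_fun(toks$text, triggers)
      toks <- cbind(toks, attrs)
      toks$section_name <- sec$name
      sentences[[length(sentences) + 1L]] <- list(
        start = sents$start[k], end = sents$end[k],
        section = sec$name, tokens = toks)
    }
  }
  note$sections <- secs
  note$sentences <- sentences
  note
}
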