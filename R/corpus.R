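# Data model for patients, notes and construct spans, with readers/writers
# for BRAT-style standoff and CoNLL-style vertical files, BIO
# encoding/decoding, and patient-level corpus splitting.
#
# Conventions: character offsets are 0-based half-open [start, end); gold
# spans never overlap (overlaps are an input error); splits are always by
# patient, never by note.

#' Create a construct span
#'
#' @param note_id note identifier.
#' @param construct two-letter construct code.
#' @param start,end 0-based half-open character offsets into the note text.
#' @param text verbatim substring of the note at `[start, end)`.
#' @return one-row data.frame with class `gstag_spans`.
#' @export
make_span <- function(note_id, construct, start, end, text) {
  stopifnot(all(is_valid_construct(construct)), all(start < end), all(start >= 0))
  df <- data.frame(note_id = note_id, construct = construct,
                   start = as.integer(start), end = as.integer(end),
                   text = text, stringsAsFactors = FALSE)
  class(df) <- c("gstag_spans", "data.frame")
  df
}

empty_spans <- function() {
  make_span("x", "FL", 0L, 1L, "x")[0, , drop = FALSE]
}

#' Create a clinical note
#'
#' @param note_id,patient_id identifiers.
#' @param text full note text.
#' @param spans `gstag_spans` data.frame of gold construct spans (may be
#'   empty). Validated: offsets in range, `text` matches the note
#'   substring, no overlaps.
#' @param encounter_type optional encounter type label.
#' @return a `gstag_note` list.
#' @export
make_note <- function(note_id, patient_id, text, spans = empty_spans(),
                      encounter_type = NA_character_) {
  spans <- as.data.frame(spans)
  if (nrow(spans) > 0L) {
    spans <- spans[order(spans$start), , drop = FALSE]
    rownames(spans) <- NULL
    n <- nchar(text)
    bad <- spans$start < 0L | spans$end > n | spans$start >= spans$end
    if (any(bad)) {
      stop("note ", note_id, ": span offsets out of range [0, ", n, ")")
    }
    if (!all(spans$note_id == note_id)) {
      stop("note ", note_id, ": span references a different note_id")
    }
    mism <- substring(text, spans$start + 1L, spans$end) != spans$text
    if (any(mism)) {
      stop("note ", note_id, ": span surface text mismatch at offset ",
           spans$start[which(mism)[1]])
    }
    if (nrow(spans) > 1L && any(spans$start[-1] < spans$end[-nrow(spans)])) {
      stop("note ", note_id, ": overlapping gold spans")
    }
  }
  class(spans) <- c("gstag_spans", "data.frame")
  structure(list(note_id = note_id, patient_id = patient_id, text = text,
                 encounter_type = encounter_type, spans = spans,
                 sections = NULL, sentences = NULL),
            class = "gstag_note")
}

#' Create a patient
#' @param patient_id identifier.
#' @param notes list of `gstag_note`, ids unique within the patient.
#' @return a `gstag_patient` list.
#' @export
make_patient <- function(patient_id, notes) {
  ids <- vapply(notes, `[[`, "", "note_id")
  if (anyDuplicated(ids)) stop("patient ", patient_id, ": duplicate note ids")
  structure(list(patient_id = patient_id, notes = notes),
            class = "gstag_patient")
}

#' @export
print.gstag_note <- function(x, ...) {
  cat(sprintf("<note %s patient %s: %d chars, %d gold spans>\n",
              x$note_id, x$patient_id, nchar(x$text), nrow(x$spans)))
  invisible(x)
}

#' @export
print.gstag_patient <- function(x, ...) {
  cat(sprintf("<patient %s: %d notes>\n", x$patient_id, length(x$notes)))
  invisible(x)
}

# -- standoff I/O -------------------------------------------------------

#' Read a corpus from note texts plus BRAT-style standoff annotations
#'
#' Notes live under `notes_path` as one UTF-8 `.txt` file per note, named
#' `<patient_id>___<note_id>.txt` (or provide a `notes.tsv` table with
#' columns `note_id`, `patient_id`, `text`, and optionally
#' `encounter_type`, where `\\n` in `text` encodes a newline). Annotations
#' live under `annotations_path` as one `.ann` per note
#' (`<patient_id>___<note_id>.ann`) with BRAT lines
#' `T1<TAB>FL start end<TAB>surface`. A missing `.ann` file means the note
#' has no gold spans.
#'
#' @param notes_path directory of note files or path to a `notes.tsv`.
#' @param annotations_path directory of `.ann` files; `NULL` for none.
#' @return list of `gstag_patient`.
#' @export
read_standoff <- function(notes_path, annotations_path = NULL) {
  notes <- list()
  if (dir.exists(notes_path)) {
    files <- sort(list.files(notes_path, pattern = "\\.txt$", full.names = TRUE))
    for (f in files) {
      stem <- sub("\\.txt$", "", basename(f))
      parts <- strsplit(stem, "___", fixed = TRUE)[[1]]
      if (length(parts) != 2L) stop("cannot parse patient/note id from ", f)
      notes[[stem]] <- list(note_id = parts[2], patient_id = parts[1],
                            text = paste(readLines(f, warn = FALSE,
                                                   encoding = "UTF-8"),
                                         collapse = "\n"),
                            encounter_type = NA_character_)
    }
  } else {
    tab <- utils::read.delim(notes_path, stringsAsFactors = FALSE,
                             quote = "", comment.char = "")
    for (i in seq_len(nrow(tab))) {
      stem <- paste0(tab$patient_id[i], "___", tab$note_id[i])
      notes[[stem]] <- list(
        note_id = as.character(tab$note_id[i]),
        patient_id = as.character(tab$patient_id[i]),
        text = gsub("\\n", "\n", tab$text[i], fixed = TRUE),
        encounter_type = if ("encounter_type" %in% names(tab))
          tab$encounter_type[i] else NA_character_)
    }
  }
  built <- list()
  for (stem in names(notes)) {
    nt <- notes[[stem]]
    spans <- empty_spans()
    if (!is.null(annotations_path)) {
      annf <- file.path(annotations_path, paste0(stem, ".ann"))
      if (file.exists(annf)) {
        spans <- parse_brat(readLines(annf, warn = FALSE, encoding = "UTF-8"),
                            nt$note_id)
      }
    }
    built[[stem]] <- make_note(nt$note_id, nt$patient_id, nt$text, spans,
                               nt$encounter_type)
  }
  pids <- vapply(built, `[[`, "", "patient_id")
  lapply(split(built, pids)[unique(pids)], function(nts) {
    make_patient(nts[[1]]$patient_id, unname(nts))
  })
}

# Parse BRAT standoff text-bound annotation lines for one note.
parse_brat <- function(lines, note_id) {
  lines <- lines[grepl("^T", lines)]
  if (length(lines) == 0L) return(empty_spans())
  out <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) stop("malformed standoff line in note ", note_id,
                                 ": ", ln)
    mid <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
    code <- mid[1]
    if (!is_valid_construct(code)) {
      stop("note ", note_id, ": unknown construct code '", code, "'")
    }
    data.frame(note_id = note_id, construct = code,
               start = as.integer(mid[2]), end = as.integer(mid[3]),
               text = parts[3], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  class(df) <- c("gstag_spans", "data.frame")
  df
}

#' Write a corpus as note texts plus BRAT standoff annotations
#'
#' Inverse of [read_standoff()] (directory layout). Round-trips losslessly.
#'
#' @param patients list of `gstag_patient`.
#' @param notes_path,annotations_path output directories (created).
#' @export
write_standoff <- function(patients, notes_path, annotations_path) {
  dir.create(notes_path, recursive = TRUE, showWarnings = FALSE)
  dir.create(annotations_path, recursive = TRUE, showWarnings = FALSE)
  for (p in patients) {
    for (nt in p$notes) {
      stem <- paste0(p$patient_id, "___", nt$note_id)
      writeLines(nt$text, file.path(notes_path, paste0(stem, ".txt")),
                 useBytes = TRUE)
      sp <- nt$spans
      lines <- character(0)
      if (nrow(sp) > 0L) {
        lines <- sprintf("T%d\t%s %d %d\t%s", seq_len(nrow(sp)),
                         sp$construct, sp$start, sp$end, sp$text)
      }
      writeLines(lines, file.path(annotations_path, paste0(stem, ".ann")),
                 useBytes = TRUE)
    }
  }
  invisible(NULL)
}

# -- BIO encoding -------------------------------------------------------

#' Encode a note's gold spans as per-sentence BIO tag sequences
#'
#' Each token fully inside a gold span of construct `c` is tagged `B-c` at
#' the span-initial token and `I-c` otherwise; all other tokens are `O`.
#' Span boundaries that do not align with token boundaries are snapped
#' outward to the enclosing tokens (each snap is logged at DEBUG level). A
#' span crossing a sentence boundary is truncated at the boundary with a
#' logged warning.
#'
#' @param note an annotated `gstag_note` (see [annotate_note()]).
#' @return list, one element per sentence, each a data.frame of the
#'   sentence's token table plus a `tag` column.
#' @export
to_bio <- function(note) {
  if (is.null(note$sentences)) stop("note must be annotated first")
  spans <- note$spans
  lapply(note$sentences, function(sent) {
    toks <- sent$tokens
    toks$tag <- "O"
    if (nrow(spans) > 0L) {
      for (i in seq_len(nrow(spans))) {
        s <- spans$start[i]; e <- spans$end[i]
        hit <- which(toks$end > s & toks$start < e)  # any overlap, snaps outward
        if (length(hit) == 0L) next
        if (s < sent$start || e > sent$end) {
          gstag_log("span [", s, ",", e, ") truncated at sentence boundary in note ",
                    note$note_id, level = "WARN")
        }
        if (toks$start[hit[1]] != s || toks$end[hit[length(hit)]] != e) {
          gstag_log("span [", s, ",", e, ") snapped to token boundaries in note ",
                    note$note_id, level = "DEBUG")
        }
        toks$tag[hit[1]] <- paste0("B-", spans$construct[i])
        if (length(hit) > 1L) {
          toks$tag[hit[-1]] <- paste0("I-", spans$construct[i])
        }
      }
    }
    toks
  })
}

#' Decode a BIO tag sequence into construct spans
#'
#' Total function over arbitrary tag sequences, including invalid ones from
#' a decoder: an `I-c` not preceded by `B-c` or `I-c` of the same construct
#' is repaired as `B-c`. Character offsets are taken from the first and
#' last token of each run.
#'
#' @param tags character vector of BIO tags.
#' @param tokens data.frame with `text`, `start`, `end` aligned to `tags`.
#' @param note_id note identifier stamped on the output spans.
#' @param note_text optional note text used to fill the spans' verbatim
#'   surface; if `NULL` the token texts are joined with single spaces.
#' @return `gstag_spans` data.frame.
#' @export
spans_from_bio <- function(tags, tokens, note_id = "note", note_text = NULL) {
  stopifnot(length(tags) == nrow(tokens))
  n <- length(tags)
  out <- list()
  i <- 1L
  while (i <= n) {
    t <- tags[i]
    if (t == "O") { i <- i + 1L; next }
    code <- sub("^[BI]-", "", t)
    j <- i + 1L
    while (j <= n && tags[j] == paste0("I-", code)) j <- j + 1L
    s <- tokens$start[i]; e <- tokens$end[j - 1L]
    surface <- if (is.null(note_text)) {
      paste(tokens$text[i:(j - 1L)], collapse = " ")
    } else substring(note_text, s + 1L, e)
    out[[length(out) + 1L]] <- data.frame(
      note_id = note_id, construct = code, start = s, end = e,
      text = surface, stringsAsFactors = FALSE)
    i <- j
  }
  if (length(out) == 0L) return(empty_spans())
  df <- do.call(rbind, out)
  class(df) <- c("gstag_spans", "data.frame")
  df
}

# -- CoNLL-style I/O ----------------------------------------------------

#' Write sentences as a CoNLL-style vertical token/tag file
#'
#' One `token<TAB>tag` line per token, blank line between sentences.
#'
#' @param bio list of sentence token tables with a `tag` column ([to_bio()]).
#' @param path output file.
#' @export
write_conll <- function(bio, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (sent in bio) {
    writeLines(paste(sent$text, sent$tag, sep = "\t"), con)
    writeLines("", con)
  }
  invisible(NULL)
}

#' Read a CoNLL-style vertical token/tag file
#' @param path input file.
#' @return list of data.frames with columns `text`, `tag`.
#' @export
read_conll <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  sents <- list()
  cur <- list()
  flush <- function() {
    if (length(cur) > 0L) {
      sents[[length(sents) + 1L]] <<- do.call(rbind, cur)
      cur <<- list()
    }
  }
  for (ln in lines) {
    if (!nzchar(ln)) { flush(); next }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    cur[[length(cur) + 1L]] <- data.frame(text = parts[1], tag = parts[2],
                                          stringsAsFactors = FALSE)
  }
  flush()
  sents
}

# -- splitting ----------------------------------------------------------

#' Split patients into train/validation/test sets by patient
#'
#' Seeded shuffle then partition; deterministic for a fixed seed. The
#' split is always by patient, never by note, so no patient's notes leak
#' across parts.
#'
#' @param patients list of `gstag_patient`.
#' @param sizes integer vector `(train, validation, test)`; default the
#'   85/50/50 design used with a 185-patient corpus.
#' @param seed integer seed.
#' @return list with elements `train`, `validation`, `test`.
#' @export
split_by_patient <- function(patients, sizes = c(85L, 50L, 50L), seed = 1L) {
  stopifnot(length(sizes) == 3L)
  if (length(patients) < sum(sizes)) {
    stop("need at least ", sum(sizes), " patients, got ", length(patients))
  }
  perm <- with_seed(seed, sample.int(length(patients)))
  shuffled <- patients[perm]
  i1 <- seq_len(sizes[1])
  i2 <- sizes[1] + seq_len(sizes[2])
  i3 <- sizes[1] + sizes[2] + seq_len(sizes[3])
  list(train = shuffled[i1], validation = shuffled[i2], test = shuffled[i3])
}

#' Collect all gold spans of a patient list
#'
#' One data.frame over every note of every patient, with a `patient_id`
#' column added — the shape the evaluation functions consume.
#'
#' @param patients list of `gstag_patient`.
#' @return data.frame: `note_id`, `construct`, `start`, `end`, `text`,
#'   `patient_id`.
#' @export
gold_spans <- function(patients) {
  out <- list()
  for (p in patients) {
    for (nt in p$notes) {
      if (nrow(nt$spans) > 0L) {
        sp <- nt$spans
        sp$patient_id <- p$patient_id
        out[[length(out) + 1L]] <- as.data.frame(sp)
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
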