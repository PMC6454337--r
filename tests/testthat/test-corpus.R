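test_that("standoff reader attaches validated spans to patients", {
  notes_dir <- withr::local_tempdir()
  ann_dir <- withr::local_tempdir()
  txt <- "She suffered a fall this past Tuesday"
  writeLines(txt, file.path(notes_dir, "p1___n1.txt"))
  writeLines("T1\tFL 13 19\ta fall", file.path(ann_dir, "p1___n1.ann"))
  pats <- read_standoff(notes_dir, ann_dir)
  expect_length(pats, 1L)
  expect_s3_class(pats[[1]], "gstag_patient")
  sp <- pats[[1]]$notes[[1]]$spans
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$construct, "FL")
  expect_equal(sp$text, "a fall")
  expect_equal(substring(txt, sp$start + 1L, sp$end), "a fall")
})

test_that("standoff reader handles empty annotations and rejects bad input", {
  notes_dir <- withr::local_tempdir()
  ann_dir <- withr::local_tempdir()
  writeLines("No syndromes here", file.path(notes_dir, "p1___n1.txt"))
  writeLines(character(0), file.path(ann_dir, "p1___n1.ann"))
  pats <- read_standoff(notes_dir, ann_dir)
  expect_equal(nrow(pats[[1]]$notes[[1]]$spans), 0L)

  # span end beyond the text
  writeLines("T1\tFL 0 999\tx", file.path(ann_dir, "p1___n1.ann"))
  expect_error(read_standoff(notes_dir, ann_dir), "out of range")
  # unknown construct code
  writeLines("T1\tZZ 0 2\tNo", file.path(ann_dir, "p1___n1.ann"))
  expect_error(read_standoff(notes_dir, ann_dir), "unknown construct")
  # overlapping gold spans
  writeLines(c("T1\tFL 0 4\tNo s", "T2\tDE 2 7\t synd"),
             file.path(ann_dir, "p1___n1.ann"))
  expect_error(read_standoff(notes_dir, ann_dir), "overlap")
})

test_that("corpus write/read round-trips losslessly", {
  pats <- toy_corpus(3L)
  notes_dir <- withr::local_tempdir()
  ann_dir <- withr::local_tempdir()
  write_standoff(pats, notes_dir, ann_dir)
  back <- read_standoff(notes_dir, ann_dir)
  expect_equal(length(back), length(pats))
  g1 <- gold_spans(pats)
  g2 <- gold_spans(back)
  ord <- function(g) g[order(g$note_id, g$start), c("note_id", "construct",
                                                    "start", "end", "text")]
  expect_equal(ord(g2), ord(g1), ignore_attr = TRUE)
})

test_that("BIO encoding marks span-initial tokens B and interior tokens I", {
  note <- annotate_note(fixture_note())
  bio <- to_bio(note)
  tags <- unlist(lapply(bio, `[[`, "tag"))
  toks <- unlist(lapply(bio, `[[`, "text"))
  expect_equal(tags[toks == "has"], "B-DE")
  expect_equal(tags[toks == "dementia"], "I-DE")
  expect_equal(tags[toks == "fall"], "I-FL")
  expect_equal(tags[toks == "a"], "B-FL")
  # a note with no spans is all O
  plain <- annotate_note(make_note("n2", "p1", "Nothing to report today ."))
  expect_true(all(unlist(lapply(to_bio(plain), `[[`, "tag")) == "O"))
})

test_that("BIO decode repairs dangling I tags and inverts encoding", {
  toks <- data.frame(text = c("x"), start = 0L, end = 1L)
  sp <- spans_from_bio("I-WD", toks, "n1")
  expect_equal(sp$construct, "WD")
  expect_equal(nrow(spans_from_bio("O", toks, "n1")), 0L)
  # adjacent same-construct spans each begin with B
  toks4 <- data.frame(text = c("a", "b", "c", "d"),
                      start = 0:3 * 2L, end = 0:3 * 2L + 1L)
  sp2 <- spans_from_bio(c("B-FL", "I-FL", "B-FL", "O"), toks4, "n1")
  expect_equal(nrow(sp2), 2L)
  expect_equal(sp2$start, c(0L, 4L))
})

test_that("BIO round-trip recovers random token-aligned spans", {
  for (seed in 1:25) {
    withr::local_seed(seed)
    n_tok <- 12L
    words <- replicate(n_tok, paste(sample(letters, 3L), collapse = ""))
    text <- paste(words, collapse = " ")
    toks <- tokenize(text)
    # random non-overlapping token-aligned spans
    n_sp <- sample.int(3L, 1L)
    starts_tok <- sort(sample.int(n_tok - 1L, n_sp))
    spans <- do.call(rbind, lapply(starts_tok, function(st) {
      len <- 1L
      data.frame(note_id = "n1",
                 construct = sample(construct_codes(), 1L),
                 start = toks$start[st], end = toks$end[st + len - 1L],
                 text = substring(text, toks$start[st] + 1L,
                                  toks$end[st + len - 1L]),
                 stringsAsFactors = FALSE)
    }))
    note <- annotate_note(make_note("n1", "p1", text, spans))
    bio <- to_bio(note)
    # validity: every I is preceded by B/I of the same construct
    for (s in bio) {
      for (i in seq_along(s$tag)) {
        if (startsWith(s$tag[i], "I-")) {
          cc <- sub("^I-", "", s$tag[i])
          expect_gt(i, 1L)
          expect_true(s$tag[i - 1L] %in% paste0(c("B-", "I-"), cc))
        }
      }
    }
    dec <- do.call(rbind, lapply(bio, function(s) {
      spans_from_bio(s$tag, s, "n1", text)
    }))
    ord <- function(d) d[order(d$start), c("construct", "start", "end")]
    expect_equal(ord(as.data.frame(dec)), ord(spans), ignore_attr = TRUE)
  }
})

test_that("patient splitting is disjoint, exhaustive on sizes, and seeded", {
  pats <- lapply(1:185, function(i) {
    make_patient(paste0("p", i), list(make_note(paste0("n", i), paste0("p", i),
                                                "text .")))
  })
  sp <- split_by_patient(pats, c(85L, 50L, 50L), seed = 3L)
  ids <- lapply(sp, function(part) vapply(part, `[[`, "", "patient_id"))
  expect_equal(lengths(ids), c(train = 85L, validation = 50L, test = 50L))
  expect_length(intersect(ids$train, ids$validation), 0L)
  expect_length(intersect(ids$train, ids$test), 0L)
  expect_length(intersect(ids$validation, ids$test), 0L)
  expect_setequal(unlist(ids), paste0("p", 1:185))
  sp2 <- split_by_patient(pats, c(85L, 50L, 50L), seed = 3L)
  expect_identical(lapply(sp2, function(p) vapply(p, `[[`, "", "patient_id")),
                   ids)
  expect_error(split_by_patient(pats[1:10], c(85L, 50L, 50L)), "at least")
  tiny <- split_by_patient(pats[1:3], c(1L, 1L, 1L), seed = 1L)
  expect_equal(lengths(tiny), c(train = 1L, validation = 1L, test = 1L),
               ignore_attr = TRUE)
})

test_that("CoNLL vertical format round-trips tokens and tags", {
  note <- annotate_note(fixture_note())
  bio <- to_bio(note)
  path <- withr::local_tempfile(fileext = ".conll")
  write_conll(bio, path)
  back <- read_conll(path)
  expect_length(back, length(bio))
  expect_equal(back[[2]]$text, bio[[2]]$text)
  expect_equal(back[[2]]$tag, bio[[2]]$tag)
})
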