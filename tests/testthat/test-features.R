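test_that("Porter stemmer matches canonical reference vectors", {
  vectors <- c(
    walking = "walk", falls = "fall", fall = "fall", ambulates = "ambul",
    caresses = "caress", ponies = "poni", ties = "ti", cats = "cat",
    feed = "feed", agreed = "agre", plastered = "plaster", bled = "bled",
    motoring = "motor", sing = "sing", conflated = "conflat",
    troubled = "troubl", sized = "size", hopping = "hop", tanned = "tan",
    hissing = "hiss", failing = "fail", filing = "file", happy = "happi",
    sky = "sky", relational = "relat", conditional = "condit",
    rational = "ration", valenci = "valenc", hesitanci = "hesit",
    digitizer = "digit", operator = "oper", feudalism = "feudal",
    decisiveness = "decis", hopefulness = "hope", callousness = "callous",
    formaliti = "formal", sensitiviti = "sensit", sensibiliti = "sensibl",
    triplicate = "triplic", formative = "form", formalize = "formal",
    electriciti = "electr", electrical = "electr", hopeful = "hope",
    goodness = "good", revival = "reviv", allowance = "allow",
    inference = "infer", airliner = "airlin", gyroscopic = "gyroscop",
    adjustable = "adjust", defensible = "defens", irritant = "irrit",
    replacement = "replac", adjustment = "adjust", dependent = "depend",
    adoption = "adopt", communism = "commun", activate = "activ",
    angulariti = "angular", probate = "probat", rate = "rate",
    cease = "ceas", controll = "control", roll = "roll")
  expect_equal(porter_stem(names(vectors)), unname(vectors))
  # non-letter tokens pass through lowercased
  expect_equal(porter_stem(c("707.0", "Dx", "A")), c("707.0", "dx", "a"))
})

test_that("basic window features cover 6 types at 3 positions", {
  toks <- data.frame(text = c("Ambulates", "slowly", "70"),
                     pos = c("VERB", "ADV", "NUM"),
                     stringsAsFactors = FALSE)
  f <- basic_features(toks, 1L)
  expect_true(all(c("cur:lower=ambulates", "cur:istitle=1", "cur:isupper=0",
                    "cur:word=Ambulates", "prev:BOS", "next:lower=slowly")
                  %in% f))
  f3 <- basic_features(toks, 3L)
  expect_true(all(c("cur:isnumeric=1", "next:EOS") %in% f3))
  # interior token: exactly 18 feature types
  f2 <- basic_features(toks, 2L)
  expect_length(f2, 18L)
  types <- sub("=.*$", "", f2)
  expect_length(unique(types), 18L)
  # single-token sentence gets both boundary markers
  single <- data.frame(text = "Falls", pos = "NOUN")
  fs <- basic_features(single, 1L)
  expect_true(all(c("prev:BOS", "next:EOS") %in% fs))
  expect_error(basic_features(toks, 4L), "out of range")
})

test_that("enhanced token features behave per contract", {
  lex <- default_lexicons()
  expect_equal(stem_feature("walking"), "cur:stem=walk")
  expect_equal(stem_feature("fall"), "cur:stem=fall")
  expect_equal(stem_feature("ambulates"), "cur:stem=ambul")

  expect_true(is_icd9_code("707.0", lex$icd9_universe))
  expect_true(is_icd9_code("707.0,", lex$icd9_universe))  # normalization
  expect_false(is_icd9_code("walker", lex$icd9_universe))

  expect_true(is_medical_unit("kg", lex$units))
  expect_true(is_medical_unit("mL", lex$units))  # case-insensitive
  expect_false(is_medical_unit("fall", lex$units))

  attrs <- data.frame(negated = TRUE, uncertain = FALSE, subject = "patient")
  expect_setequal(entity_attribute_features(attrs),
                  c("cur:neg=1", "cur:unc=0", "cur:subj=patient"))
  fam <- data.frame(negated = FALSE, uncertain = FALSE,
                    subject = "family_member")
  expect_true("cur:subj=family_member" %in% entity_attribute_features(fam))

  expect_equal(section_feature("family_history"), "sec=family_history")
  expect_equal(section_feature("other"), "sec=other")
})

test_that("shipped ICD9 construct map has the pinned per-construct counts", {
  map <- load_icd9_map()
  counts <- icd9_map_counts(map)
  expect_equal(unname(counts), c(2L, 58L, 45L, 15L, 26L, 35L, 14L, 14L, 55L,
                                 31L))
  expect_equal(sum(counts), 295L)
  expect_false(anyDuplicated(map$code) > 0L)
})

test_that("ICD9 annotation features fire at most one construct indicator", {
  map <- load_icd9_map()
  f <- icd9_annotation_features("707.0", map)
  expect_true("icd9ann:PU=1" %in% f)
  expect_equal(sum(grepl("=1$", f)), 1L)
  f0 <- icd9_annotation_features("walker", map)
  expect_length(f0, 10L)
  expect_true(all(grepl("=0$", f0)))
  # property: sum of the indicators is 0 or 1 for arbitrary tokens
  for (tok in c("250.00", "E880.0", "V60.0", "fall,", "707.0,", "x")) {
    expect_lte(sum(grepl("=1$", icd9_annotation_features(tok, map))), 1L)
  }
})

test_that("featurize composes families monotonically and purely", {
  note <- annotate_note(fixture_note())
  lex <- default_lexicons()
  basic <- featurize(note, feature_config(), lex)
  for (sent in basic) {
    for (f in sent$features) {
      expect_length(unique(sub("=.*$", "", f)), length(f))
    }
  }
  all_on <- featurize(note, full_feature_config(), lex)
  for (k in seq_along(basic)) {
    for (i in seq_along(basic[[k]]$features)) {
      expect_true(all(basic[[k]]$features[[i]] %in% all_on[[k]]$features[[i]]))
    }
  }
  # toggling stem off removes exactly the stem-namespaced features
  with_stem <- featurize(note, feature_config(stem = TRUE), lex)
  for (k in seq_along(basic)) {
    for (i in seq_along(basic[[k]]$features)) {
      diff <- setdiff(with_stem[[k]]$features[[i]], basic[[k]]$features[[i]])
      expect_true(all(grepl("^cur:stem=", diff)))
      expect_length(diff, 1L)
    }
  }
  # determinism
  expect_identical(featurize(note, full_feature_config(), lex), all_on)
})
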