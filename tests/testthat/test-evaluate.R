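mk <- function(note, cc, start, end, pid = "p1") {
  data.frame(note_id = note, construct = cc, start = start, end = end,
             text = strrep("x", end - start), patient_id = pid,
             stringsAsFactors = FALSE)
}

test_that("partial matching credits overlap that exact matching rejects", {
  # gold "with a walker" inside predicted "walks with a walker"
  gold <- mk("n1", "WD", 18L, 31L)
  pred <- mk("n1", "WD", 12L, 31L)
  partial <- match_phrase(gold, pred, "partial")
  exact <- match_phrase(gold, pred, "exact")
  k <- partial$construct == "WD"
  expect_equal(partial$tp[k], 1L)
  expect_equal(partial$fp[k] + partial$fn[k], 0L)
  expect_equal(exact$tp[k], 0L)
  expect_equal(exact$fp[k], 1L)
  expect_equal(exact$fn[k], 1L)
  # a different construct never matches
  wrong <- match_phrase(gold, mk("n1", "FL", 18L, 31L), "partial")
  expect_equal(sum(wrong$tp), 0L)
  expect_equal(sum(wrong$fp), 1L)
  expect_equal(sum(wrong$fn), 1L)
})

test_that("identical predictions yield all true positives at both levels", {
  gold <- rbind(mk("n1", "FL", 0L, 5L), mk("n1", "DE", 10L, 14L),
                mk("n2", "FL", 3L, 8L))
  for (mode in c("exact", "partial")) {
    cnt <- match_phrase(gold, gold, mode)
    expect_equal(sum(cnt$tp), 3L)
    expect_equal(sum(cnt$fp) + sum(cnt$fn), 0L)
  }
})

test_that("phrase count identities hold: TP+FN = gold, TP+FP = predictions", {
  for (seed in 1:30) {
    inst <- random_span_instance(seed)
    for (mode in c("exact", "partial")) {
      cnt <- match_phrase(inst$gold, inst$pred, mode)
      expect_equal(sum(cnt$tp) + sum(cnt$fn), nrow(inst$gold))
      expect_equal(sum(cnt$tp) + sum(cnt$fp), nrow(inst$pred))
    }
  }
})

test_that("greedy phrase matching equals optimal matching on small instances", {
  for (seed in 1:120) {
    inst <- random_span_instance(seed)
    for (mode in c("exact", "partial")) {
      cnt <- match_phrase(inst$gold, inst$pred, mode)
      opt <- 0L
      for (cc in unique(c(inst$gold$construct, inst$pred$construct))) {
        opt <- opt + opt_match_count(
          inst$gold[inst$gold$construct == cc, , drop = FALSE],
          inst$pred[inst$pred$construct == cc, , drop = FALSE], mode)
      }
      expect_equal(sum(cnt$tp), opt)
    }
  }
})

test_that("note and patient levels compare construct sets", {
  gold <- rbind(mk("n1", "FL", 0L, 5L, "p1"), mk("n2", "DE", 0L, 4L, "p1"))
  pred <- rbind(mk("n1", "FL", 2L, 6L, "p1"), mk("n1", "DE", 9L, 12L, "p1"))
  nt <- match_note(gold, pred)
  expect_equal(nt$tp[nt$construct == "FL"], 1L)
  expect_equal(nt$fp[nt$construct == "DE"], 1L)  # DE predicted in wrong note
  expect_equal(nt$fn[nt$construct == "DE"], 1L)
  # patient level unions notes: DE is correct for the patient
  pt <- match_patient(gold, pred)
  expect_equal(pt$tp[pt$construct == "DE"], 1L)
  expect_equal(sum(pt$fp) + sum(pt$fn), 0L)
  # repeated mentions collapse to one patient-level decision
  many <- do.call(rbind, lapply(1:15, function(i) {
    mk("n1", "SS", i * 10L, i * 10L + 3L, "p1")
  }))
  pt2 <- match_patient(many, mk("n1", "SS", 10L, 13L, "p1"))
  expect_equal(pt2$tp[pt2$construct == "SS"], 1L)
  expect_equal(sum(pt2$fn), 0L)
  # empty prediction: zero recall
  pt3 <- match_patient(gold, mk("n9", "FL", 0L, 1L, "p9")[0, ])
  expect_equal(sum(pt3$tp), 0L)
  expect_equal(sum(pt3$fn), 2L)
})

test_that("aggregation reproduces benchmark macro arithmetic", {
  ref <- reference_test_metrics()
  ex <- ref[ref$level == "exact" & ref$construct != "Microaverage", ]
  s <- summarize_pr(ex$precision, ex$recall)
  expect_lt(abs(s$macro_precision - 0.496), 5e-4)
  expect_lt(abs(s$macro_recall - 0.327), 5e-4)
  expect_lt(abs(s$macro_f1 - 0.394), 5e-4)
  # harmonic-mean identity and micro==macro for a single construct
  one <- aggregate_counts(data.frame(construct = "FL", tp = 3L, fp = 1L,
                                     fn = 2L))
  expect_equal(metric_cell(one, average = "Macroaverage", metric = "f1"),
               metric_cell(one, average = "Microaverage", metric = "f1"))
  expect_equal(one$f1[1], 2 * 0.75 * 0.6 / 1.35)
  pr_eq <- aggregate_counts(data.frame(construct = "FL", tp = 2L, fp = 2L,
                                       fn = 2L))
  expect_equal(pr_eq$f1[1], pr_eq$precision[1])  # P = R implies F1 = P
  # zero denominators give 0
  z <- aggregate_counts(data.frame(construct = "FL", tp = 0L, fp = 0L,
                                   fn = 0L))
  expect_equal(z$precision[1], 0)
  expect_equal(z$f1[1], 0)
})

test_that("perfect predictions give 1.0 everywhere, and recall is monotone", {
  cfg <- synth_config(n_patients = 4L, notes_per_patient_mean = 2,
                      filler_sentences_per_note = 2,
                      prevalence = stats::setNames(rep(1, 10),
                                                   construct_codes()),
                      seed = 21L)
  pats <- generate(cfg)
  gold <- gold_spans(pats)
  expect_setequal(unique(gold$construct), construct_codes())
  rep_ <- metrics_report(gold, gold)
  for (lv in names(rep_)) {
    expect_true(all(abs(rep_[[lv]]$precision - 1) < 1e-12))
    expect_true(all(abs(rep_[[lv]]$recall - 1) < 1e-12))
    expect_true(all(abs(rep_[[lv]]$f1 - 1) < 1e-12))
  }
  # recall weakens monotonically: patient >= note >= partial >= exact
  for (seed in 1:40) {
    inst <- random_span_instance(seed + 500L)
    gold1 <- inst$gold; pred1 <- inst$pred
    gold1$patient_id <- rep("p1", nrow(gold1))
    pred1$patient_id <- rep("p1", nrow(pred1))
    recalls <- vapply(list(
      match_phrase(gold1, pred1, "exact"),
      match_phrase(gold1, pred1, "partial"),
      match_note(gold1, pred1),
      match_patient(gold1, pred1)), function(cnt) {
        tp <- sum(cnt$tp); fn <- sum(cnt$fn)
        if (tp + fn == 0) 1 else tp / (tp + fn)
      }, numeric(1))
    expect_true(all(diff(recalls) >= -1e-12))
  }
})

test_that("McNemar handles exact, asymptotic, and degenerate branches", {
  # b = 15, c = 0: exact binomial branch, p < .001
  a <- c(rep(TRUE, 15L), rep(TRUE, 10L))
  b <- c(rep(FALSE, 15L), rep(TRUE, 10L))
  r <- mcnemar_paired(a, b)
  expect_equal(r$method, "exact-binomial")
  expect_lt(r$p_value, 0.001)
  # identical systems: p = 1 by convention
  expect_equal(mcnemar_paired(a, a)$p_value, 1)
  # balanced discordance: large p
  a2 <- c(rep(TRUE, 10L), rep(FALSE, 10L))
  b2 <- c(rep(FALSE, 10L), rep(TRUE, 10L))
  expect_gt(mcnemar_paired(a2, b2)$p_value, 0.5)
  # chi-square branch agrees with the standard implementation
  a3 <- c(rep(TRUE, 20L), rep(FALSE, 15L), rep(TRUE, 30L))
  b3 <- c(rep(FALSE, 20L), rep(TRUE, 15L), rep(TRUE, 30L))
  r3 <- mcnemar_paired(a3, b3)
  expect_equal(r3$method, "chi-square")
  ref <- stats::mcnemar.test(table(a3, b3), correct = TRUE)
  expect_equal(r3$p_value, ref$p.value)
  expect_equal(unname(r3$statistic), unname(ref$statistic))
})
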