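test_that("path scoring matches an independent summation oracle", {
  # all-zero weights score 0 for any path
  m0 <- crf_model(c("a", "b"), c("f1", "f2"))
  expect_equal(score_path(m0, list(c("f1"), c("f2")), c("a", "b")), 0)
  # single position, one active feature of weight w at label y
  m1 <- crf_model(c("a", "b"), "f1")
  m1$state["f1", "b"] <- 2.5
  expect_equal(score_path(m1, list("f1"), "b"), 2.5)
  expect_error(score_path(m1, list("f1"), c("a", "b")), "mismatch")
  # random small model vs brute-force resummation
  for (seed in 1:5) {
    inst <- random_toy_crf(4L, 3L, 4L, seed)
    y <- sample(inst$model$labels, 4L, replace = TRUE)
    manual <- 0
    for (t in 1:4) {
      for (f in inst$feats[[t]]) manual <- manual + inst$model$state[f, y[t]]
      if (t > 1) manual <- manual + inst$model$trans[y[t - 1], y[t]]
    }
    expect_equal(score_path(inst$model, inst$feats, y), manual)
  }
})

test_that("forward log-partition matches closed forms and enumeration", {
  # T=1, two labels with state scores a and b
  m <- crf_model(c("a", "b"), "f1")
  m$state["f1", ] <- c(1.3, -0.4)
  expect_equal(forward_log_partition(m, list("f1")),
               log(exp(1.3) + exp(-0.4)))
  # zero weights: T * log(L)
  m0 <- crf_model(paste0("y", 1:4), "f1")
  expect_equal(forward_log_partition(m0, rep(list("f1"), 3L)), 3 * log(4))
  expect_error(forward_log_partition(m0, list()), "empty")
  # enumeration oracle on random instances
  for (seed in 1:10) {
    inst <- random_toy_crf(sample(2:4, 1L), sample(2:4, 1L), 4L, seed * 7L)
    expect_equal(forward_log_partition(inst$model, inst$feats),
                 enum_logZ(inst$model, inst$feats), tolerance = 1e-10)
  }
})

test_that("path probabilities normalize and Viterbi finds the argmax", {
  for (seed in 1:10) {
    inst <- random_toy_crf(3L, 3L, 3L, seed * 13L)
    ep <- enum_paths(inst$model, inst$feats)
    logZ <- forward_log_partition(inst$model, inst$feats)
    expect_equal(sum(exp(ep$scores - logZ)), 1, tolerance = 1e-10)
    vit <- viterbi(inst$model, inst$feats)
    best <- enum_best(inst$model, inst$feats)
    expect_equal(score_path(inst$model, inst$feats, vit), best$score,
                 tolerance = 1e-10)
    if (best$unique) expect_equal(vit, best$path)
    # viterbi beats random sampled paths
    for (k in 1:5) {
      y <- sample(inst$model$labels, length(inst$feats), replace = TRUE)
      expect_gte(score_path(inst$model, inst$feats, vit) + 1e-12,
                 score_path(inst$model, inst$feats, y))
    }
  }
  # T=1: argmax of state scores; zero weights tie-break to first label
  m <- crf_model(c("a", "b"), "f1")
  m$state["f1", ] <- c(0.1, 0.9)
  expect_equal(viterbi(m, list("f1")), "b")
  m$state[] <- 0
  expect_equal(viterbi(m, list("f1")), "a")
})

test_that("analytic gradient matches central finite differences", {
  for (seed in 1:4) {
    inst <- random_toy_crf(3L, 3L, 3L, seed * 31L)
    m <- inst$model
    m$hyper$l2 <- 0.3
    withr::local_seed(seed)
    seqs <- list(
      list(features = inst$feats,
           tags = sample(m$labels, 3L, replace = TRUE)),
      list(features = inst$feats[1:2],
           tags = sample(m$labels, 2L, replace = TRUE)))
    g <- crf_gradient(m, seqs)
    F_ <- nrow(m$state); L <- length(m$labels)
    pack <- function(mm) c(as.vector(mm$state), as.vector(mm$trans))
    unpack <- function(par) {
      mm <- m
      mm$state <- matrix(par[seq_len(F_ * L)], F_, L,
                         dimnames = dimnames(m$state))
      mm$trans <- matrix(par[F_ * L + seq_len(L * L)], L, L,
                         dimnames = dimnames(m$trans))
      mm
    }
    par <- pack(m)
    h <- 1e-5
    idx <- sample(length(par), 12L)
    for (j in idx) {
      pp <- par; pp[j] <- pp[j] + h
      pm <- par; pm[j] <- pm[j] - h
      fd <- (crf_objective(unpack(pp), seqs) -
             crf_objective(unpack(pm), seqs)) / (2 * h)
      expect_equal(g[j], fd, tolerance = 1e-4)
    }
  }
})

test_that("gradient vanishes at a symmetric optimum", {
  # two single-token sequences with identical features, opposite labels:
  # at zero weights with l2 = 0 the empirical and expected counts agree
  m <- crf_model(c("a", "b"), "f1", l2 = 0)
  seqs <- list(list(features = list("f1"), tags = "a"),
               list(features = list("f1"), tags = "b"))
  expect_equal(max(abs(crf_gradient(m, seqs))), 0)
})

test_that("SGD training learns a separable corpus deterministically", {
  pats <- toy_corpus(6L, seed = 5L)
  cfg <- feature_config(stem = TRUE)
  seqs <- build_sequences(pats, cfg)
  # zero iterations: zero weights over the observed vocabulary
  m0 <- crf_train_sgd(seqs, max_iterations = 0L)
  expect_true(all(m0$state == 0) && all(m0$trans == 0))
  expect_gt(length(m0$feature_names), 0L)

  m <- crf_train_sgd(seqs, l2 = 0.1, max_iterations = 8L, seed = 2L,
                     track_objective = FALSE)
  pred <- predict_spans(m, pats, cfg, post = FALSE)
  rep_ <- aggregate_counts(match_phrase(gold_spans(pats), pred, "partial"))
  expect_gt(metric_cell(rep_, metric = "f1"), 0.95)

  # bit-identical retraining under the same seed
  m2 <- crf_train_sgd(seqs, l2 = 0.1, max_iterations = 8L, seed = 2L,
                      track_objective = FALSE)
  expect_identical(m$state, m2$state)
  expect_identical(m$trans, m2$trans)
  expect_error(crf_train_sgd(list()), "empty")
})

test_that("regularized objective is non-increasing on a fixed-order problem", {
  pats <- toy_corpus(3L, seed = 9L)
  seqs <- build_sequences(pats, feature_config())
  m <- crf_train_sgd(seqs, l2 = 0.2, max_iterations = 6L, seed = 1L,
                     shuffle = FALSE, track_objective = TRUE)
  tr <- m$objective_trace
  expect_true(all(diff(tr) <= 1e-6))
  expect_equal(m$objective, tr[length(tr)])
})

test_that("L-BFGS reaches at least the SGD objective on a tiny problem", {
  pats <- toy_corpus(2L, seed = 4L)
  seqs <- build_sequences(pats, feature_config())[1:10]
  sgd <- crf_train_sgd(seqs, l2 = 0.5, max_iterations = 4L, seed = 1L,
                       track_objective = FALSE)
  lb <- crf_train_lbfgs(seqs, l2 = 0.5, max_iterations = 40L)
  expect_lte(lb$objective, sgd$objective + 1e-6)
})

test_that("model serialization round-trips exactly", {
  inst <- random_toy_crf(2L, 3L, 4L, 99L)
  m <- inst$model
  m$objective <- 12.5
  path <- withr::local_tempfile(fileext = ".crf")
  crf_save(m, path)
  back <- crf_load(path)
  expect_equal(back$labels, m$labels)
  expect_equal(back$feature_names, m$feature_names)
  expect_equal(back$state, m$state)
  expect_equal(back$trans, m$trans)
  expect_equal(back$hyper$l2, m$hyper$l2)
  expect_equal(back$objective, 12.5)
  # decoding behavior is preserved
  expect_equal(viterbi(back, inst$feats), viterbi(m, inst$feats))
})
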