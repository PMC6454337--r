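# Linear-chain conditional random field over BIO tag sequences.
#
# The model is log-linear: the score of a tag path y for a sentence x is
#   score(x, y) = sum_t  w_state[f, y_t]  (f over active features at t)
#               + sum_t  w_trans[y_{t-1}, y_t]
# and P(y|x) = exp(score) / Z(x). Inference (forward log-partition,
# forward-backward marginals, Viterbi decoding) is exact; all arithmetic
# is in log space with max-shifted log-sum-exp. Training maximizes the
# L2-regularized conditional log-likelihood by stochastic gradient
# descent (the supported default) or full-batch L-BFGS.
#
# Invalid BIO transitions (e.g. O -> I-c) are not hard-masked: they are
# discouraged only by learned weights, and spans_from_bio() repairs any
# residual violations, matching the behavior of the standard CRF
# sequence-labeling toolchain for this task.

#' Construct an (untrained) linear-chain CRF model
#'
#' @param labels label alphabet (default [bio_tags()]); the fixed order is
#'   also the Viterbi tie-break order.
#' @param feature_names state feature vocabulary (grown automatically by
#'   the trainers).
#' @param l2 L2 regularization strength lambda; the objective is
#'   `sum_i -log P(y_i|x_i) + lambda/2 * ||w||^2`.
#' @param max_iterations maximum training epochs.
#' @param seed integer seed for epoch shuffling.
#' @return a `crf_model`: label alphabet, state-weight matrix (features x
#'   labels), transition-weight matrix (labels x labels), hyperparameters.
#' @export
crf_model <- function(labels = bio_tags(), feature_names = character(),
                      l2 = 0.2, max_iterations = 100L, seed = 1L) {
  L <- length(labels)
  F <- length(feature_names)
  structure(list(
    labels = labels,
    feature_names = feature_names,
    state = matrix(0, nrow = F, ncol = L,
                   dimnames = list(feature_names, labels)),
    trans = matrix(0, nrow = L, ncol = L, dimnames = list(labels, labels)),
    hyper = list(l2 = l2, max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)),
    objective = NA_real_,
    objective_trace = numeric(0)
  ), class = "crf_model")
}

#' @export
print.crf_model <- function(x, ...) {
  cat(sprintf("<crf_model: %d labels, %d features, l2=%g, iters=%d%s>\n",
              length(x$labels), length(x$feature_names), x$hyper$l2,
              x$hyper$max_iterations,
              if (is.finite(x$objective))
                sprintf(", objective=%.4f", x$objective) else ""))
  invisible(x)
}

# Map character feature vectors to integer indices into the model's
# feature table; unknown features contribute zero score and are dropped.
.index_feats <- function(model, features) {
  idx <- match(features, model$feature_names)
  idx[!is.na(idx)]
}

# T x L state score matrix for one sentence (features as a list of
# integer index vectors).
.state_scores <- function(state, feats_idx, L) {
  T_ <- length(feats_idx)
  S <- matrix(0, nrow = T_, ncol = L)
  for (t in seq_len(T_)) {
    ids <- feats_idx[[t]]
    if (length(ids) == 1L) S[t, ] <- state[ids, ]
    else if (length(ids) > 1L) S[t, ] <- colSums(state[ids, , drop = FALSE])
  }
  S
}

.logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# Column-wise log-sum-exp of (prev_vec + trans): returns length-L vector
# a[j] = logsumexp_i(prev[i] + trans[i, j]). Single global max-shift with
# a per-column fallback if a column underflows entirely.
.lse_step <- function(prev, trans) {
  M <- prev + trans          # recycles prev down columns (rows = prev label)
  gm <- max(M)
  cs <- .colSums(exp(M - gm), nrow(M), ncol(M))
  if (any(cs == 0)) {
    m <- apply(M, 2L, max)
    return(m + log(colSums(exp(sweep(M, 2L, m)))))
  }
  gm + log(cs)
}

#' Log-linear score of a tag path
#'
#' @param model a `crf_model`.
#' @param features_seq list (one per token) of character vectors of active
#'   feature names.
#' @param tag_seq character vector of tags, same length.
#' @return numeric scalar score.
#' @export
score_path <- function(model, features_seq, tag_seq) {
  if (length(features_seq) != length(tag_seq)) {
    stop("features_seq and tag_seq length mismatch")
  }
  y <- match(tag_seq, model$labels)
  if (anyNA(y)) stop("unknown tag in tag_seq")
  sc <- 0
  for (t in seq_along(y)) {
    ids <- .index_feats(model, features_seq[[t]])
    if (length(ids)) sc <- sc + sum(model$state[ids, y[t]])
    if (t > 1L) sc <- sc + model$trans[y[t - 1L], y[t]]
  }
  sc
}

# Forward pass in log space; returns list(alpha = T x L, logZ).
.forward <- function(S, trans) {
  T_ <- nrow(S); L <- ncol(S)
  alpha <- matrix(0, T_, L)
  alpha[1L, ] <- S[1L, ]
  if (T_ > 1L) for (t in 2:T_) {
    alpha[t, ] <- S[t, ] + .lse_step(alpha[t - 1L, ], trans)
  }
  list(alpha = alpha, logZ = .logsumexp(alpha[T_, ]))
}

.backward <- function(S, trans) {
  T_ <- nrow(S); L <- ncol(S)
  beta <- matrix(0, T_, L)
  if (T_ > 1L) for (t in (T_ - 1L):1L) {
    # beta[t, i] = logsumexp_j(trans[i, j] + S[t+1, j] + beta[t+1, j])
    v <- S[t + 1L, ] + beta[t + 1L, ]
    M <- trans + rep(v, each = L)
    gm <- max(M)
    rs <- .rowSums(exp(M - gm), L, L)
    if (any(rs == 0)) {
      m <- apply(M, 1L, max)
      beta[t, ] <- m + log(rowSums(exp(M - m)))
    } else {
      beta[t, ] <- gm + log(rs)
    }
  }
  beta
}

#' Log partition function by the forward recursion
#'
#' `log Z(x)`: log-sum-exp of [score_path()] over all `|labels|^T` paths,
#' computed in O(T L^2).
#'
#' @inheritParams score_path
#' @return numeric scalar `log Z`.
#' @export
forward_log_partition <- function(model, features_seq) {
  if (length(features_seq) == 0L) stop("empty sequence")
  feats_idx <- lapply(features_seq, .index_feats, model = model)
  S <- .state_scores(model$state, feats_idx, length(model$labels))
  .forward(S, model$trans)$logZ
}

#' Viterbi decoding
#'
#' Returns the argmax-scoring tag path. Ties are broken toward the
#' earliest label in the model's fixed alphabet order at every
#' backpointer.
#'
#' @inheritParams score_path
#' @return character vector of tags.
#' @export
viterbi <- function(model, features_seq) {
  if (length(features_seq) == 0L) return(character(0))
  feats_idx <- lapply(features_seq, .index_feats, model = model)
  L <- length(model$labels)
  S <- .state_scores(model$state, feats_idx, L)
  T_ <- nrow(S)
  delta <- matrix(-Inf, T_, L)
  back <- matrix(1L, T_, L)
  delta[1L, ] <- S[1L, ]
  if (T_ > 1L) for (t in 2:T_) {
    M <- delta[t - 1L, ] + model$trans  # rows = prev label
    bp <- apply(M, 2L, which.max)       # first max: earliest-label tie-break
    delta[t, ] <- S[t, ] + M[cbind(bp, seq_len(L))]
    back[t, ] <- bp
  }
  path <- integer(T_)
  path[T_] <- which.max(delta[T_, ])
  if (T_ > 1L) for (t in (T_ - 1L):1L) path[t] <- back[t + 1L, path[t + 1L]]
  model$labels[path]
}

# Node marginals and expected transition counts for one sentence.
# Returns list(node = T x L probabilities, trans = L x L expected counts,
# logZ).
.marginals <- function(S, trans) {
  T_ <- nrow(S); L <- ncol(S)
  fw <- .forward(S, trans)
  alpha <- fw$alpha; logZ <- fw$logZ
  beta <- .backward(S, trans)
  node <- exp(alpha + beta - logZ)
  et <- matrix(0, L, L)
  if (T_ > 1L) for (t in 2:T_) {
    M <- (alpha[t - 1L, ] + trans) + rep(S[t, ] + beta[t, ], each = L)
    et <- et + exp(M - logZ)
  }
  list(node = node, trans = et, logZ = logZ)
}

# Internal: convert API-level sequences (features as character vectors,
# tags as characters) into indexed form against a model.
.prepare_sequences <- function(model, sequences) {
  lapply(sequences, function(sq) {
    list(feats = lapply(sq$features, .index_feats, model = model),
         y = match(sq$tags, model$labels))
  })
}

#' Regularized negative log-likelihood and its gradient
#'
#' `crf_objective` computes `sum_i -log P(y_i|x_i) + lambda/2 ||w||^2`
#' over a batch; `crf_gradient` its exact gradient (empirical minus
#' expected feature counts from forward-backward, plus `lambda * w`),
#' flattened as `c(state, trans)` column-major.
#'
#' @param model a `crf_model`.
#' @param sequences list of `list(features = <list of character vectors>,
#'   tags = <character vector>)`.
#' @return scalar objective / numeric gradient vector.
#' @export
crf_objective <- function(model, sequences) {
  prep <- .prepare_sequences(model, sequences)
  L <- length(model$labels)
  nll <- 0
  for (sq in prep) {
    S <- .state_scores(model$state, sq$feats, L)
    logZ <- .forward(S, model$trans)$logZ
    sc <- sum(S[cbind(seq_along(sq$y), sq$y)])
    if (length(sq$y) > 1L) {
      sc <- sc + sum(model$trans[cbind(sq$y[-length(sq$y)], sq$y[-1L])])
    }
    nll <- nll + (logZ - sc)
  }
  nll + model$hyper$l2 / 2 * (sum(model$state^2) + sum(model$trans^2))
}

#' @rdname crf_objective
#' @export
crf_gradient <- function(model, sequences) {
  prep <- .prepare_sequences(model, sequences)
  L <- length(model$labels)
  gs <- matrix(0, nrow(model$state), L)
  gt <- matrix(0, L, L)
  for (sq in prep) {
    S <- .state_scores(model$state, sq$feats, L)
    mg <- .marginals(S, model$trans)
    for (t in seq_along(sq$y)) {
      ids <- sq$feats[[t]]
      if (length(ids)) {
        # expected minus empirical (gradient of NLL)
        gs[ids, ] <- gs[ids, ] + rep(mg$node[t, ], each = length(ids))
        gs[ids, sq$y[t]] <- gs[ids, sq$y[t]] - 1
      }
    }
    gt <- gt + mg$trans
    if (length(sq$y) > 1L) {
      emp <- table(factor(sq$y[-length(sq$y)], levels = seq_len(L)),
                   factor(sq$y[-1L], levels = seq_len(L)))
      gt <- gt - unclass(emp)
    }
  }
  gs <- gs + model$hyper$l2 * model$state
  gt <- gt + model$hyper$l2 * model$trans
  c(as.vector(gs), as.vector(gt))
}

# Build the feature vocabulary observed in training sequences.
.build_vocab <- function(sequences) {
  unique(unlist(lapply(sequences, function(sq) unlist(sq$features)),
                use.names = FALSE))
}

#' Train a linear-chain CRF by stochastic gradient descent
#'
#' Per-sequence updates with seeded shuffling each epoch, learning-rate
#' schedule `eta_t = eta0 / (1 + t/T0)` with `T0 = N` sequences, and
#' `eta0` calibrated by a trial phase: one epoch over a sample of the
#' training set for each candidate rate, keeping the rate with the best
#' sample objective. L2 decay uses the standard weight-scaling trick so
#' each update touches only the active feature rows. Stops after
#' `max_iterations` epochs; `max_iterations = 0` returns the zero-weight
#' model over the observed feature vocabulary. Bit-reproducible for a
#' fixed seed.
#'
#' @param sequences training data: list of `list(features, tags)` as in
#'   [crf_objective()].
#' @param labels label alphabet.
#' @param l2 L2 regularization strength.
#' @param max_iterations epochs.
#' @param seed integer seed (epoch shuffling).
#' @param eta0_grid candidate initial learning rates for calibration.
#' @param calibration_sample max sequences used in the calibration phase.
#' @param shuffle set FALSE to keep the fixed data order every epoch.
#' @param track_objective evaluate the full objective after every epoch
#'   (recorded in `objective_trace`); with FALSE only the final objective
#'   is computed, saving one forward pass over the data per epoch.
#' @param verbose log epoch objectives at INFO level.
#' @return a trained `crf_model` with `objective` (final epoch) and
#'   `objective_trace` (per epoch) recorded.
#' @export
crf_train_sgd <- function(sequences, labels = bio_tags(), l2 = 0.2,
                          max_iterations = 100L, seed = 1L,
                          eta0_grid = c(0.01, 0.05, 0.1, 0.5),
                          calibration_sample = 100L, shuffle = TRUE,
                          track_objective = TRUE, verbose = FALSE) {
  if (length(sequences) == 0L) stop("empty training set")
  vocab <- .build_vocab(sequences)
  model <- crf_model(labels, vocab, l2 = l2,
                     max_iterations = max_iterations, seed = seed)
  if (max_iterations == 0L) return(model)
  prep <- .prepare_sequences(model, sequences)
  if (anyNA(unlist(lapply(prep, `[[`, "y")))) stop("unknown tag in training data")
  N <- length(prep)
  L <- length(labels)

  run_epochs <- function(V, trans, s, idx_order, eta0, t0, epochs, T0) {
    t_ <- t0
    for (ep in seq_len(epochs)) {
      for (k in idx_order) {
        sq <- prep[[k]]
        eta <- eta0 / (1 + t_ / T0)
        S <- .state_scores(V, sq$feats, L) * s
        mg <- .marginals(S, trans)
        # L2 decay (all weights), via scale for the state matrix
        decay <- 1 - eta * l2 / N
        if (decay <= 0) stop("learning rate too large for l2 decay")
        s <- s * decay
        trans <- trans * decay
        for (t in seq_along(sq$y)) {
          ids <- sq$feats[[t]]
          if (length(ids)) {
            g <- -mg$node[t, ]
            g[sq$y[t]] <- g[sq$y[t]] + 1
            V[ids, ] <- V[ids, ] + rep(g * (eta / s), each = length(ids))
          }
        }
        if (length(sq$y) > 1L) {
          emp <- matrix(0, L, L)
          pairs <- cbind(sq$y[-length(sq$y)], sq$y[-1L])
          for (r in seq_len(nrow(pairs))) {
            emp[pairs[r, 1L], pairs[r, 2L]] <- emp[pairs[r, 1L], pairs[r, 2L]] + 1
          }
          trans <- trans + eta * (emp - mg$trans)
        }
        t_ <- t_ + 1L
        if (abs(s) < 1e-8) { V <- V * s; s <- 1 }
      }
    }
    list(V = V, trans = trans, s = s, t = t_)
  }

  objective_of <- function(V, trans, s, subset = seq_len(N)) {
    m2 <- model
    m2$state <- V * s
    m2$trans <- trans
    crf_objective(m2, sequences[subset])
  }

  # --- calibration: one epoch per candidate eta0 on a fixed sample
  samp <- seq_len(min(N, calibration_sample))
  best_eta <- eta0_grid[1]
  best_obj <- Inf
  for (eta0 in eta0_grid) {
    st <- tryCatch(
      run_epochs(matrix(0, length(vocab), L), matrix(0, L, L), 1,
                 samp, eta0, 0L, 1L, T0 = length(samp)),
      error = function(e) NULL)
    if (is.null(st)) next
    obj <- objective_of(st$V, st$trans, st$s, samp)
    if (is.finite(obj) && obj < best_obj) { best_obj <- obj; best_eta <- eta0 }
  }
  gstag_log("SGD calibrated eta0 = ", best_eta, level = "INFO")

  # --- main loop
  V <- matrix(0, length(vocab), L)
  trans <- matrix(0, L, L)
  s <- 1
  t_ <- 0L
  trace <- numeric(max_iterations)
  orders <- with_seed(seed, lapply(seq_len(max_iterations), function(ep) {
    if (shuffle) sample.int(N) else seq_len(N)
  }))
  for (ep in seq_len(max_iterations)) {
    st <- run_epochs(V, trans, s, orders[[ep]], best_eta, t_, 1L, T0 = N)
    V <- st$V; trans <- st$trans; s <- st$s; t_ <- st$t
    if (track_objective || ep == max_iterations) {
      trace[ep] <- objective_of(V, trans, s)
      if (!is.finite(trace[ep])) {
        stop("non-finite objective at epoch ", ep)
      }
      if (verbose) gstag_log(sprintf("epoch %d: objective %.4f", ep, trace[ep]),
                             level = "INFO")
    } else {
      trace[ep] <- NA_real_
      if (!all(is.finite(s), is.finite(trans))) {
        stop("non-finite objective at epoch ", ep)
      }
    }
  }
  model$state <- V * s
  dimnames(model$state) <- list(vocab, labels)
  model$trans <- trans
  dimnames(model$trans) <- list(labels, labels)
  model$objective <- trace[max_iterations]
  model$objective_trace <- trace
  model$hyper$eta0 <- best_eta
  model
}

#' Train a linear-chain CRF by full-batch L-BFGS
#'
#' Optional alternative optimizer: delegates the L2-regularized negative
#' log-likelihood and its exact gradient to [stats::optim()]'s
#' quasi-Newton `"L-BFGS-B"` method. SGD ([crf_train_sgd()]) is the
#' supported default.
#'
#' @inheritParams crf_train_sgd
#' @return a trained `crf_model`.
#' @export
crf_train_lbfgs <- function(sequences, labels = bio_tags(), l2 = 0.2,
                            max_iterations = 100L, seed = 1L) {
  if (length(sequences) == 0L) stop("empty training set")
  vocab <- .build_vocab(sequences)
  model <- crf_model(labels, vocab, l2 = l2,
                     max_iterations = max_iterations, seed = seed)
  L <- length(labels)
  F <- length(vocab)
  unpack <- function(par) {
    model$state <- matrix(par[seq_len(F * L)], F, L,
                          dimnames = list(vocab, labels))
    model$trans <- matrix(par[F * L + seq_len(L * L)], L, L,
                          dimnames = list(labels, labels))
    model
  }
  fn <- function(par) crf_objective(unpack(par), sequences)
  gr <- function(par) crf_gradient(unpack(par), sequences)
  opt <- stats::optim(rep(0, F * L + L * L), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = max_iterations))
  model <- unpack(opt$par)
  model$objective <- opt$value
  model
}

# -- serialization ------------------------------------------------------

#' Save / load a CRF model as a versioned flat text file
#'
#' The format stores the label alphabet, feature table and all weights in
#' plain text; `crf_load(crf_save(m))` round-trips deterministically.
#'
#' @param model a `crf_model`.
#' @param path file path.
#' @export
crf_save <- function(model, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("gstag-crf 1",
               paste("l2", format(model$hyper$l2, digits = 17)),
               paste("max_iterations", model$hyper$max_iterations),
               paste("seed", model$hyper$seed),
               paste("objective", format(model$objective, digits = 17)),
               paste0("labels\t", paste(model$labels, collapse = "\t")),
               paste("nfeatures", length(model$feature_names))), con)
  if (length(model$feature_names)) {
    writeLines(paste0("F\t", model$feature_names, "\t",
                      apply(model$state, 1L, function(r)
                        paste(format(r, digits = 17), collapse = "\t"))), con)
  }
  writeLines(paste0("T\t",
                    apply(model$trans, 1L, function(r)
                      paste(format(r, digits = 17), collapse = "\t"))), con)
  invisible(path)
}

#' @rdname crf_save
#' @return `crf_load`: the restored `crf_model`.
#' @export
crf_load <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!startsWith(lines[1], "gstag-crf 1")) stop("unrecognized model file")
  get_kv <- function(key) {
    ln <- lines[startsWith(lines, paste0(key, " "))][1]
    sub(paste0("^", key, " "), "", ln)
  }
  labels <- strsplit(sub("^labels\t", "", lines[startsWith(lines, "labels\t")][1]),
                     "\t", fixed = TRUE)[[1]]
  frows <- lines[startsWith(lines, "F\t")]
  trows <- lines[startsWith(lines, "T\t")]
  L <- length(labels)
  feature_names <- character(length(frows))
  state <- matrix(0, length(frows), L)
  if (length(frows)) {
    parts <- strsplit(frows, "\t", fixed = TRUE)
    feature_names <- vapply(parts, `[[`, "", 2L)
    state <- t(vapply(parts, function(p) as.numeric(p[-(1:2)]), numeric(L)))
  }
  trans <- t(vapply(strsplit(trows, "\t", fixed = TRUE),
                    function(p) as.numeric(p[-1L]), numeric(L)))
  model <- crf_model(labels, feature_names,
                     l2 = as.numeric(get_kv("l2")),
                     max_iterations = as.integer(get_kv("max_iterations")),
                     seed = as.integer(get_kv("seed")))
  model$state <- state
  dimnames(model$state) <- list(feature_names, labels)
  model$trans <- trans
  dimnames(model$trans) <- list(labels, labels)
  model$objective <- as.numeric(get_kv("objective"))
  model
}
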