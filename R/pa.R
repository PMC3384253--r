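## Multiclass cost-sensitive classification with an online
## passive-aggressive learner (PA-II, prediction-based updates), run for
## several shuffled rounds with weight averaging as in the averaged
## perceptron.
##
## An example is a sparse binary feature vector (character names) plus a
## per-label cost vector with minimum 0.  Weights are held in a dense
## K x V matrix over a vocabulary built from the training set; unseen
## features at prediction time contribute nothing.

#' Train a multiclass cost-sensitive PA classifier
#'
#' For each visited example the current classifier predicts
#' \eqn{\hat y = \arg\max_k w(k) \cdot x}.  If the predicted label has
#' positive cost, the learner suffers loss
#' \eqn{\ell = w(\hat y) \cdot x - w(y) \cdot x + \sqrt{c(\hat y)}}
#' (with \eqn{y} the minimum-cost label, ties to the lowest index), sets
#' the learning rate \eqn{\tau = \ell / (\|x\|^2 + 1/(2C))} and moves
#' \eqn{w(y)} by \eqn{+\tau x} and \eqn{w(\hat y)} by \eqn{-\tau x};
#' otherwise the example is passive and nothing changes.  Training runs
#' \code{R} rounds, shuffling the examples at the start of each round, and
#' predictions use the average of the weight snapshots taken after every
#' example visit.
#'
#' @param examples list of \code{list(x = <character feature names>,
#'   costs = <numeric K-vector, all >= 0>)}.
#' @param n_labels number of labels K.
#' @param C aggressiveness parameter (> 0).
#' @param rounds number of rounds R (>= 1).
#' @param seed integer seed for the per-round shuffles.
#' @return object of class "csc_pa" with the averaged weights.
#' @export
csc_train <- function(examples, n_labels, C = 1, rounds = 1, seed = 1L) {
  stopifnot(C > 0, rounds >= 1, length(examples) >= 1)
  for (e in examples) {
    if (any(e$costs < 0)) stop("negative cost in training example")
    if (length(e$costs) != n_labels) stop("inconsistent number of labels")
  }
  vocab <- new.env(parent = emptyenv(), size = 4096L)
  nv <- 0L
  xs <- vector("list", length(examples))
  for (i in seq_along(examples)) {
    nm <- examples[[i]]$x
    idx <- integer(length(nm))
    for (j in seq_along(nm)) {
      id <- vocab[[nm[j]]]
      if (is.null(id)) { nv <- nv + 1L; vocab[[nm[j]]] <- nv; id <- nv }
      idx[j] <- id
    }
    xs[[i]] <- idx
  }
  W <- matrix(0, n_labels, max(nv, 1L))
  ## averaged weights via the lazy trick: an update at global step i of N
  ## contributes to the snapshots taken at steps i..N, i.e. (N - i + 1)
  ## times, so accumulate tau * (N - i + 1) * x and divide by N at the end.
  A <- matrix(0, n_labels, max(nv, 1L))
  Tn <- length(examples)
  N <- Tn * rounds
  step <- 0L
  orng <- swap_rng(seed)
  on.exit(restore_rng(orng))
  for (r in seq_len(rounds)) {
    ord <- sample.int(Tn)
    for (i in ord) {
      step <- step + 1L
      idx <- xs[[i]]
      costs <- examples[[i]]$costs
      if (!length(idx)) next
      scores <- rowSums(W[, idx, drop = FALSE])
      yhat <- which.max(scores)  # ties -> lowest index
      if (costs[yhat] > 0) {
        y <- which.min(costs)
        loss <- scores[yhat] - scores[y] + sqrt(costs[yhat])
        tau <- loss / (length(idx) + 1 / (2 * C))
        W[y, idx] <- W[y, idx] + tau
        W[yhat, idx] <- W[yhat, idx] - tau
        rem <- N - step + 1L
        A[y, idx] <- A[y, idx] + tau * rem
        A[yhat, idx] <- A[yhat, idx] - tau * rem
      }
    }
  }
  structure(list(W = A / N, W_final = W, vocab = vocab, n_labels = n_labels,
                 C = C, rounds = rounds, seed = seed),
            class = "csc_pa")
}

#' Per-label scores of a trained classifier
#'
#' \code{score_k = w_avg(k) . x}; unknown feature names are ignored.
#' A NULL classifier (a stage that received no training examples) scores
#' all labels 0, so argmax with lowest-index tie-breaking picks the
#' negative class.
#'
#' @param clf a [csc_train()] model or NULL.
#' @param x character vector of feature names.
#' @param n_labels number of labels (needed when clf is NULL).
#' @return numeric vector of K scores.
#' @export
csc_scores <- function(clf, x, n_labels = NULL) {
  if (is.null(clf)) return(rep(0, n_labels))
  idx <- feature_indices(clf$vocab, x)
  if (!length(idx)) return(rep(0, clf$n_labels))
  rowSums(clf$W[, idx, drop = FALSE])
}

feature_indices <- function(vocab, x) {
  if (!length(x)) return(integer())
  ids <- mget(x, envir = vocab, ifnotfound = list(NULL))
  unlist(ids, use.names = FALSE)
}

#' Single PA-II cost-sensitive update (exposed for testing)
#'
#' Applies one update of the learner to explicit dense weight matrix rows.
#'
#' @param W K x V weight matrix.
#' @param idx integer feature indices of the example (binary features).
#' @param costs numeric K-vector of label costs.
#' @param C aggressiveness parameter.
#' @return list(W = updated matrix, tau = learning rate used, yhat, y).
#' @export
pa_update <- function(W, idx, costs, C = 1) {
  if (any(costs < 0)) stop("negative cost")
  scores <- rowSums(W[, idx, drop = FALSE])
  yhat <- which.max(scores)
  if (costs[yhat] == 0) return(list(W = W, tau = 0, yhat = yhat, y = yhat))
  y <- which.min(costs)
  loss <- scores[yhat] - scores[y] + sqrt(costs[yhat])
  tau <- loss / (length(idx) + 1 / (2 * C))
  W[y, idx] <- W[y, idx] + tau
  W[yhat, idx] <- W[yhat, idx] - tau
  list(W = W, tau = tau, yhat = yhat, y = y)
}

#' Dump a classifier's feature vocabulary to a text file
#'
#' One feature name per line (sorted), for debugging feature extraction.
#'
#' @param clf a [csc_train()] model.
#' @param path output file.
#' @export
dump_vocabulary <- function(clf, path) {
  writeLines(ls(clf$vocab, sorted = TRUE), path)
  invisible(path)
}

## Serialize / restore a classifier as a plain list (JSON-ready): label
## count plus sparse per-label weight maps keyed by feature name.
csc_to_list <- function(clf) {
  if (is.null(clf)) return(NULL)
  feats <- ls(clf$vocab, sorted = TRUE)
  cols <- vapply(feats, function(f) clf$vocab[[f]], 0L)
  keep <- colSums(clf$W[, cols, drop = FALSE] != 0) > 0
  feats <- feats[keep]; cols <- cols[keep]
  list(n_labels = clf$n_labels, C = clf$C, rounds = clf$rounds,
       seed = clf$seed, features = feats,
       weights = lapply(seq_len(clf$n_labels),
                        function(k) unname(clf$W[k, cols])))
}

csc_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  nv <- length(x$features)
  vocab <- new.env(parent = emptyenv())
  W <- matrix(0, x$n_labels, max(nv, 1L))
  for (j in seq_len(nv)) {
    vocab[[x$features[[j]]]] <- j
    for (k in seq_len(x$n_labels)) W[k, j] <- x$weights[[k]][[j]]
  }
  structure(list(W = W, W_final = NULL, vocab = vocab, n_labels = x$n_labels,
                 C = x$C, rounds = x$rounds, seed = x$seed),
            class = "csc_pa")
}

## RNG management: all stochastic components draw from R's generator after
## seeding it explicitly, and restore the caller's RNG state afterwards.
swap_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}

## derive a bounded sub-seed from a base seed and a stream of integers
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 1103515245 + as.numeric(p) + 12345) %% 2147483647
  as.integer(h)
}
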