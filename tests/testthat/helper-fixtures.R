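## Shared fixtures and independent oracles used across the test files.

## a bare sentence from parallel vectors; deps given as "h>d:label" strings
mk_sentence <- function(surfaces, pos = NULL, lemmas = NULL, deps = character(),
                        proteins = NULL) {
  n <- length(surfaces)
  if (is.null(pos)) pos <- rep("NN", n)
  if (is.null(lemmas)) lemmas <- surfaces
  lens <- nchar(surfaces)
  starts <- cumsum(c(0L, lens + 1L))[seq_len(n)]
  tokens <- data.frame(index = seq_len(n) - 1L, surface = surfaces,
                       lemma = lemmas, pos = pos,
                       char_start = starts, char_end = starts + lens)
  dd <- NULL
  if (length(deps)) {
    m <- regmatches(deps, regexec("^([0-9]+)>([0-9]+):(.+)$", deps))
    dd <- data.frame(head = vapply(m, function(x) as.integer(x[2]), 0L),
                     dependent = vapply(m, function(x) as.integer(x[3]), 0L),
                     label = vapply(m, function(x) x[4], ""))
  }
  new_sentence(tokens, dd, proteins)
}

## exhaustive shortest-simple-path oracle: enumerates every simple path
## over the undirected view of the dependency graph and returns the
## minimal length together with the lexicographically smallest
## label/direction string among the minimal paths.
brute_shortest_path <- function(sentence, a, b) {
  d <- sentence$deps
  steps <- function(v) {
    out <- list()
    for (k in seq_len(nrow(d))) {
      if (d$head[k] == v)
        out[[length(out) + 1L]] <- list(to = d$dependent[k],
                                        s = paste0(d$label[k], "/d"))
      if (d$dependent[k] == v)
        out[[length(out) + 1L]] <- list(to = d$head[k],
                                        s = paste0(d$label[k], "/u"))
    }
    out
  }
  best <- NULL
  rec <- function(v, visited, strs) {
    if (v == b) {
      cand <- list(length = length(strs), string = paste(strs, collapse = "|"))
      if (is.null(best) || cand$length < best$length ||
          (cand$length == best$length && cand$string < best$string))
        best <<- cand
      return(invisible())
    }
    if (!is.null(best) && length(strs) >= best$length) return(invisible())
    for (st in steps(v)) {
      if (st$to %in% visited) next
      rec(st$to, c(visited, st$to), c(strs, st$s))
    }
  }
  rec(a, a, character())
  best
}

## a random sentence-shaped dependency graph over n tokens
random_graph_sentence <- function(n, n_edges, labels = c("nn", "amod", "dobj",
                                                         "prep_of", "nsubj")) {
  deps <- character()
  for (k in seq_len(n_edges)) {
    h <- sample.int(n, 1L) - 1L
    t <- sample.int(n, 1L) - 1L
    if (h == t) next
    deps <- c(deps, sprintf("%d>%d:%s", h, t, sample(labels, 1L)))
  }
  mk_sentence(paste0("w", seq_len(n)), deps = unique(deps))
}

## run the optimal policy over a prepared sentence and return the state
oracle_state <- function(sent) {
  execute_sentence_via_optimal <- function(stage, site, state)
    optimal_policy_action(sent, state, stage, site)
  bioevents:::execute_sentence(sent, execute_sentence_via_optimal)
}

## a directly coded supervised pipeline trainer: one pass over the gold
## decomposition, 0/1 costs, no rollouts, no policy machinery.  Used as
## the independent oracle for the SEARN degeneration.
direct_pipeline_train <- function(corpus, C = 1, rounds = 5, seed = 1L) {
  pool <- list(trigger = list(), theme = list(), cause = list())
  for (doc in corpus) for (s in doc$sentences) {
    sent <- prepare_sentence(s, doc$domain)
    dec <- function(stage, site, state) {
      lab <- optimal_policy_action(sent, state, stage, site)
      feats <- bioevents:::action_features(sent, stage, site, state,
                                           structural = FALSE)
      K <- bioevents:::STAGE_K[[stage]]
      costs <- rep(1, K); costs[lab] <- 0
      pool[[stage]][[length(pool[[stage]]) + 1L]] <<-
        list(x = feats, costs = costs)
      lab
    }
    bioevents:::execute_sentence(sent, dec)
  }
  hyp <- list()
  for (stage in c("trigger", "theme", "cause")) {
    hyp[[stage]] <- if (length(pool[[stage]]))
      csc_train(pool[[stage]], bioevents:::STAGE_K[[stage]], C = C,
                rounds = rounds,
                seed = bioevents:::derive_seed(seed, 11L, 1L,
                                               match(stage, c("trigger", "theme", "cause"))))
    else NULL
  }
  structure(list(hyps = list(hyp), weights = 1, beta = 1, iterations = 1,
                 optimal_policy_prob = 0, structural = FALSE,
                 domain_adapt = FALSE,
                 regdict = build_regulation_dictionary(corpus),
                 config = searn_config(beta = 1, iterations = 1, C = C,
                                       rounds = rounds, structural = FALSE,
                                       zero_one_costs = TRUE, seed = seed)),
            class = "searn_policy")
}

## log-recording pass with a given decider (mirrors the main training pass)
recorded_pass <- function(sent, dec) {
  st <- bioevents:::execute_sentence(sent, function(stage, site, state) {
    lab <- dec(stage, site, state)
    state$action_log[[length(state$action_log) + 1L]] <-
      list(stage = stage, site = site, label = lab)
    lab
  })
  st$action_log
}

## the worked nested-event sentence, prepared
demo_sentence <- function() {
  doc <- demo_document()
  prepare_sentence(doc$sentences[[1]], doc$domain)
}

## a prepared sentence for the grouped Binding construction:
## "interactions of A and B with C"
binding_sentence <- function() {
  prot <- data.frame(ann_id = c("T1", "T2", "T3"),
                     char_start = c(16L, 22L, 30L), char_end = c(17L, 23L, 31L),
                     head_token = c(2L, 4L, 6L))
  s <- mk_sentence(c("interactions", "of", "A", "and", "B", "with", "C"),
                   pos = c("NNS", "IN", "NN", "CC", "NN", "IN", "NN"),
                   lemmas = c("interaction", "of", "A", "and", "B", "with", "C"),
                   deps = c("0>2:prep_of", "0>4:prep_of", "2>4:conj_and",
                            "0>6:prep_with"))
  s$proteins <- prot
  prepare_sentence(s)
}

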