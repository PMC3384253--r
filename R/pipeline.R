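## Rule-based event construction and the document-level prediction
## pipeline.  A completed sentence state (trigger labels plus Theme and
## Cause edges) is converted into events: Simple triggers emit one event
## per Theme; nominal Binding triggers group their Themes by the first
## label of the trigger-Theme dependency path and emit the cross-product of
## the groups; Regulation triggers emit one event per Theme with the Cause
## (if any) attached to each; the regulation dictionary stacks heuristic
## Regulation events over Simple events of consistently dual-annotated
## lemmas.

#' Build the regulation dictionary from a gold corpus
#'
#' A lemma enters the dictionary iff some gold token carries both a
#' Simple-class event and a Regulation-class event whose Theme is that
#' Simple event; the value is the Regulation type (majority over
#' occurrences, ties to the lexicographically smallest type).
#'
#' @param corpus list of gold-annotated documents.
#' @return named character vector lemma -> Regulation-class type.
#' @export
build_regulation_dictionary <- function(corpus) {
  counts <- list()
  for (doc in corpus) for (s in doc$sentences) {
    tr <- s$gold_triggers
    if (is.null(tr) || !nrow(tr)) next
    evs <- s$gold_events %||% list()
    ev_by_trig <- vapply(evs, function(e) e$trigger_id, "")
    eids <- vapply(evs, function(e) e$ann_id, "")
    for (tok in unique(tr$head_token)) {
      ids <- tr$ann_id[tr$head_token == tok]
      if (length(ids) < 2L) next
      types <- tr$type[tr$head_token == tok]
      simple_ids <- ids[event_class(types) == "Simple"]
      reg_ids <- ids[event_class(types) == "Regulation"]
      if (!length(simple_ids) || !length(reg_ids)) next
      simple_events <- eids[ev_by_trig %in% simple_ids]
      for (ri in reg_ids) {
        for (e in evs[ev_by_trig == ri]) {
          stacked <- any(vapply(e$themes, function(a)
            a$kind == "event" && a$id %in% simple_events, TRUE))
          if (stacked) {
            lemma <- s$tokens$lemma[tok + 1L]
            ty <- tr$type[tr$ann_id == ri]
            counts[[lemma]] <- c(counts[[lemma]], ty)
          }
        }
      }
    }
  }
  out <- character()
  for (lemma in sort(names(counts))) {
    tab <- sort(table(counts[[lemma]]), decreasing = TRUE)
    best <- names(tab)[tab == max(tab)]
    out[lemma] <- sort(best)[1]
  }
  out
}

## Resolve state Theme/Cause argument keys into constructed argument
## descriptors; event-valued arguments resolve to the (already built)
## events of the argument trigger token.
resolve_arg <- function(arg_key, arg_tok, by_tok) {
  if (startsWith(arg_key, "P:")) {
    id <- substring(arg_key, 3L)
    return(list(list(kind = "protein", id = id, sig = paste0("P:", id))))
  }
  lapply(by_tok[[as.character(arg_tok)]] %||% list(), function(e)
    list(kind = "event", sig = e$sig, event = e))
}

#' Construct events from a completed sentence state
#'
#' @param sentence prepared sentence.
#' @param state completed (acyclic) sentence state.
#' @param regdict regulation dictionary ([build_regulation_dictionary()]).
#' @return list of event records (type, tok, themes, cause, sig); the
#'   \code{sig} fields are the canonical signatures used by the loss and
#'   the evaluator.
#' @export
construct_events <- function(sentence, state, regdict = character()) {
  labels <- state$trigger_labels
  trig_toks <- which(!is.na(labels) & labels != 1L) - 1L
  trig_toks <- trig_toks[vapply(as.character(trig_toks), function(k)
    length(state$themes[[k]] %||% character()) > 0L, TRUE)]
  if (!length(trig_toks)) return(list())
  ## topological order: arguments before the triggers that use them
  order_out <- integer()
  visited <- character()
  visit <- function(tok) {
    key <- as.character(tok)
    if (key %in% visited) return(invisible())
    visited <<- c(visited, key)
    for (ak in c(state$themes[[key]] %||% character(),
                 state$causes[[key]] %||% character())) {
      if (startsWith(ak, "T:")) {
        at <- as.integer(substring(ak, 3L))
        if (at %in% trig_toks) visit(at)
      }
    }
    order_out <<- c(order_out, tok)
  }
  for (tok in sort(trig_toks)) visit(tok)

  by_tok <- list()
  all_events <- list()
  emit <- function(ev) all_events[[length(all_events) + 1L]] <<- ev
  for (tok in order_out) {
    key <- as.character(tok)
    ty <- TRIGGER_LABELS[labels[tok + 1L]]
    aks <- state$themes[[key]]
    atoks <- state$theme_toks[[key]]
    events <- list()
    mk <- function(themes, cause = NULL) {
      list(type = ty, tok = tok, themes = themes, cause = cause,
           sig = event_signature(ty, tok,
                                 vapply(themes, function(a) a$sig, ""),
                                 if (!is.null(cause)) cause$sig else NULL))
    }
    cls <- event_class(ty)
    if (cls == "Simple") {
      for (i in seq_along(aks)) {
        for (arg in resolve_arg(aks[i], atoks[i], by_tok))
          events[[length(events) + 1L]] <- mk(list(arg))
      }
    } else if (cls == "Binding") {
      prots <- lapply(seq_along(aks), function(i)
        resolve_arg(aks[i], atoks[i], by_tok)[[1]])
      ptoks <- atoks
      exception <- anyDuplicated(ptoks) > 0L || any(ptoks == tok) ||
        identical(sentence$tokens$lemma[tok + 1L], "bind")
      nominal <- startsWith(tok_field(sentence, tok, "pos"), "N")
      if (exception && length(prots) > 1L) {
        events[[1L]] <- mk(prots)
      } else if (nominal && length(prots) > 1L) {
        first_lab <- vapply(seq_along(prots), function(i) {
          p <- shortest_path(sentence, tok, ptoks[i])
          if (is.null(p)) "none" else p$labels[1]
        }, "")
        groups <- split(seq_along(prots), first_lab)
        combos <- expand.grid(groups, stringsAsFactors = FALSE)
        for (r in seq_len(nrow(combos))) {
          sel <- unlist(combos[r, ], use.names = FALSE)
          events[[length(events) + 1L]] <- mk(prots[sel])
        }
      } else {
        for (p in prots) events[[length(events) + 1L]] <- mk(list(p))
      }
    } else {  # Regulation class
      cks <- state$causes[[key]]
      ctoks <- state$cause_toks[[key]]
      cause_args <- if (!is.null(cks) && length(cks))
        resolve_arg(cks[1], ctoks[1], by_tok) else list()
      for (i in seq_along(aks)) {
        for (arg in resolve_arg(aks[i], atoks[i], by_tok)) {
          if (length(cause_args)) {
            for (ca in cause_args)
              events[[length(events) + 1L]] <- mk(list(arg), ca)
          } else {
            events[[length(events) + 1L]] <- mk(list(arg))
          }
        }
      }
    }
    ## dedupe by signature within the token
    sigs <- vapply(events, function(e) e$sig, "")
    events <- events[!duplicated(sigs)]
    by_tok[[key]] <- events
    for (e in events) emit(e)
    ## dictionary-stacked Regulation events over Simple events
    lemma <- sentence$tokens$lemma[tok + 1L]
    if (cls == "Simple" && lemma %in% names(regdict)) {
      rty <- regdict[[lemma]]
      for (e in events) {
        arg <- list(kind = "event", sig = e$sig, event = e)
        emit(list(type = rty, tok = tok, themes = list(arg), cause = NULL,
                  sig = event_signature(rty, tok, e$sig, NULL)))
      }
    }
  }
  sigs <- vapply(all_events, function(e) e$sig, "")
  all_events[!duplicated(sigs)]
}

#' Canonical signatures of the events a state constructs
#'
#' @inheritParams construct_events
#' @return character vector of unique event signatures.
#' @export
construct_event_signatures <- function(sentence, state, regdict = character()) {
  vapply(construct_events(sentence, state, regdict), function(e) e$sig, "")
}

#' Predict the events of a document
#'
#' Runs the policy over every sentence, constructs events, and returns both
#' per-sentence signatures and .a2-ready annotation (triggers with
#' head-token spans; events with document-wide ids).
#'
#' @param doc a parsed [new_document()].
#' @param policy a trained [searn_train()] policy.
#' @param offsets named per-stage score offsets (recall/precision control).
#' @param stochastic sample hypotheses per action instead of the
#'   deterministic ensemble.
#' @return list with \code{signatures} (character), \code{a2} (text) and
#'   \code{states} (per-sentence states).
#' @export
predict_document <- function(doc, policy,
                             offsets = c(trigger = 0, theme = 0, cause = 0),
                             stochastic = FALSE) {
  sigs <- character(); states <- list(); sent_events <- list()
  for (si in seq_along(doc$sentences)) {
    sent <- prepare_sentence(doc$sentences[[si]], doc$domain)
    orng <- swap_rng(derive_seed(policy$config$seed %||% 1L, 23L, si))
    st <- run_policy(sent, policy, mode = "test", offsets = offsets,
                     stochastic = stochastic)
    restore_rng(orng)
    evs <- construct_events(sent, st, policy$regdict)
    sigs <- c(sigs, vapply(evs, function(e) e$sig, ""))
    states[[si]] <- st
    sent_events[[si]] <- list(sentence = sent, events = evs)
  }
  list(signatures = unique(sigs), a2 = events_to_a2(doc, sent_events),
       states = states)
}

## Serialize per-sentence constructed events to .a2 text: one T-line per
## participating trigger token (head-token span), one E-line per unique
## event, ids assigned in sentence order then construction order.
events_to_a2 <- function(doc, sent_events) {
  next_t <- max(c(0L, as.integer(sub("^T", "", unlist(lapply(
    doc$sentences, function(s) s$proteins$ann_id))))), na.rm = TRUE) + 1L
  t_lines <- character(); e_lines <- character()
  e_count <- 0L
  for (se in sent_events) {
    sent <- se$sentence; evs <- se$events
    if (!length(evs)) next
    tid_of <- new.env(parent = emptyenv())  # "tok|type" -> T id
    eid_of <- new.env(parent = emptyenv())  # signature -> E id
    assign_ids <- function(e) {
      if (!is.null(eid_of[[e$sig]])) return(invisible())
      for (a in e$themes) if (!is.null(a$event)) assign_ids(a$event)
      if (!is.null(e$cause) && !is.null(e$cause$event)) assign_ids(e$cause$event)
      tkey <- paste0(e$tok, "|", e$type)
      if (is.null(tid_of[[tkey]])) {
        tid_of[[tkey]] <- paste0("T", next_t)
        next_t <<- next_t + 1L
        row <- sent$tokens[sent$tokens$index == e$tok, ]
        t_lines <<- c(t_lines, sprintf("%s\t%s %d %d\t%s", tid_of[[tkey]],
                                       e$type, row$char_start, row$char_end,
                                       row$surface))
      }
      e_count <<- e_count + 1L
      eid <- paste0("E", e_count)
      eid_of[[e$sig]] <- eid
      arg_ref <- function(a) {
        if (a$kind == "protein") a$id else eid_of[[a$event$sig]]
      }
      keys <- c("Theme", paste0("Theme", seq_along(e$themes))[-1])
      args <- paste0(keys, ":", vapply(e$themes, arg_ref, ""))
      if (!is.null(e$cause)) args <- c(args, paste0("Cause:", arg_ref(e$cause)))
      e_lines <<- c(e_lines, sprintf("%s\t%s:%s %s", eid, e$type, tid_of[[tkey]],
                                     paste(args, collapse = " ")))
    }
    for (e in evs) assign_ids(e)
  }
  paste(c(t_lines, e_lines), collapse = "\n")
}

#' Predict a whole corpus
#'
#' @param docs list of documents.
#' @param policy trained policy.
#' @inheritParams predict_document
#' @return named list doc_id -> character vector of event signatures.
#' @export
predict_corpus <- function(docs, policy,
                           offsets = c(trigger = 0, theme = 0, cause = 0),
                           stochastic = FALSE) {
  out <- lapply(docs, function(d)
    predict_document(d, policy, offsets, stochastic)$signatures)
  stats::setNames(out, vapply(docs, function(d) d$doc_id, ""))
}

#' Train the independent baseline
#'
#' The degenerate SEARN configuration: a single iteration (beta = 1), no
#' structural features, and 0/1 costs against the optimal policy -- i.e. a
#' pipeline of independently trained classifiers over gold-derived inputs.
#'
#' @param corpus gold-annotated documents.
#' @param C,rounds,seed passive-aggressive hyperparameters.
#' @param domain_adapt enable feature-augmentation domain adaptation.
#' @return a [searn_train()] policy with a single hypothesis per stage.
#' @export
train_independent <- function(corpus, C = 1, rounds = 5, seed = 1L,
                              domain_adapt = FALSE) {
  cfg <- searn_config(beta = 1, iterations = 1, C = C, rounds = rounds,
                      structural = FALSE, zero_one_costs = TRUE,
                      domain_adapt = domain_adapt, seed = seed)
  searn_train(corpus, cfg)
}

## Policy serialization -------------------------------------------------------

#' Save / load a policy as JSON
#'
#' The bundle holds the per-iteration stage classifiers (sparse weight
#' maps), the mixture weights, the regulation dictionary and the training
#' configuration; \code{load_policy(save_policy(p))} predicts identically.
#'
#' @param policy a trained policy.
#' @param path output file.
#' @export
save_policy <- function(policy, path) {
  x <- list(weights = policy$weights, beta = policy$beta,
            iterations = policy$iterations,
            optimal_policy_prob = policy$optimal_policy_prob,
            structural = policy$structural, domain_adapt = policy$domain_adapt,
            regdict = as.list(policy$regdict),
            config = unclass(policy$config),
            hyps = lapply(policy$hyps, function(h)
              lapply(h, csc_to_list)))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_policy
#' @param path path to a saved policy.
#' @export
load_policy <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg <- x$config
  hyps <- lapply(x$hyps, function(h) {
    lapply(stats::setNames(c("trigger", "theme", "cause"),
                           c("trigger", "theme", "cause")), function(stg) {
      hl <- h[[stg]]
      if (is.null(hl)) return(NULL)
      hl$features <- unlist(hl$features)
      hl$weights <- lapply(hl$weights, function(w) unlist(w))
      csc_from_list(hl)
    })
  })
  structure(list(hyps = hyps, weights = unlist(x$weights), beta = x$beta,
                 iterations = x$iterations,
                 optimal_policy_prob = x$optimal_policy_prob,
                 structural = x$structural, domain_adapt = x$domain_adapt,
                 regdict = unlist(x$regdict) %||% character(),
                 config = structure(lapply(cfg, function(v)
                   if (is.list(v)) unlist(v) else v), class = "searn_config")),
            class = "searn_policy")
}
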