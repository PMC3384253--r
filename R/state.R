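## SentenceState: the partial or complete action sequence for one sentence.
## Implemented as an environment so the executor can update it in place.

#' Create an empty sentence state
#'
#' Holds the trigger label assigned to each token (NA until the token's
#' action is taken; label 1 is "No_trigger"), the Theme and Cause edges
#' keyed by trigger token, and the ordered action log.
#'
#' @param n_tokens number of tokens in the sentence.
#' @return an environment of class "bio_state".
#' @export
new_state <- function(n_tokens) {
  st <- new.env(parent = emptyenv())
  st$trigger_labels <- rep(NA_integer_, n_tokens)
  st$themes <- list()      # token(chr) -> character argkeys, in order
  st$theme_toks <- list()  # token(chr) -> integer arg head tokens
  st$causes <- list()
  st$cause_toks <- list()
  st$action_log <- list()
  class(st) <- "bio_state"
  st
}

state_trigger_type <- function(state, tok) {
  l <- state$trigger_labels[tok + 1L]
  if (is.na(l) || l == 1L) NA_character_ else TRIGGER_LABELS[l]
}

add_theme_edge <- function(state, trigger, arg_key, arg_tok) {
  key <- as.character(trigger)
  state$themes[[key]] <- c(state$themes[[key]], arg_key)
  state$theme_toks[[key]] <- c(state$theme_toks[[key]], arg_tok)
  invisible(state)
}

add_cause_edge <- function(state, trigger, arg_key, arg_tok) {
  key <- as.character(trigger)
  state$causes[[key]] <- c(state$causes[[key]], arg_key)
  state$cause_toks[[key]] <- c(state$cause_toks[[key]], arg_tok)
  invisible(state)
}

## are two nodes already connected over the undirected Theme-edge graph?
themes_connect <- function(state, node_a, node_b) {
  edges <- list()
  for (key in names(state$themes)) {
    tn <- paste0("T:", key)
    for (ak in state$themes[[key]]) edges[[length(edges) + 1L]] <- c(tn, ak)
  }
  if (!length(edges)) return(FALSE)
  frontier <- node_a; seen <- character()
  while (length(frontier)) {
    x <- frontier[[1]]; frontier <- frontier[-1]
    if (x %in% seen) next
    if (x == node_b) return(TRUE)
    seen <- c(seen, x)
    for (e in edges) {
      if (e[1] == x && !(e[2] %in% seen)) frontier <- c(frontier, e[2])
      if (e[2] == x && !(e[1] %in% seen)) frontier <- c(frontier, e[1])
    }
  }
  FALSE
}

## Gold decomposition: per-token trigger labels and token-level Theme/Cause
## edges, the raw material of the optimal policy.  Tokens carrying both a
## Simple-class and a Regulation-class gold trigger (the "overexpress"
## pattern) are labeled with the non-Regulation type; the stacked
## Regulation event is reproduced by the regulation dictionary at event
## construction, so its edges are excluded from the decomposition.
decompose_gold <- function(sentence) {
  n <- nrow(sentence$tokens)
  tr <- sentence$gold_triggers
  gold_label <- rep(1L, n)
  dual_reg_trigs <- character()
  if (!is.null(tr) && nrow(tr)) {
    for (tok in unique(tr$head_token)) {
      types <- tr$type[tr$head_token == tok]
      if (length(types) == 1L) {
        gold_label[tok + 1L] <- match(types, TRIGGER_LABELS)
      } else {
        nonreg <- sort(types[!is_regulation_type(types)])
        chosen <- if (length(nonreg)) nonreg[1] else sort(types)[1]
        gold_label[tok + 1L] <- match(chosen, TRIGGER_LABELS)
        dual_reg_trigs <- c(dual_reg_trigs,
                            tr$ann_id[tr$head_token == tok & tr$type != chosen])
      }
    }
  }
  trig_head <- if (!is.null(tr)) stats::setNames(tr$head_token, tr$ann_id)
               else integer()
  gold_themes <- list(); gold_causes <- list()
  gold_theme_toks <- list(); gold_cause_toks <- list()
  evs <- sentence$gold_events %||% list()
  ev_head <- stats::setNames(
    vapply(evs, function(e) trig_head[[e$trigger_id]], 0L),
    vapply(evs, function(e) e$ann_id, ""))
  for (e in evs) {
    if (e$trigger_id %in% dual_reg_trigs) next
    tt <- trig_head[[e$trigger_id]]
    key <- as.character(tt)
    argkey <- function(a) {
      if (a$kind == "protein") list(k = paste0("P:", a$id), tok = NA_integer_)
      else list(k = paste0("T:", ev_head[[a$id]]), tok = ev_head[[a$id]])
    }
    for (a in e$themes) {
      ak <- argkey(a)
      if (!is.na(ak$tok) && ak$tok == tt) next  # self-edge (dictionary event)
      if (!(ak$k %in% gold_themes[[key]])) {
        gold_themes[[key]] <- c(gold_themes[[key]], ak$k)
        gold_theme_toks[[key]] <- c(gold_theme_toks[[key]], ak$tok)
      }
    }
    if (!is.null(e$cause)) {
      ak <- argkey(e$cause)
      if (is.na(ak$tok) || ak$tok != tt) {
        if (!(ak$k %in% gold_causes[[key]])) {
          gold_causes[[key]] <- c(gold_causes[[key]], ak$k)
          gold_cause_toks[[key]] <- c(gold_cause_toks[[key]], ak$tok)
        }
      }
    }
  }
  list(.gold_label = gold_label,
       .gold_themes = gold_themes, .gold_theme_toks = gold_theme_toks,
       .gold_causes = gold_causes, .gold_cause_toks = gold_cause_toks,
       .gold_sigs = gold_event_signatures(sentence))
}
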