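## Dependency-graph utilities: shortest unlexicalized dependency paths
## (followed in either direction), trigger head reduction, candidate-pair
## agendas for Theme and Cause assignment, action ordering and directed
## cycle checks.

## Adjacency representation: for each token, the incident directed edges as
## (neighbor, label, direction) with direction "d" when the edge is
## traversed head -> dependent and "u" for dependent -> head.
sentence_adjacency <- function(sentence) {
  n <- nrow(sentence$tokens)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- list(nb = integer(), lab = character(),
                                         dir = character())
  d <- sentence$deps
  for (k in seq_len(nrow(d))) {
    h <- d$head[k] + 1L; t <- d$dependent[k]; l <- d$label[k]
    adj[[h]]$nb <- c(adj[[h]]$nb, t)
    adj[[h]]$lab <- c(adj[[h]]$lab, l)
    adj[[h]]$dir <- c(adj[[h]]$dir, "d")
    adj[[t + 1L]]$nb <- c(adj[[t + 1L]]$nb, h - 1L)
    adj[[t + 1L]]$lab <- c(adj[[t + 1L]]$lab, l)
    adj[[t + 1L]]$dir <- c(adj[[t + 1L]]$dir, "u")
  }
  adj
}

#' Shortest dependency path between two tokens
#'
#' Minimal edge-count path over the dependency graph, allowing each edge to
#' be followed in either direction; each step is annotated with the edge
#' label and the direction taken ("d" head-to-dependent, "u"
#' dependent-to-head).  Among equal-length paths the one with the
#' lexicographically smallest label-direction string is returned, so path
#' features are deterministic.
#'
#' @param sentence a [new_sentence()] object.
#' @param a,b 0-based token indices, \code{a != b}.
#' @return NULL when disconnected, else a list with \code{length},
#'   \code{labels}, \code{dirs}, \code{nodes} (token index sequence
#'   including endpoints), \code{string} (unlexicalized form).
#' @export
shortest_path <- function(sentence, a, b) {
  n <- nrow(sentence$tokens)
  if (a == b) stop("endpoints must differ")
  if (a < 0L || b < 0L || a >= n || b >= n) stop("token index out of range")
  cache <- sentence$.pathcache
  ckey <- paste0(a, "|", b)
  if (!is.null(cache)) {
    hit <- cache[[ckey]]
    if (!is.null(hit)) return(if (identical(hit, "none")) NULL else hit)
  }
  adj <- sentence$.adj %||% sentence_adjacency(sentence)
  ## Dijkstra over (distance, path-string) with string as tie-break; graphs
  ## are sentence-sized so a simple frontier scan is adequate.
  INF <- .Machine$integer.max
  dist <- rep(INF, n); pstr <- rep(NA_character_, n)
  plab <- vector("list", n); pdir <- vector("list", n); pnod <- vector("list", n)
  dist[a + 1L] <- 0L; pstr[a + 1L] <- ""
  plab[[a + 1L]] <- character(); pdir[[a + 1L]] <- character()
  pnod[[a + 1L]] <- a
  done <- rep(FALSE, n)
  repeat {
    cand <- which(!done & dist < INF)
    if (!length(cand)) break
    o <- cand[order(dist[cand], pstr[cand])][1]
    done[o] <- TRUE
    if (o == b + 1L) break
    e <- adj[[o]]
    for (k in seq_along(e$nb)) {
      v <- e$nb[k] + 1L
      step <- paste0(e$lab[k], "/", e$dir[k])
      nd <- dist[o] + 1L
      ns <- if (nzchar(pstr[o])) paste0(pstr[o], "|", step) else step
      if (nd < dist[v] || (nd == dist[v] && !done[v] && ns < pstr[v])) {
        dist[v] <- nd; pstr[v] <- ns
        plab[[v]] <- c(plab[[o]], e$lab[k])
        pdir[[v]] <- c(pdir[[o]], e$dir[k])
        pnod[[v]] <- c(pnod[[o]], e$nb[k])
      }
    }
  }
  res <- if (dist[b + 1L] == INF) NULL else
    list(length = dist[b + 1L], labels = plab[[b + 1L]], dirs = pdir[[b + 1L]],
         nodes = pnod[[b + 1L]], string = pstr[b + 1L])
  if (!is.null(cache)) cache[[ckey]] <- if (is.null(res)) "none" else res
  res
}

#' Prepare a sentence for prediction
#'
#' Attaches derived structures used by the extractor: the adjacency list of
#' the dependency graph, a memoising cache for shortest paths, the
#' candidate trigger tokens (nouns/verbs/adjectives) and the gold
#' decomposition (per-token trigger labels and token-level Theme/Cause
#' edges) when gold annotation is present.
#'
#' @param sentence a [new_sentence()] object.
#' @param domain the document's domain label.
#' @return the sentence with cached fields added.
#' @export
prepare_sentence <- function(sentence, domain = "abstract") {
  sentence$.adj <- sentence_adjacency(sentence)
  sentence$.pathcache <- new.env(parent = emptyenv())
  sentence$.cand <- candidate_tokens(sentence)
  sentence$domain <- domain
  sentence <- c(sentence, decompose_gold(sentence))
  class(sentence) <- "bio_sentence"
  sentence
}

## head token of a (possibly multi-token) annotation span: the token within
## the span whose dependency head lies outside the span; if several qualify,
## the rightmost.  Single-token spans are returned unchanged.
trigger_head_token <- function(sentence, char_start, char_end) {
  tk <- sentence$tokens
  ov <- pmin(tk$char_end, char_end) - pmax(tk$char_start, char_start)
  inside <- which(ov > 0L)
  if (!length(inside)) stop("trigger span ", char_start, "..", char_end,
                            " overlaps no token")
  if (length(inside) == 1L) return(tk$index[inside])
  span_idx <- tk$index[inside]
  d <- sentence$deps
  has_outside_head <- vapply(span_idx, function(i) {
    heads <- d$head[d$dependent == i]
    !length(heads) || any(!(heads %in% span_idx))
  }, TRUE)
  cand <- span_idx[has_outside_head]
  if (!length(cand)) cand <- span_idx
  max(cand)
}

#' Reduce a multi-token gold trigger to its syntactic head
#'
#' Returns the trigger with its span replaced by the span of the head
#' token: the token inside the original span whose dependency head lies
#' outside the span (rightmost such token if several).  Idempotent on
#' single-token triggers.
#'
#' @param trigger one-row data.frame with columns ann_id, type, char_start,
#'   char_end (head_token optional).
#' @param sentence the sentence containing the trigger.
#' @return the trigger row with char_start/char_end/head_token covering
#'   exactly one token.
#' @export
reduce_trigger_to_head <- function(trigger, sentence) {
  ht <- trigger_head_token(sentence, trigger$char_start, trigger$char_end)
  row <- sentence$tokens[sentence$tokens$index == ht, ]
  trigger$char_start <- row$char_start
  trigger$char_end <- row$char_end
  trigger$head_token <- ht
  trigger
}

## Candidate trigger tokens: nouns, verbs and adjectives by coarse PoS
## (N*, V*, J*).
candidate_tokens <- function(sentence) {
  sel <- grepl("^[NVJ]", sentence$tokens$pos)
  sentence$tokens$index[sel]
}

#' Does adding an edge create a directed cycle?
#'
#' Checks reachability of \code{trigger} from \code{argument} over the
#' union of the state's Theme and Cause edges (argument keys of the form
#' "T:<token>"; protein arguments cannot start cycles).
#'
#' @param state a sentence state (see [new_state()]).
#' @param trigger 0-based trigger token index.
#' @param arg_key argument key ("P:<ann_id>" or "T:<token>").
#' @return TRUE iff the edge trigger -> argument would close a directed cycle.
#' @export
creates_directed_cycle <- function(state, trigger, arg_key) {
  if (!startsWith(arg_key, "T:")) return(FALSE)
  start <- as.integer(substring(arg_key, 3L))
  target <- paste0("T:", trigger)
  seen <- character(); frontier <- start
  while (length(frontier)) {
    tok <- frontier[[1]]; frontier <- frontier[-1]
    key <- as.character(tok)
    if (key %in% seen) next
    seen <- c(seen, key)
    outs <- c(state$themes[[key]] %||% character(),
              state$causes[[key]] %||% character())
    if (target %in% outs) return(TRUE)
    ev <- outs[startsWith(outs, "T:")]
    frontier <- c(frontier, as.integer(substring(ev, 3L)))
  }
  FALSE
}

## A candidate pair: trigger token, argument key, cached dependency path
## (NULL when disconnected), argument head token, insertion rank.
make_pair <- function(sentence, trigger, arg_key, arg_tok, rank) {
  path <- if (trigger == arg_tok) NULL else
    shortest_path(sentence, trigger, arg_tok)
  list(trigger = trigger, arg_key = arg_key, arg_tok = arg_tok,
       path = path, plen = if (is.null(path)) Inf else path$length,
       rank = rank)
}

#' Order candidate pairs for prediction
#'
#' Stable sort by increasing dependency path length; pairs with no
#' connecting path are ordered last; ties keep agenda insertion order.
#'
#' @param pairs list of candidate pairs.
#' @return the reordered list.
#' @export
order_actions <- function(pairs) {
  if (!length(pairs)) return(pairs)
  len <- vapply(pairs, function(p) p$plen, 0)
  rk <- vapply(pairs, function(p) p$rank, 0)
  pairs[order(len, rk)]
}

#' Initial Theme agenda for a sentence state
#'
#' Candidate pairs between every predicted trigger and every protein in the
#' sentence, ordered by increasing dependency path length (insertion order
#' on ties).  Pairs between Regulation-class triggers and other triggers
#' are added dynamically as those triggers receive Themes (see
#' [run_policy()]); pairs that would close a directed cycle are excluded
#' when popped.
#'
#' @param sentence a prepared sentence.
#' @param state a [new_state()] with trigger labels assigned.
#' @return ordered list of candidate pairs.
#' @export
build_theme_agenda <- function(sentence, state) {
  pairs <- list(); rank <- 0L
  trig_toks <- which(state$trigger_labels != 1L) - 1L
  for (tt in trig_toks) {
    pr <- sentence$proteins
    for (i in seq_len(nrow(pr))) {
      rank <- rank + 1L
      pairs[[length(pairs) + 1L]] <- make_pair(
        sentence, tt, paste0("P:", pr$ann_id[i]), pr$head_token[i], rank)
    }
  }
  order_actions(pairs)
}

#' Cause agenda for a sentence state
#'
#' Candidate pairs between the Regulation-class triggers that were assigned
#' at least one Theme and (a) all proteins and (b) the other triggers that
#' were assigned a Theme; no self-pairs, cycle-closing pairs excluded.
#'
#' @inheritParams build_theme_agenda
#' @return ordered list of candidate pairs.
#' @export
build_cause_agenda <- function(sentence, state) {
  pairs <- list(); rank <- 0L
  themed <- as.integer(names(state$themes)[
    vapply(state$themes, length, 0L) > 0L])
  reg_themed <- themed[is_regulation_type(
    TRIGGER_LABELS[state$trigger_labels[themed + 1L]])]
  for (tt in sort(reg_themed)) {
    pr <- sentence$proteins
    for (i in seq_len(nrow(pr))) {
      rank <- rank + 1L
      pairs[[length(pairs) + 1L]] <- make_pair(
        sentence, tt, paste0("P:", pr$ann_id[i]), pr$head_token[i], rank)
    }
    for (at in sort(themed)) {
      if (at == tt) next
      key <- paste0("T:", at)
      if (creates_directed_cycle(state, tt, key)) next
      rank <- rank + 1L
      pairs[[length(pairs) + 1L]] <- make_pair(sentence, tt, key, at, rank)
    }
  }
  order_actions(pairs)
}
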