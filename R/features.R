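## Sparse binary feature extraction for the three classification stages.
## A feature vector is a character vector of feature names (all indicators
## with value 1); names are namespaced by stage and template.  Structural
## features -- those that read earlier predictions from the sentence state
## -- are emitted only when structural = TRUE, so the independent baseline
## (which must be a pure function of the sentence) can switch them off.

tok_field <- function(sentence, tok, field) sentence$tokens[[field]][tok + 1L]

dep_neighbors <- function(sentence, tok) {
  adj <- sentence$.adj %||% sentence_adjacency(sentence)
  adj[[tok + 1L]]$nb
}

#' Trigger recognition features
#'
#' Lemma, lemma x PoS, lemma conjoined with the immediately surrounding
#' lemmas and with the lemmas of dependency neighbours; when
#' \code{structural}, also the lemma conjoined with the event types already
#' assigned to the previous/next token and the event types assigned to
#' dependency neighbours.
#'
#' @param sentence prepared sentence.
#' @param token 0-based candidate token index.
#' @param state sentence state (used only when \code{structural}).
#' @param structural emit features that read previous predictions.
#' @return character vector of feature names.
#' @export
trigger_features <- function(sentence, token, state = NULL, structural = FALSE) {
  lm <- tok_field(sentence, token, "lemma")
  n <- nrow(sentence$tokens)
  f <- c(paste0("trg:lm=", lm),
         paste0("trg:lm+pos=", lm, "|", tok_field(sentence, token, "pos")))
  if (token > 0L)
    f <- c(f, paste0("trg:lm+prev=", lm, "|", tok_field(sentence, token - 1L, "lemma")))
  if (token < n - 1L)
    f <- c(f, paste0("trg:lm+next=", lm, "|", tok_field(sentence, token + 1L, "lemma")))
  nbs <- dep_neighbors(sentence, token)
  if (length(nbs))
    f <- c(f, paste0("trg:lm+dep=", lm, "|",
                     sentence$tokens$lemma[nbs + 1L]))
  if (structural && !is.null(state)) {
    if (token > 0L) {
      ty <- state_trigger_type(state, token - 1L)
      if (!is.na(ty)) f <- c(f, paste0("trg:lm+prevtype=", lm, "|", ty))
    }
    if (token < n - 1L) {
      ty <- state_trigger_type(state, token + 1L)
      if (!is.na(ty)) f <- c(f, paste0("trg:lm+nexttype=", lm, "|", ty))
    }
    for (nb in nbs) {
      ty <- state_trigger_type(state, nb)
      if (!is.na(ty)) f <- c(f, paste0("trg:deptype=", ty))
    }
  }
  unique(f)
}

between_string <- function(sentence, a, b, cap = 10L) {
  lo <- min(a, b); hi <- max(a, b)
  if (hi - lo <= 1L) return("")
  mids <- sentence$tokens$lemma[(lo + 2L):hi]  # tokens strictly between
  if (length(mids) > cap) mids <- mids[seq_len(cap)]
  paste(mids, collapse = "_")
}

path_pair_features <- function(sentence, pair, state, prefix) {
  t <- pair$trigger
  ttype <- state_trigger_type(state, t)
  if (is.na(ttype)) ttype <- "None"
  atype <- if (startsWith(pair$arg_key, "P:")) "Protein" else {
    ty <- state_trigger_type(state, pair$arg_tok)
    if (is.na(ty)) "None" else ty
  }
  f <- character()
  if (!is.null(pair$path)) {
    p <- pair$path$string
    nodes <- pair$path$nodes
    first_lm <- sentence$tokens$lemma[nodes[min(2L, length(nodes))] + 1L]
    last_lm <- sentence$tokens$lemma[nodes[max(1L, length(nodes) - 1L)] + 1L]
    f <- c(f,
           paste0(prefix, ":p=", p),
           paste0(prefix, ":p+tl=", p, "|", tok_field(sentence, t, "lemma")),
           paste0(prefix, ":p+tp=", p, "|", tok_field(sentence, t, "pos")),
           paste0(prefix, ":p+te=", p, "|", ttype),
           paste0(prefix, ":p+at=", p, "|", atype),
           paste0(prefix, ":p+fl=", p, "|", first_lm),
           paste0(prefix, ":p+ll=", p, "|", last_lm))
  }
  c(f, paste0(prefix, ":bw=", between_string(sentence, t, pair$arg_tok),
              "|", ttype))
}

#' Theme assignment features
#'
#' Shortest-dependency-path templates (path alone and conjoined with the
#' trigger's lemma/PoS/event type, the argument type, and the first/last
#' lemmas on the path) plus the between-string fallback; when
#' \code{structural}, also the four history indicators: undirected Theme
#' cycle, protein-Theme/event-argument mixtures, argument shared with a
#' same-type trigger, and the trigger already having three Themes.
#'
#' @param sentence prepared sentence.
#' @param pair candidate pair from the Theme agenda.
#' @param state sentence state.
#' @param structural emit features that read previous predictions.
#' @return character vector of feature names.
#' @export
theme_features <- function(sentence, pair, state, structural = FALSE) {
  f <- path_pair_features(sentence, pair, state, "th")
  if (structural) {
    t <- pair$trigger
    key <- as.character(t)
    my_themes <- state$themes[[key]] %||% character()
    arg_is_event <- startsWith(pair$arg_key, "T:")
    if (themes_connect(state, paste0("T:", t), pair$arg_key))
      f <- c(f, "th:s:ucycle")
    has_prot <- any(startsWith(my_themes, "P:"))
    has_ev <- any(startsWith(my_themes, "T:"))
    if (has_prot && arg_is_event) f <- c(f, "th:s:prot-theme+ev-arg")
    if (has_ev && !arg_is_event) f <- c(f, "th:s:ev-theme+prot-arg")
    ttype <- state_trigger_type(state, t)
    if (!is.na(ttype)) {
      for (okey in names(state$themes)) {
        if (okey == key) next
        ot <- as.integer(okey)
        if (identical(state_trigger_type(state, ot), ttype) &&
            pair$arg_key %in% state$themes[[okey]]) {
          f <- c(f, "th:s:arg-shares-type")
          break
        }
      }
    }
    if (length(my_themes) >= 3L) f <- c(f, "th:s:three-themes")
  }
  unique(f)
}

#' Cause assignment features
#'
#' All Theme templates (under the "ca" namespace) plus the conjunction of
#' the candidate pair's dependency path with the path(s) from the trigger
#' to each of its assigned Themes; when \code{structural}, indicators for
#' the trigger already having a protein Cause and for the candidate Cause
#' being an event trigger.
#'
#' @inheritParams theme_features
#' @return character vector of feature names.
#' @export
cause_features <- function(sentence, pair, state, structural = FALSE) {
  t <- pair$trigger
  key <- as.character(t)
  theme_toks <- state$theme_toks[[key]]
  if (is.null(theme_toks) || !length(theme_toks))
    stop("cause features requested for a trigger without Themes")
  f <- path_pair_features(sentence, pair, state, "ca")
  p <- if (!is.null(pair$path)) pair$path$string else "none"
  for (tt in theme_toks) {
    tp <- if (is.na(tt) || tt == t) NULL else shortest_path(sentence, t, tt)
    tps <- if (is.null(tp)) "none" else tp$string
    f <- c(f, paste0("ca:p+thp=", p, "|", tps))
  }
  if (structural) {
    my_causes <- state$causes[[key]] %||% character()
    if (any(startsWith(my_causes, "P:"))) f <- c(f, "ca:s:has-prot-cause")
    if (startsWith(pair$arg_key, "T:")) f <- c(f, "ca:s:ev-arg")
  }
  unique(f)
}

#' Domain-adaptation feature augmentation
#'
#' Duplicates every feature with a domain-conjoined copy, so shared and
#' domain-specific behaviour receive separate weights.  For any token only
#' the original and its own domain's copy are ever active.
#'
#' @param fv character vector of feature names.
#' @param domain "abstract" or "fullpaper".
#' @return character vector of length \code{2 * length(fv)}.
#' @export
augment_domain <- function(fv, domain) {
  if (!(domain %in% c("abstract", "fullpaper")))
    stop("unknown domain: ", domain)
  if (!length(fv)) return(fv)
  c(fv, paste0("d=", domain, "|", fv))
}

## Stage dispatcher used by the policy executor.
action_features <- function(sentence, stage, site, state, structural,
                            domain_adapt = FALSE) {
  f <- switch(stage,
              trigger = trigger_features(sentence, site, state, structural),
              theme = theme_features(sentence, site, state, structural),
              cause = cause_features(sentence, site, state, structural),
              stop("unknown stage: ", stage))
  if (domain_adapt) f <- augment_domain(f, sentence$domain %||% "abstract")
  f
}
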