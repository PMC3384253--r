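#' @keywords internal
"_PACKAGE"

## Sentence constructor ------------------------------------------------------

#' Construct a sentence
#'
#' A sentence is the unit instance of structured prediction: tokens with
#' lemmas, PoS tags and character offsets, a (possibly disconnected)
#' dependency graph, the protein mentions it contains, and optionally the
#' gold triggers and events used for training.
#'
#' All token indices are 0-based.  Character offsets are 0-based, half-open
#' and refer to the document text.
#'
#' @param tokens data.frame with columns index, surface, lemma, pos,
#'   char_start, char_end.
#' @param deps data.frame with columns head, dependent, label (token
#'   indices); may have zero rows.
#' @param proteins data.frame with columns ann_id, char_start, char_end,
#'   head_token; may have zero rows.
#' @param gold_triggers data.frame with columns ann_id, type, char_start,
#'   char_end, head_token, or NULL.
#' @param gold_events list of gold event records (see [parse_a2()]), or NULL.
#' @param index 0-based sentence index within the document.
#' @return object of class "bio_sentence".
#' @export
new_sentence <- function(tokens, deps = NULL, proteins = NULL,
                         gold_triggers = NULL, gold_events = NULL,
                         index = 0L) {
  n <- nrow(tokens)
  if (n == 0L) stop("sentence must contain at least one token")
  if (!identical(as.integer(tokens$index), seq_len(n) - 1L))
    stop("token indices must be contiguous from 0")
  if (is.null(deps)) deps <- data.frame(head = integer(), dependent = integer(),
                                        label = character())
  if (nrow(deps)) {
    bad <- deps$head == deps$dependent |
      deps$head < 0L | deps$head >= n | deps$dependent < 0L | deps$dependent >= n
    if (any(bad)) stop("invalid dependency edge (self-loop or out of range)")
  }
  if (is.null(proteins))
    proteins <- data.frame(ann_id = character(), char_start = integer(),
                           char_end = integer(), head_token = integer())
  structure(list(tokens = tokens, deps = deps, proteins = proteins,
                 gold_triggers = gold_triggers, gold_events = gold_events,
                 index = as.integer(index)),
            class = "bio_sentence")
}

#' Construct a document
#'
#' @param doc_id document identifier.
#' @param text full document text.
#' @param sentences list of [new_sentence()] objects, in order.
#' @param domain "abstract" or "fullpaper".
#' @return object of class "bio_document".
#' @export
new_document <- function(doc_id, text, sentences = list(),
                         domain = c("abstract", "fullpaper")) {
  domain <- match.arg(domain)
  structure(list(doc_id = doc_id, text = text, domain = domain,
                 sentences = sentences),
            class = "bio_document")
}

#' @export
print.bio_document <- function(x, ...) {
  nev <- sum(vapply(x$sentences,
                    function(s) length(s$gold_events %||% list()), 0L))
  cat(sprintf("<bio_document %s: %d sentences, %d proteins, %d gold events, domain=%s>\n",
              x$doc_id, length(x$sentences),
              sum(vapply(x$sentences, function(s) nrow(s$proteins), 0L)),
              nev, x$domain))
  invisible(x)
}

#' @export
print.bio_sentence <- function(x, ...) {
  cat(sprintf("<bio_sentence #%d: %s>\n", x$index,
              paste(x$tokens$surface, collapse = " ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Event signatures ----------------------------------------------------------

## A predicted or gold event is reduced to a canonical character signature:
##   <type>@<trigger token>(T=<sorted theme sigs>)[<C=<cause sig>>]
## with protein arguments written as P:<ann_id>.  Two events match (for the
## loss and the evaluator) iff their signatures are equal, which realises the
## task rule that an event is correct only if all of its elements -- trigger
## head, type, Themes and Cause, recursively -- are correct.
event_signature <- function(type, trigger_tok, theme_sigs, cause_sig = NULL) {
  if (length(theme_sigs) > 1L)
    theme_sigs <- sort.int(theme_sigs, method = "radix")
  s <- paste0(type, "@", trigger_tok,
              "(T=", paste(theme_sigs, collapse = ","), ")")
  if (!is.null(cause_sig)) s <- paste0(s, "<C=", cause_sig, ">")
  s
}

signature_type <- function(sigs) sub("@.*$", "", sigs)

#' Canonical signatures of a sentence's gold events
#'
#' Resolves nested references and reduces every event to the canonical
#' signature used by the loss function and the evaluator.  Triggers are
#' identified by their head token, so triggers must have been head-reduced
#' (see [reduce_trigger_to_head()]) for signatures to be comparable with
#' predictions.
#'
#' @param sentence a [new_sentence()] object with gold annotations.
#' @return character vector of signatures (one per gold event).
#' @export
gold_event_signatures <- function(sentence) {
  evs <- sentence$gold_events %||% list()
  if (!length(evs)) return(character())
  byid <- stats::setNames(evs, vapply(evs, function(e) e$ann_id, ""))
  trig_head <- stats::setNames(sentence$gold_triggers$head_token,
                               sentence$gold_triggers$ann_id)
  memo <- new.env(parent = emptyenv())
  sig_of <- function(id, seen = character()) {
    if (id %in% seen) stop("cyclic event reference at ", id)
    if (!is.null(memo[[id]])) return(memo[[id]])
    e <- byid[[id]]
    if (is.null(e)) stop("dangling event reference: ", id)
    arg_sig <- function(a) {
      if (a$kind == "protein") paste0("P:", a$id)
      else sig_of(a$id, c(seen, id))
    }
    th <- vapply(e$themes, arg_sig, "")
    ca <- if (!is.null(e$cause)) arg_sig(e$cause) else NULL
    s <- event_signature(e$type, trig_head[[e$trigger_id]], th, ca)
    memo[[id]] <- s
    s
  }
  unname(vapply(names(byid), sig_of, ""))
}
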