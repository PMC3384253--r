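## A small built-in document with one fully annotated sentence containing
## three nested events.  It is used in the package documentation and the
## acceptance checks to demonstrate the decomposition, the optimal policy
## and focused costing.

#' The nested-event demonstration document
#'
#' One sentence, "SQ 22536 suppressed gp41-induced IL-10 production in
#' monocytes", annotated with two proteins (gp41, IL-10) and three nested
#' gold events: a Gene_expression on "production" with Theme IL-10, a
#' Positive_regulation on "induced" with that event as Theme and gp41 as
#' Cause, and a Negative_regulation on "suppressed" over the
#' Positive_regulation event.
#'
#' @return a gold-annotated [new_document()] object.
#' @export
demo_document <- function() {
  surfaces <- c("SQ", "22536", "suppressed", "gp41", "-", "induced",
                "IL-10", "production", "in", "monocytes")
  lemmas <- c("SQ", "22536", "suppress", "gp41", "-", "induce",
              "IL-10", "production", "in", "monocyte")
  pos <- c("NN", "CD", "VBD", "NN", "HYPH", "VBN", "NN", "NN", "IN", "NNS")
  lens <- nchar(surfaces)
  starts <- cumsum(c(0L, lens + 1L))[seq_along(surfaces)]
  ends <- starts + lens
  tokens <- data.frame(index = seq_along(surfaces) - 1L, surface = surfaces,
                       lemma = lemmas, pos = pos,
                       char_start = starts, char_end = ends)
  deps <- data.frame(
    head      = c(1L, 2L, 2L, 7L, 5L, 7L, 2L),
    dependent = c(0L, 1L, 7L, 5L, 3L, 6L, 9L),
    label     = c("nn", "nsubj", "dobj", "amod", "nn", "nn", "prep_in"))
  proteins <- data.frame(ann_id = c("T1", "T2"),
                         char_start = c(starts[4], starts[7]),
                         char_end = c(ends[4], ends[7]),
                         head_token = c(3L, 6L))
  gold_triggers <- data.frame(
    ann_id = c("T3", "T4", "T5"),
    type = c("Negative_regulation", "Positive_regulation", "Gene_expression"),
    char_start = c(starts[3], starts[6], starts[8]),
    char_end = c(ends[3], ends[6], ends[8]),
    head_token = c(2L, 5L, 7L))
  gold_events <- list(
    list(ann_id = "E1", type = "Gene_expression", trigger_id = "T5",
         themes = list(list(kind = "protein", id = "T2")), cause = NULL),
    list(ann_id = "E2", type = "Positive_regulation", trigger_id = "T4",
         themes = list(list(kind = "event", id = "E1")),
         cause = list(kind = "protein", id = "T1")),
    list(ann_id = "E3", type = "Negative_regulation", trigger_id = "T3",
         themes = list(list(kind = "event", id = "E2")), cause = NULL))
  s <- new_sentence(tokens, deps, proteins, gold_triggers, gold_events)
  new_document("demo0001", paste(surfaces, collapse = " "), list(s), "abstract")
}

#' A gold-shaped rollout decider
#'
#' A decider that emulates a partially learned hypothesis: trigger actions
#' follow the gold standard, while Theme and Cause actions attach an
#' argument whenever the gold decomposition contains that trigger-argument
#' edge, regardless of whether the trigger's assigned event type is
#' correct.  \code{extra_themes} ("<trigger token>><arg key>" strings)
#' injects additional Theme attachments, emulating specific mistakes.
#' Useful for scripting cost-estimation scenarios.
#'
#' @param sentence a prepared, gold-annotated sentence.
#' @param extra_themes character vector of extra Theme edges to accept.
#' @return a decider function(stage, site, state) -> label index.
#' @export
shape_policy_decider <- function(sentence, extra_themes = character()) {
  function(stage, site, state) {
    if (stage == "trigger") return(sentence$.gold_label[site + 1L])
    key <- as.character(site$trigger)
    edge <- paste0(site$trigger, ">", site$arg_key)
    hit <- if (stage == "theme")
      site$arg_key %in% (sentence$.gold_themes[[key]] %||% character()) ||
        edge %in% extra_themes
    else
      site$arg_key %in% (sentence$.gold_causes[[key]] %||% character())
    if (hit) 2L else 1L
  }
}
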