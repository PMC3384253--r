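## Event type inventory ------------------------------------------------------

#' Event types and classes
#'
#' The nine event types of the GENIA-style event extraction task, grouped
#' into three classes.  Simple events take exactly one protein Theme,
#' Binding events one or more protein Themes, and Regulation-class events
#' one obligatory Theme plus an optional Cause, either of which may be a
#' protein or another event (giving nested events).
#'
#' @format Character vectors of type names.
#' @name event_types
NULL

#' @rdname event_types
#' @export
SIMPLE_TYPES <- c("Gene_expression", "Transcription", "Protein_catabolism",
                  "Phosphorylation", "Localization")

#' @rdname event_types
#' @export
REGULATION_TYPES <- c("Regulation", "Positive_regulation", "Negative_regulation")

#' @rdname event_types
#' @export
EVENT_TYPES <- c(SIMPLE_TYPES, "Binding", REGULATION_TYPES)

## Label inventories for the three classification stages.  Index 1 is always
## the negative class so that an untrained (all-zero) classifier abstains.
TRIGGER_LABELS <- c("No_trigger", EVENT_TYPES)
THEME_LABELS <- c("No_Theme", "Theme")
CAUSE_LABELS <- c("No_Cause", "Cause")

#' Class of an event type
#'
#' @param type character vector of event type names.
#' @return character vector with values "Simple", "Binding" or "Regulation".
#' @export
event_class <- function(type) {
  out <- ifelse(type %in% SIMPLE_TYPES, "Simple",
                ifelse(type == "Binding", "Binding",
                       ifelse(type %in% REGULATION_TYPES, "Regulation",
                              NA_character_)))
  if (anyNA(out)) stop("unknown event type: ",
                       paste(type[is.na(out)], collapse = ", "))
  out
}

is_regulation_type <- function(type) type %in% REGULATION_TYPES

STAGE_K <- c(trigger = length(TRIGGER_LABELS), theme = 2L, cause = 2L)
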