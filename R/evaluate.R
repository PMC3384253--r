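## Event-level evaluation: matching on canonical signatures (head-token
## trigger equality, exact type, recursively matched arguments),
## micro-averaged recall/precision/F per event type and class, and the
## score-offset sweep that traces recall-precision curves.

#' Match predicted against gold events
#'
#' An event matches iff trigger head token, event type, Theme set and
#' Cause all agree, recursively through nested events (signature
#' equality).
#'
#' @param gold_sigs,pred_sigs character vectors of event signatures for
#'   one document (or corpus slice).
#' @return data.frame with one row per event type: TP, FP, FN.
#' @export
match_events <- function(gold_sigs, pred_sigs) {
  gold_sigs <- unique(gold_sigs); pred_sigs <- unique(pred_sigs)
  tp_sigs <- intersect(gold_sigs, pred_sigs)
  out <- data.frame(type = EVENT_TYPES, TP = 0L, FP = 0L, FN = 0L)
  tally <- function(sigs) {
    ty <- signature_type(sigs)
    vapply(EVENT_TYPES, function(t) sum(ty == t), 0L)
  }
  out$TP <- tally(tp_sigs)
  out$FP <- tally(setdiff(pred_sigs, gold_sigs))
  out$FN <- tally(setdiff(gold_sigs, pred_sigs))
  rownames(out) <- NULL
  out
}

prf <- function(tp, fp, fn) {
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(recall = 100 * r, precision = 100 * p, fscore = 100 * f)
}

#' Score a predicted corpus against gold
#'
#' Micro-averaged counts over aligned documents, reported per event type
#' with Simple / Binding / Regulation / TOTAL class rollups, on a 0-100
#' scale.
#'
#' @param gold_docs named list of gold-annotated documents.
#' @param pred_sigs named list doc_id -> predicted event signatures (as
#'   returned by [predict_corpus()]).
#' @return data.frame of class "event_eval" with columns type, TP, FP, FN,
#'   recall, precision, fscore.
#' @export
score_corpus <- function(gold_docs, pred_sigs) {
  gids <- vapply(gold_docs, function(d) d$doc_id, "")
  if (!setequal(gids, names(pred_sigs)))
    stop("document ids of gold and prediction do not match")
  counts <- data.frame(type = EVENT_TYPES, TP = 0L, FP = 0L, FN = 0L)
  for (d in gold_docs) {
    gsig <- unlist(lapply(d$sentences, function(s) {
      s2 <- s
      if (!is.null(s$gold_triggers) && nrow(s$gold_triggers))
        gold_event_signatures(s2) else character()
    }))
    m <- match_events(gsig, pred_sigs[[d$doc_id]])
    counts$TP <- counts$TP + m$TP
    counts$FP <- counts$FP + m$FP
    counts$FN <- counts$FN + m$FN
  }
  rollup <- function(name, types) {
    sel <- counts$type %in% types
    data.frame(type = name, TP = sum(counts$TP[sel]), FP = sum(counts$FP[sel]),
               FN = sum(counts$FN[sel]))
  }
  tab <- rbind(counts,
               rollup("Simple (TOTAL)", SIMPLE_TYPES),
               rollup("Regulation (TOTAL)", REGULATION_TYPES),
               rollup("TOTAL", EVENT_TYPES))
  prfm <- t(apply(tab[, c("TP", "FP", "FN")], 1,
                  function(r) prf(r[[1]], r[[2]], r[[3]])))
  colnames(prfm) <- c("recall", "precision", "fscore")
  out <- cbind(tab, as.data.frame(prfm))
  class(out) <- c("event_eval", "data.frame")
  out
}

#' @export
print.event_eval <- function(x, ...) {
  y <- x
  y$recall <- sprintf("%.2f", y$recall)
  y$precision <- sprintf("%.2f", y$precision)
  y$fscore <- sprintf("%.2f", y$fscore)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

eval_row <- function(report, type) {
  report[report$type == type, , drop = FALSE]
}

#' Recall-precision sweep over classifier score offsets
#'
#' Re-runs prediction with each offset triple added to the negative-class
#' score of the corresponding stage (positive offsets under-generate,
#' negative offsets over-generate) and scores each run.
#'
#' @param policy trained policy.
#' @param docs gold-annotated documents to predict and score.
#' @param offset_grid data.frame with columns trigger, theme, cause (one
#'   row per run).
#' @return data.frame with the offsets and TOTAL recall/precision/F per row.
#' @export
sweep_offsets <- function(policy, docs, offset_grid) {
  out <- offset_grid
  out$recall <- NA_real_; out$precision <- NA_real_; out$fscore <- NA_real_
  for (i in seq_len(nrow(offset_grid))) {
    off <- c(trigger = offset_grid$trigger[i], theme = offset_grid$theme[i],
             cause = offset_grid$cause[i])
    preds <- predict_corpus(docs, policy, offsets = off)
    rep <- score_corpus(docs, preds)
    tot <- eval_row(rep, "TOTAL")
    out$recall[i] <- tot$recall
    out$precision[i] <- tot$precision
    out$fscore[i] <- tot$fscore
  }
  out
}
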