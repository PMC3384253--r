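## Synthetic corpus generator.  Sentences are drawn from hand-built
## templates over a trigger lexicon for the nine event types; each
## template carries a consistent dependency parse, lemmas, PoS tags and
## gold events, so every gold structure is reachable by the trigger /
## Theme / Cause decomposition (triggers are single tokens, Binding
## groupings are recoverable by first-label grouping, and the
## "overexpression" pattern is reproduced by the regulation dictionary).
## Documents are split across the "abstract" and "fullpaper" domains,
## optionally with domain-specific trigger lemmas.

#' Synthetic corpus configuration
#'
#' @param n_docs number of documents.
#' @param sentences_per_doc sentences in each document.
#' @param seed generator seed.
#' @param p_nested probability that a regulation sentence nests an event
#'   (rather than taking a protein Theme).
#' @param p_cause probability that a nested Regulation event carries a
#'   Cause.
#' @param p_binding_multi probability that a Binding sentence uses the
#'   grouped two-Theme construction.
#' @param domain_mix fraction of documents drawn from the "fullpaper"
#'   domain.
#' @param domain_specific_vocab reserve some trigger lemmas to a single
#'   domain.
#' @param parse_noise fraction of dependency edges whose label is
#'   corrupted; at 0 (default) every gold structure is exactly recoverable
#'   from the parse, at > 0 the corpus emulates parser errors (and Binding
#'   Theme grouping is no longer guaranteed to reconstruct the gold
#'   events).
#' @return list of class "generator_config".
#' @export
generator_config <- function(n_docs = 10, sentences_per_doc = 10, seed = 1L,
                             p_nested = 0.4, p_cause = 0.5,
                             p_binding_multi = 0.3, domain_mix = 0.3,
                             domain_specific_vocab = TRUE, parse_noise = 0) {
  stopifnot(n_docs >= 1, sentences_per_doc >= 1,
            p_nested >= 0, p_nested <= 1, p_cause >= 0, p_cause <= 1,
            p_binding_multi >= 0, p_binding_multi <= 1,
            domain_mix >= 0, domain_mix <= 1,
            parse_noise >= 0, parse_noise <= 1)
  structure(list(n_docs = n_docs, sentences_per_doc = sentences_per_doc,
                 seed = as.integer(seed), p_nested = p_nested,
                 p_cause = p_cause, p_binding_multi = p_binding_multi,
                 domain_mix = domain_mix,
                 domain_specific_vocab = domain_specific_vocab,
                 parse_noise = parse_noise),
            class = "generator_config")
}

## trigger lexicons; "domain" NA = shared between domains
gen_lexicon <- function(domain, domain_specific) {
  simple_nouns <- data.frame(
    lemma = c("expression", "production", "synthesis", "biosynthesis",
              "transcription", "cotranscription",
              "degradation", "proteolysis",
              "phosphorylation", "hyperphosphorylation",
              "secretion", "translocation", "localization"),
    type = c("Gene_expression", "Gene_expression", "Gene_expression",
             "Gene_expression", "Transcription", "Transcription",
             "Protein_catabolism", "Protein_catabolism",
             "Phosphorylation", "Phosphorylation",
             "Localization", "Localization", "Localization"),
    domain = c(NA, NA, NA, "abstract", NA, "fullpaper", NA, NA, NA,
               "fullpaper", NA, NA, "abstract"))
  simple_verbs <- data.frame(
    lemma = c("express", "transcribe", "degrade", "phosphorylate", "secrete"),
    type = c("Gene_expression", "Transcription", "Protein_catabolism",
             "Phosphorylation", "Localization"),
    domain = NA)
  reg_nouns <- data.frame(
    lemma = c("regulation", "modulation", "activation", "induction",
              "upregulation", "elevation", "inhibition", "suppression",
              "downregulation", "abrogation"),
    type = c("Regulation", "Regulation", "Positive_regulation",
             "Positive_regulation", "Positive_regulation",
             "Positive_regulation", "Negative_regulation",
             "Negative_regulation", "Negative_regulation",
             "Negative_regulation"),
    domain = c(NA, NA, NA, NA, NA, "abstract", NA, NA, NA, "fullpaper"))
  reg_verbs <- data.frame(
    lemma = c("regulate", "induce", "activate", "enhance", "inhibit",
              "suppress", "modulate"),
    type = c("Regulation", "Positive_regulation", "Positive_regulation",
             "Positive_regulation", "Negative_regulation",
             "Negative_regulation", "Regulation"),
    domain = NA)
  bind_nouns <- data.frame(lemma = c("interaction", "association"),
                           type = "Binding", domain = NA)
  filt <- function(df) {
    if (domain_specific) df[is.na(df$domain) | df$domain == domain, ]
    else df[is.na(df$domain), ]
  }
  list(simple_nouns = filt(simple_nouns), simple_verbs = filt(simple_verbs),
       reg_nouns = filt(reg_nouns), reg_verbs = filt(reg_verbs),
       bind_nouns = filt(bind_nouns))
}

pick <- function(df) df[sample.int(nrow(df), 1L), ]

past_form <- function(lemma)
  if (endsWith(lemma, "e")) paste0(lemma, "d") else paste0(lemma, "ed")
pres_form <- function(lemma) paste0(lemma, "s")

new_prot <- function() paste0("PROT", sample.int(30L, 1L))

## A template instance: tokens (surface, lemma, pos), deps (head,
## dependent, label), prot_toks (token index per protein mention, in
## annotation order), triggers (list of (tok, type)), events (list of
## (trigger = index into triggers, themes = list of refs, cause = ref or
## NULL)) with refs ("prot", k) into prot_toks or ("event", j).
gen_sentence_template <- function(cfg, lex) {
  tok <- function(surface, lemma, pos) data.frame(surface = surface,
                                                  lemma = lemma, pos = pos)
  pr <- function(k) list(kind = "prot", k = k)
  ev <- function(j) list(kind = "event", j = j)
  u <- stats::runif(1)
  if (u < 0.12) {
    ## distractor sentences (no events); half use a trigger-like lemma in a
    ## non-trigger context so lemma identity alone does not solve trigger
    ## recognition
    p1 <- new_prot()
    if (stats::runif(1) < 0.5) {
      return(list(tokens = rbind(tok(p1, p1, "NN"), tok("was", "be", "VBD"),
                                 tok("purified", "purify", "VBN"),
                                 tok("from", "from", "IN"),
                                 tok("cells", "cell", "NNS"), tok(".", ".", ".")),
                  deps = data.frame(head = c(2L, 2L, 2L),
                                    dependent = c(0L, 1L, 4L),
                                    label = c("nsubjpass", "auxpass", "prep_from")),
                  prot_toks = 0L, triggers = list(), events = list()))
    }
    s <- pick(lex$simple_nouns)
    return(list(tokens = rbind(tok("the", "the", "DT"),
                               tok(s$lemma, s$lemma, "NN"),
                               tok("vector", "vector", "NN"),
                               tok("was", "be", "VBD"), tok("used", "use", "VBN"),
                               tok(".", ".", ".")),
                deps = data.frame(head = c(2L, 2L, 4L, 4L),
                                  dependent = c(0L, 1L, 2L, 3L),
                                  label = c("det", "nn", "nsubjpass", "auxpass")),
                prot_toks = integer(), triggers = list(), events = list()))
  }
  if (stats::runif(1) < cfg$p_nested) return(gen_regulation_sentence(cfg, lex))
  if (stats::runif(1) < cfg$p_binding_multi) return(gen_binding_sentence(lex))
  gen_simple_sentence(lex)
}

gen_simple_sentence <- function(lex) {
  tok <- function(surface, lemma, pos) data.frame(surface = surface,
                                                  lemma = lemma, pos = pos)
  pr <- function(k) list(kind = "prot", k = k)
  if (stats::runif(1) < 0.5) {
    s <- pick(lex$simple_nouns); p1 <- new_prot()
    list(tokens = rbind(tok(s$lemma, s$lemma, "NN"), tok("of", "of", "IN"),
                        tok(p1, p1, "NN"), tok(".", ".", ".")),
         deps = data.frame(head = 0L, dependent = 2L, label = "prep_of"),
         prot_toks = 2L,
         triggers = list(list(tok = 0L, type = s$type)),
         events = list(list(trigger = 1L, themes = list(pr(1L)),
                            cause = NULL)))
  } else {
    v <- pick(lex$simple_verbs); p1 <- new_prot()
    list(tokens = rbind(tok(p1, p1, "NN"), tok("was", "be", "VBD"),
                        tok(past_form(v$lemma), v$lemma, "VBN"),
                        tok(".", ".", ".")),
         deps = data.frame(head = c(2L, 2L), dependent = c(0L, 1L),
                           label = c("nsubjpass", "auxpass")),
         prot_toks = 0L,
         triggers = list(list(tok = 2L, type = v$type)),
         events = list(list(trigger = 1L, themes = list(pr(1L)),
                            cause = NULL)))
  }
}

gen_binding_sentence <- function(lex) {
  tok <- function(surface, lemma, pos) data.frame(surface = surface,
                                                  lemma = lemma, pos = pos)
  pr <- function(k) list(kind = "prot", k = k)
  b <- pick(lex$bind_nouns)
  u <- stats::runif(1)
  if (u < 0.4) {
    ## grouped cross-product: "<B>s of P1 and P2 with P3"
    p <- replicate(3, new_prot())
    list(tokens = rbind(tok(paste0(b$lemma, "s"), b$lemma, "NNS"),
                        tok("of", "of", "IN"), tok(p[1], p[1], "NN"),
                        tok("and", "and", "CC"), tok(p[2], p[2], "NN"),
                        tok("with", "with", "IN"), tok(p[3], p[3], "NN"),
                        tok(".", ".", ".")),
         deps = data.frame(head = c(0L, 0L, 2L, 0L),
                           dependent = c(2L, 4L, 4L, 6L),
                           label = c("prep_of", "prep_of", "conj_and",
                                     "prep_with")),
         prot_toks = c(2L, 4L, 6L),
         triggers = list(list(tok = 0L, type = "Binding")),
         events = list(list(trigger = 1L, themes = list(pr(1L), pr(3L)),
                            cause = NULL),
                       list(trigger = 1L, themes = list(pr(2L), pr(3L)),
                            cause = NULL)))
  } else if (u < 0.7) {
    ## two groups of one: "<B> of P1 with P2"
    p <- replicate(2, new_prot())
    list(tokens = rbind(tok(b$lemma, b$lemma, "NN"), tok("of", "of", "IN"),
                        tok(p[1], p[1], "NN"), tok("with", "with", "IN"),
                        tok(p[2], p[2], "NN"), tok(".", ".", ".")),
         deps = data.frame(head = c(0L, 0L), dependent = c(2L, 4L),
                           label = c("prep_of", "prep_with")),
         prot_toks = c(2L, 4L),
         triggers = list(list(tok = 0L, type = "Binding")),
         events = list(list(trigger = 1L, themes = list(pr(1L), pr(2L)),
                            cause = NULL)))
  } else {
    ## verbal with the "bind" lemma exception: "P1 binds P2"
    p <- replicate(2, new_prot())
    list(tokens = rbind(tok(p[1], p[1], "NN"),
                        tok("binds", "bind", "VBZ"),
                        tok(p[2], p[2], "NN"), tok(".", ".", ".")),
         deps = data.frame(head = c(1L, 1L), dependent = c(0L, 2L),
                           label = c("nsubj", "dobj")),
         prot_toks = c(0L, 2L),
         triggers = list(list(tok = 1L, type = "Binding")),
         events = list(list(trigger = 1L, themes = list(pr(1L), pr(2L)),
                            cause = NULL)))
  }
}

gen_regulation_sentence <- function(cfg, lex) {
  tok <- function(surface, lemma, pos) data.frame(surface = surface,
                                                  lemma = lemma, pos = pos)
  pr <- function(k) list(kind = "prot", k = k)
  ev <- function(j) list(kind = "event", j = j)
  u <- stats::runif(1)
  if (u < 0.08) {
    ## dictionary pattern: Simple + stacked Regulation on the same token
    p1 <- new_prot()
    return(list(tokens = rbind(tok(p1, p1, "NN"),
                               tok("overexpression", "overexpression", "NN"),
                               tok(".", ".", ".")),
                deps = data.frame(head = 1L, dependent = 0L, label = "nn"),
                prot_toks = 0L,
                triggers = list(list(tok = 1L, type = "Gene_expression"),
                                list(tok = 1L, type = "Positive_regulation")),
                events = list(list(trigger = 1L, themes = list(pr(1L)),
                                   cause = NULL),
                              list(trigger = 2L, themes = list(ev(1L)),
                                   cause = NULL))))
  }
  if (u < 0.23) {
    ## deep nesting: "R1 of P1 - RVed S of P2"
    rv <- pick(lex$reg_verbs[lex$reg_verbs$type == "Positive_regulation", ])
    r1 <- pick(lex$reg_nouns); s <- pick(lex$simple_nouns)
    p <- replicate(2, new_prot())
    return(list(tokens = rbind(tok(r1$lemma, r1$lemma, "NN"),
                               tok("of", "of", "IN"), tok(p[1], p[1], "NN"),
                               tok("-", "-", "HYPH"),
                               tok(past_form(rv$lemma), rv$lemma, "VBN"),
                               tok(s$lemma, s$lemma, "NN"),
                               tok("of", "of", "IN"), tok(p[2], p[2], "NN"),
                               tok(".", ".", ".")),
                deps = data.frame(head = c(0L, 5L, 4L, 5L),
                                  dependent = c(5L, 4L, 2L, 7L),
                                  label = c("prep_of", "amod", "nn", "prep_of")),
                prot_toks = c(2L, 7L),
                triggers = list(list(tok = 5L, type = s$type),
                                list(tok = 4L, type = rv$type),
                                list(tok = 0L, type = r1$type)),
                events = list(
                  list(trigger = 1L, themes = list(pr(2L)), cause = NULL),
                  list(trigger = 2L, themes = list(ev(1L)), cause = pr(1L)),
                  list(trigger = 3L, themes = list(ev(2L)), cause = NULL))))
  }
  if (u < 0.43) {
    ## ambiguous outer trigger: "positive|negative regulation of S of P"
    mod <- sample(c("positive", "negative"), 1L)
    ty <- if (mod == "positive") "Positive_regulation" else "Negative_regulation"
    s <- pick(lex$simple_nouns); p1 <- new_prot()
    return(list(tokens = rbind(tok(mod, mod, "JJ"),
                               tok("regulation", "regulation", "NN"),
                               tok("of", "of", "IN"),
                               tok(s$lemma, s$lemma, "NN"),
                               tok("of", "of", "IN"), tok(p1, p1, "NN"),
                               tok(".", ".", ".")),
                deps = data.frame(head = c(1L, 1L, 3L),
                                  dependent = c(0L, 3L, 5L),
                                  label = c("amod", "prep_of", "prep_of")),
                prot_toks = 5L,
                triggers = list(list(tok = 3L, type = s$type),
                                list(tok = 1L, type = ty)),
                events = list(
                  list(trigger = 1L, themes = list(pr(1L)), cause = NULL),
                  list(trigger = 2L, themes = list(ev(1L)), cause = NULL))))
  }
  if (stats::runif(1) < cfg$p_cause) {
    if (stats::runif(1) < 0.7) {
      ## protein Cause: "P1 RVs S of P2"
      rv <- pick(lex$reg_verbs); s <- pick(lex$simple_nouns)
      p <- replicate(2, new_prot())
      list(tokens = rbind(tok(p[1], p[1], "NN"),
                          tok(pres_form(rv$lemma), rv$lemma, "VBZ"),
                          tok(s$lemma, s$lemma, "NN"),
                          tok("of", "of", "IN"), tok(p[2], p[2], "NN"),
                          tok(".", ".", ".")),
           deps = data.frame(head = c(1L, 1L, 2L),
                             dependent = c(0L, 2L, 4L),
                             label = c("nsubj", "dobj", "prep_of")),
           prot_toks = c(0L, 4L),
           triggers = list(list(tok = 2L, type = s$type),
                           list(tok = 1L, type = rv$type)),
           events = list(
             list(trigger = 1L, themes = list(pr(2L)), cause = NULL),
             list(trigger = 2L, themes = list(ev(1L)), cause = pr(1L))))
    } else {
      ## event Cause: "R1 of P1 by R2 of P2"
      r1 <- pick(lex$reg_nouns); r2 <- pick(lex$reg_nouns)
      p <- replicate(2, new_prot())
      list(tokens = rbind(tok(r1$lemma, r1$lemma, "NN"),
                          tok("of", "of", "IN"), tok(p[1], p[1], "NN"),
                          tok("by", "by", "IN"),
                          tok(r2$lemma, r2$lemma, "NN"),
                          tok("of", "of", "IN"), tok(p[2], p[2], "NN"),
                          tok(".", ".", ".")),
           deps = data.frame(head = c(0L, 0L, 4L),
                             dependent = c(2L, 4L, 6L),
                             label = c("prep_of", "prep_by", "prep_of")),
           prot_toks = c(2L, 6L),
           triggers = list(list(tok = 0L, type = r1$type),
                           list(tok = 4L, type = r2$type)),
           events = list(
             list(trigger = 2L, themes = list(pr(2L)), cause = NULL),
             list(trigger = 1L, themes = list(pr(1L)), cause = ev(1L))))
    }
  } else {
    ## nested without Cause: "R of S of P"
    r1 <- pick(lex$reg_nouns); s <- pick(lex$simple_nouns)
    p1 <- new_prot()
    list(tokens = rbind(tok(r1$lemma, r1$lemma, "NN"),
                        tok("of", "of", "IN"),
                        tok(s$lemma, s$lemma, "NN"),
                        tok("of", "of", "IN"), tok(p1, p1, "NN"),
                        tok(".", ".", ".")),
         deps = data.frame(head = c(0L, 2L), dependent = c(2L, 4L),
                           label = c("prep_of", "prep_of")),
         prot_toks = 4L,
         triggers = list(list(tok = 2L, type = s$type),
                         list(tok = 0L, type = r1$type)),
         events = list(
           list(trigger = 1L, themes = list(pr(1L)), cause = NULL),
           list(trigger = 2L, themes = list(ev(1L)), cause = NULL)))
  }
}

DEP_LABEL_POOL <- c("prep_of", "prep_with", "prep_by", "prep_from", "nn",
                    "amod", "nsubj", "dobj", "nsubjpass", "auxpass",
                    "conj_and", "det", "advmod")

#' Generate a synthetic gold-annotated corpus
#'
#' @param cfg a [generator_config()].
#' @return named list of gold-annotated [new_document()] objects.
#' @export
generate_corpus <- function(cfg = generator_config()) {
  orng <- swap_rng(cfg$seed)
  on.exit(restore_rng(orng))
  docs <- list()
  for (di in seq_len(cfg$n_docs)) {
    doc_id <- sprintf("doc%04d", di)
    domain <- if (stats::runif(1) < cfg$domain_mix) "fullpaper" else "abstract"
    lex <- gen_lexicon(domain, cfg$domain_specific_vocab)
    sentences <- list()
    text <- ""
    prot_n <- 0L; trig_rows <- list(); ev_n <- 0L
    ## pass 1: draw templates; pass 2: lay out text and assign ids
    templates <- lapply(seq_len(cfg$sentences_per_doc), function(i)
      gen_sentence_template(cfg, lex))
    for (si in seq_along(templates)) {
      tpl <- templates[[si]]
      ntk <- nrow(tpl$tokens)
      base <- nchar(text)
      starts <- integer(ntk); ends <- integer(ntk)
      pos <- base
      for (ti in seq_len(ntk)) {
        starts[ti] <- pos
        ends[ti] <- pos + nchar(tpl$tokens$surface[ti])
        pos <- ends[ti] + 1L
      }
      text <- paste0(text, paste(tpl$tokens$surface, collapse = " "), " ")
      tokens <- data.frame(index = seq_len(ntk) - 1L,
                           surface = tpl$tokens$surface,
                           lemma = tpl$tokens$lemma, pos = tpl$tokens$pos,
                           char_start = starts, char_end = ends)
      deps <- tpl$deps
      proteins <- NULL
      if (length(tpl$prot_toks)) {
        pids <- paste0("T", prot_n + seq_along(tpl$prot_toks))
        prot_n <- prot_n + length(tpl$prot_toks)
        proteins <- data.frame(ann_id = pids,
                               char_start = starts[tpl$prot_toks + 1L],
                               char_end = ends[tpl$prot_toks + 1L],
                               head_token = tpl$prot_toks)
      }
      gold_triggers <- NULL; gold_events <- NULL
      if (length(tpl$triggers)) {
        tl <- tpl$triggers
        tids <- character(length(tl))
        gold_triggers <- do.call(rbind, lapply(seq_along(tl), function(j) {
          data.frame(ann_id = "", type = tl[[j]]$type,
                     char_start = starts[tl[[j]]$tok + 1L],
                     char_end = ends[tl[[j]]$tok + 1L],
                     head_token = tl[[j]]$tok)
        }))
        eids <- paste0("E", ev_n + seq_along(tpl$events))
        ev_n <- ev_n + length(tpl$events)
        ## trigger ids assigned after all protein ids (second pass below)
        gold_events <- lapply(seq_along(tpl$events), function(j) {
          e <- tpl$events[[j]]
          ref <- function(a) {
            if (a$kind == "prot")
              list(kind = "protein", id = proteins$ann_id[a$k])
            else list(kind = "event", id = eids[a$j])
          }
          list(ann_id = eids[j], type = tl[[e$trigger]]$type,
               trigger_id = e$trigger,  # placeholder: index into triggers
               themes = lapply(e$themes, ref),
               cause = if (!is.null(e$cause)) ref(e$cause) else NULL)
        })
      }
      sentences[[si]] <- list(tokens = tokens, deps = deps,
                              proteins = proteins,
                              gold_triggers = gold_triggers,
                              gold_events = gold_events)
    }
    ## assign trigger ids (T numbering continues after proteins)
    tn <- prot_n
    for (si in seq_along(sentences)) {
      s <- sentences[[si]]
      if (!is.null(s$gold_triggers) && nrow(s$gold_triggers)) {
        ids <- paste0("T", tn + seq_len(nrow(s$gold_triggers)))
        tn <- tn + nrow(s$gold_triggers)
        s$gold_triggers$ann_id <- ids
        s$gold_events <- lapply(s$gold_events, function(e) {
          e$trigger_id <- ids[e$trigger_id]
          e
        })
      }
      sentences[[si]] <- new_sentence(s$tokens, s$deps, s$proteins,
                                      s$gold_triggers, s$gold_events,
                                      index = si - 1L)
    }
    docs[[doc_id]] <- new_document(doc_id, sub(" $", "", text), sentences,
                                   domain)
  }
  ## parse noise is applied in a second pass from its own seed stream, so
  ## the template draws are identical with and without noise
  if (cfg$parse_noise > 0) {
    set.seed(derive_seed(cfg$seed, 99L))
    for (id in names(docs)) {
      for (si in seq_along(docs[[id]]$sentences)) {
        d <- docs[[id]]$sentences[[si]]$deps
        if (!nrow(d)) next
        flip <- stats::runif(nrow(d)) < cfg$parse_noise
        if (any(flip)) {
          d$label[flip] <- sample(DEP_LABEL_POOL, sum(flip), replace = TRUE)
          docs[[id]]$sentences[[si]]$deps <- d
        }
      }
    }
  }
  docs
}
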