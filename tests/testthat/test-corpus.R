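test_that("generation is deterministic and validates its configuration", {
  a <- generate_corpus(generator_config(n_docs = 3, sentences_per_doc = 5,
                                        seed = 71))
  b <- generate_corpus(generator_config(n_docs = 3, sentences_per_doc = 5,
                                        seed = 71))
  expect_identical(a, b)
  c <- generate_corpus(generator_config(n_docs = 3, sentences_per_doc = 5,
                                        seed = 72))
  expect_false(identical(a, c))
  expect_error(generator_config(n_docs = 0), "n_docs")
  expect_error(generator_config(p_nested = 1.5), "p_nested")
})

test_that("zero nesting and binding probabilities give only Simple events", {
  docs <- generate_corpus(generator_config(n_docs = 10, sentences_per_doc = 15,
                                           seed = 73, p_nested = 0,
                                           p_binding_multi = 0))
  for (doc in docs) for (s in doc$sentences) {
    for (e in s$gold_events %||% list()) {
      expect_true(e$type %in% SIMPLE_TYPES)
      expect_length(e$themes, 1L)
      expect_null(e$cause)
    }
  }
})

test_that("generated parses connect triggers to arguments within 4 edges", {
  docs <- generate_corpus(generator_config(n_docs = 10, sentences_per_doc = 10,
                                           seed = 74, p_nested = 0.5))
  for (doc in docs) for (s in doc$sentences) {
    sent <- prepare_sentence(s, doc$domain)
    for (key in names(sent$.gold_themes)) {
      tt <- as.integer(key)
      for (i in seq_along(sent$.gold_themes[[key]])) {
        at <- sent$.gold_theme_toks[[key]][i]
        if (is.na(at)) {
          ak <- sent$.gold_themes[[key]][i]
          at <- sent$proteins$head_token[
            sent$proteins$ann_id == substring(ak, 3L)]
        }
        p <- shortest_path(sent, tt, at)
        expect_false(is.null(p))
        expect_lte(p$length, 4L)
      }
    }
  }
})

test_that("domain-specific lemmas stay within their domain", {
  docs <- generate_corpus(generator_config(n_docs = 40, sentences_per_doc = 10,
                                           seed = 75, domain_mix = 0.5,
                                           p_nested = 0.5,
                                           domain_specific_vocab = TRUE))
  lemma_domains <- list()
  for (doc in docs) for (s in doc$sentences) {
    if (is.null(s$gold_triggers) || !nrow(s$gold_triggers)) next
    for (tok in s$gold_triggers$head_token)
      lemma_domains[[s$tokens$lemma[tok + 1L]]] <-
        union(lemma_domains[[s$tokens$lemma[tok + 1L]]], doc$domain)
  }
  ## the reserved lemmas appear (corpus is large enough) and never leak
  expect_identical(lemma_domains[["abrogation"]], "fullpaper")
  expect_identical(lemma_domains[["elevation"]], "abstract")
  ## shared lemmas occur in both domains
  expect_setequal(lemma_domains[["suppression"]],
                  c("abstract", "fullpaper"))
})

test_that("event-type frequencies track the configured probabilities", {
  cfg <- generator_config(n_docs = 100, sentences_per_doc = 12, seed = 76,
                          p_nested = 0.5, p_binding_multi = 0.4)
  docs <- generate_corpus(cfg)
  n_sent <- 0L; n_reg_sent <- 0L; n_bind_sent <- 0L
  for (doc in docs) for (s in doc$sentences) {
    n_sent <- n_sent + 1L
    types <- if (!is.null(s$gold_triggers)) s$gold_triggers$type else character()
    if (any(types %in% REGULATION_TYPES)) n_reg_sent <- n_reg_sent + 1L
    if (any(types == "Binding")) n_bind_sent <- n_bind_sent + 1L
  }
  ## regulation sentences: (1 - 0.12) * p_nested; binding:
  ## (1 - 0.12) * (1 - p_nested) * p_binding_multi; 3 standard errors
  p_reg <- 0.88 * 0.5
  p_bind <- 0.88 * 0.5 * 0.4
  tol <- function(p) 3 * sqrt(p * (1 - p) / n_sent)
  expect_lt(abs(n_reg_sent / n_sent - p_reg), tol(p_reg))
  expect_lt(abs(n_bind_sent / n_sent - p_bind), tol(p_bind))
})

test_that("parse noise corrupts edge labels but not the gold annotation", {
  clean <- generate_corpus(generator_config(n_docs = 5, sentences_per_doc = 10,
                                            seed = 77))
  noisy <- generate_corpus(generator_config(n_docs = 5, sentences_per_doc = 10,
                                            seed = 77, parse_noise = 0.5))
  changed <- 0L
  for (id in names(clean)) for (i in seq_along(clean[[id]]$sentences)) {
    a <- clean[[id]]$sentences[[i]]; b <- noisy[[id]]$sentences[[i]]
    expect_identical(a$tokens, b$tokens)
    expect_identical(gold_event_signatures(a), gold_event_signatures(b))
    changed <- changed + sum(a$deps$label != b$deps$label)
  }
  expect_gt(changed, 0L)
})

test_that("the whole generated corpus passes standoff validation", {
  docs <- generate_corpus(generator_config(n_docs = 5, sentences_per_doc = 8,
                                           seed = 78, p_nested = 0.6))
  dir <- withr::local_tempdir()
  write_corpus(docs, dir)
  ## re-reading runs parse_a1/parse_a2/parse_parses integrity checks
  expect_silent(read_corpus(dir))
})
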