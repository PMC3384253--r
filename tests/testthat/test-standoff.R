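test_that("parse_a1 reads protein mentions and validates spans", {
  m <- parse_a1("T1\tProtein 0 4\tgp41", text = "gp41 binds")
  expect_equal(m$ann_id, "T1")
  expect_equal(m$char_start, 0L)
  expect_equal(m$char_end, 4L)

  expect_equal(nrow(parse_a1(character())), 0L)
  expect_error(parse_a1("T1\tProtein 4 0\tx"), "end <= start")
  expect_error(parse_a1("T1\tProtein 0 4\tgp41", text = "XXXX binds"),
               "mismatch")
  expect_error(parse_a1("garbage line"), "malformed")
})

test_that("parse_a2 resolves triggers, nesting and rejects cycles", {
  prot <- parse_a1("T1\tProtein 0 4\tgp41")
  a2 <- parse_a2(c("T2\tGene_expression 10 20\tproduction",
                   "E1\tGene_expression:T2 Theme:T1"), prot)
  expect_equal(nrow(a2$triggers), 1L)
  expect_length(a2$events, 1L)
  expect_equal(a2$events[[1]]$themes[[1]]$kind, "protein")

  nested <- parse_a2(c("T2\tGene_expression 10 20\tproduction",
                       "T3\tNegative_regulation 30 40\tsuppression",
                       "E1\tGene_expression:T2 Theme:T1",
                       "E2\tNegative_regulation:T3 Theme:E1"), prot)
  expect_equal(nested$events[[2]]$themes[[1]]$kind, "event")

  expect_error(parse_a2(c("T2\tGene_expression 10 20\tproduction",
                          "E1\tGene_expression:T2 Theme:E1"), prot),
               "cyclic")
  expect_error(parse_a2("E1\tGene_expression:T9 Theme:T1", prot), "dangling")
})

test_that("write_a2 emits the shared-task dialect and round-trips", {
  prot <- parse_a1(c("T1\tProtein 0 2\tAA", "T2\tProtein 3 5\tBB"))
  triggers <- data.frame(ann_id = "T5", type = "Binding", char_start = 6L,
                         char_end = 13L, surface = "binding")
  events <- list(list(ann_id = "E1", type = "Binding", trigger_id = "T5",
                      themes = list(list(kind = "protein", id = "T1"),
                                    list(kind = "protein", id = "T2")),
                      cause = NULL))
  txt <- write_a2(triggers, events)
  expect_match(txt, "E1\tBinding:T5 Theme:T1 Theme2:T2", fixed = TRUE)
  back <- parse_a2(strsplit(txt, "\n")[[1]], prot)
  expect_equal(back$triggers$ann_id, "T5")
  expect_length(back$events[[1]]$themes, 2L)

  expect_error(write_a2(transform(triggers, ann_id = ""), events), "id")
})

test_that("parse_parses builds sentences and checks token integrity", {
  text <- "AA binds BB"
  lines <- c("0\tAA\tAA\tNN\t0\t2\t_",
             "1\tbinds\tbind\tVBZ\t3\t8\t_",
             "2\tBB\tBB\tNN\t9\t11\t1:dobj",
             "")
  sents <- parse_parses(lines, text)
  expect_length(sents, 1L)
  expect_equal(nrow(sents[[1]]$tokens), 3L)
  expect_equal(sents[[1]]$deps$label, "dobj")

  nodep <- parse_parses(c("0\tAA\tAA\tNN\t0\t2\t_"), text)
  expect_equal(nrow(nodep[[1]]$deps), 0L)

  expect_error(parse_parses(c("0\tAA\tAA\tNN\t0\t2\t_",
                              "0\tbinds\tbind\tVBZ\t3\t8\t_"), text),
               "duplicate")
  expect_error(parse_parses(c("0\tXX\tXX\tNN\t0\t2\t_"), text), "mismatch")
})

test_that("a generated corpus round-trips through the standoff files", {
  docs <- generate_corpus(generator_config(n_docs = 4, sentences_per_doc = 6,
                                           seed = 11))
  dir <- withr::local_tempdir()
  write_corpus(docs, dir)
  back <- read_corpus(dir)
  expect_identical(names(back), names(docs))
  for (id in names(docs)) {
    expect_identical(back[[id]]$text, docs[[id]]$text)
    expect_identical(back[[id]]$domain, docs[[id]]$domain)
    for (i in seq_along(docs[[id]]$sentences)) {
      a <- prepare_sentence(docs[[id]]$sentences[[i]], docs[[id]]$domain)
      b <- prepare_sentence(back[[id]]$sentences[[i]], back[[id]]$domain)
      expect_identical(a$tokens, b$tokens)
      expect_setequal(a$.gold_sigs, b$.gold_sigs)
    }
  }
})

test_that("annotation offsets are verifiable against the text", {
  docs <- generate_corpus(generator_config(n_docs = 3, sentences_per_doc = 5,
                                           seed = 12))
  for (doc in docs) for (s in doc$sentences) {
    expect_identical(substring(doc$text, s$tokens$char_start + 1L,
                               s$tokens$char_end),
                     s$tokens$surface)
    if (nrow(s$proteins))
      expect_true(all(grepl("^PROT", substring(doc$text,
                                               s$proteins$char_start + 1L,
                                               s$proteins$char_end))))
  }
})
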