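test_that("trigger features capture context lemmas", {
  s <- prepare_sentence(mk_sentence(
    c("positive", "regulation", "of", "PROT1"),
    pos = c("JJ", "NN", "IN", "NN"),
    lemmas = c("positive", "regulation", "of", "PROT1"),
    deps = c("1>0:amod", "1>3:prep_of")))
  f <- trigger_features(s, 1L)
  expect_true("trg:lm=regulation" %in% f)
  expect_true("trg:lm+pos=regulation|NN" %in% f)
  expect_true("trg:lm+prev=regulation|positive" %in% f)
  expect_true("trg:lm+next=regulation|of" %in% f)
  expect_true("trg:lm+dep=regulation|positive" %in% f)
  ## sentence-initial token has no prev-lemma feature
  f0 <- trigger_features(s, 0L)
  expect_false(any(grepl("prev", f0)))
  ## without structural features nothing references an assigned event type
  st <- new_state(4)
  st$trigger_labels[1] <- 2L
  expect_false(any(grepl("type", trigger_features(s, 1L, st, structural = FALSE))))
  expect_true(any(grepl("prevtype", trigger_features(s, 1L, st, structural = TRUE))))
})

test_that("theme features fall back to the between-string when disconnected", {
  s <- prepare_sentence(mk_sentence(
    c("expression", "xx", "PROT1"),
    pos = c("NN", "NN", "NN")))  # no dependency edges at all
  st <- new_state(3)
  st$trigger_labels[1] <- match("Gene_expression", bioevents:::TRIGGER_LABELS)
  pair <- bioevents:::make_pair(s, 0L, "P:T1", 2L, 1L)
  f <- theme_features(s, pair, st)
  expect_false(any(startsWith(f, "th:p")))
  expect_true("th:bw=xx|Gene_expression" %in% f)
})

test_that("theme path features conjoin trigger and argument properties", {
  s <- demo_sentence()
  st <- new_state(nrow(s$tokens))
  st$trigger_labels[8] <- match("Gene_expression", bioevents:::TRIGGER_LABELS)
  pair <- bioevents:::make_pair(s, 7L, "P:T2", 6L, 1L)
  f <- theme_features(s, pair, st)
  expect_true("th:p=nn/d" %in% f)
  expect_true("th:p+te=nn/d|Gene_expression" %in% f)
  expect_true("th:p+at=nn/d|Protein" %in% f)
  expect_true("th:p+tl=nn/d|production" %in% f)
})

test_that("structural theme indicators fire on history patterns", {
  s <- demo_sentence()
  st <- new_state(nrow(s$tokens))
  TL <- bioevents:::TRIGGER_LABELS
  st$trigger_labels[6] <- match("Positive_regulation", TL)
  st$trigger_labels[8] <- match("Gene_expression", TL)
  ## three Themes already assigned to trigger 5
  bioevents:::add_theme_edge(st, 5L, "P:T1", 3L)
  bioevents:::add_theme_edge(st, 5L, "P:T2", 6L)
  bioevents:::add_theme_edge(st, 5L, "T:7", 7L)
  pair <- bioevents:::make_pair(s, 5L, "P:T1", 3L, 1L)
  f <- theme_features(s, pair, st, structural = TRUE)
  expect_true("th:s:three-themes" %in% f)
  ## protein Theme present and candidate argument is an event trigger
  pair_ev <- bioevents:::make_pair(s, 5L, "T:7", 7L, 2L)
  expect_true("th:s:prot-theme+ev-arg" %in%
                theme_features(s, pair_ev, st, structural = TRUE))
  ## undirected cycle: 5 and 7 already connected through Themes
  expect_true("th:s:ucycle" %in%
                theme_features(s, pair_ev, st, structural = TRUE))
  expect_false(any(startsWith(theme_features(s, pair_ev, st, FALSE), "th:s:")))
})

test_that("cause features require Themes and conjoin theme paths", {
  s <- demo_sentence()
  st <- new_state(nrow(s$tokens))
  TL <- bioevents:::TRIGGER_LABELS
  st$trigger_labels[6] <- match("Positive_regulation", TL)
  pair <- bioevents:::make_pair(s, 5L, "P:T1", 3L, 1L)
  expect_error(cause_features(s, pair, st), "without Themes")
  bioevents:::add_theme_edge(st, 5L, "T:7", 7L)
  bioevents:::add_theme_edge(st, 5L, "P:T2", 6L)
  f <- cause_features(s, pair, st)
  ## one path-conjunction feature per assigned Theme
  expect_length(grep("^ca:p\\+thp=", f), 2L)
  expect_true(any(startsWith(f, "ca:p=")))
  ## structural indicators only when requested
  expect_false(any(startsWith(f, "ca:s:")))
  pair_ev <- bioevents:::make_pair(s, 5L, "T:7", 7L, 2L)
  fs <- cause_features(s, pair_ev, st, structural = TRUE)
  expect_true("ca:s:ev-arg" %in% fs)
})

test_that("domain augmentation exactly doubles the feature vector", {
  fv <- c("trg:lm=production", "trg:lm+pos=production|NN")
  out <- augment_domain(fv, "abstract")
  expect_length(out, 4L)
  expect_true(all(fv %in% out))
  expect_true("d=abstract|trg:lm=production" %in% out)
  ## two domains share exactly the original features
  out2 <- augment_domain(fv, "fullpaper")
  expect_setequal(intersect(out, out2), fv)
  expect_identical(augment_domain(character(), "abstract"), character())
  expect_error(augment_domain(fv, "webpage"), "unknown domain")
})

test_that("non-structural features are independent of action history", {
  s <- demo_sentence()
  st1 <- new_state(nrow(s$tokens))
  st2 <- new_state(nrow(s$tokens))
  TL <- bioevents:::TRIGGER_LABELS
  ## identical label for the trigger in the pair, scrambled elsewhere
  st1$trigger_labels[] <- 1L
  st2$trigger_labels[] <- match("Binding", TL)
  st1$trigger_labels[8] <- match("Gene_expression", TL)
  st2$trigger_labels[8] <- match("Gene_expression", TL)
  bioevents:::add_theme_edge(st2, 2L, "P:T1", 3L)
  pair <- bioevents:::make_pair(s, 7L, "P:T2", 6L, 1L)
  expect_setequal(theme_features(s, pair, st1, structural = FALSE),
                  theme_features(s, pair, st2, structural = FALSE))
  expect_setequal(trigger_features(s, 9L, st1, structural = FALSE),
                  trigger_features(s, 9L, st2, structural = FALSE))
})
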