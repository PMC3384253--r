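test_that("shortest_path handles single edges and disconnection", {
  s <- mk_sentence(c("a", "b", "c"), deps = "0>1:dobj")
  p <- shortest_path(s, 0, 1)
  expect_equal(p$length, 1L)
  expect_equal(p$string, "dobj/d")
  ## direction flips when traversed from the dependent
  expect_equal(shortest_path(s, 1, 0)$string, "dobj/u")
  expect_null(shortest_path(s, 0, 2))
  expect_error(shortest_path(s, 0, 0), "differ")
  expect_error(shortest_path(s, 0, 9), "range")
})

test_that("shortest_path agrees with the exhaustive oracle on small graphs", {
  set.seed(421)
  for (rep in 1:40) {
    n <- sample(3:8, 1)
    s <- random_graph_sentence(n, n_edges = sample(2:10, 1))
    a <- sample.int(n, 1) - 1L
    b <- sample.int(n, 1) - 1L
    if (a == b) next
    got <- shortest_path(s, a, b)
    want <- brute_shortest_path(s, a, b)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$length, want$length)
      expect_equal(got$string, want$string)
    }
  }
})

test_that("equal-length paths break ties on the label-direction string", {
  ## two length-2 routes from 0 to 3: via 1 (amod then dobj) and via 2
  ## (nn then nsubj); the lexicographically smaller string must win
  s <- mk_sentence(c("a", "b", "c", "d"),
                   deps = c("0>1:amod", "1>3:dobj", "0>2:nn", "2>3:nsubj"))
  p <- shortest_path(s, 0, 3)
  expect_equal(p$length, 2L)
  expect_equal(p$string, min("amod/d|dobj/d", "nn/d|nsubj/d"))
})

test_that("multi-token triggers reduce to their syntactic head", {
  ## "binding activity": activity governs binding and has its head outside
  s <- mk_sentence(c("PROTX", "binding", "activity", "rose"),
                   pos = c("NN", "NN", "NN", "VBD"),
                   deps = c("2>1:nn", "3>2:nsubj", "1>0:nn"))
  trig <- data.frame(ann_id = "T9", type = "Binding",
                     char_start = s$tokens$char_start[2],
                     char_end = s$tokens$char_end[3])
  red <- reduce_trigger_to_head(trig, s)
  expect_equal(red$head_token, 2L)
  expect_equal(red$char_start, s$tokens$char_start[3])
  ## idempotent on single-token spans
  red2 <- reduce_trigger_to_head(red, s)
  expect_identical(red2, red)
  ## span overlapping no token
  bad <- transform(trig, char_start = 999L, char_end = 1000L)
  expect_error(reduce_trigger_to_head(bad, s), "overlaps no token")
})

test_that("order_actions sorts by path length, stably, missing paths last", {
  mkp <- function(len, rank) list(trigger = 0L, arg_key = paste0("P:", rank),
                                  arg_tok = 1L, path = NULL,
                                  plen = len, rank = rank)
  pairs <- list(mkp(3, 1), mkp(1, 2), mkp(2, 3))
  expect_equal(vapply(order_actions(pairs), function(p) p$plen, 0), c(1, 2, 3))
  ties <- list(mkp(2, 1), mkp(2, 2), mkp(1, 3))
  expect_equal(vapply(order_actions(ties), function(p) p$rank, 0), c(3, 1, 2))
  with_inf <- list(mkp(Inf, 1), mkp(5, 2))
  expect_equal(vapply(order_actions(with_inf), function(p) p$rank, 0), c(2, 1))
  ## permutation: nothing lost or duplicated
  expect_setequal(vapply(order_actions(pairs), function(p) p$rank, 0), 1:3)
})

test_that("directed cycle detection matches DFS reachability", {
  st <- new_state(5)
  expect_false(creates_directed_cycle(st, 0L, "T:1"))
  bioevents:::add_theme_edge(st, 0L, "T:1", 1L)
  expect_true(creates_directed_cycle(st, 1L, "T:0"))
  ## chain 1 -> 2 -> 3, closing edge 3 -> 1
  st2 <- new_state(5)
  bioevents:::add_theme_edge(st2, 1L, "T:2", 2L)
  bioevents:::add_theme_edge(st2, 2L, "T:3", 3L)
  expect_true(creates_directed_cycle(st2, 3L, "T:1"))
  expect_false(creates_directed_cycle(st2, 3L, "T:4"))
  ## protein arguments can never close a cycle
  expect_false(creates_directed_cycle(st2, 3L, "P:T1"))
  ## Cause edges participate in the cycle check too
  st3 <- new_state(5)
  bioevents:::add_cause_edge(st3, 1L, "T:2", 2L)
  expect_true(creates_directed_cycle(st3, 2L, "T:1"))
})

test_that("theme agenda is the trigger x protein cross product", {
  s <- demo_sentence()
  st <- new_state(nrow(s$tokens))
  st$trigger_labels[3] <- match("Negative_regulation", bioevents:::TRIGGER_LABELS)
  agenda <- build_theme_agenda(s, st)
  expect_length(agenda, 2L)  # one trigger, two proteins
  st$trigger_labels[8] <- match("Gene_expression", bioevents:::TRIGGER_LABELS)
  expect_length(build_theme_agenda(s, st), 4L)
})

test_that("cause agenda covers themed Regulation triggers only", {
  s <- demo_sentence()
  st <- new_state(nrow(s$tokens))
  TL <- bioevents:::TRIGGER_LABELS
  st$trigger_labels[3] <- match("Negative_regulation", TL)  # token 2
  st$trigger_labels[6] <- match("Positive_regulation", TL)  # token 5
  st$trigger_labels[8] <- match("Gene_expression", TL)      # token 7
  ## no themes assigned yet: no cause candidates at all
  expect_length(build_cause_agenda(s, st), 0L)
  bioevents:::add_theme_edge(st, 5L, "T:7", 7L)
  bioevents:::add_theme_edge(st, 7L, "P:T2", 6L)
  ## Regulation trigger 5 with a Theme: pairs with 2 proteins + themed
  ## trigger 7 (Gene_expression trigger 7 itself contributes none)
  ag <- build_cause_agenda(s, st)
  expect_equal(unique(vapply(ag, function(p) p$trigger, 0L)), 5L)
  expect_setequal(vapply(ag, function(p) p$arg_key, ""),
                  c("P:T1", "P:T2", "T:7"))
  ## cycle-closing candidate excluded: trigger 2 themed on 5 would offer
  ## 5 -> 2 unless it closes a cycle
  bioevents:::add_theme_edge(st, 2L, "T:5", 5L)
  ag2 <- build_cause_agenda(s, st)
  keys2 <- vapply(ag2, function(p) paste0(p$trigger, ">", p$arg_key), "")
  expect_false("5>T:2" %in% keys2)
  expect_true("2>T:5" %in% keys2 || "2>P:T1" %in% keys2)
})
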