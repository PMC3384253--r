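test_that("event loss counts weighted false positives and negatives", {
  s <- demo_sentence()
  g <- s$.gold_sigs
  expect_equal(event_loss(g, g), 0)
  expect_equal(event_loss(g, character()), 3)
  expect_equal(event_loss(g, character(), w_fn = 2), 6)
  expect_equal(event_loss(character(), g, w_fp = 3), 9)
  expect_equal(event_loss(g, c(g, "Binding@0(T=P:T9)")), 1)
})

test_that("the optimal policy replays the gold decomposition", {
  s <- demo_sentence()
  st <- new_state(nrow(s$tokens))
  TL <- bioevents:::TRIGGER_LABELS
  ## non-trigger token ("SQ") and gold trigger ("production")
  expect_equal(optimal_policy_action(s, st, "trigger", 0L), 1L)
  expect_equal(TL[optimal_policy_action(s, st, "trigger", 7L)],
               "Gene_expression")
  ## a Theme pair whose trigger was mislabeled gets No_Theme
  st$trigger_labels[8] <- match("Negative_regulation", TL)
  pair <- bioevents:::make_pair(s, 7L, "P:T2", 6L, 1L)
  expect_equal(optimal_policy_action(s, st, "theme", pair), 1L)
  st$trigger_labels[8] <- match("Gene_expression", TL)
  expect_equal(optimal_policy_action(s, st, "theme", pair), 2L)
  ## an event-valued Theme requires the argument's own Themes to be correct
  st$trigger_labels[6] <- match("Positive_regulation", TL)
  pair_ev <- bioevents:::make_pair(s, 5L, "T:7", 7L, 1L)
  expect_equal(optimal_policy_action(s, st, "theme", pair_ev), 1L)
  bioevents:::add_theme_edge(st, 7L, "P:T2", 6L)
  expect_equal(optimal_policy_action(s, st, "theme", pair_ev), 2L)
  ## the Cause requires at least one correct Theme on the acting trigger
  cpair <- bioevents:::make_pair(s, 5L, "P:T1", 3L, 1L)
  expect_equal(optimal_policy_action(s, st, "cause", cpair), 1L)
  bioevents:::add_theme_edge(st, 5L, "T:7", 7L)
  expect_equal(optimal_policy_action(s, st, "cause", cpair), 2L)
})

test_that("optimal rollouts reproduce gold with zero loss corpus-wide", {
  docs <- generate_corpus(generator_config(n_docs = 12, sentences_per_doc = 8,
                                           seed = 31, p_nested = 0.5))
  regdict <- build_regulation_dictionary(docs)
  for (doc in docs) for (s in doc$sentences) {
    sent <- prepare_sentence(s, doc$domain)
    st <- oracle_state(sent)
    pred <- construct_event_signatures(sent, st, regdict)
    expect_equal(event_loss(sent$.gold_sigs, pred), 0)
  }
})

test_that("focused costing reproduces the two worked trigger scenarios", {
  s <- demo_sentence()
  cfg <- searn_config(focused = TRUE)
  TL <- bioevents:::TRIGGER_LABELS
  dec <- shape_policy_decider(s)
  log <- recorded_pass(s, dec)
  t_prod <- which(vapply(log, function(a)
    a$stage == "trigger" && identical(a$site, 7L), TRUE))
  ## mislabeling "production" while the rollout still attaches its Theme
  ## invalidates the whole nested chain: 3 FP + 3 FN
  costs <- estimate_action_costs(s, log, t_prod, dec, cfg)
  expect_equal(costs[match("Negative_regulation", TL)], 6)
  expect_equal(costs[match("Gene_expression", TL)], 0)
  ## a spurious trigger on the non-trigger token "SQ" with one attached
  ## Theme costs exactly its one false-positive event
  dec2 <- shape_policy_decider(s, extra_themes = "0>P:T2")
  t_sq <- which(vapply(log, function(a)
    a$stage == "trigger" && identical(a$site, 0L), TRUE))
  costs2 <- estimate_action_costs(s, log, t_sq, dec2, cfg)
  expect_equal(costs2[match("Negative_regulation", TL)], 1)
  expect_equal(costs2[1], 0)
})

test_that("first-iteration costing of a non-trigger token is all zeros", {
  s <- demo_sentence()
  cfg <- searn_config(focused = TRUE)
  opt_dec <- function(stage, site, state)
    optimal_policy_action(s, state, stage, site)
  log <- recorded_pass(s, opt_dec)
  t_sq <- which(vapply(log, function(a)
    a$stage == "trigger" && identical(a$site, 0L), TRUE))
  ## the optimal policy never attaches Themes to a wrongly typed trigger,
  ## so every label costs 0 and the example is dropped
  expect_equal(estimate_action_costs(s, log, t_sq, opt_dec, cfg),
               rep(0, length(bioevents:::TRIGGER_LABELS)))
})

test_that("focused and full costing agree on single-component sentences", {
  s <- demo_sentence()  # gold+predicted graph is one connected component
  dec <- shape_policy_decider(s, extra_themes = "0>P:T2")
  log <- recorded_pass(s, dec)
  for (t in seq_along(log)) {
    cf <- estimate_action_costs(s, log, t, dec, searn_config(focused = TRUE))
    cu <- estimate_action_costs(s, log, t, dec, searn_config(focused = FALSE))
    expect_equal(cf, cu)
  }
})

test_that("weighted loss weights propagate into action costs", {
  s <- demo_sentence()
  dec <- shape_policy_decider(s, extra_themes = "0>P:T2")
  log <- recorded_pass(s, dec)
  t_sq <- which(vapply(log, function(a)
    a$stage == "trigger" && identical(a$site, 0L), TRUE))
  c1 <- estimate_action_costs(s, log, t_sq, dec, searn_config(w_fp = 1))
  c4 <- estimate_action_costs(s, log, t_sq, dec, searn_config(w_fp = 4))
  ## the spurious event is a false positive: quadrupling w_fp quadruples it
  expect_equal(c4[c1 > 0], 4 * c1[c1 > 0])
})

test_that("the policy mixture schedule follows (1 - beta)^iteration", {
  docs <- generate_corpus(generator_config(n_docs = 2, sentences_per_doc = 4,
                                           seed = 77))
  pol <- searn_train(docs, searn_config(beta = 0.3, iterations = 3, C = 1,
                                        rounds = 2, seed = 5))
  expect_length(pol$hyps, 3L)
  expect_equal(pol$optimal_policy_prob, 0.7^3)
  expect_equal(sum(pol$weights), 1)
  ## later hypotheses carry more mass
  expect_true(all(diff(pol$weights) > 0))
  w <- 0.3 * 0.7^(3 - 1:3)
  expect_equal(pol$weights, w / sum(w))
})

test_that("training is deterministic under a fixed seed", {
  docs <- generate_corpus(generator_config(n_docs = 3, sentences_per_doc = 5,
                                           seed = 13))
  p1 <- searn_train(docs, searn_config(beta = 0.5, iterations = 2, rounds = 2,
                                       seed = 21))
  p2 <- searn_train(docs, searn_config(beta = 0.5, iterations = 2, rounds = 2,
                                       seed = 21))
  for (i in seq_along(p1$hyps)) for (stg in c("trigger", "theme", "cause")) {
    a <- p1$hyps[[i]][[stg]]; b <- p2$hyps[[i]][[stg]]
    if (is.null(a)) expect_null(b) else expect_identical(a$W, b$W)
  }
  ## and the serialized bundles agree byte for byte
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  save_policy(p1, f1); save_policy(p2, f2)
  expect_identical(readLines(f1, warn = FALSE), readLines(f2, warn = FALSE))
})

test_that("policy bundles reload and predict identically", {
  docs <- generate_corpus(generator_config(n_docs = 3, sentences_per_doc = 5,
                                           seed = 14))
  pol <- searn_train(docs, searn_config(beta = 0.5, iterations = 2, rounds = 2,
                                        seed = 22))
  path <- withr::local_tempfile()
  save_policy(pol, path)
  pol2 <- load_policy(path)
  te <- generate_corpus(generator_config(n_docs = 2, sentences_per_doc = 5,
                                         seed = 15))
  expect_identical(predict_corpus(te, pol2), predict_corpus(te, pol))
})

test_that("run_policy in train mode replicates gold in the first iteration", {
  docs <- generate_corpus(generator_config(n_docs = 2, sentences_per_doc = 5,
                                           seed = 16))
  regdict <- build_regulation_dictionary(docs)
  ## a policy whose optimal-policy probability is 1 acts like iteration 1
  pol <- structure(list(hyps = list(), weights = numeric(), beta = 0.3,
                        iterations = 0, optimal_policy_prob = 1,
                        structural = TRUE, domain_adapt = FALSE,
                        regdict = regdict, config = searn_config()),
                   class = "searn_policy")
  for (doc in docs) for (s in doc$sentences) {
    sent <- prepare_sentence(s, doc$domain)
    st <- run_policy(sent, pol, mode = "train")
    expect_equal(event_loss(sent$.gold_sigs,
                            construct_event_signatures(sent, st, regdict)), 0)
  }
  expect_error(run_policy(prepare_sentence(docs[[1]]$sentences[[1]]), pol,
                          mode = "test"), "no learned hypotheses")
})
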