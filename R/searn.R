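## SEARN: joint training of the stage classifiers by search-based
## structured prediction.  A sentence is predicted as a sequence of
## multiclass actions (label each candidate token; accept/reject each
## Theme pair; accept/reject each Cause pair).  Training interpolates
## stochastically between the optimal policy derived from the gold
## standard and the ensemble of learned hypotheses, and turns every action
## into a cost-sensitive example whose per-label costs are estimated by
## rolling out the remainder of the sentence.

#' SEARN training configuration
#'
#' @param beta interpolation parameter in (0, 1]; the optimal policy is
#'   used during training rollouts with probability (1 - beta)^iteration.
#' @param iterations number of SEARN iterations.
#' @param C,rounds passive-aggressive aggressiveness and rounds.
#' @param w_fp,w_fn loss weights on false-positive / false-negative events;
#'   (1, 1) is the unweighted loss.
#' @param samples_per_action independent rollouts averaged per candidate
#'   action during costing.
#' @param focused use focused costing (restrict the loss to the part of
#'   the output graph connected with the action being costed).
#' @param structural extract features that read previous predictions.
#' @param domain_adapt duplicate every feature with a domain-conjoined copy.
#' @param zero_one_costs skip rollouts and cost every action 0 if it agrees
#'   with the optimal policy and 1 otherwise (the independent-pipeline
#'   degeneration, together with beta = 1 and structural = FALSE).
#' @param seed master seed for every source of randomness.
#' @return list of class "searn_config".
#' @export
searn_config <- function(beta = 0.3, iterations = 12, C = 1, rounds = 5,
                         w_fp = 1, w_fn = 1, samples_per_action = 1,
                         focused = TRUE, structural = TRUE,
                         domain_adapt = FALSE, zero_one_costs = FALSE,
                         seed = 1L) {
  stopifnot(beta > 0, beta <= 1, iterations >= 1, w_fp > 0, w_fn > 0,
            samples_per_action >= 1)
  structure(list(beta = beta, iterations = iterations, C = C, rounds = rounds,
                 w_fp = w_fp, w_fn = w_fn,
                 samples_per_action = samples_per_action, focused = focused,
                 structural = structural, domain_adapt = domain_adapt,
                 zero_one_costs = zero_one_costs, seed = as.integer(seed)),
            class = "searn_config")
}

## Weighted event loss --------------------------------------------------------

#' Weighted event-level loss
#'
#' \code{w_fp * |predicted \\ gold| + w_fn * |gold \\ predicted|} over
#' canonical event signatures; an event counts as correct only when its
#' trigger head, type, Themes and Cause all match, recursively.
#'
#' @param gold_sigs,pred_sigs character vectors of event signatures.
#' @param w_fp,w_fn positive loss weights.
#' @return nonnegative number.
#' @export
event_loss <- function(gold_sigs, pred_sigs, w_fp = 1, w_fn = 1) {
  gold_sigs <- unique(gold_sigs); pred_sigs <- unique(pred_sigs)
  w_fp * length(setdiff(pred_sigs, gold_sigs)) +
    w_fn * length(setdiff(gold_sigs, pred_sigs))
}

## Optimal policy -------------------------------------------------------------

## Is the Theme edge (trigger -> arg_key) currently correct: present in the
## gold decomposition, trigger labeled with its gold type and, for
## event-valued arguments, the argument trigger itself correct with all of
## its gold Themes assigned?
theme_edge_correct <- function(sentence, state, trigger, arg_key) {
  key <- as.character(trigger)
  gl <- sentence$.gold_label[trigger + 1L]
  if (gl == 1L) return(FALSE)
  if (!identical(state$trigger_labels[trigger + 1L], gl)) return(FALSE)
  if (!(arg_key %in% (sentence$.gold_themes[[key]] %||% character())))
    return(FALSE)
  if (startsWith(arg_key, "T:")) {
    at <- as.integer(substring(arg_key, 3L))
    akey <- as.character(at)
    if (!identical(state$trigger_labels[at + 1L],
                   sentence$.gold_label[at + 1L])) return(FALSE)
    if (!setequal(state$themes[[akey]] %||% character(),
                  sentence$.gold_themes[[akey]] %||% character()))
      return(FALSE)
  }
  TRUE
}

#' The optimal policy's action
#'
#' Trigger stage: the gold event type of the (head-reduced) trigger at the
#' token, else "No_trigger".  Theme stage: Theme only when the trigger is
#' recognised with its gold type and the pair is a gold Theme edge -- for
#' event-valued arguments the argument's own Themes must also have been
#' recognised correctly.  Cause stage: the same conditions on the gold
#' Cause edge, plus at least one correct Theme already assigned to the
#' acting trigger.
#'
#' @param sentence prepared sentence (with gold decomposition).
#' @param state current sentence state.
#' @param stage "trigger", "theme" or "cause".
#' @param site token index (trigger stage) or candidate pair.
#' @return integer label index into the stage's label set.
#' @export
optimal_policy_action <- function(sentence, state, stage, site) {
  if (stage == "trigger") return(sentence$.gold_label[site + 1L])
  t <- site$trigger
  key <- as.character(t)
  if (stage == "theme") {
    ok <- theme_edge_correct(sentence, state, t, site$arg_key)
    return(if (ok) 2L else 1L)
  }
  ## cause
  gl <- sentence$.gold_label[t + 1L]
  if (gl == 1L || !identical(state$trigger_labels[t + 1L], gl)) return(1L)
  if (!(site$arg_key %in% (sentence$.gold_causes[[key]] %||% character())))
    return(1L)
  if (startsWith(site$arg_key, "T:")) {
    at <- as.integer(substring(site$arg_key, 3L))
    akey <- as.character(at)
    if (!identical(state$trigger_labels[at + 1L],
                   sentence$.gold_label[at + 1L])) return(1L)
    if (!setequal(state$themes[[akey]] %||% character(),
                  sentence$.gold_themes[[akey]] %||% character())) return(1L)
  }
  any_correct <- any(vapply(state$themes[[key]] %||% character(),
                            function(ak) theme_edge_correct(sentence, state, t, ak),
                            TRUE))
  if (any_correct) 2L else 1L
}

## The executor ---------------------------------------------------------------

## Runs the three stages in order, calling decider(stage, site, state) for
## every action.  Trigger actions run left to right over the candidate
## (noun/verb/adjective) tokens; Theme pairs are popped in order of
## increasing dependency path length (insertion order on ties), with
## Regulation-trigger x themed-trigger pairs appended dynamically; Cause
## pairs likewise, one Cause at most per trigger.  Pairs that would close a
## directed cycle are dropped without an action.
execute_sentence <- function(sentence, decider, record = FALSE) {
  state <- new_state(nrow(sentence$tokens))
  log_act <- function(stage, site, label, extra = NULL) {
    if (record)
      state$action_log[[length(state$action_log) + 1L]] <-
        c(list(stage = stage, site = site, label = label), extra)
  }
  for (tok in sentence$.cand) {
    lab <- decider("trigger", tok, state)
    log_act("trigger", tok, lab)
    state$trigger_labels[tok + 1L] <- lab
  }
  ## Theme stage
  pending <- build_theme_agenda(sentence, state)
  plens <- vapply(pending, function(p) p$plen, 0)
  pranks <- vapply(pending, function(p) p$rank, 0)
  rank <- if (length(pending)) max(pranks) else 0L
  seen <- character()
  reg_trigs <- which(is_regulation_type(
    TRIGGER_LABELS[ifelse(is.na(state$trigger_labels), 1L,
                          state$trigger_labels)])) - 1L
  while (length(pending)) {
    k <- which(plens == min(plens))
    if (length(k) > 1L) k <- k[which.min(pranks[k])] else k <- k[1L]
    pair <- pending[[k]]
    pending[[k]] <- NULL; plens <- plens[-k]; pranks <- pranks[-k]
    pkey <- paste0(pair$trigger, ">", pair$arg_key)
    if (pkey %in% seen) next
    seen <- c(seen, pkey)
    if (creates_directed_cycle(state, pair$trigger, pair$arg_key)) next
    lab <- decider("theme", pair, state)
    log_act("theme", pair, lab)
    if (lab == 2L) {
      first <- is.null(state$themes[[as.character(pair$trigger)]])
      add_theme_edge(state, pair$trigger, pair$arg_key, pair$arg_tok)
      if (first) {
        for (r in reg_trigs) {
          if (r == pair$trigger) next
          rank <- rank + 1L
          np <- make_pair(sentence, r, paste0("T:", pair$trigger),
                          pair$trigger, rank)
          pending[[length(pending) + 1L]] <- np
          plens <- c(plens, np$plen); pranks <- c(pranks, np$rank)
        }
      }
    }
  }
  ## Cause stage
  for (pair in build_cause_agenda(sentence, state)) {
    if (!is.null(state$causes[[as.character(pair$trigger)]])) next
    if (creates_directed_cycle(state, pair$trigger, pair$arg_key)) next
    lab <- decider("cause", pair, state)
    log_act("cause", pair, lab)
    if (lab == 2L) add_cause_edge(state, pair$trigger, pair$arg_key, pair$arg_tok)
  }
  state
}

## Deciders -------------------------------------------------------------------

## deterministic ensemble decider: mixture-weighted sum of per-label scores
## across hypotheses, with per-stage offsets added to the negative class.
ensemble_decider <- function(policy, offsets = c(trigger = 0, theme = 0, cause = 0),
                             stochastic = FALSE) {
  force(policy); force(offsets)
  function(stage, site, state, feats = NULL) {
    if (is.null(feats))
      feats <- action_features(policy$.sentence, stage, site, state,
                               policy$structural, policy$domain_adapt)
    K <- STAGE_K[[stage]]
    if (stochastic) {
      j <- sample.int(length(policy$hyps), 1L, prob = policy$weights)
      scores <- csc_scores(policy$hyps[[j]][[stage]], feats, K)
    } else {
      scores <- rep(0, K)
      for (j in seq_along(policy$hyps))
        scores <- scores + policy$weights[j] *
          csc_scores(policy$hyps[[j]][[stage]], feats, K)
    }
    scores[1] <- scores[1] + (offsets[[stage]] %||% 0)
    which.max(scores)
  }
}

## training decider: optimal policy with probability opt_prob, otherwise a
## hypothesis sampled from the current mixture.
make_train_decider <- function(sentence, hyps, hyp_weights, opt_prob,
                               structural, domain_adapt) {
  function(stage, site, state) {
    use_opt <- length(hyps) == 0L || stats::runif(1) < opt_prob
    if (use_opt) return(optimal_policy_action(sentence, state, stage, site))
    feats <- action_features(sentence, stage, site, state, structural,
                             domain_adapt)
    j <- if (length(hyps) == 1L) 1L else
      sample.int(length(hyps), 1L, prob = hyp_weights)
    scores <- csc_scores(hyps[[j]][[stage]], feats, STAGE_K[[stage]])
    which.max(scores)
  }
}

## replay decider: repeats the logged prefix, forces `forced_label` at
## 1-based position `t`, then delegates to `cont`.
make_replay_decider <- function(log, t, forced_label, cont) {
  i <- 0L
  function(stage, site, state) {
    i <<- i + 1L
    if (i < t) return(log[[i]]$label)
    if (i == t) return(forced_label)
    cont(stage, site, state)
  }
}

#' Run a policy over a sentence
#'
#' In "test" mode every action is taken by the learned ensemble
#' (deterministic mixture-weighted scores by default, or one hypothesis
#' sampled per action with \code{stochastic = TRUE}).  In "train" mode each
#' action uses the optimal policy with probability
#' \code{policy$optimal_policy_prob} and the learned ensemble otherwise;
#' the sentence must carry gold annotation.
#'
#' @param sentence a [prepare_sentence()] result.
#' @param policy a [searn_train()] policy.
#' @param mode "test" or "train".
#' @param offsets named per-stage score offsets added to the negative class.
#' @param stochastic sample one hypothesis per action instead of the
#'   deterministic mixture.
#' @return the predicted sentence state (with action log).
#' @export
run_policy <- function(sentence, policy, mode = c("test", "train"),
                       offsets = c(trigger = 0, theme = 0, cause = 0),
                       stochastic = FALSE) {
  mode <- match.arg(mode)
  if (mode == "test") {
    if (!length(policy$hyps)) stop("policy has no learned hypotheses")
    policy$.sentence <- sentence
    dec <- ensemble_decider(policy, offsets, stochastic)
    return(execute_sentence(sentence, dec, record = TRUE))
  }
  dec <- make_train_decider(sentence, policy$hyps, policy$weights,
                            policy$optimal_policy_prob,
                            policy$structural, policy$domain_adapt)
  execute_sentence(sentence, dec, record = TRUE)
}

## Focused costing ------------------------------------------------------------

## connected component (weak connectivity) of the action site over the
## union of gold and predicted trigger/argument nodes and edges.
focused_component <- function(sentence, state, site_nodes) {
  adj <- list()
  link <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
    adj[[b]] <<- c(adj[[b]], a)
  }
  add_edges <- function(themes, causes) {
    for (key in names(themes)) for (ak in themes[[key]])
      link(paste0("T:", key), ak)
    for (key in names(causes)) for (ak in causes[[key]])
      link(paste0("T:", key), ak)
  }
  add_edges(sentence$.gold_themes, sentence$.gold_causes)
  add_edges(state$themes, state$causes)
  if (length(site_nodes) == 2L) link(site_nodes[1], site_nodes[2])
  seen <- character(); frontier <- site_nodes
  while (length(frontier)) {
    x <- frontier[[1]]; frontier <- frontier[-1]
    if (x %in% seen) next
    seen <- c(seen, x)
    frontier <- c(frontier, setdiff(adj[[x]] %||% character(), seen))
  }
  seen
}

sig_trigger_node <- function(sigs) paste0("T:", sub("^[^@]*@([0-9]+)\\(.*$", "\\1", sigs))

restrict_to_component <- function(sigs, component) {
  sigs[sig_trigger_node(sigs) %in% component]
}

#' Estimate per-label costs for one action
#'
#' Replays the logged action prefix, forces each candidate label in turn,
#' completes the sentence with the supplied continuation decider, builds
#' the resulting events and measures the weighted event loss against gold
#' -- restricted, under focused costing, to the gold and predicted events
#' whose connected component (over the union of gold and predicted
#' trigger/argument graphs) touches the action site.  Costs are averaged
#' over \code{cfg$samples_per_action} rollouts and shifted so their minimum
#' is 0.
#'
#' @param sentence prepared sentence with gold annotation.
#' @param log action log of the main prediction pass.
#' @param t 1-based index of the action being costed.
#' @param cont continuation decider used for the remaining actions.
#' @param cfg a [searn_config()].
#' @param regdict regulation dictionary used during event construction.
#' @return numeric cost vector over the stage's labels, minimum 0.
#' @export
estimate_action_costs <- function(sentence, log, t, cont, cfg, regdict = list()) {
  act <- log[[t]]
  K <- STAGE_K[[act$stage]]
  site_nodes <- if (act$stage == "trigger") paste0("T:", act$site) else
    c(paste0("T:", act$site$trigger), act$site$arg_key)
  costs <- numeric(K)
  for (l in seq_len(K)) {
    acc <- 0
    for (s in seq_len(cfg$samples_per_action)) {
      dec <- make_replay_decider(log, t, l, cont)
      st <- execute_sentence(sentence, dec, record = FALSE)
      pred <- construct_event_signatures(sentence, st, regdict)
      gold <- sentence$.gold_sigs
      if (cfg$focused) {
        comp <- focused_component(sentence, st, site_nodes)
        pred <- restrict_to_component(pred, comp)
        gold <- restrict_to_component(gold, comp)
      }
      acc <- acc + event_loss(gold, pred, cfg$w_fp, cfg$w_fn)
    }
    costs[l] <- acc / cfg$samples_per_action
  }
  costs - min(costs)
}

## Training -------------------------------------------------------------------

#' Train an event extraction policy with SEARN
#'
#' Runs \code{cfg$iterations} SEARN iterations over the corpus.  Each
#' iteration predicts every sentence with the current interpolated policy,
#' generates one cost-sensitive example per action (costs by rollout, or
#' 0/1 against the optimal policy when \code{cfg$zero_one_costs}), trains
#' one passive-aggressive classifier per stage on that iteration's
#' examples, and appends it to the hypothesis ensemble.  Hypothesis j of I
#' receives mixture weight proportional to beta * (1 - beta)^(I - j), so
#' earlier hypotheses matter less.  The returned policy predicts without
#' the optimal policy.
#'
#' @param corpus list of gold-annotated [new_document()] objects.
#' @param cfg a [searn_config()].
#' @param progress print per-iteration diagnostics.
#' @return object of class "searn_policy".
#' @export
searn_train <- function(corpus, cfg = searn_config(), progress = FALSE) {
  if (!length(corpus)) stop("empty corpus")
  regdict <- build_regulation_dictionary(corpus)
  sents <- list()
  for (doc in corpus) for (s in doc$sentences)
    sents[[length(sents) + 1L]] <- prepare_sentence(s, doc$domain)
  hyps <- list(); hyp_weights <- numeric()
  for (iter in seq_len(cfg$iterations)) {
    opt_prob <- (1 - cfg$beta)^(iter - 1L)
    pool <- list(trigger = list(), theme = list(), cause = list())
    for (si in seq_along(sents)) {
      sent <- sents[[si]]
      orng <- swap_rng(derive_seed(cfg$seed, 7L, iter, si))
      dec <- make_train_decider(sent, hyps, hyp_weights, opt_prob,
                                cfg$structural, cfg$domain_adapt)
      ## main pass: record features (step 8) and the optimal action for
      ## every action along the trajectory
      state <- execute_sentence(sent, function(stage, site, state) {
        lab <- dec(stage, site, state)
        feats <- action_features(sent, stage, site, state, cfg$structural,
                                 cfg$domain_adapt)
        opt <- optimal_policy_action(sent, state, stage, site)
        state$action_log[[length(state$action_log) + 1L]] <-
          list(stage = stage, site = site, label = lab,
               feats = feats, opt = opt)
        lab
      }, record = FALSE)
      log <- state$action_log
      for (t in seq_along(log)) {
        act <- log[[t]]
        K <- STAGE_K[[act$stage]]
        if (cfg$zero_one_costs) {
          costs <- rep(1, K); costs[act$opt] <- 0
        } else {
          cont <- make_train_decider(sent, hyps, hyp_weights, opt_prob,
                                     cfg$structural, cfg$domain_adapt)
          costs <- estimate_action_costs(sent, log, t, cont, cfg, regdict)
        }
        if (max(costs) > 0)
          pool[[act$stage]][[length(pool[[act$stage]]) + 1L]] <-
            list(x = act$feats, costs = costs)
      }
      restore_rng(orng)
    }
    hnew <- list()
    for (stage in c("trigger", "theme", "cause")) {
      hnew[[stage]] <- if (length(pool[[stage]]))
        csc_train(pool[[stage]], STAGE_K[[stage]], C = cfg$C,
                  rounds = cfg$rounds,
                  seed = derive_seed(cfg$seed, 11L, iter, match(stage, names(STAGE_K))))
      else NULL
    }
    hyps[[iter]] <- hnew
    ## unrolled h = beta * h_new + (1 - beta) * h: hypothesis j of `iter`
    ## carries unnormalized weight beta * (1 - beta)^(iter - j)
    hyp_weights <- cfg$beta * (1 - cfg$beta)^(iter - seq_len(iter))
    hyp_weights <- hyp_weights / sum(hyp_weights)
    if (progress)
      message(sprintf("iteration %d: %d/%d/%d examples (opt_prob %.3f)",
                      iter, length(pool$trigger), length(pool$theme),
                      length(pool$cause), opt_prob))
  }
  structure(list(hyps = hyps, weights = hyp_weights, beta = cfg$beta,
                 iterations = cfg$iterations,
                 optimal_policy_prob = (1 - cfg$beta)^cfg$iterations,
                 structural = cfg$structural, domain_adapt = cfg$domain_adapt,
                 regdict = regdict, config = cfg),
            class = "searn_policy")
}

#' @export
print.searn_policy <- function(x, ...) {
  cat(sprintf("<searn_policy: %d hypotheses, beta=%.2f, P(optimal)=%.4f, %s features>\n",
              length(x$hyps), x$beta, x$optimal_policy_prob,
              if (x$structural) "structural" else "independent"))
  invisible(x)
}
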