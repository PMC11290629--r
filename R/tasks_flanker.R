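#' Flanker task specification
#'
#' A two-response Eriksen flanker task with four compound stimuli: two
#' target identities map to each response, and the flanker identity (one
#' of the same four stimuli) acts as a context cue. A trial is congruent
#' when the flanker's associated response coincides with the target's
#' correct response.
#'
#' @param n_trials Number of trials per agent.
#' @param p_congruent Proportion of congruent trials.
#' @param bias Magnitude of the a priori context-response association
#'   added to the habit counts of each context's associated response.
#' @param target_strength Contingency pseudo count backing the target's
#'   correct response in the one-step MDP; smaller values give a softer
#'   goal-directed likelihood (more graded evidence).
#' @return A `bcc_flanker_spec`.
#' @export
flanker_spec <- function(n_trials = 400L, p_congruent = 0.5, bias = 3,
                         target_strength = 1.75) {
  stopifnot(n_trials >= 1, p_congruent >= 0, p_congruent <= 1, bias >= 0,
            target_strength > 0)
  structure(list(n_trials = as.integer(n_trials),
                 p_congruent = p_congruent, bias = bias,
                 target_strength = target_strength),
            class = "bcc_flanker_spec")
}

#' Build the flanker task components
#'
#' @param spec A [flanker_spec()].
#' @param config An [agent_config()].
#' @return A list with the two-policy set, the [cue_model()] (cues 1-2 map
#'   to the left-response context, cues 3-4 to the right-response
#'   context), the biased habit prior, and the per-target likelihood rows
#'   (softmaxed free energies of a one-step MDP whose contingencies
#'   reward the target's correct response).
#' @export
build_flanker_task <- function(spec = flanker_spec(),
                               config = agent_config()) {
  ps <- enumerate_policies(2L, 1L)
  cm <- cue_model(2L, c(1L, 1L, 2L, 2L), config$epsilon)
  bias <- matrix(0, 2L, 2L)
  if (!config$no_bias) {
    bias[1L, 1L] <- spec$bias
    bias[2L, 2L] <- spec$bias
  }
  a <- if (config$no_bias) 0.001 else config$a
  habit <- init_prior(a, 2L, 2L, bias = bias,
                      forgetting = config$forgetting)
  # One-step MDP per target: action i leads deterministically to state i;
  # contingencies strongly reward the state reached by the correct response.
  transition <- list(matrix(c(1, 0, 1, 0), 2, 2),
                     matrix(c(0, 1, 0, 1), 2, 2))
  ts <- spec$target_strength
  lik_by_target <- lapply(1:2, function(correct) {
    counts <- matrix(1, 2L, 2L)
    counts[1L, correct] <- ts
    counts[2L, correct] <- 1
    counts[1L, 3L - correct] <- 1
    counts[2L, 3L - correct] <- ts
    mdp <- context_mdp(transition, counts, preference = config$preference)
    F <- vapply(0:1, function(act)
      predicted_free_energy(mdp, propagate_states(mdp, correct, act)),
      numeric(1))
    policy_likelihood(F)
  })
  list(policy_set = ps, cue_model = cm, habit = habit,
       lik_by_target = lik_by_target, spec = spec)
}

#' Run the flanker experiment
#'
#' Per trial: the flanker cue drives the context posterior, the sampler
#' runs on the context-mixed prior and the target-driven likelihood, the
#' habit prior is updated with the posterior context weights and then
#' decayed by the forgetting factor (the mechanism behind the Gratton
#' effect). Ablation flags in the [agent_config()] disable the biased
#' prior, habit updating, or context inference.
#'
#' @param spec A [flanker_spec()].
#' @param config An [agent_config()]; flanker defaults are
#'   `agent_config(a = 1, s = 2.5, epsilon = 0.05, gamma = 0.5,
#'   forgetting = 0.05)`.
#' @param n_agents Number of simulated agents.
#' @param master_seed Master seed (per-agent substreams).
#' @return A trial-record data frame with previous-trial congruency
#'   tagged for Gratton analyses.
#' @export
run_flanker_experiment <- function(spec = flanker_spec(),
                                   config = agent_config(
                                     a = 1, s = 2.5, epsilon = 0.05,
                                     gamma = 0.5, forgetting = 0.05),
                                   n_agents = 1L, master_seed = 1L) {
  stopifnot(inherits(config, "bcc_agent_config"), n_agents >= 1)
  scfg <- sampler_config(config$s, config$t_sample, config$t_nd,
                         config$max_samples)
  nrec <- n_agents * spec$n_trials
  rec <- empty_records(nrec)
  row <- 0L

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  for (ag in seq_len(n_agents)) {
    set.seed(agent_seed(master_seed, ag))
    task <- build_flanker_task(spec, config)
    habit <- task$habit
    belief <- c(0.5, 0.5)
    prev_con <- NA
    for (tr in seq_len(spec$n_trials)) {
      congruent <- stats::runif(1) < spec$p_congruent
      target <- sample(1:2, 1L)
      flanker_ctx <- if (congruent) target else 3L - target
      cue <- (flanker_ctx - 1L) * 2L + sample(1:2, 1L)
      w <- if (config$no_context_inference) c(0.5, 0.5) else
        context_posterior(context_predict(belief, config$gamma),
                          list(cue_likelihood(cue, task$cue_model)))
      prior_mix <- prior_probabilities(habit, w)
      lik <- task$lik_by_target[[target]]
      if (config$mixture_mode == "posterior") {
        pr_rows <- habit$counts / rowSums(habit$counts)
        sl <- mix_for_sampler(pr_rows, rbind(lik, lik), w,
                              config$mixture_mode)
        prior_mix <- sl$prior; lik <- sl$likelihood
      }
      res <- run_sampler(prior_mix, lik, scfg)
      response <- res$chosen_policy
      correct <- response == target
      # the target rule is context-independent here, so experienced
      # outcomes carry no context evidence; the posterior is cue-driven
      if (!config$no_habit_update)
        habit <- update_habit(habit, response, w)
      habit <- apply_forgetting(habit)
      belief <- w
      row <- row + 1L
      rec$agent[row] <- ag; rec$miniblock[row] <- tr; rec$trial[row] <- 1L
      rec$true_context[row] <- flanker_ctx
      rec$cue[row] <- cue
      rec$congruent[row] <- congruent
      rec$prev_congruent[row] <- prev_con
      rec$action[row] <- response
      rec$reward[row] <- as.integer(correct)
      rec$correct[row] <- correct
      rec$n_samples[row] <- res$n_samples
      rec$rt_ms[row] <- res$rt_ms
      rec$capped[row] <- res$capped
      prev_con <- congruent
    }
  }
  rec$task <- "flanker"
  rec$trials_since_switch <- NA_integer_
  rec$training_length <- NA_integer_
  rec$a <- config$a; rec$s <- config$s
  rec$epsilon <- config$epsilon; rec$gamma <- config$gamma
  rec$forgetting <- config$forgetting
  attr(rec, "mixture_mode") <- config$mixture_mode
  rec
}
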