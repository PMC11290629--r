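#' Task-switching specification
#'
#' Two task sets (contexts) over compound stimuli carrying one feature
#' per task; each feature value maps to one of two responses under its
#' own task. A trial is congruent when both features demand the same
#' response. The task cue is observed with uncertainty `epsilon` (cue-
#' target-interval proxy) and the assumed change probability `gamma`
#' plays the role of the response-stimulus interval.
#'
#' @param training_length Trials of single-task training per context
#'   before the switching phase.
#' @param n_runs Number of task runs in the switching phase.
#' @param run_length Trials per run (trials-since-switch 1..run_length).
#' @param single_task If `TRUE`, the test phase never switches (the
#'   single-task reference condition of cue-uncertainty sweeps).
#' @return A `bcc_taskswitch_spec`.
#' @export
taskswitch_spec <- function(training_length = 40L, n_runs = 18L,
                            run_length = 4L, single_task = FALSE) {
  stopifnot(training_length >= 0, n_runs >= 1, run_length >= 1)
  structure(list(training_length = as.integer(training_length),
                 n_runs = as.integer(n_runs),
                 run_length = as.integer(run_length),
                 single_task = isTRUE(single_task)),
            class = "bcc_taskswitch_spec")
}

# Per-context contingency counts: outcome (reward / no reward) x
# state, where a state is a (feature value, action) pair of that task:
# state = (value - 1) * 2 + action.
.ts_state <- function(value, action) (value - 1L) * 2L + action

#' Run the task-switching experiment
#'
#' A training phase (each context in turn, cued like test trials) lets
#' the agent learn each task's outcome rules; the switching phase then
#' alternates the active task every `run_length` trials. Per trial the
#' cue passes through the uncertainty `epsilon`, the belief through the
#' change probability `gamma`, and experienced outcomes feed back into
#' the context posterior -- residual belief in the previous task is what
#' produces switch costs.
#'
#' @param spec A [taskswitch_spec()].
#' @param config An [agent_config()]; task-switching defaults are the
#'   value-only learner `agent_config(a = 0.001, s = 2.5, epsilon = 0.05,
#'   gamma = 0.1, contingency_init = 3)` (the larger contingency init
#'   slows rule learning so the length of training is visible in the
#'   switching phase).
#' @param n_agents Number of simulated agents.
#' @param master_seed Master seed (per-agent substreams).
#' @return A trial-record data frame; switching-phase rows are tagged
#'   with `trials_since_switch`, training rows carry `miniblock <= 0`.
#' @export
run_taskswitch_experiment <- function(spec = taskswitch_spec(),
                                      config = agent_config(
                                        a = 0.001, s = 2.5,
                                        epsilon = 0.05, gamma = 0.1,
                                        contingency_init = 3),
                                      n_agents = 1L, master_seed = 1L) {
  stopifnot(inherits(config, "bcc_agent_config"), n_agents >= 1)
  scfg <- sampler_config(config$s, config$t_sample, config$t_nd,
                         config$max_samples)
  cm <- cue_model(2L, c(1L, 2L), config$epsilon)
  pref <- config$preference
  n_train <- 2L * spec$training_length
  n_test <- spec$n_runs * spec$run_length
  nrec <- n_agents * (n_train + n_test)
  rec <- empty_records(nrec)
  row <- 0L

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  # schedule: training runs of each context, then alternating runs
  train_ctx <- rep(1:2, each = spec$training_length)
  test_ctx <- rep(rep(1:2, length.out = spec$n_runs),
                  each = spec$run_length)
  if (spec$single_task) test_ctx <- rep(1L, n_test)
  tss <- rep(seq_len(spec$run_length), spec$n_runs)
  if (spec$single_task) tss <- seq_len(n_test)

  for (ag in seq_len(n_agents)) {
    set.seed(agent_seed(master_seed, ag))
    ci <- config$contingency_init
    cont <- list(matrix(ci, 2L, 4L), matrix(ci, 2L, 4L))
    habit <- init_prior(config$a, 2L, 2L, forgetting = config$forgetting)
    belief <- c(0.5, 0.5)
    phase_ctx <- c(train_ctx, test_ctx)
    phase_idx <- c(seq_len(n_train) - n_train, seq_len(n_test))
    phase_tss <- c(rep(NA_integer_, n_train), tss)
    for (i in seq_along(phase_ctx)) {
      active <- phase_ctx[i]
      v <- sample(1:2, 2L, replace = TRUE)  # feature value per task
      congruent <- v[1L] == v[2L]
      target <- v[active]
      w <- if (config$no_context_inference) c(0.5, 0.5) else
        context_posterior(context_predict(belief, config$gamma),
                          list(cue_likelihood(active, cm)))
      lik_rows <- t(vapply(1:2, function(c) {
        q <- vapply(1:2, function(act) {
          st <- .ts_state(v[c], act)
          cont[[c]][1L, st] / sum(cont[[c]][, st])
        }, numeric(1))
        F <- .kl2(q, pref)
        policy_likelihood(F)
      }, numeric(2)))
      pr_rows <- habit$counts / rowSums(habit$counts)
      sl <- mix_for_sampler(pr_rows, lik_rows, w, config$mixture_mode)
      res <- run_sampler(sl$prior, sl$likelihood, scfg)
      action <- res$chosen_policy
      correct <- action == target
      r <- as.integer(correct)
      ev <- vapply(1:2, function(c) {
        st <- .ts_state(v[c], action)
        q1 <- cont[[c]][1L, st] / sum(cont[[c]][, st])
        if (r == 1L) q1 else 1 - q1
      }, numeric(1))
      w_post <- if (config$no_context_inference) c(0.5, 0.5) else
        context_posterior(w, list(ev))
      r_row <- if (r == 1L) 1L else 2L
      for (c in 1:2) {
        st <- .ts_state(v[c], action)
        cont[[c]][r_row, st] <- cont[[c]][r_row, st] + w_post[c]
      }
      if (!config$no_habit_update)
        habit <- update_habit(habit, action, w_post)
      if (config$forgetting > 0) habit <- apply_forgetting(habit)
      belief <- w_post
      row <- row + 1L
      rec$agent[row] <- ag
      rec$miniblock[row] <- phase_idx[i]
      rec$trial[row] <- 1L
      rec$true_context[row] <- active
      rec$cue[row] <- active
      rec$congruent[row] <- congruent
      rec$trials_since_switch[row] <- phase_tss[i]
      rec$action[row] <- action
      rec$reward[row] <- r
      rec$correct[row] <- correct
      rec$n_samples[row] <- res$n_samples
      rec$rt_ms[row] <- res$rt_ms
      rec$capped[row] <- res$capped
    }
  }
  rec$task <- "taskswitch"
  rec$prev_congruent <- NA
  rec$training_length <- spec$training_length
  rec$a <- config$a; rec$s <- config$s
  rec$epsilon <- config$epsilon; rec$gamma <- config$gamma
  rec$forgetting <- config$forgetting
  attr(rec, "mixture_mode") <- config$mixture_mode
  rec
}

#' Parameter sweep for the task-switching experiment
#'
#' Reruns [run_taskswitch_experiment()] at each value of `epsilon` (the
#' cue-target-interval proxy) or `gamma` (the response-stimulus-interval
#' proxy) and stacks the tagged records.
#'
#' @param parameter `"epsilon"` or `"gamma"`.
#' @param values Numeric sweep values.
#' @param spec,config,n_agents,master_seed As in
#'   [run_taskswitch_experiment()].
#' @return Combined trial records; the swept column varies by condition.
#' @export
run_taskswitch_sweep <- function(parameter = c("epsilon", "gamma"),
                                 values,
                                 spec = taskswitch_spec(),
                                 config = agent_config(a = 0.001, s = 2.5,
                                                       epsilon = 0.05,
                                                       gamma = 0.1,
                                                       contingency_init = 3),
                                 n_agents = 1L, master_seed = 1L) {
  parameter <- match.arg(parameter)
  out <- lapply(values, function(val) {
    cfg <- config
    cfg[[parameter]] <- val
    run_taskswitch_experiment(spec, cfg, n_agents, master_seed)
  })
  do.call(rbind, out)
}
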