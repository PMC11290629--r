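#' Grid-world task specification
#'
#' A 4 x 5 grid (20 cells, numbered 1-based bottom-up row-major:
#' `cell = (row - 1) * cols + col`). Every four-trial miniblock starts in
#' the bottom-row middle (cell 3); goal 1 (cell 15) pays off during the
#' first phase, goal 2 (cell 11) afterwards. Both goals sit in row 3 at
#' Manhattan distance 4 from the start, so a miniblock succeeds iff the
#' agent occupies the active goal at its final step.
#'
#' @param rows,cols Grid dimensions.
#' @param start_cell Starting cell of every miniblock.
#' @param goal_cells Goal cell of context 1 and context 2.
#' @param miniblocks Number of miniblocks in the experiment.
#' @param trials_per_miniblock Steps per miniblock.
#' @param switch_at First miniblock of context 2.
#' @return A `bcc_gridworld_spec`.
#' @export
gridworld_spec <- function(rows = 4L, cols = 5L, start_cell = 3L,
                           goal_cells = c(15L, 11L), miniblocks = 200L,
                           trials_per_miniblock = 4L, switch_at = 101L) {
  stopifnot(rows >= 1, cols >= 1, length(goal_cells) == 2L,
            start_cell >= 1, start_cell <= rows * cols,
            all(goal_cells >= 1), all(goal_cells <= rows * cols),
            miniblocks >= 1, trials_per_miniblock >= 1,
            switch_at >= 1, switch_at <= miniblocks + 1L)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 start_cell = as.integer(start_cell),
                 goal_cells = as.integer(goal_cells),
                 miniblocks = as.integer(miniblocks),
                 trials_per_miniblock = as.integer(trials_per_miniblock),
                 switch_at = as.integer(switch_at)),
            class = "bcc_gridworld_spec")
}

#' One deterministic grid move
#'
#' Actions 0 = left, 1 = up, 2 = right; moves off the edge leave the cell
#' unchanged (boundary clamp).
#'
#' @param cell Current cell (1-based).
#' @param action Action index (0, 1 or 2).
#' @param rows,cols Grid dimensions.
#' @return The next cell.
#' @export
grid_move <- function(cell, action, rows = 4L, cols = 5L) {
  row <- (cell - 1L) %/% cols + 1L
  col <- (cell - 1L) %% cols + 1L
  if (action == 0L && col > 1L) col <- col - 1L
  else if (action == 1L && row < rows) row <- row + 1L
  else if (action == 2L && col < cols) col <- col + 1L
  (row - 1L) * cols + col
}

#' Build the grid-world environment
#'
#' Constructs the shared deterministic transition kernels, one
#' [context_mdp()] per goal context (contingency counts start uniform:
#' the agent must discover the goal by trial and error), the 81-policy
#' set, and the precomputed cell trajectory of every policy from the
#' start cell.
#'
#' @param spec A [gridworld_spec()].
#' @param preference Outcome preference passed to [context_mdp()].
#' @return A list with `policy_set`, `mdps` (one per context),
#'   `trajectories` (policies x steps matrix of visited cells), and the
#'   spec.
#' @export
build_grid_world <- function(spec = gridworld_spec(),
                             preference = c(0.995, 0.005)) {
  n <- spec$rows * spec$cols
  transition <- lapply(0:2, function(a) {
    Tm <- matrix(0, n, n)
    for (s in seq_len(n)) Tm[grid_move(s, a, spec$rows, spec$cols), s] <- 1
    Tm
  })
  mdps <- lapply(spec$goal_cells, function(g)
    context_mdp(transition, preference = preference))
  ps <- enumerate_policies(3L, spec$trials_per_miniblock)
  K <- nrow(ps$policies)
  traj <- matrix(0L, K, spec$trials_per_miniblock)
  for (k in seq_len(K)) {
    cell <- spec$start_cell
    for (t in seq_len(spec$trials_per_miniblock)) {
      cell <- grid_move(cell, ps$policies[k, t], spec$rows, spec$cols)
      traj[k, t] <- cell
    }
  }
  list(policy_set = ps, mdps = mdps, trajectories = traj, spec = spec)
}

# KL(p || q) for two-outcome distributions, vectorized over p1.
.kl2 <- function(p1, q) {
  p0 <- 1 - p1
  out <- numeric(length(p1))
  nz1 <- p1 > 0
  out[nz1] <- p1[nz1] * log(p1[nz1] / q[1L])
  nz0 <- p0 > 0
  out[nz0] <- out[nz0] + p0[nz0] * log(p0[nz0] / q[2L])
  out
}

#' Run the grid-world experiment
#'
#' The full closed loop: per miniblock the context belief is propagated
#' (there are no cues; evidence comes from experienced outcomes), per
#' trial the policy space is restricted to the sequences consistent with
#' the actions already executed, habit counts are renormalized as the
#' proposal, the reward likelihood over the remaining steps is computed
#' from the learned contingencies, and the MH sampler picks the policy
#' whose next action is executed. After the miniblock, the context
#' posterior folds in the outcome evidence and weights the contingency
#' and habit updates.
#'
#' @param spec A [gridworld_spec()].
#' @param config An [agent_config()]; `a = 1` for automatism+value
#'   learners, `a = 0.001` for value-only learners.
#' @param n_agents Number of simulated agents.
#' @param master_seed Master seed; each agent runs on its own substream.
#' @return A trial-record data frame (one row per trial) with attribute
#'   `mixture_mode`.
#' @export
run_gridworld_experiment <- function(spec = gridworld_spec(),
                                     config = agent_config(
                                       a = 1.0, s = 0.5, gamma = 0.01,
                                       preference = c(0.995, 0.005)),
                                     n_agents = 1L, master_seed = 1L) {
  stopifnot(inherits(config, "bcc_agent_config"), n_agents >= 1)
  env <- build_grid_world(spec, preference = config$preference)
  K <- nrow(env$policy_set$policies)
  Tm <- spec$trials_per_miniblock
  n_cells <- spec$rows * spec$cols
  pref <- config$preference
  scfg <- sampler_config(config$s, config$t_sample, config$t_nd,
                         config$max_samples)
  pol <- env$policy_set$policies
  traj <- env$trajectories
  # lexicographic prefix blocks: policies sharing the first t-1 actions
  # are contiguous, with block size 3^(T - t + 1)
  block <- 3L^(Tm - seq_len(Tm) + 1L)

  nrec <- n_agents * spec$miniblocks * Tm
  rec <- empty_records(nrec)
  row <- 0L

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  for (ag in seq_len(n_agents)) {
    set.seed(agent_seed(master_seed, ag))
    ci <- config$contingency_init
    cont <- list(matrix(ci, 2, n_cells), matrix(ci, 2, n_cells))
    habit <- init_prior(config$a, 2L, K, forgetting = config$forgetting)
    belief <- c(1, 0)  # the agent starts committed to a first context;
                       # the second slot stands for "unknown/new rules"
    for (mb in seq_len(spec$miniblocks)) {
      active <- if (mb < spec$switch_at) 1L else 2L
      goal <- spec$goal_cells[active]
      w_pre <- if (config$no_context_inference) c(0.5, 0.5) else
        context_predict(belief, config$gamma)
      # per-context KL of each cell's predicted outcome from the preference
      klt <- rbind(.kl2(cont[[1L]][1L, ] / colSums(cont[[1L]]), pref),
                   .kl2(cont[[2L]][1L, ] / colSums(cont[[2L]]), pref))
      offset <- 0L
      prior_ctx <- habit$counts / rowSums(habit$counts)
      for (t in seq_len(Tm)) {
        cand <- offset + seq_len(block[t])
        if (config$preference_mode == "terminal") {
          F1 <- klt[1L, traj[cand, Tm]]
          F2 <- klt[2L, traj[cand, Tm]]
        } else {
          steps <- t:Tm
          F1 <- rowSums(matrix(klt[1L, traj[cand, steps]], length(cand)))
          F2 <- rowSums(matrix(klt[2L, traj[cand, steps]], length(cand)))
        }
        lik_rows <- rbind(policy_likelihood(F1), policy_likelihood(F2))
        pr <- prior_ctx[, cand, drop = FALSE]
        pr <- pr / rowSums(pr)
        sl <- mix_for_sampler(pr, lik_rows, w_pre, config$mixture_mode)
        res <- run_sampler(sl$prior, sl$likelihood, scfg)
        chosen <- cand[res$chosen_policy]
        act <- pol[chosen, t]
        offset <- offset + act * (block[t] %/% 3L)
        row <- row + 1L
        rec$miniblock[row] <- mb; rec$trial[row] <- t
        rec$agent[row] <- ag; rec$true_context[row] <- active
        rec$action[row] <- act
        rec$n_samples[row] <- res$n_samples
        rec$rt_ms[row] <- res$rt_ms
        rec$capped[row] <- res$capped
      }
      executed <- offset + 1L  # block size has shrunk to 1
      cells <- traj[executed, ]
      rewards <- as.integer(cells == goal)
      success <- cells[Tm] == goal
      rec$reward[(row - Tm + 1L):row] <- rewards
      rec$correct[(row - Tm + 1L):row] <- success
      # outcome evidence: each context's predicted probability of the
      # observed rewards at the visited cells; under terminal preference
      # the reward channel lives on the episode-final step only, so both
      # evidence and contingency learning use that step
      steps_used <- if (config$preference_mode == "terminal") Tm else
        seq_len(Tm)
      ev <- vapply(1:2, function(c) {
        cs <- cells[steps_used]
        q1 <- cont[[c]][1L, cs] / colSums(cont[[c]][, cs, drop = FALSE])
        prod(ifelse(rewards[steps_used] == 1L, q1, 1 - q1))
      }, numeric(1))
      w_post <- if (config$no_context_inference) c(0.5, 0.5) else
        context_posterior(w_pre, list(ev))
      for (t in steps_used) {
        r_row <- if (rewards[t] == 1L) 1L else 2L
        cont[[1L]][r_row, cells[t]] <- cont[[1L]][r_row, cells[t]] + w_post[1L]
        cont[[2L]][r_row, cells[t]] <- cont[[2L]][r_row, cells[t]] + w_post[2L]
      }
      if (!config$no_habit_update)
        habit <- update_habit(habit, executed, w_post)
      if (config$forgetting > 0) habit <- apply_forgetting(habit)
      belief <- w_post
    }
  }
  rec$task <- "gridworld"
  rec$cue <- NA_integer_
  rec$congruent <- NA
  rec$prev_congruent <- NA
  rec$trials_since_switch <- NA_integer_
  rec$training_length <- NA_integer_
  rec$a <- config$a; rec$s <- config$s
  rec$epsilon <- NA_real_; rec$gamma <- config$gamma
  rec$forgetting <- config$forgetting
  attr(rec, "mixture_mode") <- config$mixture_mode
  rec
}
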