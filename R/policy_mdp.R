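#' Enumerate the policy space
#'
#' All fixed-length action sequences (policies) over a discrete action set,
#' in lexicographic order so that policy indices are stable across runs.
#'
#' @param n_actions Number of actions (positive integer).
#' @param horizon Sequence length (positive integer).
#' @return A `bcc_policy_set`: `n_actions`, `horizon`, and `policies`, a
#'   `n_actions^horizon` by `horizon` integer matrix of 0-based action
#'   indices, rows in lexicographic order.
#' @examples
#' enumerate_policies(3, 4)   # the 81 grid-world policies
#' @export
enumerate_policies <- function(n_actions, horizon) {
  if (length(n_actions) != 1L || length(horizon) != 1L ||
      n_actions < 1 || horizon < 1 ||
      n_actions != round(n_actions) || horizon != round(horizon))
    stop("`n_actions` and `horizon` must be positive integers")
  n_actions <- as.integer(n_actions)
  horizon <- as.integer(horizon)
  K <- n_actions^horizon
  pol <- matrix(0L, K, horizon)
  # lexicographic: leftmost position is the most significant digit
  for (t in seq_len(horizon)) {
    reps <- n_actions^(horizon - t)
    pol[, t] <- rep(rep(0:(n_actions - 1L), each = reps),
                    length.out = K)
  }
  structure(list(n_actions = n_actions, horizon = horizon, policies = pol),
            class = "bcc_policy_set")
}

#' @export
print.bcc_policy_set <- function(x, ...) {
  cat("<bcc_policy_set>", nrow(x$policies), "policies =",
      x$n_actions, "actions ^", x$horizon, "steps\n")
  invisible(x)
}

#' Context-specific Markov decision process
#'
#' Holds one context's transition kernels, its learnable reward-contingency
#' pseudo counts, and the agent's outcome preference (desired rewards).
#'
#' @param transition List with one `n_states x n_states` column-stochastic
#'   matrix per action: entry `[s', s]` is the probability of moving to
#'   state `s'` from state `s` under that action.
#' @param contingency_counts `n_outcomes x n_states` matrix of strictly
#'   positive pseudo counts over reward outcomes per state. Default:
#'   uniform 1 per (state, outcome) with two outcomes (reward, no reward) --
#'   an uninformed agent.
#' @param preference Probability vector over outcomes with full support
#'   (default `c(0.95, 0.05)` for reward / no reward); full support keeps
#'   Kullback-Leibler divergences finite.
#' @return A `bcc_context_mdp`.
#' @export
context_mdp <- function(transition, contingency_counts = NULL,
                        preference = c(0.95, 0.05)) {
  stopifnot(is.list(transition), length(transition) >= 1L)
  n_states <- ncol(transition[[1L]])
  for (Tm in transition) {
    stopifnot(is.matrix(Tm), nrow(Tm) == n_states, ncol(Tm) == n_states)
    if (any(abs(colSums(Tm) - 1) > 1e-10))
      stop("each transition column must sum to 1")
  }
  if (is.null(contingency_counts))
    contingency_counts <- matrix(1, length(preference), n_states)
  stopifnot(is.matrix(contingency_counts),
            ncol(contingency_counts) == n_states,
            nrow(contingency_counts) == length(preference))
  if (any(contingency_counts <= 0))
    stop("contingency counts must be strictly positive")
  if (any(preference <= 0) || abs(sum(preference) - 1) > 1e-10)
    stop("`preference` must be a probability vector with full support")
  structure(list(n_states = n_states, transition = transition,
                 contingency_counts = contingency_counts,
                 preference = preference),
            class = "bcc_context_mdp")
}

#' @export
print.bcc_context_mdp <- function(x, ...) {
  cat("<bcc_context_mdp>", x$n_states, "states,",
      length(x$transition), "actions,",
      nrow(x$contingency_counts), "outcomes\n")
  invisible(x)
}

#' Mean reward contingencies of a context
#'
#' Contingency pseudo counts normalized per state: column `s` is the
#' current posterior-mean outcome distribution `p(r | s)`.
#'
#' @param mdp A [context_mdp()].
#' @return An `n_outcomes x n_states` matrix with unit column sums.
#' @export
mean_contingency <- function(mdp) {
  sweep(mdp$contingency_counts, 2, colSums(mdp$contingency_counts), "/")
}

#' Propagate state beliefs through a policy
#'
#' @param mdp A [context_mdp()].
#' @param start_state 1-based state index the episode starts in.
#' @param policy Integer vector of 0-based action indices.
#' @return A `(length(policy) + 1) x n_states` matrix of state
#'   distributions; row 1 is a point mass on `start_state`.
#' @export
propagate_states <- function(mdp, start_state, policy) {
  n <- mdp$n_states
  if (length(start_state) != 1L || start_state < 1 || start_state > n)
    stop("invalid start state")
  if (any(policy < 0 | policy >= length(mdp$transition)))
    stop("invalid action index in policy")
  d <- matrix(0, length(policy) + 1L, n)
  d[1L, start_state] <- 1
  for (t in seq_along(policy)) {
    d[t + 1L, ] <- as.numeric(mdp$transition[[policy[t] + 1L]] %*% d[t, ])
  }
  d
}

.kl <- function(p, q) {
  idx <- p > 0
  sum(p[idx] * log(p[idx] / q[idx]))
}

#' Predicted free energy of a belief trajectory
#'
#' Sum over time steps 2..T of the Kullback-Leibler divergence between the
#' predicted outcome distribution `q_t(r) = sum_s p(r | s) d_t(s)` and the
#' outcome preference. Under exact forward propagation this is the policy's
#' divergence between predicted and preferred outcomes; its negated softmax
#' is the reward likelihood.
#'
#' @param mdp A [context_mdp()].
#' @param state_beliefs Matrix of state distributions, one row per time
#'   step; row 1 is the (unscored) starting belief, as returned by
#'   [propagate_states()].
#' @return Non-negative scalar; 0 iff the predicted outcome distribution
#'   equals the preference at every scored step.
#' @export
predicted_free_energy <- function(mdp, state_beliefs) {
  if (is.null(dim(state_beliefs)))
    state_beliefs <- matrix(state_beliefs, nrow = 1L)
  if (any(abs(rowSums(state_beliefs) - 1) > 1e-10))
    stop("state beliefs must be normalized")
  mc <- mean_contingency(mdp)
  rows <- if (nrow(state_beliefs) > 1L) 2:nrow(state_beliefs) else 1L
  f <- 0
  for (t in rows) {
    q_t <- as.numeric(mc %*% state_beliefs[t, ])
    f <- f + .kl(q_t, mdp$preference)
  }
  f
}

#' Reward likelihood from free energies
#'
#' `softmax(-F)` with max-subtraction stabilization; invariant to adding a
#' constant to all entries.
#'
#' @param F Finite vector of predicted free energies.
#' @return Probability vector over policies.
#' @export
policy_likelihood <- function(F) {
  if (length(F) < 1L) stop("empty free-energy vector")
  if (any(!is.finite(F))) stop("free energies must be finite")
  w <- exp(-(F - min(F)))
  w / sum(w)
}

#' Update reward contingencies from experience
#'
#' Increments the pseudo count of each observed (state, outcome) pair by
#' `weight` -- typically the posterior probability of the context the MDP
#' belongs to.
#'
#' @param mdp A [context_mdp()].
#' @param observed List of `c(state, outcome)` pairs (1-based indices).
#' @param weight Update weight in `[0, 1]`.
#' @return The updated [context_mdp()].
#' @export
update_contingencies <- function(mdp, observed, weight) {
  stopifnot(weight >= 0, weight <= 1)
  for (obs in observed) {
    s <- obs[1L]; r <- obs[2L]
    if (s < 1 || s > mdp$n_states || r < 1 || r > nrow(mdp$contingency_counts))
      stop("invalid (state, outcome) observation")
    mdp$contingency_counts[r, s] <- mdp$contingency_counts[r, s] + weight
  }
  mdp
}
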