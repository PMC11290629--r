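#' Initialize a context-specific habit prior over policies
#'
#' The prior over policies is Dirichlet with pseudo counts `alpha`, one
#' per (context, policy). Counting starts at `alpha_init = 1 / a`, where
#' `a` is the automatization tendency: `a = 1` makes every choice reshape
#' the prior strongly (automatism+value learner), `a = 0.001` starts the
#' counts at 1000 so the prior stays effectively uniform (value-only
#' learner). Optional additive offsets implement a priori context-response
#' associations (e.g. flanker-response biases).
#'
#' @param a Automatization tendency, `a > 0`; initial counts are `1 / a`.
#' @param n_contexts,n_policies Dimensions of the count matrix.
#' @param bias Optional `n_contexts x n_policies` matrix of non-negative
#'   additive offsets on the initial counts.
#' @param forgetting Forgetting factor `f` in `[0, 1]` applied by
#'   [apply_forgetting()] once per episode; 0 (default) is the stable-
#'   environment case.
#' @return A `bcc_habit_prior` with fields `counts`, `alpha_init`,
#'   `automatization_tendency`, `forgetting`.
#' @export
init_prior <- function(a, n_contexts, n_policies, bias = NULL,
                       forgetting = 0) {
  stopifnot(length(a) == 1L, is.finite(a))
  if (a <= 0) stop("automatization tendency `a` must be > 0")
  stopifnot(n_contexts >= 1, n_policies >= 1,
            forgetting >= 0, forgetting <= 1)
  counts <- matrix(1 / a, n_contexts, n_policies)
  if (!is.null(bias)) {
    stopifnot(is.matrix(bias), nrow(bias) == n_contexts,
              ncol(bias) == n_policies, all(bias >= 0))
    counts <- counts + bias
  }
  structure(list(counts = counts, alpha_init = counts,
                 automatization_tendency = a, forgetting = forgetting),
            class = "bcc_habit_prior")
}

#' @export
print.bcc_habit_prior <- function(x, ...) {
  cat("<bcc_habit_prior>", nrow(x$counts), "contexts x",
      ncol(x$counts), "policies | a =", x$automatization_tendency,
      "| f =", x$forgetting, "\n")
  invisible(x)
}

#' Context-mixed prior probabilities over policies
#'
#' Each context's counts are normalized to a distribution; the result is
#' their convex combination under the context weights.
#'
#' @param prior A [init_prior()] habit prior.
#' @param context_weights Normalized weights over contexts.
#' @return Probability vector over policies.
#' @export
prior_probabilities <- function(prior, context_weights) {
  stopifnot(inherits(prior, "bcc_habit_prior"),
            length(context_weights) == nrow(prior$counts))
  per_ctx <- prior$counts / rowSums(prior$counts)
  mix_over_contexts(per_ctx, context_weights)
}

#' Record an executed policy in the habit prior
#'
#' Adds each context's posterior weight to that context's count for the
#' executed policy (repetition-based automatism learning).
#'
#' @param prior A [init_prior()] habit prior.
#' @param executed_policy Policy index (1-based).
#' @param context_weights Normalized posterior over contexts.
#' @return The updated prior.
#' @export
update_habit <- function(prior, executed_policy, context_weights) {
  stopifnot(inherits(prior, "bcc_habit_prior"))
  if (length(executed_policy) != 1L || executed_policy < 1 ||
      executed_policy > ncol(prior$counts))
    stop("invalid policy index")
  stopifnot(length(context_weights) == nrow(prior$counts),
            abs(sum(context_weights) - 1) < 1e-8)
  prior$counts[, executed_policy] <-
    prior$counts[, executed_policy] + context_weights
  prior
}

#' Decay habit counts toward their initial values
#'
#' `counts <- alpha_init + (1 - f) * (counts - alpha_init)`, applied once
#' per episode. A contraction toward `alpha_init`: `f = 0` leaves counts
#' unchanged, `f = 1` resets them. Forgetting keeps later episodes
#' influential in slowly changing environments and drives the sequential
#' (Gratton) modulation in the flanker task.
#'
#' @param prior A [init_prior()] habit prior.
#' @return The updated prior.
#' @export
apply_forgetting <- function(prior) {
  stopifnot(inherits(prior, "bcc_habit_prior"))
  f <- prior$forgetting
  prior$counts <- prior$alpha_init + (1 - f) * (prior$counts - prior$alpha_init)
  prior
}
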