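#' Agent configuration
#'
#' The free parameters of a simulated agent, shared by all task runners.
#'
#' @param a Automatization tendency (`1 / alpha_init`): 1 gives an
#'   automatism+value learner, 0.001 a value-only learner whose habit
#'   prior stays effectively uniform.
#' @param s Speed-accuracy trade-off of the stopping rule (see
#'   [sampler_config()]).
#' @param epsilon Context cue uncertainty in `[0, 1)`; ignored by tasks
#'   without cues (grid world).
#' @param gamma Assumed context change probability in `[0, 1]`.
#' @param forgetting Forgetting factor `f` of the habit prior in `[0, 1]`.
#' @param t_sample,t_nd,max_samples Reaction-time mapping and chain cap,
#'   see [sampler_config()].
#' @param preference Outcome preference (reward, no reward); full support.
#' @param contingency_init Initial Dirichlet pseudo count per
#'   (state, outcome) of the learnable reward contingencies. The mean is
#'   uniform regardless; smaller values make the first observations move
#'   the contingency estimate faster (a vaguer uninformed prior).
#' @param preference_mode `"terminal"` (default): the outcome preference
#'   scores the episode-final predicted outcome; `"per_step"`: every step
#'   of the belief trajectory is scored.
#' @param mixture_mode How context-specific beliefs enter the sampler:
#'   `"product"` (default) feeds the context-mixed prior as proposal and
#'   the context-mixed likelihood into the acceptance ratio;
#'   `"posterior"` targets the mixture of per-context posteriors instead.
#' @param no_bias Disable the a priori context-response bias (the habit
#'   prior is kept effectively uniform).
#' @param no_habit_update Freeze the habit prior (no repetition learning).
#' @param no_context_inference Replace context inference by a fixed
#'   uniform context belief.
#' @return A `bcc_agent_config`.
#' @export
agent_config <- function(a = 1.0, s = 0.5, epsilon = 0.1, gamma = 0.1,
                         forgetting = 0, t_sample = 0.2, t_nd = 100,
                         max_samples = 200000L,
                         preference = c(0.99, 0.01),
                         contingency_init = 1,
                         preference_mode = c("terminal", "per_step"),
                         mixture_mode = c("product", "posterior"),
                         no_bias = FALSE, no_habit_update = FALSE,
                         no_context_inference = FALSE) {
  stopifnot(a > 0, s > 0, epsilon >= 0, epsilon < 1,
            gamma >= 0, gamma <= 1, forgetting >= 0, forgetting <= 1,
            t_sample >= 0, t_nd >= 0, max_samples >= 1,
            length(preference) == 2L, all(preference > 0),
            abs(sum(preference) - 1) < 1e-8, contingency_init > 0)
  structure(list(a = a, s = s, epsilon = epsilon, gamma = gamma,
                 forgetting = forgetting, t_sample = t_sample,
                 t_nd = t_nd, max_samples = as.integer(max_samples),
                 preference = preference,
                 contingency_init = contingency_init,
                 preference_mode = match.arg(preference_mode),
                 mixture_mode = match.arg(mixture_mode),
                 no_bias = isTRUE(no_bias),
                 no_habit_update = isTRUE(no_habit_update),
                 no_context_inference = isTRUE(no_context_inference)),
            class = "bcc_agent_config")
}

#' @export
print.bcc_agent_config <- function(x, ...) {
  cat("<bcc_agent_config> a =", x$a, "| s =", x$s, "| epsilon =",
      x$epsilon, "| gamma =", x$gamma, "| f =", x$forgetting, "\n")
  abl <- c("no_bias", "no_habit_update", "no_context_inference")
  on <- abl[vapply(x[abl], isTRUE, logical(1))]
  if (length(on)) cat("  ablations:", paste(on, collapse = ", "), "\n")
  invisible(x)
}

# Deterministic per-agent RNG substream seed below 2^31, so adding agents
# never perturbs earlier agents' draws.
agent_seed <- function(master_seed, agent_index) {
  as.integer((as.numeric(master_seed) %% 2147483647 * 48271 +
                agent_index * 16807) %% 2147483629 + 1)
}

# Sampler prior/likelihood pair for the configured mixture mode.
# In "posterior" mode the chain still proposes from the mixed prior but
# targets the mixture of per-context posteriors, via the ratio
# target / proposal in the acceptance likelihood.
mix_for_sampler <- function(prior_rows, lik_rows, weights, mixture_mode) {
  prior_mix <- mix_over_contexts(prior_rows, weights)
  if (mixture_mode == "product") {
    list(prior = prior_mix, likelihood = mix_over_contexts(lik_rows, weights))
  } else {
    if (is.list(prior_rows)) prior_rows <- do.call(rbind, prior_rows)
    if (is.list(lik_rows)) lik_rows <- do.call(rbind, lik_rows)
    post <- prior_rows * lik_rows
    post <- post / rowSums(post)
    post_mix <- mix_over_contexts(post, weights)
    lik <- ifelse(prior_mix > 0, post_mix / pmax(prior_mix, 1e-300), 0)
    list(prior = prior_mix, likelihood = lik)
  }
}

# Column template shared by all task runners.
empty_records <- function(n) {
  data.frame(task = character(n), agent = integer(n),
             miniblock = integer(n), trial = integer(n),
             true_context = integer(n), cue = integer(n),
             congruent = logical(n), trials_since_switch = integer(n),
             training_length = integer(n),
             action = integer(n), reward = integer(n),
             correct = logical(n), n_samples = integer(n),
             rt_ms = numeric(n), capped = logical(n),
             prev_congruent = logical(n),
             a = numeric(n), s = numeric(n), epsilon = numeric(n),
             gamma = numeric(n), forgetting = numeric(n),
             stringsAsFactors = FALSE)
}
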