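#' Canonical prior/likelihood demonstration settings
#'
#' The four input configurations used to characterize the reaction-time
#' engine on the 81-policy grid-world space: a pronounced distribution
#' concentrates `high_mass` on `n_high` policies (the six goal-leading
#' policies, in the grid world) and spreads the rest uniformly.
#'
#' * `"prior_only"` -- pronounced prior, uniform likelihood (fully
#'   automatic behavior);
#' * `"likelihood_only"` -- uniform prior, pronounced likelihood (fully
#'   goal-directed, what a value-only learner converges to);
#' * `"agreement"` -- prior and likelihood pronounced on the same
#'   policies (the automatism+value learner in a stable context);
#' * `"conflict"` -- likelihood pronounced on one policy set, prior on a
#'   disjoint set (the post-switch regime).
#'
#' The sharpness of each setting mirrors the agent state it stands for:
#' the moderately learned prior/likelihood share 0.5 of their mass over
#' the six favored policies, the well-automatized agreement setting 0.7,
#' and the conflict likelihood has three levels -- high on the six
#' currently rewarded policies, very low on the six prior-favored ones
#' (their outcome is known to be unrewarded after a goal switch), and a
#' moderately uncertain tail over the remaining, less-explored policies.
#'
#' @param setting Which configuration to build.
#' @param n_policies Size of the policy space.
#' @param n_high Number of favored policies.
#' @return A list with `prior`, `likelihood`, and the exact normalized
#'   `posterior` (prior x likelihood renormalized).
#' @export
demo_distributions <- function(setting = c("prior_only", "likelihood_only",
                                           "agreement", "conflict"),
                               n_policies = 81L, n_high = 6L) {
  setting <- match.arg(setting)
  stopifnot(n_policies >= 2L, n_high >= 1L, 2L * n_high <= n_policies)
  shaped <- function(idx, mass) {
    v <- rep((1 - mass) / (n_policies - length(idx)), n_policies)
    v[idx] <- mass / length(idx)
    v
  }
  flat <- rep(1 / n_policies, n_policies)
  first <- seq_len(n_high)
  second <- n_high + seq_len(n_high)
  conflict_lik <- function() {
    hi <- 0.07; lo <- 0.0005
    v <- rep((1 - n_high * (hi + lo)) / (n_policies - 2L * n_high),
             n_policies)
    v[first] <- hi
    v[second] <- lo
    v
  }
  pl <- switch(setting,
    prior_only = list(prior = shaped(first, 0.5), likelihood = flat),
    likelihood_only = list(prior = flat, likelihood = shaped(first, 0.5)),
    agreement = list(prior = shaped(first, 0.7),
                     likelihood = shaped(first, 0.7)),
    conflict = list(prior = shaped(second, 0.6),
                    likelihood = conflict_lik()))
  post <- pl$prior * pl$likelihood
  pl$posterior <- post / sum(post)
  pl
}
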