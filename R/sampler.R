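#' Sampler configuration
#'
#' Bundles the free parameters of the reaction-time engine: the
#' speed-accuracy trade-off `s`, the linear mapping from sample counts to
#' milliseconds, and the hard cap on chain length.
#'
#' @param s Speed-accuracy trade-off, `s > 0`. Scales how far below its
#'   initial value the Dirichlet entropy of the online posterior estimate
#'   must fall before sampling stops: the threshold is
#'   `H_init + (H_init - 1) * s`.
#' @param t_sample Milliseconds per sample (default 0.2 ms).
#' @param t_nd Non-decision time in milliseconds (default 100 ms).
#' @param max_samples Hard cap on the number of sampling steps; runs that
#'   hit it are flagged `capped`, never silently truncated.
#' @param record_trace If `TRUE`, [run_sampler()] returns a per-step trace
#'   (proposal, acceptance ratio, chain entry, entropy).
#' @return An object of class `bcc_sampler_config`.
#' @seealso [run_sampler()], [samples_to_rt()]
#' @export
sampler_config <- function(s, t_sample = 0.2, t_nd = 100,
                           max_samples = 200000L, record_trace = FALSE) {
  stopifnot(is.numeric(s), length(s) == 1L, s > 0,
            t_sample >= 0, t_nd >= 0, max_samples >= 1)
  structure(list(s = s, t_sample = t_sample, t_nd = t_nd,
                 max_samples = as.integer(max_samples),
                 record_trace = isTRUE(record_trace)),
            class = "bcc_sampler_config")
}

#' @export
print.bcc_sampler_config <- function(x, ...) {
  cat("<bcc_sampler_config> s =", x$s, "| t_sample =", x$t_sample,
      "ms | t_nd =", x$t_nd, "ms | max_samples =", x$max_samples, "\n")
  invisible(x)
}

#' Differential entropy of a Dirichlet distribution
#'
#' Closed form `ln B(eta) + (eta0 - K) psi(eta0) - sum_j (eta_j - 1) psi(eta_j)`
#' with `eta0 = sum(eta)`. May be negative (differential entropy).
#'
#' @param eta Positive concentration parameters.
#' @return The differential entropy (scalar).
#' @export
dirichlet_entropy <- function(eta) {
  if (length(eta) < 1L || any(!is.finite(eta)) || any(eta <= 0))
    stop("`eta` must be a vector of positive finite values")
  eta0 <- sum(eta)
  K <- length(eta)
  lnB <- sum(lgamma(eta)) - lgamma(eta0)
  lnB + (eta0 - K) * digamma(eta0) - sum((eta - 1) * digamma(eta))
}

#' Entropy stopping threshold
#'
#' The sampler stops once the Dirichlet entropy of its online posterior
#' estimate falls to `h_init + (h_init - 1) * s`. The `- s` part keeps the
#' threshold strictly below `h_init` even when the initial entropy is 0
#' (two options with flat pseudo counts).
#'
#' @param h_init Entropy of the flat initial Dirichlet.
#' @param s Speed-accuracy trade-off, `s > 0`.
#' @return The threshold value.
#' @export
entropy_threshold <- function(h_init, s) {
  stopifnot(is.numeric(h_init), is.numeric(s), s > 0)
  h_init + (h_init - 1) * s
}

#' Initial state of the sampling chain
#'
#' @param n_policies Number of policies the chain ranges over.
#' @return A `bcc_sampler_state`: step counter `n`, current chain entry,
#'   pseudo counts `eta` (all ones), their entropy, and the acceptance
#'   ratio of the last step.
#' @export
new_sampler_state <- function(n_policies) {
  stopifnot(n_policies >= 1)
  h <- -lgamma(n_policies)
  structure(list(n = 0L, chain = NA_integer_,
                 eta = rep(1, n_policies),
                 entropy = h, h_init = h, rho = NA_real_),
            class = "bcc_sampler_state")
}

#' One Metropolis-Hastings step
#'
#' Proposes a policy from the prior, accepts it with probability
#' `min(L(proposal) / L(previous), 1)` (the first proposal is accepted
#' unconditionally; a zero-likelihood previous sample is always left), and
#' increments the Dirichlet pseudo count of the resulting chain entry --
#' whether or not the proposal was accepted.
#'
#' Uses R's global RNG; seed with [set.seed()] for reproducibility.
#'
#' @param prior Normalized proposal distribution over policies.
#' @param likelihood Non-negative likelihood values, same length.
#' @param state A `bcc_sampler_state`.
#' @return The updated state. `q_estimate(state)` gives the current online
#'   posterior estimate `eta / (K + n)`.
#' @export
mh_step <- function(prior, likelihood, state) {
  K <- length(prior)
  stopifnot(inherits(state, "bcc_sampler_state"),
            length(likelihood) == K, length(state$eta) == K,
            all(prior >= 0), all(likelihood >= 0))
  tot <- sum(prior)
  if (tot <= 0) stop("prior has zero mass everywhere")
  cum <- cumsum(prior / tot)
  cum[K] <- 1
  u <- stats::runif(1)
  prop <- sum(u > cum) + 1L
  if (state$n == 0L) {
    state$chain <- prop
    state$rho <- 1
  } else {
    lprev <- likelihood[state$chain]
    rho <- if (lprev <= 0) 1 else min(likelihood[prop] / lprev, 1)
    if (stats::runif(1) < rho) state$chain <- prop
    state$rho <- rho
  }
  state$eta[state$chain] <- state$eta[state$chain] + 1
  state$n <- state$n + 1L
  state$entropy <- dirichlet_entropy(state$eta)
  state
}

#' Online posterior estimate from a sampler state
#'
#' @param state A `bcc_sampler_state`.
#' @return `eta / (K + n)`, a probability vector.
#' @export
q_estimate <- function(state) {
  state$eta / (length(state$eta) + state$n)
}

#' Run the reaction-time sampler
#'
#' Iterates Metropolis-Hastings steps (see [mh_step()]) until the entropy
#' of the online Dirichlet posterior estimate falls below
#' `entropy_threshold(h_init, s)` or `max_samples` is reached. The last
#' chain entry is the policy that gets executed; the number of steps maps
#' to milliseconds via [samples_to_rt()].
#'
#' @param prior Proposal distribution over policies (normalized internally).
#' @param likelihood Non-negative likelihood vector, same length.
#' @param config A [sampler_config()].
#' @param engine `"cpp"` (default, compiled hot loop) or `"r"` (pure-R
#'   reference implementation; identical draws and results for a given
#'   seed state).
#' @return A `bcc_sampler_result`: `chosen_policy`, `n_samples`, `rt_ms`,
#'   `capped`, the chain-entry histogram `counts` (the online pseudo counts
#'   minus one), `h_init`, `h_thr`, final `entropy`, and (if requested) a
#'   per-step `trace` data frame.
#' @export
run_sampler <- function(prior, likelihood, config, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "bcc_sampler_config"))
  K <- length(prior)
  if (K < 1L) stop("empty prior")
  if (length(likelihood) != K) stop("prior and likelihood lengths differ")
  if (engine == "cpp") {
    res <- .cpp_run_sampler(as.numeric(prior), as.numeric(likelihood),
                            config$s, config$max_samples,
                            config$record_trace)
  } else {
    res <- run_sampler_r(prior, likelihood, config)
  }
  out <- list(chosen_policy = as.integer(res$chosen),
              n_samples = as.integer(res$n_samples),
              rt_ms = samples_to_rt(res$n_samples, config),
              capped = isTRUE(res$capped),
              counts = as.numeric(res$counts),
              h_init = res$h_init, h_thr = res$h_thr,
              entropy = res$entropy)
  if (!is.null(res$trace)) out$trace <- as.data.frame(res$trace)
  class(out) <- "bcc_sampler_result"
  out
}

# Pure-R reference loop; same uniform-draw discipline as the C++ engine.
run_sampler_r <- function(prior, likelihood, config) {
  K <- length(prior)
  h_init <- -lgamma(K)
  h_thr <- entropy_threshold(h_init, config$s)
  if (K == 1L)
    return(list(chosen = 1L, n_samples = 1L, capped = FALSE,
                h_init = h_init, h_thr = h_thr, entropy = h_thr,
                counts = 1, trace = NULL))
  state <- new_sampler_state(K)
  trace <- if (config$record_trace) vector("list", 64L) else NULL
  repeat {
    prev_chain <- state$chain
    state <- mh_step(prior, likelihood, state)
    if (config$record_trace) {
      if (state$n > length(trace)) trace <- c(trace, vector("list", length(trace)))
      trace[[state$n]] <- c(step = state$n, proposal = NA, rho = state$rho,
                            accepted = as.numeric(!identical(prev_chain, state$chain) ||
                                                    state$rho >= 1),
                            chain = state$chain, entropy = state$entropy)
    }
    if (state$entropy <= h_thr || state$n >= config$max_samples) break
  }
  tr <- NULL
  if (config$record_trace) {
    tr <- do.call(rbind, trace[seq_len(state$n)])
  }
  list(chosen = state$chain, n_samples = state$n,
       capped = state$entropy > h_thr,
       h_init = h_init, h_thr = h_thr, entropy = state$entropy,
       counts = state$eta - 1, trace = tr)
}

#' @export
print.bcc_sampler_result <- function(x, ...) {
  cat("<bcc_sampler_result> policy", x$chosen_policy, "after",
      x$n_samples, "samples (", round(x$rt_ms, 1), "ms )",
      if (x$capped) "[capped]" else "", "\n")
  invisible(x)
}

#' Convert a sample count to a reaction time
#'
#' `RT = t_nd + t_sample * n_samples`.
#'
#' @param n_samples Non-negative number of sampling steps.
#' @param config A [sampler_config()].
#' @return Reaction time in milliseconds.
#' @export
samples_to_rt <- function(n_samples, config) {
  stopifnot(all(n_samples >= 0))
  config$t_nd + config$t_sample * n_samples
}

#' Kullback-Leibler divergence of a sample histogram from a reference
#'
#' `sum h * log(h / ref)` over the support of `h`. Returns `Inf` when the
#' reference has zero mass where the histogram is positive.
#'
#' @param sample_histogram Probability vector (e.g. normalized chain-entry
#'   counts).
#' @param reference Probability vector of the same length.
#' @return Non-negative divergence in nats (possibly `Inf`).
#' @export
chain_dkl <- function(sample_histogram, reference) {
  stopifnot(length(sample_histogram) == length(reference))
  h <- sample_histogram / sum(sample_histogram)
  idx <- h > 0
  if (any(reference[idx] <= 0)) return(Inf)
  sum(h[idx] * log(h[idx] / (reference[idx] / sum(reference))))
}

#' Per-step posterior estimates from a sampler trace
#'
#' Reconstructs the online estimate `q(pi | eta_n) = eta_n / (K + n)` for
#' every step of a recorded trace, for trajectory plots.
#'
#' @param trace The `trace` data frame of a [run_sampler()] result.
#' @param n_policies Number of policies the chain ranged over.
#' @return A matrix with one row per step and one column per policy.
#' @export
trace_q_estimate <- function(trace, n_policies) {
  stopifnot(is.data.frame(trace), n_policies >= 1)
  n <- nrow(trace)
  counts <- matrix(0, n, n_policies)
  eta <- rep(1, n_policies)
  for (i in seq_len(n)) {
    j <- trace$chain[i]
    eta[j] <- eta[j] + 1
    counts[i, ] <- eta / (n_policies + i)
  }
  counts
}
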