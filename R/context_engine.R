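#' Cue observation model
#'
#' Maps cue identities to contexts with perceptual uncertainty `epsilon`:
#' a cue supports its own context with probability `1 - epsilon` and
#' spreads `epsilon` evenly over the remaining contexts.
#'
#' @param n_contexts Number of contexts (>= 2 for `epsilon` to matter).
#' @param cue_to_context Integer vector mapping each cue identity (its
#'   position) to a context index.
#' @param epsilon Cue uncertainty in `[0, 1)`. In task switching this is
#'   the proxy for the cue-target interval: shorter intervals mean noisier
#'   cue perception, i.e. larger `epsilon`.
#' @return A `bcc_cue_model`.
#' @export
cue_model <- function(n_contexts, cue_to_context, epsilon) {
  stopifnot(n_contexts >= 1, epsilon >= 0, epsilon < 1,
            all(cue_to_context >= 1), all(cue_to_context <= n_contexts))
  structure(list(n_contexts = as.integer(n_contexts),
                 cue_to_context = as.integer(cue_to_context),
                 epsilon = epsilon),
            class = "bcc_cue_model")
}

#' Likelihood of contexts given a cue
#'
#' @param cue Cue identity (index into the model's `cue_to_context` map).
#' @param model A [cue_model()].
#' @return Probability vector over contexts: `1 - epsilon` at the cued
#'   context, `epsilon / (n_contexts - 1)` elsewhere.
#' @export
cue_likelihood <- function(cue, model) {
  stopifnot(inherits(model, "bcc_cue_model"))
  if (length(cue) != 1L || cue < 1 || cue > length(model$cue_to_context))
    stop("unknown cue")
  n <- model$n_contexts
  if (n == 1L) return(1)
  out <- rep(model$epsilon / (n - 1), n)
  out[model$cue_to_context[cue]] <- 1 - model$epsilon
  out
}

#' Propagate context beliefs across an episode boundary
#'
#' Applies the context transition matrix parameterized by the change
#' probability `gamma`: stay with `1 - gamma`, move to each other context
#' with `gamma / (n_contexts - 1)`. In task switching `gamma` is the proxy
#' for the response-stimulus interval: longer intervals mean the agent
#' expects a change more.
#'
#' @param probabilities Normalized belief over contexts.
#' @param gamma Change probability in `[0, 1]`.
#' @return The predicted (prior-to-evidence) belief for the next episode.
#' @export
context_predict <- function(probabilities, gamma) {
  stopifnot(gamma >= 0, gamma <= 1,
            abs(sum(probabilities) - 1) < 1e-8)
  n <- length(probabilities)
  if (n == 1L) return(probabilities)
  out <- (1 - gamma) * probabilities +
    gamma / (n - 1) * (sum(probabilities) - probabilities)
  out / sum(out)
}

#' Posterior over contexts
#'
#' Normalized elementwise product of the predicted belief and any number
#' of evidence vectors (cue likelihood, episode outcome likelihood, ...).
#'
#' @param predicted Predicted belief over contexts.
#' @param evidences List of non-negative vectors of the same length; may
#'   be empty, in which case the prediction is returned unchanged.
#' @return Normalized posterior over contexts.
#' @export
context_posterior <- function(predicted, evidences = list()) {
  out <- predicted
  for (ev in evidences) {
    if (length(ev) != length(out)) stop("evidence length mismatch")
    out <- out * ev
  }
  tot <- sum(out)
  if (tot <= 0)
    stop("impossible observation: all-zero context posterior")
  out / tot
}

#' Mix per-context vectors by context weights
#'
#' Convex combination `sum_c weights[c] * vectors[[c]]`; if the inputs are
#' normalized distributions so is the output.
#'
#' @param per_context_vectors List of equal-length vectors, one per
#'   context, or a matrix with one row per context.
#' @param weights Normalized context weights.
#' @return The mixed vector.
#' @export
mix_over_contexts <- function(per_context_vectors, weights) {
  if (is.list(per_context_vectors))
    per_context_vectors <- do.call(rbind, per_context_vectors)
  if (nrow(per_context_vectors) != length(weights))
    stop("one vector per context weight required")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must be normalized")
  as.numeric(crossprod(per_context_vectors, weights))
}
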