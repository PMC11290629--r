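# Shared fixtures and a cache for the expensive closed-loop simulations,
# so several acceptance checks can reuse one grid-world run.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache))
    assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

gridworld_runs <- function(n_agents = 50L, master_seed = 101L) {
  cached(paste0("grid_", n_agents, "_", master_seed), {
    list(
      auto = run_gridworld_experiment(
        gridworld_spec(),
        agent_config(a = 1.0, s = 0.5, gamma = 0.01,
                     preference = c(0.995, 0.005)),
        n_agents = n_agents, master_seed = master_seed),
      value = run_gridworld_experiment(
        gridworld_spec(),
        agent_config(a = 0.001, s = 0.5, gamma = 0.01,
                     preference = c(0.995, 0.005)),
        n_agents = n_agents, master_seed = master_seed))
  })
}

flanker_config <- function(...) {
  agent_config(a = 1, s = 2.5, epsilon = 0.05, gamma = 0.5,
               forgetting = 0.05, ...)
}

taskswitch_config <- function(...) {
  agent_config(a = 0.001, s = 2.5, epsilon = 0.05, gamma = 0.1,
               contingency_init = 3, ...)
}

# Stopping-step oracle for a chain that deterministically increments one
# pseudo count: iterate the closed-form Dirichlet entropy directly.
brute_force_point_mass_n <- function(K, s, max_n = 100000L) {
  eta <- rep(1, K)
  h_thr <- entropy_threshold(-lgamma(K), s)
  for (n in seq_len(max_n)) {
    eta[1L] <- eta[1L] + 1
    if (dirichlet_entropy(eta) <= h_thr) return(n)
  }
  stop("oracle did not terminate")
}
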