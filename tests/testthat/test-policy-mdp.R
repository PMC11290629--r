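test_that("policy enumeration is lexicographic and complete", {
  ps <- enumerate_policies(3, 4)
  expect_equal(nrow(ps$policies), 81L)
  expect_equal(ps$policies[1L, ], rep(0L, 4L))
  expect_equal(ps$policies[81L, ], rep(2L, 4L))
  # lexicographic order: rows sorted as base-3 numbers
  codes <- ps$policies %*% c(27L, 9L, 3L, 1L)
  expect_equal(as.integer(codes), 0:80)

  expect_equal(nrow(enumerate_policies(2, 1)$policies), 2L)
  deg <- enumerate_policies(1, 7)
  expect_equal(nrow(deg$policies), 1L)
  expect_equal(deg$policies[1L, ], rep(0L, 7L))

  expect_error(enumerate_policies(0, 3), "positive")
  expect_error(enumerate_policies(2, 0), "positive")
})

test_that("state propagation follows the kernels and stays normalized", {
  # deterministic cycle on 3 states plus an identity action
  shift <- matrix(0, 3, 3); shift[cbind(c(2, 3, 1), 1:3)] <- 1
  ident <- diag(3)
  mdp <- context_mdp(list(shift, ident))

  d <- propagate_states(mdp, 1L, c(0L, 0L, 0L))
  expect_equal(d[1L, ], c(1, 0, 0))
  expect_equal(d[2L, ], c(0, 1, 0))
  expect_equal(d[4L, ], c(1, 0, 0))

  d <- propagate_states(mdp, 2L, c(1L, 1L))
  expect_true(all(apply(d, 1, function(x) x[2L] == 1)))

  unif <- matrix(1 / 3, 3, 3)
  mdp2 <- context_mdp(list(unif))
  d <- propagate_states(mdp2, 3L, 0L)
  expect_equal(d[2L, ], rep(1 / 3, 3))
  expect_equal(rowSums(d), rep(1, 2), tolerance = 1e-10)

  expect_error(propagate_states(mdp, 9L, 0L), "start state")
  expect_error(propagate_states(mdp, 1L, 5L), "action")
})

test_that("predicted free energy matches analytic KL values", {
  ident <- diag(2)
  # outcome distribution equal to the preference at the scored step -> 0
  mdp <- context_mdp(list(ident),
                     contingency_counts = matrix(c(1, 1, 1, 1), 2, 2),
                     preference = c(0.5, 0.5))
  expect_equal(predicted_free_energy(mdp, propagate_states(mdp, 1L, 0L)), 0)

  # point outcome (1, 0) against (0.5, 0.5): ln 2
  mdp <- context_mdp(list(ident),
                     contingency_counts = matrix(c(1e9, 1e-9, 1e9, 1e-9), 2, 2),
                     preference = c(0.5, 0.5))
  expect_equal(predicted_free_energy(mdp, propagate_states(mdp, 1L, 0L)),
               log(2), tolerance = 1e-6)

  # (0.5, 0.5) against (0.95, 0.05): 0.5 ln(.5/.95) + 0.5 ln(.5/.05)
  mdp <- context_mdp(list(ident),
                     contingency_counts = matrix(1, 2, 2),
                     preference = c(0.95, 0.05))
  expect_equal(predicted_free_energy(mdp, propagate_states(mdp, 1L, 0L)),
               0.5 * log(0.5 / 0.95) + 0.5 * log(0.5 / 0.05),
               tolerance = 1e-10)
})

test_that("free energy is additive over belief-trajectory segments", {
  set.seed(42)
  n <- 4
  rand_kernel <- function() {
    m <- matrix(stats::rexp(n * n), n, n)
    sweep(m, 2, colSums(m), "/")
  }
  mdp <- context_mdp(list(rand_kernel(), rand_kernel()),
                     contingency_counts = matrix(stats::rexp(2 * n) + 0.1, 2, n),
                     preference = c(0.9, 0.1))
  for (i in 1:5) {
    pol <- sample(0:1, 6, replace = TRUE)
    d <- propagate_states(mdp, sample(n, 1), pol)
    whole <- predicted_free_energy(mdp, d)
    k <- sample(2:5, 1)
    parts <- predicted_free_energy(mdp, d[1:k, ]) +
      predicted_free_energy(mdp, d[k:nrow(d), ])
    expect_equal(whole, parts, tolerance = 1e-10)
  }
})

test_that("policy likelihood is a shift-invariant softmax", {
  expect_equal(policy_likelihood(c(1, 1, 1)), rep(1 / 3, 3))
  expect_equal(policy_likelihood(c(0, log(2))), c(2 / 3, 1 / 3),
               tolerance = 1e-12)
  F <- c(0.3, 1.7, 0.2, 5)
  expect_equal(policy_likelihood(F), policy_likelihood(F + 5))
  expect_equal(sum(policy_likelihood(F)), 1, tolerance = 1e-12)
  expect_error(policy_likelihood(numeric(0)), "empty")
  expect_error(policy_likelihood(c(1, Inf)), "finite")
})

test_that("contingency updates add posterior-weighted counts", {
  mdp <- context_mdp(list(diag(20)), matrix(1, 2, 20))
  up <- update_contingencies(mdp, list(c(15L, 1L)), 1)
  expect_equal(up$contingency_counts[1L, 15L], 2)
  expect_equal(sum(up$contingency_counts), sum(mdp$contingency_counts) + 1)

  expect_equal(update_contingencies(mdp, list(c(3L, 2L)), 0)$contingency_counts,
               mdp$contingency_counts)

  half_twice <- update_contingencies(
    update_contingencies(mdp, list(c(15L, 1L)), 0.5), list(c(15L, 1L)), 0.5)
  expect_equal(half_twice$contingency_counts[1L, 15L], 2)

  expect_error(update_contingencies(mdp, list(c(40L, 1L)), 1), "invalid")
})

test_that("repeated observation drives the mean contingency to certainty", {
  mdp <- context_mdp(list(diag(3)), matrix(1, 2, 3))
  m_prev <- mean_contingency(mdp)[1L, 2L]
  for (i in 1:200) {
    mdp <- update_contingencies(mdp, list(c(2L, 1L)), 1)
    m <- mean_contingency(mdp)[1L, 2L]
    expect_gt(m, m_prev)
    m_prev <- m
  }
  expect_gt(m_prev, 0.99)
})
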