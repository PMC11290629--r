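test_that("Dirichlet entropy matches analytic values", {
  expect_equal(dirichlet_entropy(c(1, 1)), 0)
  expect_equal(dirichlet_entropy(c(1, 1, 1)), -log(2))
  expect_equal(dirichlet_entropy(c(2, 1)), -log(2) + 0.5)
  expect_error(dirichlet_entropy(c(1, 0)), "positive")
})

test_that("the stopping threshold scales the drop below the initial entropy", {
  expect_equal(entropy_threshold(0, 0.5), -0.5)
  expect_equal(entropy_threshold(-1, 1), -3)
  expect_equal(entropy_threshold(-2, 1e-9), -2, tolerance = 1e-6)
  h <- -lgamma(81)
  expect_lt(entropy_threshold(h, 0.3), h)
})

test_that("a single MH step follows the acceptance-ratio contract", {
  # uniform likelihood: every proposal accepted, counts are iid prior draws
  set.seed(1)
  st <- new_sampler_state(3)
  for (i in 1:50) {
    st <- mh_step(c(0.2, 0.5, 0.3), c(1, 1, 1), st)
    expect_equal(st$rho, 1)
  }
  expect_equal(sum(st$eta), 3 + 50)
  expect_equal(sum(q_estimate(st)), 1, tolerance = 1e-12)

  # likelihood ratio 0.2 / 0.4 gives rho = 0.5 when that move is proposed
  set.seed(7)
  st <- new_sampler_state(2)
  st <- mh_step(c(0, 1), c(0.2, 0.4), st)   # chain starts at 2
  expect_equal(st$chain, 2L)
  st <- mh_step(c(1, 0), c(0.2, 0.4), st)   # must propose 1: rho = 0.5
  expect_equal(st$rho, 0.5)

  # zero prior mass on a policy: never proposed, its count stays 1
  set.seed(2)
  st <- new_sampler_state(3)
  for (i in 1:200) st <- mh_step(c(0.5, 0.5, 0), c(0.1, 0.9, 5), st)
  expect_equal(st$eta[3L], 1)
})

test_that("R and C++ engines produce identical chains for identical seeds", {
  d <- demo_distributions("conflict", 27, 3)
  cfg <- sampler_config(s = 0.3)
  for (seed in 1:3) {
    set.seed(seed); a <- run_sampler(d$prior, d$likelihood, cfg, engine = "cpp")
    set.seed(seed); b <- run_sampler(d$prior, d$likelihood, cfg, engine = "r")
    expect_identical(a$n_samples, b$n_samples)
    expect_identical(a$chosen_policy, b$chosen_policy)
    expect_equal(a$counts, b$counts)
    expect_equal(a$entropy, b$entropy, tolerance = 1e-9)
  }
})

test_that("a deterministic chain stops exactly at the brute-force step count", {
  # point-mass prior + uniform likelihood: every step increments the same
  # pseudo count, so N_samples is seed-independent and equals the count of
  # closed-form entropy evaluations until the threshold is crossed
  for (K in c(2L, 5L, 81L)) for (s in c(0.3, 0.5)) {
    oracle <- brute_force_point_mass_n(K, s)
    prior <- c(1, rep(0, K - 1L))
    ns <- vapply(1:3, function(seed) {
      set.seed(seed)
      run_sampler(prior, rep(1, K), sampler_config(s))$n_samples
    }, integer(1))
    expect_true(all(ns == oracle))
  }
})

test_that("count conservation holds after every step", {
  d <- demo_distributions("likelihood_only", 81)
  set.seed(3)
  res <- run_sampler(d$prior, d$likelihood, sampler_config(0.3))
  expect_equal(sum(res$counts), res$n_samples)
})

test_that("pooled chain entries converge to the exact posterior", {
  # two-policy case at large s
  prior <- c(0.6, 0.4); lik <- c(0.3, 0.7)
  post <- prior * lik / sum(prior * lik)
  set.seed(11)
  counts <- c(0, 0)
  for (i in 1:40)
    counts <- counts + run_sampler(prior, lik, sampler_config(2.5))$counts
  expect_lt(chain_dkl(counts / sum(counts), post), 0.01)

  # 81-policy conflict fixture
  d <- demo_distributions("conflict", 81)
  set.seed(12)
  counts <- numeric(81)
  for (i in 1:40)
    counts <- counts + run_sampler(d$prior, d$likelihood,
                                   sampler_config(0.7))$counts
  expect_lt(chain_dkl(counts / sum(counts), d$posterior), 0.01)
})

test_that("the chain cap flags unconverged runs", {
  d <- demo_distributions("conflict", 81)
  set.seed(4)
  res <- run_sampler(d$prior, d$likelihood, sampler_config(0.5, max_samples = 10))
  expect_true(res$capped)
  expect_equal(res$n_samples, 10L)
})

test_that("sample counts convert linearly to milliseconds", {
  cfg <- sampler_config(1, t_sample = 0.2, t_nd = 100)
  expect_equal(samples_to_rt(1000, cfg), 300)
  expect_equal(samples_to_rt(0, cfg), 100)
  cfg0 <- sampler_config(1, t_sample = 0, t_nd = 100)
  expect_equal(samples_to_rt(5000, cfg0), 100)
})

test_that("chain DKL handles identity, analytic and support-violation cases", {
  expect_equal(chain_dkl(c(0.25, 0.75), c(0.25, 0.75)), 0)
  expect_equal(chain_dkl(c(1, 0), c(0.5, 0.5)), log(2))
  expect_equal(chain_dkl(c(0.5, 0.5), c(1, 0)), Inf)
})

test_that("the recorded trace reconstructs the online posterior estimate", {
  d <- demo_distributions("agreement", 27, 3)
  set.seed(5)
  res <- run_sampler(d$prior, d$likelihood,
                     sampler_config(0.3, record_trace = TRUE))
  expect_s3_class(res$trace, "data.frame")
  expect_equal(nrow(res$trace), res$n_samples)
  expect_true(all(diff(res$trace$step) == 1))
  q <- trace_q_estimate(res$trace, 27)
  expect_equal(rowSums(q), rep(1, nrow(q)), tolerance = 1e-10)
  # the last-step estimate matches the final pseudo counts
  expect_equal(q[nrow(q), ], (res$counts + 1) / (27 + res$n_samples))
  # entropy at the last step is at or below the threshold
  expect_lte(res$trace$entropy[res$n_samples], res$h_thr)
})

test_that("conflict choices follow the prior under time pressure", {
  # two-response conflict (the flanker regime): the prior favors one
  # response, the likelihood the other; under a tight deadline the
  # chain stops while still dominated by prior draws
  prior <- c(0.75, 0.25)
  lik <- c(0.18, 0.82)
  frac <- vapply(c(0.5, 2.5), function(s) {
    set.seed(31)
    ch <- vapply(1:400, function(i)
      run_sampler(prior, lik, sampler_config(s))$chosen_policy,
      integer(1))
    mean(ch == 1L)
  }, numeric(1))
  expect_gt(frac[1L], frac[2L])
  expect_gt(frac[1L], 0.2)
})
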