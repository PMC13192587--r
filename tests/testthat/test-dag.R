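test_that("acyclicity test agrees with brute-force ordering search", {
  expect_true(is_acyclic(matrix(integer(0), ncol = 2), 3))
  expect_false(is_acyclic(rbind(c(1, 2), c(2, 1)), 3))
  cases <- list(
    rbind(c(1, 2), c(2, 3), c(1, 3)),
    rbind(c(1, 2), c(2, 3), c(3, 1)),
    rbind(c(3, 1), c(3, 2)),
    rbind(c(1, 3), c(2, 3), c(3, 1)))
  for (e in cases)
    expect_identical(is_acyclic(e, 3), acyclic_by_enumeration(e, 3))
  expect_error(is_acyclic(rbind(c(1, 5)), 3), "invalid")
})

test_that("causal_dag validates its invariants", {
  expect_error(causal_dag(rbind(c(1, 1)), 3), "self-loops")
  expect_error(causal_dag(rbind(c(1, 2), c(2, 3), c(3, 1)), 3), "cycle")
  expect_error(causal_dag(rbind(c(0, 2)), 3), "indices")
  d <- causal_dag(rbind(c(2, 1), c(1, 3)), 3)
  expect_identical(d$edges[, "cause"], c(1L, 2L))  # canonical order
})

test_that("enumeration is exhaustive, duplicate-free and correctly sized", {
  expect_length(enumerate_dags(1), 1)
  d2 <- enumerate_dags(2)
  expect_length(d2, 3)
  expect_setequal(vapply(d2, format, character(1)), c("(empty)", "A>B", "B>A"))
  d3 <- enumerate_dags(3)
  expect_length(d3, 25)
  expect_true(all(vapply(d3, function(d) is_acyclic(d$edges, 3), logical(1))))
  keys <- vapply(d3, format, character(1))
  expect_identical(anyDuplicated(keys), 0L)
  expect_length(enumerate_dags(4), 543)
  expect_error(enumerate_dags(5), "1 to 4")
})

test_that("the six categories partition the 25 three-node DAGs", {
  counts <- table(vapply(enumerate_dags(3), categorize_dag, character(1)))
  expect_identical(
    as.integer(counts[c("empty", "single_edge", "fork", "collider", "chain",
                        "mediator")]),
    c(1L, 6L, 3L, 3L, 6L, 6L))
  expect_identical(sum(counts), 25L)
  expect_identical(categorize_dag(causal_dag(rbind(c(3, 1), c(3, 2)), 3)), "fork")
  expect_identical(categorize_dag(causal_dag(NULL, 3)), "empty")
  expect_identical(categorize_dag(causal_dag(rbind(c(1, 3), c(2, 3)), 3)),
                   "collider")
  expect_identical(categorize_dag(causal_dag(rbind(c(1, 2), c(2, 3)), 3)),
                   "chain")
  expect_error(categorize_dag(causal_dag(NULL, 2)), "3-node")
})

test_that("noisy-or activation probability follows the closed form", {
  p <- noisy_or_params(0.1, 0.5)
  expect_equal(activation_probability(0, p), 0.1)
  expect_equal(activation_probability(2, p), 0.775)
  ## monotone nondecreasing, bounded in [p_spont, 1)
  vals <- activation_probability(0:5, noisy_or_params(0.2, 0.7))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0.2 - 1e-12 & vals < 1))
  ## p_cause -> 0 limit: causes have no effect
  expect_equal(activation_probability(3, noisy_or_params(0.1, 1e-12)), 0.1,
               tolerance = 1e-9)
  expect_error(noisy_or_params(0, 0.5), "p_spont")
  expect_error(noisy_or_params(0.5, 1), "p_cause")
})

test_that("ancestral sampling matches closed-form frequencies", {
  p <- noisy_or_params(0.1, 0.8)
  n <- 10000
  se <- function(q) sqrt(q * (1 - q) / n)
  ## empty DAG: all nodes at p_spont
  v <- sample_observations(causal_dag(NULL, 3), n, p, seed = 11)$activity
  for (i in 1:3)
    expect_lt(abs(mean(v[i, ]) - 0.1), 3 * se(0.1))
  ## single edge A -> B: child more active than parent
  v <- sample_observations(causal_dag(rbind(c(1, 2)), 3), n, p, seed = 12)$activity
  rate_b <- 0.9 * 0.1 + 0.1 * 0.82
  expect_lt(abs(mean(v[1, ]) - 0.1), 3 * se(0.1))
  expect_lt(abs(mean(v[2, ]) - rate_b), 3 * se(rate_b))
  expect_gt(mean(v[2, ]), mean(v[1, ]))
  ## chain: P(B = 1 | A = 1) = 1 - 0.9 * 0.2 = 0.82
  v <- sample_observations(causal_dag(rbind(c(1, 2), c(2, 3)), 3), n, p,
                           seed = 13)$activity
  pba <- mean(v[2, v[1, ] == 1])
  expect_lt(abs(pba - 0.82), 3 * sqrt(0.82 * 0.18 / sum(v[1, ] == 1)))
})

test_that("sampling is reproducible and columns are independent draws", {
  dag <- causal_dag(rbind(c(1, 2), c(1, 3)), 3)
  a <- sample_observations(dag, 100, seed = 5)
  b <- sample_observations(dag, 100, seed = 5)
  expect_identical(a$activity, b$activity)
  ## a cyclic edge set cannot even be constructed
  expect_error(causal_dag(rbind(c(1, 2), c(2, 1)), 3))
})

test_that("sampler frequencies pass a goodness-of-fit screen per parent pattern", {
  p <- noisy_or_params(0.1, 0.9)
  dag <- causal_dag(rbind(c(1, 3), c(2, 3)), 3)  # collider A -> C <- B
  v <- sample_observations(dag, 10000, p, seed = 21)$activity
  a <- v[1, ] + v[2, ]
  for (k in 0:2) {
    sel <- a == k
    obs_rate <- mean(v[3, sel])
    expect_rate <- activation_probability(k, p)
    expect_lt(abs(obs_rate - expect_rate),
              3 * sqrt(expect_rate * (1 - expect_rate) / sum(sel)))
  }
})
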