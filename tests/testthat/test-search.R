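test_that("default proposal weights follow log(1 + mutation count)", {
  # symmetric counts give symmetric weights
  G <- mutation_matrix(rbind(c(1, 0), c(0, 1)))
  expect_equal(unname(as.numeric(default_gamma(G))), c(0.5, 0.5))
  # unmutated genes are never proposable
  G2 <- mutation_matrix(rbind(c(0, 1), c(0, 1), c(0, 1)))
  expect_equal(unname(as.numeric(default_gamma(G2))), c(0, 1))
  # counts (1, 3): weights log(2), log(4) -> (1/3, 2/3)
  G3 <- mutation_matrix(rbind(c(1, 1), c(0, 1), c(0, 1)))
  expect_equal(unname(as.numeric(default_gamma(G3))), c(1 / 3, 2 / 3))
  expect_error(default_gamma(mutation_matrix(matrix(0L, 2, 2))),
               "unmutated")
})

test_that("proposals always return exactly nu genes", {
  w <- rep(0.25, 4)
  set.seed(11)
  # expansion from the empty set
  for (r in 1:20) {
    prop <- propose_gene_set(integer(0), w, nu = 3)
    expect_length(prop, 3)
    expect_false(anyDuplicated(prop) > 0)
  }
  # swap case: symmetric difference with the input is exactly 2 genes
  for (r in 1:20) {
    cur <- sort(sample.int(4, 3))
    prop <- propose_gene_set(cur, w, nu = 3)
    expect_length(prop, 3)
    expect_length(union(setdiff(cur, prop), setdiff(prop, cur)), 2)
  }
  # zero-weight genes never enter
  wz <- c(0.5, 0, 0.5, 0)
  for (r in 1:20) {
    expect_true(all(propose_gene_set(integer(0), wz, nu = 2) %in% c(1, 3)))
  }
})

test_that("expansion samples genes at their proposal frequencies", {
  # uniform weights over 4 genes, current {1}, nu = 2: each of genes
  # 2..4 should complete the set a third of the time
  w <- rep(0.25, 4)
  set.seed(303)
  draws <- replicate(30000, setdiff(propose_gene_set(1L, w, nu = 2), 1L))
  freq <- tabulate(draws, 4) / length(draws)
  expect_equal(freq[2:4], rep(1 / 3, 3), tolerance = 0.02 * 3)
  expect_equal(freq[1], 0)
})

test_that("insufficient proposable genes raise an informative error", {
  w <- c(0.6, 0.4, 0, 0)
  expect_error(propose_gene_set(integer(0), w, nu = 3),
               "2 proposable genes")
  expect_error(propose_gene_set(c(1L, 2L), w, nu = 2), "no proposable")
  expect_error(propose_gene_set(1:3, w, nu = 2), "more than 'nu'")
})

test_that("local improvement prunes to the restricted optimum", {
  G <- mutation_matrix(rbind(c(1, 1), c(1, 0)))
  imp <- local_improve(c(1L, 2L), G, k = 1, C = 1)
  expect_identical(imp$genes, 1L)
  expect_equal(imp$objective, 1)
  # idempotent when the candidate is already restricted-optimal
  again <- local_improve(imp$genes, G, k = 1, C = 1)
  expect_identical(again$genes, 1L)
  expect_equal(again$objective, 1)
})

test_that("local improvement never worsens the candidate", {
  set.seed(17)
  for (r in 1:25) {
    G <- random_mutation_matrix(sample(5:15, 1), 10)
    k <- runif(1, 0.2, 3)
    C <- runif(1, 0, 2)
    cand <- sort(sample.int(10, sample(2:6, 1)))
    imp <- local_improve(cand, G, k, C)
    expect_lte(imp$objective, total_penalty(G, cand, k, C) + 1e-9)
    expect_true(all(imp$genes %in% cand))
    expect_equal(imp$objective, total_penalty(G, imp$genes, k, C),
                 tolerance = 1e-9)
  }
})

test_that("acceptance follows the Metropolis rule", {
  # improvements and ties are always accepted
  set.seed(1)
  expect_true(all(replicate(50, mh_accept(10, 9, tau = 0.5))))
  expect_true(all(replicate(50, mh_accept(10, 10, tau = 0.5))))
  # a worsening of exactly tau is accepted with frequency exp(-1)
  set.seed(2)
  acc <- mean(replicate(50000, mh_accept(0, 0.7, tau = 0.7)))
  expect_equal(acc, exp(-1), tolerance = 0.015 / exp(-1))
  # tiny tau: strict hill climbing
  set.seed(3)
  expect_false(any(replicate(50, mh_accept(0, 0.01, tau = 1e-12))))
  expect_error(mh_accept(1, 2, tau = 0), "positive")
})

test_that("a single-iteration run is the improved initial proposal", {
  set.seed(55)
  G <- random_mutation_matrix(12, 8, prob = 0.35)
  w <- default_gamma(G)
  fit <- mutex_search(G, nu = 4, iterations = 1, seed = 99)
  set.seed(99)
  prop <- propose_gene_set(integer(0), w, nu = 4)
  imp <- local_improve(prop, G, k = 1, C = 1)
  expect_identical(fit$gene_indices, imp$genes)
  expect_equal(fit$objective, imp$objective)
})

test_that("runs are reproducible and traces are coherent", {
  set.seed(4)
  G <- random_mutation_matrix(15, 10, prob = 0.3)
  a <- mutex_search(G, nu = 5, iterations = 100, seed = 7)
  b <- mutex_search(G, nu = 5, iterations = 100, seed = 7)
  expect_identical(a[setdiff(names(a), "seed")],
                   b[setdiff(names(b), "seed")])
  expect_identical(a$genes, b$genes)
  # the best objective never exceeds any accepted objective
  expect_true(all(a$trace >= a$objective - 1e-9))
  # the running best along the trace is non-increasing
  expect_true(all(diff(cummin(a$trace)) <= 0))
  # reported objective and metrics are consistent with the reported set
  expect_equal(a$objective, total_penalty(G, a$gene_indices, 1, 1),
               tolerance = 1e-9)
  expect_equal(a$metrics$coverage, coverage(G, a$gene_indices))
  # seeded runs restore the caller's RNG stream
  set.seed(123)
  before <- rnorm(3)
  set.seed(123)
  invisible(mutex_search(G, nu = 5, iterations = 20, seed = 1))
  expect_identical(rnorm(3), before)
})

test_that("search attains the enumerated optimum on a small matrix", {
  # 8 patients x 6 genes, nu = p: every proposal covers all genes, so the
  # run must return the global optimum found by full enumeration
  set.seed(6)
  G <- random_mutation_matrix(8, 6, prob = 0.4)
  truth <- enumerate_global_optimum(G, k = 1, C = 1)
  fit <- mutex_search(G, nu = 6, iterations = 5, seed = 2)
  expect_equal(fit$objective, truth$objective, tolerance = 1e-9)
  # and with a genuinely partial nu as well, given a few iterations
  fit2 <- mutex_search(G, nu = 3, iterations = 300, seed = 3)
  expect_equal(fit2$objective, truth$objective, tolerance = 1e-9)
  expect_identical(sort(fit2$gene_indices), truth$genes)
})

test_that("iterated runs return disjoint sets and pool their union", {
  # two disjoint planted exclusive sets; two rounds recover both
  sim <- simulate_mutations(n_patients = 80, n_genes = 30,
                            planted_sets = list(1:4, 5:8),
                            coverage_prob = 0.95, excess_prob = 0.05,
                            passenger_rate = 0.01, seed = 5)
  it <- mutex_iterate(sim$matrix, rounds = 2, nu = 8, iterations = 800,
                      seed = 9)
  expect_length(it$rounds, 2)
  g1 <- it$rounds[[1]]$genes
  g2 <- it$rounds[[2]]$genes
  expect_length(intersect(g1, g2), 0)
  expect_setequal(it$pooled_genes, c(g1, g2))
  found <- list(sort(g1), sort(g2))
  expect_true(setequal(found[[1]], sim$planted[[1]]) ||
                setequal(found[[1]], sim$planted[[2]]))
  expect_true(setequal(unlist(found),
                       unlist(lapply(sim$planted, sort))))
  # a single round equals a plain run with the same derived seed
  one <- mutex_iterate(sim$matrix, rounds = 1, nu = 8, iterations = 100,
                       seed = 3)
  set.seed(3)
  s1 <- sample.int(.Machine$integer.max, 1)
  direct <- mutex_search(sim$matrix, nu = 8, iterations = 100, seed = s1)
  expect_identical(one$rounds[[1]]$genes, direct$genes)
  expect_equal(one$rounds[[1]]$objective, direct$objective)
})

test_that("iterated runs stop early when the matrix is exhausted", {
  # 4 genes, nu capped by what is left; round 3+ has nothing to find
  G <- mutation_matrix(rbind(c(1, 0, 0, 0), c(0, 1, 0, 0),
                             c(0, 0, 1, 1), c(1, 0, 1, 0)))
  expect_warning(
    it <- mutex_iterate(G, rounds = 5, nu = 2, iterations = 50,
                        C = 0.1, seed = 1),
    "exhausted|consumed")
  expect_lt(length(it$rounds), 5)
  sets <- lapply(it$rounds, `[[`, "genes")
  expect_length(unlist(sets), length(unique(unlist(sets))))
})
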