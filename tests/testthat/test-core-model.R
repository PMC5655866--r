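test_that("mutation_matrix enforces its invariants", {
  expect_error(mutation_matrix(matrix(c(0, 2), 1, 2)), "0 or 1")
  expect_error(mutation_matrix(matrix(c(0, NA), 1, 2)), "missing")
  expect_error(mutation_matrix(matrix(0L, 1, 2), genes = c("A", "A")),
               "unique")
  expect_error(mutation_matrix(matrix(0L, 2, 1),
                               patients = c("P", "P")), "unique")
  G <- mutation_matrix(matrix(c(TRUE, FALSE), 1, 2))
  expect_identical(as.vector(unclass(G)), c(1L, 0L))
  expect_equal(n_patients(G), 1L)
  expect_equal(n_genes(G), 2L)
})

test_that("gene sets are accepted as indicators, indices and symbols", {
  G <- mutation_matrix(matrix(0L, 2, 3), genes = c("TP53", "KRAS", "EGFR"))
  expect_identical(gene_indicator(G, c(0, 1, 1)), c(0L, 1L, 1L))
  expect_identical(gene_indicator(G, c(2L, 3L)), c(0L, 1L, 1L))
  expect_identical(gene_indicator(G, c("KRAS", "EGFR")), c(0L, 1L, 1L))
  expect_identical(gene_indicator(G, integer(0)), c(0L, 0L, 0L))
  expect_error(gene_indicator(G, "BRAF"), "unknown gene")
  expect_error(gene_indicator(G, 5L), "out of range")
})

test_that("per-patient penalty matches its closed form", {
  # one mutation is never penalized; zero mutations always cost 1
  for (k in c(0, 0.25, 0.5, 1, 2, 4)) {
    expect_equal(per_patient_penalty(1, k), 0)
    expect_equal(per_patient_penalty(0, k), 1)
  }
  # the ratio penalty(2)/penalty(0) is exactly k
  for (k in c(0.25, 0.5, 1, 2, 4)) {
    expect_equal(per_patient_penalty(2, k), k)
  }
  # direct evaluation at m = 3, k = 2: (3/2) * 2 * (3 - 2/3) = 7 = 3k + 1
  expect_equal(per_patient_penalty(3, 2), 7)
  # with k = 1 the penalty is the integer square (m - 1)^2 exactly
  expect_identical(per_patient_penalty(0:10, 1), as.numeric((0:10 - 1)^2))
  expect_error(per_patient_penalty(-1, 1), "non-negative")
  expect_error(per_patient_penalty(2, -0.5), "non-negative")
  expect_error(per_patient_penalty(2.5, 1), "integer")
})

test_that("penalty is nonnegative, zero only at m = 1, increasing beyond", {
  for (k in c(0.1, 0.5, 1, 3, 7.5)) {
    pen <- per_patient_penalty(0:12, k)
    expect_true(all(pen >= 0))
    expect_identical(which(pen == 0), 2L)  # m = 1
    expect_true(all(diff(pen[-(1:2)]) > 0))
  }
})

test_that("total penalty matches hand-computed values", {
  G <- tiny_matrix()
  # empty set: every patient uncovered
  expect_equal(total_penalty(G, c(0, 0), k = 3, C = 2), 2)
  # {G1}: both patients covered exactly once, one gene
  expect_equal(total_penalty(G, c(1, 0), k = 1, C = 1), 1)
  # {G1, G2}: patient 2 double-covered (penalty k = 1), two genes
  expect_equal(total_penalty(G, c(1, 1), k = 1, C = 1), 3)
  expect_error(total_penalty(G, c(1, 0, 0)), "out of range|indicator")
})

test_that("BQP coefficients match the hand-derived instance", {
  inst <- bqp_coefficients(tiny_matrix(), k = 1, C = 1)
  expect_equal(unname(inst$Q), rbind(c(2, 1), c(1, 1)))
  expect_equal(unname(inst$f), c(3, 1))
  expect_equal(inst$offset, 2)
  # all-zero matrix: zero Gram matrix, f = -C
  z <- bqp_coefficients(mutation_matrix(matrix(0L, 3, 2),
                                        patients = paste0("P", 1:3)),
                        k = 2, C = 0.7)
  expect_equal(unname(z$Q), matrix(0, 2, 2))
  expect_equal(unname(z$f), c(-0.7, -0.7))
  expect_equal(z$offset, 3)
  expect_error(bqp_coefficients(tiny_matrix(), genes = c(1L, 3L)),
               "out of range")
  expect_error(bqp_coefficients(tiny_matrix(), genes = c(1L, 1L)),
               "unique")
})

test_that("quadratic form reproduces the penalty for every subset", {
  # exhaustive check on a random 10 x 6 matrix, all 64 indicators
  set.seed(421)
  G <- random_mutation_matrix(10, 6)
  k <- 1.7
  C <- 0.9
  inst <- bqp_coefficients(G, k = k, C = C)
  for (v in 0:63) {
    x <- as.integer(intToBits(v)[1:6])
    expect_equal(bqp_objective(inst, x), total_penalty(G, x, k, C),
                 tolerance = 1e-12)
  }
})

test_that("restricted instances agree with the embedded full problem", {
  set.seed(77)
  G <- random_mutation_matrix(12, 8)
  sub <- c(2L, 5L, 7L)
  inst <- bqp_coefficients(G, k = 0.5, C = 1.2, genes = sub)
  for (v in 0:7) {
    xs <- as.integer(intToBits(v)[1:3])
    full <- integer(8)
    full[sub] <- xs
    expect_equal(bqp_objective(inst, xs),
                 total_penalty(G, full, 0.5, 1.2), tolerance = 1e-12)
  }
})

test_that("Q is positive semidefinite for binary matrices", {
  set.seed(5)
  for (r in 1:20) {
    G <- random_mutation_matrix(sample(2:10, 1), sample(2:8, 1))
    k <- runif(1, 0, 5)
    ev <- eigen(bqp_coefficients(G, k = k)$Q, symmetric = TRUE,
                only.values = TRUE)$values
    expect_true(all(ev > -1e-9))
  }
})

test_that("coverage, excess coverage and Dendrix score match hand counts", {
  I3 <- mutation_matrix(diag(3))
  expect_equal(coverage(I3, c(1, 1, 1)), 1)
  expect_equal(excess_coverage(I3, c(1, 1, 1)), 0)
  expect_equal(dendrix_score(I3, c(1, 1, 1)), 3)

  G <- mutation_matrix(rbind(c(1, 0), c(0, 0), c(1, 1)))
  expect_equal(coverage(G, c(1, 1)), 2 / 3)
  expect_equal(coverage(G, c(0, 0)), 0)

  G2 <- mutation_matrix(rbind(c(1, 1), c(1, 0)))
  expect_equal(excess_coverage(G2, c(1, 1)), 1 / 2)

  G3 <- mutation_matrix(rbind(c(1, 1), c(1, 0), c(0, 0)))
  expect_equal(dendrix_score(G3, c(1, 1)), 1)
  expect_equal(dendrix_score(G3, c(0, 0)), 0)

  # degenerate excess coverage: defined as 0, with a warning
  expect_warning(ec <- excess_coverage(G, c(0, 0)), "no patient")
  expect_equal(ec, 0)

  m <- set_metrics(G3, c(1, 1))
  expect_equal(m$coverage, 2 / 3)
  expect_equal(m$excess_coverage, 1 / 2)
  expect_equal(m$dendrix_score, 1)
})

test_that("metrics stay within their ranges on random inputs", {
  set.seed(99)
  for (r in 1:25) {
    G <- random_mutation_matrix(sample(2:15, 1), sample(2:10, 1))
    x <- rbinom(n_genes(G), 1, 0.5)
    m <- suppressWarnings(set_metrics(G, x))
    expect_gte(m$coverage, 0)
    expect_lte(m$coverage, 1)
    expect_gte(m$excess_coverage, 0)
    expect_lte(m$excess_coverage, 1)
    expect_lte(m$dendrix_score, n_patients(G))
  }
})
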