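# small deterministic fixtures shared across test files

# 2 patients x 2 genes: patient 1 mutated in gene 1, patient 2 in both
tiny_matrix <- function() {
  mutation_matrix(rbind(c(1L, 0L), c(1L, 1L)),
                  patients = c("P1", "P2"), genes = c("G1", "G2"))
}

random_mutation_matrix <- function(n, p, prob = 0.3) {
  mutation_matrix(matrix(rbinom(n * p, 1, prob), n, p))
}

# random symmetric instance; about half the draws have negative Q entries
random_bqp_instance <- function(m, psd = FALSE) {
  A <- matrix(rnorm(m * m), m, m)
  Q <- if (psd) crossprod(A) / m else (A + t(A)) / 2
  bqp_instance(Q, f = rnorm(m, sd = 2), offset = rnorm(1))
}

# margin-preserving null matrix: each gene's mutation count is fixed,
# mutated patients drawn uniformly and independently per gene
null_matrix <- function(counts, n) {
  M <- vapply(counts, function(cnt) {
    v <- integer(n)
    v[sample.int(n, cnt)] <- 1L
    v
  }, integer(n))
  mutation_matrix(M)
}

# exhaustive minimum of the total penalty over all gene subsets (p <= 20)
enumerate_global_optimum <- function(G, k = 1, C = 1) {
  sol <- solve_bqp_enumerate(bqp_coefficients(G, k = k, C = C))
  list(genes = which(sol$indicator == 1L), objective = sol$objective)
}
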