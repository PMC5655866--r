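#' Column-permutation null model
#'
#' Independently permutes the entries of each gene column of the mutation
#' matrix.  Every gene keeps exactly its observed number of mutated
#' patients, but any co-occurrence or exclusivity pattern across genes
#' within a patient is destroyed — the standard null model for mutual
#' exclusivity testing.
#'
#' @param G a `mutation_matrix`.
#' @return a `mutation_matrix` of the same dimensions, dimnames and
#'   column sums.
#' @export
permute_columns <- function(G) {
  G <- as_mutation_matrix(G)
  M <- mm_values(G)
  n <- nrow(M)
  for (j in seq_len(ncol(M))) {
    M[, j] <- M[sample.int(n), j]
  }
  mutation_matrix(M, patients = rownames(G), genes = colnames(G))
}

#' Permutation significance test for a discovered gene set
#'
#' Runs the search on the observed matrix, then on `n_perm`
#' column-permuted copies with identical search settings, and compares
#' the observed best penalty against the null distribution of best
#' penalties.  The p-value uses the add-one estimator
#' `(1 + #\{null <= observed\}) / (1 + n_perm)` ("<=" because a lower
#' penalty is better), which is never exactly zero.
#'
#' Each null run receives its own deterministic sub-seed derived from
#' `seed`, so the test is reproducible and the null runs get the same
#' optimization effort as the observed run.
#'
#' @inheritParams mutex_search
#' @param n_perm number of permuted datasets (the add-one estimator
#'   bounds the p-value below by `1 / (n_perm + 1)`).
#' @return object of class `"mutex_permtest"`: the observed
#'   `"mutex_result"` (with `p_value` attached), `observed_objective`,
#'   `null_objectives` (length `n_perm`), `p_value`, and `n_perm`.
#' @export
permutation_test <- function(G, n_perm = 1000L, k = 1, C = 1, nu = 30,
                             iterations = 10000L, tau = 1, gamma = NULL,
                             seed = NULL) {
  G <- as_mutation_matrix(G)
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L) {
    stop("'n_perm' must be a positive integer", call. = FALSE)
  }
  if (!is.null(seed)) {
    old_seed <- get_rng_state()
    on.exit(restore_rng_state(old_seed), add = TRUE)
    set.seed(seed)
  }
  sub_seeds <- sample.int(.Machine$integer.max, n_perm + 1L)

  observed <- mutex_search(G, k = k, C = C, nu = nu,
                           iterations = iterations, tau = tau,
                           gamma = gamma, seed = sub_seeds[1L],
                           keep_trace = FALSE)
  null_obj <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    set.seed(sub_seeds[b + 1L])
    Gb <- permute_columns(G)
    res <- mutex_search(Gb, k = k, C = C, nu = nu,
                        iterations = iterations, tau = tau,
                        gamma = gamma, keep_trace = FALSE)
    null_obj[b] <- res$objective
  }
  p <- (1 + sum(null_obj <= observed$objective)) / (1 + n_perm)
  observed$p_value <- p
  structure(list(observed = observed,
                 observed_objective = observed$objective,
                 null_objectives = null_obj,
                 p_value = p,
                 n_perm = n_perm,
                 seed = seed),
            class = "mutex_permtest")
}

#' @export
print.mutex_permtest <- function(x, ...) {
  cat(sprintf(
    "permutation test: observed penalty %.4g vs %d column-permuted nulls\n",
    x$observed_objective, x$n_perm))
  cat(sprintf("  null penalty range [%.4g, %.4g], p-value %.4g\n",
              min(x$null_objectives), max(x$null_objectives), x$p_value))
  invisible(x)
}
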