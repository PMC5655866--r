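#' Simulate a mutation matrix with planted mutually exclusive driver sets
#'
#' Emulates the driver/passenger structure the search is designed to
#' detect: for each patient and each planted set, with probability
#' `coverage_prob` one member gene (chosen uniformly) is mutated, and with
#' probability `excess_prob` a second, distinct member is additionally
#' mutated (a mutator-phenotype knob; at most one extra hit per set per
#' patient).  Every cell outside the planted-set columns is mutated
#' independently with probability `passenger_rate`.  The defaults give a
#' small fixture — 60 patients, 40 genes, one planted 5-gene set with
#' near-complete coverage, little excess and a sparse passenger
#' background — whose planted set is (with high probability) the global
#' penalty optimum, small enough for exhaustive verification.
#'
#' @param n_patients,n_genes matrix dimensions.
#' @param planted_sets list of pairwise disjoint integer vectors of gene
#'   indices (each within `1..n_genes`).
#' @param coverage_prob per-patient probability of a driver mutation in
#'   each planted set (recycled over sets).
#' @param excess_prob probability that a covered patient gets a second
#'   mutation within the same set (recycled over sets).
#' @param passenger_rate background mutation probability per
#'   non-planted cell.
#' @param seed optional integer seed; RNG state is restored on exit.
#' @return list of class `"mutex_sim"`: `matrix` (a `mutation_matrix`),
#'   `planted` (list of gene-symbol vectors), `planted_indices`, and the
#'   generating parameters.
#' @examples
#' sim <- simulate_mutations(seed = 1)
#' coverage(sim$matrix, sim$planted_indices[[1]])
#' @export
simulate_mutations <- function(n_patients = 60, n_genes = 40,
                               planted_sets = list(1:5),
                               coverage_prob = 0.95, excess_prob = 0.05,
                               passenger_rate = 0.02, seed = NULL) {
  n_patients <- as.integer(n_patients)
  n_genes <- as.integer(n_genes)
  if (is.na(n_patients) || n_patients < 1L ||
      is.na(n_genes) || n_genes < 1L) {
    stop("'n_patients' and 'n_genes' must be positive integers",
         call. = FALSE)
  }
  if (!is.list(planted_sets)) {
    planted_sets <- list(planted_sets)
  }
  planted_sets <- lapply(planted_sets, as.integer)
  all_planted <- unlist(planted_sets)
  if (length(all_planted)) {
    if (min(all_planted) < 1L || max(all_planted) > n_genes) {
      stop("planted gene indices must lie in 1..n_genes", call. = FALSE)
    }
    if (anyDuplicated(all_planted)) {
      stop("planted sets must be pairwise disjoint", call. = FALSE)
    }
  }
  n_sets <- length(planted_sets)
  coverage_prob <- rep_len(as.numeric(coverage_prob), n_sets)
  excess_prob <- rep_len(as.numeric(excess_prob), n_sets)
  probs <- c(coverage_prob, excess_prob, passenger_rate)
  if (anyNA(probs) || any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(lengths(planted_sets) < 1L)) {
    stop("each planted set needs at least one gene", call. = FALSE)
  }
  if (any(excess_prob > 0 & lengths(planted_sets) < 2L)) {
    stop("excess mutations need planted sets of at least two genes",
         call. = FALSE)
  }
  if (!is.null(seed)) {
    old_seed <- get_rng_state()
    on.exit(restore_rng_state(old_seed), add = TRUE)
    set.seed(seed)
  }

  M <- matrix(0L, n_patients, n_genes)
  for (s in seq_len(n_sets)) {
    members <- planted_sets[[s]]
    sz <- length(members)
    for (i in seq_len(n_patients)) {
      if (stats::runif(1) < coverage_prob[s]) {
        first <- members[sample.int(sz, 1L)]
        M[i, first] <- 1L
        if (stats::runif(1) < excess_prob[s]) {
          others <- members[members != first]
          second <- others[sample.int(length(others), 1L)]
          M[i, second] <- 1L
        }
      }
    }
  }
  background <- setdiff(seq_len(n_genes), all_planted)
  if (length(background) && passenger_rate > 0) {
    B <- matrix(stats::runif(n_patients * length(background)) <
                  passenger_rate,
                n_patients, length(background))
    M[, background] <- M[, background] | B
    storage.mode(M) <- "integer"
  }
  G <- mutation_matrix(M)
  structure(list(
    matrix = G,
    planted = lapply(planted_sets, function(ix) colnames(G)[ix]),
    planted_indices = planted_sets,
    params = list(n_patients = n_patients, n_genes = n_genes,
                  coverage_prob = coverage_prob, excess_prob = excess_prob,
                  passenger_rate = passenger_rate, seed = seed)
  ), class = "mutex_sim")
}

#' @export
print.mutex_sim <- function(x, ...) {
  cat(sprintf(
    "simulated cohort: %d patients x %d genes, %d planted set(s)\n",
    nrow(x$matrix), ncol(x$matrix), length(x$planted)))
  for (s in seq_along(x$planted)) {
    cat(sprintf("  set %d: %s\n", s, paste(x$planted[[s]], collapse = ", ")))
  }
  invisible(x)
}
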