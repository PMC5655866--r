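#' Default proposal distribution over genes
#'
#' Genes are proposed into candidate solutions with probability
#' proportional to `log(1 + c_j)`, where `c_j` is the number of patients
#' mutated in gene `j`.  The logarithm damps the dominance of very
#' frequently mutated genes while keeping genes mutated in a single
#' patient proposable; genes never mutated get weight zero and are never
#' proposed.
#'
#' @param G a `mutation_matrix`.
#' @return numeric weight vector over the genes of `G`, summing to 1, of
#'   class `"gene_proposal"`.
#' @export
default_gamma <- function(G) {
  G <- as_mutation_matrix(G)
  counts <- colSums(mm_values(G))
  if (all(counts == 0)) {
    stop("all genes are unmutated; no gene can be proposed", call. = FALSE)
  }
  w <- log1p(counts)
  w <- w / sum(w)
  names(w) <- colnames(G)
  class(w) <- "gene_proposal"
  w
}

#' Validate / normalize a user-supplied proposal distribution
#'
#' @param G a `mutation_matrix`.
#' @param gamma `NULL` (use [default_gamma()]) or a non-negative weight
#'   vector of length `n_genes(G)`.
#' @return normalized weight vector.
#' @keywords internal
resolve_gamma <- function(G, gamma = NULL) {
  if (is.null(gamma)) {
    return(default_gamma(G))
  }
  w <- as.numeric(gamma)
  if (length(w) != ncol(G)) {
    stop("'gamma' must have one weight per gene", call. = FALSE)
  }
  if (anyNA(w) || any(w < 0)) {
    stop("'gamma' weights must be non-negative", call. = FALSE)
  }
  if (sum(w) <= 0) {
    stop("'gamma' must put positive weight on at least one gene",
         call. = FALSE)
  }
  w <- w / sum(w)
  names(w) <- colnames(G)
  class(w) <- "gene_proposal"
  w
}

#' Propose a new candidate gene set
#'
#' The proposal always returns a set of exactly `nu` genes.  If the
#' current solution already holds `nu` genes, one of them is removed
#' uniformly at random and one gene outside the current solution is drawn
#' from the proposal distribution renormalized over genes not in the
#' solution; the removed gene cannot re-enter in the same move, so the
#' symmetric difference between input and output is exactly two genes.  If
#' the current solution holds fewer than `nu` genes, it is expanded by
#' sampling the missing genes without replacement (sequential
#' draw-and-renormalize) from the same excluded-renormalized
#' distribution.
#'
#' @param current integer vector of gene indices in the current solution
#'   (possibly empty); at most `nu` genes.
#' @param gamma proposal weights from [default_gamma()] or
#'   [resolve_gamma()].
#' @param nu target solution size (integer, at least 2).
#' @return integer vector of `nu` gene indices (sorted).
#' @export
propose_gene_set <- function(current, gamma, nu) {
  w <- as.numeric(gamma)
  current <- as.integer(current)
  if (length(current) > nu) {
    stop("current solution has more than 'nu' genes", call. = FALSE)
  }
  if (length(current) && (min(current) < 1L || max(current) > length(w))) {
    stop("current gene index out of range", call. = FALSE)
  }
  propose_impl(current, w, as.integer(nu))
}

# unchecked fast path shared with mutex_search()
propose_impl <- function(current, w, nu) {
  p <- length(w)
  if (length(current) == nu) {
    drop_pos <- sample.int(nu, 1L)
    kept <- current[-drop_pos]
    wx <- w
    wx[current] <- 0              # the removed gene cannot re-enter
    if (sum(wx > 0) < 1L) {
      stop("no proposable gene outside the current solution ",
           "(need 1 more gene with positive proposal weight)",
           call. = FALSE)
    }
    added <- sample.int(p, 1L, prob = wx)
    return(sort(c(kept, added)))
  }
  need <- nu - length(current)
  wx <- w
  wx[current] <- 0
  avail <- sum(wx > 0)
  if (avail < need) {
    stop("only ", avail, " proposable genes outside the current solution, ",
         "but ", need, " more are needed to reach nu = ", nu, call. = FALSE)
  }
  added <- sample.int(p, need, replace = FALSE, prob = wx)
  sort(c(current, added))
}

#' Exact local improvement of a candidate gene set
#'
#' Restricts the penalty to the genes of the candidate, solves the
#' resulting binary quadratic subproblem to global optimality with
#' [solve_bqp_exact()], and embeds the optimum back into the full gene
#' space (all other genes zero).  The returned objective can never exceed
#' the candidate's own penalty, since the candidate is itself a feasible
#' point of the subproblem.
#'
#' @param candidate integer vector of gene indices (at most the solver
#'   capacity, see [solve_bqp_exact()]).
#' @inheritParams total_penalty
#' @return list with `genes` (integer indices of the improved set, a
#'   subset of `candidate`) and `objective` (its total penalty).
#' @export
local_improve <- function(candidate, G, k = 1, C = 1) {
  G <- as_mutation_matrix(G)
  check_penalty_params(k, C)
  candidate <- as.integer(candidate)
  if (length(candidate) &&
      (min(candidate) < 1L || max(candidate) > ncol(G))) {
    stop("candidate gene index out of range", call. = FALSE)
  }
  inst <- bqp_coefficients(G, k = k, C = C, genes = candidate)
  sol <- solve_bqp_exact(inst)
  list(genes = candidate[sol$indicator == 1L], objective = sol$objective)
}

#' Metropolis acceptance rule
#'
#' A proposed solution is always accepted when its objective does not
#' exceed the current one; a worse solution is accepted with probability
#' `exp(-(new - old) / tau)`.  As `tau` tends to zero the rule reduces to
#' strict hill climbing.
#'
#' @param old_objective,new_objective penalties of current and proposed
#'   solutions.
#' @param tau positive acceptance temperature.
#' @return logical.
#' @export
mh_accept <- function(old_objective, new_objective, tau = 1) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0) {
    stop("'tau' must be a single positive number", call. = FALSE)
  }
  if (new_objective <= old_objective) {
    return(TRUE)
  }
  stats::runif(1L) < exp(-(new_objective - old_objective) / tau)
}

# candidate strictly better, or tied with fewer genes / lexicographically
# smaller index set (deterministic best-tracking, mirrors the BQP solver)
better_solution <- function(obj, genes, best_obj, best_genes, tol = 1e-9) {
  if (obj < best_obj - tol) return(TRUE)
  if (obj > best_obj + tol) return(FALSE)
  if (length(genes) != length(best_genes)) {
    return(length(genes) < length(best_genes))
  }
  d <- which(genes != best_genes)
  if (length(d) == 0L) return(FALSE)
  genes[d[1L]] < best_genes[d[1L]]
}

#' Search for a minimum-penalty driver gene set
#'
#' The main optimization loop.  Starting from the empty set, each of the
#' `iterations` steps (i) proposes a candidate of exactly `nu` genes by
#' stochastic expansion/swap ([propose_gene_set()]), (ii) prunes it to the
#' exact optimum of the penalty restricted to those genes
#' ([local_improve()]), and (iii) accepts or rejects the pruned candidate
#' by the Metropolis rule ([mh_accept()]).  The best (lowest-penalty)
#' solution evaluated at any point is tracked and returned; ties are
#' broken toward fewer genes for reproducibility.
#'
#' @param G a `mutation_matrix`.
#' @param k two-mutation / no-mutation penalty ratio (default 1).
#' @param C per-gene solution-size penalty (default 1).
#' @param nu maximum genes per candidate subproblem (default 30).
#' @param iterations number of search iterations `T` (default 10000).
#' @param tau Metropolis acceptance temperature (default 1).
#' @param gamma optional proposal weights; defaults to [default_gamma()].
#' @param seed optional integer seed; when given, the run is fully
#'   reproducible and the R random number generator state is restored on
#'   exit.
#' @param keep_trace record the accepted objective at every iteration.
#' @return object of class `"mutex_result"`: list with `genes` (symbols of
#'   the best set), `gene_indices`, `indicator`, `objective`, `metrics`
#'   (coverage, excess coverage, Dendrix score), `gene_counts` (patients
#'   mutated per selected gene), parameter settings, `seed`, and `trace`.
#' @examples
#' sim <- simulate_mutations(n_patients = 40, n_genes = 20,
#'                           planted_sets = list(1:4), seed = 7)
#' fit <- mutex_search(sim$matrix, nu = 8, iterations = 300, seed = 1)
#' fit
#' @export
mutex_search <- function(G, k = 1, C = 1, nu = 30, iterations = 10000L,
                         tau = 1, gamma = NULL, seed = NULL,
                         keep_trace = TRUE) {
  G <- as_mutation_matrix(G)
  check_penalty_params(k, C, nu)
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L) {
    stop("'iterations' must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0) {
    stop("'tau' must be a single positive number", call. = FALSE)
  }
  nu <- as.integer(nu)
  n <- nrow(G)
  p <- ncol(G)
  if (nu > p) {
    stop("'nu' must not exceed the number of genes (", p, ")",
         call. = FALSE)
  }
  w <- resolve_gamma(G, gamma)
  if (sum(w > 0) < nu) {
    stop("only ", sum(w > 0), " genes have positive proposal weight; ",
         "need at least nu = ", nu, call. = FALSE)
  }
  if (!is.null(seed)) {
    old_seed <- get_rng_state()
    on.exit(restore_rng_state(old_seed), add = TRUE)
    set.seed(seed)
  }

  M <- mm_values(G)
  wv <- as.numeric(w)
  q_scale <- (k + 1) / 2
  f_scale <- (k + 3) / 2

  current <- integer(0)
  cur_obj <- n                     # empty set: every patient uncovered
  best_genes <- NULL
  best_obj <- Inf
  trace <- if (keep_trace) numeric(iterations) else NULL

  for (t in seq_len(iterations)) {
    cand <- propose_impl(current, wv, nu)
    Gs <- M[, cand, drop = FALSE]
    Q <- q_scale * crossprod(Gs)
    f <- f_scale * .colSums(Gs, n, nu) - C
    sol <- bqp_solve_bb(Q, f, n, 1e-9)
    genes <- cand[sol$indicator == 1L]
    obj <- sol$objective

    if (is.null(best_genes) ||
        better_solution(obj, genes, best_obj, best_genes)) {
      best_genes <- genes
      best_obj <- obj
    }
    if (obj <= cur_obj || stats::runif(1L) < exp(-(obj - cur_obj) / tau)) {
      current <- genes
      cur_obj <- obj
    }
    if (keep_trace) trace[t] <- cur_obj
  }

  build_result(G, best_genes, best_obj, k = k, C = C, nu = nu,
               iterations = iterations, tau = tau, seed = seed,
               trace = trace)
}

build_result <- function(G, gene_idx, objective, k, C, nu, iterations,
                         tau, seed, trace = NULL) {
  M <- mm_values(G)
  ind <- integer(ncol(G))
  ind[gene_idx] <- 1L
  metrics <- set_metrics(G, ind)
  counts <- colSums(M[, gene_idx, drop = FALSE])
  structure(list(
    genes = colnames(G)[gene_idx],
    gene_indices = gene_idx,
    indicator = ind,
    objective = objective,
    metrics = metrics,
    gene_counts = stats::setNames(as.integer(counts),
                                  colnames(G)[gene_idx]),
    params = list(k = k, C = C, nu = nu, iterations = iterations,
                  tau = tau),
    seed = seed,
    n_patients = nrow(G),
    n_genes = ncol(G),
    trace = trace
  ), class = "mutex_result")
}

#' @export
print.mutex_result <- function(x, ...) {
  cat(sprintf("driver gene set: %d genes, penalty %.4g\n",
              length(x$genes), x$objective))
  cat(sprintf("  coverage %.4f | excess coverage %.4f | Dendrix score %d\n",
              x$metrics$coverage, x$metrics$excess_coverage,
              as.integer(x$metrics$dendrix_score)))
  if (length(x$genes)) {
    cat("  genes: ",
        paste0(x$genes, " (", x$gene_counts, ")", collapse = ", "),
        "\n", sep = "")
  }
  if (!is.null(x$p_value)) {
    cat(sprintf("  permutation p-value: %.4g\n", x$p_value))
  }
  invisible(x)
}

#' Iterated discovery of multiple driver gene sets
#'
#' A single search run returns one set of (putatively functionally
#' related) mutually exclusive genes.  To uncover several such sets —
#' e.g. one per disrupted pathway — the search is applied repeatedly,
#' each round removing the genes found in previous rounds from the
#' working matrix so they cannot mask further sets.
#'
#' @inheritParams mutex_search
#' @param rounds number of successive runs.
#' @param ... further arguments passed to [mutex_search()]
#'   (`k`, `C`, `nu`, `iterations`, `tau`, `gamma`, `keep_trace`).
#' @return object of class `"mutex_iterate"`: list with `rounds` (one
#'   `"mutex_result"` per completed round, gene identities referring to
#'   the original matrix) and `pooled_genes` (union of the per-round
#'   sets, pairwise disjoint by construction).
#' @export
mutex_iterate <- function(G, rounds = 4, seed = NULL, ...) {
  G <- as_mutation_matrix(G)
  rounds <- as.integer(rounds)
  if (is.na(rounds) || rounds < 1L) {
    stop("'rounds' must be a positive integer", call. = FALSE)
  }
  if (!is.null(seed)) {
    old_seed <- get_rng_state()
    on.exit(restore_rng_state(old_seed), add = TRUE)
    set.seed(seed)
    round_seeds <- sample.int(.Machine$integer.max, rounds)
  } else {
    round_seeds <- rep(list(NULL), rounds)
  }
  dots <- list(...)
  nu <- if (!is.null(dots$nu)) as.integer(dots$nu) else 30L

  keep <- seq_len(ncol(G))          # original column indices still in play
  work <- G
  results <- vector("list", rounds)
  done <- 0L
  for (r in seq_len(rounds)) {
    counts <- colSums(mm_values(work))
    # nu can never exceed the proposable genes left on the board
    nu_eff <- min(nu, sum(counts > 0), ncol(work))
    if (nu_eff < 2L) {
      warning("matrix exhausted of mutated genes after ", done,
              " round(s); stopping early", call. = FALSE)
      break
    }
    args <- c(list(G = work, seed = round_seeds[[r]]), dots)
    args$nu <- nu_eff
    res <- do.call(mutex_search, args)
    # re-express indices in the original matrix
    res$gene_indices <- keep[res$gene_indices]
    ind <- integer(ncol(G))
    ind[res$gene_indices] <- 1L
    res$indicator <- ind
    results[[r]] <- res
    done <- r
    found_local <- match(res$genes, colnames(work))
    if (length(found_local)) {
      keep <- keep[-found_local]
      if (length(keep) == 0L) {
        if (r < rounds) {
          warning("all genes consumed after ", r,
                  " round(s); stopping early", call. = FALSE)
        }
        break
      }
      work <- mutation_matrix(mm_values(work)[, -found_local, drop = FALSE],
                              patients = rownames(work),
                              genes = colnames(work)[-found_local])
    }
  }
  results <- results[seq_len(done)]
  structure(list(rounds = results,
                 pooled_genes = unlist(lapply(results, `[[`, "genes"))),
            class = "mutex_iterate")
}

#' @export
print.mutex_iterate <- function(x, ...) {
  cat(sprintf("iterated search: %d round(s), %d genes pooled\n",
              length(x$rounds), length(x$pooled_genes)))
  for (r in seq_along(x$rounds)) {
    res <- x$rounds[[r]]
    cat(sprintf("  round %d: %d genes, penalty %.4g, coverage %.4f\n",
                r, length(res$genes), res$objective,
                res$metrics$coverage))
  }
  invisible(x)
}

# save/restore .Random.seed so seeded runs do not disturb the caller's RNG
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
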