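#' Quadratic per-patient exclusivity penalty
#'
#' The penalty contributed by a single patient carrying `m` mutations in the
#' genes of a candidate driver set:
#' \deqn{L(m) = \frac{1+k}{2}\,(m - 1)\left(m - \frac{2}{1+k}\right).}
#' A patient with exactly one mutation in the set contributes nothing; an
#' uncovered patient contributes 1; a patient with two mutations contributes
#' `k`.  The ratio `k` of the two-mutation penalty to the no-mutation
#' penalty is the tunable coverage vs. exclusivity trade-off: low `k`
#' tolerates multiple hits (mutator-phenotype tumors), high `k` demands
#' strict mutual exclusivity.  With `k = 1` the penalty is exactly
#' `(m - 1)^2`.
#'
#' @param m non-negative integer vector: number of mutations a patient has
#'   in the genes of the candidate set.
#' @param k non-negative scalar: two-mutation / no-mutation penalty ratio.
#' @return numeric vector of penalties, same length as `m`.
#' @examples
#' per_patient_penalty(0:4, k = 1)  # (m - 1)^2
#' per_patient_penalty(2, k = 0.5)  # equals k
#' @export
per_patient_penalty <- function(m, k = 1) {
  if (!is.numeric(m) || anyNA(m) || any(m < 0) || any(m != round(m))) {
    stop("'m' must be a non-negative integer count", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0) {
    stop("'k' must be a single non-negative number", call. = FALSE)
  }
  (1 + k) / 2 * (m - 1) * (m - 2 / (1 + k))
}

#' Total penalty of a candidate gene set
#'
#' Sum of per-patient penalties plus the solution-size penalty
#' `C * ||x||_0`: the objective minimized by [mutex_search()].
#'
#' @param G a `mutation_matrix` (or coercible binary matrix).
#' @param x gene set: 0/1 indicator, gene indices, or gene symbols
#'   (see [gene_indicator()]).
#' @param k two-mutation / no-mutation penalty ratio (non-negative).
#' @param C penalty per gene included in the solution (non-negative).
#' @return scalar penalty; the empty set scores `n_patients(G)`.
#' @examples
#' G <- mutation_matrix(rbind(c(1, 0), c(1, 1)))
#' total_penalty(G, c(1, 0))     # 1: both patients covered once, one gene
#' total_penalty(G, c(1, 1))     # 3: one double-covered patient, two genes
#' @export
total_penalty <- function(G, x, k = 1, C = 1) {
  G <- as_mutation_matrix(G)
  ind <- gene_indicator(G, x)
  check_penalty_params(k, C)
  m <- as.vector(mm_values(G) %*% ind)
  sum(per_patient_penalty(m, k)) + C * sum(ind)
}

check_penalty_params <- function(k, C, nu = NULL) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0) {
    stop("'k' must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(C) || length(C) != 1L || is.na(C) || C < 0) {
    stop("'C' must be a single non-negative number", call. = FALSE)
  }
  if (!is.null(nu)) {
    if (!is.numeric(nu) || length(nu) != 1L || is.na(nu) ||
        nu != round(nu) || nu < 2) {
      stop("'nu' must be a single integer >= 2", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Binary quadratic program coefficients of the penalty
#'
#' Rewrites the total penalty as an unconstrained binary quadratic program
#' over the gene indicator `x`:
#' \deqn{L(G, x) = x^T Q x - f^T x + n,\qquad
#'   Q = \frac{k+1}{2} G^T G,\quad
#'   f = \frac{k+3}{2} G^T \mathbf{1}_n - C \mathbf{1}_p.}
#' The constant offset `n` (number of patients) is carried explicitly so
#' that solver objectives equal the total penalty, not a shifted value.
#' Restricting to a gene subset gives the subproblem solved exactly during
#' local improvement.
#'
#' @inheritParams total_penalty
#' @param genes optional gene subset (indices or symbols); default all genes.
#' @return a `bqp_instance`: list with `Q` (symmetric PSD matrix), `f`
#'   (linear coefficients), `offset` (`n_patients(G)`), and `genes`
#'   (column indices of `G` the variables refer to).
#' @examples
#' G <- mutation_matrix(rbind(c(1, 0), c(1, 1)))
#' bqp_coefficients(G, k = 1, C = 1)
#' @export
bqp_coefficients <- function(G, k = 1, C = 1, genes = NULL) {
  G <- as_mutation_matrix(G)
  check_penalty_params(k, C)
  p <- ncol(G)
  if (is.null(genes)) {
    idx <- seq_len(p)
  } else if (is.character(genes)) {
    idx <- match(genes, colnames(G))
    if (anyNA(idx)) {
      stop("unknown gene symbol(s): ",
           paste(genes[is.na(idx)], collapse = ", "), call. = FALSE)
    }
  } else {
    idx <- as.integer(genes)
    if (length(idx) && (min(idx) < 1L || max(idx) > p)) {
      stop("gene subset index out of range 1..", p, call. = FALSE)
    }
  }
  if (anyDuplicated(idx)) {
    stop("gene subset indices must be unique", call. = FALSE)
  }
  Gs <- mm_values(G)[, idx, drop = FALSE]
  Q <- (k + 1) / 2 * crossprod(Gs)
  f <- (k + 3) / 2 * colSums(Gs) - C
  bqp_instance(Q, f, offset = nrow(G), genes = idx,
               gene_names = colnames(G)[idx])
}

#' Construct a binary quadratic program instance
#'
#' Container for the restricted minimization
#' `min_x x^T Q x - f^T x + offset` over binary `x`; produced by
#' [bqp_coefficients()] and consumed by [solve_bqp_exact()] /
#' [solve_bqp_enumerate()].
#'
#' @param Q symmetric numeric matrix.
#' @param f numeric vector, `length(f) == nrow(Q)`.
#' @param offset scalar added to every objective value.
#' @param genes optional integer indices the variables refer to.
#' @param gene_names optional symbols for reporting.
#' @return a list of class `"bqp_instance"`.
#' @export
bqp_instance <- function(Q, f, offset = 0, genes = NULL, gene_names = NULL) {
  Q <- as.matrix(Q)
  storage.mode(Q) <- "double"
  f <- as.numeric(f)
  if (nrow(Q) != ncol(Q)) {
    stop("'Q' must be square", call. = FALSE)
  }
  if (length(f) != nrow(Q)) {
    stop("'f' must have length nrow(Q)", call. = FALSE)
  }
  if (nrow(Q) > 0 && max(abs(Q - t(Q))) > 1e-9) {
    stop("'Q' must be symmetric", call. = FALSE)
  }
  structure(list(Q = Q, f = f, offset = as.numeric(offset),
                 genes = genes, gene_names = gene_names),
            class = "bqp_instance")
}

#' @export
print.bqp_instance <- function(x, ...) {
  cat(sprintf("binary quadratic program: %d variables, offset %g\n",
              length(x$f), x$offset))
  invisible(x)
}

#' Evaluate a binary quadratic program instance at a binary vector
#'
#' @param instance a `bqp_instance`.
#' @param x 0/1 vector over the instance variables.
#' @return `x' Q x - f' x + offset`.
#' @export
bqp_objective <- function(instance, x) {
  x <- as.numeric(x)
  if (length(x) != length(instance$f)) {
    stop("'x' must have length ", length(instance$f), call. = FALSE)
  }
  as.numeric(crossprod(x, instance$Q %*% x) - sum(instance$f * x) +
               instance$offset)
}

#' Coverage of a gene set
#'
#' Fraction of patients with at least one mutation in the genes of the set.
#'
#' @inheritParams total_penalty
#' @return scalar in `[0, 1]`.
#' @export
coverage <- function(G, x) {
  G <- as_mutation_matrix(G)
  m <- as.vector(mm_values(G) %*% gene_indicator(G, x))
  mean(m >= 1)
}

#' Excess coverage of a gene set
#'
#' Among patients covered by the set, the fraction carrying more than one
#' mutation in it — the departure from perfect mutual exclusivity.  When no
#' patient is covered the ratio is undefined; by convention 0 is returned
#' with a warning so that metric tables stay total.
#'
#' @inheritParams total_penalty
#' @return scalar in `[0, 1]`.
#' @export
excess_coverage <- function(G, x) {
  G <- as_mutation_matrix(G)
  m <- as.vector(mm_values(G) %*% gene_indicator(G, x))
  covered <- sum(m >= 1)
  if (covered == 0) {
    warning("no patient is covered by the gene set; excess coverage ",
            "reported as 0", call. = FALSE)
    return(0)
  }
  sum(m > 1) / covered
}

#' Dendrix score of a gene set
#'
#' The coverage-minus-overlap score maximized by the Dendrix family of
#' tools: `n - sum_i |G_i x - 1|`, i.e. the number of covered patients
#' minus the total count of mutations in excess of one per patient.  Used
#' here as an external quality metric, not as the optimization objective.
#'
#' @inheritParams total_penalty
#' @return integer-valued scalar, at most `n_patients(G)`.
#' @export
dendrix_score <- function(G, x) {
  G <- as_mutation_matrix(G)
  m <- as.vector(mm_values(G) %*% gene_indicator(G, x))
  nrow(G) - sum(abs(m - 1))
}

#' All evaluation metrics of a gene set
#'
#' @inheritParams total_penalty
#' @return named list: `coverage`, `excess_coverage`, `dendrix_score`.
#' @export
set_metrics <- function(G, x) {
  G <- as_mutation_matrix(G)
  m <- as.vector(mm_values(G) %*% gene_indicator(G, x))
  covered <- sum(m >= 1)
  excess <- if (covered == 0) 0 else sum(m > 1) / covered
  list(coverage = covered / nrow(G),
       excess_coverage = excess,
       dendrix_score = nrow(G) - sum(abs(m - 1)))
}
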