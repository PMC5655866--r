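#' Solve a small binary quadratic program exactly
#'
#' Global minimizer of `x' Q x - f' x + offset` over binary vectors `x`,
#' obtained by depth-first branch and bound with variables ordered by
#' decreasing `|f|` and a lower bound that clamps each remaining term of
#' the quadratic at its coordinate-wise minimum.  The problem is NP-hard
#' in general, but the restricted instances produced during local
#' improvement have at most `nu` variables and solve in well under a
#' second for `nu` up to 50.
#'
#' Ties between equal-objective optima (within `tol`) are broken toward
#' fewer selected variables, then toward the lexicographically smallest
#' indicator, so repeated calls are deterministic.
#'
#' @param instance a [bqp_instance()].
#' @param max_vars hard capacity cap on the number of variables
#'   (default 50); larger instances raise an error suggesting a smaller
#'   subproblem size.
#' @param tol absolute tolerance for objective comparisons.
#' @return list of class `"bqp_solution"`: `indicator` (0/1 integer
#'   vector), `objective` (including the instance offset), `optimal`
#'   (`TRUE`), and `genes` (original column indices selected, when the
#'   instance carries them).
#' @seealso [solve_bqp_enumerate()] for the exhaustive-enumeration oracle.
#' @export
solve_bqp_exact <- function(instance, max_vars = 50L, tol = 1e-9) {
  stopifnot(inherits(instance, "bqp_instance"))
  m <- length(instance$f)
  if (m > max_vars) {
    stop("BQP instance has ", m, " variables, above the exact-solver cap ",
         "of ", max_vars, "; reduce the subproblem size 'nu'",
         call. = FALSE)
  }
  if (m == 0L) {
    sol <- list(indicator = integer(0), objective = instance$offset,
                optimal = TRUE)
  } else {
    sol <- bqp_solve_bb(instance$Q, instance$f, instance$offset, tol)
    sol$indicator <- as.integer(sol$indicator)
  }
  finish_bqp_solution(sol, instance)
}

#' Solve a binary quadratic program by exhaustive enumeration
#'
#' Evaluates the objective at all `2^m` binary vectors and returns the
#' minimizer, with the same deterministic tie-breaking as
#' [solve_bqp_exact()] (fewest variables, then lexicographically smallest
#' indicator).  Intended as an independent correctness oracle for the
#' branch-and-bound solver; limited to 20 variables.
#'
#' @inheritParams solve_bqp_exact
#' @return a `"bqp_solution"` list, as for [solve_bqp_exact()].
#' @export
solve_bqp_enumerate <- function(instance, tol = 1e-9) {
  stopifnot(inherits(instance, "bqp_instance"))
  m <- length(instance$f)
  if (m > 20L) {
    stop("enumeration oracle is limited to 20 variables; got ", m,
         call. = FALSE)
  }
  if (m == 0L) {
    sol <- list(indicator = integer(0), objective = instance$offset,
                optimal = TRUE)
    return(finish_bqp_solution(sol, instance))
  }
  ncand <- 2^m
  chunk <- 2^14
  obj <- numeric(ncand)
  starts <- seq(0, ncand - 1, by = chunk)
  for (s in starts) {
    v <- s + seq_len(min(chunk, ncand - s)) - 1
    X <- bit_matrix(v, m)
    obj[v + 1] <- rowSums((X %*% instance$Q) * X) -
      as.vector(X %*% instance$f)
  }
  best <- min(obj)
  ties <- which(obj <= best + tol)
  Xt <- bit_matrix(ties - 1, m)
  card <- rowSums(Xt)
  # lexicographic key: first variable is the most significant digit
  lexkey <- as.vector(Xt %*% 2^(m - seq_len(m)))
  pick <- order(card, lexkey)[1L]
  sol <- list(indicator = as.integer(Xt[pick, ]),
              objective = obj[ties[pick]] + instance$offset,
              optimal = TRUE)
  finish_bqp_solution(sol, instance)
}

# rows = binary expansion of the integers v (bit b -> variable b + 1)
bit_matrix <- function(v, m) {
  X <- matrix(0, length(v), m)
  for (b in seq_len(m)) {
    X[, b] <- bitwAnd(bitwShiftR(v, b - 1L), 1L)
  }
  X
}

finish_bqp_solution <- function(sol, instance) {
  sol$optimal <- TRUE
  if (!is.null(instance$genes)) {
    sol$genes <- instance$genes[sol$indicator == 1L]
  }
  if (!is.null(instance$gene_names)) {
    sol$gene_names <- instance$gene_names[sol$indicator == 1L]
  }
  class(sol) <- "bqp_solution"
  sol
}

#' @export
print.bqp_solution <- function(x, ...) {
  cat(sprintf("BQP solution: %d of %d variables selected, objective %g\n",
              sum(x$indicator), length(x$indicator), x$objective))
  invisible(x)
}
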