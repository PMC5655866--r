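#' Construct a binary patient-by-gene mutation matrix
#'
#' The central data structure of the package: an `n` patients by `p` genes
#' binary matrix `G` with `G[i, j] = 1` if patient `i` carries at least one
#' non-silent somatic mutation in gene `j`, and 0 otherwise.  Rows are
#' patients, columns are genes; both must carry unique identifiers.
#'
#' @param x a numeric, integer or logical matrix containing only 0/1
#'   (or `TRUE`/`FALSE`) values.
#' @param patients optional character vector of patient identifiers; taken
#'   from `rownames(x)` when missing, or generated as `P1..Pn`.
#' @param genes optional character vector of gene symbols; taken from
#'   `colnames(x)` when missing, or generated as `G1..Gp`.
#'
#' @return an integer matrix of class `"mutation_matrix"` with patient row
#'   names and gene column names.
#' @examples
#' G <- mutation_matrix(rbind(c(1, 0), c(1, 1)),
#'                      patients = c("P1", "P2"),
#'                      genes = c("TP53", "KRAS"))
#' n_patients(G)
#' n_genes(G)
#' @export
mutation_matrix <- function(x, patients = NULL, genes = NULL) {
  if (!is.matrix(x)) {
    x <- as.matrix(x)
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop("a mutation matrix needs at least one patient and one gene",
         call. = FALSE)
  }
  if (is.logical(x)) {
    storage.mode(x) <- "integer"
  }
  if (!is.numeric(x)) {
    stop("mutation matrix values must be numeric 0/1", call. = FALSE)
  }
  if (anyNA(x)) {
    stop("mutation matrix must not contain missing values", call. = FALSE)
  }
  if (!all(x == 0 | x == 1)) {
    stop("mutation matrix entries must all be 0 or 1", call. = FALSE)
  }
  storage.mode(x) <- "integer"

  if (is.null(patients)) {
    patients <- rownames(x)
  }
  if (is.null(patients)) {
    patients <- paste0("P", seq_len(nrow(x)))
  }
  if (is.null(genes)) {
    genes <- colnames(x)
  }
  if (is.null(genes)) {
    genes <- paste0("G", seq_len(ncol(x)))
  }
  patients <- as.character(patients)
  genes <- as.character(genes)
  if (length(patients) != nrow(x)) {
    stop("length of 'patients' must equal nrow(x)", call. = FALSE)
  }
  if (length(genes) != ncol(x)) {
    stop("length of 'genes' must equal ncol(x)", call. = FALSE)
  }
  if (anyDuplicated(patients)) {
    stop("patient identifiers must be unique", call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    stop("gene symbols must be unique", call. = FALSE)
  }
  dimnames(x) <- list(patients, genes)
  class(x) <- c("mutation_matrix", class(x))
  x
}

#' Coerce to a mutation matrix
#'
#' @param x an object coercible to a binary matrix.
#' @return a `mutation_matrix`.
#' @export
as_mutation_matrix <- function(x) {
  if (inherits(x, "mutation_matrix")) {
    return(x)
  }
  mutation_matrix(x)
}

#' @rdname mutation_matrix
#' @param G a `mutation_matrix`.
#' @export
n_patients <- function(G) nrow(G)

#' @rdname mutation_matrix
#' @export
n_genes <- function(G) ncol(G)

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf("mutation matrix: %d patients x %d genes, %d mutations\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

# strip the class so plain matrix algebra applies
mm_values <- function(G) {
  unclass(as_mutation_matrix(G))
}

#' Resolve a gene-set specification to a binary indicator
#'
#' Gene sets (the solution vector `x` of the model) can be given as a
#' full-length 0/1 indicator, as a vector of column indices, or as a
#' character vector of gene symbols.  This helper normalizes any of the
#' three to a 0/1 integer indicator of length `n_genes(G)`.
#'
#' @param G a `mutation_matrix`.
#' @param x indicator vector, integer gene indices, or gene symbols.
#' @return integer 0/1 vector of length `n_genes(G)`.
#' @export
gene_indicator <- function(G, x) {
  G <- as_mutation_matrix(G)
  p <- ncol(G)
  if (is.character(x)) {
    idx <- match(x, colnames(G))
    if (anyNA(idx)) {
      stop("unknown gene symbol(s): ",
           paste(x[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    ind <- integer(p)
    ind[idx] <- 1L
    return(ind)
  }
  if (is.logical(x)) {
    if (length(x) != p) {
      stop("logical gene indicator must have length n_genes(G)",
           call. = FALSE)
    }
    return(as.integer(x))
  }
  if (!is.numeric(x)) {
    stop("gene set must be an indicator, indices, or gene symbols",
         call. = FALSE)
  }
  if (length(x) == p && all(x == 0 | x == 1)) {
    # full-length 0/1 vector is read as an indicator
    return(as.integer(x))
  }
  idx <- as.integer(x)
  if (length(idx) && (min(idx) < 1L || max(idx) > p)) {
    stop("gene index out of range 1..", p, call. = FALSE)
  }
  if (anyDuplicated(idx)) {
    stop("duplicate gene indices in gene set", call. = FALSE)
  }
  ind <- integer(p)
  ind[idx] <- 1L
  ind
}
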