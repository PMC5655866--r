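#' Read a mutation matrix from disk
#'
#' Three plain-text dialects are supported:
#' \describe{
#'   \item{`tsv_matrix`}{canonical: a TSV table with a header row of gene
#'     symbols, first column of patient identifiers, and 0/1 cells.}
#'   \item{`pair_list`}{two tab-separated columns `patient<TAB>gene`, one
#'     mutated patient-gene pair per line; duplicates collapse to a
#'     single 1.}
#'   \item{`dendrix`}{one patient per line: the patient identifier
#'     followed by the tab-separated symbols of its mutated genes.}
#' }
#' Patients and genes keep their order of first appearance.  Typical MAF
#' preprocessing (keep non-silent variants, emit `sample<TAB>gene` pairs)
#' produces the `pair_list` dialect directly.
#'
#' @param path file to read.
#' @param format one of `"tsv_matrix"`, `"pair_list"`, `"dendrix"`.
#' @return a `mutation_matrix`.
#' @export
read_mutation_matrix <- function(path,
                                 format = c("tsv_matrix", "pair_list",
                                            "dendrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  switch(format,
         tsv_matrix = read_tsv_matrix(path),
         pair_list = read_pair_list(path),
         dendrix = read_dendrix(path))
}

read_tsv_matrix <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, row.names = NULL,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) {
    stop("TSV matrix needs a patient column plus at least one gene column",
         call. = FALSE)
  }
  patients <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(vals), nrow(vals)))) & !is.na(vals),
      arr.ind = TRUE)
    line <- if (nrow(bad)) bad[1L, 1L] + 1L else NA_integer_
    stop("non-numeric cell in TSV matrix near line ", line, call. = FALSE)
  }
  if (anyNA(vals) || !all(vals == 0 | vals == 1)) {
    bad <- which(is.na(vals) | (vals != 0 & vals != 1), arr.ind = TRUE)
    stop("non-binary value in TSV matrix at line ", bad[1L, 1L] + 1L,
         " (patient ", patients[bad[1L, 1L]], ")", call. = FALSE)
  }
  mutation_matrix(vals, patients = patients, genes = colnames(tab)[-1L])
}

read_pair_list <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in which(keep)) {
    if (length(fields[[i]]) != 2L || any(!nzchar(fields[[i]]))) {
      stop("malformed pair-list line ", i,
           ": expected 'patient<TAB>gene'", call. = FALSE)
    }
  }
  fields <- fields[keep]
  if (!length(fields)) {
    stop("pair list is empty", call. = FALSE)
  }
  patients <- vapply(fields, `[[`, "", 1L)
  genes <- vapply(fields, `[[`, "", 2L)
  pats <- unique(patients)
  gens <- unique(genes)
  M <- matrix(0L, length(pats), length(gens),
              dimnames = list(pats, gens))
  M[cbind(match(patients, pats), match(genes, gens))] <- 1L
  mutation_matrix(M)
}

read_dendrix <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) {
    stop("file is empty", call. = FALSE)
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    if (!nzchar(fields[[i]][1L])) {
      stop("malformed line ", keep[i], ": missing patient identifier",
           call. = FALSE)
    }
  }
  patients <- vapply(fields, `[[`, "", 1L)
  gene_lists <- lapply(fields, function(f) unique(f[-1L][nzchar(f[-1L])]))
  gens <- unique(unlist(gene_lists))
  if (!length(gens)) {
    stop("no genes found in Dendrix-format file", call. = FALSE)
  }
  M <- matrix(0L, length(patients), length(gens),
              dimnames = list(patients, gens))
  for (i in seq_along(patients)) {
    M[i, match(gene_lists[[i]], gens)] <- 1L
  }
  mutation_matrix(M)
}

#' Write a mutation matrix to disk
#'
#' Inverse of [read_mutation_matrix()]; all three dialects round-trip
#' losslessly (up to empty patients, which the pair-oriented dialects
#' cannot represent... the `dendrix` dialect keeps them as bare lines).
#'
#' @param G a `mutation_matrix`.
#' @inheritParams read_mutation_matrix
#' @return the path, invisibly.
#' @export
write_mutation_matrix <- function(G, path,
                                  format = c("tsv_matrix", "pair_list",
                                             "dendrix")) {
  G <- as_mutation_matrix(G)
  format <- match.arg(format)
  M <- mm_values(G)
  if (format == "tsv_matrix") {
    tab <- data.frame(patient = rownames(M), M, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "pair_list") {
    hits <- which(M == 1L, arr.ind = TRUE)
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    writeLines(paste(rownames(M)[hits[, 1L]], colnames(M)[hits[, 2L]],
                     sep = "\t"), path)
  } else {
    lines <- vapply(seq_len(nrow(M)), function(i) {
      genes <- colnames(M)[M[i, ] == 1L]
      paste(c(rownames(M)[i], genes), collapse = "\t")
    }, "")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Default hypermutated-gene filter
#'
#' Frequently mutated gene families with no established driver role that
#' are conventionally removed before exclusivity analysis: olfactory
#' receptors, mucins, and titin.  Shipped as a plain-text file
#' (`inst/extdata/hypermutated_filter.txt`), one entry per line; entries
#' are anchored regular expressions matched case-insensitively, so plain
#' symbols match exactly.  Replace with your own list via the `filter`
#' argument of [apply_gene_filter()].
#'
#' @return character vector of filter patterns.
#' @export
default_gene_filter <- function() {
  path <- system.file("extdata", "hypermutated_filter.txt",
                      package = "mutexquad", mustWork = TRUE)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Remove filtered genes from a mutation matrix
#'
#' Drops the columns whose symbols match an entry of the filter list.
#' Matching is case-insensitive on the whole symbol; entries may be
#' anchored regular expressions (e.g. `OR[0-9]+[A-Z][0-9]*` for the
#' olfactory receptors), and plain symbols match exactly.  Patient rows
#' are retained even if they lose all their mutations.
#'
#' @param G a `mutation_matrix`.
#' @param filter character vector of symbols / patterns; defaults to
#'   [default_gene_filter()].
#' @return filtered `mutation_matrix`.
#' @export
apply_gene_filter <- function(G, filter = default_gene_filter()) {
  G <- as_mutation_matrix(G)
  filter <- as.character(filter)
  if (!length(filter)) {
    return(G)
  }
  symbols <- toupper(colnames(G))
  drop <- rep(FALSE, ncol(G))
  for (pat in filter) {
    drop <- drop | grepl(paste0("^(?:", toupper(pat), ")$"), symbols,
                         perl = TRUE)
  }
  if (!any(drop)) {
    return(G)
  }
  if (all(drop)) {
    # a zero-gene mutation_matrix is not representable; hand back a bare
    # matrix so the caller sees the warning here and the error downstream
    warning("gene filter removed every gene; downstream analysis will ",
            "fail on an empty matrix", call. = FALSE)
    return(mm_values(G)[, 0, drop = FALSE])
  }
  mutation_matrix(mm_values(G)[, !drop, drop = FALSE],
                  patients = rownames(G),
                  genes = colnames(G)[!drop])
}
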