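#' Write a machine-readable solution report
#'
#' Serializes the result of [mutex_search()], [mutex_iterate()] or
#' [permutation_test()].  JSON is the canonical format (keys emitted in
#' sorted order so reports diff stably); TSV writes one gene per row with
#' its patient mutation count, preceded by `#`-prefixed metadata lines.
#'
#' @param result a `"mutex_result"`, `"mutex_iterate"` or
#'   `"mutex_permtest"` object.
#' @param path output file.
#' @param format `"json"` or `"tsv"`.
#' @return the path, invisibly.
#' @seealso [read_report()]
#' @export
write_report <- function(result, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (inherits(result, "mutex_permtest")) {
    res <- result$observed
    extra <- list(n_perm = result$n_perm,
                  null_objective_min = min(result$null_objectives),
                  null_objective_max = max(result$null_objectives))
  } else if (inherits(result, "mutex_iterate")) {
    return(write_iterate_report(result, path, format))
  } else if (inherits(result, "mutex_result")) {
    res <- result
    extra <- NULL
  } else {
    stop("'result' must come from mutex_search(), mutex_iterate() or ",
         "permutation_test()", call. = FALSE)
  }
  rep <- solution_report(res, extra)
  if (format == "json") {
    write_canonical_json(rep, path)
  } else {
    write_tsv_report(rep, path)
  }
  invisible(path)
}

solution_report <- function(res, extra = NULL) {
  rep <- list(
    genes = as.character(res$genes),
    gene_counts = as.integer(res$gene_counts),
    objective = res$objective,
    coverage = res$metrics$coverage,
    excess_coverage = res$metrics$excess_coverage,
    dendrix_score = res$metrics$dendrix_score,
    k = res$params$k,
    C = res$params$C,
    nu = res$params$nu,
    iterations = res$params$iterations,
    tau = res$params$tau,
    seed = if (is.null(res$seed)) NA else res$seed,
    n_patients = res$n_patients,
    n_genes = res$n_genes
  )
  if (!is.null(res$p_value)) {
    rep$p_value <- res$p_value
  }
  c(rep, extra)
}

write_canonical_json <- function(x, path) {
  x <- x[order(names(x))]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

write_tsv_report <- function(rep, path) {
  scalars <- rep[setdiff(names(rep), c("genes", "gene_counts"))]
  scalars <- scalars[order(names(scalars))]
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(scalars)) {
    writeLines(sprintf("# %s\t%s", key, format(scalars[[key]], digits = 15)),
               con)
  }
  writeLines("gene\tpatient_count", con)
  if (length(rep$genes)) {
    writeLines(paste(rep$genes, rep$gene_counts, sep = "\t"), con)
  }
  invisible(path)
}

write_iterate_report <- function(result, path, format) {
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# iterated search report", con)
    writeLines("round\tgene\tpatient_count", con)
    for (r in seq_along(result$rounds)) {
      res <- result$rounds[[r]]
      if (length(res$genes)) {
        writeLines(paste(r, res$genes, res$gene_counts, sep = "\t"), con)
      }
    }
    return(invisible(path))
  }
  rounds <- lapply(result$rounds, function(res) {
    rep <- solution_report(res)
    rep[order(names(rep))]
  })
  out <- list(pooled_genes = as.character(result$pooled_genes),
              rounds = rounds)
  write_canonical_json(out, path)
}

#' Read back a JSON solution report
#'
#' @param path a JSON file written by [write_report()].
#' @return named list of report fields.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
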