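#' Read a gene-by-sample expression matrix from TSV
#'
#' The matrix dialect used throughout the pipeline: a header row of sample
#' IDs, a first column named `gene_id`, tab separation, plain decimal
#' numbers. The reader validates the file strictly and reports the offending
#' line on failure; `write_matrix_tsv()` round-trips losslessly to at least
#' 12 significant digits.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix with genes as rows and samples as columns.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2 || !nzchar(lines[1]))
    stop2("empty or header-only matrix file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "gene_id")
    stop2("matrix TSV must have 'gene_id' as its first column, found '",
          header[1], "'")
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids))
    stop2("duplicated sample ID in header: ",
          sample_ids[duplicated(sample_ids)][1])
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  nfield <- lengths(body)
  if (any(nfield != length(header))) {
    bad <- which(nfield != length(header))[1]
    stop2("ragged row at line ", bad + 1L, ": expected ", length(header),
          " fields, found ", nfield[bad])
  }
  gene_ids <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(gene_ids))
    stop2("duplicated gene ID: ", gene_ids[duplicated(gene_ids)][1])
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1]), numeric(length(sample_ids))))
  vals <- if (length(sample_ids) == 1L) matrix(vals, nrow = 1L) else vals
  if (anyNA(vals)) {
    bad <- which(colSums(is.na(vals)) > 0)[1]
    stop2("non-numeric cell at line ", bad + 1L)
  }
  m <- t(vals)
  dimnames(m) <- list(gene_ids, sample_ids)
  m
}

#' Write an expression matrix as TSV
#'
#' @param matrix Numeric genes-by-samples matrix with dimnames.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(matrix, path) {
  check_expression_matrix(matrix)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(matrix)), collapse = "\t"), con)
  body <- apply(matrix, 1L, function(r)
    paste(formatC(r, digits = 15, format = "g"), collapse = "\t"))
  writeLines(paste(rownames(matrix), body, sep = "\t"), con)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then members. Blank member fields are dropped.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of gene IDs; descriptions kept
#'   in the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop2("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names_))
    stop2("duplicated gene-set name: ", names_[duplicated(names_)][1])
  sets <- lapply(fields, function(f) {
    members <- f[-(1:2)]
    members[nzchar(members)]
  })
  empty <- lengths(fields) < 3L | lengths(sets) == 0L
  if (any(empty))
    stop2("gene set with no members: ", names_[empty][1])
  names(sets) <- names_
  attr(sets, "descriptions") <-
    stats::setNames(vapply(fields, `[[`, "", 2L), names_)
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop2("sets must be a uniquely named list")
  desc <- descriptions %||% attr(sets, "descriptions") %||%
    stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]] %||% "", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read sample metadata from TSV
#' @param path Path to a TSV with a header row.
#' @return A data.frame.
#' @export
read_metadata_tsv <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_metadata(md)
  md
}

#' Write sample metadata (or any flat table) as TSV
#' @param table A data.frame.
#' @param path Output path.
#' @export
write_table_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an analyte table from TSV (long format)
#' @param path Path to a TSV with columns subject_id, timepoint, analyte,
#'   raw, creatinine, normalized.
#' @return A data.frame.
#' @export
read_analytes_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("subject_id", "timepoint", "analyte", "raw", "creatinine")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop2("analyte table is missing columns: ", paste(missing, collapse = ", "))
  tab
}

#' Read the expression table from a GEO series-matrix file
#'
#' Convenience reader for the series-matrix flavour of TSV: comment lines
#' start with `!`, and the numeric table sits between the
#' `!series_matrix_table_begin` and `!series_matrix_table_end` markers with
#' quoted probe IDs in the first column. Provided as plumbing for users who
#' wish to score real reference series; nothing in the pipeline requires it.
#'
#' @param path Path to an (uncompressed) series-matrix file.
#' @return A numeric matrix, probes as rows and samples as columns.
#' @export
read_series_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
    stop2("no series-matrix table found in ", path)
  block <- lines[(beg + 1L):(end - 1L)]
  block <- gsub('"', "", block, fixed = TRUE)
  fields <- strsplit(block, "\t", fixed = TRUE)
  header <- fields[[1]]
  body <- fields[-1]
  gene_ids <- vapply(body, `[[`, "", 1L)
  vals <- t(vapply(body, function(f) as.numeric(f[-1]),
                   numeric(length(header) - 1L)))
  dimnames(vals) <- list(gene_ids, header[-1])
  vals
}
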