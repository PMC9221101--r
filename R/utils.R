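# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop2 <- function(...) stop(..., call. = FALSE)

# Check that x is a numeric genes-x-samples matrix with unique dimnames.
check_expression_matrix <- function(x, arg = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop2(arg, " must be a numeric matrix (genes x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop2(arg, " must have gene IDs as rownames and sample IDs as colnames")
  if (anyDuplicated(rownames(x)))
    stop2(arg, " has duplicated gene IDs")
  if (anyDuplicated(colnames(x)))
    stop2(arg, " has duplicated sample IDs")
  if (!all(is.finite(x)))
    stop2(arg, " contains non-finite values")
  invisible(x)
}

check_metadata <- function(md, required = c("sample_id", "subject_id", "arm",
                                            "timepoint", "batch", "rin", "sex")) {
  if (!is.data.frame(md)) stop2("metadata must be a data.frame")
  missing <- setdiff(required, names(md))
  if (length(missing))
    stop2("metadata is missing columns: ", paste(missing, collapse = ", "))
  if ("sample_id" %in% names(md) && anyDuplicated(md$sample_id))
    stop2("metadata has duplicated sample IDs")
  invisible(md)
}

# sd with the n-1 denominator, returning 0 for length-1 input
sd1 <- function(x) if (length(x) < 2) 0 else stats::sd(x)

# Row-wise means/vars without matrixStats
row_vars <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

#' @keywords internal
timepoint_levels <- function() c("baseline", "end", "post1wk")
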