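#' Flag principal-component outlier samples
#'
#' QC PCA with samples as observations and genes as (centered, unscaled)
#' variables; samples whose first-PC score lies more than `sd_threshold`
#' sample standard deviations (n-1 denominator) from the mean PC1 score are
#' flagged. A zero-variance PC1 flags nothing. Probe-level quality metrics
#' (NUSE/RLE) require raw array data and are outside this report's scope.
#'
#' @param matrix Genes-by-samples expression matrix.
#' @param sd_threshold Positive flagging threshold in SD units (default 2).
#' @return A list of class `qc_report` with `flagged_sample_ids`,
#'   `pc1_scores`, `sd_threshold`, and a `note` on metric coverage.
#' @export
pc1_outlier_flags <- function(matrix, sd_threshold = 2) {
  check_expression_matrix(matrix)
  if (ncol(matrix) < 3) stop2("PC1 outlier detection needs at least 3 samples")
  if (!is.numeric(sd_threshold) || length(sd_threshold) != 1 ||
      is.na(sd_threshold) || sd_threshold <= 0)
    stop2("sd_threshold must be a positive number")
  x <- scale(t(matrix), center = TRUE, scale = FALSE)
  sv <- svd(x, nu = 1, nv = 0)
  pc1 <- stats::setNames(drop(sv$u * sv$d[1]), colnames(matrix))
  s <- sd1(pc1)
  flagged <- if (s == 0) character(0) else
    names(pc1)[abs(pc1 - mean(pc1)) > sd_threshold * s]
  structure(list(flagged_sample_ids = flagged, pc1_scores = pc1,
                 sd_threshold = sd_threshold,
                 note = paste("PCA-based sample QC only; probe-level",
                              "NUSE/RLE metrics are out of scope")),
            class = "qc_report")
}

#' Infer sample sex from Y-chromosome marker genes
#'
#' Averages the expression of the supplied Y-chromosome-specific genes per
#' sample and splits the samples into two clusters at the largest gap
#' between consecutive sorted means; the higher cluster is labeled male. If
#' the split is degenerate (gap below `min_gap`), all samples receive a
#' single label -- chosen by comparing the Y-gene level to the matrix grand
#' mean -- and the result carries a `degenerate` warning flag.
#'
#' @param matrix Genes-by-samples expression matrix.
#' @param y_gene_ids Non-empty character vector of Y-marker gene IDs present
#'   in the matrix.
#' @param min_gap Smallest between-cluster gap (log2 units) accepted as a
#'   real two-cluster split.
#' @return Named character vector of labels (`"male"`/`"female"`) with a
#'   logical attribute `degenerate`.
#' @export
infer_sex <- function(matrix, y_gene_ids, min_gap = 1) {
  check_expression_matrix(matrix)
  if (length(y_gene_ids) == 0) stop2("y_gene_ids must be non-empty")
  if (!all(y_gene_ids %in% rownames(matrix)))
    stop2("y_gene_ids absent from matrix: ",
          paste(setdiff(y_gene_ids, rownames(matrix)), collapse = ", "))
  ym <- colMeans(matrix[y_gene_ids, , drop = FALSE])
  ord <- order(ym)
  gaps <- diff(ym[ord])
  if (length(gaps) == 0 || max(gaps) < min_gap) {
    warning("Y-gene expression forms a single cluster; sex not separable",
            call. = FALSE)
    lab <- if (mean(ym) > mean(matrix)) "male" else "female"
    out <- stats::setNames(rep(lab, ncol(matrix)), colnames(matrix))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  cut <- which.max(gaps)
  thr <- (ym[ord][cut] + ym[ord][cut + 1]) / 2
  out <- stats::setNames(ifelse(ym > thr, "male", "female"), colnames(matrix))
  attr(out, "degenerate") <- FALSE
  out
}

#' Remove nuisance-covariate effects from expression values
#'
#' Per gene, fits ordinary least squares on the combined design of the
#' `keep` factors and `remove` covariates, then subtracts only the fitted
#' contribution of the `remove` terms. Continuous removed covariates are
#' centered and removed factors use sum-to-zero coding, so removal does not
#' shift gene means. `keep` terms (e.g., the arm-by-timepoint design) are
#' estimated jointly so their signal is not absorbed into the removal.
#'
#' @param matrix Genes-by-samples expression matrix.
#' @param metadata Sample metadata with rows matching `colnames(matrix)`
#'   via the `sample_id` column.
#' @param remove Character vector of metadata columns to remove (e.g.
#'   `"rin"`, `"batch"`).
#' @param keep Character vector of metadata columns whose effects must be
#'   preserved; interactions may be written as `"a:b"`.
#' @return The adjusted matrix, same shape as the input.
#' @export
residualize <- function(matrix, metadata, remove, keep = character(0)) {
  check_expression_matrix(matrix)
  if (!"sample_id" %in% names(metadata)) stop2("metadata needs sample_id")
  if (length(intersect(remove, keep)))
    stop2("remove and keep must be disjoint")
  if (!length(remove)) return(matrix)
  md <- metadata[match(colnames(matrix), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop2("metadata missing for some samples")
  base_vars <- unique(unlist(strsplit(c(remove, keep), ":", fixed = TRUE)))
  miss <- setdiff(base_vars, names(md))
  if (length(miss))
    stop2("metadata is missing columns: ", paste(miss, collapse = ", "))

  term_cols <- function(terms) {
    if (!length(terms)) return(NULL)
    blocks <- lapply(terms, function(tm) {
      vars <- strsplit(tm, ":", fixed = TRUE)[[1]]
      cols <- lapply(vars, function(v) {
        x <- md[[v]]
        if (is.numeric(x)) {
          out <- matrix(x - mean(x), ncol = 1,
                        dimnames = list(NULL, v))
        } else {
          f <- factor(x)
          if (nlevels(f) < 2) return(NULL)
          out <- stats::model.matrix(~ f,
            contrasts.arg = list(f = "contr.sum"))[, -1, drop = FALSE]
          colnames(out) <- paste0(v, seq_len(ncol(out)))
          out
        }
      })
      if (any(vapply(cols, is.null, TRUE))) return(NULL)
      out <- Reduce(function(a, b) {
        res <- do.call(cbind, lapply(seq_len(ncol(b)), function(j) a * b[, j]))
        colnames(res) <- as.vector(outer(colnames(a), colnames(b), paste,
                                         sep = ":"))
        res
      }, cols)
      out
    })
    blocks <- blocks[!vapply(blocks, is.null, TRUE)]
    if (!length(blocks)) NULL else do.call(cbind, blocks)
  }

  Zr <- term_cols(remove)
  if (is.null(Zr)) return(matrix)
  Zk <- term_cols(keep)
  X <- cbind(`(Intercept)` = 1, Zk, Zr)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop2("design is rank deficient; collinear terms: ",
          paste(aliased, collapse = ", "))
  }
  beta <- qr.coef(qrx, t(matrix))          # p x genes
  rm_idx <- ncol(X) - rev(seq_len(ncol(Zr))) + 1L
  fitted_rm <- Zr %*% beta[rm_idx, , drop = FALSE]
  out <- matrix - t(fitted_rm)
  dimnames(out) <- dimnames(matrix)
  out
}

#' Z-score each gene across samples
#'
#' Centers and scales every gene to mean 0, SD 1 (n-1 denominator) across
#' samples. Constant genes map to all-zero rows so the matrix shape is
#' preserved for downstream signature scoring.
#'
#' @param matrix Genes-by-samples expression matrix.
#' @return Matrix of the same shape.
#' @export
zscore_genes <- function(matrix) {
  check_expression_matrix(matrix)
  mu <- rowMeans(matrix)
  s <- sqrt(row_vars(matrix))
  s[s == 0] <- Inf                       # constant genes -> zero rows
  (matrix - mu) / s
}
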