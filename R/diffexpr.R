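#' Build the trial design matrix
#'
#' Fixed-effect design for the gene-wise models: intercept, treatment
#' indicator (placebo reference), two timepoint indicators (baseline
#' reference), the two treatment-by-timepoint interaction columns (the
#' contrasts of interest: end-of-treatment and one-week post), centered
#' RIN, and dummy-coded batch (first level dropped; absent when only one
#' batch is present).
#'
#' @param metadata Sample metadata with subject_id, arm, timepoint, batch,
#'   rin columns; row order defines the sample order of the design.
#' @return A numeric design matrix with attributes `interaction_cols`
#'   (named column indices of the two interaction contrasts), `sample_ids`,
#'   and `blocks` (subject labels for the correlation structure).
#' @export
build_design <- function(metadata) {
  md <- check_metadata(metadata,
                       c("sample_id", "subject_id", "arm", "timepoint",
                         "batch", "rin"))
  if (anyNA(md$rin)) stop2("missing RIN for samples: ",
                           paste(md$sample_id[is.na(md$rin)], collapse = ", "))
  arm <- factor(md$arm, levels = c("placebo", "treatment"))
  tp <- factor(md$timepoint, levels = timepoint_levels())
  if (anyNA(arm) || anyNA(tp))
    stop2("arm/timepoint contain values outside the expected levels")
  X <- stats::model.matrix(~ arm * tp)
  colnames(X) <- sub("armtreatment", "treatment", colnames(X))
  colnames(X) <- sub("^tp", "tp_", colnames(X))
  colnames(X) <- sub(":tp", ":tp_", colnames(X))
  rin_c <- md$rin - mean(md$rin)
  X <- cbind(X[, 1:4, drop = FALSE], rin = rin_c)
  batch <- factor(md$batch)
  if (nlevels(batch) > 1) {
    Bm <- stats::model.matrix(~ batch)[, -1, drop = FALSE]
    X <- cbind(X, Bm)
  }
  XI <- stats::model.matrix(~ arm * tp)
  inter <- XI[, grep(":", colnames(XI)), drop = FALSE]
  colnames(inter) <- c("treatment:tp_end", "treatment:tp_post1wk")
  X <- cbind(X, inter)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop2("design is rank deficient; aliased columns: ",
          paste(aliased, collapse = ", "))
  }
  attr(X, "interaction_cols") <-
    stats::setNames(match(colnames(inter), colnames(X)),
                    c("end", "post1wk"))
  attr(X, "sample_ids") <- md$sample_id
  attr(X, "blocks") <- md$subject_id
  X
}

# Symmetric inverse square root of the exchangeable correlation matrix for
# one block of size k, applied to the rows of M belonging to that block.
whiten_blocks <- function(M, blocks, rho) {
  if (rho == 0) return(M)
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    k <- length(idx)
    if (k == 1) { M[idx, ] <- M[idx, , drop = FALSE] / sqrt(1 + 0) ; next }
    a1 <- 1 / sqrt(1 - rho)
    a2 <- 1 / sqrt(1 - rho + k * rho)
    sub <- M[idx, , drop = FALSE]
    cm <- colMeans(sub)
    M[idx, ] <- a1 * sweep(sub, 2, cm) + a2 * matrix(cm, k, ncol(sub),
                                                     byrow = TRUE)
  }
  M
}

# log|V(rho)| for the exchangeable block-diagonal correlation matrix
logdet_V <- function(blocks, rho) {
  k <- table(blocks)
  sum((k - 1) * log(1 - rho) + log(1 - rho + k * rho))
}

#' Consensus within-subject correlation
#'
#' Estimates, for every gene, the within-block (within-subject) correlation
#' under the single-correlation exchangeable model by restricted maximum
#' likelihood, profiling out the fixed effects and the gene variance, and
#' pools the per-gene estimates by a 15%-per-tail trimmed mean on the
#' hyperbolic-arctangent scale. The REML profile is evaluated on a shared
#' correlation grid (the whitening transform and design determinants depend
#' only on rho, so one grid pass serves all genes) and each gene's optimum
#' is refined by quadratic interpolation.
#'
#' @param matrix Genes-by-samples expression matrix.
#' @param design Design matrix from [build_design()] (or any full-rank
#'   fixed-effect design aligned with the columns of `matrix`).
#' @param blocks Subject label per sample; at least two blocks of size >= 2.
#' @param grid_step Spacing of the rho grid (default 0.01).
#' @param rho_max Upper cap on the correlation (default 0.99).
#' @param trim Trimming fraction per tail for the pooled estimate.
#' @return The consensus correlation (scalar) with the per-gene estimates
#'   in attribute `per_gene`.
#' @export
consensus_correlation <- function(matrix, design, blocks,
                                  grid_step = 0.01, rho_max = 0.99,
                                  trim = 0.15) {
  check_expression_matrix(matrix)
  n <- ncol(matrix)
  if (nrow(design) != n) stop2("design rows must match samples")
  blocks <- as.character(blocks)
  ksizes <- table(blocks)
  if (all(ksizes == 1)) stop2("all blocks are singletons; no within-block ",
                              "correlation is estimable")
  kmax <- max(ksizes)
  lb <- -1 / (kmax - 1) + 1e-3
  grid <- seq(max(lb, -0.9), rho_max, by = grid_step)
  p <- ncol(design)
  Yt <- t(matrix)                                   # samples x genes
  G <- nrow(matrix)

  ll <- matrix(NA_real_, length(grid), G)
  for (i in seq_along(grid)) {
    rho <- grid[i]
    Xw <- whiten_blocks(design, blocks, rho)
    Yw <- whiten_blocks(Yt, blocks, rho)
    qrx <- qr(Xw)
    if (qrx$rank < p) next
    rss <- colSums(qr.resid(qrx, Yw)^2)
    ldV <- logdet_V(blocks, rho)
    ldXX <- 2 * sum(log(abs(diag(qr.R(qrx)))))
    ll[i, ] <- -0.5 * ((n - p) * log(rss) + ldV + ldXX)
  }

  per_gene <- vapply(seq_len(G), function(g) {
    lg <- ll[, g]
    i <- which.max(lg)
    if (i == 1 || i == length(grid)) return(grid[i])
    # quadratic refinement through the three points around the maximum
    y1 <- lg[i - 1]; y2 <- lg[i]; y3 <- lg[i + 1]
    denom <- y1 - 2 * y2 + y3
    if (!is.finite(denom) || denom >= 0) return(grid[i])
    grid[i] + 0.5 * grid_step * (y1 - y3) / denom
  }, numeric(1))
  per_gene <- pmin(pmax(per_gene, lb), rho_max)

  rho <- tanh(mean(atanh(per_gene), trim = trim))
  attr(rho, "per_gene") <- per_gene
  rho
}

# Inverse of the trigamma function (Newton iterations on 1/trigamma,
# which is nearly linear), to relative tolerance 1e-8.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) < 1e-8 * x) break
  }
  x
}

# Fit a scaled inverse-chi-square prior (d0, s02) to observed gene
# variances s2 with df degrees of freedom, by matching the mean and
# variance of log s2 through digamma/trigamma moment equations.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0) {
    warning("log-variances underdispersed relative to chi-square; ",
            "using the no-moderation limit d0 = Inf", call. = FALSE)
    return(list(d0 = Inf, s02 = mean(s2[ok])))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Gene-wise moderated fit with within-subject correlation
#'
#' Fits every gene by generalized least squares under the exchangeable
#' within-block correlation `rho` (data and design whitened by the inverse
#' square root of the block correlation matrix, then ordinary least
#' squares), estimates residual variances, shrinks them toward a scaled
#' inverse-chi-square prior fitted across genes by moment matching of
#' log-variances, and returns moderated t-statistics and two-sided
#' p-values for each coefficient with `d_g + d0` degrees of freedom.
#'
#' @param matrix Genes-by-samples expression matrix.
#' @param design Design matrix from [build_design()].
#' @param rho Consensus within-block correlation (0 = independent samples).
#' @param blocks Subject labels (required when `rho != 0`).
#' @return A list of class `moderated_fit`: `coefficients`,
#'   `stdev_unscaled`, `sigma2`, `df_residual`, `d0`, `s02`, `s2_post`,
#'   `t`, `p` (each genes x coefficients where applicable), `rho`, and
#'   `interaction_cols`.
#' @export
fit_moderated <- function(matrix, design, rho = 0, blocks = NULL) {
  check_expression_matrix(matrix)
  n <- ncol(matrix)
  p <- ncol(design)
  if (nrow(design) != n) stop2("design rows must match samples")
  if (rho != 0 && is.null(blocks))
    stop2("blocks are required when rho != 0")
  if (!is.null(blocks)) {
    kmax <- max(table(blocks))
    if (rho <= -1 / max(kmax - 1, 1) || rho >= 1)
      stop2("rho outside the valid exchangeable range")
  }
  Xw <- if (rho != 0) whiten_blocks(design, blocks, rho) else design
  Yw <- if (rho != 0) whiten_blocks(t(matrix), blocks, rho) else t(matrix)
  qrx <- qr(Xw)
  if (qrx$rank < p) stop2("design is rank deficient")
  beta <- t(qr.coef(qrx, Yw))                       # genes x p
  res <- qr.resid(qrx, Yw)
  dfr <- n - p
  s2 <- colSums(res^2) / dfr
  if (any(!is.finite(s2)))
    stop2("non-finite residual variance estimates")
  XtXinv_piv <- chol2inv(qr.R(qrx))
  XtXinv <- matrix(0, p, p)
  XtXinv[qrx$pivot, qrx$pivot] <- XtXinv_piv
  se_unscaled <- sqrt(diag(XtXinv))
  prior <- fit_variance_prior(s2, dfr)
  d0 <- prior$d0; s02 <- prior$s02
  s2_post <- if (is.finite(d0)) (d0 * s02 + dfr * s2) / (d0 + dfr)
             else rep(s02, length(s2))
  tmat <- beta / outer(sqrt(s2_post), se_unscaled)
  # total df capped at the pooled residual df across all genes
  df_total <- min(dfr + d0, length(s2) * dfr)
  pmat <- 2 * stats::pt(-abs(tmat), df_total)
  colnames(tmat) <- colnames(pmat) <- colnames(beta) <- colnames(design)
  structure(list(coefficients = beta, stdev_unscaled = se_unscaled,
                 sigma2 = s2, df_residual = dfr, d0 = d0, s02 = s02,
                 s2_post = s2_post, t = tmat, p = pmat, rho = rho,
                 interaction_cols = attr(design, "interaction_cols")),
            class = "moderated_fit")
}

#' Extract treatment-by-time gene lists
#'
#' Genes with interaction p below `alpha` at each interaction contrast,
#' split by coefficient sign. No multiple-testing adjustment is applied:
#' the analysis gates on the raw per-contrast p-value.
#'
#' @param fit A [fit_moderated()] result whose design carried the two
#'   interaction contrasts.
#' @param alpha Per-gene p-value threshold (default 0.01).
#' @return A list of class `interaction_signature`: per contrast
#'   (`end`, `post1wk`), `up_genes` and `down_genes`; `alpha` records the
#'   threshold.
#' @export
interaction_gene_lists <- function(fit, alpha = 0.01) {
  ic <- fit$interaction_cols
  if (is.null(ic) || length(ic) < 2)
    stop2("fit does not carry the two interaction contrasts")
  genes <- rownames(fit$coefficients)
  out <- lapply(names(ic), function(nm) {
    j <- ic[[nm]]
    hit <- fit$p[, j] < alpha
    list(up_genes = genes[hit & fit$coefficients[, j] > 0],
         down_genes = genes[hit & fit$coefficients[, j] < 0])
  })
  names(out) <- names(ic)
  out$alpha <- alpha
  class(out) <- "interaction_signature"
  out
}

#' Write a moderated fit as TSV
#'
#' One row per gene with the coefficient, moderated t, and p-value of each
#' interaction contrast.
#'
#' @param fit A [fit_moderated()] result.
#' @param path Output path.
#' @export
write_fit_tsv <- function(fit, path) {
  ic <- fit$interaction_cols
  tab <- data.frame(gene_id = rownames(fit$coefficients))
  for (nm in names(ic)) {
    j <- ic[[nm]]
    tab[[paste0("coef_", nm)]] <- fit$coefficients[, j]
    tab[[paste0("t_", nm)]] <- fit$t[, j]
    tab[[paste0("p_", nm)]] <- fit$p[, j]
  }
  write_table_tsv(tab, path)
}
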