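#' Empirical-Bayes location/scale batch adjustment
#'
#' Removes per-gene batch effects by the parametric empirical-Bayes
#' procedure: (1) standardize the data with a gene-wise model containing
#' batch indicators (plus optional covariates) and a batch-size-weighted
#' pooled variance; (2) estimate per-gene-per-batch location (`gamma`) and
#' scale (`delta2`) parameters on the standardized scale; (3) fit a normal
#' prior to the locations and an inverse-gamma prior to the scales across
#' genes by the method of moments; (4) iterate the joint posterior updates
#' to convergence; (5) adjust the data with the posterior estimates,
#' restoring the pooled scale, grand mean, and any covariate effects
#' unchanged.
#'
#' @param matrix Genes-by-samples expression matrix.
#' @param batch Batch label per sample (character or factor, length
#'   `ncol(matrix)`); at least 2 batches with at least 2 samples each.
#' @param covariates Optional numeric matrix / data.frame of biological
#'   covariates (one row per sample) whose effects must be preserved; must
#'   not be confounded with batch.
#' @param tol Convergence tolerance on the maximum relative parameter
#'   change (default 1e-4).
#' @param maxit Iteration cap for the posterior updates (default 100).
#' @return A list of class `combat_result`: `adjusted` (matrix of the input
#'   shape) and `model` (grand parameters, batch estimates, hyperpriors,
#'   posteriors, iteration count, convergence flag).
#' @export
combat_adjust <- function(matrix, batch, covariates = NULL,
                          tol = 1e-4, maxit = 100L) {
  check_expression_matrix(matrix)
  n <- ncol(matrix)
  if (length(batch) != n) stop2("batch must have one label per sample")
  batch <- factor(batch)
  if (nlevels(batch) < 2) stop2("batch adjustment needs at least 2 batches")
  n_b <- table(batch)
  if (any(n_b < 2))
    stop2("every batch needs at least 2 samples; too small: ",
          paste(names(n_b)[n_b < 2], collapse = ", "))
  B <- stats::model.matrix(~ 0 + batch)
  colnames(B) <- levels(batch)
  X <- B
  q <- 0L
  if (!is.null(covariates)) {
    cov <- as.matrix(as.data.frame(covariates))
    if (nrow(cov) != n) stop2("covariates must have one row per sample")
    q <- ncol(cov)
    X <- cbind(B, cov)
  }
  if (qr(X)$rank < ncol(X))
    stop2("batch and covariates are confounded (rank-deficient design)")

  G <- nrow(matrix)
  nb <- nlevels(batch)
  # gene-wise OLS: batch means plus covariate effects
  bhat <- qr.coef(qr(X), t(matrix))                       # (nb+q) x G
  w <- as.numeric(n_b) / n
  grand <- drop(crossprod(w, bhat[seq_len(nb), , drop = FALSE]))  # length G
  fitted <- X %*% bhat
  var_pooled <- colSums((t(matrix) - fitted)^2) / n              # length G
  if (any(var_pooled <= 0)) stop2("genes with zero pooled variance present")
  stand_mean <- matrix(grand, G, n)
  if (q > 0) {
    cov_fit <- X[, nb + seq_len(q), drop = FALSE] %*%
      bhat[nb + seq_len(q), , drop = FALSE]
    stand_mean <- stand_mean + t(cov_fit)
  }
  z <- (matrix - stand_mean) / sqrt(var_pooled)

  gamma_hat <- sapply(levels(batch), function(b)
    rowMeans(z[, batch == b, drop = FALSE]))                     # G x nb
  delta2_hat <- sapply(levels(batch), function(b)
    row_vars(z[, batch == b, drop = FALSE]))

  gamma_bar <- colMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 2, stats::var)
  m <- colMeans(delta2_hat)
  s2 <- apply(delta2_hat, 2, stats::var)
  lambda <- (2 * s2 + m^2) / s2            # inverse-gamma shape
  theta <- (m * s2 + m^3) / s2             # inverse-gamma scale

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  iters <- integer(nb)
  converged <- logical(nb)
  for (b in seq_len(nb)) {
    zb <- z[, batch == levels(batch)[b], drop = FALSE]
    nbb <- ncol(zb)
    g_old <- gamma_hat[, b]
    d_old <- delta2_hat[, b]
    it <- 0L
    repeat {
      it <- it + 1L
      g_new <- (nbb * tau2[b] * gamma_hat[, b] + d_old * gamma_bar[b]) /
        (nbb * tau2[b] + d_old)
      sum2 <- rowSums((zb - g_new)^2)
      d_new <- (theta[b] + 0.5 * sum2) / (nbb / 2 + lambda[b] - 1)
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                    abs(d_new - d_old) / d_old)
      g_old <- g_new
      d_old <- d_new
      if (change < tol) { converged[b] <- TRUE; break }
      if (it >= maxit) break
    }
    gamma_star[, b] <- g_old
    delta2_star[, b] <- d_old
    iters[b] <- it
  }

  adj <- z
  for (b in seq_len(nb)) {
    idx <- batch == levels(batch)[b]
    adj[, idx] <- (z[, idx, drop = FALSE] - gamma_star[, b]) /
      sqrt(delta2_star[, b])
  }
  adjusted <- adj * sqrt(var_pooled) + stand_mean
  dimnames(adjusted) <- dimnames(matrix)

  model <- list(alpha = grand, sigma2_pooled = var_pooled,
                gamma_hat = gamma_hat, delta2_hat = delta2_hat,
                gamma_bar = gamma_bar, tau2 = tau2,
                lambda = lambda, theta = theta,
                gamma_star = gamma_star, delta2_star = delta2_star,
                iterations = iters, converged = converged,
                batch_levels = levels(batch), batch_sizes = as.numeric(n_b))
  structure(list(adjusted = adjusted, model = model), class = "combat_result")
}

#' Harmonize a study matrix with a reference dataset
#'
#' Concatenates study and reference samples over their shared genes
#' (study gene order preserved), treats dataset of origin as the batch, and
#' runs [combat_adjust()]. Covariates default to none: quality covariates
#' are expected to have been residualized out of the study data beforehand.
#'
#' @param study,reference Genes-by-samples matrices; sample IDs must not
#'   collide.
#' @param covariates Optional covariates for the combined samples (study
#'   rows first).
#' @param ... Passed to [combat_adjust()].
#' @return The merged adjusted matrix with an `origin` attribute
#'   (`"study"`/`"reference"` per column).
#' @export
harmonize_with_reference <- function(study, reference, covariates = NULL,
                                     ...) {
  check_expression_matrix(study, "study")
  check_expression_matrix(reference, "reference")
  shared <- intersect(rownames(study), rownames(reference))
  if (!length(shared)) stop2("study and reference share no gene IDs")
  shared <- rownames(study)[rownames(study) %in% shared]
  if (any(colnames(reference) %in% colnames(study)))
    stop2("study and reference sample IDs collide")
  combined <- cbind(study[shared, , drop = FALSE],
                    reference[shared, , drop = FALSE])
  origin <- rep(c("study", "reference"), c(ncol(study), ncol(reference)))
  res <- combat_adjust(combined, batch = origin, covariates = covariates, ...)
  out <- res$adjusted
  attr(out, "origin") <- stats::setNames(origin, colnames(combined))
  attr(out, "model") <- res$model
  out
}

#' Write a fitted batch-adjustment model as TSV
#'
#' One row per gene-by-batch combination with the raw and posterior
#' location/scale estimates, for inspection.
#'
#' @param model The `model` element of a [combat_adjust()] result.
#' @param path Output path.
#' @export
write_combat_model_tsv <- function(model, path) {
  nb <- length(model$batch_levels)
  genes <- rownames(model$gamma_hat) %||%
    sprintf("gene%05d", seq_len(nrow(model$gamma_hat)))
  tab <- do.call(rbind, lapply(seq_len(nb), function(b) {
    data.frame(gene_id = genes, batch = model$batch_levels[b],
               gamma_hat = model$gamma_hat[, b],
               delta2_hat = model$delta2_hat[, b],
               gamma_star = model$gamma_star[, b],
               delta2_star = model$delta2_star[, b])
  }))
  write_table_tsv(tab, path)
}
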