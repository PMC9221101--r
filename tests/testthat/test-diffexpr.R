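test_that("the trial design matrix has the expected columns and rank", {
  md <- balanced_metadata(n_per_arm = 5, batches = 2)
  X <- build_design(md)
  expect_identical(ncol(X), 8L)          # 1+1+2+1+1+2
  expect_identical(qr(X)$rank, 8L)
  ic <- attr(X, "interaction_cols")
  expect_named(ic, c("end", "post1wk"))
  expect_identical(colnames(X)[ic[["end"]]], "treatment:tp_end")
  # RIN is centered
  expect_lt(abs(sum(X[, "rin"])), 1e-10)

  md1 <- md; md1$batch <- "B1"
  X1 <- build_design(md1)
  expect_false(any(grepl("batch", colnames(X1))))

  md_na <- md; md_na$rin[3] <- NA
  expect_error(build_design(md_na), "missing RIN")
})

test_that("consensus correlation recovers known intra-subject correlation", {
  # subject intercept SD = noise SD: true ICC 0.5
  set.seed(40)
  nsub <- 30; k <- 3; G <- 500
  subj <- rep(sprintf("P%02d", 1:nsub), each = k)
  u <- matrix(rnorm(G * nsub), G, nsub)
  y <- u[, rep(1:nsub, each = k)] + matrix(rnorm(G * nsub * k), G, nsub * k)
  dimnames(y) <- list(sprintf("G%04d", 1:G), sprintf("s%03d", 1:(nsub * k)))
  X <- cbind(1, rep_len(c(0, 1), nsub * k))
  rho <- consensus_correlation(y, X, subj)
  expect_gte(as.numeric(rho), 0.42)
  expect_lte(as.numeric(rho), 0.58)

  # no subject effect: consensus near zero
  y0 <- matrix(rnorm(G * nsub * k), G, nsub * k, dimnames = dimnames(y))
  rho0 <- consensus_correlation(y0, X, subj)
  expect_lt(abs(as.numeric(rho0)), 0.08)

  # exact duplicates drive the estimate to the cap
  ydup <- y[, rep(seq(1, nsub * k, by = 3), each = 2)]
  colnames(ydup) <- sprintf("d%03d", seq_len(ncol(ydup)))
  subj2 <- rep(sprintf("Q%02d", 1:nsub), each = 2)
  rhod <- consensus_correlation(ydup, cbind(rep(1, ncol(ydup))), subj2)
  expect_gte(as.numeric(rhod), 0.98)

  expect_error(consensus_correlation(y[, 1:5], X[1:5, ],
                                     blocks = paste0("b", 1:5)),
               "singleton")
})

test_that("consensus correlation agrees with the mixed-model reference", {
  skip_if_not_installed("limma")
  set.seed(41)
  tr <- gen_trial(trial_params(n_subjects_per_arm = 10, n_genes = 200,
                               n_y_genes = 0, seed = 41))
  X <- build_design(tr$metadata)
  ours <- as.numeric(consensus_correlation(tr$matrix, X,
                                           attr(X, "blocks")))
  ref <- limma::duplicateCorrelation(tr$matrix, X,
                                     block = tr$metadata$subject_id)
  expect_lt(abs(ours - ref$consensus.correlation), 0.02)
})

test_that("GLS fitting equals whitened OLS and the dense-matrix oracle", {
  set.seed(42)
  md <- balanced_metadata(n_per_arm = 4)
  X <- build_design(md)
  G <- 20
  y <- random_matrix(G, nrow(md))
  colnames(y) <- md$sample_id
  rho <- 0.45
  fit <- fit_moderated(y, X, rho = rho, blocks = md$subject_id)

  # dense oracle: explicit block correlation matrix, eigen inverse sqrt
  n <- nrow(md)
  V <- diag(n)
  for (s in unique(md$subject_id)) {
    idx <- which(md$subject_id == s)
    V[idx, idx] <- rho
    diag(V)[] <- 1
  }
  e <- eigen(V, symmetric = TRUE)
  W <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  Xw <- W %*% X
  beta_oracle <- t(qr.coef(qr(Xw), W %*% t(y)))
  expect_lt(max(abs(fit$coefficients - beta_oracle)), 1e-8)

  # rho = 0 reduces exactly to gene-wise OLS
  fit0 <- fit_moderated(y, X, rho = 0)
  g <- 7
  ols <- lm.fit(X, y[g, ])
  expect_lt(max(abs(fit0$coefficients[g, ] - ols$coefficients)), 1e-10)
  s2 <- sum(ols$residuals^2) / ols$df.residual
  expect_equal(unname(fit0$sigma2[g]), s2, tolerance = 1e-10)
})

test_that("moderated statistics match the reference empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(43)
  tr <- gen_trial(trial_params(n_subjects_per_arm = 12, n_genes = 300,
                               n_responsive_genes = 30, n_y_genes = 0,
                               treatment_effect = 0.8, seed = 43))
  X <- build_design(tr$metadata)
  rho <- 0.4
  fit <- fit_moderated(tr$matrix, X, rho = rho,
                       blocks = tr$metadata$subject_id)
  lf <- limma::eBayes(limma::lmFit(tr$matrix, X,
                                   block = tr$metadata$subject_id,
                                   correlation = rho))
  expect_equal(fit$d0, lf$df.prior, tolerance = 1e-6)
  expect_equal(fit$s02, lf$s2.prior, tolerance = 1e-8)
  expect_lt(max(abs(fit$t - lf$t)), 1e-8)
  expect_lt(max(abs(fit$p - lf$p.value)), 1e-10)
})

test_that("variance-prior moment matching recovers generating hyperparameters", {
  set.seed(44)
  d0 <- 4; s02 <- 0.25; d <- 10; G <- 5000
  sigma2 <- d0 * s02 / rchisq(G, d0)        # scaled inverse-chi-square
  n <- d + 1
  y <- matrix(rnorm(G * n, 0, sqrt(sigma2)), G, n,
              dimnames = list(sprintf("G%05d", 1:G), sprintf("s%02d", 1:n)))
  fit <- fit_moderated(y, matrix(1, n, 1))
  expect_lt(abs(fit$d0 - d0) / d0, 0.2)
  expect_lt(abs(fit$s02 - s02) / s02, 0.05)
})

test_that("equal true variances drive the prior df large", {
  set.seed(45)
  G <- 3000; n <- 12
  y <- matrix(rnorm(G * n, 0, 0.7), G, n,
              dimnames = list(sprintf("G%05d", 1:G), sprintf("s%02d", 1:n)))
  fit <- fit_moderated(y, matrix(1, n, 1))
  expect_gt(fit$d0, 50)
  expect_lt(max(abs(fit$s2_post - fit$s02)) / fit$s02, 0.25)
})

test_that("interaction gene lists follow the p-value gate", {
  set.seed(46)
  tr <- gen_trial(trial_params(n_subjects_per_arm = 12, n_genes = 400,
                               n_responsive_genes = 40, n_y_genes = 0,
                               treatment_effect = 1.2, seed = 46))
  X <- build_design(tr$metadata)
  fit <- fit_moderated(tr$matrix, X, rho = 0)
  l0 <- interaction_gene_lists(fit, alpha = 0)
  expect_length(c(l0$end$up_genes, l0$end$down_genes), 0)
  l_tight <- interaction_gene_lists(fit, alpha = 0.001)
  l_loose <- interaction_gene_lists(fit, alpha = 0.01)
  expect_true(all(l_tight$end$up_genes %in% l_loose$end$up_genes))
  expect_true(all(l_tight$post1wk$down_genes %in%
                    l_loose$post1wk$down_genes))
  expect_length(intersect(l_loose$end$up_genes, l_loose$end$down_genes), 0)
})
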