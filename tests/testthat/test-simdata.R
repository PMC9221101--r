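test_that("reference generator is deterministic and hits its effect size", {
  p <- ref_params(n_genes = 500, n_signature_genes = 50, effect_size = 1.0,
                  noise_sd = 0.5, n_case = 20, n_control = 20, seed = 1)
  r1 <- gen_reference(p)
  r2 <- gen_reference(p)
  expect_identical(r1, r2)

  lab <- r1$class_labels
  delta <- rowMeans(r1$matrix[r1$signature_gene_ids, lab == "case"]) -
    rowMeans(r1$matrix[r1$signature_gene_ids, lab == "control"])
  expect_lt(abs(mean(delta) - 1.0), 0.1)

  null <- gen_reference(ref_params(effect_size = 0, seed = 2))
  dn <- rowMeans(null$matrix[, null$class_labels == "case"]) -
    rowMeans(null$matrix[, null$class_labels == "control"])
  expect_lt(abs(mean(dn)), 0.05)
  # per-gene differences stay within a generous Gaussian envelope
  expect_lt(max(abs(dn)), 5 * null$params$noise_sd * sqrt(2 / 20))

  expect_error(ref_params(n_genes = 10, n_signature_genes = 20),
               "n_signature_genes")
  expect_error(ref_params(noise_sd = 0), "noise_sd")
})

test_that("trial generator has the stated structure", {
  p <- trial_params(n_subjects_per_arm = 10, n_genes = 100, seed = 5)
  t1 <- gen_trial(p)
  expect_identical(t1, gen_trial(p))
  md <- t1$metadata
  expect_true(all(c("sample_id", "subject_id", "arm", "timepoint", "batch",
                    "rin", "sex") %in% names(md)))
  expect_false(anyDuplicated(md[, c("subject_id", "timepoint")]) > 0)
  expect_identical(nrow(t1$matrix), 100L + p$n_y_genes)

  # all nuisance terms off: i.i.d. noise around the gene baselines
  p0 <- trial_params(n_subjects_per_arm = 30, n_genes = 200,
                     treatment_effect = 0, subject_sd = 0,
                     batch_shift_sd = 0, batch_scale_sd = 0,
                     rin_slope_sd = 0, noise_sd = 0.5, var_df = Inf,
                     dropout_rate = 0, n_y_genes = 0, seed = 6)
  t0 <- gen_trial(p0)
  centered <- t0$matrix - rowMeans(t0$matrix)
  expect_lt(abs(sd(centered) - 0.5), 0.02)
  expect_lt(max(abs(colMeans(centered))), 4 * 0.5 / sqrt(200))

  # monotone dropout at the stated rate
  pd <- trial_params(n_subjects_per_arm = 150, n_genes = 5,
                     n_responsive_genes = 0, dropout_rate = 0.3,
                     n_y_genes = 0, seed = 7)
  td <- gen_trial(pd)
  frac_complete <- mean(table(td$metadata$subject_id) == 3)
  expect_lt(abs(frac_complete - 0.7), 4 * sqrt(0.3 * 0.7 / 300))
  n_tp <- tapply(td$metadata$timepoint, td$metadata$subject_id, function(x)
    all(x %in% c("baseline", "end", "post1wk")) &&
      "baseline" %in% x)
  expect_true(all(n_tp))

  expect_error(trial_params(n_genes = 10, n_responsive_genes = 20),
               "n_responsive_genes")
  expect_error(trial_params(dropout_rate = 1), "dropout_rate")
})

test_that("interaction test recovers most responsive genes at effect 1.0", {
  set.seed(99)
  hits <- replicate(25, {
    seed <- sample.int(1e6, 1)
    tr <- gen_trial(trial_params(n_subjects_per_arm = 20, n_genes = 1000,
                                 n_responsive_genes = 50,
                                 treatment_effect = 1.0, dropout_rate = 0,
                                 n_y_genes = 0, seed = seed))
    des <- build_design(tr$metadata)
    rho <- consensus_correlation(tr$matrix, des, attr(des, "blocks"),
                                 grid_step = 0.02)
    fit <- fit_moderated(tr$matrix, des, rho = as.numeric(rho),
                         blocks = attr(des, "blocks"))
    lists <- interaction_gene_lists(fit, alpha = 0.01)
    found <- c(lists$end$up_genes, lists$end$down_genes)
    mean(tr$responsive_gene_ids %in% found)
  })
  expect_gt(mean(hits), 0.6)
})

test_that("detection power is monotone in the treatment effect", {
  set.seed(1234)
  power_at <- function(effect) {
    mean(replicate(25, {
      tr <- gen_trial(trial_params(n_subjects_per_arm = 10, n_genes = 300,
                                   n_responsive_genes = 30,
                                   treatment_effect = effect,
                                   subject_sd = 0, dropout_rate = 0,
                                   n_y_genes = 0,
                                   seed = sample.int(1e6, 1)))
      des <- build_design(tr$metadata)
      fit <- fit_moderated(tr$matrix, des, rho = 0)
      j <- fit$interaction_cols[["end"]]
      mean(fit$p[tr$responsive_gene_ids, j] < 0.01)
    }))
  }
  pw <- vapply(c(0, 0.25, 0.5, 1.0), power_at, numeric(1))
  expect_true(all(diff(pw) > -0.1))    # Monte-Carlo slack at 25 replicates
  expect_gt(pw[4], pw[1] + 0.3)
  expect_lt(pw[1], 0.05)
})

test_that("analyte generator carries the multiplicative structure", {
  md <- balanced_metadata(n_per_arm = 200)
  p <- analyte_params(gender_ratio = 1.5, treatment_ratio_lte4 = 1,
                      treatment_ratio_pgem = 1, cv = 0.5, seed = 3)
  an <- gen_analytes(p, md)
  expect_identical(an, gen_analytes(p, md))
  expect_equal(an$normalized, an$raw / an$creatinine, tolerance = 1e-12)

  lt <- an[an$analyte == "LTE4" & an$timepoint == "baseline", ]
  sex <- md$sex[match(lt$subject_id, md$subject_id)]
  gm <- function(x) exp(mean(log(x)))
  ratio <- gm(lt$normalized[sex == "female"]) /
    gm(lt$normalized[sex == "male"])
  expect_lt(abs(ratio - 1.5), 0.15)

  # null treatment ratio: no arm difference in log-changes
  arm <- md$arm[match(lt$subject_id, md$subject_id)]
  lte <- an[an$analyte == "LTE4", ]
  ch <- log(lte$normalized[lte$timepoint == "end"]) -
    log(lte$normalized[lte$timepoint == "baseline"])
  expect_lt(abs(mean(ch[arm == "treatment"]) - mean(ch[arm == "placebo"])),
            0.2)
  expect_error(gen_analytes(p, md[, setdiff(names(md), "sex")]), "sex")
})

test_that("suppressed analyte is detected by the log-scale arm test", {
  set.seed(321)
  md <- balanced_metadata(n_per_arm = 20)
  hits <- replicate(25, {
    an <- gen_analytes(analyte_params(treatment_ratio_lte4 = 0.4, cv = 0.5,
                                      seed = sample.int(1e6, 1)), md)
    res <- analyte_change_tests(an, md, log_scale = TRUE)
    res$LTE4$between_arms$all.change_post$p < 0.01
  })
  expect_gte(mean(hits), 0.8)
})
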