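test_that("enrichment score matches exhaustive enumeration for small lists", {
  set.seed(50)
  for (N in c(5, 8, 12)) {
    stat <- setNames(sort(rnorm(N), decreasing = TRUE) * 2,
                     sprintf("g%02d", 1:N))
    for (sz in 2:(N - 1)) {
      for (rep in 1:3) {
        members <- sample(names(stat), sz)
        for (w in c(0, 1)) {
          res <- gsea_preranked(stat, list(s = members), weight = w,
                                n_perm = 10, seed = 1)
          oracle <- brute_force_es(stat, names(stat) %in% members, w)
          expect_equal(res$ES, oracle, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("enrichment score agrees with the reference preranked method", {
  skip_if_not_installed("fgsea")
  set.seed(51)
  stat <- setNames(rnorm(500), sprintf("G%04d", 1:500))
  sets <- list(a = sample(names(stat), 30), b = sample(names(stat), 12),
               c = names(stat)[order(-stat)][1:20])
  ours <- gsea_preranked(stat, sets, n_perm = 100, seed = 2)
  ref <- suppressWarnings(fgsea::fgsea(sets, stat, nPermSimple = 100))
  expect_equal(ours$ES, ref$ES[match(ours$set, ref$pathway)],
               tolerance = 1e-10)
})

test_that("reversing the ranking negates the unweighted score", {
  set.seed(52)
  stat <- setNames(sample(seq(-3, 3, length.out = 40)),
                   sprintf("g%02d", 1:40))
  members <- sample(names(stat), 8)
  es_fwd <- gsea_preranked(stat, list(s = members), weight = 0,
                           n_perm = 10, seed = 1)$ES
  es_rev <- gsea_preranked(-stat, list(s = members), weight = 0,
                           n_perm = 10, seed = 1)$ES
  expect_equal(es_rev, -es_fwd, tolerance = 1e-12)
})

test_that("random gene sets look null in NES and FDR", {
  set.seed(53)
  stat <- setNames(rnorm(400), sprintf("G%04d", 1:400))
  draws <- do.call(rbind, lapply(1:20, function(i) {
    sets <- lapply(1:10, function(k) sample(names(stat), 25))
    names(sets) <- paste0("r", 1:10)
    res <- gsea_preranked(stat, sets, n_perm = 200,
                          seed = sample.int(1e6, 1))
    res[, c("NES", "qval")]
  }))
  # the signed extremum lands positive slightly more often than negative
  # under the weighted statistic, so the null NES mean sits near but not
  # exactly at zero
  expect_lt(abs(mean(draws$NES)), 0.25)
  expect_gte(mean(draws$qval > 0.25), 0.9)
})

test_that("q-values are monotone in |NES| within each sign pool", {
  set.seed(54)
  stat <- setNames(rnorm(300), sprintf("G%04d", 1:300))
  sets <- c(lapply(1:8, function(i) sample(names(stat), 20)),
            list(top = names(stat)[order(-stat)][1:20],
                 bottom = names(stat)[order(stat)][1:20]))
  names(sets)[1:8] <- paste0("rand", 1:8)
  res <- gsea_preranked(stat, sets, n_perm = 300, seed = 3)
  for (sgn in c(-1, 1)) {
    pool <- res[sign(res$NES) == sgn, ]
    pool <- pool[order(-abs(pool$NES)), ]
    expect_true(all(diff(pool$qval) >= -1e-12))
  }
})

test_that("concordance flags self-enrichment and flips with swapped sets", {
  set.seed(55)
  stat <- setNames(rnorm(600), sprintf("G%04d", 1:600))
  up <- names(stat)[order(-stat)][1:40]
  down <- names(stat)[order(stat)][1:40]
  res <- concordance_enrichment(stat, up, down, n_perm = 300, seed = 4)
  expect_true(attr(res, "concordant"))
  swapped <- concordance_enrichment(stat, down, up, n_perm = 300, seed = 4)
  expect_equal(sort(swapped$ES), sort(-res$ES), tolerance = 1e-10)
  expect_false(attr(swapped, "concordant"))
  expect_warning(
    res1 <- concordance_enrichment(stat, up, character(0), n_perm = 100,
                                   seed = 4),
    "empty signature")
  expect_false(attr(res1, "concordant"))
})

test_that("independent null signatures are rarely called concordant", {
  set.seed(56)
  stat <- setNames(rnorm(300), sprintf("G%04d", 1:300))
  flags <- replicate(60, {
    up <- sample(names(stat), 20)
    down <- sample(setdiff(names(stat), up), 20)
    attr(concordance_enrichment(stat, up, down, n_perm = 150,
                                seed = sample.int(1e6, 1)), "concordant")
  })
  expect_lte(mean(flags), 0.05)
})

test_that("per-sample set scores behave as a rank statistic", {
  set.seed(57)
  m <- random_matrix(200, 20)
  sets <- list(A = rownames(m)[1:15], B = rownames(m)[101:120])
  # identical columns get identical score rows
  m2 <- m
  m2[, 2] <- m2[, 1]
  s2 <- sample_set_scores(m2, sets)
  expect_equal(s2[1, ], s2[2, ], tolerance = 1e-12)

  # raising the set genes of one sample raises that sample's score
  s0 <- sample_set_scores(m, sets)
  m3 <- m
  m3[sets$A, 5] <- m3[sets$A, 5] + 3
  s3 <- sample_set_scores(m3, sets)
  expect_gt(s3[5, "A"], s0[5, "A"])

  # with the rank-based CDF the score is exactly invariant to monotone
  # per-gene transforms; the kernel CDF preserves it approximately
  mono <- m
  mono[1:100, ] <- exp(m[1:100, ] / 3)
  mono[101:200, ] <- m[101:200, ]^3 + 10
  se0 <- sample_set_scores(m, sets, kernel = "ecdf")
  expect_equal(sample_set_scores(mono, sets, kernel = "ecdf"), se0,
               tolerance = 1e-12)
  expect_gt(cor(as.vector(sample_set_scores(mono, sets)), as.vector(s0)),
            0.9)

  # constant genes are dropped with a warning
  m4 <- m
  m4[50, ] <- 1
  expect_warning(sample_set_scores(m4, sets), "constant genes")
})

test_that("random-set sample scores center near zero", {
  set.seed(58)
  m <- random_matrix(1000, 50)
  sets <- list(r = sample(rownames(m), 40))
  s <- sample_set_scores(m, sets)
  expect_lt(abs(mean(s)), 0.1)
})

test_that("score-analyte change correlations use average ranks and arms", {
  md <- balanced_metadata(n_per_arm = 8)
  subj <- unique(md$subject_id)
  set.seed(59)
  sc <- matrix(rnorm(nrow(md)), nrow(md), 1,
               dimnames = list(md$sample_id, "SIG"))
  an <- gen_analytes(analyte_params(seed = 59), md)
  # analyte change as a monotone function of score change: rho = 1
  for (s in subj) {
    d <- sc[paste0(s, "_end"), 1] - sc[paste0(s, "_baseline"), 1]
    sel <- an$analyte == "LTE4" & an$subject_id == s & an$timepoint == "end"
    base <- an$normalized[an$analyte == "LTE4" & an$subject_id == s &
                            an$timepoint == "baseline"]
    an$normalized[sel] <- base + exp(d)
  }
  res <- change_correlation(sc, an, md, arm = "treatment")
  expect_equal(res$rho[res$analyte == "LTE4"], 1, tolerance = 1e-12)
  expect_identical(unique(res$n), 8L)
  expect_false(any(res$unreliable))

  # tied values give the mid-rank result
  sc2 <- sc
  sc2[, 1] <- 0
  sc2[paste0(subj, "_end"), 1] <- rep(c(0, 1, 1, 2), 4)
  sc2[paste0(subj, "_baseline"), 1] <- 0
  res2 <- change_correlation(sc2, an, md, arm = "placebo")
  plc <- subj[md$arm[match(subj, md$subject_id)] == "placebo"]
  dx <- sc2[paste0(plc, "_end"), 1] - sc2[paste0(plc, "_baseline"), 1]
  dy <- vapply(plc, function(s) {
    v <- an[an$analyte == "PGEM" & an$subject_id == s, ]
    v$normalized[v$timepoint == "end"] - v$normalized[v$timepoint == "baseline"]
  }, numeric(1))
  oracle <- cor(rank(dx), rank(dy))      # mid-rank Spearman
  expect_equal(res2$rho[res2$analyte == "PGEM"], oracle, tolerance = 1e-12)
})

test_that("null score-analyte correlations are uniform in p", {
  md <- balanced_metadata(n_per_arm = 10)
  set.seed(60)
  pvals <- replicate(200, {
    sc <- matrix(rnorm(nrow(md)), nrow(md), 1,
                 dimnames = list(md$sample_id, "SIG"))
    an <- gen_analytes(analyte_params(seed = sample.int(1e6, 1)), md)
    change_correlation(sc, an, md, arm = "treatment")$p[1]
  })
  # small-n Spearman p-values are discrete, hence tied
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})
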