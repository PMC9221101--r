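# Weighted Kolmogorov-Smirnov running sum over a ranked list.
# stats_sorted: statistic in ranked (descending) order; member: logical.
# Returns the signed extremum of the walk (largest absolute deviation).
running_es <- function(stats_sorted, member, weight = 1) {
  N <- length(stats_sorted)
  Nh <- sum(member)
  w <- abs(stats_sorted)^weight
  hit <- ifelse(member, w, 0)
  denom <- sum(hit)
  if (denom == 0) hit <- ifelse(member, 1, 0) / max(Nh, 1)
  else hit <- hit / denom
  miss <- ifelse(member, 0, 1 / (N - Nh))
  walk <- cumsum(hit - miss)
  walk[which.max(abs(walk))]
}

#' Pre-ranked gene-set enrichment
#'
#' Classical pre-ranked GSEA: genes are sorted by the supplied statistic
#' (descending, ties broken by gene ID for determinism); the running sum
#' increments by `|stat|^weight` (normalized over set members) at member
#' genes and decrements by `1/(N - Nh)` elsewhere; the enrichment score
#' (ES) is the signed extremum. The null is built from `n_perm` random
#' gene sets of the same size (gene-set permutation -- the only scheme
#' available for a ranked-list input); NES divides ES by the mean of
#' same-sign null ES, the nominal p is the same-sign null tail fraction,
#' and FDR q follows the positive/negative-pool convention, made monotone
#' in |NES| within each sign pool.
#'
#' @param ranked Named numeric vector: per-gene ranking statistic, no
#'   missing values.
#' @param sets Named list of gene-ID character vectors.
#' @param weight Weighting exponent on the statistic (default 1; 0 gives
#'   the classical unweighted KS statistic).
#' @param n_perm Number of random-set permutations (default 1000).
#' @param seed Integer seed for the permutation null.
#' @return A data.frame of class `enrichment_result`: set, size, ES, NES,
#'   pval, qval; `n_perm` and `seed` are carried as attributes.
#' @export
gsea_preranked <- function(ranked, sets, weight = 1, n_perm = 1000,
                           seed = 1L) {
  if (is.null(names(ranked)) || anyNA(ranked))
    stop2("ranked must be a named numeric vector without missing values")
  ord <- order(-ranked, names(ranked))
  stats_sorted <- ranked[ord]
  genes_sorted <- names(stats_sorted)
  N <- length(ranked)

  sizes <- vapply(sets, function(s) sum(genes_sorted %in% s), 0L)
  if (any(sizes >= N))
    stop2("gene set covering every ranked gene: ",
          names(sets)[sizes >= N][1])
  drop <- sizes < 2
  if (any(drop)) {
    warning("dropping sets intersecting the ranking in < 2 genes: ",
            paste(names(sets)[drop], collapse = ", "), call. = FALSE)
    sets <- sets[!drop]
    sizes <- sizes[!drop]
  }
  if (!length(sets)) stop2("no usable gene sets")

  es <- vapply(seq_along(sets), function(i)
    running_es(stats_sorted, genes_sorted %in% sets[[i]], weight),
    numeric(1))

  set.seed(seed)
  usizes <- sort(unique(sizes))
  null_by_size <- lapply(usizes, function(sz) {
    vapply(seq_len(n_perm), function(j) {
      member <- logical(N)
      member[sample.int(N, sz)] <- TRUE
      running_es(stats_sorted, member, weight)
    }, numeric(1))
  })
  names(null_by_size) <- as.character(usizes)

  nes_of <- function(e, null) {
    if (e >= 0) {
      mpos <- mean(null[null > 0])
      if (!is.finite(mpos) || mpos == 0) return(NA_real_)
      e / mpos
    } else {
      mneg <- mean(abs(null[null < 0]))
      if (!is.finite(mneg) || mneg == 0) return(NA_real_)
      e / mneg
    }
  }
  nes <- pval <- numeric(length(sets))
  null_nes_all <- numeric(0)
  for (i in seq_along(sets)) {
    null <- null_by_size[[as.character(sizes[i])]]
    nes[i] <- nes_of(es[i], null)
    same <- if (es[i] >= 0) null[null >= 0] else null[null <= 0]
    pval[i] <- if (!length(same)) 1 else
      mean(abs(same) >= abs(es[i]))
  }
  # pooled null NES for the FDR: every permutation of every set, normalized
  for (i in seq_along(sets)) {
    null <- null_by_size[[as.character(sizes[i])]]
    null_nes_all <- c(null_nes_all,
                      vapply(null, nes_of, numeric(1), null = null))
  }
  null_nes_all <- null_nes_all[is.finite(null_nes_all)]
  qval <- vapply(seq_along(sets), function(i) {
    s <- nes[i]
    if (!is.finite(s)) return(NA_real_)
    if (s >= 0) {
      num_pool <- null_nes_all[null_nes_all >= 0]
      obs_pool <- nes[nes >= 0 & is.finite(nes)]
      num <- if (length(num_pool)) mean(num_pool >= s) else 0
      den <- mean(obs_pool >= s)
    } else {
      num_pool <- null_nes_all[null_nes_all <= 0]
      obs_pool <- nes[nes <= 0 & is.finite(nes)]
      num <- if (length(num_pool)) mean(num_pool <= s) else 0
      den <- mean(obs_pool <= s)
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))
  # enforce monotone q in |NES| within each sign pool
  for (sgn in c(1, -1)) {
    idx <- which(is.finite(nes) & sign(nes) == sgn | (sgn == 1 & nes == 0))
    if (length(idx) > 1) {
      o <- idx[order(-abs(nes[idx]))]
      qval[o] <- cummax(qval[o])
      qval[o] <- rev(cummin(rev(qval[o])))
    }
  }
  out <- data.frame(set = names(sets), size = as.integer(sizes),
                    ES = es, NES = nes, pval = pval, qval = qval,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("enrichment_result", "data.frame")
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  out
}

#' Concordance enrichment of one signature in another ranking
#'
#' Tests whether the up- and downregulated gene lists from one contrast are
#' concordantly enriched at the top and bottom of another contrast's ranked
#' list: the `concordant` flag is set when the up-set ES is positive, the
#' down-set ES is negative, and both carry FDR q below `fdr`.
#'
#' @param ranking_a Named ranking statistic (e.g., moderated t for the
#'   end-of-treatment interaction).
#' @param signature_b_up,signature_b_down Gene-ID vectors (e.g., the
#'   one-week-post interaction lists).
#' @param fdr Concordance FDR threshold (default 0.05).
#' @param ... Passed to [gsea_preranked()].
#' @return The [gsea_preranked()] table for the non-empty sets, with
#'   attribute `concordant`.
#' @export
concordance_enrichment <- function(ranking_a, signature_b_up,
                                   signature_b_down, fdr = 0.05, ...) {
  sets <- list(up = signature_b_up, down = signature_b_down)
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning("empty signature set skipped: ",
            paste(names(sets)[empty], collapse = ", "), call. = FALSE)
    sets <- sets[!empty]
  }
  if (!length(sets)) {
    out <- data.frame(set = character(0), size = integer(0), ES = numeric(0),
                      NES = numeric(0), pval = numeric(0), qval = numeric(0))
    attr(out, "concordant") <- FALSE
    return(out)
  }
  res <- gsea_preranked(ranking_a, sets, ...)
  up_ok <- "up" %in% res$set &&
    res$ES[res$set == "up"] > 0 && res$qval[res$set == "up"] < fdr
  down_ok <- "down" %in% res$set &&
    res$ES[res$set == "down"] < 0 && res$qval[res$set == "down"] < fdr
  attr(res, "concordant") <- isTRUE(up_ok) && isTRUE(down_ok) &&
    all(c("up", "down") %in% res$set)
  res
}

#' Per-sample gene-set scores
#'
#' Rank-based single-sample scoring in the style of gene-set variation
#' analysis: each gene's expression is mapped through a Gaussian-kernel
#' smoothed cross-sample CDF (bandwidth = gene SD / 4); within each sample,
#' genes are ranked by these values and a weighted KS random walk is run
#' over the ranking with weight `|N/2 - rank|` (exponent 1, normalized over
#' set members) at member genes; the score is the walk's maximum deviation
#' from zero (signed extremum). Constant genes carry no rank information
#' and are dropped with a warning.
#'
#' @param matrix Genes-by-samples expression matrix.
#' @param sets Named list of gene-ID vectors; each must intersect the
#'   (non-constant) genes in at least 2 members.
#' @param kernel `"gaussian"` (default) for the kernel-smoothed CDF, or
#'   `"ecdf"` for the plain empirical CDF (average-tie ranks), which makes
#'   the score exactly invariant to monotone per-gene transforms.
#' @return A samples-by-sets numeric matrix of class `sample_set_scores`.
#' @export
sample_set_scores <- function(matrix, sets,
                              kernel = c("gaussian", "ecdf")) {
  kernel <- match.arg(kernel)
  check_expression_matrix(matrix)
  s <- sqrt(row_vars(matrix))
  if (any(s == 0)) {
    warning("dropping constant genes: ", sum(s == 0), call. = FALSE)
    matrix <- matrix[s > 0, , drop = FALSE]
    s <- s[s > 0]
  }
  G <- nrow(matrix); n <- ncol(matrix)
  if (G < 2) stop2("need at least 2 non-constant genes")
  bw <- s / 4
  # kernel-smoothed ECDF value of each cell against its own gene's samples
  F <- matrix(0, G, n, dimnames = dimnames(matrix))
  for (g in seq_len(G)) {
    x <- matrix[g, ]
    F[g, ] <- if (kernel == "gaussian")
      rowMeans(stats::pnorm(outer(x, x, `-`) / bw[g]))
    else rank(x) / n
  }
  genes <- rownames(matrix)
  sizes <- vapply(sets, function(st) sum(genes %in% st), 0L)
  if (any(sizes < 2))
    stop2("gene sets intersecting < 2 genes: ",
          paste(names(sets)[sizes < 2], collapse = ", "))
  member_mask <- lapply(sets, function(st) genes %in% st)
  out <- matrix(0, n, length(sets),
                dimnames = list(colnames(matrix), names(sets)))
  half <- G / 2
  for (j in seq_len(n)) {
    ord <- order(-F[, j], genes)
    rnk <- seq_len(G)
    wdev <- abs(half - rnk)                 # rank deviation weight, tau = 1
    for (k in seq_along(sets)) {
      member <- member_mask[[k]][ord]
      hit <- ifelse(member, wdev, 0)
      hit <- hit / sum(hit)
      miss <- ifelse(member, 0, 1 / (G - sizes[k]))
      walk <- cumsum(hit - miss)
      out[j, k] <- walk[which.max(abs(walk))]
    }
  }
  class(out) <- c("sample_set_scores", class(out))
  out
}

#' Correlate gene-set score changes with analyte changes
#'
#' For each gene set and analyte, computes the Spearman rank correlation of
#' per-subject changes (`to_tp - from_tp`) in the set score against changes
#' in the creatinine-normalized analyte, within one arm, restricted to
#' subjects with samples at all three timepoints. Ties are handled by
#' average ranks.
#'
#' @param scores A samples-by-sets matrix from [sample_set_scores()].
#' @param analytes Long-format analyte table (see [gen_analytes()]).
#' @param metadata Sample metadata joinable by `sample_id`.
#' @param arm Which arm to analyze (`"treatment"` or `"placebo"`).
#' @param from_tp,to_tp Timepoints defining the change.
#' @return A data.frame: set, analyte, rho, p, n, unreliable (fewer than 4
#'   paired subjects).
#' @export
change_correlation <- function(scores, analytes, metadata,
                               arm = "treatment",
                               from_tp = "baseline", to_tp = "end") {
  md <- check_metadata(metadata,
                       c("sample_id", "subject_id", "arm", "timepoint"))
  md <- md[md$sample_id %in% rownames(scores), , drop = FALSE]
  ev <- evaluable_subjects(md, unique(metadata$timepoint))
  md <- md[md$subject_id %in% ev & md$arm == arm, , drop = FALSE]
  subj <- unique(md$subject_id)
  sid <- function(s, tp) md$sample_id[md$subject_id == s & md$timepoint == tp]
  out <- list()
  for (set in colnames(scores)) {
    dscore <- vapply(subj, function(s)
      scores[sid(s, to_tp), set] - scores[sid(s, from_tp), set], numeric(1))
    for (an in unique(analytes$analyte)) {
      at <- analytes[analytes$analyte == an, ]
      aval <- function(s, tp) {
        v <- at$normalized[at$subject_id == s & at$timepoint == tp]
        if (length(v) != 1) NA_real_ else v
      }
      dan <- vapply(subj, function(s)
        aval(s, to_tp) - aval(s, from_tp), numeric(1))
      ok <- is.finite(dscore) & is.finite(dan)
      n_ok <- sum(ok)
      if (n_ok >= 2) {
        ct <- suppressWarnings(
          stats::cor.test(dscore[ok], dan[ok], method = "spearman",
                          exact = FALSE))
        rho <- unname(ct$estimate); pv <- ct$p.value
      } else {
        rho <- NA_real_; pv <- NA_real_
      }
      out[[length(out) + 1L]] <-
        data.frame(set = set, analyte = an, rho = rho, p = pv, n = n_ok,
                   unreliable = n_ok < 4, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
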