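#' Score study samples against a reference signature
#'
#' The signature-transfer pipeline: harmonize the study matrix with the
#' reference via [harmonize_with_reference()], z-score every gene across
#' the combined samples, restrict to the signature genes shared by both
#' datasets, fit PCA on the reference samples only (samples as
#' observations, genes centered at their reference means), and project all
#' samples onto the first loading vector. The axis is oriented so that the
#' `orientation_class` reference samples score higher on average; a
#' decreasing score in the study arm is then movement away from the
#' disease/exposure class.
#'
#' @param study Genes-by-samples study matrix (log2 scale).
#' @param reference A `reference_signature_dataset` (see [gen_reference()]):
#'   list with `matrix`, `class_labels`, `signature_gene_ids`, and
#'   `orientation_class`.
#' @param harmonize Set `FALSE` to skip the batch harmonization step (for
#'   data already on a common scale).
#' @return A data.frame of class `signature_score_table`: `sample_id`,
#'   `score`, `origin` (`"study"`/`"reference"`); the number of signature
#'   genes dropped for being absent is in attribute `n_dropped_genes`.
#' @export
signature_scores <- function(study, reference, harmonize = TRUE) {
  check_expression_matrix(study, "study")
  ref <- reference
  check_expression_matrix(ref$matrix, "reference$matrix")
  labels <- ref$class_labels[colnames(ref$matrix)]
  classes <- unique(labels)
  if (length(classes) != 2 || any(table(labels) < 2))
    stop2("reference needs two classes with at least 2 samples each")
  orient <- ref$orientation_class %||% classes[1]

  if (harmonize) {
    merged <- harmonize_with_reference(study, ref$matrix)
    origin <- attr(merged, "origin")
  } else {
    shared <- intersect(rownames(study), rownames(ref$matrix))
    if (!length(shared)) stop2("study and reference share no gene IDs")
    merged <- cbind(study[shared, , drop = FALSE],
                    ref$matrix[shared, , drop = FALSE])
    origin <- stats::setNames(
      rep(c("study", "reference"), c(ncol(study), ncol(ref$matrix))),
      colnames(merged))
  }
  z <- zscore_genes(merged)
  sig <- intersect(ref$signature_gene_ids, rownames(z))
  n_dropped <- length(ref$signature_gene_ids) - length(sig)
  if (n_dropped > 0)
    message(n_dropped, " signature gene(s) absent from the combined matrix")
  if (length(sig) < 2) stop2("fewer than 2 signature genes available")
  zs <- z[sig, , drop = FALSE]

  is_ref <- origin == "reference"
  ref_means <- rowMeans(zs[, is_ref, drop = FALSE])
  centered <- zs - ref_means
  sv <- svd(t(centered[, is_ref, drop = FALSE]), nu = 0, nv = 1)
  loading <- drop(sv$v)
  scores <- drop(crossprod(centered, loading))
  ref_labels <- labels[colnames(zs)[is_ref]]
  if (mean(scores[is_ref][ref_labels == orient]) <
      mean(scores[is_ref][ref_labels != orient]))
    scores <- -scores
  out <- data.frame(sample_id = colnames(zs), score = unname(scores),
                    origin = unname(origin), stringsAsFactors = FALSE)
  class(out) <- c("signature_score_table", "data.frame")
  attr(out, "n_dropped_genes") <- n_dropped
  out
}

# Subjects having every timepoint level present in the metadata
evaluable_subjects <- function(metadata,
                               timepoints = timepoint_levels()) {
  tab <- table(metadata$subject_id,
               factor(metadata$timepoint, levels = timepoints))
  rownames(tab)[apply(tab >= 1, 1, all)]
}

#' Test arm differences in signature-score changes
#'
#' Restricts to evaluable subjects (those with samples at all three
#' timepoints), computes each subject's score change `to_tp - from_tp`,
#' and returns the two-sample t-test of changes between arms together with
#' within-arm paired t-tests and gender-stratified versions of both.
#'
#' @param scores A `signature_score_table` (study rows are used).
#' @param metadata Sample metadata joinable by `sample_id`.
#' @param from_tp,to_tp Timepoint labels defining the change.
#' @param pooled Use the pooled-variance two-sample t-test (default) or
#'   Welch.
#' @return A list of class `score_change_result`: `between_arms`
#'   (test result), `paired` (per-arm one-sample tests of the change),
#'   `by_sex` (the same pair of analyses per gender stratum), `changes`
#'   (per-subject change table), and `n_evaluable`.
#' @export
score_change_test <- function(scores, metadata, from_tp = "baseline",
                              to_tp = "end", pooled = TRUE) {
  md <- metadata
  check_metadata(md, c("sample_id", "subject_id", "arm", "timepoint", "sex"))
  stud <- scores[scores$origin %in% "study", , drop = FALSE]
  if (!nrow(stud)) stud <- scores
  md <- md[md$sample_id %in% stud$sample_id, , drop = FALSE]
  ev <- evaluable_subjects(md, unique(metadata$timepoint))
  md <- md[md$subject_id %in% ev, , drop = FALSE]
  md$score <- stud$score[match(md$sample_id, stud$sample_id)]

  wide <- function(tp) {
    sel <- md[md$timepoint == tp, ]
    stats::setNames(sel$score, sel$subject_id)
  }
  s_from <- wide(from_tp)
  s_to <- wide(to_tp)
  subj <- intersect(names(s_from), names(s_to))
  info <- unique(md[, c("subject_id", "arm", "sex")])
  changes <- data.frame(subject_id = subj,
                        arm = info$arm[match(subj, info$subject_id)],
                        sex = info$sex[match(subj, info$subject_id)],
                        change = unname(s_to[subj] - s_from[subj]),
                        stringsAsFactors = FALSE)

  analyze <- function(ch) {
    arms <- split(ch$change, ch$arm)
    if (length(arms) < 2 || any(lengths(arms) < 2))
      stop2("each arm needs at least 2 evaluable subjects")
    trt <- arms[["treatment"]]; plc <- arms[["placebo"]]
    between <- ttest_from_summary(mean(trt), sd1(trt), length(trt),
                                  mean(plc), sd1(plc), length(plc),
                                  pooled = pooled)
    paired <- lapply(arms, function(x) {
      if (length(x) < 2 || sd1(x) == 0)
        return(list(flagged = TRUE, reason = "degenerate stratum"))
      tt <- stats::t.test(x)
      list(estimate = mean(x), t = unname(tt$statistic),
           df = unname(tt$parameter), p = tt$p.value,
           mean = mean(x), sd = sd1(x), n = length(x), flagged = FALSE)
    })
    list(between_arms = between, paired = paired)
  }
  overall <- analyze(changes)
  by_sex <- lapply(split(changes, changes$sex), function(ch)
    tryCatch(analyze(ch), error = function(e)
      list(flagged = TRUE, reason = conditionMessage(e))))
  structure(list(between_arms = overall$between_arms,
                 paired = overall$paired, by_sex = by_sex,
                 changes = changes, n_evaluable = length(subj)),
            class = "score_change_result")
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance (default) or Welch two-sided two-sample t-test computed
#' from group means, SDs, and sizes alone -- the form needed to reproduce
#' published-table p-values from printed summaries.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @param pooled Pooled-variance test if `TRUE` (default), Welch otherwise.
#' @return A list of class `summary_ttest`: `estimate` (mean1 - mean2),
#'   `t`, `df`, `p`, and per-group summaries.
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                               pooled = TRUE) {
  if (any(c(n1, n2) < 2)) stop2("each group needs n >= 2")
  if (any(c(sd1, sd2) < 0)) stop2("SDs must be >= 0")
  if (sd1 == 0 && sd2 == 0) stop2("at least one SD must be positive")
  se2_1 <- sd1^2 / n1
  se2_2 <- sd2^2 / n2
  if (pooled) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(se2_1 + se2_2)
    df <- (se2_1 + se2_2)^2 /
      (se2_1^2 / (n1 - 1) + se2_2^2 / (n2 - 1))
  }
  est <- mean1 - mean2
  t <- if (est == 0) 0 else est / se
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(estimate = est, t = t, df = df, p = p,
                 groups = data.frame(mean = c(mean1, mean2),
                                     sd = c(sd1, sd2), n = c(n1, n2)),
                 pooled = pooled),
            class = "summary_ttest")
}

#' @export
print.summary_ttest <- function(x, ...) {
  cat(sprintf("%s two-sample t-test: estimate = %.4g, t = %.4g, df = %.4g, p = %.4g\n",
              if (x$pooled) "Pooled" else "Welch",
              x$estimate, x$t, x$df, x$p))
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value over the hypergeometric support with fixed
#' margins: the sum of probabilities of all tables no more likely than the
#' observed one, with a relative tolerance of 1e-7 on the comparison.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise
#'   (`a b / c d`).
#' @return The two-sided p-value.
#' @export
fisher2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop2("cell counts must be non-negative integers")
  if (a + b + c + d == 0) stop2("table margins must be positive")
  m <- a + b            # row 1 total
  n <- c + d            # row 2 total
  k <- a + c            # column 1 total
  support <- max(0, k - n):min(m, k)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}
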