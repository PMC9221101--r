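#' Pipeline configuration
#'
#' Collects every stage's parameters and toggles with defaults matching the
#' analysis conventions used throughout the package: interaction gate at
#' p < 0.01, concordance FDR < 0.05, pathway-collection FDR < 0.25, PC1
#' outlier threshold of 2 SD, 1000 gene-set permutations, pooled-variance
#' t-tests.
#'
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @param trial [trial_params()] for the simulated study (or `NULL` to
#'   supply `matrix`/`metadata`/`analytes` yourself).
#' @param reference [ref_params()] for the simulated reference signature
#'   dataset.
#' @param analyte [analyte_params()] for the simulated analyte table.
#' @param alpha Interaction p-value gate for the gene lists.
#' @param concordance_fdr,pathway_fdr FDR thresholds for the two enrichment
#'   readouts.
#' @param n_perm Permutations for the enrichment null.
#' @param sd_threshold PC1 outlier threshold (SD units).
#' @param pooled Pooled-variance (vs Welch) two-sample t-tests.
#' @param stages Character vector of stages to run, a subset of
#'   `c("qc", "residualize", "score", "de", "enrich", "analytes")`.
#' @param pathway_sets Optional named list of gene sets for the
#'   pathway-collection enrichment; when `NULL`, a synthetic collection of
#'   random sets plus the truly responsive set is built.
#' @param matrix,metadata,analytes Supply data directly instead of
#'   simulating.
#' @param outdir Optional directory; when set, stage artifacts are written
#'   there as TSV.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            trial = trial_params(seed = seed),
                            reference = ref_params(seed = seed + 1L),
                            analyte = analyte_params(seed = seed + 2L),
                            alpha = 0.01, concordance_fdr = 0.05,
                            pathway_fdr = 0.25, n_perm = 1000,
                            sd_threshold = 2, pooled = TRUE,
                            stages = c("qc", "residualize", "score", "de",
                                       "enrich", "analytes"),
                            pathway_sets = NULL,
                            matrix = NULL, metadata = NULL,
                            analytes = NULL, outdir = NULL) {
  structure(list(seed = as.integer(seed), trial = trial,
                 reference = reference, analyte = analyte, alpha = alpha,
                 concordance_fdr = concordance_fdr,
                 pathway_fdr = pathway_fdr, n_perm = n_perm,
                 sd_threshold = sd_threshold, pooled = pooled,
                 stages = stages, pathway_sets = pathway_sets,
                 matrix = matrix, metadata = metadata,
                 analytes = analytes, outdir = outdir),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop2("pipeline stage '", name, "' failed: ", conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data simulation (unless data is supplied), sample
#' QC (PC1 outliers, sex verification), RIN residualization, signature
#' scoring against the reference with arm change tests, moderated
#' differential expression with the consensus within-subject correlation,
#' concordance and pathway-collection enrichment, per-sample gene-set
#' scoring with analyte correlations, and analyte change tests. Each stage
#' logs its input/output shapes and dropped samples; the whole run is a
#' pure function of the configuration (seeds included).
#'
#' @param config A [pipeline_config()].
#' @return A list of class `run_report` with one element per executed
#'   stage plus `shapes`, `dropped`, and `seed`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cf <- config
  report <- list(seed = cf$seed, shapes = list(), dropped = list())

  sim <- NULL
  if (is.null(cf$matrix)) {
    sim <- run_stage("simulate", gen_trial(cf$trial))
    mat <- sim$matrix
    md <- sim$metadata
    analytes <- run_stage("simulate", gen_analytes(cf$analyte, md))
    y_genes <- sim$y_gene_ids
    report$truth <- list(responsive_gene_ids = sim$responsive_gene_ids)
  } else {
    mat <- cf$matrix
    md <- cf$metadata
    analytes <- cf$analytes
    y_genes <- intersect(grep("^YG", rownames(mat), value = TRUE),
                         rownames(mat))
  }
  report$shapes$input <- dim(mat)

  if ("qc" %in% cf$stages) {
    qc <- run_stage("qc", pc1_outlier_flags(mat, cf$sd_threshold))
    inferred <- if (length(y_genes))
      run_stage("qc", infer_sex(mat, y_genes)) else NULL
    mismatch <- if (!is.null(inferred))
      md$sample_id[inferred[md$sample_id] != md$sex] else character(0)
    report$qc <- list(flagged = qc$flagged_sample_ids,
                      pc1_scores = qc$pc1_scores,
                      inferred_sex = inferred, sex_mismatch = mismatch,
                      note = qc$note)
    keep <- setdiff(colnames(mat), qc$flagged_sample_ids)
    report$dropped$qc <- ncol(mat) - length(keep)
    mat <- mat[, keep, drop = FALSE]
    md <- md[md$sample_id %in% keep, , drop = FALSE]
  }
  if (length(y_genes)) mat <- mat[setdiff(rownames(mat), y_genes), ,
                                  drop = FALSE]

  if ("residualize" %in% cf$stages) {
    mat <- run_stage("residualize",
                     residualize(mat, md, remove = "rin",
                                 keep = c("arm", "timepoint",
                                          "arm:timepoint")))
    report$shapes$residualized <- dim(mat)
  }

  if ("score" %in% cf$stages) {
    ref <- run_stage("score", gen_reference(cf$reference))
    scores <- run_stage("score", signature_scores(mat, ref))
    change <- run_stage("score",
                        score_change_test(scores, md, pooled = cf$pooled))
    report$score <- list(scores = scores, change = change,
                         n_evaluable = change$n_evaluable)
  }

  fit <- NULL
  if ("de" %in% cf$stages) {
    md_de <- md
    design <- run_stage("de", build_design(md_de))
    mat_de <- mat[, md_de$sample_id, drop = FALSE]
    rho <- run_stage("de", consensus_correlation(mat_de, design,
                                                 attr(design, "blocks")))
    fit <- run_stage("de", fit_moderated(mat_de, design, rho = as.numeric(rho),
                                         blocks = attr(design, "blocks")))
    lists <- run_stage("de", interaction_gene_lists(fit, cf$alpha))
    report$de <- list(rho = as.numeric(rho), fit = fit, lists = lists,
                      n_end = length(lists$end$up_genes) +
                        length(lists$end$down_genes),
                      n_post1wk = length(lists$post1wk$up_genes) +
                        length(lists$post1wk$down_genes))
  }

  if ("enrich" %in% cf$stages) {
    if (is.null(fit))
      stop2("pipeline stage 'enrich' requires the 'de' stage")
    ic <- fit$interaction_cols
    rank_end <- stats::setNames(fit$t[, ic[["end"]]],
                                rownames(fit$coefficients))
    lists <- report$de$lists
    conc <- run_stage("enrich",
      concordance_enrichment(rank_end, lists$post1wk$up_genes,
                             lists$post1wk$down_genes,
                             fdr = cf$concordance_fdr, n_perm = cf$n_perm,
                             seed = cf$seed + 10L))
    sets <- cf$pathway_sets
    if (is.null(sets)) {
      set.seed(cf$seed + 11L)
      genes <- rownames(fit$coefficients)
      sets <- lapply(1:10, function(i) sample(genes, 25))
      names(sets) <- sprintf("RANDOM_SET_%02d", 1:10)
      if (!is.null(report$truth))
        sets$RESPONSIVE <- report$truth$responsive_gene_ids
    }
    hall <- run_stage("enrich",
                      gsea_preranked(rank_end, sets, n_perm = cf$n_perm,
                                     seed = cf$seed + 12L))
    gsva_sets <- sets[lengths(lapply(sets, intersect,
                                     rownames(mat))) >= 2]
    sscores <- run_stage("enrich", sample_set_scores(mat, gsva_sets))
    corr <- run_stage("enrich", rbind(
      cbind(arm = "treatment",
            change_correlation(sscores, analytes, md, "treatment")),
      cbind(arm = "placebo",
            change_correlation(sscores, analytes, md, "placebo"))))
    report$enrich <- list(
      concordance = conc, concordant = attr(conc, "concordant"),
      pathways = hall,
      pathways_hit = hall$set[!is.na(hall$qval) &
                                hall$qval < cf$pathway_fdr],
      sample_scores = sscores, analyte_correlation = corr)
  }

  if ("analytes" %in% cf$stages) {
    report$analytes <- run_stage("analytes",
                                 analyte_change_tests(analytes, md))
  }

  if (!is.null(cf$outdir)) {
    dir.create(cf$outdir, showWarnings = FALSE, recursive = TRUE)
    write_matrix_tsv(mat, file.path(cf$outdir, "expression.tsv"))
    write_table_tsv(md, file.path(cf$outdir, "metadata.tsv"))
    if (!is.null(report$score))
      write_table_tsv(report$score$scores,
                      file.path(cf$outdir, "signature_scores.tsv"))
    if (!is.null(fit))
      write_fit_tsv(fit, file.path(cf$outdir, "moderated_fit.tsv"))
    if (!is.null(report$enrich))
      write_table_tsv(report$enrich$pathways,
                      file.path(cf$outdir, "pathway_enrichment.tsv"))
    write_table_tsv(analytes, file.path(cf$outdir, "analytes.tsv"))
  }
  report$config <- cf
  class(report) <- "run_report"
  report
}
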