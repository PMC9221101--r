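#!/usr/bin/env Rscript
# Stage 5: enrichment readouts.
#
# (1) Concordance: are the one-week-post up/down gene lists enriched at
#     the corresponding ends of the end-of-treatment ranking (FDR < 0.05)?
# (2) Pathway-style pre-ranked enrichment of a gene-set collection
#     against the end-of-treatment ranking (FDR < 0.25).
# (3) Per-sample gene-set scores and their per-arm Spearman correlation
#     with analyte changes (end - baseline).

library(airwaysig)

m <- read_matrix_tsv("results/expression_clean.tsv")
md <- read_metadata_tsv("results/metadata_clean.tsv")
an <- read_analytes_tsv("results/data/analytes.tsv")
fit_tab <- utils::read.delim("results/moderated_fit.tsv")
sigs <- read_gmt("results/interaction_signatures.gmt")
truth <- read_gmt("results/data/gene_sets.gmt")$responsive_truth

ranking <- setNames(fit_tab$t_end, fit_tab$gene_id)
conc <- concordance_enrichment(ranking, sigs$post1wk_up,
                               sigs$post1wk_down, fdr = 0.05,
                               n_perm = 1000, seed = 11)
cat(sprintf("concordance of one-week-post signature in end-of-treatment ranking: %s\n",
            if (attr(conc, "concordant")) "concordant (FDR < 0.05)"
            else "not concordant"))
print(conc)

set.seed(12)
collection <- lapply(1:15, function(i) sample(names(ranking), 30))
names(collection) <- sprintf("RANDOM_%02d", 1:15)
collection$RESPONSIVE <- truth
enr <- gsea_preranked(ranking, collection, n_perm = 1000, seed = 13)
hit <- enr$set[!is.na(enr$qval) & enr$qval < 0.25]
cat(sprintf("collection sets at FDR < 0.25: %s\n",
            if (length(hit)) paste(hit, collapse = ", ") else "none"))
write_table_tsv(enr, "results/pathway_enrichment.tsv")

gsva <- sample_set_scores(m, list(RESPONSIVE = truth,
                                  RANDOM = collection$RANDOM_01))
write_table_tsv(data.frame(sample_id = rownames(gsva), gsva,
                           check.names = FALSE),
                "results/sample_set_scores.tsv")
corr <- rbind(cbind(arm = "treatment",
                    change_correlation(gsva, an, md, "treatment")),
              cbind(arm = "placebo",
                    change_correlation(gsva, an, md, "placebo")))
write_table_tsv(corr, "results/score_analyte_correlation.tsv")
cat("score-analyte change correlations (Spearman):\n")
print(corr, row.names = FALSE)
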