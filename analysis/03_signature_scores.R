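#!/usr/bin/env Rscript
# Stage 3: signature score transfer and arm comparison.
#
# Harmonizes the study matrix with the reference dataset (dataset of
# origin as batch), z-scores genes across the combined samples, fits PCA
# on the reference and projects every sample onto the oriented first
# component, then tests whether score changes (end - baseline) differ
# between arms among subjects with all three timepoints.

library(airwaysig)

study <- read_matrix_tsv("results/expression_clean.tsv")
md <- read_metadata_tsv("results/metadata_clean.tsv")
refm <- read_matrix_tsv("results/data/reference.tsv")
cls <- utils::read.delim("results/data/reference_classes.tsv")
sets <- read_gmt("results/data/gene_sets.gmt")

reference <- list(matrix = refm,
                  class_labels = setNames(cls$class, cls$sample_id),
                  signature_gene_ids = sets$signature,
                  orientation_class = "case")
scores <- signature_scores(study, reference)
write_table_tsv(scores, "results/signature_scores.tsv")

change <- score_change_test(scores, md, from_tp = "baseline", to_tp = "end")
bt <- change$between_arms
cat(sprintf("evaluable subjects: %d\n", change$n_evaluable))
cat(sprintf("between-arm change in signature score: estimate %.2f, t = %.2f, df = %.0f, p = %.3g\n",
            bt$estimate, bt$t, bt$df, bt$p))
for (arm in names(change$paired)) {
  pa <- change$paired[[arm]]
  if (!isTRUE(pa$flagged))
    cat(sprintf("  %s arm paired change: %.2f +/- %.2f (n=%d), p = %.3g\n",
                arm, pa$mean, pa$sd, pa$n, pa$p))
}
write_table_tsv(change$changes, "results/score_changes.tsv")
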