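#!/usr/bin/env Rscript
# Stage 2: sample QC and nuisance removal.
#
# Flags first-principal-component outliers (> 2 SD from the mean PC1
# score), verifies the recorded sex against Y-marker expression, drops
# flagged samples, and removes the RIN (RNA-quality) effect by gene-wise
# least squares while protecting the arm-by-timepoint design.

library(airwaysig)

m <- read_matrix_tsv("results/data/expression.tsv")
md <- read_metadata_tsv("results/data/metadata.tsv")
sets <- read_gmt("results/data/gene_sets.gmt")

qc <- pc1_outlier_flags(m, sd_threshold = 2)
cat(sprintf("PC1 outliers flagged: %d of %d samples\n",
            length(qc$flagged_sample_ids), ncol(m)))

sex <- infer_sex(m, sets$y_genes)
mismatch <- md$sample_id[sex[md$sample_id] != md$sex]
cat(sprintf("sex check: %d mismatches against recorded annotations\n",
            length(mismatch)))

keep <- setdiff(colnames(m), qc$flagged_sample_ids)
m <- m[setdiff(rownames(m), sets$y_genes), keep]
md <- md[md$sample_id %in% keep, ]

clean <- residualize(m, md, remove = "rin",
                     keep = c("arm", "timepoint", "arm:timepoint"))

dir.create("results", showWarnings = FALSE)
write_matrix_tsv(clean, "results/expression_clean.tsv")
write_table_tsv(md, "results/metadata_clean.tsv")
write_table_tsv(
  data.frame(sample_id = names(qc$pc1_scores),
             pc1 = unname(qc$pc1_scores),
             flagged = names(qc$pc1_scores) %in% qc$flagged_sample_ids,
             inferred_sex = unname(sex[names(qc$pc1_scores)])),
  "results/qc_report.tsv")
cat(sprintf("retained %d genes x %d samples after QC and RIN removal\n",
            nrow(clean), ncol(clean)))
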