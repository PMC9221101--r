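#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulates a two-arm (treatment vs placebo), three-timepoint (baseline /
# end-of-treatment / one-week-post) nasal-brushing trial: subject random
# intercepts, three processing batches with location/scale effects, a
# per-gene RNA-quality (RIN) slope, a treatment-by-time effect on a known
# subset of genes, male-marker genes for the sex check, and matched urinary
# LTE4/PGEM measurements with a treated-arm suppression and a female
# baseline elevation. Everything downstream reads only the TSVs written
# here.

library(airwaysig)

outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
seed <- 20260920L

trial <- gen_trial(trial_params(
  n_subjects_per_arm = 20, n_genes = 1000, n_responsive_genes = 50,
  treatment_effect = 1.0, carryover_fraction = 0.75,
  subject_sd = 0.5, batch_count = 3, dropout_rate = 0.05, seed = seed))
reference <- gen_reference(ref_params(
  n_genes = 1000, n_signature_genes = 80, effect_size = 1.0,
  seed = seed + 1L))
# Align the reference signature with the trial's treatment-suppressed
# genes (plus neutral ones): signature genes are elevated in the
# reference disease class, and treatment pushes a quarter of them down,
# so the treated arm should show a favorable score decrease.
down_ids <- names(trial$responsive_direction)[trial$responsive_direction < 0]
sig_ids <- c(down_ids, setdiff(sprintf("G%05d", 51:1000),
                               down_ids)[seq_len(80 - length(down_ids))])
gene_ids <- sprintf("G%05d", 1:1000)
rownames(reference$matrix) <- c(sig_ids, setdiff(gene_ids, sig_ids))
reference$signature_gene_ids <- sig_ids
analytes <- gen_analytes(analyte_params(seed = seed + 2L), trial$metadata)

write_matrix_tsv(trial$matrix, file.path(outdir, "expression.tsv"))
write_table_tsv(trial$metadata, file.path(outdir, "metadata.tsv"))
write_matrix_tsv(reference$matrix, file.path(outdir, "reference.tsv"))
write_table_tsv(
  data.frame(sample_id = names(reference$class_labels),
             class = unname(reference$class_labels)),
  file.path(outdir, "reference_classes.tsv"))
write_gmt(list(signature = reference$signature_gene_ids,
               responsive_truth = trial$responsive_gene_ids,
               y_genes = trial$y_gene_ids),
          file.path(outdir, "gene_sets.gmt"))
write_table_tsv(analytes, file.path(outdir, "analytes.tsv"))

cat(sprintf("simulated %d genes x %d samples (%d subjects, %d with all 3 timepoints)\n",
            nrow(trial$matrix), ncol(trial$matrix),
            length(unique(trial$metadata$subject_id)),
            sum(table(trial$metadata$subject_id) == 3)))
cat(sprintf("reference: %d samples, %d signature genes; analytes: %d rows\n",
            ncol(reference$matrix), length(reference$signature_gene_ids),
            nrow(analytes)))
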