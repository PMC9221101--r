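#!/usr/bin/env Rscript
# Stage 6: urinary analyte statistics.
#
# Creatinine-normalized LTE4 and PGEM summarized per stratum (all /
# female / male x overall / arm) with between-arm two-sample t-tests on
# per-subject changes and within-arm paired t-tests, restricted to
# subjects with all three timepoints.

library(airwaysig)

an <- read_analytes_tsv("results/data/analytes.tsv")
md <- read_metadata_tsv("results/metadata_clean.tsv")

res <- analyte_change_tests(an, md)
for (analyte in names(res)) {
  r <- res[[analyte]]
  cat(sprintf("%s: %d evaluable subjects\n", analyte, r$n_evaluable))
  bt <- r$between_arms$all.change_post
  if (!isTRUE(bt$flagged))
    cat(sprintf("  between-arm change (end - baseline): estimate %.2f, p = %.3g\n",
                bt$estimate, bt$p))
  for (str in c("female", "male")) {
    t2 <- r$between_arms[[paste0(str, ".change_post")]]
    if (!isTRUE(t2$flagged))
      cat(sprintf("  %s stratum between-arm change: p = %.3g\n", str, t2$p))
  }
  write_table_tsv(r$summary,
                  sprintf("results/analyte_summary_%s.tsv", analyte))
}
# multiplicative effects are better powered on the log scale
logres <- analyte_change_tests(an, md, log_scale = TRUE)
for (analyte in names(logres)) {
  bt <- logres[[analyte]]$between_arms$all.change_post
  if (!isTRUE(bt$flagged))
    cat(sprintf("%s log-scale between-arm change: p = %.3g\n", analyte,
                bt$p))
}
cat("summary tables written under results/\n")
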