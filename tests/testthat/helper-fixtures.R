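# Shared fixture builders; all randomness is seeded by the caller.

random_matrix <- function(n_genes, n_samples, mean = 7, sd = 1,
                          gene_prefix = "G", sample_prefix = "S") {
  matrix(rnorm(n_genes * n_samples, mean, sd), n_genes, n_samples,
         dimnames = list(sprintf("%s%04d", gene_prefix, seq_len(n_genes)),
                         sprintf("%s%04d", sample_prefix,
                                 seq_len(n_samples))))
}

# Balanced longitudinal metadata: n_per_arm subjects per arm, all three
# timepoints, round-robin batches, deterministic RIN and sex.
balanced_metadata <- function(n_per_arm = 10, batches = 2) {
  subjects <- sprintf("S%03d", seq_len(2 * n_per_arm))
  arm <- rep(c("treatment", "placebo"), each = n_per_arm)
  tps <- c("baseline", "end", "post1wk")
  md <- expand.grid(timepoint = tps, subject_id = subjects,
                    stringsAsFactors = FALSE)[, 2:1]
  md$arm <- arm[match(md$subject_id, subjects)]
  md$sample_id <- paste(md$subject_id, md$timepoint, sep = "_")
  md$batch <- paste0("B", (seq_len(nrow(md)) %% batches) + 1)
  md$rin <- 7 + (seq_len(nrow(md)) %% 5) / 2
  md$sex <- rep(c("male", "female"), length.out = 2 * n_per_arm)[
    match(md$subject_id, subjects)]
  md[, c("sample_id", "subject_id", "arm", "timepoint", "batch",
         "rin", "sex")]
}

# Independent brute-force running-sum oracle for the enrichment walk:
# literal loop over positions, no shared code with the implementation.
brute_force_es <- function(stat_sorted, member, weight) {
  N <- length(stat_sorted)
  nh <- sum(member)
  wsum <- sum(abs(stat_sorted[member])^weight)
  cur <- 0
  best <- 0
  for (i in seq_len(N)) {
    if (member[i]) {
      cur <- cur + if (wsum > 0) abs(stat_sorted[i])^weight / wsum else 1 / nh
    } else {
      cur <- cur - 1 / (N - nh)
    }
    if (abs(cur) > abs(best)) best <- cur
  }
  unname(best)
}

# Longitudinal score table with subject random intercepts (intra-subject
# correlation 0.5 at level SD `sd`) and a treated-arm end-of-treatment
# shift; the regime of the published score-change tables.
correlated_scores <- function(md, shift = 0, sd = 4) {
  subj <- unique(md$subject_id)
  b <- rnorm(length(subj), 0, sd / sqrt(2))
  x <- b[match(md$subject_id, subj)] + rnorm(nrow(md), 0, sd / sqrt(2))
  x <- x + shift * (md$arm == "treatment" & md$timepoint == "end")
  make_score_table(md$sample_id, x)
}

# A score table in the shape signature_scores() returns.
make_score_table <- function(sample_ids, scores, origin = "study") {
  out <- data.frame(sample_id = sample_ids, score = scores,
                    origin = origin, stringsAsFactors = FALSE)
  class(out) <- c("signature_score_table", "data.frame")
  out
}
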