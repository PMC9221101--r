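#' Parameters for a two-class reference signature dataset
#'
#' Describes a synthetic stand-in for a published reference series (e.g., a
#' case/control brushing study from which a disease signature was derived):
#' `n_signature_genes` of the `n_genes` carry a class-mean shift of
#' `effect_size` log2 units in the case class.
#'
#' @param n_genes Total number of genes.
#' @param n_signature_genes Number of genes carrying the class difference.
#' @param n_case,n_control Samples per class (each at least 2).
#' @param effect_size Log2-unit shift of signature genes in the case class.
#' @param noise_sd Per-measurement Gaussian noise SD (log2 units), > 0.
#' @param baseline_mean,baseline_sd Distribution of per-gene baseline means.
#' @param seed Integer seed; generation is a pure function of it.
#' @return A list of class `ref_params`.
#' @export
ref_params <- function(n_genes = 500, n_signature_genes = 50,
                       n_case = 20, n_control = 20,
                       effect_size = 1.0, noise_sd = 0.5,
                       baseline_mean = 7, baseline_sd = 1.5,
                       seed = 1L) {
  p <- list(n_genes = as.integer(n_genes),
            n_signature_genes = as.integer(n_signature_genes),
            n_case = as.integer(n_case), n_control = as.integer(n_control),
            effect_size = effect_size, noise_sd = noise_sd,
            baseline_mean = baseline_mean, baseline_sd = baseline_sd,
            seed = as.integer(seed))
  if (p$n_signature_genes > p$n_genes)
    stop2("n_signature_genes must be <= n_genes")
  if (p$n_case < 2 || p$n_control < 2)
    stop2("each class needs at least 2 samples")
  if (!is.finite(p$noise_sd) || p$noise_sd <= 0)
    stop2("noise_sd must be > 0")
  structure(p, class = "ref_params")
}

#' Generate a two-class reference signature dataset
#'
#' @param params A [ref_params()] object.
#' @return A list of class `reference_signature_dataset` with elements
#'   `matrix` (genes x samples, log2 scale), `class_labels`
#'   (`"case"`/`"control"` per sample), `signature_gene_ids`, and
#'   `orientation_class` (`"case"`: the class that should score high).
#' @export
gen_reference <- function(params) {
  if (!inherits(params, "ref_params")) params <- do.call(ref_params, params)
  set.seed(params$seed)
  n <- params$n_case + params$n_control
  genes <- sprintf("G%05d", seq_len(params$n_genes))
  samples <- sprintf("REF%03d", seq_len(n))
  labels <- rep(c("case", "control"), c(params$n_case, params$n_control))
  base <- stats::rnorm(params$n_genes, params$baseline_mean, params$baseline_sd)
  m <- matrix(stats::rnorm(params$n_genes * n, 0, params$noise_sd),
              params$n_genes, n, dimnames = list(genes, samples)) + base
  sig <- genes[seq_len(params$n_signature_genes)]
  m[sig, labels == "case"] <- m[sig, labels == "case"] + params$effect_size
  structure(list(matrix = m,
                 class_labels = stats::setNames(labels, samples),
                 signature_gene_ids = sig,
                 orientation_class = "case",
                 params = params),
            class = "reference_signature_dataset")
}

#' Parameters for a synthetic two-arm, three-timepoint trial
#'
#' Encodes the generative model assumed by the downstream analysis: per-gene
#' baselines, subject random intercepts, additive/multiplicative batch
#' effects, a per-gene RNA-quality (RIN) slope, and a treatment-by-time
#' effect confined to `n_responsive_genes` in the treated arm at
#' non-baseline timepoints (scaled by `carryover_fraction` one week post).
#'
#' @param n_subjects_per_arm Subjects randomized to each arm.
#' @param timepoints The three ordered collection labels.
#' @param n_genes,n_responsive_genes Gene counts (responsive <= total).
#' @param treatment_effect Log2-unit change at end-of-treatment in the
#'   treated arm for responsive genes.
#' @param carryover_fraction Fraction of `treatment_effect` persisting one
#'   week post-treatment, in \[0, 1\].
#' @param frac_down Fraction of responsive genes suppressed (rather than
#'   induced) by treatment; drug responses move in both directions.
#' @param subject_sd SD of the subject random intercept (log2 units).
#' @param batch_count Number of processing batches.
#' @param batch_shift_sd SD of the per-gene additive batch shift.
#' @param batch_scale_sd SD (log scale) of the per-gene multiplicative batch
#'   effect on the noise.
#' @param rin_range RNA-integrity interval samples are drawn from.
#' @param rin_slope_sd SD of the per-gene RIN sensitivity.
#' @param noise_sd Residual noise SD (log2 units); per-gene variances are
#'   drawn around `noise_sd^2`.
#' @param var_df Degrees of freedom of the scaled inverse-chi-square
#'   distribution of per-gene noise variances (smaller = more
#'   heterogeneous; `Inf` = identical variance for every gene). Must
#'   exceed 2 so the mean variance equals `noise_sd^2`.
#' @param dropout_rate Probability that a subject loses later timepoints
#'   (monotone missingness), in \[0, 1).
#' @param n_y_genes Extra male-only marker genes appended to the matrix
#'   (IDs `YG...`) supporting the sex check.
#' @param baseline_mean,baseline_sd Distribution of per-gene baselines.
#' @param seed Integer seed.
#' @return A list of class `trial_params`.
#' @export
trial_params <- function(n_subjects_per_arm = 20,
                         timepoints = timepoint_levels(),
                         n_genes = 1000, n_responsive_genes = 50,
                         treatment_effect = 1.0, carryover_fraction = 0.75,
                         frac_down = 0.5, subject_sd = 0.5,
                         batch_count = 3, batch_shift_sd = 0.3,
                         batch_scale_sd = 0.1,
                         rin_range = c(6, 10), rin_slope_sd = 0.1,
                         noise_sd = 0.5, var_df = 10, dropout_rate = 0.05,
                         n_y_genes = 10,
                         baseline_mean = 7, baseline_sd = 1.5,
                         seed = 1L) {
  p <- list(n_subjects_per_arm = as.integer(n_subjects_per_arm),
            timepoints = as.character(timepoints),
            n_genes = as.integer(n_genes),
            n_responsive_genes = as.integer(n_responsive_genes),
            treatment_effect = treatment_effect,
            carryover_fraction = carryover_fraction,
            frac_down = frac_down,
            subject_sd = subject_sd, batch_count = as.integer(batch_count),
            batch_shift_sd = batch_shift_sd, batch_scale_sd = batch_scale_sd,
            rin_range = rin_range, rin_slope_sd = rin_slope_sd,
            noise_sd = noise_sd, var_df = var_df,
            dropout_rate = dropout_rate,
            n_y_genes = as.integer(n_y_genes),
            baseline_mean = baseline_mean, baseline_sd = baseline_sd,
            seed = as.integer(seed))
  if (length(p$timepoints) != 3L)
    stop2("timepoints must have exactly 3 ordered levels")
  if (p$n_responsive_genes > p$n_genes)
    stop2("n_responsive_genes must be <= n_genes")
  if (p$carryover_fraction < 0 || p$carryover_fraction > 1)
    stop2("carryover_fraction must be in [0, 1]")
  if (p$frac_down < 0 || p$frac_down > 1)
    stop2("frac_down must be in [0, 1]")
  sds <- c(p$subject_sd, p$batch_shift_sd, p$batch_scale_sd,
           p$rin_slope_sd, p$noise_sd)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop2("all SD parameters must be finite and >= 0")
  if (p$dropout_rate < 0 || p$dropout_rate >= 1)
    stop2("dropout_rate must be in [0, 1)")
  if (!is.infinite(p$var_df) && p$var_df <= 2)
    stop2("var_df must exceed 2 (or be Inf)")
  structure(p, class = "trial_params")
}

#' Generate a synthetic two-arm, three-timepoint trial
#'
#' Per-sample expression is built as gene baseline + subject intercept +
#' additive batch shift + per-gene RIN slope times centered RIN +
#' treatment-by-time effect (responsive genes, treated arm, non-baseline
#' timepoints) + noise scaled by a per-gene multiplicative batch factor.
#' `n_y_genes` male-marker genes are appended: near-silent background in
#' female-labeled samples, +4 log2 units in males.
#'
#' @param params A [trial_params()] object.
#' @return A list of class `trial_dataset` with elements `matrix`,
#'   `metadata` (sample_id, subject_id, arm, timepoint, batch, rin, sex),
#'   `responsive_gene_ids`, and `y_gene_ids`.
#' @export
gen_trial <- function(params) {
  if (!inherits(params, "trial_params")) params <- do.call(trial_params, params)
  p <- params
  set.seed(p$seed)
  n_sub <- 2L * p$n_subjects_per_arm
  subjects <- sprintf("S%03d", seq_len(n_sub))
  arm <- rep(c("treatment", "placebo"), each = p$n_subjects_per_arm)
  sex <- sample(c("male", "female"), n_sub, replace = TRUE)

  # monotone dropout: an affected subject keeps only timepoints before a
  # uniformly chosen cut after baseline
  kept <- lapply(seq_len(n_sub), function(i) {
    if (stats::runif(1) < p$dropout_rate) {
      p$timepoints[seq_len(sample(1:2, 1))]
    } else p$timepoints
  })
  md <- do.call(rbind, lapply(seq_len(n_sub), function(i) {
    data.frame(subject_id = subjects[i], arm = arm[i],
               timepoint = kept[[i]], sex = sex[i],
               stringsAsFactors = FALSE)
  }))
  md$sample_id <- paste(md$subject_id, md$timepoint, sep = "_")
  n <- nrow(md)
  md$batch <- paste0("B", sample.int(p$batch_count, n, replace = TRUE))
  md$rin <- stats::runif(n, p$rin_range[1], p$rin_range[2])
  md <- md[, c("sample_id", "subject_id", "arm", "timepoint",
               "batch", "rin", "sex")]

  genes <- sprintf("G%05d", seq_len(p$n_genes))
  responsive <- genes[seq_len(p$n_responsive_genes)]
  base <- stats::rnorm(p$n_genes, p$baseline_mean, p$baseline_sd)
  subj_int <- stats::setNames(stats::rnorm(n_sub, 0, p$subject_sd), subjects)
  batches <- paste0("B", seq_len(p$batch_count))
  shift <- matrix(stats::rnorm(p$n_genes * p$batch_count, 0, p$batch_shift_sd),
                  p$n_genes, p$batch_count, dimnames = list(genes, batches))
  scale_ <- matrix(exp(stats::rnorm(p$n_genes * p$batch_count, 0,
                                    p$batch_scale_sd)),
                   p$n_genes, p$batch_count, dimnames = list(genes, batches))
  rin_slope <- stats::rnorm(p$n_genes, 0, p$rin_slope_sd)
  rin_c <- md$rin - mean(p$rin_range)
  gene_sd <- if (is.infinite(p$var_df)) rep(p$noise_sd, p$n_genes)
    else p$noise_sd * sqrt((p$var_df - 2) / stats::rchisq(p$n_genes,
                                                          p$var_df))

  eff <- c(0, p$treatment_effect,
           p$treatment_effect * p$carryover_fraction)[match(md$timepoint,
                                                            p$timepoints)]
  eff[md$arm != "treatment"] <- 0

  m <- matrix(0, p$n_genes, n, dimnames = list(genes, md$sample_id))
  noise <- matrix(stats::rnorm(p$n_genes * n, 0, gene_sd), p$n_genes, n)
  for (j in seq_len(n)) {
    b <- md$batch[j]
    m[, j] <- base + subj_int[[md$subject_id[j]]] + shift[, b] +
      rin_slope * rin_c[j] + noise[, j] * scale_[, b]
  }
  n_down <- floor(p$n_responsive_genes * p$frac_down)
  sign_r <- rep(c(1, -1), c(p$n_responsive_genes - n_down, n_down))
  m[responsive, ] <- m[responsive, , drop = FALSE] + outer(sign_r, eff)

  y_gene_ids <- character(0)
  if (p$n_y_genes > 0) {
    y_gene_ids <- sprintf("YG%03d", seq_len(p$n_y_genes))
    ym <- matrix(stats::rnorm(p$n_y_genes * n, 3, p$noise_sd), p$n_y_genes, n,
                 dimnames = list(y_gene_ids, md$sample_id))
    ym[, md$sex == "male"] <- ym[, md$sex == "male"] + 4
    m <- rbind(m, ym)
  }
  structure(list(matrix = m, metadata = md,
                 responsive_gene_ids = responsive,
                 responsive_direction =
                   if (p$n_responsive_genes > 0)
                     stats::setNames(sign_r, responsive) else integer(0),
                 y_gene_ids = y_gene_ids, params = p),
            class = "trial_dataset")
}

#' Parameters for synthetic urinary analyte measurements
#'
#' Lognormal analyte model on the creatinine-normalized scale: subject
#' baselines around an analyte geometric mean, a multiplicative female/male
#' baseline factor, a multiplicative end-of-treatment effect in the treated
#' arm (< 1 = suppression), and a partial rebound toward baseline one week
#' post-treatment.
#'
#' @param lte4_baseline_gm,pgem_baseline_gm Baseline geometric means
#'   (pg/mg creatinine).
#' @param gender_ratio Multiplicative female/male baseline factor.
#' @param treatment_ratio_lte4,treatment_ratio_pgem End/baseline ratio under
#'   treatment.
#' @param rebound_fraction Fraction of the (log-scale) suppression lost one
#'   week post-treatment.
#' @param cv Lognormal coefficient of variation of a single measurement.
#' @param creatinine_range Uniform sampling interval for urinary creatinine
#'   (mg/mL).
#' @param seed Integer seed.
#' @return A list of class `analyte_params`.
#' @export
analyte_params <- function(lte4_baseline_gm = 70, pgem_baseline_gm = 9,
                           gender_ratio = 1.5,
                           treatment_ratio_lte4 = 0.4,
                           treatment_ratio_pgem = 0.9,
                           rebound_fraction = 0.8, cv = 0.5,
                           creatinine_range = c(0.5, 3), seed = 1L) {
  p <- list(lte4_baseline_gm = lte4_baseline_gm,
            pgem_baseline_gm = pgem_baseline_gm,
            gender_ratio = gender_ratio,
            treatment_ratio_lte4 = treatment_ratio_lte4,
            treatment_ratio_pgem = treatment_ratio_pgem,
            rebound_fraction = rebound_fraction, cv = cv,
            creatinine_range = creatinine_range, seed = as.integer(seed))
  if (p$lte4_baseline_gm <= 0 || p$pgem_baseline_gm <= 0)
    stop2("baseline geometric means must be > 0")
  if (p$gender_ratio <= 0 || p$treatment_ratio_lte4 <= 0 ||
      p$treatment_ratio_pgem <= 0)
    stop2("all ratios must be > 0")
  if (p$cv <= 0) stop2("cv must be > 0")
  structure(p, class = "analyte_params")
}

#' Generate synthetic urinary analyte measurements
#'
#' One LTE4 and one PGEM measurement per subject-timepoint present in the
#' metadata. Values are generated on the creatinine-normalized scale
#' (pg/mg Cr) and un-normalized by a uniformly drawn creatinine so that raw
#' pg/mL and creatinine mg/mL are both returned; dividing raw by creatinine
#' recovers the normalized value exactly.
#'
#' @param params An [analyte_params()] object.
#' @param metadata A sample metadata table with subject_id, arm, timepoint,
#'   sex columns (one row per sample; duplicated subject-timepoints are
#'   collapsed).
#' @return A long-format data.frame: subject_id, timepoint, analyte, raw,
#'   creatinine, normalized.
#' @export
gen_analytes <- function(params, metadata) {
  if (!inherits(params, "analyte_params"))
    params <- do.call(analyte_params, params)
  need <- c("subject_id", "arm", "timepoint", "sex")
  missing <- setdiff(need, names(metadata))
  if (length(missing))
    stop2("metadata is missing columns: ", paste(missing, collapse = ", "))
  if (anyNA(metadata$sex)) stop2("metadata has missing sex annotations")
  p <- params
  set.seed(p$seed)
  key <- unique(metadata[, need])
  sdlog <- sqrt(log(1 + p$cv^2))
  out <- do.call(rbind, lapply(c("LTE4", "PGEM"), function(an) {
    gm <- if (an == "LTE4") p$lte4_baseline_gm else p$pgem_baseline_gm
    tr <- if (an == "LTE4") p$treatment_ratio_lte4 else p$treatment_ratio_pgem
    log_eff <- c(0, log(tr), log(tr) * (1 - p$rebound_fraction))
    eff <- log_eff[match(key$timepoint, timepoint_levels())]
    eff[key$arm != "treatment"] <- 0
    mu <- log(gm) + log(p$gender_ratio) * (key$sex == "female") + eff
    normalized <- exp(stats::rnorm(nrow(key), mu, sdlog))
    creatinine <- stats::runif(nrow(key), p$creatinine_range[1],
                               p$creatinine_range[2])
    data.frame(subject_id = key$subject_id, timepoint = key$timepoint,
               analyte = an, raw = normalized * creatinine,
               creatinine = creatinine, normalized = normalized,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
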