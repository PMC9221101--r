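#' Normalize a urinary analyte to creatinine
#'
#' Converts raw urinary concentrations (pg/mL) to creatinine-normalized
#' values (pg/mg Cr) by straight division, correcting for urine dilution.
#'
#' @param raw Raw concentration(s), pg/mL.
#' @param creatinine Urinary creatinine concentration(s), mg/mL; must be
#'   strictly positive.
#' @return raw / creatinine, in pg/mg Cr.
#' @export
normalize_to_creatinine <- function(raw, creatinine) {
  if (any(!is.finite(creatinine)) || any(creatinine <= 0))
    stop2("creatinine must be > 0")
  raw / creatinine
}

#' Arm and gender change statistics for urinary analytes
#'
#' Restricts to evaluable subjects (all three timepoints present for the
#' analyte), computes per-subject changes on the creatinine-normalized
#' scale (end - baseline; one-week-post - baseline), and summarizes each
#' analyte as a table of mean +/- SD cells per stratum (all/female/male x
#' overall/treatment/placebo x level or change), with two-sample t-tests of
#' changes (and baselines) between arms overall and within gender, and
#' paired t-tests of the changes within each arm. Strata with fewer than 2
#' subjects are flagged rather than tested. Tests run on the normalized
#' scale untransformed, so printed change means equal differences of the
#' printed level means; set `log_scale = TRUE` to analyze log values
#' instead (useful in simulation studies of multiplicative effects).
#'
#' @param table Long-format analyte table: subject_id, timepoint, analyte,
#'   raw, creatinine, and (optionally) normalized -- recomputed from
#'   raw/creatinine when absent.
#' @param metadata Sample metadata providing arm and sex per subject.
#' @param log_scale Analyze natural-log values instead of the plain scale.
#' @return A list of class `analyte_change_result`, one element per
#'   analyte, each containing `summary` (the cell table), `between_arms`,
#'   `paired`, and `n_evaluable`.
#' @export
analyte_change_tests <- function(table, metadata, log_scale = FALSE) {
  if (!all(c("subject_id", "timepoint", "analyte") %in% names(table)))
    stop2("analyte table needs subject_id, timepoint, analyte columns")
  if (!"normalized" %in% names(table))
    table$normalized <- normalize_to_creatinine(table$raw, table$creatinine)
  subj_info <- unique(metadata[, c("subject_id", "arm", "sex")])
  if (anyDuplicated(subj_info$subject_id))
    stop2("inconsistent arm/sex annotations per subject")
  tps <- timepoint_levels()

  per_analyte <- function(at) {
    at <- at[at$timepoint %in% tps, ]
    cnt <- table(at$subject_id, factor(at$timepoint, levels = tps))
    ev <- rownames(cnt)[apply(cnt == 1, 1, all)]
    ev <- ev[ev %in% subj_info$subject_id]
    at <- at[at$subject_id %in% ev, ]
    val <- function(tp) {
      v <- at$normalized[at$timepoint == tp][match(ev, at$subject_id[at$timepoint == tp])]
      if (log_scale) log(v) else v
    }
    base <- val("baseline"); post <- val("end"); wk1 <- val("post1wk")
    d_post <- post - base
    d_wk1 <- wk1 - base
    arm <- subj_info$arm[match(ev, subj_info$subject_id)]
    sex <- subj_info$sex[match(ev, subj_info$subject_id)]

    quantities <- list(baseline = base, post = post, post1wk = wk1,
                       change_post = d_post, change_1wk = d_wk1)
    cells <- list()
    tests <- list()
    paired <- list()
    for (stratum in c("all", "female", "male")) {
      in_str <- if (stratum == "all") rep(TRUE, length(ev)) else sex == stratum
      for (qn in names(quantities)) {
        q <- quantities[[qn]]
        for (grp in c("overall", "treatment", "placebo")) {
          sel <- in_str & (grp == "overall" | arm == grp)
          cells[[length(cells) + 1L]] <- data.frame(
            stratum = stratum, arm = grp, quantity = qn,
            mean = if (sum(sel)) mean(q[sel]) else NA_real_,
            sd = if (sum(sel) > 1) sd1(q[sel]) else NA_real_,
            n = sum(sel), stringsAsFactors = FALSE)
        }
        if (qn %in% c("baseline", "change_post", "change_1wk")) {
          trt <- q[in_str & arm == "treatment"]
          plc <- q[in_str & arm == "placebo"]
          tests[[paste(stratum, qn, sep = ".")]] <-
            if (length(trt) >= 2 && length(plc) >= 2 &&
                (sd1(trt) > 0 || sd1(plc) > 0))
              ttest_from_summary(mean(trt), sd1(trt), length(trt),
                                 mean(plc), sd1(plc), length(plc))
            else list(flagged = TRUE,
                      reason = "fewer than 2 subjects or zero variance")
        }
      }
      for (grp in c("treatment", "placebo")) {
        for (qn in c("change_post", "change_1wk")) {
          x <- quantities[[qn]][in_str & arm == grp]
          paired[[paste(stratum, grp, qn, sep = ".")]] <-
            if (length(x) >= 2 && sd1(x) > 0) {
              tt <- stats::t.test(x)
              list(estimate = mean(x), t = unname(tt$statistic),
                   df = unname(tt$parameter), p = tt$p.value,
                   n = length(x), flagged = FALSE)
            } else list(flagged = TRUE,
                        reason = "fewer than 2 subjects or zero variance")
        }
      }
    }
    list(summary = do.call(rbind, cells), between_arms = tests,
         paired = paired, n_evaluable = length(ev))
  }
  out <- lapply(split(table, table$analyte), per_analyte)
  class(out) <- "analyte_change_result"
  out
}
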