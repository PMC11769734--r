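#' Empirical AUROC (Mann-Whitney statistic with half-tie credit)
#'
#' Area under the empirical ROC curve of a continuous (or ordinal) score
#' against a binary truth label, computed as the normalized Mann-Whitney
#' U statistic: the proportion of (positive, negative) case pairs where the
#' positive scores higher, with ties counting one half. This equals the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric suspicion scores (higher = more suspicious).
#' @param labels binary truth labels (1 = diseased).
#' @return AUROC in [0, 1].
#' @examples
#' empirical_auroc(c(3, 1, 2, 4, 2), c(1, 0, 0, 1, 1))  # 11/12
#' @export
empirical_auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop_classed("pairedmrmc_degenerate_error",
                 "AUROC needs both classes (got %d positive, %d negative)",
                 n_pos, n_neg)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Define a positivity rule for binarizing patient-level PI-RADS categories
#'
#' Three biopsy-triggering rules are supported: `"p3"` (PI-RADS >= 3, the
#' primary operating point), `"p4psad"` (PI-RADS >= 4, or PI-RADS 3 with an
#' elevated PSA density), and `"p4"` (PI-RADS >= 4 only).
#'
#' @param rule_id one of `"p3"`, `"p4psad"`, `"p4"`.
#' @param psad_threshold PSA-density cutoff in ng/ml^2 for the `"p4psad"`
#'   rule; the conventional risk cutoff 0.15 by default, inclusive.
#' @return an object of class `positivity_rule`.
#' @export
positivity_rule <- function(rule_id = c("p3", "p4psad", "p4"),
                            psad_threshold = 0.15) {
  rule_id <- match.arg(rule_id)
  stopifnot(psad_threshold > 0)
  structure(list(rule_id = rule_id, psad_threshold = psad_threshold),
            class = "positivity_rule")
}

#' Apply a positivity rule to patient-level categories
#'
#' Vectorized over exams. A missing PSA density under the `"p4psad"` rule is
#' treated as below threshold (the exam is not called positive on PSAd
#' grounds) and a warning is emitted.
#'
#' @param patient_category integer categories in \{2,3,4,5\}.
#' @param psad PSA density values (ng/ml^2), may be `NA`.
#' @param rule a [positivity_rule()].
#' @return logical vector of positive calls.
#' @export
apply_positivity_rule <- function(patient_category, psad, rule) {
  stopifnot(inherits(rule, "positivity_rule"))
  if (!all(patient_category %in% CATEGORIES))
    stop_classed("pairedmrmc_domain_error",
                 "patient_category must be in {2,3,4,5}")
  switch(rule$rule_id,
    p3 = patient_category >= 3L,
    p4 = patient_category >= 4L,
    p4psad = {
      psad <- rep_len(psad, length(patient_category))
      if (any(is.na(psad) & patient_category == 3L))
        warning("missing PSAd for PI-RADS 3 exam(s); treated as below threshold")
      elevated <- !is.na(psad) & psad >= rule$psad_threshold
      patient_category >= 4L | (patient_category == 3L & elevated)
    })
}

#' Sensitivity and specificity of one reader under a positivity rule
#'
#' @param patient_category integer categories for the reader's cases.
#' @param psad PSA densities aligned with `patient_category`.
#' @param labels binary truth labels aligned with `patient_category`.
#' @param rule a [positivity_rule()].
#' @return named numeric vector `c(sensitivity =, specificity =)`.
#' @export
sens_spec <- function(patient_category, psad, labels, rule) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop_classed("pairedmrmc_degenerate_error",
                 "sens/spec needs both classes (got %d positive, %d negative)",
                 n_pos, n_neg)
  calls <- apply_positivity_rule(patient_category, psad, rule)
  c(sensitivity = sum(calls & labels == 1L) / n_pos,
    specificity = sum(!calls & labels == 0L) / n_neg)
}

reader_modality_split <- function(study) {
  cs <- study$cases
  rd <- study$readings
  idx <- match(rd$case_id, cs$case_id)
  rd$label <- cs$label[idx]
  rd$psad <- cs$psad[idx]
  split(rd, list(rd$modality, rd$reader_id), drop = TRUE, sep = "\r")
}

compute_metric <- function(sub, metric, rule) {
  switch(metric,
    auroc = empirical_auroc(sub$suspicion, sub$label),
    sensitivity = sens_spec(sub$patient_pirads, sub$psad, sub$label,
                            rule)[["sensitivity"]],
    specificity = sens_spec(sub$patient_pirads, sub$psad, sub$label,
                            rule)[["specificity"]])
}

#' Per-reader accuracy table for one metric
#'
#' Computes one accuracy value per (modality, reader): empirical AUROC from
#' the 0-100 suspicion scores (the positivity rule is ignored), or
#' sensitivity/specificity of the patient-level categories binarized by
#' `rule`. Values are per reader, never pooled over readers; averaging is
#' done downstream by the Obuchowski-Rockette machinery.
#'
#' @param study a `reader_study`.
#' @param metric `"auroc"`, `"sensitivity"` or `"specificity"`.
#' @param rule a [positivity_rule()]; required for sensitivity/specificity.
#' @param readers optional character vector restricting to a reader subset
#'   (e.g. the expert subgroup).
#' @return an `accuracy_table`: data frame with columns `reader_id`,
#'   `block_id`, `modality`, `value`, `n_cases`, `n_pos`, `n_neg`.
#' @export
per_reader_metric_table <- function(study,
                                    metric = c("auroc", "sensitivity",
                                               "specificity"),
                                    rule = positivity_rule("p3"),
                                    readers = NULL) {
  stopifnot(inherits(study, "reader_study"))
  metric <- match.arg(metric)
  splits <- reader_modality_split(study)
  if (!is.null(readers)) {
    keep <- vapply(splits, function(s) s$reader_id[1] %in% readers, logical(1))
    splits <- splits[keep]
  }
  block_of <- setNames(study$readers$block_id, study$readers$reader_id)
  rows <- lapply(splits, function(sub) {
    value <- tryCatch(compute_metric(sub, metric, rule), error = function(e)
      stop_classed("pairedmrmc_degenerate_error",
                   "reader %s, modality %s: %s",
                   sub$reader_id[1], sub$modality[1], conditionMessage(e)))
    data.frame(reader_id = sub$reader_id[1],
               block_id = unname(block_of[sub$reader_id[1]]),
               modality = sub$modality[1],
               value = value,
               n_cases = nrow(sub),
               n_pos = sum(sub$label == 1L),
               n_neg = sum(sub$label == 0L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$modality, out$reader_id), ]
  rownames(out) <- NULL
  structure(out, metric = metric, rule = rule,
            class = c("accuracy_table", "data.frame"))
}
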