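#' Net benefit of a biopsy strategy at a threshold probability
#'
#' Net benefit trades true positives against false positives at a
#' threshold probability p_t (the csPCa risk at which a patient would
#' accept a biopsy): NB = TP/N - (FP/N) * p_t / (1 - p_t).
#'
#' @param tp,fp true/false positive counts.
#' @param n cohort size.
#' @param p_t threshold probability, strictly inside (0, 1); vectorized.
#' @return numeric net benefit (same length as `p_t`).
#' @examples
#' net_benefit(tp = 133, fp = 267, n = 400, p_t = 0.10)  # treat-all at 10%
#' @export
net_benefit <- function(tp, fp, n, p_t) {
  if (any(p_t <= 0 | p_t >= 1))
    stop_classed("pairedmrmc_domain_error",
                 "threshold probability must lie strictly in (0, 1)")
  stopifnot(tp + fp <= n, tp >= 0, fp >= 0)
  tp / n - (fp / n) * p_t / (1 - p_t)
}

#' Define a biopsy strategy for decision curve analysis
#'
#' A strategy is either a (modality, positivity rule) pair applied to each
#' reader's patient-level calls, or one of the reference policies
#' `treat_all` / `treat_none`.
#'
#' @param name display name.
#' @param modality `"bp"` or `"mp"` (rule-based strategies only).
#' @param rule a [positivity_rule()] (rule-based strategies only).
#' @param type `"rule"`, `"treat_all"` or `"treat_none"`.
#' @return a `dca_strategy` object.
#' @export
dca_strategy <- function(name, modality = NULL, rule = NULL,
                         type = c("rule", "treat_all", "treat_none")) {
  type <- match.arg(type)
  if (type == "rule") {
    if (is.null(modality) || !modality %in% MODALITIES ||
        !inherits(rule, "positivity_rule"))
      stop_classed("pairedmrmc_config_error",
                   "rule-based strategy '%s' needs a modality and a positivity rule",
                   name)
  }
  structure(list(name = name, modality = modality, rule = rule, type = type),
            class = "dca_strategy")
}

#' The six clinical pathways plus reference policies
#'
#' Convenience set: each modality crossed with the three positivity rules,
#' plus treat-all and treat-none.
#' @param psad_threshold PSA-density cutoff for the PSAd-conditional rule.
#' @return list of [dca_strategy()] objects.
#' @export
default_strategies <- function(psad_threshold = 0.15) {
  out <- list()
  for (m in MODALITIES) for (r in c("p3", "p4psad", "p4")) {
    nm <- sprintf("%s_%s", m, r)
    out[[nm]] <- dca_strategy(nm, m, positivity_rule(r, psad_threshold))
  }
  out$treat_all <- dca_strategy("treat_all", type = "treat_all")
  out$treat_none <- dca_strategy("treat_none", type = "treat_none")
  out
}

strategy_counts <- function(study, strategy) {
  # one confusion table per reader; treat_all/none are reader-independent
  # but evaluated per reader block for symmetry of averaging
  cs <- study$cases
  rd <- study$readings
  readers <- study$readers$reader_id
  idx <- match(rd$case_id, cs$case_id)
  rd$label <- cs$label[idx]
  rd$psad <- cs$psad[idx]
  per_reader <- lapply(readers, function(j) {
    if (strategy$type == "rule") {
      sub <- rd[rd$reader_id == j & rd$modality == strategy$modality, ]
      calls <- apply_positivity_rule(sub$patient_pirads, sub$psad,
                                     strategy$rule)
      labs <- sub$label
    } else {
      block <- study$readers$block_id[match(j, study$readers$reader_id)]
      labs <- cs$label[cs$block_id == block]
      calls <- rep(strategy$type == "treat_all", length(labs))
    }
    c(tp = sum(calls & labs == 1L), fp = sum(calls & labs == 0L),
      n = length(labs))
  })
  names(per_reader) <- readers
  per_reader
}

#' Decision curve over a threshold grid, averaged over readers
#'
#' For each strategy and each reader, patient-level binary calls are
#' scored against the truth labels to give one confusion table per reader;
#' the net benefit at each threshold is then averaged over readers (the
#' same reader-level averaging used for every other endpoint).
#'
#' @param study a `reader_study`.
#' @param strategies list of [dca_strategy()] objects
#'   (default [default_strategies()]).
#' @param thresholds threshold probability grid; default 5% to 30% in
#'   0.5% steps.
#' @return a `decision_curve` data frame with columns `strategy`, `p_t`,
#'   `nb` and `net_reduction` (net reduction in interventions per 100
#'   patients relative to treat-all).
#' @export
decision_curve <- function(study, strategies = default_strategies(),
                           thresholds = seq(0.05, 0.30, by = 0.005)) {
  stopifnot(inherits(study, "reader_study"))
  if (any(p_bad <- thresholds <= 0 | thresholds >= 1))
    stop_classed("pairedmrmc_domain_error",
                 "thresholds outside (0,1): %s",
                 paste(thresholds[p_bad], collapse = ", "))
  if (is.null(names(strategies)))
    names(strategies) <- vapply(strategies, `[[`, character(1), "name")
  curves <- lapply(names(strategies), function(nm) {
    st <- strategies[[nm]]
    if (!inherits(st, "dca_strategy"))
      stop_classed("pairedmrmc_config_error", "unknown strategy: %s", nm)
    counts <- strategy_counts(study, st)
    nb <- vapply(thresholds, function(pt) {
      mean(vapply(counts, function(ct)
        net_benefit(ct[["tp"]], ct[["fp"]], ct[["n"]], pt), numeric(1)))
    }, numeric(1))
    data.frame(strategy = nm, p_t = thresholds, nb = nb,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, curves)
  nb_all <- out$nb[out$strategy == "treat_all"]
  if (length(nb_all) == length(thresholds)) {
    out$net_reduction <- net_reduction_interventions(
      out$nb, rep(nb_all, length.out = nrow(out)), out$p_t)
  } else {
    out$net_reduction <- NA_real_
  }
  rownames(out) <- NULL
  structure(out, class = c("decision_curve", "data.frame"))
}

#' Net reduction in interventions per 100 patients
#'
#' Expresses a net-benefit advantage over treat-all as the number of
#' interventions avoided per 100 patients without missing additional
#' cancers: 100 * (NB_strategy - NB_all) / (p_t / (1 - p_t)).
#'
#' @param nb_strategy,nb_all net benefits of the strategy and of treat-all.
#' @param p_t threshold probability (vectorized).
#' @return net reduction per 100 patients.
#' @export
net_reduction_interventions <- function(nb_strategy, nb_all, p_t) {
  if (any(p_t <= 0 | p_t >= 1))
    stop_classed("pairedmrmc_domain_error",
                 "threshold probability must lie strictly in (0, 1)")
  100 * (nb_strategy - nb_all) / (p_t / (1 - p_t))
}

#' Examinations needed per additional true-positive diagnosis
#'
#' The reciprocal of a net-benefit difference between two strategies: how
#' many examinations under the better strategy are needed to diagnose one
#' additional case. A zero difference is reported as infinite with a
#' message.
#'
#' @param delta_nb net-benefit difference.
#' @return numeric; `Inf` when `delta_nb == 0`.
#' @examples
#' exams_per_additional_case(0.002)  # 500
#' @export
exams_per_additional_case <- function(delta_nb) {
  stopifnot(length(delta_nb) == 1, is.finite(delta_nb))
  if (delta_nb == 0) {
    message("net-benefit difference is zero: no finite trade-off; reporting Inf")
    return(Inf)
  }
  1 / delta_nb
}
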