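#' Holm-Bonferroni step-down adjustment
#'
#' Adjusts a family of p-values by the Holm step-down rule (via
#' [stats::p.adjust()]) and applies the sequential rejection decision:
#' hypotheses are rejected in ascending order of adjusted p-value while the
#' adjusted value stays at or below `alpha`; the first failure stops all
#' later rejections.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @param alpha family-wise error level.
#' @return data frame with `p_raw`, `p_adj`, `reject`, in input order;
#'   empty input yields an empty data frame.
#' @export
holm_adjust <- function(p, alpha = 0.05) {
  if (length(p) == 0)
    return(data.frame(p_raw = numeric(0), p_adj = numeric(0),
                      reject = logical(0)))
  stopifnot(all(p >= 0 & p <= 1))
  p_adj <- stats::p.adjust(p, method = "holm")
  ord <- order(p)
  reject <- logical(length(p))
  for (k in seq_along(ord)) {
    if (p_adj[ord[k]] <= alpha) reject[ord[k]] <- TRUE else break
  }
  data.frame(p_raw = p, p_adj = p_adj, reject = reject)
}

#' Hierarchical gatekeeping over families of hypotheses
#'
#' Tests a tree of hypotheses level by level. Hypotheses sharing a `family`
#' label are tested together with a Holm adjustment at level `alpha`; a
#' family is tested only if every parent referenced by its members was
#' rejected. Members of untested families are marked `"not tested"` -
#' never "accepted", since no test was performed.
#'
#' The default tree for the paired bp/mp study is a single family holding
#' the three coprimary noninferiority hypotheses (AUROC, sensitivity and
#' specificity at PI-RADS >= 3).
#'
#' @param nodes data frame with columns `hypothesis_id`, `p_raw`, `family`,
#'   and `parent` (`NA` for root-level hypotheses; otherwise a
#'   `hypothesis_id` in an earlier family).
#' @param alpha family-wise error level.
#' @return data frame with per-node `decision` (`"rejected"`,
#'   `"not rejected"`, `"not tested"`) and adjusted p-values (`NA` where
#'   not tested).
#' @export
gatekeep <- function(nodes, alpha = 0.05) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  stopifnot(all(c("hypothesis_id", "p_raw", "family") %in% names(nodes)))
  if (!"parent" %in% names(nodes)) nodes$parent <- NA_character_
  if (anyDuplicated(nodes$hypothesis_id))
    stop_classed("pairedmrmc_structure_error", "duplicate hypothesis_id")
  unknown <- setdiff(stats::na.omit(nodes$parent), nodes$hypothesis_id)
  if (length(unknown))
    stop_classed("pairedmrmc_structure_error",
                 "parent(s) not defined: %s", paste(unknown, collapse = ", "))

  # cycle check via repeated parent-following
  for (id in nodes$hypothesis_id) {
    seen <- character(0); cur <- id
    repeat {
      par <- nodes$parent[nodes$hypothesis_id == cur]
      if (is.na(par)) break
      if (par %in% c(seen, cur))
        stop_classed("pairedmrmc_structure_error",
                     "cycle in hypothesis tree at %s", par)
      seen <- c(seen, cur); cur <- par
    }
  }

  nodes$decision <- "not tested"
  nodes$p_adj <- NA_real_
  decided <- character(0)  # rejected hypothesis ids
  remaining <- unique(nodes$family)
  progress <- TRUE
  while (length(remaining) && progress) {
    progress <- FALSE
    for (fam in remaining) {
      idx <- which(nodes$family == fam)
      parents <- unique(stats::na.omit(nodes$parent[idx]))
      parents_tested <- all(parents %in% nodes$hypothesis_id[
        nodes$decision != "not tested"])
      if (!parents_tested) next
      remaining <- setdiff(remaining, fam)
      progress <- TRUE
      if (all(parents %in% decided)) {
        h <- holm_adjust(nodes$p_raw[idx], alpha)
        nodes$p_adj[idx] <- h$p_adj
        nodes$decision[idx] <- ifelse(h$reject, "rejected", "not rejected")
        decided <- c(decided, nodes$hypothesis_id[idx][h$reject])
      }
      # else: family's gate failed; members stay "not tested"
    }
  }
  nodes
}

#' Default coprimary hypothesis family
#'
#' Builds the gatekeeping input for the three coprimary noninferiority
#' endpoints (AUROC, sensitivity and specificity at the PI-RADS >= 3
#' operating point) as a single Holm family.
#'
#' @param p_auroc,p_sens,p_spec one-sided noninferiority p-values.
#' @return data frame suitable for [gatekeep()].
#' @export
coprimary_family <- function(p_auroc, p_sens, p_spec) {
  data.frame(
    hypothesis_id = c("noninf_auroc", "noninf_sens_p3", "noninf_spec_p3"),
    p_raw = c(p_auroc, p_sens, p_spec),
    family = "coprimary",
    parent = NA_character_,
    stringsAsFactors = FALSE)
}
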