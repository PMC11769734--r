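#' Concordance flow table between bp and mp patient-level categories
#'
#' Cross-tabulates each (reader, case) pair's bp category against its mp
#' category over the categories \{2,3,4,5\}, the accounting behind the
#' upgrade/downgrade flow diagram: cell counts, the concordant fraction
#' (trace over total), and - when case labels are available - the csPCa
#' fraction within each cell.
#'
#' @param study a `reader_study`, or a paired readings data frame.
#' @param cases optional case manifest (needed for per-cell disease
#'   fractions when `study` is a bare readings data frame).
#' @return a `flow_table`: list with `counts` (4x4 matrix, bp rows, mp
#'   columns), `total`, `concordant` (count), `concordant_fraction`, and
#'   `cs_fraction` (4x4 matrix, `NA` where labels are unavailable or the
#'   cell is empty).
#' @export
concordance_flow <- function(study, cases = NULL) {
  if (inherits(study, "reader_study")) {
    readings <- study$readings
    cases <- study$cases
  } else readings <- study
  bp <- readings[readings$modality == "bp", ]
  mp <- readings[readings$modality == "mp", ]
  key_bp <- paste(bp$reader_id, bp$case_id)
  key_mp <- paste(mp$reader_id, mp$case_id)
  if (length(key_bp) != length(key_mp) || !setequal(key_bp, key_mp)) {
    offenders <- c(setdiff(key_bp, key_mp), setdiff(key_mp, key_bp))
    stop_classed("pairedmrmc_pairing_error",
                 "unpaired readings for (reader, case): %s",
                 paste(utils::head(offenders, 5), collapse = "; "))
  }
  mp <- mp[match(key_bp, key_mp), ]
  lv <- as.character(CATEGORIES)
  counts <- table(factor(bp$patient_pirads, levels = CATEGORIES),
                  factor(mp$patient_pirads, levels = CATEGORIES))
  counts <- matrix(as.integer(counts), 4, 4, dimnames = list(bp = lv, mp = lv))
  total <- sum(counts)
  concordant <- sum(diag(counts))

  cs_fraction <- matrix(NA_real_, 4, 4, dimnames = list(bp = lv, mp = lv))
  if (!is.null(cases)) {
    label <- cases$label[match(bp$case_id, cases$case_id)]
    for (a in lv) for (b in lv) {
      in_cell <- bp$patient_pirads == as.integer(a) &
        mp$patient_pirads == as.integer(b)
      if (any(in_cell)) cs_fraction[a, b] <- mean(label[in_cell])
    }
  }
  structure(list(counts = counts, total = total, concordant = concordant,
                 concordant_fraction = concordant / total,
                 cs_fraction = cs_fraction),
            class = "flow_table")
}

#' @export
print.flow_table <- function(x, ...) {
  cat(sprintf("bp -> mp patient-level category flow (%d paired reads)\n",
              x$total))
  print(x$counts)
  cat(sprintf("concordant: %d (%s%%)\n", x$concordant,
              format(as_percent(x$concordant_fraction), nsmall = 1)))
  invisible(x)
}

#' Run the full analysis battery and export report tables
#'
#' Produces the standard result set of a paired bp/mp observer study:
#' per-subgroup (all/expert/nonexpert) Obuchowski-Rockette results for
#' AUROC and for sensitivity/specificity under each positivity rule, the
#' bp/mp concordance flow table, the decision curves, and a JSON run
#' manifest (seed, configuration hash, package version). Percentages in
#' the exported tables are rounded to one decimal; all internal values
#' keep full precision.
#'
#' @param study a `reader_study`.
#' @param out_dir output directory for the CSV/JSON files.
#' @param margin,alpha noninferiority margin and one-sided level.
#' @param seed seed recorded in the manifest (not used for computation).
#' @param run_dca set `FALSE` to skip decision curves; the manifest then
#'   records `"dca": "not run"`.
#' @param quiet suppress progress lines.
#' @return invisibly, a list with `results` (data frame shaped like the
#'   published accuracy tables), `flow`, `dca` and `manifest`.
#' @export
run_report <- function(study, out_dir, margin = 0.05, alpha = 0.05,
                       seed = NA, run_dca = TRUE, quiet = FALSE) {
  stopifnot(inherits(study, "reader_study"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- rbind(
    expand.grid(metric = "auroc", rule = "none",
                subgroup = c("all", "expert", "nonexpert"),
                stringsAsFactors = FALSE),
    expand.grid(metric = c("sensitivity", "specificity"),
                rule = c("p3", "p4psad", "p4"),
                subgroup = c("all", "expert", "nonexpert"),
                stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    rule <- positivity_rule(if (g$rule == "none") "p3" else g$rule)
    res <- or_analysis(study, g$metric, rule, subgroup = g$subgroup,
                       margin = margin, alpha = alpha)
    data.frame(metric = g$metric, rule = g$rule, subgroup = g$subgroup,
               n_readers = res$n_readers,
               bp = as_percent(res$mean_bp), mp = as_percent(res$mean_mp),
               bp_lo = as_percent(res$ci_mean_bp[1]),
               bp_hi = as_percent(res$ci_mean_bp[2]),
               mp_lo = as_percent(res$ci_mean_mp[1]),
               mp_hi = as_percent(res$ci_mean_mp[2]),
               diff = as_percent(res$diff),
               diff_lo = as_percent(res$ci_low),
               diff_hi = as_percent(res$ci_high),
               p_noninf = res$p_noninf,
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  write.csv(results, file.path(out_dir, "accuracy_results.csv"),
            row.names = FALSE)
  log_stage("accuracy tables: %d rows", nrow(results), quiet = quiet)

  flow <- concordance_flow(study)
  flow_df <- as.data.frame(as.table(flow$counts), stringsAsFactors = FALSE)
  names(flow_df) <- c("bp_category", "mp_category", "n")
  flow_df$cs_fraction <- round(as.vector(flow$cs_fraction), 3)
  write.csv(flow_df, file.path(out_dir, "flow_table.csv"), row.names = FALSE)
  log_stage("flow table: concordance %.1f%%",
            100 * flow$concordant_fraction, quiet = quiet)

  dca <- NULL
  if (run_dca) {
    dca <- decision_curve(study)
    dca_out <- dca
    dca_out$nb <- round(dca_out$nb, 4)
    dca_out$net_reduction <- round(dca_out$net_reduction, 2)
    write.csv(dca_out, file.path(out_dir, "decision_curves.csv"),
              row.names = FALSE)
    log_stage("decision curves: %d strategies x %d thresholds",
              length(unique(dca$strategy)), length(unique(dca$p_t)),
              quiet = quiet)
  }

  manifest <- list(
    package = "pairedmrmc",
    version = as.character(utils::packageVersion("pairedmrmc")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    margin = margin, alpha = alpha,
    n_readings = nrow(study$readings), n_cases = nrow(study$cases),
    n_readers = nrow(study$readers),
    config_hash = sum(utf8ToInt(paste(
      capture_config(study), collapse = ""))),
    dca = if (run_dca) "run" else "not run")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(results = results, flow = flow, dca = dca,
                 manifest = manifest))
}

capture_config <- function(study) {
  c(sort(study$readers$reader_id), sort(study$cases$case_id),
    as.character(nrow(study$readings)))
}
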