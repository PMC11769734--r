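#' @importFrom stats aggregate complete.cases cov pnorm qnorm quantile rbinom
#'   rlnorm rnorm runif sd setNames uniroot var
#' @importFrom utils read.csv write.csv
NULL

MODALITIES <- c("bp", "mp")
CATEGORIES <- 2:5

stop_classed <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "pairedmrmc_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

#' Aggregate lesion-level PI-RADS categories to a patient-level category
#'
#' The patient-level PI-RADS category is the highest category among the
#' reader's suspicious lesions (readers assign categories 3-5 to lesions).
#' An exam with no suspicious lesions is negative and coded as category 2,
#' collapsing PI-RADS 1-2 into a single reporting bucket.
#'
#' @param lesion_categories integer vector of lesion categories, each in
#'   \{3, 4, 5\}; may be empty.
#' @return a single patient-level category in \{2, 3, 4, 5\}.
#' @examples
#' aggregate_patient_category(c(3, 5, 4))  # 5
#' aggregate_patient_category(integer(0))  # 2 (negative exam)
#' @export
aggregate_patient_category <- function(lesion_categories) {
  if (length(lesion_categories) == 0) return(2L)
  if (anyNA(lesion_categories) || !all(lesion_categories %in% 3:5))
    stop_classed("pairedmrmc_domain_error",
                 "lesion categories must all be in {3,4,5}; got [%s]",
                 paste(lesion_categories, collapse = ", "))
  as.integer(max(lesion_categories))
}

parse_lesions <- function(x) {
  if (is.na(x) || !nzchar(x)) return(integer(0))
  as.integer(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Construct and validate a paired split-plot reader study
#'
#' Bundles the three long-format tables of an observer study (one row per
#' reader x case x modality reading, a case manifest, a reader manifest)
#' and checks the structural contract: type and range invariants on every
#' field, unique (reader, case, modality) readings, referential integrity,
#' consistency between lesion-level and patient-level categories, and the
#' split-plot contract (blocks partition readers and cases; each reader
#' reads only its own block's cases; readings are paired across the two
#' modalities unless a pair was dropped entirely).
#'
#' @param readings data frame with columns `reader_id`, `case_id`,
#'   `modality` (`"bp"`/`"mp"`), `patient_pirads` (2-5), `suspicion`
#'   (0-100), and optionally `lesions` (semicolon-joined categories 3-5).
#' @param cases data frame with columns `case_id`, `center`, `block_id`,
#'   `label` (0/1, 1 = clinically significant cancer, grade group >= 2),
#'   `gg` (0-5), `psad`, `psa`, `volume`, `age`.
#' @param readers data frame with columns `reader_id`, `block_id`,
#'   `expertise` (`"expert"`/`"nonexpert"`).
#' @return an object of class `reader_study` with elements `readings`,
#'   `cases`, `readers` and `design` (block membership and modality pair).
#' @export
reader_study <- function(readings, cases, readers) {
  readings <- as.data.frame(readings, stringsAsFactors = FALSE)
  cases <- as.data.frame(cases, stringsAsFactors = FALSE)
  readers <- as.data.frame(readers, stringsAsFactors = FALSE)
  if (!"lesions" %in% names(readings)) readings$lesions <- NA_character_
  check_columns(readings, c("reader_id", "case_id", "modality",
                            "patient_pirads", "suspicion"), "readings")
  check_columns(cases, c("case_id", "center", "block_id", "label", "gg",
                         "psad", "psa", "volume", "age"), "cases")
  check_columns(readers, c("reader_id", "block_id", "expertise"), "readers")

  for (id_col in c("reader_id", "case_id"))
    readings[[id_col]] <- as.character(readings[[id_col]])
  cases$case_id <- as.character(cases$case_id)
  readers$reader_id <- as.character(readers$reader_id)
  readings$lesions <- as.character(readings$lesions)
  readings$lesions[is.na(readings$lesions)] <- ""  # absent list, not missing data

  validate_cases(cases)
  validate_readers(readers)
  validate_readings(readings, cases, readers)

  design <- infer_design(cases, readers, readings)
  structure(list(readings = readings, cases = cases, readers = readers,
                 design = design),
            class = "reader_study")
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_classed("pairedmrmc_schema_error",
                 "%s: missing column(s): %s", what,
                 paste(missing, collapse = ", "))
}

validate_cases <- function(cases) {
  if (anyDuplicated(cases$case_id))
    stop_classed("pairedmrmc_integrity_error", "cases: duplicate case_id")
  if (!all(cases$label %in% c(0L, 1L)))
    stop_classed("pairedmrmc_domain_error", "cases: label must be 0 or 1")
  if (!all(cases$gg %in% 0:5))
    stop_classed("pairedmrmc_domain_error", "cases: gg must be in 0..5")
  bad <- cases$case_id[(cases$label == 1) != (cases$gg >= 2)]
  if (length(bad))
    stop_classed("pairedmrmc_domain_error",
                 "cases: label inconsistent with grade group (csPCa iff GG>=2): %s",
                 paste(utils::head(bad, 5), collapse = ", "))
  for (col in c("psad", "psa", "volume", "age")) {
    v <- cases[[col]]
    if (any(v < 0, na.rm = TRUE))
      stop_classed("pairedmrmc_domain_error", "cases: negative %s", col)
  }
  invisible(TRUE)
}

validate_readers <- function(readers) {
  if (anyDuplicated(readers$reader_id))
    stop_classed("pairedmrmc_integrity_error", "readers: duplicate reader_id")
  if (!all(readers$expertise %in% c("expert", "nonexpert")))
    stop_classed("pairedmrmc_domain_error",
                 "readers: expertise must be 'expert' or 'nonexpert'")
  invisible(TRUE)
}

validate_readings <- function(readings, cases, readers) {
  if (!all(readings$modality %in% MODALITIES))
    stop_classed("pairedmrmc_domain_error",
                 "readings: modality must be one of %s",
                 paste(MODALITIES, collapse = "/"))
  if (!all(readings$patient_pirads %in% CATEGORIES))
    stop_classed("pairedmrmc_domain_error",
                 "readings: patient_pirads must be in {2,3,4,5}")
  if (any(is.na(readings$suspicion)) ||
      any(readings$suspicion < 0 | readings$suspicion > 100))
    stop_classed("pairedmrmc_domain_error",
                 "readings: suspicion must lie in [0, 100]")

  key <- paste(readings$reader_id, readings$case_id, readings$modality)
  if (anyDuplicated(key))
    stop_classed("pairedmrmc_integrity_error",
                 "readings: duplicate (reader, case, modality) rows: %s",
                 paste(utils::head(unique(key[duplicated(key)]), 3),
                       collapse = "; "))

  orphan_case <- setdiff(readings$case_id, cases$case_id)
  if (length(orphan_case))
    stop_classed("pairedmrmc_reference_error",
                 "readings reference unknown case(s): %s",
                 paste(utils::head(orphan_case, 5), collapse = ", "))
  orphan_reader <- setdiff(readings$reader_id, readers$reader_id)
  if (length(orphan_reader))
    stop_classed("pairedmrmc_reference_error",
                 "readings reference unknown reader(s): %s",
                 paste(utils::head(orphan_reader, 5), collapse = ", "))

  # lesion list must aggregate to the recorded patient category
  for (i in seq_len(nrow(readings))) {
    les <- parse_lesions(readings$lesions[i])
    expected <- aggregate_patient_category(les)
    if (length(les) == 0 && readings$patient_pirads[i] != 2L) next
    # a category-3+ exam may omit the lesion list entirely (optional field);
    # when present it must agree
    if (length(les) > 0 && readings$patient_pirads[i] != expected)
      stop_classed("pairedmrmc_domain_error",
        "readings: patient_pirads %d disagrees with lesion list [%s] (row %d)",
        readings$patient_pirads[i], readings$lesions[i], i)
  }

  # reader must stay inside its block
  case_block <- setNames(cases$block_id, cases$case_id)
  reader_block <- setNames(readers$block_id, readers$reader_id)
  bad <- reader_block[readings$reader_id] != case_block[readings$case_id]
  if (any(bad))
    stop_classed("pairedmrmc_design_error",
                 "readings cross block boundaries (e.g. reader %s, case %s)",
                 readings$reader_id[which(bad)[1]],
                 readings$case_id[which(bad)[1]])

  # pairing: every (reader, case) pair present under both modalities
  pair <- paste(readings$reader_id, readings$case_id)
  n_mod <- table(pair)
  unpaired <- names(n_mod)[n_mod != 2L]
  if (length(unpaired))
    stop_classed("pairedmrmc_pairing_error",
                 "unpaired (reader, case) readings: %s",
                 paste(utils::head(unpaired, 5), collapse = "; "))
  invisible(TRUE)
}

infer_design <- function(cases, readers, readings) {
  block_ids <- sort(unique(c(cases$block_id, readers$block_id)))
  blocks <- lapply(block_ids, function(b) {
    list(readers = sort(readers$reader_id[readers$block_id == b]),
         cases = sort(cases$case_id[cases$block_id == b]))
  })
  names(blocks) <- block_ids
  list(blocks = blocks, modalities = MODALITIES)
}

#' @export
print.reader_study <- function(x, ...) {
  cat(sprintf(
    "Paired split-plot reader study: %d readings, %d cases (%d csPCa), %d readers, %d blocks\n",
    nrow(x$readings), nrow(x$cases), sum(x$cases$label),
    nrow(x$readers), length(x$design$blocks)))
  invisible(x)
}

#' Load a reader study from CSV files
#'
#' Reads the three long-format CSV tables (readings, case manifest, reader
#' manifest), validates every structural invariant, and infers the
#' split-plot design from the manifests.
#'
#' @param readings_path,cases_path,readers_path paths to UTF-8 CSV files
#'   with header rows; see [reader_study()] for the column contracts.
#' @param quiet suppress the row-count log line.
#' @return a validated `reader_study`.
#' @export
load_study <- function(readings_path, cases_path, readers_path,
                       quiet = FALSE) {
  for (p in c(readings_path, cases_path, readers_path))
    if (!file.exists(p))
      stop_classed("pairedmrmc_io_error", "no such file: %s", p)
  readings <- read.csv(readings_path, stringsAsFactors = FALSE,
                       colClasses = c(reader_id = "character",
                                      case_id = "character"))
  cases <- read.csv(cases_path, stringsAsFactors = FALSE,
                    colClasses = c(case_id = "character"))
  readers <- read.csv(readers_path, stringsAsFactors = FALSE,
                      colClasses = c(reader_id = "character"))
  if ("lesions" %in% names(readings))
    readings$lesions <- as.character(readings$lesions)
  study <- reader_study(readings, cases, readers)
  log_stage("loaded study: %d readings, %d cases, %d readers, %d blocks",
            nrow(study$readings), nrow(study$cases), nrow(study$readers),
            length(study$design$blocks), quiet = quiet)
  study
}

#' Write a reader study to CSV files
#'
#' Inverse of [load_study()]: writes `readings.csv`, `cases.csv` and
#' `readers.csv` under `dir` so that loading them reproduces the study
#' exactly (round-trip identity).
#'
#' @param study a `reader_study`.
#' @param dir output directory (created if absent).
#' @return invisibly, the three file paths.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "reader_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("readings.csv", "cases.csv", "readers.csv"))
  write.csv(study$readings, paths[1], row.names = FALSE, na = "")
  write.csv(study$cases, paths[2], row.names = FALSE, na = "")
  write.csv(study$readers, paths[3], row.names = FALSE, na = "")
  invisible(paths)
}

#' Drop noncompliant (reader, case) assessments
#'
#' Removes both modality rows for each excluded (reader, case) pair, so
#' the paired structure the jackknife relies on is preserved, and reports
#' the retained fraction of patient assessments. Exclusions are counted in
#' (reader, case) units: one "assessment" covers both modality reads.
#'
#' @param study a `reader_study`, or a readings data frame.
#' @param exclusions data frame with columns `reader_id`, `case_id`.
#' @return a list with `study` (or `readings`), and `report` containing
#'   `n_total`, `n_excluded`, `n_retained` (assessment counts) and
#'   `retained_pct` (percentage, 1 decimal).
#' @export
exclude_noncompliant <- function(study, exclusions) {
  readings <- if (inherits(study, "reader_study")) study$readings else study
  exclusions <- as.data.frame(exclusions, stringsAsFactors = FALSE)
  pair <- paste(readings$reader_id, readings$case_id)
  excl_pair <- unique(paste(exclusions$reader_id, exclusions$case_id))
  unknown <- setdiff(excl_pair, pair)
  if (length(unknown))
    warning(sprintf("exclusion of %d unknown (reader, case) pair(s) ignored",
                    length(unknown)))
  keep <- !(pair %in% excl_pair)
  n_total <- length(unique(pair))
  n_excluded <- length(intersect(excl_pair, pair))
  report <- list(
    n_total = n_total,
    n_excluded = n_excluded,
    n_retained = n_total - n_excluded,
    retained_pct = round(100 * (n_total - n_excluded) / n_total, 1))
  retained <- readings[keep, , drop = FALSE]
  rownames(retained) <- NULL
  if (inherits(study, "reader_study")) {
    study$readings <- retained
    list(study = study, report = report)
  } else {
    list(readings = retained, report = report)
  }
}
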