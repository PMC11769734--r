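#' Configuration for the paired split-plot reader-study simulator
#'
#' The simulator draws a latent suspicion variable for every reader x case
#' x modality read from a Roe-Metz-style variance-component model:
#' \deqn{X_{ijk} = t_k \mu_{ij} + C_k + R_{j t_k} + RC_{jk} + MC_{ik} +
#'   MR_{ij t_k} + \epsilon_{ijk}}
#' where \eqn{t_k} is the case's disease status, \eqn{\mu_{ij} = \mu_{sep}
#' - d \cdot 1[\mathrm{nonexpert}_j] + \Delta \cdot 1[i = mp]} is the
#' effective class separation, and the random components (case, reader,
#' reader x case, modality x case, modality x reader, pure error) are
#' independent zero-mean normals. Components indexed identically are drawn
#' once and shared across the two modalities, producing the strong bp/mp
#' pairing real readers exhibit; reader-level components are drawn per
#' truth state (the Roe-Metz device that makes accuracy vary across
#' readers). The 0-100 suspicion score and the patient-level PI-RADS
#' category are deterministic monotone transforms of the same latent draw,
#' so a higher score always accompanies an equal-or-higher category.
#'
#' Default sizes and calibration reproduce the published study's
#' marginals: 400 cases at 33.25% csPCa prevalence over 4 centers and 4
#' blocks, 62 readers (46 expert / 16 nonexpert), mean reader AUROC near
#' 0.85 with experts outperforming nonexperts by about 0.04, about 91% of
#' reads with identical bp/mp patient category, patient-level category
#' frequencies near 49/7/18/27% for PI-RADS <=2/3/4/5, and a pooled PSA
#' density distribution with median/IQR near 0.13 (0.09-0.21) ng/ml^2.
#'
#' @param n_cases,prevalence,n_blocks,n_readers,expert_fraction study size.
#' @param mu_sep latent class separation for expert readers.
#' @param expertise_deficit separation shortfall of nonexpert readers.
#' @param delta additive mp separation benefit (0 = no modality effect).
#' @param sigma2_case,sigma2_reader,sigma2_reader_case,sigma2_mod_case,sigma2_mod_reader,sigma2_error
#'   variance components of the latent model.
#' @param category_targets marginal read-level frequencies for categories
#'   <=2, 3, 4, 5 used to place the cutpoints.
#' @param psad_meanlog_pos,psad_meanlog_neg,psad_sdlog lognormal PSA
#'   density parameters by disease class.
#' @param cutpoints optional explicit latent cutpoints `c(c3, c4, c5)`;
#'   computed from `category_targets` when `NULL`.
#' @return a `sim_config` list with derived fields (`cutpoints`,
#'   `score_center`, `score_scale`).
#' @export
sim_config <- function(n_cases = 400, prevalence = 0.3325, n_blocks = 4,
                       n_readers = 62, expert_fraction = 46 / 62,
                       mu_sep = 1.702, expertise_deficit = 0.244,
                       delta = 0,
                       sigma2_case = 1, sigma2_reader = 0.03,
                       sigma2_reader_case = 0.2,
                       sigma2_mod_case = 0.004,
                       sigma2_mod_reader = 0.001,
                       sigma2_error = 0.006,
                       category_targets = c(0.49, 0.07, 0.18, 0.27),
                       psad_meanlog_pos = log(0.18),
                       psad_meanlog_neg = log(0.11),
                       psad_sdlog = 0.55,
                       cutpoints = NULL) {
  vars <- c(sigma2_case, sigma2_reader, sigma2_reader_case,
            sigma2_mod_case, sigma2_mod_reader, sigma2_error)
  if (any(vars < 0)) stop_classed("pairedmrmc_config_error",
                                  "variance components must be nonnegative")
  if (prevalence < 0 || prevalence > 1)
    stop_classed("pairedmrmc_config_error", "prevalence must lie in [0, 1]")
  stopifnot(n_blocks >= 1, n_readers >= 1, n_cases >= n_blocks)
  cfg <- list(n_cases = n_cases, prevalence = prevalence,
              n_blocks = n_blocks, n_readers = n_readers,
              expert_fraction = expert_fraction,
              mu_sep = mu_sep, expertise_deficit = expertise_deficit,
              delta = delta,
              sigma2_case = sigma2_case, sigma2_reader = sigma2_reader,
              sigma2_reader_case = sigma2_reader_case,
              sigma2_mod_case = sigma2_mod_case,
              sigma2_mod_reader = sigma2_mod_reader,
              sigma2_error = sigma2_error,
              category_targets = category_targets,
              psad_meanlog_pos = psad_meanlog_pos,
              psad_meanlog_neg = psad_meanlog_neg,
              psad_sdlog = psad_sdlog)
  class(cfg) <- "sim_config"
  mom <- latent_moments(cfg)
  cfg$score_center <- mom$mean
  cfg$score_scale <- mom$sd
  cfg$cutpoints <- if (is.null(cutpoints))
    calibrate_cutpoints(cfg, category_targets) else cutpoints
  if (length(cfg$cutpoints) != 3)
    stop_classed("pairedmrmc_config_error", "need exactly 3 cutpoints")
  fin <- is.finite(cfg$cutpoints)
  if (any(fin) && is.unsorted(cfg$cutpoints[fin], strictly = TRUE))
    stop_classed("pairedmrmc_calibration_error",
                 "cutpoints must be strictly increasing")
  cfg
}

mu_effective <- function(cfg, modality, expertise) {
  cfg$mu_sep -
    cfg$expertise_deficit * (expertise == "nonexpert") +
    cfg$delta * (modality == "mp")
}

sigma2_within <- function(cfg) {
  cfg$sigma2_case + cfg$sigma2_reader + cfg$sigma2_reader_case +
    cfg$sigma2_mod_case + cfg$sigma2_mod_reader + cfg$sigma2_error
}

# mixture cells of the pooled latent distribution: truth x expertise x
# modality, each normal with the within-cell variance
latent_cells <- function(cfg) {
  grid <- expand.grid(t = c(0, 1), expertise = c("expert", "nonexpert"),
                      modality = MODALITIES, stringsAsFactors = FALSE)
  w_e <- c(expert = cfg$expert_fraction, nonexpert = 1 - cfg$expert_fraction)
  grid$weight <- ifelse(grid$t == 1, cfg$prevalence, 1 - cfg$prevalence) *
    w_e[grid$expertise] * 0.5
  grid$mean <- grid$t * mu_effective(cfg, grid$modality, grid$expertise)
  grid$sd <- sqrt(sigma2_within(cfg))
  grid
}

latent_moments <- function(cfg) {
  cells <- latent_cells(cfg)
  m <- sum(cells$weight * cells$mean)
  v <- sum(cells$weight * (cells$sd^2 + cells$mean^2)) - m^2
  list(mean = m, sd = sqrt(v))
}

latent_cdf <- function(cfg, x) {
  cells <- latent_cells(cfg)
  vapply(x, function(xx)
    sum(cells$weight * pnorm(xx, cells$mean, cells$sd)), numeric(1))
}

#' Place category cutpoints to match target marginal frequencies
#'
#' Chooses the latent cutpoints c3 < c4 < c5 as the quantiles of the
#' pooled latent read distribution at the cumulative target frequencies,
#' so the simulated marginal PI-RADS category mix matches `targets`.
#' By default the quantiles are taken from the exact mixture distribution
#' implied by the configuration; passing a simulated latent sample uses
#' its empirical quantiles instead.
#'
#' @param cfg a [sim_config()] (class may be incomplete during
#'   construction).
#' @param targets frequencies for categories <=2, 3, 4, 5; positive parts
#'   must sum to about 1.
#' @param latent optional numeric sample of pooled latent reads.
#' @return numeric cutpoints `c(c3, c4, c5)`; a zero tail target yields an
#'   infinite cutpoint (the category is never produced).
#' @export
calibrate_cutpoints <- function(cfg, targets, latent = NULL) {
  if (length(targets) != 4 || any(targets < 0) ||
      abs(sum(targets) - 1) > 0.02)
    stop_classed("pairedmrmc_calibration_error",
                 "targets must be 4 nonnegative frequencies summing to ~1")
  targets <- targets / sum(targets)  # tolerate rounded published percentages
  q <- cumsum(targets)[1:3]
  if (!is.null(latent)) {
    cuts <- unname(quantile(latent, pmin(q, 1), type = 7))
    cuts[q >= 1] <- Inf
  } else {
    rng <- c(-20, 20) * max(1, sqrt(sigma2_within(cfg)))
    cuts <- vapply(q, function(p) {
      if (p >= 1) return(Inf)
      if (p <= 0) return(-Inf)
      uniroot(function(x) latent_cdf(cfg, x) - p,
              interval = rng, tol = 1e-9)$root
    }, numeric(1))
  }
  fin <- is.finite(cuts)
  if (any(fin) && is.unsorted(cuts[fin], strictly = FALSE))
    stop_classed("pairedmrmc_calibration_error",
                 "non-monotone quantiles: targets infeasible")
  cuts
}

#' Expected per-population mean reader AUROC under the latent model
#'
#' Closed binormal form: a reader with effective separation mu sees
#' diseased and nondiseased latents differing by mu plus the reader's
#' truth-state deviations, so the population mean AUROC is
#' \eqn{\Phi(\mu / \sqrt{2\sigma^2_{cv} + 2(\sigma^2_R + \sigma^2_{MR})})}
#' with \eqn{\sigma^2_{cv}} the case-varying variance
#' (case + reader x case + modality x case + error), averaged over the
#' expertise mix.
#'
#' @param cfg a [sim_config()].
#' @param modality `"bp"` or `"mp"`.
#' @return expected mean reader AUROC.
#' @export
expected_auroc <- function(cfg, modality = "bp") {
  s2_cv <- cfg$sigma2_case + cfg$sigma2_reader_case +
    cfg$sigma2_mod_case + cfg$sigma2_error
  s_eff <- sqrt(2 * s2_cv + 2 * (cfg$sigma2_reader + cfg$sigma2_mod_reader))
  w_e <- c(expert = cfg$expert_fraction, nonexpert = 1 - cfg$expert_fraction)
  sum(w_e * pnorm(mu_effective(cfg, modality, names(w_e)) / s_eff))
}

#' Modality effect giving a prescribed true AUROC difference
#'
#' Solves for the latent mp separation benefit `delta` such that the
#' expected bp - mp mean AUROC difference equals `target_diff` (negative
#' values mean mp is better), using the closed form of
#' [expected_auroc()].
#'
#' @param cfg a [sim_config()].
#' @param target_diff desired bp - mp AUROC difference.
#' @return the `delta` value.
#' @export
calibrate_modality_effect <- function(cfg, target_diff) {
  f <- function(d) {
    cfg$delta <- d
    expected_auroc(cfg, "bp") - expected_auroc(cfg, "mp") - target_diff
  }
  uniroot(f, interval = c(-5, 5), tol = 1e-9)$root
}

largest_remainder <- function(total, shares) {
  # integer apportionment of `total` across blocks proportional to shares
  ideal <- total * shares / sum(shares)
  base <- floor(ideal)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(ideal - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate the case manifest with block allocation
#'
#' Draws disease labels at the configured prevalence, stratified as evenly
#' as possible across blocks (largest-remainder apportionment of the
#' rounded total positive count), assigns centers round-robin, draws
#' PSA density lognormally with a class-dependent location (so the pooled
#' median/IQR sits near 0.13 (0.09-0.21) ng/ml^2), prostate volume
#' lognormally, serum PSA as the product PSAd x volume, and grade groups
#' with the published frequency mix within each class.
#'
#' @param cfg a [sim_config()].
#' @param seed master seed; the case substream is derived from it.
#' @return data frame of case records with `block_id`.
#' @export
simulate_cases <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  n_b <- largest_remainder(cfg$n_cases, rep(1, cfg$n_blocks))
  if (length(unique(n_b)) > 1)
    warning("n_cases not divisible by n_blocks; block sizes differ by 1")
  total_pos <- round(cfg$prevalence * cfg$n_cases)
  pos_b <- largest_remainder(total_pos, n_b)

  with_seed(derive_seed(seed, "cases"), {
    block_id <- rep(paste0("B", seq_len(cfg$n_blocks)), times = n_b)
    label <- unlist(lapply(seq_len(cfg$n_blocks), function(b) {
      v <- c(rep(1L, pos_b[b]), rep(0L, n_b[b] - pos_b[b]))
      sample(v)
    }))
    n <- cfg$n_cases
    case_id <- sprintf("case-%04d", seq_len(n))
    center <- paste0("C", ((seq_len(n) - 1L) %% 4L) + 1L)
    psad <- rlnorm(n,
                   ifelse(label == 1, cfg$psad_meanlog_pos,
                          cfg$psad_meanlog_neg),
                   cfg$psad_sdlog)
    volume <- rlnorm(n, log(54), 0.49)
    psa <- psad * volume
    age <- pmin(pmax(round(rnorm(n, 66, 6)), 45), 90)
    # grade-group mix within class (published case-mix proportions)
    gg <- integer(n)
    gg[label == 1] <- sample(2:5, sum(label), replace = TRUE,
                             prob = c(67, 38, 10, 18))
    gg[label == 0] <- sample(0:1, sum(label == 0), replace = TRUE,
                             prob = c(209, 58))
    data.frame(case_id = case_id, center = center, block_id = block_id,
               label = label, gg = gg,
               psad = round(psad, 4), psa = round(psa, 2),
               volume = round(volume, 1), age = age,
               stringsAsFactors = FALSE)
  })
}

#' Simulate the reader manifest with block allocation
#'
#' Allocates `n_readers` readers (the configured expert fraction, rounded)
#' round-robin across blocks, stratified by expertise so each block gets a
#' near-equal share of experts and nonexperts.
#'
#' @inheritParams simulate_cases
#' @return data frame of reader records.
#' @export
simulate_readers <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  n_exp <- round(cfg$expert_fraction * cfg$n_readers)
  expertise <- c(rep("expert", n_exp), rep("nonexpert", cfg$n_readers - n_exp))
  # stratified round-robin block assignment within each expertise stratum
  block <- character(cfg$n_readers)
  block[expertise == "expert"] <-
    paste0("B", ((seq_len(n_exp) - 1L) %% cfg$n_blocks) + 1L)
  block[expertise == "nonexpert"] <-
    paste0("B", ((seq_len(cfg$n_readers - n_exp) - 1L) %% cfg$n_blocks) + 1L)
  data.frame(reader_id = sprintf("reader-%02d", seq_len(cfg$n_readers)),
             block_id = block, expertise = expertise,
             stringsAsFactors = FALSE)
}

#' Simulate paired bp/mp readings for every reader on its block's cases
#'
#' Draws the latent variable of the Roe-Metz-style model (see
#' [sim_config()]) and transforms it deterministically into the 0-100
#' suspicion score (probit transform standardized by the pooled latent
#' moments, rounded to integers) and the patient-level PI-RADS category
#' (cutpoints). Case-level components are drawn in a case substream and
#' reader-level components in per-reader substreams, so adding readers
#' leaves existing draws untouched.
#'
#' @param cfg a [sim_config()].
#' @param cases output of [simulate_cases()].
#' @param readers output of [simulate_readers()].
#' @param seed master seed.
#' @return data frame of readings (both modalities for every reader x case
#'   pair in the reader's block).
#' @export
simulate_readings <- function(cfg, cases, readers, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- nrow(cases)
  case_fx <- with_seed(derive_seed(seed, "case-effects"), list(
    C = rnorm(n, 0, sqrt(cfg$sigma2_case)),
    MC_bp = rnorm(n, 0, sqrt(cfg$sigma2_mod_case)),
    MC_mp = rnorm(n, 0, sqrt(cfg$sigma2_mod_case))))
  names(case_fx$C) <- names(case_fx$MC_bp) <- names(case_fx$MC_mp) <-
    cases$case_id

  out <- vector("list", nrow(readers))
  for (r in seq_len(nrow(readers))) {
    rid <- readers$reader_id[r]
    exp_r <- readers$expertise[r]
    idx <- which(cases$block_id == readers$block_id[r])
    ids <- cases$case_id[idx]
    t_k <- cases$label[idx]
    m <- length(idx)
    draws <- with_seed(derive_seed(seed, paste0("reader-", rid)), list(
      R = rnorm(2, 0, sqrt(cfg$sigma2_reader)),          # truth states 0, 1
      MR = matrix(rnorm(4, 0, sqrt(cfg$sigma2_mod_reader)), 2, 2,
                  dimnames = list(MODALITIES, NULL)),    # modality x truth
      RC = rnorm(m, 0, sqrt(cfg$sigma2_reader_case)),
      eps_bp = rnorm(m, 0, sqrt(cfg$sigma2_error)),
      eps_mp = rnorm(m, 0, sqrt(cfg$sigma2_error))))
    shared <- case_fx$C[ids] + draws$R[t_k + 1L] + draws$RC
    lat <- list(
      bp = t_k * mu_effective(cfg, "bp", exp_r) + shared +
        case_fx$MC_bp[ids] + draws$MR["bp", t_k + 1L] + draws$eps_bp,
      mp = t_k * mu_effective(cfg, "mp", exp_r) + shared +
        case_fx$MC_mp[ids] + draws$MR["mp", t_k + 1L] + draws$eps_mp)
    rows <- lapply(MODALITIES, function(i) {
      x <- lat[[i]]
      category <- 2L + findInterval(x, cfg$cutpoints)
      data.frame(reader_id = rid, case_id = ids, modality = i,
                 patient_pirads = category,
                 suspicion = round(100 * pnorm(x, cfg$score_center,
                                               cfg$score_scale)),
                 lesions = ifelse(category >= 3L, as.character(category), ""),
                 stringsAsFactors = FALSE)
    })
    out[[r]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a complete paired split-plot reader study
#'
#' Runs [simulate_cases()], [simulate_readers()] and [simulate_readings()]
#' from one master seed, validates the result through [reader_study()],
#' and optionally writes the three CSV files.
#'
#' @param cfg a [sim_config()].
#' @param seed master seed; a fixed seed reproduces the study exactly.
#' @param out_dir optional directory for `readings.csv`, `cases.csv`,
#'   `readers.csv`.
#' @return a validated `reader_study`.
#' @export
simulate_study <- function(cfg = sim_config(), seed = 1, out_dir = NULL) {
  cases <- simulate_cases(cfg, seed)
  readers <- simulate_readers(cfg, seed)
  readings <- simulate_readings(cfg, cases, readers, seed)
  study <- reader_study(readings, cases, readers)
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}
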