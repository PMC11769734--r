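#' Leave-one-case-out jackknife of a reader's accuracy
#'
#' Recomputes one reader's accuracy under one modality with each case
#' deleted in turn. These vectors feed the Obuchowski-Rockette covariance
#' estimator. Fast closed-form updates are used (pairwise Mann-Whitney
#' decomposition for AUROC; count updates for sensitivity/specificity); a
#' deletion that leaves a single-class sample yields `NA` for that element
#' with a warning naming the case.
#'
#' @param sub data frame of one reader's readings under one modality, with
#'   columns `case_id`, `suspicion`, `patient_pirads`, `label`, `psad`.
#' @param metric `"auroc"`, `"sensitivity"` or `"specificity"`.
#' @param rule a [positivity_rule()] (ignored for AUROC).
#' @return named numeric vector (names = case ids) of leave-one-out values,
#'   length `nrow(sub)`.
#' @export
jackknife_accuracies <- function(sub,
                                 metric = c("auroc", "sensitivity",
                                            "specificity"),
                                 rule = positivity_rule("p3")) {
  metric <- match.arg(metric)
  stopifnot(nrow(sub) >= 3L)
  labels <- as.integer(sub$label)
  n <- nrow(sub)
  out <- numeric(n)
  names(out) <- sub$case_id

  if (metric == "auroc") {
    pos <- which(labels == 1L)
    neg <- which(labels == 0L)
    np <- length(pos); nn <- length(neg)
    if (np == 0L || nn == 0L)
      stop_classed("pairedmrmc_degenerate_error",
                   "jackknife AUROC needs both classes")
    sp <- sub$suspicion[pos]; sn <- sub$suspicion[neg]
    M <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
    W <- sum(M)
    if (np >= 2L) out[pos] <- (W - rowSums(M)) / ((np - 1) * nn)
    else out[pos] <- NA_real_
    if (nn >= 2L) out[neg] <- (W - colSums(M)) / (np * (nn - 1))
    else out[neg] <- NA_real_
  } else {
    calls <- apply_positivity_rule(sub$patient_pirads, sub$psad, rule)
    if (metric == "sensitivity") {
      pos <- labels == 1L
      np <- sum(pos)
      tp <- sum(calls & pos)
      full <- tp / np
      out[!pos] <- full  # deleting a negative never changes sensitivity
      out[pos] <- if (np >= 2L) (tp - calls[pos]) / (np - 1) else NA_real_
    } else {
      neg <- labels == 0L
      nn <- sum(neg)
      tn <- sum(!calls & neg)
      full <- tn / nn
      out[!neg] <- full
      out[neg] <- if (nn >= 2L) (tn - !calls[neg]) / (nn - 1) else NA_real_
    }
  }
  if (anyNA(out))
    warning(sprintf("leave-one-out sample single-class for case(s): %s",
                    paste(names(out)[is.na(out)], collapse = ", ")))
  out
}

jk_cov <- function(v1, v2) {
  common <- intersect(names(v1), names(v2))
  x <- v1[common]; y <- v2[common]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  ((n - 1) / n) * sum((x - mean(x)) * (y - mean(y)))
}

#' Obuchowski-Rockette covariance components for a split-plot study
#'
#' Estimates the error covariance structure of the reader-by-modality
#' accuracy table by the case jackknife, separately within each split-plot
#' block (readers in different blocks share no cases, so their error
#' covariances are structurally zero). Within a block, the pairwise
#' jackknife covariance between units (i, j) and (i', j') is
#' \eqn{((n-1)/n) \sum_k (\theta^{(k)}_{ij} - \bar\theta_{ij})
#' (\theta^{(k)}_{i'j'} - \bar\theta_{i'j'})}{((n-1)/n) sum_k ...};
#' the classical components are means over qualifying pairs:
#' `var_error` (same unit), `cov1` (same reader, different modality),
#' `cov2` (same modality, different readers), `cov3` (different both).
#' Negative component means are truncated at zero for inference; raw
#' values are retained in the output.
#'
#' @param acc_table an `accuracy_table` from [per_reader_metric_table()].
#' @param jk named list of jackknife vectors, one per (modality, reader)
#'   unit, with names `"<modality>.<reader_id>"`; built automatically by
#'   [or_analysis()].
#' @return an object of class `or_components`: per-block component
#'   estimates, treatment-by-reader mean squares, per-modality reader mean
#'   squares, block means, and pair-count-weighted overall components.
#' @export
covariance_components <- function(acc_table, jk) {
  stopifnot(inherits(acc_table, "accuracy_table"))
  blocks <- sort(unique(acc_table$block_id))
  per_block <- lapply(blocks, function(b) {
    tab <- acc_table[acc_table$block_id == b, ]
    readers <- sort(unique(tab$reader_id))
    J <- length(readers)
    theta <- matrix(NA_real_, nrow = 2, ncol = J,
                    dimnames = list(MODALITIES, readers))
    for (i in MODALITIES) for (j in readers) {
      v <- tab$value[tab$modality == i & tab$reader_id == j]
      if (length(v) != 1L)
        stop_classed("pairedmrmc_pairing_error",
                     "reader %s lacks a value under modality %s", j, i)
      theta[i, j] <- v
    }
    units <- expand.grid(modality = MODALITIES, reader = readers,
                         stringsAsFactors = FALSE)
    key <- paste(units$modality, units$reader, sep = ".")
    miss <- setdiff(key, names(jk))
    if (length(miss))
      stop_classed("pairedmrmc_pairing_error",
                   "missing jackknife vector(s): %s",
                   paste(miss, collapse = ", "))
    U <- nrow(units)
    sums <- c(var_error = 0, cov1 = 0, cov2 = 0, cov3 = 0)
    counts <- c(var_error = 0, cov1 = 0, cov2 = 0, cov3 = 0)
    for (a in seq_len(U)) for (bb in a:U) {
      cv <- jk_cov(jk[[key[a]]], jk[[key[bb]]])
      if (is.na(cv)) next
      kind <- if (a == bb) "var_error"
        else if (units$reader[a] == units$reader[bb]) "cov1"
        else if (units$modality[a] == units$modality[bb]) "cov2"
        else "cov3"
      sums[kind] <- sums[kind] + cv
      counts[kind] <- counts[kind] + 1
    }
    comps <- ifelse(counts > 0, sums / counts, NA_real_)
    names(comps) <- names(sums)
    # treatment-by-reader interaction mean square, I = 2 modalities
    resid <- theta - rowMeans(theta) -
      rep(colMeans(theta), each = 2) + mean(theta)
    ms_tr <- if (J >= 2) sum(resid^2) / (J - 1) else NA_real_
    ms_r <- apply(theta, 1, var)  # reader mean square within each modality
    n_cases <- length(jk[[key[1]]])
    list(block_id = b, n_readers = J, n_cases = n_cases,
         theta = theta, components = comps, pair_counts = counts,
         ms_tr = ms_tr, ms_r = ms_r,
         mean_bp = mean(theta["bp", ]), mean_mp = mean(theta["mp", ]))
  })
  names(per_block) <- blocks

  totals <- Reduce(`+`, lapply(per_block, function(x)
    ifelse(is.na(x$components), 0, x$components) * x$pair_counts))
  counts <- Reduce(`+`, lapply(per_block, `[[`, "pair_counts"))
  overall_raw <- totals / counts
  overall <- pmax(overall_raw, 0)
  overall[-1] <- pmin(overall[-1], overall[["var_error"]])

  structure(list(blocks = per_block,
                 overall = overall, overall_raw = overall_raw,
                 metric = attr(acc_table, "metric")),
            class = "or_components")
}

#' @export
print.or_components <- function(x, ...) {
  cat(sprintf("OR covariance components (%s), %d block(s):\n",
              x$metric, length(x$blocks)))
  print(signif(x$overall, 4))
  invisible(x)
}

#' Pool split-plot blocks into overall means and a difference variance
#'
#' Each block contributes an independent Obuchowski-Rockette analysis
#' (disjoint readers and cases). The block variance of the bp - mp
#' difference is \eqn{(2/J_b)(MS_{TR,b} + J_b \max(cov2_b - cov3_b, 0))};
#' overall means are reader-count-weighted block means and the pooled
#' variance is \eqn{\sum_b w_b^2 Var_b} with \eqn{w_b = J_b / J}.
#' Denominator degrees of freedom are Hillis-style per block and combined
#' by Satterthwaite.
#'
#' @param components an `or_components` object.
#' @return list with pooled means, difference, standard errors, per-block
#'   detail and Satterthwaite degrees of freedom.
#' @export
pool_blocks <- function(components) {
  stopifnot(inherits(components, "or_components"))
  blk <- components$blocks
  usable <- vapply(blk, function(b) b$n_readers >= 2L, logical(1))
  if (any(!usable))
    warning(sprintf("block(s) with <2 readers excluded: %s",
                    paste(names(blk)[!usable], collapse = ", ")))
  blk <- blk[usable]
  if (!length(blk))
    stop_classed("pairedmrmc_design_error", "no block with >= 2 readers")
  J_b <- vapply(blk, `[[`, numeric(1), "n_readers")
  J <- sum(J_b)
  w <- J_b / J
  mean_bp_b <- vapply(blk, `[[`, numeric(1), "mean_bp")
  mean_mp_b <- vapply(blk, `[[`, numeric(1), "mean_mp")
  ms_tr <- vapply(blk, `[[`, numeric(1), "ms_tr")
  cov2 <- vapply(blk, function(b) max(b$components[["cov2"]], 0), numeric(1))
  cov3 <- vapply(blk, function(b) max(b$components[["cov3"]], 0), numeric(1))
  cov23 <- pmax(vapply(blk, function(b)
    b$components[["cov2"]] - b$components[["cov3"]], numeric(1)), 0)

  var_b <- (2 / J_b) * (ms_tr + J_b * cov23)
  var_diff <- sum(w^2 * var_b)
  # Hillis-style df per block (I = 2), Satterthwaite across blocks; a
  # degenerate block (zero interaction mean square) contributes no df noise
  ddf_b <- ifelse(ms_tr > 0,
                  (ms_tr + J_b * cov23)^2 / (ms_tr^2 / (J_b - 1)), Inf)
  contrib <- ifelse(is.finite(ddf_b), (w^2 * var_b)^2 / ddf_b, 0)
  denom <- sum(contrib)
  ddf <- if (denom > 0 && var_diff > 0) var_diff^2 / denom else Inf

  # single-modality mean variances: (MS_R(i) + J * cov2+) / J per block
  var_mean <- sapply(MODALITIES, function(i) {
    ms_r_i <- vapply(blk, function(b) b$ms_r[[i]], numeric(1))
    sum(w^2 * (ms_r_i + J_b * cov2) / J_b)
  })

  list(mean_bp = sum(w * mean_bp_b),
       mean_mp = sum(w * mean_mp_b),
       diff = sum(w * (mean_bp_b - mean_mp_b)),
       var_diff = var_diff, se_diff = sqrt(var_diff),
       se_mean = sqrt(var_mean),
       ddf = ddf, n_readers = J, weights = w, var_blocks = var_b)
}

#' Noninferiority test and Wald interval for the modality difference
#'
#' Tests H0: true difference (bp - mp, larger metric better) <= -margin
#' against noninferiority, using the pooled split-plot OR variance. The
#' default interval and p-value use normal (Wald) quantiles; `ci = "t"`
#' substitutes t quantiles at the Hillis/Satterthwaite denominator df.
#'
#' @param pooled output of [pool_blocks()] (or an `or_components` object,
#'   pooled on the fly).
#' @param margin noninferiority margin on the accuracy scale (default 0.05).
#' @param alpha base one-sided significance level (default 0.05); the
#'   two-sided interval has level `1 - 2*alpha` quantile coverage per tail
#'   at 0.025 when `alpha = 0.05` (95% interval).
#' @param ci `"wald"` (normal quantiles) or `"t"`.
#' @param conf_level two-sided confidence level for the intervals.
#' @return an object of class `or_result`.
#' @export
or_test <- function(pooled, margin = 0.05, alpha = 0.05,
                    ci = c("wald", "t"), conf_level = 0.95) {
  ci <- match.arg(ci)
  if (inherits(pooled, "or_components")) pooled <- pool_blocks(pooled)
  stopifnot(margin > 0)
  se <- pooled$se_diff
  diff <- pooled$diff
  q <- if (ci == "wald") qnorm(1 - (1 - conf_level) / 2)
       else stats::qt(1 - (1 - conf_level) / 2, pooled$ddf)
  if (se == 0) {
    if (isTRUE(all.equal(diff, -margin))) {
      warning("zero standard error with difference at the margin; p = 0.5")
      p <- 0.5
    } else p <- as.numeric(diff <= -margin)
  } else {
    z <- (diff + margin) / se
    p <- if (ci == "wald") pnorm(-z) else stats::pt(-z, pooled$ddf)
  }
  res <- list(mean_bp = pooled$mean_bp, mean_mp = pooled$mean_mp,
              diff = diff, se_diff = se,
              ci_low = diff - q * se, ci_high = diff + q * se,
              ci_mean_bp = pooled$mean_bp + c(-1, 1) * q * pooled$se_mean[["bp"]],
              ci_mean_mp = pooled$mean_mp + c(-1, 1) * q * pooled$se_mean[["mp"]],
              ddf = if (ci == "wald") Inf else pooled$ddf,
              p_noninf = p, margin = margin, alpha = alpha,
              reject_noninf = p < alpha,
              n_readers = pooled$n_readers, ci_type = ci,
              conf_level = conf_level)
  class(res) <- "or_result"
  res
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf(
    paste0("OR noninferiority analysis (%d readers)\n",
           "  bp: %.3f (%.3f-%.3f)   mp: %.3f (%.3f-%.3f)\n",
           "  diff (bp-mp): %+.4f  [%.1f%% CI %+.4f to %+.4f]\n",
           "  noninferiority (margin %.2f): p = %.4g%s\n"),
    x$n_readers, x$mean_bp, x$ci_mean_bp[1], x$ci_mean_bp[2],
    x$mean_mp, x$ci_mean_mp[1], x$ci_mean_mp[2],
    x$diff, 100 * x$conf_level, x$ci_low, x$ci_high,
    x$margin, x$p_noninf,
    if (x$reject_noninf) "  (noninferior)" else ""))
  invisible(x)
}

#' Full Obuchowski-Rockette MRMC analysis of a paired split-plot study
#'
#' One-call pipeline: per-reader accuracy table, leave-one-case-out
#' jackknife, split-plot covariance components, block pooling, and the
#' Wald noninferiority test of bp versus mp.
#'
#' @inheritParams per_reader_metric_table
#' @inheritParams or_test
#' @param subgroup `"all"`, `"expert"` or `"nonexpert"` reader subset.
#' @return an `or_result`; the `accuracy_table` and `or_components` are
#'   attached as attributes `"table"` and `"components"`.
#' @export
or_analysis <- function(study, metric = c("auroc", "sensitivity",
                                          "specificity"),
                        rule = positivity_rule("p3"),
                        subgroup = c("all", "expert", "nonexpert"),
                        margin = 0.05, alpha = 0.05,
                        ci = c("wald", "t"), conf_level = 0.95) {
  metric <- match.arg(metric)
  subgroup <- match.arg(subgroup)
  readers <- if (subgroup == "all") NULL
             else study$readers$reader_id[study$readers$expertise == subgroup]
  tab <- per_reader_metric_table(study, metric, rule, readers = readers)
  jk <- jackknife_study(study, metric, rule, readers = readers)
  comps <- covariance_components(tab, jk)
  res <- or_test(pool_blocks(comps), margin = margin, alpha = alpha,
                 ci = ci, conf_level = conf_level)
  attr(res, "table") <- tab
  attr(res, "components") <- comps
  res
}

#' Jackknife vectors for every (modality, reader) unit of a study
#'
#' @inheritParams per_reader_metric_table
#' @return named list of leave-one-out accuracy vectors with names
#'   `"<modality>.<reader_id>"`.
#' @export
jackknife_study <- function(study, metric = c("auroc", "sensitivity",
                                              "specificity"),
                            rule = positivity_rule("p3"), readers = NULL) {
  metric <- match.arg(metric)
  splits <- reader_modality_split(study)
  if (!is.null(readers)) {
    keep <- vapply(splits, function(s) s$reader_id[1] %in% readers, logical(1))
    splits <- splits[keep]
  }
  out <- lapply(splits, jackknife_accuracies, metric = metric, rule = rule)
  names(out) <- vapply(splits, function(s)
    paste(s$modality[1], s$reader_id[1], sep = "."), character(1))
  out
}
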