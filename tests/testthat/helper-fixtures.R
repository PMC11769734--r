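# Hand-built fixtures and independent oracles used across the suite.

# Independent AUROC oracle: trapezoidal area under the empirical ROC curve,
# built from first principles (sweep thresholds, integrate TPR over FPR).
trapezoid_auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(c(Inf, thr), function(t) mean(scores[labels == 1] >= t),
                numeric(1))
  fpr <- vapply(c(Inf, thr), function(t) mean(scores[labels == 0] >= t),
                numeric(1))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Independent AUROC oracle #2: brute-force pair counting.
paircount_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Holm step-down oracle, straight from the definition.
holm_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (k in seq_len(m)) {
    running <- max(running, (m - k + 1) * p[ord[k]])
    adj[ord[k]] <- min(running, 1)
  }
  adj
}

# Definitional jackknife covariance between two leave-one-out vectors.
jk_cov_oracle <- function(v1, v2) {
  n <- length(v1)
  ((n - 1) / n) * sum((v1 - mean(v1)) * (v2 - mean(v2)))
}

# Small deterministic study: `readers_per_block` readers and the given
# case score patterns in each of `n_blocks` blocks, both modalities.
make_tiny_study <- function(n_blocks = 2, readers_per_block = 2,
                            labels = c(0, 1, 0, 1),
                            suspicion = NULL, categories = NULL,
                            psad = NULL, mp_offset = 0) {
  n_cases <- length(labels)
  if (is.null(suspicion)) suspicion <- seq(10, 90, length.out = n_cases)
  if (is.null(categories)) categories <- rep(c(2, 4), length.out = n_cases)
  if (is.null(psad)) psad <- rep(0.2, n_cases)
  cases <- readers <- readings <- list()
  for (b in seq_len(n_blocks)) {
    bid <- paste0("B", b)
    cid <- sprintf("c%d_%d", b, seq_len(n_cases))
    cases[[b]] <- data.frame(
      case_id = cid, center = "C1", block_id = bid,
      label = labels, gg = ifelse(labels == 1, 2, 0),
      psad = psad, psa = 7, volume = 50, age = 65,
      stringsAsFactors = FALSE)
    for (r in seq_len(readers_per_block)) {
      rid <- sprintf("r%d_%d", b, r)
      readers[[length(readers) + 1]] <- data.frame(
        reader_id = rid, block_id = bid,
        expertise = if (r == 1) "expert" else "nonexpert",
        stringsAsFactors = FALSE)
      for (mod in c("bp", "mp")) {
        off <- if (mod == "mp") mp_offset else 0
        readings[[length(readings) + 1]] <- data.frame(
          reader_id = rid, case_id = cid, modality = mod,
          patient_pirads = categories,
          suspicion = pmin(pmax(suspicion + off, 0), 100),
          lesions = ifelse(categories >= 3, as.character(categories), ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  reader_study(do.call(rbind, readings), do.call(rbind, cases),
               do.call(rbind, readers))
}

# Random small study through the simulator at reduced size (fast).
small_sim <- function(seed = 1, ...) {
  simulate_study(sim_config(n_readers = 8, n_cases = 40, ...), seed = seed)
}
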