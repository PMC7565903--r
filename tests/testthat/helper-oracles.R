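# Independent oracles and small fixture builders used across the suite.

# Brute-force O(n^2) Mann-Whitney AUC: all malignant/benign pairs, ties half.
auc_oracle <- function(labels, scores) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Exhaustive nearest-to-equality cutoff: independent of select_cutoff's code.
cutoff_oracle <- function(cutoffs, fp, fn, rate) {
  gap <- abs(fn - fp * rate)
  cutoffs[which(gap == min(gap))[1]]
}

# Four-patient toy used by several hand-count examples: two benign then two
# malignant, scores (percent) 10, 30, 20, 40.
toy_cohort <- function() {
  list(labels = c(FALSE, FALSE, TRUE, TRUE),
       mp = c(0.10, 0.30, 0.20, 0.40))
}

# Random scored cohort for property tests.
random_scored_cohort <- function(n, seed) {
  set.seed(seed)
  mp <- stats::runif(n)
  labels <- stats::runif(n) < mp
  # guarantee both classes
  labels[1] <- TRUE
  labels[2] <- FALSE
  list(labels = labels, mp = mp)
}

small_config <- function(seed = 1, ...) {
  cohort_config(n_pd = 40, n_dp = 30, seed = seed, ...)
}
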