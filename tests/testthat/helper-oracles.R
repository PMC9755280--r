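# Independent brute-force oracles, kept deliberately naive so they cannot
# share a code path with the implementation under test.

# conformal p-value by direct counting over the calibration scores
brute_pvalue <- function(scores, a, smoothed = FALSE, tau = NULL) {
  n <- length(scores)
  ge <- sum(scores >= a)
  if (!smoothed) return((ge + 1) / (n + 1))
  gt <- sum(scores > a)
  eq <- sum(scores == a)
  (gt + tau * (eq + 1)) / (n + 1)
}

# two-sample KS statistic as the sup of |F_a - F_b| over all sample points
brute_ks_stat <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}

# AUC over all positive/negative pairs, ties counted half
brute_auc <- function(score, is_pos) {
  pos <- score[is_pos]; neg <- score[!is_pos]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# small labeled table with probabilities supplied directly
make_table <- function(probs, truth, ls, subject = NA) {
  score_table(sprintf("e%03d", seq_len(nrow(probs))), probs, ls,
              true_label = truth, subject_id = subject, dataset_tag = "test")
}

# calibration table for a binary label set whose per-class nonconformity
# scores are exactly `benign_scores` / `cancer_scores`
make_binary_calibration <- function(benign_scores, cancer_scores) {
  ls <- binary_labels()
  probs <- rbind(cbind(1 - benign_scores, benign_scores),
                 cbind(cancer_scores, 1 - cancer_scores))
  truth <- c(rep("benign", length(benign_scores)),
             rep("cancer", length(cancer_scores)))
  make_table(probs, truth, ls)
}
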