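#' @title Drift detection and power analysis
#' @description Conformal validity rests on exchangeability: calibration and
#' deployment examples drawn in random order from one distribution. A new
#' scanner, a different laboratory, or tissue types absent from training
#' break that premise, and the break is visible as a difference between the
#' calibration set's nonconformity-score distribution and the deployment
#' set's. The two-sample Kolmogorov-Smirnov test compares the two; the power
#' analysis estimates, by repeated subsampling from a shifted pool, how many
#' deployment observations are needed before the shift is detected reliably.
#' @name drift
NULL

#' Two-sample Kolmogorov-Smirnov test
#'
#' Thin wrapper around [stats::ks.test()] that records whether the exact
#' small-sample p-value or the asymptotic Kolmogorov distribution was used:
#' exact when both samples hold at most 100 observations (and no ties
#' prevent it), asymptotic otherwise.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return List with `statistic` (sup-distance between the two empirical
#'   distribution functions), `p_value` (two-sided), and `method`
#'   (`"exact"` or `"asymptotic"`).
#' @export
ks_two_sample <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b))
    stop("both samples must be non-empty", call. = FALSE)
  exact <- length(sample_a) <= 100 && length(sample_b) <= 100
  has_ties <- anyDuplicated(c(sample_a, sample_b)) > 0
  kt <- suppressWarnings(
    stats::ks.test(sample_a, sample_b, exact = exact && !has_ties))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value),
       method = if (exact && !has_ties) "exact" else "asymptotic")
}

#' KS drift test of a deployment table against the calibration distribution
#'
#' "Distribution of the predictions" is operationalized as the distribution
#' of nonconformity scores, pooled across classes. In `labeled` mode the
#' test-set scores are taken at the true labels (matching the calibration
#' scores, which are always at true labels); in `predicted_label` mode the
#' argmax label stands in for the unknown truth — the monitoring setting
#' where deployment data arrive unlabeled. The mode is always recorded with
#' the result.
#'
#' @param calibrator A [mondrian_calibrate()] result.
#' @param test_table A [score_table()] of deployment examples.
#' @param mode `"labeled"` (requires true labels) or `"predicted_label"`.
#' @param alpha Two-sided significance level; default 0.05.
#' @return A `drift_test_result`: list with `ks_statistic`, `p_value`,
#'   `n_cal`, `n_test`, `mode`, `alpha`, `significant`, `method`.
#' @export
drift_test <- function(calibrator, test_table,
                       mode = c("labeled", "predicted_label"),
                       alpha = 0.05) {
  mode <- match.arg(mode)
  ls <- calibrator$label_set
  if (!identical(ls$labels, table_label_set(test_table)$labels))
    stop("table and calibrator label sets differ", call. = FALSE)
  probs <- prob_matrix(test_table)
  if (mode == "labeled") {
    if (anyNA(test_table$true_label))
      stop("labeled mode needs true labels on the test table", call. = FALSE)
    lab <- test_table$true_label
  } else {
    lab <- ls$labels[max.col(probs, ties.method = "first")]
  }
  test_scores <- nonconformity(probs, lab, ls)
  cal_scores <- unlist(calibrator$scores, use.names = FALSE)
  kt <- ks_two_sample(cal_scores, test_scores)
  structure(list(ks_statistic = kt$statistic, p_value = kt$p_value,
                 n_cal = length(cal_scores), n_test = length(test_scores),
                 mode = mode, alpha = alpha,
                 significant = kt$p_value < alpha, method = kt$method),
            class = "drift_test_result")
}

#' @export
print.drift_test_result <- function(x, ...) {
  cat(sprintf(
    "<drift_test_result> D = %.4f, p = %.3g (%s, %s mode, n_cal = %d, n_test = %d)\n%s\n",
    x$ks_statistic, x$p_value, x$method, x$mode, x$n_cal, x$n_test,
    if (x$significant) sprintf("Drift detected at alpha = %g", x$alpha)
    else sprintf("No drift detected at alpha = %g", x$alpha)))
  invisible(x)
}

#' Power of the KS drift test versus deployment sample size
#'
#' For each size `n` on the grid, `n_reps` subsamples of `n` rows are drawn
#' without replacement from the shifted pool, the drift test is run on each,
#' and power is the fraction of subsamples rejecting at `alpha`. The minimal
#' detecting sample size is the smallest grid `n` whose estimated power
#' reaches `power_threshold`.
#'
#' @param calibrator A [mondrian_calibrate()] result.
#' @param shifted_pool A [score_table()] larger than `max(n_grid)`.
#' @param n_grid Strictly increasing integer sample sizes.
#' @param n_reps Subsampling repetitions per grid point; default 500.
#' @param alpha KS significance level; default 0.05.
#' @param power_threshold Target power defining `n_required`; default 0.80.
#' @param mode Passed to [drift_test()].
#' @param seed Integer seed governing the whole curve.
#' @return A `power_curve`: data frame with `n`, `power`, `n_reps`, `alpha`,
#'   plus attributes `n_required` (NA when never reached) and
#'   `power_threshold`.
#' @export
power_curve <- function(calibrator, shifted_pool, n_grid, n_reps = 500L,
                        alpha = 0.05, power_threshold = 0.80,
                        mode = "labeled", seed = 1L) {
  n_grid <- as.integer(n_grid)
  if (is.unsorted(n_grid, strictly = TRUE))
    stop("n_grid must be strictly increasing", call. = FALSE)
  if (max(n_grid) > nrow(shifted_pool))
    stop("n_grid exceeds the pool size", call. = FALSE)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  power <- with_seed(seed, vapply(n_grid, function(n) {
    hits <- vapply(seq_len(n_reps), function(r) {
      rows <- sample.int(nrow(shifted_pool), n)
      drift_test(calibrator, shifted_pool[rows, ], mode = mode,
                 alpha = alpha)$p_value < alpha
    }, logical(1))
    mean(hits)
  }, numeric(1)))
  reached <- which(power >= power_threshold)
  out <- data.frame(n = n_grid, power = power, n_reps = n_reps,
                    alpha = alpha)
  attr(out, "n_required") <- if (length(reached)) n_grid[min(reached)]
                             else NA_integer_
  attr(out, "power_threshold") <- power_threshold
  class(out) <- c("power_curve", "data.frame")
  out
}

#' @export
print.power_curve <- function(x, ...) {
  nr <- attr(x, "n_required")
  cat("<power_curve> threshold ", attr(x, "power_threshold"),
      "; minimal detecting sample size: ",
      if (is.na(nr)) "not reached on grid" else nr, "\n", sep = "")
  print.data.frame(as.data.frame(x), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Write a power curve as CSV plus a JSON summary
#'
#' @param curve A [power_curve()] result.
#' @param csv_path,json_path Output file paths (either may be `NULL`).
#' @export
write_power_curve <- function(curve, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(curve), csv_path, row.names = FALSE,
                     quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(n_required = attr(curve, "n_required"),
           power_threshold = attr(curve, "power_threshold"),
           alpha = curve$alpha[1], n_reps = curve$n_reps[1],
           grid = curve$n, power = curve$power),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(curve)
}
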