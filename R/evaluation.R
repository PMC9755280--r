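#' @title Evaluation of prediction regions
#' @description Region tallies mirror the study design for conformal QC of a
#' diagnostic classifier: every evaluated example falls in exactly one of
#' four categories — *error* (non-empty region excluding the truth), *empty*
#' (no label included), *correct single* (region is exactly the true label)
#' and *correct multiple* (several labels including the truth). Efficiency is
#' the fraction of correct single-label predictions. Two error notions are
#' kept distinct on purpose: the tally's `error` row excludes empty regions
#' (the four categories partition n), while the calibration-curve error —
#' the validity diagnostic — counts every example whose true label is outside
#' the region, empty regions included.
#' @name evaluation
NULL

#' Tally prediction regions into the four-way report
#'
#' @param regions A [predict_regions()] result.
#' @param truths True labels aligned with `regions`; defaults to the
#'   categories already stored in `regions` (which requires the scored table
#'   to have carried true labels).
#' @param label_set A [label_set()]; taken from `regions` when absent.
#' @return An `evaluation_report`: long-format `data.frame` with columns
#'   `class` (one row group per true class plus `"all"`), `category`,
#'   `count`, `percent` (rounded to whole percent), plus attributes
#'   `efficiency` (overall and per class) and `n`.
#' @export
tally_regions <- function(regions, truths = NULL, label_set = NULL) {
  ls <- if (!is.null(label_set)) label_set else attr(regions, "label_set")
  assert_label_set(ls)
  sets <- region_sets(regions)
  if (is.null(truths))
    stop("supply `truths` (true labels aligned with the regions)",
         call. = FALSE)
  if (length(truths) != nrow(regions))
    stop("`truths` and `regions` lengths differ", call. = FALSE)
  assert_labels_in_set(truths, ls)
  size <- lengths(sets)
  truth_in <- mapply(function(s, t) t %in% s, sets, truths)
  category <- ifelse(size == 0, "empty",
              ifelse(!truth_in, "error",
              ifelse(size == 1, "correct_single", "correct_multiple")))
  cats <- c("error", "empty", "correct_single", "correct_multiple")
  tally_one <- function(idx) {
    tab <- table(factor(category[idx], levels = cats))
    data.frame(category = cats, count = as.integer(tab),
               percent = round(100 * as.integer(tab) / max(1, length(idx))),
               stringsAsFactors = FALSE)
  }
  pieces <- lapply(ls$labels, function(lab) {
    idx <- which(truths == lab)
    cbind(class = lab, tally_one(idx), n = length(idx))
  })
  pieces <- c(pieces, list(cbind(class = "all",
                                 tally_one(seq_along(category)),
                                 n = length(category))))
  report <- do.call(rbind, pieces)
  eff <- vapply(c(ls$labels, "all"), function(lab) {
    idx <- if (lab == "all") seq_along(category) else which(truths == lab)
    if (!length(idx)) return(NA_real_)
    mean(category[idx] == "correct_single")
  }, numeric(1))
  attr(report, "efficiency") <- eff
  attr(report, "n") <- length(category)
  attr(report, "label_set") <- ls
  class(report) <- c("evaluation_report", "data.frame")
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  eff <- attr(x, "efficiency")
  cat("<evaluation_report> n =", attr(x, "n"),
      sprintf("| overall efficiency %.0f%%\n", 100 * eff[["all"]]))
  wide <- stats::reshape(as.data.frame(x)[, c("class", "category", "count")],
                         idvar = "category", timevar = "class",
                         direction = "wide")
  names(wide) <- sub("^count\\.", "", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report as long-format CSV
#'
#' Columns: class, category, count, percent, n. Percentages recompute
#' exactly from the emitted counts.
#'
#' @param report An `evaluation_report`.
#' @param path File path.
#' @export
write_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Point-prediction (argmax) tally: the conformal-free baseline
#'
#' The predicted label is the argmax of the probability vector; ties are
#' broken toward the earlier label in label-set order (and reported).
#'
#' @param table A labeled [score_table()].
#' @return `data.frame` with per-class and overall `error` / `correct`
#'   counts and whole-percent shares; the number of argmax ties is in the
#'   `"n_ties"` attribute.
#' @export
point_prediction_tally <- function(table) {
  ls <- table_label_set(table)
  if (anyNA(table$true_label))
    stop("point predictions need true labels", call. = FALSE)
  probs <- prob_matrix(table)
  pred_idx <- max.col(probs, ties.method = "first")
  n_ties <- sum(rowSums(probs == probs[cbind(seq_len(nrow(probs)),
                                             pred_idx)]) > 1)
  pred <- ls$labels[pred_idx]
  ok <- pred == table$true_label
  rows <- lapply(c(ls$labels, "all"), function(lab) {
    idx <- if (lab == "all") seq_along(ok) else which(table$true_label == lab)
    data.frame(class = lab,
               error = sum(!ok[idx]), correct = sum(ok[idx]),
               error_pct = round(100 * mean(!ok[idx])),
               correct_pct = round(100 * mean(ok[idx])),
               n = length(idx), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_ties") <- n_ties
  out
}

#' Observed error versus significance level (validity diagnostic)
#'
#' For each significance level `eps` on a uniform grid over `[0, 1]`, the
#' observed error is the fraction of true-label p-values at most `eps` —
#' i.e. the fraction of true labels excluded from the region at that level.
#' A valid conformal predictor tracks the diagonal (error close to, and for
#' non-smoothed p-values at most, `eps`); departure from the diagonal is the
#' visual signature of a dataset shift.
#'
#' @param true_pvalues Conformal p-values of the true labels, in `(0, 1]`.
#' @param grid_size Number of grid points; default 1001.
#' @return A `calibration_curve` data frame with columns `epsilon`,
#'   `observed_error`, `n`.
#' @export
calibration_curve <- function(true_pvalues, grid_size = 1001L) {
  if (!length(true_pvalues)) stop("empty p-value input", call. = FALSE)
  if (any(true_pvalues <= 0 | true_pvalues > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  eps <- seq(0, 1, length.out = grid_size)
  sorted <- sort(true_pvalues)
  err <- findInterval(eps, sorted) / length(sorted)
  out <- data.frame(epsilon = eps, observed_error = err,
                    n = length(true_pvalues))
  class(out) <- c("calibration_curve", "data.frame")
  out
}

#' True-label p-values for a labeled table
#'
#' Convenience accessor used by the calibration-curve and drift analyses.
#'
#' @inheritParams predict_regions
#' @return Numeric vector of p-values, one per labeled row.
#' @export
true_label_pvalues <- function(calibrator, table, smoothed = FALSE,
                               seed = 1L) {
  ls <- calibrator$label_set
  if (anyNA(table$true_label))
    stop("all rows need true labels", call. = FALSE)
  probs <- prob_matrix(table)
  alpha <- nonconformity(probs, table$true_label, ls)
  tie <- if (smoothed) with_seed(seed, stats::runif(nrow(probs))) else NULL
  p <- numeric(nrow(probs))
  for (lab in ls$labels) {
    idx <- which(table$true_label == lab)
    if (!length(idx)) next
    p[idx] <- conformal_pvalue(calibrator, lab, alpha[idx],
                               smoothed = smoothed, tie_draw = tie[idx])
  }
  p
}

#' Proportion of panel votes covered by the prediction regions
#'
#' For a case reviewed independently by a panel (e.g. 23 uropathologists
#' each assigning an ISUP grade), coverage is the share of individual votes
#' whose label lies in that case's prediction region. High coverage at a
#' given confidence level indicates the region widths track genuine
#' inter-observer uncertainty.
#'
#' @param regions A [predict_regions()] result.
#' @param votes `data.frame` with columns `example_id` and `label`, one row
#'   per individual vote.
#' @return Proportion in `[0, 1]`.
#' @export
panel_coverage <- function(regions, votes) {
  if (!all(c("example_id", "label") %in% names(votes)))
    stop("`votes` needs example_id and label columns", call. = FALSE)
  sets <- region_sets(regions)
  names(sets) <- regions$example_id
  missing_ids <- setdiff(unique(votes$example_id), regions$example_id)
  if (length(missing_ids))
    stop("votes reference examples with no region: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  covered <- mapply(function(id, lab) lab %in% sets[[id]],
                    votes$example_id, votes$label)
  mean(covered)
}

#' Region-size summary
#'
#' @param regions A [predict_regions()] result.
#' @param multiples_only Restrict to multi-label regions (size >= 2)?
#' @return List with `sizes` (table of size frequencies), `median`, `n`.
#' @export
region_size_stats <- function(regions, multiples_only = FALSE) {
  size <- lengths(region_sets(regions))
  if (multiples_only) size <- size[size >= 2]
  list(sizes = table(size), median = if (length(size))
    stats::median(size) else NA_real_, n = length(size))
}

# Midrank Mann-Whitney AUC of score against a binary truth indicator
auc_rank <- function(score, is_positive) {
  n1 <- sum(is_positive); n0 <- sum(!is_positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Simulated human-in-the-loop AUC experiment
#'
#' A thought experiment on a binary (benign vs cancer) table: the standalone
#' classifier is scored by its cancer probability; in the combined system,
#' every example flagged as unreliable by the conformal predictor (empty or
#' multiple region) is re-read by an expert whose call is correct with
#' probability `expert_accuracy`, replacing the classifier score with the
#' truth-indicating extreme (1 for cancer, 0 for benign) or its opposite.
#' Both AUCs are computed by the midrank Mann-Whitney statistic.
#'
#' @param table A labeled binary [score_table()].
#' @param regions Matching [predict_regions()] result.
#' @param expert_accuracy Probability in `[0, 1]` that the simulated expert
#'   calls the flagged case correctly.
#' @param seed Integer seed for the expert's calls.
#' @return List with `auc_standalone`, `auc_combined`, `n_flagged`.
#' @export
human_in_loop_auc <- function(table, regions, expert_accuracy = 1.0,
                              seed = 1L) {
  ls <- table_label_set(table)
  if (n_labels(ls) != 2)
    stop("the human-in-the-loop experiment needs a binary label set",
         call. = FALSE)
  if (anyNA(table$true_label))
    stop("true labels required", call. = FALSE)
  if (expert_accuracy < 0 || expert_accuracy > 1)
    stop("expert_accuracy must be in [0, 1]", call. = FALSE)
  positive <- ls$labels[2]
  score <- prob_matrix(table)[, positive]
  is_pos <- table$true_label == positive
  size <- lengths(region_sets(regions))
  flagged <- size != 1
  combined <- score
  with_seed(seed, {
    correct <- stats::runif(sum(flagged)) < expert_accuracy
    truth_extreme <- as.numeric(is_pos[flagged])
    combined[flagged] <- ifelse(correct, truth_extreme, 1 - truth_extreme)
  })
  list(auc_standalone = auc_rank(score, is_pos),
       auc_combined = auc_rank(combined, is_pos),
       n_flagged = sum(flagged))
}
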