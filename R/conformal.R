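#' @title Mondrian inductive conformal prediction
#' @description The conformal predictor sits on top of any classifier that
#' outputs class probabilities. A held-out calibration set provides, for each
#' true class, the empirical distribution of nonconformity scores (one minus
#' the predicted probability of the true class). For a new example and a
#' candidate label, the conformal p-value is the proportion of calibration
#' examples of that class — plus the new example itself — whose nonconformity
#' is at least as extreme. Labels whose p-value exceeds the significance
#' level `1 - c` are included in the prediction region; under exchangeability
#' the true label is excluded with probability at most `1 - c`, and the
#' class-wise (Mondrian) calibration makes that guarantee hold within every
#' class, however imbalanced.
#' @name conformal
NULL

#' Split a labeled table into proper-training and calibration parts
#'
#' Mirrors the inductive-conformal design: the proper-training part feeds the
#' underlying classifier, the calibration part feeds [mondrian_calibrate()].
#' When a grouping field is given (subjects contribute several biopsies
#' each), whole groups are assigned to one side only, so calibration and
#' training never share a subject; the calibration share of rows then lands
#' within one group's size of the target fraction.
#'
#' @param table A labeled [score_table()]; every row must have a true label.
#' @param calibration_fraction Target calibration share, in (0, 1);
#'   default `0.10`.
#' @param group_field Column to split by (`"subject_id"` used automatically
#'   when present); `NULL` for a plain row-level split.
#' @param seed Integer seed; identical inputs give identical partitions.
#' @return A list with `training` and `calibration` score tables.
#' @export
split_train_calibration <- function(table, calibration_fraction = 0.10,
                                    group_field = "subject_id", seed = 1L) {
  if (calibration_fraction <= 0 || calibration_fraction >= 1)
    stop("calibration_fraction must be in (0, 1)", call. = FALSE)
  if (anyNA(table$true_label))
    stop("all rows must have true labels before splitting", call. = FALSE)
  n <- nrow(table)
  use_groups <- !is.null(group_field) && group_field %in% names(table) &&
    !anyNA(table[[group_field]])
  with_seed(seed, {
    if (use_groups) {
      groups <- split(seq_len(n), table[[group_field]])
      sizes <- lengths(groups)
      if (max(sizes) > (1 - calibration_fraction) * n)
        warning("a single group holds more than the training share; ",
                "the split is degenerate", call. = FALSE)
      ord <- sample.int(length(groups))
      target <- calibration_fraction * n
      cal_idx <- integer(0)
      for (g in ord) {
        if (length(cal_idx) >= target) break
        cal_idx <- c(cal_idx, groups[[g]])
      }
    } else {
      cal_idx <- sample.int(n, max(1L, round(calibration_fraction * n)))
    }
    list(training = table[setdiff(seq_len(n), cal_idx), ],
         calibration = table[cal_idx, ])
  })
}

#' Nonconformity score: one minus the predicted probability
#'
#' Larger scores mean the example-label pair conforms less with the training
#' data.
#'
#' @param probs Numeric matrix of class probabilities (or a single vector).
#' @param label Candidate label(s), recycled against the rows of `probs`.
#' @param label_set A [label_set()].
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
nonconformity <- function(probs, label, label_set) {
  assert_label_set(label_set)
  if (!is.matrix(probs)) probs <- matrix(probs, nrow = 1)
  idx <- match(label, label_set$labels)
  if (anyNA(idx))
    stop("label not in label set", call. = FALSE)
  idx <- rep_len(idx, nrow(probs))
  1 - probs[cbind(seq_len(nrow(probs)), idx)]
}

#' Build a Mondrian (class-conditional) calibrator
#'
#' Stores, for each class, the ascending-sorted nonconformity scores of the
#' calibration rows whose true label is that class. With fewer than
#' `min_per_class` calibration examples in some class the per-class guarantee
#' becomes vacuous at small significance levels (a class with `n_c`
#' calibration scores can never yield a p-value below `1/(n_c + 1)`); a
#' warning is emitted.
#'
#' @param calibration_table A fully labeled [score_table()].
#' @param min_per_class Minimum per-class calibration count before warning;
#'   default 25.
#' @return An object of class `mondrian_calibrator`.
#' @export
mondrian_calibrate <- function(calibration_table, min_per_class = 25L) {
  ls <- table_label_set(calibration_table)
  if (nrow(calibration_table) == 0)
    stop("empty calibration table", call. = FALSE)
  if (anyNA(calibration_table$true_label))
    stop("all calibration rows must be labeled", call. = FALSE)
  probs <- prob_matrix(calibration_table)
  alpha <- nonconformity(probs, calibration_table$true_label, ls)
  scores <- lapply(ls$labels, function(lab) {
    sort(alpha[calibration_table$true_label == lab])
  })
  names(scores) <- ls$labels
  small <- ls$labels[lengths(scores) < min_per_class]
  if (length(small))
    warning("class(es) with fewer than ", min_per_class,
            " calibration examples: ", paste(small, collapse = ", "),
            call. = FALSE)
  structure(list(label_set = ls, scores = scores,
                 n_per_class = lengths(scores)),
            class = "mondrian_calibrator")
}

#' @export
print.mondrian_calibrator <- function(x, ...) {
  cat("<mondrian_calibrator> classes:",
      paste(sprintf("%s (n=%d)", x$label_set$labels, x$n_per_class),
            collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a calibrator to / from JSON
#'
#' @param calibrator A `mondrian_calibrator`.
#' @param path File path.
#' @return `read_calibrator()` returns the calibrator; `write_calibrator()`
#'   invisibly returns `path`.
#' @export
write_calibrator <- function(calibrator, path) {
  jsonlite::write_json(
    list(labels = calibrator$label_set$labels,
         ordinal = calibrator$label_set$ordinal,
         scores = calibrator$scores),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibrator
#' @export
read_calibrator <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ls <- label_set(x$labels, ordinal = isTRUE(x$ordinal))
  scores <- lapply(x$scores, as.numeric)
  # jsonlite may return an empty list for a zero-length class
  scores <- lapply(scores[ls$labels], function(s) sort(as.numeric(s)))
  names(scores) <- ls$labels
  structure(list(label_set = ls, scores = scores,
                 n_per_class = lengths(scores)),
            class = "mondrian_calibrator")
}

# Vectorized counts against one sorted score vector: for each a in alphas,
# how many calibration scores are >= a, > a, == a.
count_extreme <- function(sorted_scores, alphas) {
  n <- length(sorted_scores)
  n_le <- findInterval(alphas, sorted_scores)               # #{s <= a}
  n_lt <- findInterval(alphas, sorted_scores, left.open = TRUE) # #{s < a}
  list(ge = n - n_lt, gt = n - n_le, eq = n_le - n_lt)
}

#' Conformal p-value for a candidate label
#'
#' Non-smoothed: `(#\{a_i >= a\} + 1) / (n_c + 1)` over the candidate
#' label's class stratum. Smoothed:
#' `(#\{a_i > a\} + tau (#\{a_i = a\} + 1)) / (n_c + 1)` with a tie-breaking
#' draw `tau ~ U(0, 1)`; smoothed p-values are exactly uniform under
#' exchangeability, non-smoothed ones are conservative but deterministic.
#' Vectorized over `alpha_new`.
#'
#' @param calibrator A [mondrian_calibrate()] result.
#' @param label Single candidate label naming the Mondrian stratum.
#' @param alpha_new Nonconformity score(s) of the new example(s), in
#'   `[0, 1]`.
#' @param smoothed Logical; use tie-randomized p-values.
#' @param tie_draw Uniform draws in `[0, 1]`, recycled against `alpha_new`;
#'   required when `smoothed = TRUE`.
#' @return Numeric p-values in `(0, 1]`.
#' @export
conformal_pvalue <- function(calibrator, label, alpha_new, smoothed = FALSE,
                             tie_draw = NULL) {
  if (!label %in% calibrator$label_set$labels)
    stop("label not in label set", call. = FALSE)
  if (any(alpha_new < 0 | alpha_new > 1))
    stop("alpha_new must lie in [0, 1]", call. = FALSE)
  s <- calibrator$scores[[label]]
  n_c <- length(s)
  cnt <- count_extreme(s, alpha_new)
  if (!smoothed) return((cnt$ge + 1) / (n_c + 1))
  if (is.null(tie_draw))
    stop("smoothed p-values need `tie_draw`", call. = FALSE)
  tau <- rep_len(tie_draw, length(alpha_new))
  (cnt$gt + tau * (cnt$eq + 1)) / (n_c + 1)
}

#' Specify per-class confidence levels
#'
#' A single number applies one global confidence to every class; a named
#' vector sets class-wise levels (e.g. 85% for ISUP 1, 67% for ISUP 2-5, the
#' mixed-confidence design for grade groups whose classifier performance
#' differs). The significance level of class `k` is `eps(k) = 1 - c(k)`.
#'
#' @param confidence Numeric scalar in (0, 1), or named vector covering every
#'   label.
#' @param label_set A [label_set()].
#' @return A `confidence_spec`: named numeric vector of per-class confidences.
#' @export
confidence_spec <- function(confidence, label_set) {
  assert_label_set(label_set)
  if (any(confidence <= 0 | confidence >= 1))
    stop("confidence levels must be in (0, 1)", call. = FALSE)
  if (is.null(names(confidence))) {
    if (length(confidence) != 1)
      stop("unnamed confidence must be a single global level", call. = FALSE)
    confidence <- stats::setNames(rep(confidence, n_labels(label_set)),
                                  label_set$labels)
  } else {
    missing <- setdiff(label_set$labels, names(confidence))
    if (length(missing))
      stop("no confidence level for: ", paste(missing, collapse = ", "),
           call. = FALSE)
    confidence <- confidence[label_set$labels]
  }
  structure(confidence, class = "confidence_spec")
}

#' Prediction regions for a table of examples
#'
#' For each example, p-values are computed for every candidate label against
#' that label's Mondrian stratum, and a label enters the region iff its
#' p-value is strictly larger than `1 - c(label)`. Regions can be empty (the
#' example conforms to no class — typically data unlike anything in training)
#' or contain several labels (the prediction is inconclusive and flagged for
#' human review).
#'
#' @param calibrator A [mondrian_calibrate()] result.
#' @param table A [score_table()] (true labels optional).
#' @param confidence A [confidence_spec()], or a number / named vector
#'   coerced through it.
#' @param smoothed Logical; tie-randomized p-values (seeded).
#' @param seed Integer seed for the tie draws when `smoothed = TRUE`.
#' @return A `data.frame` of class `prediction_regions`: `example_id`, one
#'   `pval_<label>` column per class, `region` (semicolon-joined included
#'   labels, `""` for the empty set), and `category` (one of `empty`,
#'   `correct_single`, `correct_multiple`, `error`, `unknown_truth`).
#' @export
predict_regions <- function(calibrator, table, confidence, smoothed = FALSE,
                            seed = 1L) {
  ls <- calibrator$label_set
  if (!identical(ls$labels, table_label_set(table)$labels))
    stop("table and calibrator label sets differ", call. = FALSE)
  conf <- if (inherits(confidence, "confidence_spec")) confidence
          else confidence_spec(confidence, ls)
  eps <- 1 - unclass(conf)
  probs <- prob_matrix(table)
  n <- nrow(probs)
  pvals <- matrix(NA_real_, n, n_labels(ls),
                  dimnames = list(NULL, ls$labels))
  tie <- if (smoothed)
    with_seed(seed, matrix(stats::runif(n * n_labels(ls)), n)) else NULL
  for (j in seq_along(ls$labels)) {
    lab <- ls$labels[j]
    pvals[, j] <- conformal_pvalue(calibrator, lab, 1 - probs[, j],
                                   smoothed = smoothed,
                                   tie_draw = if (smoothed) tie[, j])
  }
  included <- sweep(pvals, 2, eps, ">")
  region <- apply(included, 1, function(z) paste(ls$labels[z], collapse = ";"))
  size <- rowSums(included)
  truth <- table$true_label
  category <- rep("unknown_truth", n)
  category[size == 0] <- "empty"
  known <- !is.na(truth)
  if (any(known)) {
    truth_in <- rep(FALSE, n)
    truth_in[known] <- included[cbind(which(known),
                                      match(truth[known], ls$labels))]
    category[known & size >= 1 & !truth_in] <- "error"
    category[known & size == 1 & truth_in] <- "correct_single"
    category[known & size >= 2 & truth_in] <- "correct_multiple"
  }
  out <- data.frame(example_id = table$example_id,
                    stringsAsFactors = FALSE)
  pv <- as.data.frame(pvals)
  names(pv) <- paste0("pval_", ls$labels)
  out <- cbind(out, pv)
  out$region <- region
  out$category <- category
  attr(out, "label_set") <- ls
  attr(out, "confidence") <- conf
  class(out) <- c("prediction_regions", "data.frame")
  out
}

#' @export
print.prediction_regions <- function(x, ...) {
  cat("<prediction_regions> ", nrow(x), " examples; confidence: ",
      paste(sprintf("%s=%.3f", names(attr(x, "confidence")),
                    as.numeric(attr(x, "confidence"))), collapse = ", "),
      "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 4)
  if (nrow(x) > 6) cat("... ", nrow(x) - 6, " more rows\n", sep = "")
  invisible(x)
}

# included label sets as a list of character vectors
region_sets <- function(regions) {
  strsplit(ifelse(regions$region == "", "", regions$region), ";", fixed = TRUE)
}

#' Write / read prediction regions as CSV
#'
#' @param regions A `prediction_regions` data frame.
#' @param path File path.
#' @param label_set A [label_set()] (needed when reading).
#' @return `read_regions()` returns a `prediction_regions` object.
#' @export
write_regions <- function(regions, path) {
  out <- as.data.frame(regions)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_regions
#' @export
read_regions <- function(path, label_set) {
  assert_label_set(label_set)
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(example_id = "character"))
  need <- paste0("pval_", label_set$labels)
  missing_cols <- setdiff(c(need, "region", "category"), names(out))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  out$region[is.na(out$region)] <- ""
  attr(out, "label_set") <- label_set
  class(out) <- c("prediction_regions", "data.frame")
  out
}
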