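#' Labeled score tables
#'
#' A score table holds one row per example (e.g. one biopsy core) with an
#' example identifier, an optional subject identifier, an optional true label,
#' a dataset tag, and a probability vector over the label set stored in
#' `p_<label>` columns. This is the exchange format between the synthetic
#' generator, the conformal predictor and the evaluation functions.
#'
#' @param example_id Character vector of unique example identifiers.
#' @param probs Numeric matrix (rows = examples, columns in label-set order)
#'   of class probabilities; rows must sum to 1 within `1e-6` and are
#'   renormalized to machine precision.
#' @param label_set A [label_set()].
#' @param true_label Optional character vector of true labels (`NA` allowed).
#' @param subject_id Optional character vector of subject identifiers.
#' @param dataset_tag Single string tagging the dataset the rows belong to.
#' @return A `data.frame` of class `score_table` with columns `example_id`,
#'   `subject_id`, `true_label`, `dataset_tag` and one `p_<label>` column per
#'   class; the label set is carried in the `"label_set"` attribute.
#' @export
score_table <- function(example_id, probs, label_set, true_label = NA,
                        subject_id = NA, dataset_tag = "unnamed") {
  assert_label_set(label_set)
  probs <- as.matrix(probs)
  n <- length(example_id)
  if (nrow(probs) != n)
    stop("`probs` must have one row per example", call. = FALSE)
  if (ncol(probs) != n_labels(label_set))
    stop("`probs` must have one column per label", call. = FALSE)
  if (anyDuplicated(example_id))
    stop("`example_id` must be unique within a table", call. = FALSE)
  if (any(probs < 0))
    stop("probabilities must be non-negative", call. = FALSE)
  sums <- rowSums(probs)
  if (any(abs(sums - 1) > 1e-6))
    stop("probability rows must sum to 1 within 1e-6; worst deviation ",
         format(max(abs(sums - 1))), " at row ",
         which.max(abs(sums - 1)), call. = FALSE)
  probs <- probs / sums
  true_label <- as.character(rep_len(true_label, n))
  assert_labels_in_set(true_label, label_set)
  tab <- data.frame(
    example_id = as.character(example_id),
    subject_id = as.character(rep_len(subject_id, n)),
    true_label = true_label,
    dataset_tag = as.character(rep_len(dataset_tag, n)),
    stringsAsFactors = FALSE
  )
  pm <- as.data.frame(probs)
  names(pm) <- prob_cols(label_set)
  tab <- cbind(tab, pm)
  attr(tab, "label_set") <- label_set
  class(tab) <- c("score_table", "data.frame")
  tab
}

prob_cols <- function(ls) paste0("p_", ls$labels)

#' Extract the probability matrix of a score table
#'
#' @param table A `score_table`.
#' @return Numeric matrix with one column per label, in label-set order.
#' @export
prob_matrix <- function(table) {
  ls <- table_label_set(table)
  m <- as.matrix(as.data.frame(table)[, prob_cols(ls), drop = FALSE])
  colnames(m) <- ls$labels
  m
}

table_label_set <- function(table) {
  ls <- attr(table, "label_set")
  if (is.null(ls))
    stop("score table is missing its label_set attribute", call. = FALSE)
  ls
}

#' @export
print.score_table <- function(x, ...) {
  ls <- table_label_set(x)
  cat("<score_table> ", nrow(x), " examples, ", n_labels(ls), " classes (",
      paste(ls$labels, collapse = ", "), "), tag: ",
      paste(unique(x$dataset_tag), collapse = ", "), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 4)
  if (nrow(x) > 6) cat("... ", nrow(x) - 6, " more rows\n", sep = "")
  invisible(x)
}

# Subsetting drops the class via [.data.frame; restore attributes.
#' @export
`[.score_table` <- function(x, ...) {
  ls <- attr(x, "label_set")
  out <- NextMethod()
  if (is.data.frame(out) && all(prob_cols(ls) %in% names(out))) {
    attr(out, "label_set") <- ls
    class(out) <- c("score_table", "data.frame")
  }
  out
}

#' Read / write score tables as CSV
#'
#' The on-disk contract is a comma- or tab-separated text file with header
#' columns `example_id, subject_id, true_label, dataset_tag` followed by one
#' `p_<label>` column per class in label-set order. Missing true labels are
#' written as empty fields. On ingest, probability rows whose sum deviates
#' from 1 by at most `1e-6` are renormalized (with a warning when the
#' deviation exceeds `1e-9`); larger deviations, negative entries, unknown
#' labels or missing probability columns are rejected with row-indexed
#' messages.
#'
#' @param path File path; the delimiter is sniffed from the header line
#'   (comma or tab).
#' @param label_set A [label_set()] declaring the expected classes.
#' @return `read_score_table()` returns a `score_table`;
#'   `write_score_table()` invisibly returns `path`.
#' @export
read_score_table <- function(path, label_set) {
  assert_label_set(label_set)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character())
  need <- prob_cols(label_set)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing probability column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  probs <- sapply(raw[need], as.numeric)
  probs <- matrix(probs, ncol = length(need))
  if (anyNA(probs))
    stop("non-numeric probability at row(s) ",
         paste(utils::head(which(rowSums(is.na(probs)) > 0), 5), collapse = ", "),
         call. = FALSE)
  neg <- which(apply(probs < 0, 1, any))
  if (length(neg))
    stop("negative probability at row(s) ",
         paste(utils::head(neg, 5), collapse = ", "), call. = FALSE)
  dev <- abs(rowSums(probs) - 1)
  if (any(dev > 1e-6))
    stop("probability rows not summing to 1 (beyond 1e-6) at row(s) ",
         paste(utils::head(which(dev > 1e-6), 5), collapse = ", "),
         call. = FALSE)
  if (any(dev > 1e-9))
    warning(sum(dev > 1e-9), " row(s) renormalized (sum deviation <= 1e-6)",
            call. = FALSE)
  truth <- raw$true_label
  truth[!nzchar(truth)] <- NA_character_
  bad <- setdiff(unique(truth[!is.na(truth)]), label_set$labels)
  if (length(bad))
    stop("unknown true_label value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  subj <- if ("subject_id" %in% names(raw)) raw$subject_id else NA
  if (!is.null(subj)) subj[!nzchar(subj)] <- NA_character_
  tag <- if ("dataset_tag" %in% names(raw)) raw$dataset_tag else "unnamed"
  score_table(raw$example_id, probs, label_set, true_label = truth,
              subject_id = subj, dataset_tag = tag)
}

#' @rdname read_score_table
#' @param table A `score_table` to write.
#' @export
write_score_table <- function(table, path) {
  out <- as.data.frame(table)
  ls <- table_label_set(table)
  for (cc in prob_cols(ls))
    out[[cc]] <- formatC(out[[cc]], digits = 12, format = "g")
  out$true_label[is.na(out$true_label)] <- ""
  out$subject_id[is.na(out$subject_id)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
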