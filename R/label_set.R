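#' Define an ordered set of class labels
#'
#' A label set fixes the classes a score table's probability columns refer to
#' and the order in which they are reported. For prostate biopsy grading the
#' order is diagnostically meaningful (benign, then ISUP grade groups 1-5);
#' for plain cancer detection it is benign vs cancer.
#'
#' @param labels Character vector of unique class names, at least two.
#' @param ordinal Logical; whether the order of `labels` is meaningful
#'   (`TRUE` for ISUP grade groups).
#' @return An object of class `label_set`.
#' @examples
#' binary_labels()
#' isup_labels()
#' @export
label_set <- function(labels, ordinal = FALSE) {
  labels <- as.character(labels)
  if (length(labels) < 2L)
    stop("a label set needs at least 2 labels", call. = FALSE)
  if (anyDuplicated(labels))
    stop("label names must be unique", call. = FALSE)
  structure(list(labels = labels, ordinal = isTRUE(ordinal)),
            class = "label_set")
}

#' @rdname label_set
#' @export
binary_labels <- function() label_set(c("benign", "cancer"))

#' @rdname label_set
#' @export
isup_labels <- function() {
  label_set(c("benign", "ISUP1", "ISUP2", "ISUP3", "ISUP4", "ISUP5"),
            ordinal = TRUE)
}

#' @export
print.label_set <- function(x, ...) {
  cat("<label_set> ", paste(x$labels, collapse = " < "),
      if (x$ordinal) " (ordinal)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.label_set <- function(x) length(x$labels)

n_labels <- function(ls) length(ls$labels)

assert_label_set <- function(ls) {
  if (!inherits(ls, "label_set"))
    stop("expected a `label_set` object", call. = FALSE)
  invisible(ls)
}

assert_labels_in_set <- function(labels, ls) {
  bad <- setdiff(unique(labels[!is.na(labels)]), ls$labels)
  if (length(bad))
    stop("labels not in label set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(labels)
}
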