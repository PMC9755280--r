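#' @title Synthetic classifier-score generator
#' @description Generates labeled probability-vector tables with the
#' statistical structure the conformal analysis assumes: exchangeable rows,
#' user-set class prevalences, and a tunable difficulty knob. Two generative
#' regimes are provided. In `class_conditional` mode, a label is drawn first
#' and the probability vector follows a Dirichlet law concentrated on the
#' true class. In `calibrated` mode the probability vector is drawn first
#' from a symmetric Dirichlet prior and the label is then sampled *from* the
#' vector, so the scores are perfectly calibrated by construction — the regime
#' of choice for validity experiments, since conformal validity needs only
#' exchangeability, not score quality. Shift scenarios (temperature
#' distortion, near-uniform contamination, prevalence shift) stand in for
#' deployment changes such as a new scanner or laboratory, or atypical tissue.
#' @name synthetic_scores
NULL

# Run code with a private RNG stream, restoring the caller's .Random.seed.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Dirichlet sampler via normalized gammas; alpha is a vector (one draw per
# row of the returned matrix when n > 1) or a matrix of per-row parameters.
rdirichlet <- function(n, alpha) {
  if (is.matrix(alpha)) {
    k <- ncol(alpha)
    x <- matrix(stats::rgamma(n * k, shape = as.vector(t(alpha))),
                nrow = n, ncol = k, byrow = TRUE)
  } else {
    k <- length(alpha)
    x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)),
                nrow = n, ncol = k)
  }
  # rgamma(shape ~ 0) can underflow to exactly 0; nudge to keep rows on the
  # open simplex
  x[x == 0] <- .Machine$double.xmin
  x / rowSums(x)
}

normalize_prevalence <- function(prevalence, k = NULL) {
  prevalence <- as.numeric(prevalence)
  if (any(!is.finite(prevalence)) || any(prevalence < 0))
    stop("prevalence entries must be finite and non-negative", call. = FALSE)
  s <- sum(prevalence)
  if (s <= 0) stop("prevalence must have a positive sum", call. = FALSE)
  # raw counts (e.g. a Table-1-style column) are accepted and normalized
  if (abs(s - 1) > 1e-9 && s < 1 + 1e-9)
    stop("prevalence sums to ", format(s), ", not 1 (within 1e-9)",
         call. = FALSE)
  prevalence <- prevalence / s
  if (!is.null(k) && length(prevalence) != k)
    stop("prevalence length does not match the label set", call. = FALSE)
  prevalence
}

#' Configuration for the synthetic score generator
#'
#' @param n_examples Number of rows to generate (>= 1).
#' @param prevalence Class prevalence vector in label-set order; raw counts
#'   (e.g. 3724, 1530, ...) are accepted and normalized. Ignored by
#'   `calibrated` mode, whose label marginal is determined by the symmetric
#'   prior.
#' @param discriminability Positive real controlling score sharpness. In
#'   `class_conditional` mode it is the extra Dirichlet concentration placed
#'   on the true class; in `calibrated` mode the symmetric prior has
#'   concentration `1/discriminability` per class, so larger values give
#'   sharper (more decisive) probability vectors in both modes.
#' @param mode `"calibrated"` or `"class_conditional"` (see
#'   [synthetic_scores]).
#' @param shift Optional [shift_spec()] applied after generation.
#' @param seed Integer seed; recorded in the output's `dataset_tag` metadata.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_examples, prevalence = NULL,
                             discriminability = 4,
                             mode = c("calibrated", "class_conditional"),
                             shift = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (n_examples < 1) stop("n_examples must be >= 1", call. = FALSE)
  if (discriminability <= 0)
    stop("discriminability must be > 0", call. = FALSE)
  if (!is.null(prevalence)) prevalence <- normalize_prevalence(prevalence)
  if (!is.null(shift) && !inherits(shift, "shift_spec"))
    stop("`shift` must be a shift_spec", call. = FALSE)
  structure(list(n_examples = as.integer(n_examples), prevalence = prevalence,
                 discriminability = discriminability, mode = mode,
                 shift = shift, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Draw true labels from a categorical prevalence distribution
#'
#' @param n Number of labels to draw.
#' @param prevalence Probability vector (or raw counts) in label-set order.
#' @param label_set A [label_set()].
#' @param seed Integer seed; identical inputs give identical output.
#' @return Character vector of `n` labels.
#' @examples
#' generate_labels(5, c(0.5, 0.5), binary_labels(), seed = 1)
#' @export
generate_labels <- function(n, prevalence, label_set, seed = 1L) {
  assert_label_set(label_set)
  prevalence <- normalize_prevalence(prevalence, n_labels(label_set))
  with_seed(seed, {
    label_set$labels[sample.int(n_labels(label_set), n, replace = TRUE,
                                prob = prevalence)]
  })
}

#' Attach probability vectors to a label sequence
#'
#' Implements the two generative regimes described in [synthetic_scores].
#' In `calibrated` mode the supplied labels are *replaced* by labels sampled
#' from the generated probability vectors — that is what makes the scores
#' perfectly calibrated.
#'
#' @param labels Character vector of true labels (class-conditional mode) or
#'   a placeholder of the right length (calibrated mode).
#' @param config A [synthetic_config()].
#' @param label_set A [label_set()].
#' @param dataset_tag Tag recorded on every row.
#' @return A [score_table()].
#' @export
generate_probs <- function(labels, config, label_set,
                           dataset_tag = "synthetic") {
  assert_label_set(label_set)
  k <- n_labels(label_set)
  n <- length(labels)
  d <- config$discriminability
  if (d <= 0) stop("discriminability must be > 0", call. = FALSE)
  with_seed(config$seed + 1L, {
    if (config$mode == "class_conditional") {
      assert_labels_in_set(labels, label_set)
      idx <- match(labels, label_set$labels)
      alpha <- matrix(1, n, k)
      alpha[cbind(seq_len(n), idx)] <- 1 + d
      probs <- rdirichlet(n, alpha)
      truth <- labels
    } else {
      probs <- rdirichlet(n, rep(1 / d, k))
      u <- stats::runif(n)
      cum <- probs
      for (j in seq_len(k)[-1]) cum[, j] <- cum[, j - 1] + cum[, j]
      idx <- max.col(cum >= u, ties.method = "first")
      truth <- label_set$labels[idx]
    }
    score_table(sprintf("ex%06d", seq_len(n)), probs, label_set,
                true_label = truth, dataset_tag = dataset_tag)
  })
}

#' Simulate a labeled score table in one call
#'
#' Draws labels per `config$prevalence` (class-conditional mode), generates
#' probability vectors, and applies `config$shift` when present.
#'
#' @inheritParams generate_probs
#' @param config A [synthetic_config()].
#' @return A [score_table()].
#' @export
simulate_scores <- function(config, label_set, dataset_tag = "synthetic") {
  assert_label_set(label_set)
  prev <- config$prevalence
  if (is.null(prev)) prev <- rep(1, n_labels(label_set))
  labels <- generate_labels(config$n_examples, prev, label_set,
                            seed = config$seed)
  tab <- generate_probs(labels, config, label_set, dataset_tag = dataset_tag)
  if (!is.null(config$shift))
    tab <- apply_shift(tab, config$shift, seed = config$seed + 2L)
  tab
}

#' Specify a distribution shift scenario
#'
#' Stand-ins for deployment-time changes: `temperature` flattens (T > 1) or
#' sharpens (T < 1) every probability vector, mimicking the systematic score
#' distortion seen when slides come from a different scanner or laboratory;
#' `contamination` replaces a fraction of rows with near-uniform vectors,
#' mimicking atypical tissue on which the classifier is uninformative;
#' `prevalence_shift` resamples rows to a new class mix.
#'
#' @param kind One of `"temperature"`, `"contamination"`,
#'   `"prevalence_shift"`.
#' @param magnitude Temperature T > 0, or contamination fraction in `[0, 1]`.
#'   `T = 1` and fraction `0` are exact identities.
#' @param target_prevalence Required for `prevalence_shift`.
#' @return A `shift_spec` list.
#' @export
shift_spec <- function(kind = c("temperature", "contamination",
                                "prevalence_shift"),
                       magnitude = 1, target_prevalence = NULL) {
  kind <- match.arg(kind)
  if (kind == "temperature" && magnitude <= 0)
    stop("temperature must be > 0", call. = FALSE)
  if (kind == "contamination" && (magnitude < 0 || magnitude > 1))
    stop("contamination fraction must be in [0, 1]", call. = FALSE)
  if (kind == "prevalence_shift") {
    if (is.null(target_prevalence))
      stop("prevalence_shift needs a target_prevalence", call. = FALSE)
    target_prevalence <- normalize_prevalence(target_prevalence)
  }
  structure(list(kind = kind, magnitude = magnitude,
                 target_prevalence = target_prevalence),
            class = "shift_spec")
}

#' Apply a shift scenario to a score table
#'
#' @param table A [score_table()].
#' @param shift A [shift_spec()].
#' @param seed Integer seed for the stochastic scenarios.
#' @return The shifted `score_table`; its `dataset_tag` records the scenario.
#' @export
apply_shift <- function(table, shift, seed = 1L) {
  if (!inherits(shift, "shift_spec"))
    stop("`shift` must be a shift_spec", call. = FALSE)
  ls <- table_label_set(table)
  probs <- prob_matrix(table)
  truth <- table$true_label
  subj <- table$subject_id
  ids <- table$example_id
  tag <- paste0(table$dataset_tag[1], "+", shift$kind, "=",
                format(shift$magnitude))
  with_seed(seed, {
    if (shift$kind == "temperature") {
      if (shift$magnitude != 1) {
        probs <- probs^(1 / shift$magnitude)
        probs <- probs / rowSums(probs)
      }
    } else if (shift$kind == "contamination") {
      n_hit <- round(shift$magnitude * nrow(probs))
      if (n_hit > 0) {
        hit <- sample.int(nrow(probs), n_hit)
        # high symmetric concentration: near-uniform but tie-free
        probs[hit, ] <- rdirichlet(n_hit, rep(200, ncol(probs)))
      }
    } else { # prevalence_shift
      idx <- match(truth, ls$labels)
      new_lab <- sample.int(n_labels(ls), nrow(probs), replace = TRUE,
                            prob = shift$target_prevalence)
      pick <- integer(nrow(probs))
      for (cls in unique(new_lab)) {
        pool <- which(idx == cls)
        if (!length(pool))
          stop("prevalence_shift: no source rows of class ",
               ls$labels[cls], call. = FALSE)
        sel <- which(new_lab == cls)
        pick[sel] <- pool[sample.int(length(pool), length(sel),
                                     replace = TRUE)]
      }
      probs <- probs[pick, , drop = FALSE]
      truth <- truth[pick]
      subj <- subj[pick]
      ids <- sprintf("%s_r%06d", ids[pick], seq_along(pick))
    }
    score_table(ids, probs, ls, true_label = truth, subject_id = subj,
                dataset_tag = tag)
  })
}
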