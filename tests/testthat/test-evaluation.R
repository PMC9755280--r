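# build a prediction_regions object directly from label sets, bypassing the
# conformal machinery, so the tallies are tested in isolation
fake_regions <- function(sets, ls) {
  out <- data.frame(example_id = sprintf("e%03d", seq_along(sets)),
                    stringsAsFactors = FALSE)
  out$region <- vapply(sets, paste, character(1), collapse = ";")
  out$category <- "unknown_truth"
  attr(out, "label_set") <- ls
  class(out) <- c("prediction_regions", "data.frame")
  out
}

test_that("tally_regions categorizes the toy example by hand", {
  ls <- label_set(c("B", "C"))
  reg <- fake_regions(list("B", character(0), "B", c("B", "C"), "C"), ls)
  truths <- c("B", "B", "C", "C", "B")
  rep_ <- tally_regions(reg, truths)
  all_rows <- subset(as.data.frame(rep_), class == "all")
  expect_equal(all_rows$count[match(c("correct_single", "empty", "error",
                                      "correct_multiple"),
                                    all_rows$category)],
               c(1L, 1L, 2L, 1L))
  expect_equal(attr(rep_, "efficiency")[["all"]], 0.2)
})

test_that("full regions always contain the truth", {
  ls <- label_set(c("B", "C"))
  reg <- fake_regions(rep(list(c("B", "C")), 7), ls)
  rep_ <- tally_regions(reg, c(rep("B", 4), rep("C", 3)))
  all_rows <- subset(as.data.frame(rep_), class == "all")
  expect_equal(all_rows$count[all_rows$category == "correct_multiple"], 7L)
  expect_equal(sum(all_rows$count), 7L)
  expect_equal(attr(rep_, "efficiency")[["all"]], 0)
})

test_that("tally counts partition n per class on random region sets", {
  ls <- isup_labels()
  set.seed(13)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    sets <- lapply(seq_len(n), function(j)
      sample(ls$labels, min(6, rpois(1, 1.2)), replace = FALSE))
    truths <- sample(ls$labels, n, replace = TRUE)
    rep_ <- tally_regions(fake_regions(sets, ls), truths)
    df <- as.data.frame(rep_)
    for (cls in c(ls$labels, "all")) {
      rows <- df[df$class == cls, ]
      expect_equal(sum(rows$count), rows$n[1])
    }
    expect_equal(df$n[df$class == "all"][1], n)
  }
})

test_that("point predictions are argmax with first-label tie break", {
  ls <- binary_labels()
  probs <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.3, 0.7), c(0.6, 0.4))
  tab <- make_table(probs, c("benign", "benign", "cancer", "cancer"), ls)
  out <- point_prediction_tally(tab)
  all_row <- out[out$class == "all", ]
  expect_equal(all_row$error, 1L)    # the misranked 4th row
  expect_equal(all_row$correct, 3L)
  tie <- make_table(rbind(c(0.5, 0.5)), "cancer", ls)
  out_tie <- point_prediction_tally(tie)
  expect_equal(out_tie[out_tie$class == "all", "error"], 1L)  # benign wins
  expect_equal(attr(out_tie, "n_ties"), 1L)
})

test_that("the calibration curve counts excluded truths", {
  pv <- seq(0.1, 1.0, by = 0.1)
  cc <- calibration_curve(pv, grid_size = 21)
  expect_equal(cc$observed_error[which.min(abs(cc$epsilon - 0.35))], 0.3)
  expect_equal(cc$observed_error[1], 0)  # all p-values strictly positive
  expect_true(all(diff(cc$observed_error) >= 0))
  expect_true(all(cc$observed_error >= 0 & cc$observed_error <= 1))
  expect_error(calibration_curve(numeric(0)), "empty")
  expect_error(calibration_curve(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("tally error plus empty equals the curve's validity error", {
  ls <- binary_labels()
  cfg <- synthetic_config(2000, mode = "calibrated", seed = 17)
  tab <- simulate_scores(cfg, ls)
  parts <- split_train_calibration(tab, 0.4, group_field = NULL, seed = 2)
  cal <- mondrian_calibrate(parts$calibration)
  conf <- 0.8
  reg <- predict_regions(cal, parts$training, conf)
  rep_ <- tally_regions(reg, parts$training$true_label)
  df <- subset(as.data.frame(rep_), class == "all")
  tally_err <- sum(df$count[df$category %in% c("error", "empty")]) / df$n[1]
  pv <- true_label_pvalues(cal, parts$training)
  expect_equal(tally_err, mean(pv <= 1 - conf))
})

test_that("panel coverage counts individual votes inside regions", {
  ls <- isup_labels()
  reg <- fake_regions(list(c("ISUP1", "ISUP2"), "ISUP2"), ls)
  votes <- data.frame(
    example_id = c(rep("e001", 3), rep("e002", 3)),
    label = c("ISUP1", "ISUP1", "ISUP3", "ISUP2", "ISUP2", "ISUP2"))
  expect_equal(panel_coverage(reg, votes), 5 / 6)
  # full regions cover everything; empty regions nothing
  full <- fake_regions(rep(list(ls$labels), 2), ls)
  expect_equal(panel_coverage(full, votes), 1)
  none <- fake_regions(rep(list(character(0)), 2), ls)
  expect_equal(panel_coverage(none, votes), 0)
  expect_error(panel_coverage(reg, data.frame(example_id = "zzz",
                                              label = "ISUP1")),
               "no region")
  # enlarging regions never lowers coverage
  expect_gte(panel_coverage(full, votes), panel_coverage(reg, votes))
})

test_that("region size statistics summarize the selected subset", {
  ls <- isup_labels()
  reg <- fake_regions(list("ISUP1", c("ISUP1", "ISUP2"),
                           c("ISUP2", "ISUP3"),
                           c("ISUP1", "ISUP2", "ISUP3")), ls)
  all_stats <- region_size_stats(reg)
  expect_equal(all_stats$median, 2)
  mult <- region_size_stats(reg, multiples_only = TRUE)
  expect_equal(mult$median, 2)
  expect_equal(mult$n, 3)
  singles <- fake_regions(rep(list("ISUP1"), 5), ls)
  expect_equal(region_size_stats(singles)$median, 1)
})

test_that("human-in-the-loop AUC matches the brute-force rank statistic", {
  ls <- binary_labels()
  probs <- rbind(c(0.9, 0.1), c(0.7, 0.3), c(0.6, 0.4),
                 c(0.4, 0.6), c(0.2, 0.8), c(0.35, 0.65))
  truth <- c("benign", "benign", "cancer", "cancer", "cancer", "benign")
  tab <- make_table(probs, truth, ls)
  # no flagged examples: combined equals standalone, and both match the
  # pairwise oracle
  reg_single <- fake_regions(as.list(truth), ls)
  res <- human_in_loop_auc(tab, reg_single, expert_accuracy = 1, seed = 5)
  expect_equal(res$n_flagged, 0L)
  expect_equal(res$auc_combined, res$auc_standalone)
  expect_equal(res$auc_standalone,
               brute_auc(probs[, 2], truth == "cancer"))
  # two flagged rows read by a perfect expert go to the extremes
  sets <- as.list(truth)
  sets[[3]] <- c("benign", "cancer")
  sets[[6]] <- character(0)
  res2 <- human_in_loop_auc(tab, fake_regions(sets, ls),
                            expert_accuracy = 1, seed = 5)
  comb <- probs[, 2]
  comb[3] <- 1; comb[6] <- 0
  expect_equal(res2$n_flagged, 2L)
  expect_equal(res2$auc_combined, brute_auc(comb, truth == "cancer"))
  # everything flagged with a perfect expert gives AUC 1
  all_flagged <- fake_regions(rep(list(character(0)), 6), ls)
  res3 <- human_in_loop_auc(tab, all_flagged, expert_accuracy = 1, seed = 5)
  expect_equal(res3$auc_combined, 1)
  expect_error(human_in_loop_auc(
    make_table(matrix(rep(1 / 6, 6), 1), "ISUP1", isup_labels()),
    fake_regions(list("ISUP1"), isup_labels()), 1, 1), "binary")
})
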