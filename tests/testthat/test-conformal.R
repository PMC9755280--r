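test_that("grouped splitting keeps subjects on one side at the target share", {
  ls <- binary_labels()
  probs <- matrix(rep(c(0.4, 0.6), each = 100), ncol = 2)
  tab <- make_table(probs, rep(c("benign", "cancer"), 50), ls,
                    subject = rep(sprintf("s%02d", 1:10), each = 10))
  parts <- split_train_calibration(tab, 0.10, group_field = "subject_id",
                                   seed = 21)
  expect_equal(nrow(parts$calibration), 10)  # exactly one 10-row subject
  expect_length(unique(parts$calibration$subject_id), 1)
  expect_length(intersect(parts$calibration$subject_id,
                          parts$training$subject_id), 0)
  expect_setequal(c(parts$calibration$example_id, parts$training$example_id),
                  tab$example_id)
  # the default calibration fraction is one tenth
  expect_equal(formals(split_train_calibration)$calibration_fraction, 0.10)
  # seeded determinism
  p2 <- split_train_calibration(tab, 0.10, group_field = "subject_id",
                                seed = 21)
  expect_identical(parts$calibration$example_id, p2$calibration$example_id)
  # a dominant group degrades the split with a warning
  tab2 <- make_table(probs, rep(c("benign", "cancer"), 50), ls,
                     subject = c(rep("big", 95), rep("small", 5)))
  expect_warning(split_train_calibration(tab2, 0.10, seed = 1), "degenerate")
  # unlabeled rows are refused
  tab3 <- make_table(probs[1:4, ], c("benign", NA, "cancer", NA), ls)
  expect_error(split_train_calibration(tab3, 0.5, seed = 1), "true labels")
})

test_that("nonconformity is one minus the predicted probability", {
  ls <- binary_labels()
  expect_equal(nonconformity(c(0, 1), "cancer", ls), 0)
  expect_equal(nonconformity(c(1, 0), "cancer", ls), 1)
  expect_equal(nonconformity(c(0.7, 0.3), "benign", ls), 0.3)
  expect_error(nonconformity(c(0.5, 0.5), "ISUP9", ls), "not in label set")
})

test_that("the calibrator stores sorted per-class scores of true labels", {
  tab <- make_binary_calibration(benign_scores = c(0.1, 0.4, 0.2),
                                 cancer_scores = numeric(0))
  cal <- suppressWarnings(mondrian_calibrate(tab))
  expect_equal(cal$scores$benign, c(0.1, 0.2, 0.4))
  expect_length(cal$scores$cancer, 0)
  expect_equal(sum(cal$n_per_class), nrow(tab))
  # permuting the rows leaves the calibrator unchanged
  cal2 <- suppressWarnings(mondrian_calibrate(tab[c(3, 1, 2), ]))
  expect_equal(cal$scores, cal2$scores)
  expect_warning(mondrian_calibrate(tab, min_per_class = 25), "fewer than")
  expect_error(mondrian_calibrate(tab[0, ]), "empty")
})

test_that("p-values match the hand-counted examples", {
  tab <- make_binary_calibration(c(0.1, 0.2, 0.3), c(0.5, 0.6))
  cal <- suppressWarnings(mondrian_calibrate(tab))
  expect_equal(conformal_pvalue(cal, "benign", 0.25), 0.5)    # (1+1)/(3+1)
  expect_equal(conformal_pvalue(cal, "benign", 0.05), 1.0)    # (3+1)/(3+1)
  # an empty stratum forces p = 1
  tab0 <- make_binary_calibration(c(0.1, 0.2, 0.3), numeric(0))
  cal0 <- suppressWarnings(mondrian_calibrate(tab0))
  expect_equal(conformal_pvalue(cal0, "cancer", 0.99), 1.0)
  expect_error(conformal_pvalue(cal, "benign", 1.5), "\\[0, 1\\]")
  expect_error(conformal_pvalue(cal, "benign", 0.5, smoothed = TRUE),
               "tie_draw")
})

test_that("vectorized p-values equal the brute-force counting oracle", {
  set.seed(77)
  for (i in 1:200) {
    n_c <- sample(0:50, 1)
    # score grid with repeats forces exact ties
    scores <- sample(seq(0, 1, by = 0.05), n_c, replace = TRUE)
    tab <- make_binary_calibration(scores, c(0.5))
    cal <- suppressWarnings(mondrian_calibrate(tab))
    a <- sample(seq(0, 1, by = 0.05), 8, replace = TRUE)
    tau <- runif(8)
    expect_identical(conformal_pvalue(cal, "benign", a),
                     vapply(a, function(x)
                       brute_pvalue(cal$scores$benign, x), numeric(1)))
    expect_equal(conformal_pvalue(cal, "benign", a, smoothed = TRUE,
                                  tie_draw = tau),
                 mapply(function(x, t)
                   brute_pvalue(cal$scores$benign, x, TRUE, t), a, tau),
                 tolerance = 1e-12)
  }
})

test_that("p-values are non-increasing in the nonconformity score", {
  tab <- make_binary_calibration(runif(40), runif(25))
  cal <- mondrian_calibrate(tab)
  a <- seq(0, 1, length.out = 101)
  for (lab in c("benign", "cancer")) {
    p <- conformal_pvalue(cal, lab, a)
    expect_true(all(diff(p) <= 0))
    expect_true(all(p > 0 & p <= 1))
  }
})

test_that("region inclusion follows the strict p > 1 - c rule", {
  # benign stratum of 4 scores below 0.35 -> p(benign) = 1/5 at alpha 0.35;
  # cancer stratum of 9 scores, two >= 0.65 -> p(cancer) = 3/10
  tab <- make_binary_calibration(c(0.1, 0.15, 0.2, 0.3),
                                 c(0.1, 0.2, 0.25, 0.3, 0.35, 0.4, 0.45,
                                   0.66, 0.7))
  cal <- suppressWarnings(mondrian_calibrate(tab))
  new <- make_table(matrix(c(0.65, 0.35), 1), "benign", binary_labels())
  reg999 <- predict_regions(cal, new, 0.999)
  expect_equal(reg999$region, "benign;cancer")  # both p-values exceed 0.001
  expect_equal(reg999$pval_benign, 0.2)
  expect_equal(reg999$pval_cancer, 0.3)
  # at 75% confidence only p > 0.25 survives
  reg75 <- predict_regions(cal, new, 0.75)
  expect_equal(reg75$region, "cancer")
  # class-wise levels: benign at 85% (eps 0.15), cancer at 67% (eps 0.33)
  regcw <- predict_regions(cal, new, c(benign = 0.85, cancer = 0.67))
  expect_equal(regcw$region, "benign")          # 0.2 > 0.15 but 0.3 <= 0.33
  # strictness: p exactly equal to eps is excluded (0.25 is exactly
  # representable, so the comparison is a true tie)
  tabq <- make_binary_calibration(c(0.1, 0.15, 0.2), c(0.1, 0.2, 0.3))
  calq <- suppressWarnings(mondrian_calibrate(tabq))
  regq <- predict_regions(calq, new, 0.75)  # both p-values are exactly 1/4
  expect_equal(regq$pval_benign, 0.25)
  expect_equal(regq$pval_cancer, 0.25)
  expect_equal(regq$region, "")
  expect_equal(regq$category, "empty")
})

test_that("regions are nested under increasing confidence", {
  ls <- isup_labels()
  cfg <- synthetic_config(600, rep(1, 6), mode = "class_conditional",
                          seed = 31)
  tab <- simulate_scores(cfg, ls)
  parts <- split_train_calibration(tab, 0.5, group_field = NULL, seed = 1)
  cal <- mondrian_calibrate(parts$calibration)
  sets_at <- function(conf)
    conformalqc:::region_sets(predict_regions(cal, parts$training, conf))
  lo <- sets_at(0.60)
  hi <- sets_at(0.90)
  expect_true(all(mapply(function(a, b) all(a %in% b), lo, hi)))
})

test_that("calibrators survive a JSON round trip", {
  tab <- make_binary_calibration(runif(30), runif(30))
  cal <- mondrian_calibrate(tab)
  path <- withr::local_tempfile(fileext = ".json")
  write_calibrator(cal, path)
  cal2 <- read_calibrator(path)
  expect_equal(cal$scores, cal2$scores)
  expect_equal(cal$label_set$labels, cal2$label_set$labels)
})

test_that("regions survive a CSV round trip", {
  tab <- make_binary_calibration(runif(30), runif(30))
  cal <- mondrian_calibrate(tab)
  new <- simulate_scores(synthetic_config(40, c(.5, .5),
                                          mode = "class_conditional",
                                          seed = 3), binary_labels())
  reg <- predict_regions(cal, new, 0.8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_regions(reg, path)
  reg2 <- read_regions(path, binary_labels())
  expect_equal(reg2$region, reg$region)
  expect_equal(reg2$category, reg$category)
  expect_equal(reg2$pval_benign, reg$pval_benign, tolerance = 1e-12)
})
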