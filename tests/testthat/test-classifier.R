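test_that("design assembly appends the right covariates per block", {
  data <- planted_table(6, 6, 10, 2, 1, seed = 91)
  sel <- sprintf("f%03d", 1:5)
  expect_equal(ncol(assemble_design(data, sel, "brain")$x), 7)        # +age +sex
  expect_equal(ncol(assemble_design(data, sel, "metabolite")$x), 8)   # +diet too
  des <- assemble_design(data, sel, "combined")
  expect_true("diet" %in% colnames(des$x))
  expect_error(assemble_design(data, c("f001", "nope"), "brain"), "nope")
})

test_that("ridge classifier matches the hand-solved normal equations", {
  # 2 points per class in 2 features, lambda = 1, no standardization:
  # Xc'Xc + I and Xc'yc solved by hand below
  x <- matrix(c(1, 2, -1, -2,
                0, 1, 0, -1), 4, 2)
  colnames(x) <- c("a", "b")
  y <- c(1, 1, 0, 0)
  fit <- train_linear(x, y, family = "ridge", lambda = 1, standardize = FALSE)
  # Xc = x (already centered), ypm = (1,1,-1,-1), yc = ypm
  # X'X = [[10, 4], [4, 2]]; + I = [[11, 4], [4, 3]]; X'y = (6, 2)
  # solve: det = 33 - 16 = 17; b = ((18 - 8)/17, (22 - 24)/17)... recompute:
  # beta = inv([[11,4],[4,3]]) %*% (6,2) = (1/17) [[3,-4],[-4,11]] (6,2)
  #      = (1/17) (18 - 8, -24 + 22) = (10/17, -2/17)
  expect_equal(unname(fit$weights), c(10 / 17, -2 / 17), tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
})

test_that("weights length matches the design and duplicates separate cleanly", {
  data <- planted_table(8, 8, 4, 1, 3, seed = 95)
  des <- assemble_design(data, sprintf("f%03d", 1:4), "brain")
  fit <- train_linear(des$x, des$y, "svm")
  expect_length(fit$weights, ncol(des$x))
  # separable toy data: training accuracy 1 for the SVM
  pred <- predict(fit, des$x, type = "class")
  sep <- cbind(x1 = c(-3, -2.5, -2.8, 3, 2.5, 2.8))
  ysep <- c(0, 0, 0, 1, 1, 1)
  fit2 <- train_linear(sep, ysep, "svm")
  expect_equal(predict(fit2, sep, "class"), ysep)
})

test_that("LOO evaluation is perfect on well-separated clusters for every family", {
  withr::with_seed(101, {
    n <- 24
    label <- rep(c(0L, 1L), each = n / 2)
    f <- ifelse(label == 1, 10, -10) + rnorm(n)
    data <- tibble::tibble(subject_id = sprintf("S%02d", 1:n), label = label,
                           age = rnorm(n, 30, 5), sex = rbinom(n, 1, 0.5),
                           diet = rbinom(n, 1, 0.5), f001 = f)
  })
  accs <- vapply(c("svm", "ridge", "logistic"), function(fam) {
    rep <- suppressWarnings(loo_evaluate(data, "f001", "brain", fam))
    expect_equal(sum(rep$confusion), n)
    expect_equal(rep$accuracy, mean(rep$predictions$truth == rep$predictions$predicted))
    rep$accuracy
  }, numeric(1))
  expect_equal(unname(accs), c(1, 1, 1))
  rep <- loo_evaluate(data, "f001", "brain", "svm")
  pr <- rep$precision_recall
  expect_equal(pr$precision, c(1, 1))
  expect_equal(pr$recall, c(1, 1))
  expect_equal(rep$auc, 1)
})

test_that("families agree on strongly separable synthetic cohorts", {
  spec <- cohort_spec(n_obese = 24, n_overweight = 20, n_regions = 2,
                      n_metabolites = 30, informative_regions = 1,
                      informative_metabolites = 1:5, metabolite_effect = 3.5,
                      seed = 17)
  data <- cohort_features(generate_cohort(spec, "metabolite"), "metabolite")
  # the planted group difference is linear on the log-abundance scale
  sel <- sprintf("met_%04d", 1:5)
  data <- dplyr::mutate(data, dplyr::across(dplyr::all_of(feature_names(data)), log))
  accs <- vapply(c("svm", "ridge", "logistic"), function(fam)
    suppressWarnings(loo_evaluate(data, sel, "metabolite", fam))$accuracy,
    numeric(1))
  expect_lt(max(accs) - min(accs), 0.05 + 1e-9)
})

test_that("LOO accuracy sits at the majority rate when labels are independent of features", {
  accs <- vapply(1:10, function(s) {
    data <- planted_table(11, 13, 4, 0, 0, seed = 900 + s)
    loo_evaluate(data, sprintf("f%03d", 1:4), "brain", "svm")$accuracy
  }, numeric(1))
  # majority-class rate 13/24 = 0.542; allow Monte-Carlo spread
  expect_lt(abs(mean(accs) - 13 / 24), 0.12)
})

test_that("precision/recall formulas, degenerate flags and label-swap symmetry", {
  pr <- precision_recall(c(tp = 9, fp = 1, fn = 3, tn = 7))
  expect_equal(pr$precision[pr$class == 1], 0.9)
  expect_equal(pr$recall[pr$class == 1], 0.75)
  # 0/0 reported as NA with a flag, not 0
  pr0 <- precision_recall(c(tp = 0, fp = 0, fn = 0, tn = 10))
  expect_true(is.na(pr0$recall[pr0$class == 1]))
  expect_true(pr0$recall_undefined[pr0$class == 1])
  expect_true(is.na(pr0$precision[pr0$class == 1]))
  # swapping the positive class exchanges the per-class rows
  a <- precision_recall(c(tp = 5, fp = 2, fn = 1, tn = 8))
  b <- precision_recall(c(tp = 8, fp = 1, fn = 2, tn = 5))
  expect_equal(a$precision[a$class == 1], b$precision[b$class == 0])
  expect_equal(a$recall[a$class == 0], b$recall[b$class == 1])
  expect_error(precision_recall(c(tp = -1, fp = 0, fn = 0, tn = 0)), ">= 0")
})

test_that("ROC endpoints, monotonicity, sign reversal and a pROC cross-check", {
  withr::with_seed(111, {
    labels <- rbinom(40, 1, 0.5)
    labels[1:2] <- c(0, 1)
    scores <- labels + rnorm(40, sd = 0.8)
  })
  roc <- roc_points(scores, labels)
  pts <- roc$points
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  # independent implementation agrees
  expect_equal(roc$auc, as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                                       direction = "<"))),
               tolerance = 1e-10)
  # perfect and reversed scores
  expect_equal(roc_points(labels, labels)$auc, 1)
  expect_equal(roc_points(-scores, labels)$auc, 1 - roc$auc, tolerance = 1e-10)
  expect_error(roc_points(scores, rep(1, 40)), "classes")
})
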