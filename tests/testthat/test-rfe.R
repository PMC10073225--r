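test_that("RFE identity and count-conservation contracts hold", {
  data <- planted_table(10, 10, 8, 2, 2, seed = 31)
  cfg <- rfe_config()
  all_feats <- feature_names(data)
  res <- svm_rfe_rank(data, k_target = 8, cfg)
  expect_setequal(res$survivors, all_feats)
  expect_length(res$elimination_order, 0)
  res3 <- svm_rfe_rank(data, k_target = 3, cfg)
  expect_length(res3$elimination_order, 5)
  expect_length(res3$survivors, 3)
  expect_setequal(c(res3$survivors, res3$elimination_order), all_feats)
  expect_error(svm_rfe_rank(data, k_target = 0, cfg), "k_target")
})

test_that("RFE recovers a strongly planted pair among noise", {
  hits <- vapply(1:50, function(s) {
    data <- planted_table(40, 40, 10, 2, 3, seed = 400 + s)
    res <- svm_rfe_rank(data, k_target = 2, rfe_config())
    all(c("f001", "f002") %in% res$survivors)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("constant features are dropped with a warning and rank worst", {
  data <- planted_table(10, 10, 6, 1, 3, seed = 33)
  data$f006 <- 1  # constant
  expect_warning(res <- svm_rfe_rank(data, k_target = 2, rfe_config()),
                 "constant")
  expect_equal(res$elimination_order[1], "f006")
  expect_false("f006" %in% res$survivors)
})

test_that("optimal-k search picks k = 1 for a single dominant feature", {
  withr::with_seed(51, {
    n <- 30
    label <- rep(c(0L, 1L), each = n / 2)
    x <- matrix(rnorm(n * 10), n, 10)
    x[, 4] <- ifelse(label == 1, 1, -1) + rnorm(n, sd = 0.05)
    colnames(x) <- sprintf("f%03d", 1:10)
    data <- dplyr::bind_cols(
      tibble::tibble(subject_id = sprintf("S%02d", 1:n), label = label,
                     age = rnorm(n, 30, 5), sex = rbinom(n, 1, 0.5),
                     diet = rbinom(n, 1, 0.5)),
      tibble::as_tibble(x))
  })
  res <- optimal_k_search(data, rfe_config(k_grid = c(1, 5, 10)))
  expect_equal(res$optimal_k, 1)
  expect_true(all(res$curve$accuracy >= 0 & res$curve$accuracy <= 1))
  expect_equal(res$curve$k, c(1, 5, 10))
})

test_that("pure-noise optimal-k curve stays near chance even at its maximum", {
  # selection-maximum inflation over the grid is quantified against a
  # shuffled-label reference on the same cohorts
  best <- numeric(12); best_shuf <- numeric(12)
  for (s in 1:12) {
    data <- planted_table(20, 20, 8, 0, 0, seed = 700 + s)
    cfg <- rfe_config(k_grid = c(1, 2, 4, 8), step = 2)
    best[s] <- max(optimal_k_search(data, cfg)$curve$accuracy)
    shuf <- data
    shuf$label <- withr::with_seed(800 + s, sample(shuf$label))
    best_shuf[s] <- max(optimal_k_search(shuf, cfg)$curve$accuracy)
  }
  # labels are already unrelated to features, so reshuffling changes nothing
  # systematically: the two max-curve distributions should overlap
  expect_lt(abs(mean(best) - mean(best_shuf)), 0.12)
  expect_lt(mean(best), 0.80)  # inflated above 0.5, but bounded
})

test_that("vote tallies conserve votes and respect the target size", {
  data <- planted_table(20, 20, 12, 3, 3, seed = 61)
  cfg <- rfe_config(n_folds = 5, seed = 9)
  vt <- vote_selection(data, target_n = 4, cfg)
  expect_equal(sum(vt$tally$votes), 5 * 4)
  expect_length(vt$final_features, 4)
  expect_true(all(vt$tally$votes <= 5))
  # planted features should dominate the vote
  expect_true(all(c("f001", "f002", "f003") %in% vt$final_features))
  # a no-boundary-tie ordering keeps the top votes
  ord <- vt$tally[order(-vt$tally$votes), ]
  expect_true(all(vt$final_features %in% ord$feature[seq_len(sum(ord$votes >= ord$votes[4]))]))
})

test_that("selection is deterministic under a fixed seed", {
  data <- planted_table(15, 15, 10, 2, 1.5, seed = 71)
  cfg <- rfe_config(k_grid = c(1, 3, 5), step = 2, n_folds = 5, seed = 4)
  a <- optimal_k_search(data, cfg); b <- optimal_k_search(data, cfg)
  expect_identical(a$curve, b$curve)
  expect_identical(a$optimal_k, b$optimal_k)
  va <- vote_selection(data, 3, cfg); vb <- vote_selection(data, 3, cfg)
  expect_identical(va$tally, vb$tally)
  expect_identical(va$final_features, vb$final_features)
})

test_that("held-out subjects never influence elimination or standardization", {
  # the held-out subject carries an extreme outlier; the split's elimination
  # path, fit and prediction must match a manual train-only reconstruction
  data <- planted_table(12, 12, 6, 1, 2.5, seed = 81)
  n <- nrow(data)
  data$f002[n] <- 1e6  # absurd outlier in the last subject only
  cfg <- rfe_config(k_grid = c(1, 3), step = 1)

  res <- optimal_k_search(data, cfg)

  # manual split-wise oracle: for every i, rank and fit on the other n-1 only
  for (k in c(1, 3)) {
    correct <- vapply(seq_len(n), function(i) {
      train <- data[-i, ]
      sel <- svm_rfe_rank(train, k, cfg)$survivors
      x_tr <- as.matrix(train[sel])
      ctr <- colMeans(x_tr); scl <- apply(x_tr, 2, sd); scl[scl == 0] <- 1
      fit <- braingut:::fit_svm_linear(scale(x_tr, ctr, scl), train$label, cost = 1)
      x_new <- (unlist(data[i, sel]) - ctr) / scl
      pred <- as.integer(sum(x_new * fit$weights) + fit$intercept > 0)
      pred == data$label[i]
    }, logical(1))
    expect_equal(res$curve$accuracy[res$curve$k == k], mean(correct))
  }

  # loo_evaluate: held-out score equals a train-only refit's score exactly
  sel <- c("f001", "f003")
  rep <- loo_evaluate(data, sel, "metabolite", "svm")
  i <- n
  train <- data[-i, ]
  des <- assemble_design(train, sel, "metabolite")
  fit <- train_linear(des$x, des$y, "svm")
  x_new <- cbind(as.matrix(data[i, sel]), as.matrix(data[i, des$covariate_cols]))
  expect_equal(rep$predictions$score[i], unname(predict(fit, x_new, "score")),
               tolerance = 1e-10)
})
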