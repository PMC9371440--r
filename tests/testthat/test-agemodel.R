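test_that("partition_cells balances within windows deterministically", {
  widx <- rep(0, 110)
  p <- partition_cells(widx, 11, seed = 1)
  expect_equal(unname(table(p)), rep(10L, 11), ignore_attr = TRUE)

  widx2 <- rep(c(0, 1), each = 22)
  p2 <- partition_cells(widx2, 11, seed = 2)
  expect_true(all(table(p2, widx2) == 2))

  expect_identical(partition_cells(widx2, 11, seed = 9),
                   partition_cells(widx2, 11, seed = 9))
  expect_error(partition_cells(rep(0, 5), 11), "at least n_partitions")
})

test_that("select_time_features ranks by |correlation| with time", {
  centers <- c(1, 2, 3, 5, 7, 9, 11, 13)
  n <- length(centers)
  set.seed(4)
  x <- rbind(copy = centers,
             noisy = centers + rnorm(n, 0, 3),
             flat = rep(5, n),
             anti = -centers)
  x <- Matrix::Matrix(x, sparse = TRUE)
  sel <- select_time_features(x, centers, 2)
  # |r| = 1 for both "copy" and "anti"; the tie breaks by feature id
  expect_setequal(sel, c("anti", "copy"))
  expect_equal(sel[1], "anti")
  expect_false("flat" %in%
                 select_time_features(x, centers, 3))  # zero variance
  # planted |r| ordering is respected
  expect_equal(select_time_features(x, centers, 3),
               c("anti", "copy", "noisy"))
  expect_error(select_time_features(Matrix::Matrix(matrix(1, 2, 8),
                                                   sparse = TRUE),
                                    centers, 1), "zero variance")
})

test_that("lasso age model matches linear-regression oracles", {
  win <- collection_windows(seq(0, 10, 2), seq(2, 12, 2))
  set.seed(1)
  n <- 240
  widx <- rep(win$index, each = n / 6)
  y <- win$center_h[match(widx, win$index)]
  # single feature equal to the target, tiny penalty: exact fit
  x1 <- matrix(y, nrow = 1, dimnames = list("f1", NULL))
  m1 <- fit_lasso_age(x1, widx, win, lambda = c(1e-6, 1e-7), n_folds = 5,
                      preprocess = FALSE)
  expect_equal(unname(predict_age(m1, x1)), y, tolerance = 1e-3)

  # huge penalty shrinks to the intercept-only model
  m0 <- fit_lasso_age(x1, widx, win, lambda = c(1e6, 1e5), n_folds = 5,
                      preprocess = FALSE)
  expect_equal(unname(predict_age(m0, x1)), rep(mean(y), n),
               tolerance = 1e-6)

  # noiseless linear relationship center = 2 * feature + 3: with a tiny
  # penalty the recovered slope matches the least-squares oracle within 1%
  xg <- seq(-1, 3.5, length.out = 10)
  win3 <- collection_windows(2 * xg + 3 - 1, 2 * xg + 3 + 1)
  widx3 <- rep(win3$index, each = 12)
  x3 <- matrix(rep(xg, each = 12), nrow = 1,
               dimnames = list("f1", NULL))
  m3 <- fit_lasso_age(x3, widx3, win3, lambda = c(1e-5, 1e-6),
                      n_folds = 4, preprocess = FALSE)
  slope <- as.numeric(coef(m3$fit, s = "lambda.min"))[2]
  y3 <- win3$center_h[match(widx3, win3$index)]
  oracle_slope <- unname(coef(lm(y3 ~ x3["f1", ]))[2])
  expect_equal(oracle_slope, 2, tolerance = 1e-10)
  expect_equal(slope, oracle_slope, tolerance = 0.01)

  expect_error(fit_lasso_age(x1, widx, win, lambda = numeric(0)),
               "non-empty")
})

test_that("nn age model learns constants and is seed-deterministic", {
  win <- collection_windows(4, 6)  # constant target 5.0
  set.seed(2)
  x <- matrix(rnorm(5 * 400), nrow = 5,
              dimnames = list(paste0("f", 1:5), NULL))
  widx <- rep(0L, 400)
  m <- fit_nn_age(x, widx, win, preprocess = FALSE,
                  hyper_grid = list(list(hidden = c(8, 4),
                                         learning_rate = 1e-2)),
                  max_epochs = 60, seed = 3)
  err <- abs(predict_age(m, x) - 5)
  expect_lt(mean(err), 0.1)
  expect_lt(median(err), 0.1)

  grid <- list(list(hidden = c(8, 4), learning_rate = 1e-2),
               list(hidden = c(4, 2), learning_rate = 1e-3))
  m1 <- fit_nn_age(x, widx, win, preprocess = FALSE, hyper_grid = grid,
                   n_folds = 2, max_epochs = 10, seed = 11)
  m2 <- fit_nn_age(x, widx, win, preprocess = FALSE, hyper_grid = grid,
                   n_folds = 2, max_epochs = 10, seed = 11)
  expect_identical(m1$hyper, m2$hyper)
  expect_identical(m1$cv_record, m2$cv_record)
  expect_error(fit_nn_age(x, widx, win, hyper_grid = list()), "non-empty")
})

test_that("nn and lasso are comparable when the age map is linear", {
  # features linear in the target: the linear model is ideal and the NN
  # should come within 20% relative MSE
  win <- collection_windows(seq(0, 16, 4), seq(4, 20, 4))
  set.seed(6)
  n <- 1200
  widx <- rep(win$index, each = n / 5)
  y <- win$center_h[match(widx, win$index)]
  x <- rbind(f1 = y + rnorm(n, 0, 1.5), f2 = y + rnorm(n, 0, 2),
             f3 = rnorm(n))
  tr <- seq_len(n) %% 5 != 0
  ml <- fit_lasso_age(x[, tr], widx[tr], win, preprocess = FALSE,
                      n_folds = 5, seed = 1)
  mn <- fit_nn_age(x[, tr], widx[tr], win, preprocess = FALSE,
                   hyper_grid = list(list(hidden = c(16, 8),
                                          learning_rate = 1e-2)),
                   max_epochs = 60, seed = 1)
  mse <- function(m) mean((predict_age(m, x[, !tr]) - y[!tr])^2)
  expect_lt(abs(mse(mn) - mse(ml)) / mse(ml), 0.2)
})

test_that("predict_age enforces its feature contract", {
  win <- collection_windows(c(0, 4), c(4, 8))
  x <- matrix(1:48 / 10, nrow = 2, dimnames = list(c("a", "b"), NULL))
  m <- fit_lasso_age(x, rep(c(0L, 1L), each = 12), win,
                     lambda = c(1, 0.1), n_folds = 4,
                     preprocess = FALSE)
  expect_error(predict_age(m, x[1, , drop = FALSE]), "model feature")
  # prediction ignores features outside feature_ids
  extra <- rbind(x, junk = rnorm(24))
  expect_equal(predict_age(m, extra), predict_age(m, x))
  # deterministic given the frozen model
  expect_identical(predict_age(m, x), predict_age(m, x))
})

test_that("evaluate_age matches a brute-force recomputation", {
  win <- default_window_schedule()
  set.seed(5)
  widx <- sample(win$index, 200, replace = TRUE)
  centers <- win$center_h[match(widx, win$index)]
  pred <- pmax(centers + rnorm(200, 0, 2), 0)
  ev <- evaluate_age(pred, widx, win)
  oracle <- evaluate_age_oracle(pred, widx, win)
  expect_equal(ev$mse, oracle$mse)
  expect_equal(ev$proportion_correct, oracle$proportion_correct)

  # arithmetic examples in 2-h windows
  w2 <- collection_windows(c(0, 2), c(2, 4))
  wi <- c(0L, 1L)
  cen <- w2$center_h
  expect_equal(evaluate_age(cen, wi, w2)$mse, 0)
  expect_equal(evaluate_age(cen, wi, w2)$proportion_correct, 1)
  ev2 <- evaluate_age(cen + 0.5, wi, w2)
  expect_equal(ev2$mse, 0.25)
  expect_equal(ev2$proportion_correct, 1)
  expect_equal(evaluate_age(cen + 3, wi, w2)$proportion_correct, 0)
  expect_error(evaluate_age(1, wi, w2), "equal length")
})

test_that("bulk prediction is the single-pseudo-cell path", {
  at <- small_atlas()
  m <- fit_lasso_age(at$rna$counts, at$rna$cells$window_index,
                     at$windows, n_features = 150, n_folds = 5, seed = 1)
  one <- at$rna$counts[, 7, drop = FALSE]
  expect_equal(unname(predict_bulk_age(m, one)),
               unname(predict_age(m, one)))
  # bulks summed from cells of young vs old ages keep their order
  cells <- at$rna$cells
  young <- Matrix::rowSums(at$rna$counts[, cells$true_age_h < 4])
  old <- Matrix::rowSums(at$rna$counts[, cells$true_age_h > 12])
  bulk <- cbind(young = young, old = old)
  pb <- predict_bulk_age(m, bulk)
  expect_lt(pb[1], pb[2])
  expect_error(predict_bulk_age(m, bulk * 0), "zero total")
})

test_that("contamination_fraction and filter_by_age follow their rules", {
  expect_equal(contamination_fraction(c(1, 1, 1, 5), 4), 0.25)
  expect_equal(contamination_fraction(c(1, 2), 0), 1.0)
  expect_error(contamination_fraction(numeric(0)), "no cells")

  ages <- c(17.9, 18.0, 18.1)
  expect_equal(filter_by_age(ages), c(TRUE, TRUE, FALSE))
  expect_equal(filter_by_age(ages, Inf), rep(TRUE, 3))
  expect_equal(filter_by_age(numeric(0)), logical(0))
  df <- data.frame(id = 1:3)
  expect_equal(filter_by_age(ages, cells = df)$id, 1:2)
})

test_that("sex classification separates the planted chrX mixture", {
  set.seed(9)
  truth <- rep(c("XX", "XY"), each = 400)
  fr <- pmin(pmax(rnorm(800, ifelse(truth == "XX", 0.04, 0.02), 0.004),
                  0), 1)
  res <- classify_sex_gmm(fr, seed = 1)
  expect_gte(mean(res$sex == truth), 0.99)
  # midpoint-threshold oracle agrees on the unambiguous cells
  midpoint <- mean(res$means)
  oracle <- ifelse(fr > midpoint, "XX", "XY")
  expect_gte(mean(res$sex == oracle), 0.99)
  # shift invariance of the two-component assignment
  res2 <- classify_sex_gmm(fr * 0 + fr + 0.01, seed = 1)
  expect_identical(res$sex, res2$sex)
  # higher-mean component is XX
  expect_identical(classify_sex_gmm(c(0.02, 0.04))$sex, c("XY", "XX"))
  expect_error(classify_sex_gmm(rep(0.03, 50)), "degenerate")
  expect_error(classify_sex_gmm(c(0.5, 1.5)), "\\[0, 1\\]")
})
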