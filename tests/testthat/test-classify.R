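# small seeded dataset helper used across classifier tests
toy_dataset <- function(n_per = 15, K = 3, sep = 3, seed = 101, D = 6) {
  set.seed(seed)
  centers <- matrix(rnorm(K * D, sd = sep), K, D)
  M <- do.call(rbind, lapply(1:K, function(k)
    sweep(matrix(rnorm(n_per * D), n_per, D), 2, centers[k, ], "+")))
  colnames(M) <- sprintf("f%02d", 1:D)
  labeled_dataset(M, sprintf("p%03d", 1:(K * n_per)),
                  rep(sprintf("c%d", 1:K), each = n_per))
}

test_that("min-max scaler maps training data into [-1, 1] with stored params", {
  M <- cbind(a = c(2, 4, 6), b = c(1, 1, 1), c = c(-3, 0, 3))
  sc <- fit_scaler(M)
  S <- apply_scaler(sc, M)
  expect_equal(unname(S[2, "a"]), 0)          # midpoint of [2, 6]
  expect_true(all(S[, "b"] == 0))     # constant feature
  expect_true(all(S >= -1 & S <= 1))
  # unseen test values: constant feature still 0, others use train range
  S2 <- apply_scaler(sc, cbind(a = 8, b = 99, c = 0))
  expect_equal(unname(S2[1, "b"]), 0)
  expect_equal(unname(S2[1, "a"]), 2)  # linear extrapolation past the max
  expect_error(fit_scaler(M[0, , drop = FALSE]), "empty")
})

test_that("SMO solution satisfies the KKT conditions of the soft-margin dual", {
  for (s in 1:5) {
    set.seed(400 + s)
    n <- 30
    X <- rbind(matrix(rnorm(n / 2 * 3, 1.2), n / 2, 3),
               matrix(rnorm(n / 2 * 3, -1.2), n / 2, 3))
    y <- rep(c(1, -1), each = n / 2)
    C <- 2^sample(-2:6, 1)
    K <- exp(-0.5 * as.matrix(dist(X))^2)
    fit <- pssmfold:::smo_solve(K, y, C)
    a <- fit$alpha
    expect_true(all(a >= -1e-9 & a <= C + 1e-9))     # box constraint
    expect_lt(abs(sum(a * y)), 1e-8)                 # equality constraint
    f <- drop(K %*% (a * y)) + fit$b
    free <- a > 1e-6 * C & a < C * (1 - 1e-6)
    if (any(free)) expect_lt(max(abs(y[free] * f[free] - 1)), 5e-3)
    expect_true(all(y[a < 1e-9] * f[a < 1e-9] >= 1 - 5e-3))   # margin outside
    expect_true(all(y[a > C - 1e-9] * f[a > C - 1e-9] <= 1 + 5e-3))
  }
})

test_that("a separable two-class problem is reproduced; K = 2 is one machine", {
  d <- toy_dataset(n_per = 10, K = 2, sep = 4, seed = 55)
  m <- grid_search_train(d, 0, 0, folds = 2, seed = 1)
  expect_length(m$machines, 1L)
  expect_equal(predict(m, d), d$labels)
})

test_that("a 1x1 grid returns exactly that pair; full tie picks smallest", {
  d <- toy_dataset(seed = 66)
  m <- grid_search_train(d, 3, -2, folds = 3, seed = 1)
  expect_equal(m$c_exp, 3); expect_equal(m$gamma_exp, -2)
  # strongly separable: every grid point reaches the same CV accuracy,
  # so the documented tie-break must pick smallest C then smallest gamma
  m2 <- grid_search_train(d, c(1, 5), c(-3, -1), folds = 3, seed = 1)
  tied <- m2$cv_table[m2$cv_table$cv_accuracy == max(m2$cv_table$cv_accuracy), ]
  expect_equal(m2$c_exp, min(tied$c_exp))
  expect_equal(m2$gamma_exp,
               min(tied$gamma_exp[tied$c_exp == m2$c_exp]))
})

test_that("training validates its inputs", {
  d <- toy_dataset(seed = 5)
  one <- labeled_dataset(d$matrix, d$protein_ids, rep("only", nrow(d$matrix)))
  expect_error(grid_search_train(one, 0, 0), "2 classes")
  expect_error(grid_search_train(d, integer(0), 0), "empty")
  expect_warning(grid_search_train(d, 0, 0, folds = 40, seed = 1),
                 "reducing folds")
})

test_that("predictions are invariant to input column permutation", {
  d <- toy_dataset(seed = 77)
  m <- grid_search_train(d, c(0, 4), c(-4, -1), folds = 3, seed = 2)
  perm <- sample(ncol(d$matrix))
  shuffled <- d$matrix[, perm]
  expect_equal(predict(m, shuffled), predict(m, d$matrix))
  expect_error(predict(m, d$matrix[, 1:3]), "lacks selected features")
})

test_that("grid search is deterministic end to end", {
  d <- toy_dataset(seed = 88)
  m1 <- grid_search_train(d, c(-1, 2), c(-5, -2), folds = 4, seed = 9)
  m2 <- grid_search_train(d, c(-1, 2), c(-5, -2), folds = 4, seed = 9)
  expect_identical(m1$cv_table, m2$cv_table)
  expect_identical(m1$c_exp, m2$c_exp)
  expect_identical(predict(m1, d), predict(m2, d))
})

test_that("evaluate reproduces the hand-computed metric example", {
  # class A: TP = 9, FN = 1, FP = 2
  truth <- c(rep("A", 10), rep("B", 5))
  pred <- c(rep("A", 9), "B", rep("A", 2), rep("B", 3))
  r <- evaluate(truth, pred, c("A", "B"))
  a <- r$per_class[r$per_class$class == "A", ]
  expect_equal(a$sensitivity, 0.9, tolerance = 1e-4)
  expect_equal(a$precision, 9 / 11, tolerance = 1e-4)
  expect_equal(a$f1, 18 / 21, tolerance = 1e-4)
  expect_equal(r$accuracy, sum(diag(r$confusion_matrix)) / 15)
  expect_equal(unname(rowSums(r$confusion_matrix)), c(10, 5))
})

test_that("evaluate handles perfect and degenerate predictors", {
  y <- rep(c("x", "y", "z"), each = 4)
  perfect <- evaluate(y, y)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro_f1, 1)
  expect_true(all(perfect$confusion_matrix[upper.tri(perfect$confusion_matrix)] == 0))

  truth <- rep(c("A", "B"), each = 6)
  allA <- evaluate(truth, rep("A", 12), c("A", "B"))
  expect_equal(allA$accuracy, 0.5)
  expect_equal(allA$per_class$precision[1], 0.5)
  expect_equal(allA$per_class$f1[2], 0)        # TP = 0 forces F1 = 0
  expect_error(evaluate(truth, rep("C", 12), c("A", "B")), "outside")
  expect_error(evaluate(truth, truth[1:3]), "equal length")
  # class absent from truth is flagged and scored 0 sensitivity
  r <- evaluate(c("A", "A"), c("A", "B"), c("A", "B"))
  expect_equal(r$undefined_classes, "B")
  expect_equal(r$per_class$sensitivity[2], 0)
})

test_that("macro F1 is invariant under class-label permutation", {
  set.seed(3)
  truth <- sample(c("a", "b", "c"), 60, replace = TRUE)
  pred <- sample(c("a", "b", "c"), 60, replace = TRUE)
  r1 <- evaluate(truth, pred, c("a", "b", "c"))
  map <- c(a = "q", b = "r", c = "p")
  r2 <- evaluate(unname(map[truth]), unname(map[pred]), unname(map[c("a", "b", "c")]))
  expect_equal(r1$macro_f1, r2$macro_f1, tolerance = 1e-12)
  expect_equal(r1$accuracy, r2$accuracy)
})

test_that("model archives round-trip through JSON with manifest check", {
  d <- toy_dataset(n_per = 8, seed = 12)
  m <- grid_search_train(d, c(0, 3), c(-4, -2), folds = 2, seed = 4,
                         selection = list(n_bins = 5, band_fraction = 0.5))
  dir <- withr::local_tempdir()
  write_fold_model(m, dir)
  m2 <- read_fold_model(dir)
  expect_equal(m2$C, m$C)
  expect_equal(m2$gamma, m$gamma)
  expect_equal(predict(m2, d), predict(m, d))
  # corrupt the payload -> manifest mismatch
  cat("\n", file = file.path(dir, "model.json"), append = TRUE)
  expect_error(read_fold_model(dir), "md5 mismatch")
})
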