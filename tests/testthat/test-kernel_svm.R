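test_that("gamma grid adapts to the observed log-distance range", {
  # all ln d within [-3, 3] -> default grid from e^-3 to e^3
  D <- matrix(0, 3, 3)
  D[1, 2] <- D[2, 1] <- exp(-1)
  D[1, 3] <- D[3, 1] <- exp(1)
  D[2, 3] <- D[3, 2] <- 1
  g <- gamma_grid(D)
  expect_length(g, 10)
  expect_equal(g[1], exp(-3))
  expect_equal(g[10], exp(3))
  expect_equal(diff(log(g)), rep(6 / 9, 9))       # log-uniform

  # min ln d = -5, max ln d = 2  ->  t = -5, s = 8/9
  D2 <- matrix(0, 3, 3)
  D2[1, 2] <- D2[2, 1] <- exp(-5)
  D2[1, 3] <- D2[3, 1] <- exp(2)
  D2[2, 3] <- D2[3, 2] <- 1
  g2 <- gamma_grid(D2)
  expect_equal(log(g2[1]), -5)
  expect_equal(diff(log(g2)), rep(8 / 9, 9))
  expect_equal(g2[10], exp(9 * 8 / 9 - 5))

  expect_warning(g3 <- gamma_grid(rbind(c(0, 0, 1), c(0, 0, 1), c(1, 1, 0))),
                 "zero off-diagonal")
  suppressWarnings(expect_error(gamma_grid(matrix(0, 3, 3)), "degenerate"),
                   classes = "pairprop_zero_distance")
})

test_that("Gaussian kernel maps distances to (0, 1] with unit diagonal", {
  D <- pairwise_matrix(toy_descriptors())
  for (gamma in gamma_grid(D)) {
    K <- gaussian_kernel(D, gamma)
    expect_equal(diag(K), rep(1, nrow(D)), ignore_attr = TRUE)
    # entries lie in (0, 1]; exp() may underflow to exactly 0 for d^2 >> gamma
    expect_true(all(K >= 0 & K <= 1))
    expect_identical(K[lower.tri(K)], t(K)[lower.tri(K)])
  }
  expect_equal(gaussian_kernel(matrix(2, 1, 1), gamma = 4)[1, 1], exp(-1))
  expect_error(gaussian_kernel(D, -1), "positive")
  expect_error(gaussian_kernel(D, 0), "positive")
  # monotone decrease in d at fixed gamma
  d <- seq(0, 3, by = 0.5)
  expect_true(all(diff(gaussian_kernel(matrix(d, 1), 2)[1, ]) < 0))
})

test_that("SMO solver matches the frozen reference solution", {
  # Reference alpha/b computed with scikit-learn SVC(kernel='precomputed',
  # C=1, tol=1e-3) on this exact kernel during development, then frozen.
  set.seed(7)
  X <- matrix(rnorm(40), 20, 2); X[11:20, ] <- X[11:20, ] + 2
  K <- exp(-as.matrix(dist(X))^2 / 2)
  y <- c(rep(-1L, 10), rep(1L, 10))
  fit <- pairprop:::.smo_train(unname(K), y, C = 1)
  ref_alpha <- c(1, 0.321089, 0, 0.848129, 0.514064, 0, 1, 0, 0, 1,
                 1, 0.83174, 0, 0, 0.498055, 0.345451, 0.968685, 1, 0,
                 0.039351)
  expect_equal(fit$alpha, ref_alpha, tolerance = 0.01)
  expect_equal(fit$b, -0.049646, tolerance = 0.01)
  # dual feasibility
  expect_true(all(fit$alpha >= 0 & fit$alpha <= 1))
  expect_equal(sum(fit$alpha * y), 0, tolerance = 1e-9)
})

test_that("grid search visits 110 points and finds separable data separable", {
  set.seed(3)
  # two tight clusters far apart in pseudo-distance
  n <- 16
  D <- matrix(0, n, n)
  cl <- rep(c(0, 1), each = n / 2)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- abs(cl[i] - cl[j]) * 4 + runif(1, 0.05, 0.3)
  }
  rownames(D) <- colnames(D) <- paste0("m", 1:n)
  labels <- cl
  model <- train_select(D, labels, svm_grid_config(folds = 4))
  expect_equal(dim(model$cv_accuracy), c(10, 11))   # 110 (gamma, C) fits
  expect_equal(model$cv_best, 1.0)
  # training accuracy 1.0 at the selected point
  scores <- svm_decision(model, D)
  expect_equal(as.integer(scores > 0), labels)
  expect_error(train_select(D, rep(1, n)), "single class")
})

test_that("tie-breaking prefers smaller C then smaller gamma", {
  # a 2-point toy where every grid point scores identically
  D <- matrix(c(0, 1, 2, 3, 1, 0, 2.5, 3.5, 2, 2.5, 0, 1.2, 3, 3.5, 1.2, 0),
              4, 4)
  rownames(D) <- colnames(D) <- paste0("m", 1:4)
  model <- train_select(D, c(0, 0, 1, 1), svm_grid_config(folds = 2))
  acc <- model$cv_accuracy
  best <- max(acc)
  cand <- which(acc == best, arr.ind = TRUE)   # columns: gamma index, C index
  Cs <- 2^(-5:5)
  expect_equal(model$C, min(Cs[cand[, 2]]))
  gam_at_minC <- gamma_grid(D)[cand[cand[, 2] == which(Cs == model$C), 1]]
  expect_equal(model$gamma, min(gam_at_minC))
})

test_that("permuted labels give chance-level CV accuracy", {
  set.seed(21)
  n <- 30
  D <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- runif(1, 0.5, 2)
  rownames(D) <- colnames(D) <- paste0("m", 1:n)
  labels <- sample(rep(0:1, each = n / 2))
  model <- train_select(D, labels, svm_grid_config(folds = 5))
  expect_lt(abs(model$cv_best - 0.5), 0.25)  # majority rate 0.5 here
})

test_that("AUC follows the midrank convention and monotone invariance", {
  expect_equal(auc_score(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_score(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(auc_score(c(0.1, 0.9, 0.2, 0.8), c(0, 1, 0, 1)), 1.0)
  s <- c(0.3, 0.1, 0.45, 0.2, 0.9, 0.7)
  y <- c(1, 0, 0, 1, 1, 0)
  expect_equal(auc_score(exp(5 * s), y), auc_score(s, y))
  expect_equal(auc_score(rank(s), y), auc_score(s, y))
  # ties across classes use midranks
  expect_equal(auc_score(c(1, 1, 0), c(1, 0, 0)), 0.75)
  expect_warning(a <- auc_score(c(0.2, 0.4), c(1, 1)), "single-class")
  expect_true(is.na(a))
})

test_that("model JSON round-trips and predicts identically", {
  set.seed(5)
  n <- 10
  D <- matrix(0, n, n)
  cl <- rep(0:1, each = 5)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- abs(cl[i] - cl[j]) * 3 + runif(1, 0.1, 0.4)
  rownames(D) <- colnames(D) <- paste0("m", 1:n)
  model <- train_select(D, cl, svm_grid_config(folds = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(svm_decision(back, D), svm_decision(model, D), tolerance = 1e-12)
})
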