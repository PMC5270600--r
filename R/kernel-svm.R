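# Gaussian kernels over an adaptive bandwidth grid, and grid-searched
# precomputed-kernel SVM classification.

#' Adaptive Gaussian bandwidth grid
#'
#' Ten log-uniform bandwidths adapted to the observed pseudo-distance range:
#' with `t = min(-3, min ln d)` and `s = (max(3, max ln d) - t) / 9` over all
#' distinct positive off-diagonal distances, the grid is
#' `exp(s * i + t), i = 0..9`. When all log-distances fall inside [-3, 3]
#' this is the default range `[e^-3, e^3]`.
#'
#' @param D symmetric pseudo-distance matrix.
#' @return increasing numeric vector of length 10.
#' @export
gamma_grid <- function(D) {
  off <- D[upper.tri(D)]
  if (any(off == 0))
    warning(warningCondition(
      "zero off-diagonal distances skipped in gamma grid statistics",
      class = "pairprop_zero_distance"))
  off <- off[off > 0]
  if (!length(off))
    stop("degenerate molecule set: all pseudo-distances are zero", call. = FALSE)
  lnd <- log(off)
  t0 <- min(-3, min(lnd))
  s <- (max(3, max(lnd)) - t0) / 9
  exp(s * (0:9) + t0)
}

#' Gaussian kernel from a pseudo-distance matrix
#'
#' Element-wise `exp(-d^2 / gamma)`; the diagonal is exactly 1.
#'
#' @param D symmetric pseudo-distance matrix (or a rectangular cross-distance
#'   matrix, for test-versus-train kernels).
#' @param gamma bandwidth, > 0.
#' @return matrix of kernel values with a `gamma` attribute.
#' @export
gaussian_kernel <- function(D, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0)
    stop("gamma must be a positive scalar", call. = FALSE)
  K <- exp(-D^2 / gamma)
  attr(K, "gamma") <- gamma
  K
}

#' SVM grid-search configuration
#'
#' @param C_grid cost grid; default `2^(-5:5)` (11 values).
#' @param folds number of cross-validation folds used to score each
#'   (gamma, C) grid point; default 10.
#' @param seed seed for the fold assignment.
#' @return list of class `svm_grid_config`.
#' @export
svm_grid_config <- function(C_grid = 2^(-5:5), folds = 10, seed = 1L) {
  stopifnot(all(C_grid > 0), folds >= 2)
  structure(list(C_grid = C_grid, folds = folds, seed = as.integer(seed)),
            class = "svm_grid_config")
}

.as_pm1 <- function(labels) {
  u <- sort(unique(labels))
  if (length(u) < 2) stop("labels contain a single class", call. = FALSE)
  if (length(u) > 2) stop("binary labels required", call. = FALSE)
  ifelse(labels == u[2], 1L, -1L)   # larger value = positive class
}

.fold_assignment <- function(n, k, seed) {
  k <- min(k, n)
  f <- rep(seq_len(k), length.out = n)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample(f)
}

#' Train a precomputed-kernel SVM with exhaustive (gamma, C) grid search
#'
#' Builds the adaptive 10-point gamma grid from the training distances,
#' scores every (gamma, C) pair (10 x 11 = 110 fits per fold set) by k-fold
#' cross-validated accuracy, picks the best — ties broken by smaller C, then
#' smaller gamma — and refits on the full training set.
#'
#' @param D training pseudo-distance matrix (symmetric, ids as dimnames), or
#'   a list of kernel matrices carrying `gamma` attributes.
#' @param labels binary labels, one per training molecule.
#' @param config an [svm_grid_config()].
#' @return object of class `pairprop_svm`: support coefficients
#'   (`coef = alpha * y`), bias `b`, chosen `gamma` and `C`, training ids,
#'   and the full `cv_accuracy` grid (gammas x Cs).
#' @export
train_select <- function(D, labels, config = svm_grid_config()) {
  if (is.list(D) && !is.matrix(D)) {
    gammas <- vapply(D, attr, numeric(1), "gamma")
    K1 <- D[[1]]
    D <- sqrt(pmax(-log(pmax(K1, .Machine$double.xmin)) * gammas[1], 0))
    diag(D) <- 0
  } else {
    gammas <- gamma_grid(D)
  }
  n <- nrow(D)
  stopifnot(length(labels) == n)
  y <- .as_pm1(labels)
  fold <- .fold_assignment(n, config$folds, config$seed)
  acc <- .svm_grid_cv(unname(D), y, gammas, config$C_grid, fold)
  best <- max(acc, na.rm = TRUE)
  cand <- which(acc == best, arr.ind = TRUE)   # cols: gamma index, C index
  cand <- cand[order(cand[, 2], cand[, 1]), , drop = FALSE]
  g_best <- gammas[cand[1, 1]]
  C_best <- config$C_grid[cand[1, 2]]
  dimnames(acc) <- list(gamma = signif(gammas, 6), C = config$C_grid)
  K <- gaussian_kernel(D, g_best)
  fit <- .smo_train(unname(K), y, C_best)
  structure(list(coef = fit$alpha * y, b = fit$b, gamma = g_best, C = C_best,
                 y = y, ids = rownames(D), cv_accuracy = acc,
                 cv_best = best, config = config),
            class = "pairprop_svm")
}

#' @export
print.pairprop_svm <- function(x, ...) {
  cat(sprintf(
    "<pairprop_svm: n=%d, gamma=%.4g, C=%.4g, CV accuracy=%.3f, %d SVs>\n",
    length(x$coef), x$gamma, x$C, x$cv_best, sum(abs(x$coef) > 1e-12)))
  invisible(x)
}

#' Decision scores for new molecules
#'
#' @param model a `pairprop_svm`.
#' @param D_cross test-versus-train pseudo-distance matrix (rows = test
#'   molecules, columns in the model's training order).
#' @return numeric decision scores (positive = positive class).
#' @export
svm_decision <- function(model, D_cross) {
  D_cross <- rbind(D_cross)   # tolerate a single test row given as a vector
  stopifnot(ncol(D_cross) == length(model$coef))
  K <- gaussian_kernel(D_cross, model$gamma)
  drop(K %*% model$coef + model$b)
}

#' ROC AUC with midrank tie handling
#'
#' Rank-sum formulation: `(sum of positive ranks - npos(npos+1)/2) /
#' (npos * nneg)`, using midranks for tied scores, so identical scores for
#' all samples give 0.5 and AUC is invariant under strictly monotone score
#' transforms.
#'
#' @param scores numeric decision scores.
#' @param labels binary labels.
#' @return AUC in [0, 1]; `NA` with a warning when only one class is present.
#' @export
auc_score <- function(scores, labels) {
  y <- labels == sort(unique(labels))[length(unique(labels))]
  npos <- sum(y); nneg <- sum(!y)
  if (npos == 0 || nneg == 0) {
    warning("AUC undefined for a single-class test set")
    return(NA_real_)
  }
  r <- rank(scores)   # midranks
  (sum(r[y]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Predict a test set and compute its AUC
#'
#' @param model a `pairprop_svm`.
#' @param D_cross test-versus-train pseudo-distance matrix.
#' @param labels test labels.
#' @return list with `scores`, `predicted` (0/1) and `auc`.
#' @export
predict_and_auc <- function(model, D_cross, labels) {
  scores <- svm_decision(model, D_cross)
  list(scores = scores, predicted = as.integer(scores > 0),
       auc = auc_score(scores, labels))
}

#' Write / read a trained model as JSON
#'
#' Stores support-vector ids and coefficients, bias, gamma and C. Reading
#' restores a model usable with [svm_decision()] given cross-distances in
#' the stored training order.
#'
#' @param model a `pairprop_svm`; `path` file path.
#' @param path file path.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(
    list(ids = model$ids, coef = model$coef, b = model$b,
         gamma = model$gamma, C = model$C, y = model$y),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coef = m$coef, b = m$b, gamma = m$gamma, C = m$C,
                 y = m$y, ids = m$ids, cv_accuracy = NULL, cv_best = NA,
                 config = NULL),
            class = "pairprop_svm")
}
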