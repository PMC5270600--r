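# Genetic-algorithm optimization of the 11 feature weights.
#
# Fitness of a weight vector is the mean out-of-bag SVM accuracy over
# bootstrap resamples of the training set ("bagging"): each bag trains a
# grid-searched precomputed-kernel SVM on the in-bag molecules and is scored
# on the out-of-bag ones. The pseudo-distance matrix is computed once per
# genome and sub-indexed per bag.

#' GA configuration
#'
#' Full-scale defaults follow the published setup (population 32, mutation
#' 0.15, crossover 0.8, 20 generations, 1000 bags); desk-scale runs for
#' tests use population 8, generations 5, bags 20.
#'
#' @param population population size (default 32).
#' @param p_mutation per-gene mutation probability (default 0.15).
#' @param p_crossover crossover probability (default 0.8).
#' @param generations number of generations (default 20).
#' @param step per-generation weight-step bound: mutation draws a uniform
#'   step in `[-step, step]` (default 0.1).
#' @param bags number of bootstrap resamples per fitness evaluation
#'   (default 1000).
#' @param seed RNG seed driving the whole optimization.
#' @param svm an [svm_grid_config()] used inside fitness evaluations.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(population = 32L, p_mutation = 0.15, p_crossover = 0.8,
                      generations = 20L, step = 0.1, bags = 1000L,
                      seed = 1L, svm = svm_grid_config()) {
  stopifnot(population >= 1, generations >= 1, bags >= 1, step > 0,
            p_mutation >= 0, p_mutation <= 1,
            p_crossover >= 0, p_crossover <= 1)
  structure(list(population = as.integer(population), p_mutation = p_mutation,
                 p_crossover = p_crossover,
                 generations = as.integer(generations), step = step,
                 bags = as.integer(bags), seed = as.integer(seed), svm = svm),
            class = "ga_config")
}

.genome <- function(w, fitness = NA_real_) list(w = weight_vector(w),
                                                fitness = fitness)

# Duplicated molecules make some pseudo-distances zero; inside resampling
# loops the per-call gamma-grid warning about them is expected noise.
.muffle_zero_dist <- function(expr) {
  withCallingHandlers(expr, pairprop_zero_distance = function(w)
    invokeRestart("muffleWarning"))
}

#' Initialize a GA population
#'
#' One genome is the unperturbed initial weight vector; the rest are
#' uniform perturbations of it within the step bound, clipped at zero.
#' Consumes the current RNG stream (callers seed via [optimize_weights()]).
#'
#' @param initial 11-weight vector.
#' @param cfg a [ga_config()].
#' @return list of genomes (`w` + `fitness`).
#' @export
init_population <- function(initial, cfg = ga_config()) {
  initial <- weight_vector(initial)
  pop <- vector("list", cfg$population)
  pop[[1]] <- .genome(initial)
  for (k in seq_len(cfg$population)[-1]) {
    w <- initial + stats::runif(11, -cfg$step, cfg$step)
    pop[[k]] <- .genome(pmax(w, 0))
  }
  pop
}

#' Bagged out-of-bag fitness of a weight vector
#'
#' For each bag, a bootstrap resample of the training molecules defines the
#' in-bag training set and its complement the validation set; a grid-searched
#' SVM is trained on the in-bag pseudo-distances and out-of-bag accuracy
#' recorded. Bags whose in-bag part is single-class (or with an empty
#' out-of-bag part) are redrawn up to 10 times, then skipped with a message.
#'
#' @param w 11-weight vector.
#' @param descriptors list of `pair_descriptor` for the training molecules.
#' @param labels binary labels.
#' @param cfg a [ga_config()].
#' @param D optional precomputed pseudo-distance matrix for `w` (cached by
#'   [optimize_weights()]).
#' @return mean out-of-bag accuracy.
#' @export
bagged_fitness <- function(w, descriptors, labels, cfg = ga_config(),
                           D = NULL) {
  if (length(unique(labels)) < 2)
    stop("training labels contain a single class", call. = FALSE)
  if (is.null(D)) D <- pairwise_matrix(descriptors, w)
  n <- nrow(D)
  accs <- numeric(0)
  for (bag in seq_len(cfg$bags)) {
    ok <- FALSE
    for (try in 1:10) {
      idx <- sample.int(n, n, replace = TRUE)
      inbag <- sort(unique(idx))
      oob <- setdiff(seq_len(n), inbag)
      if (length(oob) && length(unique(labels[inbag])) == 2) { ok <- TRUE; break }
    }
    if (!ok) { message("bag ", bag, " skipped: could not draw a two-class bag"); next }
    model <- .muffle_zero_dist(
      train_select(D[inbag, inbag, drop = FALSE], labels[inbag], cfg$svm))
    scores <- svm_decision(model, D[oob, inbag, drop = FALSE])
    pos <- sort(unique(labels[inbag]))[2]
    pred <- ifelse(scores > 0, pos, sort(unique(labels[inbag]))[1])
    accs <- c(accs, mean(pred == labels[oob]))
  }
  mean(accs)
}

#' One GA generation
#'
#' Fitness-proportional (roulette) selection, single-point crossover on the
#' 11-gene vector, per-gene mutation by a uniform step within the bound,
#' clipping at zero, and one-elite preservation of the best genome.
#'
#' @param population list of genomes with fitness set.
#' @param cfg a [ga_config()].
#' @return next population (fitness reset except for the carried elite).
#' @export
evolve <- function(population, cfg = ga_config()) {
  fit <- vapply(population, `[[`, numeric(1), "fitness")
  if (anyNA(fit)) stop("evaluate all fitnesses before evolving", call. = FALSE)
  n <- length(population)
  probs <- if (sum(fit) > 0) fit / sum(fit) else rep(1 / n, n)
  pick <- function() population[[sample.int(n, 1, prob = probs)]]
  nxt <- vector("list", n)
  elite <- population[[which.max(fit)]]
  nxt[[1]] <- elite
  k <- 2L
  while (k <= n) {
    p1 <- pick()$w; p2 <- pick()$w
    if (stats::runif(1) < cfg$p_crossover) {
      cut <- sample.int(10, 1)          # crossover point between genes
      c1 <- c(p1[seq_len(cut)], p2[-seq_len(cut)])
      c2 <- c(p2[seq_len(cut)], p1[-seq_len(cut)])
    } else {
      c1 <- p1; c2 <- p2
    }
    for (child in list(c1, c2)) {
      if (k > n) break
      mut <- stats::runif(11) < cfg$p_mutation
      child[mut] <- child[mut] + stats::runif(sum(mut), -cfg$step, cfg$step)
      nxt[[k]] <- .genome(pmax(child, 0))
      k <- k + 1L
    }
  }
  nxt
}

#' Break fitness ties by cross-validation on the original training set
#'
#' GA runs routinely end with several weight sets at identical fitness. Each
#' tied genome is scored by the best k-fold CV accuracy of the (gamma, C)
#' grid search on the full training set; the highest wins, and residual ties
#' fall back to lexicographic order of the weight vector.
#'
#' @param genomes list of tied genomes.
#' @param descriptors,labels the original training set.
#' @param cfg a [ga_config()].
#' @return the selected genome.
#' @export
select_among_ties <- function(genomes, descriptors, labels,
                              cfg = ga_config()) {
  if (length(genomes) == 1) return(genomes[[1]])
  cv <- vapply(genomes, function(g) {
    D <- pairwise_matrix(descriptors, g$w)
    .muffle_zero_dist(train_select(D, labels, cfg$svm)$cv_best)
  }, numeric(1))
  best <- which(cv == max(cv))
  if (length(best) > 1) {
    wmat <- t(vapply(genomes[best], function(g) unname(g$w), numeric(11)))
    best <- best[do.call(order, as.data.frame(wmat))[1]]
  }
  genomes[[best[1]]]
}

#' Optimize the 11 feature weights by GA
#'
#' Runs the full loop: seeded population around the initial weights,
#' bagged-fitness evaluation, roulette selection with crossover, mutation and
#' elitism for the configured number of generations, then CV tie-breaking
#' among the top-fitness genomes of the final population. Bit-reproducible
#' for a fixed `cfg$seed`.
#'
#' @param descriptors list of `pair_descriptor` (training molecules).
#' @param labels binary labels.
#' @param cfg a [ga_config()].
#' @param initial starting 11-weight vector (default [default_weights()]).
#' @param verbose print per-generation best/mean fitness.
#' @return list with `weights`, `fitness`, per-generation `history`
#'   (best/mean fitness) and the final `population`.
#' @export
optimize_weights <- function(descriptors, labels, cfg = ga_config(),
                             initial = default_weights(), verbose = FALSE) {
  set.seed(cfg$seed)
  evaluate <- function(pop) {
    for (k in seq_along(pop)) {
      if (!is.na(pop[[k]]$fitness)) next
      D <- pairwise_matrix(descriptors, pop[[k]]$w)
      pop[[k]]$fitness <- bagged_fitness(pop[[k]]$w, descriptors, labels,
                                         cfg, D = D)
    }
    pop
  }
  pop <- evaluate(init_population(initial, cfg))
  history <- data.frame(generation = 0L,
                        best = max(vapply(pop, `[[`, numeric(1), "fitness")),
                        mean = mean(vapply(pop, `[[`, numeric(1), "fitness")))
  for (gen in seq_len(cfg$generations)) {
    pop <- evaluate(evolve(pop, cfg))
    fit <- vapply(pop, `[[`, numeric(1), "fitness")
    history <- rbind(history,
                     data.frame(generation = gen, best = max(fit),
                                mean = mean(fit)))
    if (verbose)
      message(sprintf("generation %d: best %.4f mean %.4f", gen, max(fit),
                      mean(fit)))
  }
  fit <- vapply(pop, `[[`, numeric(1), "fitness")
  tied <- pop[fit >= max(fit) - 1e-12]
  winner <- select_among_ties(tied, descriptors, labels, cfg)
  list(weights = winner$w, fitness = winner$fitness, history = history,
       population = pop)
}
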