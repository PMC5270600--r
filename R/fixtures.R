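# Toy molecules, synthetic labeled sets and the repeated random-split
# evaluation protocol.

#' Built-in toy molecules
#'
#' Small fixtures spanning the descriptor's feature space: ethane, acetic
#' acid, methanesulfonic acid, the ortho and meta chloro-fluorobenzenes
#' (positional isomers that plain property sets cannot separate), pyridine,
#' and cis/trans 2-butene (identical graphs, different geometry).
#'
#' @return named list of `mol_graph` objects.
#' @export
toy_molecules <- function() {
  smi <- c(ethane = "CC",
           acetic_acid = "CC(=O)O",
           methanesulfonic_acid = "CS(=O)(=O)O",
           chloro_fluorobenzene_ortho = "Fc1ccccc1Cl",
           chloro_fluorobenzene_meta = "Fc1cccc(Cl)c1",
           pyridine = "c1ccncc1",
           butene_cis = "C/C=C\\C",
           butene_trans = "C/C=C/C")
  out <- lapply(names(smi), function(nm) parse_smiles(smi[[nm]], nm))
  stats::setNames(out, names(smi))
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic labeled molecule set
#'
#' Simple valid structures whose binary class is determined exactly (no
#' label noise) by a named structural rule:
#' \describe{
#'   \item{ring-presence}{positives are (hetero)cycles with random alkyl
#'     tails, negatives are heteroatom-decorated chains;}
#'   \item{halogen-position}{positives carry F and Cl ortho on a benzene
#'     ring, negatives meta, with varying alkyl tails;}
#'   \item{path-length}{positives have two amine nitrogens two bonds apart,
#'     negatives four or more bonds apart, in chains of varying length.}
#' }
#' Classes are balanced within one molecule and generation is deterministic
#' per seed (the global RNG state is left untouched).
#'
#' @param n number of molecules (>= 8).
#' @param rule one of `"ring-presence"`, `"halogen-position"`,
#'   `"path-length"`.
#' @param seed integer seed.
#' @return list of class `labeled_set` with `molecules`, `labels` (0/1
#'   integer), and `name`.
#' @export
synthetic_labeled_set <- function(n, rule = c("ring-presence",
                                              "halogen-position",
                                              "path-length"),
                                  seed = 1L) {
  rule <- match.arg(rule)
  if (n < 8) stop("n must be at least 8", call. = FALSE)
  npos <- ceiling(n / 2)
  nneg <- n - npos
  .with_seed(seed, {
    smi_pos <- character(npos); smi_neg <- character(nneg)
    if (rule == "ring-presence") {
      cores <- c("C1CCCCC1", "C1CCCC1", "C1CCNCC1", "C1CCOC1", "C1CCNC1")
      for (k in seq_len(npos)) {
        tail_len <- sample(0:3, 1)
        smi_pos[k] <- paste0(strrep("C", tail_len), sample(cores, 1))
      }
      for (k in seq_len(nneg)) {
        len <- sample(4:9, 1)
        atoms <- c("C", sample(c("C", "C", "C", "N", "O"), len - 1,
                               replace = TRUE))
        smi_neg[k] <- paste(atoms, collapse = "")
      }
    } else if (rule == "halogen-position") {
      for (k in seq_len(npos)) {
        t <- sample(0:3, 1)
        smi_pos[k] <- if (t == 0) "Fc1ccccc1Cl" else
          sprintf("Fc1ccc(%s)cc1Cl", strrep("C", t))
      }
      for (k in seq_len(nneg)) {
        t <- sample(0:3, 1)
        smi_neg[k] <- if (t == 0) "Fc1cccc(Cl)c1" else
          sprintf("Fc1ccc(%s)c(Cl)c1", strrep("C", t))
      }
    } else {
      for (k in seq_len(npos))
        smi_pos[k] <- paste0("NCN", strrep("C", sample(0:4, 1)))
      for (k in seq_len(nneg))
        smi_neg[k] <- paste0("N", strrep("C", sample(3:6, 1)), "N",
                             strrep("C", sample(0:2, 1)))
    }
    smiles <- c(smi_pos, smi_neg)
    labels <- c(rep(1L, npos), rep(0L, nneg))
    perm <- sample(n)
    mols <- lapply(seq_len(n), function(k)
      parse_smiles(smiles[perm[k]], sprintf("syn%03d", k)))
    structure(list(molecules = mols, labels = labels[perm],
                   name = paste0("synthetic-", rule)),
              class = "labeled_set")
  })
}

#' @export
print.labeled_set <- function(x, ...) {
  cat(sprintf("<labeled_set %s: %d molecules (%d positive, %d negative)>\n",
              x$name, length(x$molecules), sum(x$labels == 1),
              sum(x$labels == 0)))
  invisible(x)
}

#' Repeated random-split plan
#'
#' @param repeats number of random splits (default 20).
#' @param train_fraction fraction of molecules in each training set
#'   (default 0.9).
#' @param seed integer seed.
#' @return list of class `split_plan`.
#' @export
split_plan <- function(repeats = 20L, train_fraction = 0.9, seed = 1L) {
  stopifnot(repeats >= 1, train_fraction > 0, train_fraction < 1)
  structure(list(repeats = as.integer(repeats),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "split_plan")
}

#' Run the repeated random-split evaluation protocol
#'
#' For each repeat the set is split at random (unstratified, matching the
#' protocol's plain "randomly split") into train and test parts, a
#' grid-searched SVM is trained on the training pseudo-distances — after an
#' optional GA weight optimization on the training set — and the test AUC is
#' recorded. Repeats whose test split contains a single class get a missing
#' AUC and are flagged in the summary.
#'
#' @param set a `labeled_set`.
#' @param plan a [split_plan()].
#' @param weights fixed 11-weight vector used when `optimize = FALSE`.
#' @param optimize run GA weight optimization on each training split.
#' @param ga a [ga_config()] (used when `optimize = TRUE`).
#' @param svm an [svm_grid_config()].
#' @return list with `per_repeat` (data.frame of repeat, auc, n_test,
#'   single_class flag) and `summary` (mean/sd AUC over valid repeats,
#'   number missing).
#' @export
run_protocol <- function(set, plan = split_plan(),
                         weights = default_weights(), optimize = FALSE,
                         ga = ga_config(), svm = svm_grid_config()) {
  stopifnot(inherits(set, "labeled_set"))
  n <- length(set$molecules)
  descriptors <- lapply(set$molecules, build_descriptor)
  labels <- set$labels
  D_fixed <- if (!optimize) pairwise_matrix(descriptors, weights) else NULL
  set.seed(plan$seed)
  out <- data.frame(repeat_ = integer(), auc = numeric(), n_test = integer(),
                    single_class = logical())
  for (r in seq_len(plan$repeats)) {
    n_test <- max(1L, round((1 - plan$train_fraction) * n))
    test <- sort(sample.int(n, n_test))
    train <- setdiff(seq_len(n), test)
    if (length(unique(labels[train])) < 2) {
      out[r, ] <- list(r, NA_real_, n_test, TRUE)
      next
    }
    if (optimize) {
      opt <- optimize_weights(descriptors[train], labels[train], ga,
                              initial = weights)
      D <- pairwise_matrix(descriptors, opt$weights)
    } else D <- D_fixed
    model <- pairprop:::.muffle_zero_dist(
      train_select(D[train, train, drop = FALSE], labels[train], svm))
    single <- length(unique(labels[test])) < 2
    auc <- if (single) NA_real_ else
      predict_and_auc(model, D[test, train, drop = FALSE], labels[test])$auc
    out[r, ] <- list(r, auc, n_test, single)
  }
  list(per_repeat = out,
       summary = list(mean_auc = mean(out$auc, na.rm = TRUE),
                      sd_auc = stats::sd(out$auc, na.rm = TRUE),
                      n_missing = sum(is.na(out$auc))))
}

#' Write / read binary labels as two-column TSV `mol_id<TAB>{0,1}`
#' @param labels named integer vector (names = molecule ids) or
#'   `labeled_set`.
#' @param path file path.
#' @export
write_labels <- function(labels, path) {
  if (inherits(labels, "labeled_set"))
    labels <- stats::setNames(labels$labels,
                              vapply(labels$molecules, `[[`, character(1),
                                     "id"))
  utils::write.table(data.frame(id = names(labels), label = labels), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(as.integer(tab[[2]]), tab[[1]])
}
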