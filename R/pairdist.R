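# Weighted frequency-matched pseudo-distance between molecule descriptors.
#
# The distance between two grouped descriptors A and B is built from a
# greedy matching: each row a_i of A consumes the nearest remaining rows of B
# until a_i's frequency is spent (with a ratio correction when B runs out
# first); the directed distance is the RMS of these row distances over A's
# total pair count, and the symmetric pseudo-distance combines both
# directions. It is symmetric, non-negative and zero on identity, but the
# triangle inequality is not guaranteed — hence "pseudo".

.weight_names <- c("period", "family", "single_bonds", "double_bonds",
                   "triple_bonds", "aromatic_bonds", "ring_atom", "pka",
                   "ring_pair", "path_bonds", "cis_trans")

#' Default 11-weight vector
#'
#' The shipped defaults are the initial weights used before any per-set
#' optimization (obtained from a rough preliminary search on a
#' carcinogenicity set): period 0.927, family 0.400, single bonds 0.370,
#' double bonds 0.013, triple bonds 0.504, aromatic bonds 0.931, atom ring
#' flag 0.340, pKa 0.688, pair ring flag 0.264, path bonds 0.013, cis/trans
#' 0.925.
#'
#' @return named numeric vector of length 11.
#' @export
default_weights <- function() {
  stats::setNames(c(0.927, 0.400, 0.370, 0.013, 0.504, 0.931, 0.340, 0.688,
                    0.264, 0.013, 0.925), .weight_names)
}

#' Construct and validate an 11-weight vector
#'
#' @param w numeric vector of length 11, optionally named (names are matched
#'   against the canonical feature-weight names; unnamed input is taken in
#'   canonical order: period, family, single/double/triple/aromatic bonds,
#'   atom ring flag, pKa, pair ring flag, path bonds, cis/trans).
#' @return named numeric vector of length 11.
#' @export
weight_vector <- function(w) {
  if (length(w) != 11) stop("weight vector must have 11 components", call. = FALSE)
  if (!is.null(names(w)) && all(nzchar(names(w)))) {
    if (!setequal(names(w), .weight_names))
      stop("unknown weight names: ",
           paste(setdiff(names(w), .weight_names), collapse = ", "),
           call. = FALSE)
    w <- w[.weight_names]
  } else names(w) <- .weight_names
  if (any(!is.finite(w))) stop("weights must be finite", call. = FALSE)
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  w
}

#' Expand 11 tied weights to the 19 feature columns
#'
#' The two atoms of a pair share one set of 8 atom-type weights (applied
#' identically to columns 1-8 and 9-16); columns 17-18 carry the two
#' relationship weights and column 19 the cis/trans weight.
#'
#' @param w an 11-weight vector (see [weight_vector()]).
#' @return numeric vector of length 19 named by [pair_feature_names()].
#' @export
expand_weights <- function(w) {
  w <- weight_vector(w)
  stats::setNames(c(w[1:8], w[1:8], w["ring_pair"], w["path_bonds"],
                    w["cis_trans"]), pair_feature_names())
}

#' Weighted Euclidean distance between two 19-feature rows
#'
#' `sqrt(sum_k (w19_k * (a_k - b_k))^2)`; the frequency column never
#' participates.
#'
#' @param a,b numeric feature vectors of length 19.
#' @param w19 expanded weight vector of length 19.
#' @return non-negative real.
#' @export
feature_distance <- function(a, b, w19) {
  sqrt(sum((w19 * (a - b))^2))
}

# all row distances from one row to a descriptor's feature matrix
.row_distances <- function(a, B_features, w19) {
  d <- sweep(B_features, 2, a, `-`)
  d <- sweep(d, 2, w19, `*`)
  sqrt(rowSums(d * d))
}

#' Frequency-matched distance from one row to a whole descriptor
#'
#' Greedy matching that makes the row distance frequency-aware: starting
#' with `n' = freq(a)`, repeatedly take the nearest remaining row `b_m` of
#' `B` (ties broken by canonical row order); if `n' <= freq(b_m)` add
#' `n' * dist` and stop, else add `freq(b_m) * dist`, subtract `freq(b_m)`
#' from `n'` and remove `b_m`. If B is exhausted first the accumulated
#' distance is rescaled by `freq(a) / n_B`. B's frequency pool is a working
#' copy: calls do not interact.
#'
#' @param a_features numeric length-19 feature row.
#' @param a_freq its frequency.
#' @param B a `pair_descriptor`.
#' @param w19 expanded 19-weight vector.
#' @return non-negative real.
#' @export
frequency_matched_distance <- function(a_features, a_freq, B, w19) {
  if (!nrow(B$features)) stop("empty descriptor B", call. = FALSE)
  dists <- .row_distances(a_features, B$features, w19)
  ord <- order(dists)             # stable: ties keep canonical row order
  d <- 0
  nprime <- a_freq
  for (m in ord) {
    fb <- B$freq[m]
    if (nprime <= fb) {
      d <- d + nprime * dists[m]
      return(d)
    }
    d <- d + fb * dists[m]
    nprime <- nprime - fb
  }
  # B exhausted before a's frequency: ratio correction
  d * a_freq / sum(B$freq)
}

#' Directed distance from descriptor A to descriptor B
#'
#' Root mean square of the frequency-matched row distances of all grouped
#' rows of A, normalized by A's total ordered-pair count:
#' `sqrt(sum_i f(a_i, B)^2 / n_A)`.
#'
#' @param A,B `pair_descriptor` objects (nonempty).
#' @param w19 expanded 19-weight vector.
#' @return non-negative real.
#' @export
directed_distance <- function(A, B, w19) {
  if (!nrow(A$features) || !nrow(B$features))
    stop("directed distance undefined for empty descriptors", call. = FALSE)
  f <- vapply(seq_len(nrow(A$features)), function(i)
    frequency_matched_distance(A$features[i, ], A$freq[i], B, w19),
    numeric(1))
  sqrt(sum(f^2) / A$n_pairs)
}

#' Symmetric pseudo-distance between two molecules
#'
#' Combines the two directed distances as `sqrt(dAB^2 + dBA^2)` (the printed
#' formula); `rms = TRUE` uses the root-mean-square variant
#' `sqrt((dAB^2 + dBA^2) / 2)` instead.
#'
#' @param A,B `pair_descriptor` objects.
#' @param w 11-weight vector (defaults to [default_weights()]).
#' @param rms logical; divide the sum of squares by 2 before the root.
#' @return non-negative real; zero when `A` and `B` have identical rows.
#' @export
pseudo_distance <- function(A, B, w = default_weights(), rms = FALSE) {
  w19 <- expand_weights(w)
  dab <- directed_distance(A, B, w19)
  dba <- directed_distance(B, A, w19)
  out <- sqrt(dab^2 + dba^2)
  if (rms) out <- out / sqrt(2)
  out
}

#' Pairwise pseudo-distance matrix
#'
#' Computes the upper triangle and mirrors it; the diagonal is exactly zero.
#'
#' @param descriptors list of `pair_descriptor` objects with unique ids.
#' @param w 11-weight vector.
#' @param rms see [pseudo_distance()].
#' @return symmetric numeric matrix with molecule ids as dimnames.
#' @export
pairwise_matrix <- function(descriptors, w = default_weights(), rms = FALSE) {
  n <- length(descriptors)
  if (n < 2) stop("need at least 2 descriptors", call. = FALSE)
  ids <- vapply(descriptors, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate molecule ids", call. = FALSE)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  w19 <- expand_weights(w)
  dir_cache <- function(A, B) directed_distance(A, B, w19)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dab <- dir_cache(descriptors[[i]], descriptors[[j]])
    dba <- dir_cache(descriptors[[j]], descriptors[[i]])
    v <- sqrt(dab^2 + dba^2)
    if (rms) v <- v / sqrt(2)
    D[i, j] <- D[j, i] <- v
  }
  D
}

#' Write / read a distance matrix as TSV with id header row and column
#' @param D symmetric matrix with dimnames.
#' @param path file path.
#' @export
write_distance_matrix <- function(D, path) {
  utils::write.table(cbind(id = rownames(D), as.data.frame(D)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- tab[[1]]
  D <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(D) <- list(ids, ids)
  D
}

#' Write / read an 11-weight vector as JSON
#' @param w 11-weight vector; `path` file path.
#' @param path file path.
#' @export
write_weights <- function(w, path) {
  jsonlite::write_json(as.list(weight_vector(w)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  weight_vector(unlist(jsonlite::read_json(path)))
}
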