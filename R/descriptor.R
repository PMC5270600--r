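# Atom-pair property descriptor.
#
# A molecule is described as a list of grouped atom-pair feature sets: every
# ordered pair (i, j) of heavy atoms, i != j, contributes one 19-feature row
# (8 atom-type features for each atom, 2 relationship features, 1 cis/trans
# flag); identical rows are merged and their count kept as a frequency
# column, which is never itself a feature.

#' Names of the 19 feature columns of an atom-pair row
#' @export
pair_feature_names <- function() {
  atom <- c("period", "family", "single_bonds", "double_bonds", "triple_bonds",
            "aromatic_bonds", "ring_atom", "pka")
  c(paste0(atom, "_i"), paste0(atom, "_j"), "ring_pair", "path_bonds",
    "cis_trans")
}

#' Atom-type features for one atom
#'
#' The 8 per-atom features: periodic period, main-group family, counts of
#' single/double/triple/aromatic bonds to heavy neighbours, a ring-membership
#' flag, and the shifted pKa (pKa - 7, 0 when absent).
#'
#' @param graph a `mol_graph` (with pKa already attached via [set_pka()] if
#'   desired).
#' @param atom 1-based atom index.
#' @return named numeric vector of length 8.
#' @export
atom_type_features <- function(graph, atom) {
  stopifnot(atom >= 1, atom <= n_atoms(graph))
  b <- graph$bonds
  inc <- b$order[b$i == atom | b$j == atom]
  c(period = graph$atoms$period[atom],
    family = graph$atoms$family[atom],
    single_bonds = sum(inc == "single"),
    double_bonds = sum(inc == "double"),
    triple_bonds = sum(inc == "triple"),
    aromatic_bonds = sum(inc == "aromatic"),
    ring_atom = graph$ring_atom[atom],
    pka = graph$pka_shifted[atom])
}

#' Cis/trans isomerism feature for an atom pair
#'
#' Evaluated on the shortest path between the pair. The configuration is
#' only defined when the path has at least 3 bonds, its first three bonds are
#' single, double, single and none of the first four path atoms is aromatic.
#' The geometry of the first and fourth path atoms relative to the line
#' through the double bond (2D cross-product sign) then gives -1 for cis and
#' 1 for trans; anything else (including degenerate, near-collinear
#' placements) is 0.
#'
#' @param graph a `mol_graph`.
#' @param path atom-index sequence as returned by [shortest_path()].
#' @return -1, 0 or 1.
#' @export
isomerism_feature <- function(graph, path) {
  if (length(path) < 4) return(0)
  a4 <- path[1:4]
  if (any(graph$aromatic_atom[a4])) return(0)
  orders <- c(.bond_order_between(graph, a4[1], a4[2]),
              .bond_order_between(graph, a4[2], a4[3]),
              .bond_order_between(graph, a4[3], a4[4]))
  if (!identical(orders, c("single", "double", "single"))) return(0)
  if (is.null(graph$coords))
    stop("2D coordinates required for cis/trans perception; generate a ",
         "layout first", call. = FALSE)
  p <- graph$coords
  v <- p[a4[3], ] - p[a4[2], ]
  cross <- function(r) (r[1] - p[a4[2], 1]) * v[2] - (r[2] - p[a4[2], 2]) * v[1]
  s1 <- cross(p[a4[1], ]); s4 <- cross(p[a4[4], ])
  if (abs(s1) < 1e-6 || abs(s4) < 1e-6) return(0)
  if (s1 * s4 > 0) -1 else 1
}

#' Build the grouped atom-pair descriptor of a molecule
#'
#' Enumerates all ordered heavy-atom pairs (n * (n - 1) of them), computes
#' the 19 features per pair, merges identical rows summing their
#' frequencies, and sorts rows lexicographically over the feature tuple so
#' serialized descriptors are bit-stable. The pKa feature is carried at 0.01
#' resolution so grouping keys equal feature values exactly.
#'
#' @param graph a connected `mol_graph`.
#' @return object of class `pair_descriptor`: list with `id`, `features`
#'   (rows x 19 numeric matrix), `freq` (integer vector) and `n_pairs`
#'   (total ordered pairs).
#' @examples
#' d <- build_descriptor(parse_smiles("c1ccncc1", "pyridine"))
#' sum(d$freq)   # 30 ordered pairs
#' @export
build_descriptor <- function(graph) {
  n <- n_atoms(graph)
  if (!is_connected_graph(graph))
    stop("descriptor undefined for disconnected molecules", call. = FALSE)
  if (n < 2) {
    return(structure(list(id = graph$id,
                          features = matrix(numeric(), 0, 19,
                                            dimnames = list(NULL, pair_feature_names())),
                          freq = integer(), n_pairs = 0L),
                     class = "pair_descriptor"))
  }
  atom_feats <- t(vapply(seq_len(n), function(a) atom_type_features(graph, a),
                         numeric(8)))
  atom_feats[, "pka"] <- round(atom_feats[, "pka"], 2)
  rf <- ring_flags(graph)
  rows <- matrix(0, n * (n - 1L), 19)
  colnames(rows) <- pair_feature_names()
  r <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    path <- shortest_path(graph, i, j)
    r <- r + 1L
    rows[r, ] <- c(atom_feats[i, ], atom_feats[j, ],
                   rf$pair(i, j), length(path) - 1L,
                   isomerism_feature(graph, path))
  }
  key <- apply(rows, 1, paste, collapse = "\r")
  grp <- match(key, unique(key))
  freq <- as.integer(tabulate(grp))
  feats <- rows[!duplicated(grp), , drop = FALSE]
  ord <- do.call(order, as.data.frame(feats))
  structure(list(id = graph$id, features = feats[ord, , drop = FALSE],
                 freq = freq[ord], n_pairs = n * (n - 1L)),
            class = "pair_descriptor")
}

#' @export
print.pair_descriptor <- function(x, ...) {
  cat(sprintf("<pair_descriptor %s: %d grouped rows, %d atom pairs>\n",
              x$id, nrow(x$features), x$n_pairs))
  invisible(x)
}

#' Write descriptors to a TSV file
#'
#' One `#mol <id> <n_pairs>` header line per molecule, followed by its rows:
#' 19 feature columns plus the frequency as column 20.
#'
#' @param descriptors list of `pair_descriptor` objects.
#' @param path output file.
#' @export
write_descriptors <- function(descriptors, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (d in descriptors) {
    writeLines(sprintf("#mol %s %d", d$id, d$n_pairs), con)
    if (nrow(d$features)) {
      m <- cbind(d$features, d$freq)
      utils::write.table(format(m, trim = TRUE, scientific = FALSE), con,
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
  }
  invisible(path)
}

#' Read descriptors from a TSV file written by [write_descriptors()]
#' @param path input file.
#' @return list of `pair_descriptor` objects.
#' @export
read_descriptors <- function(path) {
  lines <- readLines(path, warn = FALSE)
  heads <- grep("^#mol ", lines)
  if (!length(heads)) stop("no descriptor records in ", path, call. = FALSE)
  bounds <- c(heads, length(lines) + 1L)
  out <- vector("list", length(heads))
  for (k in seq_along(heads)) {
    hd <- strsplit(lines[heads[k]], " ")[[1]]
    body <- lines[seq(heads[k] + 1L, bounds[k + 1L] - 1L, length.out =
                        max(0L, bounds[k + 1L] - heads[k] - 1L))]
    body <- body[nzchar(body)]
    if (length(body)) {
      m <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
      feats <- m[, 1:19, drop = FALSE]
      colnames(feats) <- pair_feature_names()
      freq <- as.integer(m[, 20])
    } else {
      feats <- matrix(numeric(), 0, 19,
                      dimnames = list(NULL, pair_feature_names()))
      freq <- integer()
    }
    out[[k]] <- structure(list(id = hd[2], features = feats, freq = freq,
                               n_pairs = as.integer(hd[3])),
                          class = "pair_descriptor")
  }
  out
}
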