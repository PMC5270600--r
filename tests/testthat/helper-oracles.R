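# Independent oracles and fixture builders used across the suite.

# Brute-force simple-cycle enumeration on a small graph. Returns the list of
# vertex sets of all simple cycles (length >= 3). Only for graphs <= ~12
# atoms.
enumerate_cycles <- function(n, bonds) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$i[k]]] <- c(adj[[bonds$i[k]]], bonds$j[k])
    adj[[bonds$j[k]]] <- c(adj[[bonds$j[k]]], bonds$i[k])
  }
  cycles <- list()
  path <- integer()
  dfs <- function(v, start) {
    path[[length(path) + 1L]] <<- v
    for (u in adj[[v]]) {
      if (u == start && length(path) >= 3) {
        key <- paste(sort(path), collapse = ",")
        if (!key %in% names(cycles)) cycles[[key]] <<- sort(path)
      } else if (u > start && !(u %in% path)) {
        dfs(u, start)
      }
    }
    path <<- path[-length(path)]
  }
  for (s in seq_len(n)) dfs(s, s)
  unname(cycles)
}

# Oracle for ring flags: atom on any cycle / pair on a common cycle.
ring_oracle <- function(graph) {
  cyc <- enumerate_cycles(nrow(graph$atoms), graph$bonds)
  n <- nrow(graph$atoms)
  atom <- rep(0L, n)
  pair <- matrix(0L, n, n)
  for (cs in cyc) {
    atom[cs] <- 1L
    pair[cs, cs] <- 1L
  }
  diag(pair) <- 0L
  list(atom = atom, pair = pair)
}

# Literal step-through of the frequency-consuming matching: working copy of
# B's rows as a list, explicit nearest-row scan, ratio correction at
# exhaustion. Deliberately scalar and list-based, unlike the package path.
freq_match_oracle <- function(a_row, a_freq, B_rows, B_freqs, w19) {
  pool <- lapply(seq_along(B_freqs),
                 function(k) list(row = B_rows[k, ], freq = B_freqs[k]))
  d <- 0
  nprime <- a_freq
  n_B <- sum(B_freqs)
  while (length(pool) > 0) {
    dists <- vapply(pool, function(p)
      sqrt(sum((w19 * (a_row - p$row))^2)), numeric(1))
    m <- which.min(dists)                       # first minimum = canonical tie-break
    if (nprime <= pool[[m]]$freq)
      return(d + nprime * dists[m])
    d <- d + pool[[m]]$freq * dists[m]
    nprime <- nprime - pool[[m]]$freq
    pool[[m]] <- NULL
  }
  d * a_freq / n_B
}

# Build a pair_descriptor by hand from a feature matrix + frequencies.
make_descriptor <- function(id, features, freq,
                            n_pairs = sum(freq)) {
  colnames(features) <- pair_feature_names()
  structure(list(id = id, features = features, freq = as.integer(freq),
                 n_pairs = as.integer(n_pairs)),
            class = "pair_descriptor")
}

# A 19-feature row that is zero except at named columns.
feat_row <- function(...) {
  v <- stats::setNames(rep(0, 19), pair_feature_names())
  set <- list(...)
  for (nm in names(set)) v[nm] <- set[[nm]]
  matrix(v, 1, 19, dimnames = list(NULL, pair_feature_names()))
}

# Expand a grouped descriptor to frequency-1 rows.
expand_descriptor <- function(d) {
  idx <- rep(seq_along(d$freq), d$freq)
  make_descriptor(paste0(d$id, "_expanded"),
                  d$features[idx, , drop = FALSE],
                  rep(1L, length(idx)), n_pairs = d$n_pairs)
}

# Rebuild a mol_graph with atoms renumbered by a permutation (perm[k] is the
# new index of old atom k).
permute_graph <- function(graph, perm) {
  inv <- order(perm)
  bonds <- graph$bonds
  bonds$i <- perm[bonds$i]
  bonds$j <- perm[bonds$j]
  g <- pairprop:::mol_graph(paste0(graph$id, "_perm"),
                            graph$atoms$symbol[inv], bonds,
                            coords = graph$coords[inv, , drop = FALSE])
  g$pka_shifted <- graph$pka_shifted[inv]
  g
}

# Toy descriptors, computed once per test run.
toy_descriptors <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- lapply(toy_molecules(), build_descriptor)
    cache
  }
})
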