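# Molecular graph parsing and queries.
#
# Molecules are held as hydrogen-suppressed graphs: a data.frame of heavy
# atoms (element, periodic period, main-group family, 2D coordinates) plus a
# bond table with orders in {single, double, triple, aromatic}. Only
# main-group elements are supported; molecules containing transition elements
# are skipped with a warning.

# Main-group element table: period and family (group 1-8, noble gases = 8).
.periodic_table <- local({
  tab <- rbind(
    c("H", 1, 1), c("He", 1, 8),
    c("Li", 2, 1), c("Be", 2, 2), c("B", 2, 3), c("C", 2, 4), c("N", 2, 5),
    c("O", 2, 6), c("F", 2, 7), c("Ne", 2, 8),
    c("Na", 3, 1), c("Mg", 3, 2), c("Al", 3, 3), c("Si", 3, 4), c("P", 3, 5),
    c("S", 3, 6), c("Cl", 3, 7), c("Ar", 3, 8),
    c("K", 4, 1), c("Ca", 4, 2), c("Ga", 4, 3), c("Ge", 4, 4), c("As", 4, 5),
    c("Se", 4, 6), c("Br", 4, 7), c("Kr", 4, 8),
    c("Rb", 5, 1), c("Sr", 5, 2), c("In", 5, 3), c("Sn", 5, 4), c("Sb", 5, 5),
    c("Te", 5, 6), c("I", 5, 7), c("Xe", 5, 8),
    c("Cs", 6, 1), c("Ba", 6, 2), c("Tl", 6, 3), c("Pb", 6, 4), c("Bi", 6, 5),
    c("Po", 6, 6), c("At", 6, 7), c("Rn", 6, 8))
  data.frame(symbol = tab[, 1], period = as.integer(tab[, 2]),
             family = as.integer(tab[, 3]), stringsAsFactors = FALSE)
})

.bond_orders <- c("single", "double", "triple", "aromatic")

.lookup_element <- function(symbols) {
  idx <- match(symbols, .periodic_table$symbol)
  list(period = .periodic_table$period[idx], family = .periodic_table$family[idx])
}

#' Construct a molecular graph object
#'
#' Assembles the hydrogen-suppressed molecular graph used throughout the
#' package. Ring membership (per atom and per biconnected component) and
#' aromatic-atom flags are computed here once.
#'
#' @param id molecule identifier (character scalar).
#' @param symbols character vector of heavy-atom element symbols.
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (one of `"single"`, `"double"`, `"triple"`, `"aromatic"`).
#' @param coords numeric matrix (n x 2) of 2D coordinates, or `NULL`.
#' @param stereo optional data.frame of double-bond configurations with
#'   columns `a`, `b` (double-bond atoms), `x`, `y` (reference substituents)
#'   and `config` (`"cis"` or `"trans"`); used by the SMILES layout.
#' @return an object of class `mol_graph`.
#' @keywords internal
mol_graph <- function(id, symbols, bonds, coords = NULL, stereo = NULL) {
  n <- length(symbols)
  el <- .lookup_element(symbols)
  if (anyNA(el$period)) {
    bad <- unique(symbols[is.na(el$period)])
    stop("unsupported (transition or unknown) element(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bonds <- as.data.frame(bonds)
  if (nrow(bonds)) {
    stopifnot(all(bonds$i >= 1), all(bonds$j <= n), all(bonds$i != bonds$j),
              all(bonds$order %in% .bond_orders))
    # canonical bond orientation i < j, no duplicates
    swap <- bonds$i > bonds$j
    tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
    if (anyDuplicated(bonds[, c("i", "j")]))
      stop("duplicate bonds in input", call. = FALSE)
  }
  g <- list(id = id,
            atoms = data.frame(symbol = symbols, period = el$period,
                               family = el$family, stringsAsFactors = FALSE),
            bonds = bonds[, c("i", "j", "order")],
            coords = coords,
            stereo = stereo,
            pka_shifted = rep(0, n))
  g$aromatic_atom <- rep(FALSE, n)
  if (nrow(bonds)) {
    ar <- bonds[bonds$order == "aromatic", , drop = FALSE]
    g$aromatic_atom[unique(c(ar$i, ar$j))] <- TRUE
  }
  rf <- .ring_membership(n, bonds)
  g$ring_atom <- rf$atom
  g$ring_blocks <- rf$blocks
  class(g) <- "mol_graph"
  g
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph %s: %d heavy atoms, %d bonds>\n",
              x$id, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

n_atoms <- function(graph) nrow(graph$atoms)

.as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    d = if (nrow(graph$bonds)) graph$bonds[, c("i", "j")] else
      data.frame(i = integer(), j = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(graph))))
}

# Ring membership from biconnected components: an edge is in a ring iff its
# biconnected component has >= 2 edges (i.e. it is not a bridge); an atom is
# in a ring iff incident to such an edge; two atoms lie on a common cycle iff
# they share a non-bridge biconnected component.
.ring_membership <- function(n, bonds) {
  atom <- rep(0L, n)
  blocks <- list()
  if (nrow(bonds) == 0)
    return(list(atom = atom, blocks = blocks))
  ig <- igraph::graph_from_data_frame(bonds[, c("i", "j")], directed = FALSE,
                                      vertices = data.frame(name = seq_len(n)))
  bc <- igraph::biconnected_components(ig)
  for (k in seq_along(bc$component_edges)) {
    if (length(bc$component_edges[[k]]) >= 2) {
      verts <- as.integer(names(bc$components[[k]]))
      atom[verts] <- 1L
      blocks[[length(blocks) + 1L]] <- sort(verts)
    }
  }
  list(atom = atom, blocks = blocks)
}

#' Ring flags for atoms and atom pairs
#'
#' @param graph a `mol_graph`.
#' @return a list with `atom`, an integer 0/1 vector flagging atoms that lie
#'   on any cycle, and `pair`, a function `(i, j)` returning 1 iff atoms `i`
#'   and `j` lie on a common cycle (share a cyclic biconnected block).
#' @examples
#' g <- parse_smiles("c1ccncc1", "pyridine")
#' ring_flags(g)$atom              # all 1
#' ring_flags(g)$pair(1, 4)        # 1
#' @export
ring_flags <- function(graph) {
  blocks <- graph$ring_blocks
  pair <- function(i, j) {
    for (b in blocks) if (i %in% b && j %in% b) return(1L)
    0L
  }
  list(atom = graph$ring_atom, pair = pair)
}

#' Shortest bond path between two atoms
#'
#' Breadth-first shortest path in bond count. Among equally short paths the
#' lexicographically smallest atom-index sequence is returned, so results are
#' deterministic and independent of input bond order.
#'
#' @param graph a `mol_graph`.
#' @param i,j distinct 1-based atom indices.
#' @return integer vector of atom indices from `i` to `j` inclusive.
#' @export
shortest_path <- function(graph, i, j) {
  n <- n_atoms(graph)
  stopifnot(i >= 1, j >= 1, i <= n, j <= n)
  if (i == j) stop("i and j must differ", call. = FALSE)
  adj <- .adjacency_list(graph)
  # BFS distances from j, then greedy descent from i picking the smallest
  # admissible neighbour: yields the lexicographically smallest shortest path.
  dist <- rep(NA_integer_, n)
  dist[j] <- 0L
  queue <- j
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (u in adj[[v]]) if (is.na(dist[u])) {
      dist[u] <- dist[v] + 1L
      queue <- c(queue, u)
    }
  }
  if (is.na(dist[i]))
    stop("atoms ", i, " and ", j, " are disconnected (multi-fragment input?)",
         call. = FALSE)
  path <- i
  v <- i
  while (v != j) {
    cand <- adj[[v]][!is.na(dist[adj[[v]]]) & dist[adj[[v]]] == dist[v] - 1L]
    v <- min(cand)
    path <- c(path, v)
  }
  path
}

.adjacency_list <- function(graph) {
  n <- n_atoms(graph)
  adj <- vector("list", n)
  for (k in seq_len(n)) adj[[k]] <- integer()
  b <- graph$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$i[k]]] <- c(adj[[b$i[k]]], b$j[k])
    adj[[b$j[k]]] <- c(adj[[b$j[k]]], b$i[k])
  }
  lapply(adj, sort)
}

.bond_order_between <- function(graph, i, j) {
  b <- graph$bonds
  hit <- (b$i == min(i, j)) & (b$j == max(i, j))
  if (!any(hit)) return(NA_character_)
  b$order[which(hit)[1]]
}

is_connected_graph <- function(graph) {
  if (n_atoms(graph) <= 1) return(TRUE)
  igraph::is_connected(.as_igraph(graph))
}

#' Shifted pKa feature values
#'
#' Applies the pKa atom feature convention: atoms with a provided value get
#' `pka - 7.0`; atoms without one get 0. The provider is pluggable because
#' pKa engines are external; the built-in provider is a per-molecule lookup
#' table (see [read_pka_table()]).
#'
#' @param graph a `mol_graph`.
#' @param provider named numeric vector mapping 0-based atom indices (as
#'   names) to pKa values, or `NULL` for the all-absent fallback.
#' @return numeric vector of shifted pKa values, one per atom.
#' @export
shifted_pka <- function(graph, provider = NULL) {
  out <- rep(0, n_atoms(graph))
  if (is.null(provider) || !length(provider)) return(out)
  idx <- as.integer(names(provider)) + 1L
  ok <- !is.na(idx) & idx >= 1 & idx <= n_atoms(graph) & !is.na(provider)
  out[idx[ok]] <- provider[ok] - 7.0
  out
}

#' Attach pKa values to a molecular graph
#'
#' @param graph a `mol_graph`.
#' @param provider see [shifted_pka()].
#' @return the graph with its `pka_shifted` field populated.
#' @export
set_pka <- function(graph, provider = NULL) {
  graph$pka_shifted <- shifted_pka(graph, provider)
  graph
}

#' Read a pKa lookup table
#'
#' Reads a CSV `mol_id,atom_index,pka` (0-based atom indices in input atom
#' order) into a per-molecule provider list usable with [set_pka()].
#'
#' @param path CSV file path.
#' @return named list: one named numeric vector per molecule id.
#' @export
read_pka_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("mol_id", "atom_index", "pka") %in% names(tab)))
  split_tab <- split(tab, tab$mol_id)
  lapply(split_tab, function(d) stats::setNames(d$pka, d$atom_index))
}

## ---------------------------------------------------------------- SMILES --

.ORGANIC_TWO <- c("Cl", "Br")
.ORGANIC_ONE <- c("B", "C", "N", "O", "P", "S", "F", "I")
.AROMATIC_ONE <- c("b", "c", "n", "o", "p", "s")

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset (B, C, N, O, P, S, F, Cl, Br, I), aromatic
#' lowercase atoms, bracket atoms (isotope, charge, explicit H and chirality
#' marks are parsed and discarded), branches, ring-bond closures (including
#' `%nn`), bond symbols `- = # :` and directional bonds `/ \\` for double-bond
#' configuration. Explicit hydrogens are suppressed. Dot-separated
#' (multi-fragment) inputs are rejected. A deterministic 2D layout honouring
#' directional bonds is generated so cis/trans perception is reproducible.
#'
#' @param smiles SMILES string.
#' @param id molecule id (defaults to the SMILES itself).
#' @return a `mol_graph` with 2D coordinates.
#' @examples
#' parse_smiles("c1ccncc1", "pyridine")
#' @export
parse_smiles <- function(smiles, id = smiles) {
  chars <- strsplit(smiles, "")[[1]]
  np <- 0L
  symbols <- character(); aromatic_in <- logical(); is_h <- logical()
  bonds <- data.frame(i = integer(), j = integer(), order = character(),
                      sdir = integer(), worder = integer(),
                      stringsAsFactors = FALSE)
  ring_open <- list()   # closure digit -> list(atom, sym, sdir)
  stack <- integer()
  prev <- 0L
  pending_sym <- NA_character_   # explicit bond symbol
  pending_sdir <- 0L             # +1 for '/', -1 for '\'

  add_atom <- function(sym, arom) {
    np <<- np + 1L
    symbols[np] <<- sym
    aromatic_in[np] <<- arom
    is_h[np] <<- identical(sym, "H")
    np
  }
  add_bond <- function(a, b, sym, sdir, wfirst) {
    order <- if (!is.na(sym)) sym
      else if (aromatic_in[a] && aromatic_in[b]) "aromatic" else "single"
    bonds[nrow(bonds) + 1L, ] <<- list(a, b, order, sdir, wfirst)
  }
  close_or_open_ring <- function(key, atom) {
    if (!is.null(ring_open[[key]])) {
      op <- ring_open[[key]]
      sym <- if (!is.na(pending_sym)) pending_sym else op$sym
      sdir <- if (pending_sdir != 0L) -pending_sdir else op$sdir
      add_bond(op$atom, atom, sym, sdir, op$atom)
      ring_open[[key]] <<- NULL
    } else {
      ring_open[[key]] <<- list(atom = atom, sym = pending_sym,
                                sdir = pending_sdir)
    }
    pending_sym <<- NA_character_; pending_sdir <<- 0L
  }

  k <- 1L
  nc <- length(chars)
  while (k <= nc) {
    ch <- chars[k]
    if (ch == ".") stop("multi-fragment SMILES rejected: ", smiles, call. = FALSE)
    if (ch == "(") { stack <- c(stack, prev); k <- k + 1L; next }
    if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMILES: ", smiles, call. = FALSE)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      k <- k + 1L; next
    }
    if (ch %in% c("-", "=", "#", ":")) {
      pending_sym <- switch(ch, "-" = "single", "=" = "double",
                            "#" = "triple", ":" = "aromatic")
      k <- k + 1L; next
    }
    if (ch == "/") { pending_sdir <- 1L; pending_sym <- "single"; k <- k + 1L; next }
    if (ch == "\\") { pending_sdir <- -1L; pending_sym <- "single"; k <- k + 1L; next }
    if (grepl("[0-9]", ch)) {
      close_or_open_ring(ch, prev); k <- k + 1L; next
    }
    if (ch == "%") {
      key <- paste0(chars[k + 1L], chars[k + 2L])
      close_or_open_ring(key, prev); k <- k + 3L; next
    }
    atom <- NA_integer_
    if (ch == "[") {
      close_k <- k
      while (close_k <= nc && chars[close_k] != "]") close_k <- close_k + 1L
      if (close_k > nc) stop("unterminated bracket atom in SMILES: ", smiles,
                             call. = FALSE)
      body <- paste(chars[(k + 1L):(close_k - 1L)], collapse = "")
      body <- sub("^[0-9]*", "", body)                 # isotope
      m <- regmatches(body, regexpr("^([A-Z][a-z]?|[a-z])", body))[1]
      if (is.na(m) || !nzchar(m))
        stop("cannot read bracket atom in SMILES: ", smiles, call. = FALSE)
      arom <- m %in% .AROMATIC_ONE
      sym <- if (arom) toupper(m) else m
      atom <- add_atom(sym, arom)
      k <- close_k + 1L
    } else {
      two <- if (k < nc) paste0(ch, chars[k + 1L]) else ""
      if (two %in% .ORGANIC_TWO) {
        atom <- add_atom(two, FALSE); k <- k + 2L
      } else if (ch %in% .ORGANIC_ONE) {
        atom <- add_atom(ch, FALSE); k <- k + 1L
      } else if (ch %in% .AROMATIC_ONE) {
        atom <- add_atom(toupper(ch), TRUE); k <- k + 1L
      } else {
        stop("unexpected character '", ch, "' in SMILES: ", smiles, call. = FALSE)
      }
    }
    if (prev > 0L) add_bond(prev, atom, pending_sym, pending_sdir, prev)
    pending_sym <- NA_character_; pending_sdir <- 0L
    prev <- atom
  }
  if (length(ring_open) && any(!vapply(ring_open, is.null, logical(1))))
    stop("unclosed ring bond in SMILES: ", smiles, call. = FALSE)
  if (length(stack))
    stop("unbalanced '(' in SMILES: ", smiles, call. = FALSE)

  # suppress explicit hydrogens
  keep <- !is_h
  remap <- cumsum(keep)
  bonds <- bonds[keep[bonds$i] & keep[bonds$j], , drop = FALSE]
  bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
  bonds$worder <- remap[bonds$worder]
  symbols <- symbols[keep]; aromatic_in <- aromatic_in[keep]
  if (!length(symbols)) stop("SMILES contains no heavy atoms: ", smiles,
                             call. = FALSE)

  stereo <- .smiles_stereo(bonds, aromatic_in)
  coords <- .layout_2d(length(symbols), bonds, stereo)
  mol_graph(id, symbols, bonds[, c("i", "j", "order")], coords = coords,
            stereo = stereo)
}

# Decode directional-bond (/ \) annotations into per-double-bond cis/trans
# configurations between one marked substituent on each side.
.smiles_stereo <- function(bonds, aromatic_in) {
  out <- data.frame(a = integer(), b = integer(), x = integer(),
                    y = integer(), config = character(),
                    stringsAsFactors = FALSE)
  if (!nrow(bonds)) return(out)
  dbl <- which(bonds$order == "double" &
                 !aromatic_in[bonds$i] & !aromatic_in[bonds$j])
  # e: slash sign normalized to "written arriving at the anchor atom"
  anchored <- function(anchor) {
    hits <- which(bonds$sdir != 0L & (bonds$i == anchor | bonds$j == anchor))
    if (!length(hits)) return(NULL)
    k <- hits[1]
    other <- if (bonds$i[k] == anchor) bonds$j[k] else bonds$i[k]
    written_second <- !(bonds$worder[k] == anchor)
    e <- if (written_second) bonds$sdir[k] else -bonds$sdir[k]
    list(x = other, e = e)
  }
  for (k in dbl) {
    a <- bonds$i[k]; b <- bonds$j[k]
    sa <- anchored(a); sb <- anchored(b)
    if (is.null(sa) || is.null(sb)) next
    if (sa$x == b || sb$x == a) next
    cfg <- if (sa$e == sb$e) "cis" else "trans"
    out[nrow(out) + 1L, ] <- list(a, b, sa$x, sb$x, cfg)
  }
  out
}

# Deterministic 2D layout: 120-degree zigzag over a DFS spanning tree, then
# subtree reflection wherever an encoded double-bond configuration disagrees
# with the drawn geometry. Distorted rings are acceptable: only local
# geometry at acyclic stereo double bonds is consumed downstream.
.layout_2d <- function(n, bonds, stereo = NULL) {
  coords <- matrix(0, n, 2)
  if (n == 1L || !nrow(bonds)) return(coords)
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$i[k]]] <- c(adj[[bonds$i[k]]], bonds$j[k])
    adj[[bonds$j[k]]] <- c(adj[[bonds$j[k]]], bonds$i[k])
  }
  adj <- lapply(adj, sort)
  placed <- rep(FALSE, n)
  place <- function(v, parent, angle_in, turn) {
    kids <- adj[[v]][!placed[adj[[v]]]]
    offsets <- c(turn * pi / 3, -turn * pi / 3, 0, turn * 2 * pi / 3,
                 -turn * 2 * pi / 3)
    ki <- 0L
    for (u in kids) {
      if (placed[u]) next      # may have been placed via another branch
      ki <- ki + 1L
      ang <- angle_in + offsets[min(ki, length(offsets))]
      coords[u, ] <<- coords[v, ] + c(cos(ang), sin(ang))
      placed[u] <<- TRUE
      place(u, v, ang, -turn)
    }
  }
  for (root in seq_len(n)) {
    if (placed[root]) next
    placed[root] <- TRUE
    place(root, 0L, 0, 1)
  }
  if (!is.null(stereo) && nrow(stereo))
    coords <- .apply_stereo(coords, n, bonds, stereo)
  coords
}

.apply_stereo <- function(coords, n, bonds, stereo) {
  side <- function(p, q, r) {
    v <- q - p
    (r[1] - p[1]) * v[2] - (r[2] - p[2]) * v[1]
  }
  for (k in seq_len(nrow(stereo))) {
    a <- stereo$a[k]; b <- stereo$b[k]
    x <- stereo$x[k]; y <- stereo$y[k]
    sx <- side(coords[a, ], coords[b, ], coords[x, ])
    sy <- side(coords[a, ], coords[b, ], coords[y, ])
    drawn <- if (sx * sy > 0) "cis" else "trans"
    if (drawn == stereo$config[k]) next
    # collect b's side with the a=b edge removed; skip if the bond is cyclic
    reach <- rep(FALSE, n); reach[b] <- TRUE
    queue <- b
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- c(bonds$j[bonds$i == v], bonds$i[bonds$j == v])
      for (u in nb) {
        if (v == b && u == a) next   # do not cross the stereo bond itself
        if (!reach[u]) { reach[u] <- TRUE; queue <- c(queue, u) }
      }
    }
    if (reach[a]) {
      warning("stereo marker on ring double bond ignored")
      next
    }
    p <- coords[a, ]; d <- coords[b, ] - p
    len2 <- sum(d^2)
    for (v in which(reach)) {
      if (v == b) next
      r <- coords[v, ] - p
      proj <- sum(r * d) / len2
      coords[v, ] <- p + 2 * proj * d - r
    }
  }
  coords
}

## ------------------------------------------------------------------- SDF --

.parse_sdf_record <- function(lines, id) {
  if (length(lines) < 4) stop("truncated SDF record")
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || na < 1) stop("bad counts line in SDF record")
  atom_lines <- lines[5:(4 + na)]
  symbols <- character(na); xs <- numeric(na); ys <- numeric(na)
  for (k in seq_len(na)) {
    f <- strsplit(trimws(atom_lines[k]), "\\s+")[[1]]
    xs[k] <- as.numeric(f[1]); ys[k] <- as.numeric(f[2])
    symbols[k] <- f[4]
  }
  bonds <- data.frame(i = integer(), j = integer(), order = character(),
                      stringsAsFactors = FALSE)
  if (nb > 0) {
    bond_lines <- lines[(5 + na):(4 + na + nb)]
    for (k in seq_len(nb)) {
      ln <- bond_lines[k]
      bi <- as.integer(substr(ln, 1, 3))
      bj <- as.integer(substr(ln, 4, 6))
      bo <- as.integer(substr(ln, 7, 9))
      order <- c("single", "double", "triple", "aromatic")[bo]
      if (is.na(order)) stop("unsupported bond order ", bo, " in SDF record")
      bonds[nrow(bonds) + 1L, ] <- list(bi, bj, order)
    }
  }
  # suppress hydrogens, keep SDF coordinates verbatim for the rest
  keep <- symbols != "H"
  remap <- cumsum(keep)
  bonds <- bonds[keep[bonds$i] & keep[bonds$j], , drop = FALSE]
  bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
  mol_graph(id, symbols[keep], bonds,
            coords = cbind(xs[keep], ys[keep]))
}

#' Write molecular graphs to an SDF (V2000) file
#'
#' Heavy atoms only, with the stored 2D coordinates; aromatic bonds use
#' order code 4. Round-tripping through [read_molecules()] preserves the
#' heavy-atom count and bond multiset.
#'
#' @param mols list of `mol_graph` objects.
#' @param path output file.
#' @export
write_sdf <- function(mols, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in mols) {
    n <- n_atoms(m); nb <- nrow(m$bonds)
    co <- if (is.null(m$coords)) matrix(0, n, 2) else m$coords
    writeLines(c(m$id, "  pairprop", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb), con)
    for (a in seq_len(n))
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         co[a, 1], co[a, 2], 0, m$atoms$symbol[a]), con)
    if (nb) {
      code <- match(m$bonds$order, .bond_orders)
      for (k in seq_len(nb))
        writeLines(sprintf("%3d%3d%3d  0", m$bonds$i[k], m$bonds$j[k],
                           code[k]), con)
    }
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}

#' Read molecules from an SDF or SMILES file
#'
#' SDF records must be V2000; 2D coordinates are taken verbatim from the
#' file. SMILES files contain one molecule per line, optionally followed by a
#' tab-separated id (and further ignored columns); coordinates come from the
#' deterministic layout of [parse_smiles()]. Records that fail to parse are
#' skipped with a warning naming their index; a file with zero parseable
#' records is an error.
#'
#' @param path input file.
#' @param format `"sdf"` or `"smiles"`.
#' @return list of `mol_graph` objects.
#' @export
read_molecules <- function(path, format = c("sdf", "smiles")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  mols <- list()
  if (format == "sdf") {
    recs <- split(lines, cumsum(c(1, utils::head(lines, -1) == "$$$$")))
    idx <- 0L
    for (rec in recs) {
      rec <- rec[rec != "$$$$"]
      if (!length(rec) || all(!nzchar(trimws(rec)))) next
      idx <- idx + 1L
      id <- trimws(rec[1])
      if (!nzchar(id)) id <- paste0("mol", idx)
      m <- tryCatch(.parse_sdf_record(rec, id), error = function(e) e)
      if (inherits(m, "error")) {
        warning("skipping SDF record ", idx, ": ", conditionMessage(m),
                call. = FALSE)
      } else mols[[length(mols) + 1L]] <- m
    }
  } else {
    lines <- lines[nzchar(trimws(lines))]
    for (idx in seq_along(lines)) {
      f <- strsplit(lines[idx], "\t")[[1]]
      id <- if (length(f) >= 2 && nzchar(f[2])) f[2] else paste0("mol", idx)
      m <- tryCatch(parse_smiles(trimws(f[1]), id), error = function(e) e)
      if (inherits(m, "error")) {
        warning("skipping SMILES line ", idx, ": ", conditionMessage(m),
                call. = FALSE)
      } else mols[[length(mols) + 1L]] <- m
    }
  }
  if (!length(mols)) stop("no parseable records in ", path, call. = FALSE)
  mols
}
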