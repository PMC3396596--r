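# Distance computation and tree building.

# Character matrix of an alignment tibble; unknowns (X/N) are treated as
# missing data, like gaps.
alignment_matrix <- function(alignment) {
  if (length(unique(nchar(alignment$aligned))) != 1L) {
    abort("aligned strings have unequal lengths")
  }
  mat <- do.call(rbind, lapply(alignment$aligned, str_chars))
  rownames(mat) <- alignment$id
  mat
}

#' Pairwise p-distances from an alignment
#'
#' `p = mismatches / compared columns`. Gap treatment: `"complete"` drops
#' every column containing a gap; `"pairwise"` compares, per pair, the
#' columns ungapped in both rows; `"partial"` first drops columns whose
#' non-gap fraction is below `coverage` (default 0.95, the usual
#' site-coverage cutoff), then compares pairwise-complete columns within the
#' rest. Unknown residues count as gaps.
#'
#' @param alignment Alignment tibble (`id`, `aligned`), >= 2 rows.
#' @param deletion_mode `"partial"` (default), `"pairwise"` or `"complete"`.
#' @param coverage Site-coverage cutoff for partial deletion.
#' @return Symmetric distance matrix with ids as dimnames.
#' @export
pdistance <- function(alignment,
                      deletion_mode = c("partial", "pairwise", "complete"),
                      coverage = 0.95) {
  deletion_mode <- match.arg(deletion_mode)
  if (nrow(alignment) < 2L) abort("pdistance needs >= 2 rows")
  mat <- alignment_matrix(alignment)
  alpha <- if (all(mat %in% c(NT_ALPHABET, "N", "-", "X"))) NT_ALPHABET
           else AA_ALPHABET
  res <- matrix(mat %in% alpha, nrow = nrow(mat))   # non-gap indicator
  keep <- switch(deletion_mode,
    complete = colSums(res) == nrow(mat),
    pairwise = rep(TRUE, ncol(mat)),
    partial = colMeans(res) >= coverage
  )
  mat <- mat[, keep, drop = FALSE]
  res <- res[, keep, drop = FALSE]
  comparable <- tcrossprod(res * 1)
  match_ct <- matrix(0, nrow(mat), nrow(mat))
  for (a in alpha) {
    xa <- (mat == a) * 1
    match_ct <- match_ct + tcrossprod(xa)
  }
  offdiag <- row(comparable) != col(comparable)
  if (any(comparable[offdiag] == 0)) {
    bad <- sort(which(comparable == 0 & offdiag, arr.ind = TRUE)[1, ])
    abort(paste0("no comparable columns between ",
                 alignment$id[bad[1]], " and ", alignment$id[bad[2]]))
  }
  d <- (comparable - match_ct) / comparable
  diag(d) <- 0
  dimnames(d) <- list(alignment$id, alignment$id)
  d
}

#' Poisson-corrected distance
#'
#' `-ln(1 - p)` applied elementwise to a p-distance matrix; with
#' `gamma_shape` set, the Gamma variant `a * ((1 - p)^(-1/a) - 1)` is used.
#'
#' @param p A p-distance matrix.
#' @param gamma_shape Optional Gamma shape parameter.
#' @return Corrected distance matrix.
#' @export
poisson_correct <- function(p, gamma_shape = NULL) {
  if (any(p >= 1)) abort("p-distances must be < 1 for correction")
  d <- if (is.null(gamma_shape)) -log(1 - p)
       else gamma_shape * ((1 - p)^(-1 / gamma_shape) - 1)
  diag(d) <- 0
  d
}

validate_distance <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) abort("distance must be square")
  if (any(!is.finite(D))) abort("distance matrix has non-finite entries")
  if (max(abs(D - t(D))) > 1e-8) abort("distance matrix is asymmetric")
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  }
  D
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Iteratively joins the pair minimising
#' `Q(i,j) = (n - 2) d(i,j) - R(i) - R(j)`; branch lengths follow the
#' standard formulas with negative lengths clamped to zero; ties in `Q` are
#' broken by the lexicographically smallest id pair (each cluster is keyed
#' by its smallest leaf id). The final three nodes join at a trifurcation,
#' giving the conventional unrooted representation.
#'
#' @param D Symmetric distance matrix with ids as dimnames (n >= 3).
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(D) {
  D <- validate_distance(D)
  n <- nrow(D)
  if (n < 3L) abort("nj_tree needs >= 3 taxa")
  labels <- rownames(D)
  frag <- labels                  # newick fragment per active node
  key <- labels                   # lexicographic tie-break key
  while (length(frag) > 3L) {
    m <- nrow(D)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_keys <- cbind(pmin(key[cand[, 1]], key[cand[, 2]]),
                       pmax(key[cand[, 1]], key[cand[, 2]]))
    best <- order(pair_keys[, 1], pair_keys[, 2])[1]
    i <- cand[best, 1]
    j <- cand[best, 2]
    li <- max(0, 0.5 * D[i, j] + (R[i] - R[j]) / (2 * (m - 2)))
    lj <- max(0, D[i, j] - (0.5 * D[i, j] + (R[i] - R[j]) / (2 * (m - 2))))
    new_frag <- paste0("(", frag[i], ":", fmt10(li), ",",
                       frag[j], ":", fmt10(lj), ")")
    dk <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    frag <- c(frag[keep], new_frag)
    key <- c(key[keep], min(key[c(i, j)]))
  }
  la <- max(0, 0.5 * (D[1, 2] + D[1, 3] - D[2, 3]))
  lb <- max(0, 0.5 * (D[1, 2] + D[2, 3] - D[1, 3]))
  lc <- max(0, 0.5 * (D[1, 3] + D[2, 3] - D[1, 2]))
  nwk <- paste0("(", frag[1], ":", fmt10(la), ",", frag[2], ":", fmt10(lb),
                ",", frag[3], ":", fmt10(lc), ");")
  ape::read.tree(text = nwk)
}

fmt10 <- function(x) sprintf("%.10f", x)

# Non-trivial bipartitions of an unrooted phylo: named list, internal node
# number (as character) -> leaf labels of its descendant side.
phylo_bipartitions <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  leafsets <- list()
  collect <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    leaves <- unlist(lapply(kids[[as.character(node)]], collect))
    leafsets[[as.character(node)]] <<- leaves
    leaves
  }
  collect(root)
  leafsets[[as.character(root)]] <- NULL
  keep <- vapply(leafsets, function(l) {
    length(l) >= 2L && length(l) <= n_tip - 2L
  }, logical(1))
  leafsets[keep]
}

# Canonical key of a bipartition side, stable under re-rooting: use the side
# that does not contain the alphabetically first leaf of the whole tree.
canonical_bipart_key <- function(side, all_leaves) {
  ref <- min(all_leaves)
  if (ref %in% side) side <- setdiff(all_leaves, side)
  bipart_key(side)
}

#' Resampling support for a neighbor-joining tree
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `n_replicates` times (seeded), rebuilds the tree per
#' replicate, and reports for each internal edge of the full-data tree the
#' percentage of replicate trees containing the same bipartition. Supports
#' are attached as internal `node.label`s.
#'
#' @param alignment Alignment tibble (`id`, `aligned`).
#' @param n_replicates Number of replicates (>= 10; 1000 for publication
#'   trees, fewer for interactive work).
#' @param seed Integer seed; results are deterministic given
#'   (alignment, seed, n_replicates).
#' @inheritParams pdistance
#' @return `ape::phylo` with `node.label` supports in \[0, 100\].
#' @export
support_resample <- function(alignment, n_replicates = 100L, seed = 1L,
                             deletion_mode = "partial", coverage = 0.95) {
  if (n_replicates < 10L) abort("n_replicates must be >= 10")
  tree <- nj_tree(pdistance(alignment, deletion_mode, coverage = coverage))
  mat <- alignment_matrix(alignment)
  n_var <- sum(vapply(seq_len(ncol(mat)), function(j) {
    length(unique(mat[, j])) > 1L
  }, logical(1)))
  if (n_var == 0L) {
    warning("alignment has no variable columns; supports are degenerate",
            call. = FALSE)
  }
  parts <- phylo_bipartitions(tree)
  all_leaves <- tree$tip.label
  keys <- vapply(parts, canonical_bipart_key, character(1),
                 all_leaves = all_leaves)
  hits <- setNames(rep(0L, length(keys)), keys)
  cols <- with_seed(seed, {
    lapply(seq_len(n_replicates), function(b) {
      sample.int(ncol(mat), ncol(mat), replace = TRUE)
    })
  })
  for (b in seq_len(n_replicates)) {
    boot <- alignment
    boot$aligned <- apply(mat[, cols[[b]], drop = FALSE], 1,
                          paste, collapse = "")
    rep_tree <- tryCatch(
      nj_tree(pdistance(boot, deletion_mode, coverage = coverage)),
      error = function(e) NULL
    )
    if (is.null(rep_tree)) next
    rep_keys <- vapply(phylo_bipartitions(rep_tree), canonical_bipart_key,
                       character(1), all_leaves = all_leaves)
    seen <- keys %in% rep_keys
    hits[seen] <- hits[seen] + 1L
  }
  support <- round(100 * hits / n_replicates)
  n_tip <- length(tree$tip.label)
  labels <- rep("", tree$Nnode)
  for (k in seq_along(parts)) {
    node <- as.integer(names(parts)[k])
    labels[node - n_tip] <- as.character(support[k])
  }
  tree$node.label <- labels
  tree
}

# --- brute-force minimum evolution ------------------------------------------

# Enumerate all unrooted binary topologies on leaves 1..n as edge matrices.
enumerate_topologies <- function(n) {
  base <- cbind(n + 1L, 1:3)       # star on leaves 1..3
  grow <- function(edges, k, next_internal) {
    if (k > n) return(list(edges))
    out <- list()
    for (e in seq_len(nrow(edges))) {
      w <- next_internal
      new_edges <- rbind(edges[-e, , drop = FALSE],
                         c(edges[e, 1], w), c(w, edges[e, 2]), c(w, k))
      out <- c(out, grow(new_edges, k + 1L, next_internal + 1L))
    }
    out
  }
  grow(base, 4L, n + 2L)
}

# OLS branch lengths for a fixed topology; returns list(lengths, total).
ols_fit <- function(edges, D) {
  n <- nrow(D)
  adj <- lapply(seq_len(max(edges)), function(v) integer(0))
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]; v <- edges[e, 2]
    adj[[u]] <- c(adj[[u]], e)
    adj[[v]] <- c(adj[[v]], e)
  }
  other <- function(e, v) if (edges[e, 1] == v) edges[e, 2] else edges[e, 1]
  path_edges <- function(a, b) {
    prev_edge <- rep(NA_integer_, length(adj))
    visited <- rep(FALSE, length(adj))
    queue <- a
    visited[a] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v == b) break
      for (e in adj[[v]]) {
        w <- other(e, v)
        if (!visited[w]) {
          visited[w] <- TRUE
          prev_edge[w] <- e
          queue <- c(queue, w)
        }
      }
    }
    path <- integer(0)
    v <- b
    while (v != a) {
      e <- prev_edge[v]
      path <- c(path, e)
      v <- other(e, v)
    }
    path
  }
  pairs <- combn(n, 2)
  A <- matrix(0, ncol(pairs), nrow(edges))
  d <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    A[p, path_edges(i, j)] <- 1
    d[p] <- D[i, j]
  }
  b <- qr.coef(qr(A), d)
  b[is.na(b)] <- 0
  b <- pmax(b, 0)
  list(lengths = b, total = sum(b))
}

# Convert an edge matrix + branch lengths into a phylo, rooted at the
# internal neighbour of leaf 1 (unrooted semantics preserved).
edges_to_phylo <- function(edges, lengths, labels) {
  n <- length(labels)
  adj <- lapply(seq_len(max(edges)), function(v) integer(0))
  for (e in seq_len(nrow(edges))) {
    adj[[edges[e, 1]]] <- c(adj[[edges[e, 1]]], e)
    adj[[edges[e, 2]]] <- c(adj[[edges[e, 2]]], e)
  }
  other <- function(e, v) if (edges[e, 1] == v) edges[e, 2] else edges[e, 1]
  root <- other(adj[[1]][1], 1L)
  render <- function(v, from_edge) {
    es <- setdiff(adj[[v]], from_edge)
    if (length(es) == 0L) return(labels[v])
    parts <- vapply(es, function(e) {
      w <- other(e, v)
      paste0(render(w, e), ":", fmt10(lengths[e]))
    }, character(1))
    if (v <= n) return(labels[v])   # unreachable for internal nodes
    paste0("(", paste(parts, collapse = ","), ")")
  }
  nwk <- paste0(render(root, NA_integer_), ";")
  ape::read.tree(text = nwk)
}

#' Brute-force minimum-evolution tree (exhaustive oracle)
#'
#' Enumerates every unrooted binary topology ((2n-5)!! of them), fits
#' ordinary-least-squares branch lengths per topology (negatives clamped to
#' zero after fitting), and returns the topology with the smallest total
#' branch length. Intended as an independent oracle for [nj_tree()] at small
#' n.
#'
#' @param D Symmetric distance matrix (4 <= n <= `max_taxa`).
#' @param max_taxa Hard cap on n (default 8).
#' @return `ape::phylo`; the total tree length is in `attr(, "total_length")`
#'   and the number of topologies scanned in `attr(, "n_topologies")`.
#' @export
me_brute <- function(D, max_taxa = 8L) {
  D <- validate_distance(D)
  n <- nrow(D)
  if (n < 4L || n > max_taxa) {
    abort(paste0("me_brute requires 4 <= n <= ", max_taxa))
  }
  topos <- enumerate_topologies(n)
  best <- NULL
  best_total <- Inf
  for (edges in topos) {
    fit <- ols_fit(edges, D)
    if (fit$total < best_total - 1e-12) {
      best_total <- fit$total
      best <- list(edges = edges, lengths = fit$lengths)
    }
  }
  tree <- edges_to_phylo(best$edges, best$lengths, rownames(D))
  attr(tree, "total_length") <- best_total
  attr(tree, "n_topologies") <- length(topos)
  tree
}

#' Total OLS tree length of a fixed topology
#'
#' Fits OLS branch lengths (clamped at zero) on the given topology and
#' returns the total length; used to compare NJ topologies against the
#' minimum-evolution optimum.
#'
#' @param tree `ape::phylo`.
#' @param D Distance matrix covering the tree's leaves.
#' @return Total branch length under OLS.
#' @export
ols_tree_length <- function(tree, D) {
  D <- validate_distance(D)
  tree <- ape::unroot(tree)
  labels <- tree$tip.label
  D <- D[labels, labels]
  edges <- tree$edge
  # re-number: leaves 1..n keep ape numbering which matches rownames order
  ols_fit(edges, D)$total
}
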