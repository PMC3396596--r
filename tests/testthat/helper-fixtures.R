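# Shared fixtures and independent oracles, built in code.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n, exclude = character(0)) {
  paste(sample(setdiff(AA, exclude), n, replace = TRUE), collapse = "")
}

# A small two-clade generator configuration for fast end-to-end tests:
# one teleost and one non-teleost pair of species, reduced counts.
small_config <- function(seed = 11L, mu = 0.05, ...) {
  generator_config(
    seed = seed, mu = mu,
    counts_non_teleost = c("HEY1/2/L" = 1L, "DEC1/2" = 1L, "HESL" = 1L,
                           "HES1-7" = 2L),
    species = tibble::tibble(
      name = c("Human", "Mouse", "Zebrafish", "Fugu"),
      is_teleost = c(FALSE, FALSE, TRUE, TRUE),
      n_chromosomes = 4L, chrom_length = 3e6),
    tandem_arrays = tibble::tibble(species = "Zebrafish", group = "HES1-7",
                                   size = 4L, gap_min = 5000,
                                   gap_max = 30000),
    ...
  )
}

# Independent brute-force global affine-gap alignment score: recursive
# enumeration of all alignments (no dynamic programming). States: 0 = no
# open gap, 1 = gap open in a, 2 = gap open in b.
brute_align_score <- function(a, b, M, gap_open = 10, gap_extend = 1) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(ac) && j > length(bc)) return(0)
    best <- -Inf
    if (i <= length(ac) && j <= length(bc)) {
      best <- max(best, M[ac[i], bc[j]] + rec(i + 1, j + 1, 0L))
    }
    if (j <= length(bc)) {  # gap in a, consume b[j]
      pen <- if (state == 1L) gap_extend else gap_open
      best <- max(best, -pen + rec(i, j + 1, 1L))
    }
    if (i <= length(ac)) {  # gap in b, consume a[i]
      pen <- if (state == 2L) gap_extend else gap_open
      best <- max(best, -pen + rec(i + 1, j, 2L))
    }
    best
  }
  rec(1L, 1L, 0L)
}

# Random additive distance matrix from a random binary tree; returns the
# tree (ape::phylo) and its path-length matrix.
random_additive <- function(n, seed) {
  withr::with_seed(seed, {
    tree <- ape::rtree(n, rooted = FALSE,
                       tip.label = paste0("t", seq_len(n)))
    tree$edge.length <- stats::runif(nrow(tree$edge), 0.3, 1.5)
    list(tree = tree, D = ape::cophenetic.phylo(tree))
  })
}

# O(n^2) oracle for tandem chaining: two loci are linked when their
# intergenic gap is within the threshold; clusters are connected components
# within (species, chromosome, group).
brute_tandem <- function(loci, gap_threshold = 40000) {
  if (!"species" %in% names(loci)) loci$species <- "unknown"
  key <- paste(loci$species, loci$chromosome, loci$group, sep = "\r")
  clusters <- list()
  for (k in unique(key)) {
    d <- loci[key == k, , drop = FALSE]
    d <- d[order(d$start, d$end, d$gene_id), , drop = FALSE]
    n <- nrow(d)
    if (n < 2L) next
    linked <- matrix(FALSE, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        gap <- max(0, max(d$start[i], d$start[j]) -
                     min(d$end[i], d$end[j]))
        # adjacency in coordinate order only
        if (j == i + 1) linked[i, j] <- gap <= gap_threshold
      }
    }
    comp <- seq_len(n)
    for (i in seq_len(n - 1)) {
      if (linked[i, i + 1]) comp[comp == comp[i + 1]] <- comp[i]
    }
    for (cc in unique(comp)) {
      ids <- d$gene_id[comp == cc]
      if (length(ids) >= 2L) clusters[[length(clusters) + 1L]] <- sort(ids)
    }
  }
  clusters[order(vapply(clusters, paste, character(1), collapse = ","))]
}

# Unrooted topology comparison.
same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# Independent oracle for the exact rank-sum p-value: enumerate all n!
# orderings recursively (not just subsets) and tabulate the rank sum of the
# first n1 positions.
perm_ranksum_p <- function(x, y) {
  ranks <- rank(c(x, y))
  n1 <- length(x)
  W <- sum(ranks[seq_len(n1)])
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  sums <- vapply(perms(ranks), function(p) sum(p[seq_len(n1)]), numeric(1))
  min(1, 2 * min(mean(sums <= W + 1e-9), mean(sums >= W - 1e-9)))
}
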