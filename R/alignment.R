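# Pairwise and progressive alignment of protein sequences.

# Cache BLOSUM62 from Biostrings on first use.
the <- new.env(parent = emptyenv())
get_submat <- function(substitution_matrix = "BLOSUM62") {
  if (is.matrix(substitution_matrix)) return(substitution_matrix)
  key <- paste0("submat_", substitution_matrix)
  if (is.null(the[[key]])) {
    e <- new.env()
    utils::data(list = substitution_matrix, package = "Biostrings", envir = e)
    the[[key]] <- e[[substitution_matrix]]
  }
  the[[key]]
}

#' Optimal global pairwise alignment (Needleman-Wunsch with affine gaps)
#'
#' Gotoh's three-state recursion; gap of length k costs
#' `gap_open + (k - 1) * gap_extend`. Traceback ties prefer match/mismatch
#' over a gap in `a` over a gap in `b`, so results are deterministic.
#'
#' @param a,b Non-empty protein sequences.
#' @param substitution_matrix Matrix name in Biostrings (default
#'   `"BLOSUM62"`) or a numeric matrix with residue dimnames.
#' @param gap_open,gap_extend Positive gap penalties (defaults 10 and 1).
#' @return List of class `pairwise_alignment`: `a_aligned`, `b_aligned`
#'   (gap `-`), `score`.
#' @export
nw_align <- function(a, b, substitution_matrix = "BLOSUM62",
                     gap_open = 10, gap_extend = 1) {
  if (!is_string(a) || !is_string(b) || !nzchar(a) || !nzchar(b)) {
    abort("nw_align requires two non-empty sequences")
  }
  M <- get_submat(substitution_matrix)
  ac <- str_chars(a)
  bc <- str_chars(b)
  bad <- setdiff(unique(c(ac, bc)), rownames(M))
  if (length(bad)) {
    abort(paste0("residues not in substitution matrix: ",
                 paste(bad, collapse = ", ")))
  }
  S <- M[ac, bc, drop = FALSE]
  res <- gotoh_align_cpp(matrix(as.numeric(S), nrow = length(ac)),
                         gap_open, gap_extend)
  a_al <- ifelse(res$a_idx == 0L, "-", ac[pmax(res$a_idx, 1L)])
  b_al <- ifelse(res$b_idx == 0L, "-", bc[pmax(res$b_idx, 1L)])
  structure(list(a_aligned = paste(a_al, collapse = ""),
                 b_aligned = paste(b_al, collapse = ""),
                 score = res$score),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> score ", x$score, "\n", x$a_aligned, "\n",
      x$b_aligned, "\n", sep = "")
  invisible(x)
}

# Fractional k-mer distance between two sequences (guide-tree metric):
# 1 - shared_kmers / (min_length - k + 1).
kmer_distance <- function(a, b, k = 3L) {
  km <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }
  ka <- km(a)
  kb <- km(b)
  if (length(ka) == 0L || length(kb) == 0L) return(1)
  ta <- table(ka)
  tb <- table(kb)
  common <- intersect(names(ta), names(tb))
  shared <- sum(pmin(ta[common], tb[common]))
  1 - shared / min(length(ka), length(kb))
}

# Average-linkage (UPGMA) guide tree as a nested merge list over indices.
upgma_merge_order <- function(D) {
  n <- nrow(D)
  active <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  Dm <- D
  diag(Dm) <- Inf
  while (length(active) > 1L) {
    idx <- which(Dm == min(Dm), arr.ind = TRUE)[1, ]
    i <- min(idx)
    j <- max(idx)
    merged <- list(active[[i]], active[[j]])
    new_d <- (Dm[i, ] * sizes[i] + Dm[j, ] * sizes[j]) / (sizes[i] + sizes[j])
    keep <- setdiff(seq_along(active), c(i, j))
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], new_d[keep]),
                c(new_d[keep], Inf))
    active <- c(active[keep], list(merged))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
  }
  active[[1]]
}

# Align two profiles (lists of equal-length aligned strings) with the Gotoh
# kernel on frequency-weighted column scores.
align_profiles <- function(pa, pb, M, gap_open, gap_extend) {
  freq <- function(p) {
    mat <- do.call(rbind, lapply(p, str_chars))
    vapply(seq_len(ncol(mat)), function(j) {
      tabulate(match(mat[, j], AA_ALPHABET), nbins = 20L) / nrow(mat)
    }, numeric(20))   # 20 x L; gaps/unknowns contribute nothing
  }
  fa <- freq(pa)
  fb <- freq(pb)
  M20 <- M[AA_ALPHABET, AA_ALPHABET]
  S <- t(fa) %*% M20 %*% fb
  res <- gotoh_align_cpp(S, gap_open, gap_extend)
  expand <- function(strings, idx) {
    mat <- do.call(rbind, lapply(strings, str_chars))
    cols <- matrix("-", nrow = nrow(mat), ncol = length(idx))
    cols[, idx != 0L] <- mat[, idx[idx != 0L], drop = FALSE]
    apply(cols, 1, paste, collapse = "")
  }
  c(expand(pa, res$a_idx), expand(pb, res$b_idx))
}

#' Progressive multiple alignment of protein records
#'
#' A simplified ClustalX-like scheme: a UPGMA guide tree on fractional 3-mer
#' distances, then profile-profile alignment up the guide tree with columns
#' scored by frequency-weighted substitution scores. Output rows preserve
#' the input record order, and each sequence's residue order is preserved
#' within its row.
#'
#' @param records Sequence tibble with `id`, `sequence` (>= 2 rows).
#' @inheritParams nw_align
#' @return An alignment tibble (class `hes_alignment`): `id`, `aligned`.
#' @export
progressive_align <- function(records, substitution_matrix = "BLOSUM62",
                              gap_open = 10, gap_extend = 1) {
  n <- nrow(records)
  if (is.null(n) || n < 2L) abort("progressive_align needs >= 2 records")
  M <- get_submat(substitution_matrix)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- kmer_distance(records$sequence[i],
                                          records$sequence[j])
    }
  }
  merge_tree <- if (n == 2L) list(1L, 2L) else upgma_merge_order(D)
  build <- function(node) {
    if (!is.list(node)) {
      return(list(ids = node, rows = records$sequence[node]))
    }
    l <- build(node[[1]])
    r <- build(node[[2]])
    rows <- align_profiles(l$rows, r$rows, M, gap_open, gap_extend)
    list(ids = c(l$ids, r$ids), rows = rows)
  }
  res <- build(merge_tree)
  ord <- order(res$ids)
  out <- tibble(id = records$id[res$ids[ord]], aligned = res$rows[ord])
  class(out) <- c("hes_alignment", class(out))
  out
}

#' Concatenate the bHLH and Orange hit substrings of members
#'
#' Extracts, per member, the bHLH hit region followed immediately by the
#' Orange hit region (no separator), preserving the record id. These
#' concatenated domain regions are the substrate for alignment and tree
#' building.
#'
#' @param membership Membership tibble from [call_membership()].
#' @param records Sequence tibble the calls were made on.
#' @return Sequence tibble with `id`, `species`, `sequence`.
#' @export
concat_domains <- function(membership, records) {
  if (any(!membership$is_member)) {
    abort("concat_domains: non-member rows present; filter on is_member first")
  }
  m <- left_join(membership, select(records, "id", "sequence"), by = "id")
  tibble(
    id = m$id,
    species = m$species,
    sequence = paste0(
      substring(m$sequence, m$bhlh_start, m$bhlh_end),
      substring(m$sequence, m$orange_start, m$orange_end)
    )
  )
}
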