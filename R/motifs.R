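# C-terminal tetrapeptide classification and conserved motif blocks.

TETRA_CLASSES <- c("WRPW", "YRPW", "FRPW", "YXXW_TEGAF", "DEGENERATE_W",
                   "ABSENT")

classify_one_tail <- function(sequence, window = 10L, tegaf_window = 10L) {
  n <- nchar(sequence)
  if (n < 4L) {
    return(list(class = "ABSENT", observed = "", position_from_end = NA_integer_))
  }
  win_start <- max(1L, n - window + 1L)
  starts <- seq(win_start, n - 3L)
  if (length(starts) == 0L) {
    return(list(class = "ABSENT", observed = "", position_from_end = NA_integer_))
  }
  fourmers <- substring(sequence, starts, starts + 3L)
  from_end <- n - (starts + 3L)
  hit <- function(i, class) {
    list(class = class, observed = fourmers[i],
         position_from_end = as.integer(from_end[i]))
  }
  # (1) exact [WYF]RPW, rightmost
  exact <- grepl("^[WYF]RPW$", fourmers)
  if (any(exact)) {
    i <- max(which(exact))
    return(hit(i, paste0(substring(fourmers[i], 1L, 1L), "RPW")))
  }
  # (2) Y-x-x-W followed by TE[IV]GAF within tegaf_window residues
  yxxw <- grepl("^Y..W$", fourmers)
  if (any(yxxw)) {
    for (i in rev(which(yxxw))) {
      down <- substring(sequence, starts[i] + 4L,
                        min(n, starts[i] + 3L + tegaf_window + 5L))
      if (grepl("TE[IV]GAF", down)) return(hit(i, "YXXW_TEGAF"))
    }
  }
  # (3) any 4-mer ending in W whose middle is not RP
  endw <- grepl("W$", fourmers) & substring(fourmers, 2L, 3L) != "RP"
  if (any(endw)) return(hit(max(which(endw)), "DEGENERATE_W"))
  list(class = "ABSENT", observed = "", position_from_end = NA_integer_)
}

#' Classify C-terminal tetrapeptide motifs
#'
#' Searches the last `window` residues of each protein; within a class the
#' rightmost match wins, and classes take priority in the order: exact
#' `[WYF]RPW` (class named by the first letter), then a `YxxW` tetrapeptide
#' followed downstream within `tegaf_window` residues by a `TE(I/V)GAF`
#' peptide (`YXXW_TEGAF`), then any 4-mer ending in W whose middle two
#' residues are not `RP` (`DEGENERATE_W`, the matched 4-mer reported
#' verbatim), else `ABSENT`. This priority encodes the family's
#' FRPW -> YRPW -> WRPW evolutionary series of corepressor-recruitment
#' motifs.
#'
#' @param records Sequence tibble ([read_fasta()]) or a single sequence.
#' @param window C-terminal search window in residues (default 10).
#' @param tegaf_window Residues after the YxxW within which TE(I/V)GAF must
#'   start (default 10).
#' @return Tibble: `id`, `class`, `observed`, `position_from_end`.
#' @export
classify_tetrapeptide <- function(records, window = 10L, tegaf_window = 10L) {
  if (is.character(records)) records <- tibble(id = "query",
                                               sequence = records)
  calls <- lapply(records$sequence, classify_one_tail, window = window,
                  tegaf_window = tegaf_window)
  tibble(
    id = records$id,
    class = vapply(calls, `[[`, character(1), "class"),
    observed = vapply(calls, `[[`, character(1), "observed"),
    position_from_end = vapply(calls, `[[`, integer(1), "position_from_end")
  )
}

#' Find conserved blocks in an alignment
#'
#' Per-column conservation is the frequency of the modal non-gap residue
#' among non-gap rows, scaled by the non-gap fraction. Maximal runs of at
#' least `min_len` columns, each at or above `min_conservation`, are
#' reported with per-column residue frequency tables (the data behind a
#' sequence logo).
#'
#' @param alignment Alignment tibble (`id`, `aligned`), >= 4 rows.
#' @param min_len Minimum block length in columns (default 6).
#' @param min_conservation Per-column conservation threshold (default 0.5).
#' @return Tibble of disjoint, sorted blocks: `start`, `end`, `length`,
#'   `consensus`, `mean_conservation`, `frequencies` (list of L x residues
#'   tibbles).
#' @export
find_conserved_blocks <- function(alignment, min_len = 6L,
                                  min_conservation = 0.5) {
  if (nrow(alignment) < 4L) abort("find_conserved_blocks needs >= 4 rows")
  mat <- alignment_matrix(alignment)
  n <- nrow(mat)
  col_stats <- lapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    res <- col[col %in% AA_ALPHABET]
    if (length(res) == 0L) {
      return(list(cons = 0, modal = "-", freq = NULL))
    }
    tab <- tabulate(match(res, AA_ALPHABET), nbins = 20L)
    modal <- AA_ALPHABET[which.max(tab)]
    cons <- max(tab) / length(res) * (length(res) / n)
    list(cons = cons, modal = modal, freq = tab / length(res))
  })
  cons <- vapply(col_stats, `[[`, numeric(1), "cons")
  ok <- cons >= min_conservation
  if (!any(ok)) {
    return(tibble(start = integer(), end = integer(), length = integer(),
                  consensus = character(), mean_conservation = numeric(),
                  frequencies = list()))
  }
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_len
  blocks <- lapply(which(keep), function(k) {
    s <- starts[k]; e <- ends[k]
    freq_tbl <- bind_rows(lapply(s:e, function(j) {
      f <- col_stats[[j]]$freq
      tibble(column = j, residue = AA_ALPHABET, frequency = f)
    }))
    tibble(
      start = s, end = e, length = e - s + 1L,
      consensus = paste(vapply(col_stats[s:e], `[[`, character(1), "modal"),
                        collapse = ""),
      mean_conservation = mean(cons[s:e]),
      frequencies = list(freq_tbl)
    )
  })
  bind_rows(blocks)
}
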