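#' Build a position-specific scoring matrix from a seed alignment
#'
#' Columns with a gap fraction above `max_gap_fraction` are dropped. The
#' retained columns get pseudocounted probabilities
#' `p_j(a) = (n_j(a) + beta * q(a)) / (N_j + beta)` where `n_j(a)` counts
#' residue `a` in column `j` and `N_j` the non-gap residues, and log-odds
#' scores `S_j(a) = log2(p_j(a) / q(a))`.
#'
#' @param seed Aligned protein records: a tibble from [read_fasta()] or a
#'   character vector of equal-length aligned sequences (gap `-`).
#' @param name Profile name, conventionally `"bHLH"` or `"Orange"`.
#' @param beta Positive pseudocount weight (default 1).
#' @param background Length-20 residue background frequencies summing to 1;
#'   default uniform (0.05 each).
#' @param max_gap_fraction Columns gappier than this are excluded.
#' @return An object of class `profile_model`.
#' @export
build_profile <- function(seed, name = "domain", beta = 1,
                          background = NULL, max_gap_fraction = 0.5) {
  seqs <- if (is.data.frame(seed)) seed$sequence else seed
  if (length(seqs) < 2L) abort("seed alignment needs >= 2 sequences")
  if (length(unique(nchar(seqs))) != 1L) {
    abort("seed sequences have unequal aligned lengths")
  }
  if (beta <= 0) abort("beta must be positive")
  q <- background %||% rep(1 / 20, 20)
  if (length(q) != 20L || abs(sum(q) - 1) > 1e-8) {
    abort("background must be 20 frequencies summing to 1")
  }
  names(q) <- AA_ALPHABET
  mat <- do.call(rbind, lapply(seqs, str_chars))
  is_res <- matrix(mat %in% AA_ALPHABET, nrow = nrow(mat))
  gap_frac <- 1 - colMeans(is_res)
  keep <- which(gap_frac <= max_gap_fraction)
  if (length(keep) == 0L) abort("all columns exceeded the gap threshold")
  if (length(keep) < 5L) abort("profile needs >= 5 retained columns")
  probs <- vapply(keep, function(j) {
    col <- mat[is_res[, j], j]
    n <- tabulate(match(col, AA_ALPHABET), nbins = 20L)
    unname((n + beta * q) / (length(col) + beta))
  }, numeric(20))
  rownames(probs) <- AA_ALPHABET   # 20 x L
  logodds <- log2(probs / unname(q))
  structure(
    list(name = name, length = length(keep),
         logodds = t(logodds),          # L x 20
         probs = t(probs),              # L x 20, columns AA_ALPHABET
         background = q, beta = beta, included_columns = keep,
         consensus = paste(AA_ALPHABET[apply(probs, 2, which.max)],
                           collapse = "")),
    class = "profile_model"
  )
}

#' @export
print.profile_model <- function(x, ...) {
  cat("<profile_model> ", x$name, ": ", x$length, " columns, beta = ",
      x$beta, "\n consensus: ", x$consensus, "\n", sep = "")
  invisible(x)
}

#' Tidy a profile model into a per-column tibble
#'
#' @param x A `profile_model`.
#' @param ... Unused.
#' @return Tibble with one row per (column, residue) pair: `column`,
#'   `seed_column`, `residue`, `prob`, `logodds`.
#' @export
tidy.profile_model <- function(x, ...) {
  tibble(
    column = rep(seq_len(x$length), each = 20L),
    seed_column = rep(x$included_columns, each = 20L),
    residue = rep(AA_ALPHABET, times = x$length),
    prob = as.vector(t(x$probs)),
    logodds = as.vector(t(x$logodds))
  )
}

# All window scores for one sequence (full windows plus terminal windows
# covering >= ceil(L/2) profile columns, flagged truncated).
profile_window_scores <- function(sequence, profile) {
  L <- profile$length
  min_cols <- ceiling(L / 2)
  if (nchar(sequence) < min_cols) {
    return(tibble(start = integer(), end = integer(), n_cols = integer(),
                  truncated = logical(), score = numeric()))
  }
  idx <- aa_index0(str_chars(sequence))
  as_tibble(pssm_window_scores_cpp(idx, profile$logodds, as.integer(min_cols)))
}

#' Scan a sequence (or a set of sequences) with a profile
#'
#' Ungapped sliding-window scan. Every full-length window is scored, plus
#' truncated terminal windows covering at least half the profile columns
#' (flagged `truncated`). Hits are selected greedily in decreasing score
#' order among non-overlapping windows, keeping scores at or above
#' `score_floor`.
#'
#' @param records Sequence tibble ([read_fasta()]) or a single sequence
#'   string.
#' @param profile A `profile_model`.
#' @param score_floor Minimum reported bit score (default 0).
#' @return Tibble of hits: `sequence_id`, `domain`, `start`, `end`, `score`,
#'   `truncated`.
#' @export
scan_profile <- function(records, profile, score_floor = 0) {
  if (is.character(records)) {
    records <- tibble(id = "query", sequence = records)
  }
  out <- lapply(seq_len(nrow(records)), function(i) {
    w <- profile_window_scores(records$sequence[i], profile)
    w <- w[w$score >= score_floor, , drop = FALSE]
    if (nrow(w) == 0L) return(NULL)
    w <- w[order(-w$score, w$start), , drop = FALSE]
    sel <- logical(0)
    taken <- matrix(numeric(0), ncol = 2)
    keep <- rep(FALSE, nrow(w))
    for (k in seq_len(nrow(w))) {
      if (nrow(taken) == 0 ||
          all(w$start[k] > taken[, 2] | w$end[k] < taken[, 1])) {
        keep[k] <- TRUE
        taken <- rbind(taken, c(w$start[k], w$end[k]))
      }
    }
    w <- w[keep, , drop = FALSE]
    tibble(sequence_id = records$id[i], domain = profile$name,
           start = w$start, end = w$end, score = w$score,
           truncated = w$truncated)
  })
  bind_rows(out)
}

#' Empirical permutation p-value for a profile hit score
#'
#' The null is the best window score over residue permutations of the
#' record; `p = (1 + #{null >= score}) / (n_shuffles + 1)`. Deterministic
#' given `seed`.
#'
#' @param hit_score Observed bit score.
#' @param sequence The sequence the hit came from.
#' @param profile A `profile_model`.
#' @param n_shuffles Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return p-value in (0, 1].
#' @export
empirical_pvalue <- function(hit_score, sequence, profile,
                             n_shuffles = 200L, seed = 1L) {
  if (n_shuffles < 100L) abort("n_shuffles must be >= 100")
  chars <- str_chars(sequence)
  null_best <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      shuf <- paste(sample(chars), collapse = "")
      w <- profile_window_scores(shuf, profile)
      if (nrow(w) == 0L) -Inf else max(w$score)
    }, numeric(1))
  })
  (1 + sum(null_best >= hit_score)) / (n_shuffles + 1)
}

#' Call family membership by dual-domain architecture
#'
#' A record is a member iff its best bHLH hit and best Orange hit both reach
#' empirical significance `p <= alpha` and the bHLH hit starts before the
#' Orange hit. `complete` records that neither hit is truncated (full-length
#' domains). Non-members carry a `reason`: `no_bhlh`, `no_orange` (missing
#' or insignificant hit) or `wrong_order`.
#'
#' Per-record permutation seeds are derived by hashing the record id with
#' `seed`, so calls are invariant to record order.
#'
#' @param records Sequence tibble ([read_fasta()]).
#' @param bhlh_profile,orange_profile `profile_model`s for the two domains.
#' @param alpha Significance threshold (default 0.01).
#' @param n_shuffles Permutations per record and domain (default 200).
#' @param seed Integer base seed.
#' @param max_gap Optional maximum residue gap between the bHLH end and the
#'   Orange start (default `NULL`: unconstrained).
#' @param score_floor Reporting floor passed to [scan_profile()].
#' @return Membership tibble: `id`, `species`, `is_member`, `complete`,
#'   `reason`, and `bhlh_*` / `orange_*` hit columns.
#' @export
call_membership <- function(records, bhlh_profile, orange_profile,
                            alpha = 0.01, n_shuffles = 200L, seed = 1L,
                            max_gap = NULL, score_floor = 0) {
  one <- function(i) {
    id <- records$id[i]
    seqc <- records$sequence[i]
    best_hit <- function(profile, domain_tag) {
      h <- scan_profile(records[i, ], profile, score_floor = score_floor)
      if (nrow(h) == 0L) return(NULL)
      h <- h[order(-h$score, h$start), ][1, ]
      h$p <- empirical_pvalue(
        h$score, seqc, profile, n_shuffles = n_shuffles,
        seed = string_seed(paste0(id, "::", domain_tag), seed))
      h
    }
    bh <- best_hit(bhlh_profile, "bhlh")
    oh <- best_hit(orange_profile, "orange")
    bh_ok <- !is.null(bh) && bh$p <= alpha
    oh_ok <- !is.null(oh) && oh$p <= alpha
    reason <- NA_character_
    member <- FALSE
    if (!bh_ok) {
      reason <- "no_bhlh"
    } else if (!oh_ok) {
      reason <- "no_orange"
    } else if (bh$start >= oh$start) {
      reason <- "wrong_order"
    } else if (!is.null(max_gap) && (oh$start - bh$end - 1L) > max_gap) {
      reason <- "domain_gap"
    } else {
      member <- TRUE
    }
    hit_cols <- function(h, prefix) {
      if (is.null(h)) {
        h <- tibble(start = NA_integer_, end = NA_integer_,
                    score = NA_real_, truncated = NA, p = NA_real_)
      }
      setNames(h[c("start", "end", "score", "p", "truncated")],
               paste0(prefix, "_", c("start", "end", "score", "p",
                                     "truncated")))
    }
    bind_cols(
      tibble(id = id,
             species = records$species[i] %||% "unknown",
             is_member = member,
             complete = member && !bh$truncated && !oh$truncated,
             reason = reason),
      hit_cols(bh, "bhlh"), hit_cols(oh, "orange")
    )
  }
  bind_rows(lapply(seq_len(nrow(records)), one))
}

#' Percent identity of the optimal global alignment of two sequences
#'
#' Identity is the number of exactly matching aligned positions divided by
#' the length of the shorter sequence (the CD-HIT convention).
#'
#' @param a,b Protein sequences.
#' @param ... Passed to [nw_align()].
#' @return Identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b, ...) {
  aln <- nw_align(a, b, ...)
  ac <- str_chars(aln$a_aligned)
  bc <- str_chars(aln$b_aligned)
  sum(ac == bc & ac != "-") / min(nchar(a), nchar(b))
}

#' Greedy redundancy clustering of sequences
#'
#' Re-implements CD-HIT's greedy scheme: sequences are sorted by decreasing
#' length (ties broken lexicographically by id) and each is assigned to the
#' first existing cluster whose representative (founder) has global-alignment
#' identity at or above `identity_threshold`; otherwise it founds a new
#' cluster.
#'
#' @param records Sequence tibble with `id`, `sequence`.
#' @param identity_threshold Fraction in (0.5, 1\]; default 0.9.
#' @return The input tibble with added columns `cluster_rep` (representative
#'   id) and `is_representative`, in the original row order.
#' @export
deduplicate <- function(records, identity_threshold = 0.9) {
  if (identity_threshold <= 0.5 || identity_threshold > 1) {
    abort("identity_threshold must be in (0.5, 1]")
  }
  ord <- order(-nchar(records$sequence), records$id)
  reps <- character(0)
  rep_seq <- character(0)
  assign <- setNames(character(nrow(records)), records$id)
  for (i in ord) {
    id <- records$id[i]
    s <- records$sequence[i]
    placed <- FALSE
    for (r in seq_along(reps)) {
      if (pairwise_identity(s, rep_seq[r]) >= identity_threshold) {
        assign[id] <- reps[r]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      rep_seq <- c(rep_seq, s)
      assign[id] <- id
    }
  }
  mutate(records,
         cluster_rep = unname(assign[records$id]),
         is_representative = .data$cluster_rep == .data$id)
}
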