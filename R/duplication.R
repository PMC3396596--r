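# Tandem-duplication clusters, count tables and the rank-sum expansion test.

#' Detect tandem gene-duplication clusters
#'
#' Within each chromosome (and species, when a `species` column is present;
#' and group, when `require_same_group`), loci sorted by start are chained
#' while each consecutive intergenic gap (`next start - previous end`,
#' floored at 0 for overlaps) stays at or below `gap_threshold`; chains of
#' two or more genes are reported. Strand is ignored.
#'
#' @param loci Tibble with `gene_id`, `chromosome`, `start`, `end`; optional
#'   `species`, `group`, `strand`.
#' @param gap_threshold Maximum intergenic gap in bp (default 40000, the
#'   40 kb rule).
#' @param require_same_group Chain only within one group label (default
#'   TRUE).
#' @return Tibble: `species`, `chromosome`, `group`, `n`, `members` (list
#'   column, coordinate order), `span`, `max_gap`.
#' @export
detect_tandem_clusters <- function(loci, gap_threshold = 40000,
                                   require_same_group = TRUE) {
  if (gap_threshold <= 0) abort("gap_threshold must be positive")
  if (nrow(loci) == 0L) {
    return(tibble(species = character(), chromosome = character(),
                  group = character(), n = integer(), members = list(),
                  span = numeric(), max_gap = numeric()))
  }
  df <- loci
  if (!"species" %in% names(df)) df$species <- "unknown"
  if (!"group" %in% names(df)) df$group <- NA_character_
  key_group <- if (require_same_group) df$group else ""
  df$chain_key <- paste(df$species, df$chromosome, key_group, sep = "\r")
  out <- list()
  for (key in unique(df$chain_key)) {
    d <- df[df$chain_key == key, , drop = FALSE]
    d <- d[order(d$start, d$end, d$gene_id), , drop = FALSE]
    gaps <- if (nrow(d) > 1L) pmax(0, d$start[-1] - d$end[-nrow(d)])
            else numeric(0)
    breaks <- c(0, cumsum(gaps > gap_threshold))
    for (chain_id in unique(breaks)) {
      idx <- which(breaks == chain_id)
      if (length(idx) < 2L) next
      cg <- gaps[idx[-length(idx)]]
      out[[length(out) + 1L]] <- tibble(
        species = d$species[idx[1]],
        chromosome = d$chromosome[idx[1]],
        group = d$group[idx[1]],
        n = length(idx),
        members = list(d$gene_id[idx]),
        span = max(d$end[idx]) - min(d$start[idx]) + 1,
        max_gap = if (length(cg)) max(cg) else 0
      )
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble(species = character(), chromosome = character(),
                  group = character(), n = integer(), members = list(),
                  span = numeric(), max_gap = numeric()))
  }
  arrange(res, .data$species, .data$chromosome, desc(.data$n))
}

#' Species-by-group member count table
#'
#' @param members Tibble with `species` and `group` columns, one row per
#'   member gene.
#' @param groups Group levels to tabulate (defaults to the four canonical
#'   groups plus any others present).
#' @return Wide tibble (class `hes_counts`): one row per species, one column
#'   per group, plus `total`.
#' @export
count_table <- function(members, groups = NULL) {
  if (nrow(members) == 0L) {
    out <- tibble(species = character(), total = integer())
    class(out) <- c("hes_counts", class(out))
    return(out)
  }
  lvls <- groups %||% union(GROUP_LEVELS[GROUP_LEVELS %in% members$group],
                            sort(unique(members$group)))
  long <- members |>
    count(.data$species, .data$group) |>
    tidyr::complete(species = unique(members$species), group = lvls,
                    fill = list(n = 0L))
  wide <- tidyr::pivot_wider(long, names_from = "group", values_from = "n",
                             values_fill = 0L)
  wide <- wide[, c("species", lvls)]
  wide$total <- as.integer(rowSums(wide[, lvls, drop = FALSE]))
  class(wide) <- c("hes_counts", class(wide))
  wide
}

#' Wilcoxon rank-sum (Mann-Whitney) test, exact by enumeration
#'
#' Midranks handle ties; `W` is the rank sum of `x` and
#' `U = W - n1 (n1 + 1) / 2`. For `n1 + n2 <= exact_limit` the two-sided
#' p-value is computed by complete enumeration of the `choose(n, n1)`
#' equally likely assignments of the pooled midranks (`p = min(1, 2 *
#' min(P(W <= w), P(W >= w)))`); otherwise a normal approximation with
#' tie-corrected variance and continuity correction is used.
#'
#' @param x,y Numeric vectors (e.g. per-species gene counts of two
#'   lineages); both non-empty.
#' @param exact_limit Largest `n1 + n2` for exact enumeration (default 12).
#' @return Object of class `hes_ranksum`: `statistic` (W), `u_statistic`,
#'   `p_two_sided`, `method`, `n1`, `n2`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 12L) {
  if (length(x) == 0L || length(y) == 0L) abort("both groups must be non-empty")
  n1 <- length(x)
  n2 <- length(y)
  n <- n1 + n2
  ranks <- rank(c(x, y))
  W <- sum(ranks[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  if (n <= exact_limit) {
    combos <- combn(n, n1)
    sums <- colSums(matrix(ranks[combos], nrow = n1))
    p_le <- mean(sums <= W + 1e-9)
    p_ge <- mean(sums >= W - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(ranks)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  structure(list(statistic = W, u_statistic = U, p_two_sided = p,
                 method = method, n1 = n1, n2 = n2),
            class = "hes_ranksum")
}

#' @export
print.hes_ranksum <- function(x, ...) {
  cat("Wilcoxon rank-sum test (", x$method, ")\n",
      "W = ", x$statistic, ", U = ", x$u_statistic,
      ", n = (", x$n1, ", ", x$n2, "), two-sided p = ",
      signif(x$p_two_sided, 4), "\n", sep = "")
  invisible(x)
}

#' Tidy a rank-sum test result
#' @param x An `hes_ranksum` object.
#' @param ... Unused.
#' @return One-row tibble with the statistic, U, p-value, method and sizes.
#' @export
tidy.hes_ranksum <- function(x, ...) {
  tibble(statistic = x$statistic, u_statistic = x$u_statistic,
         p_value = x$p_two_sided, method = x$method, n1 = x$n1, n2 = x$n2)
}

#' @rdname tidy.hes_ranksum
#' @export
glance.hes_ranksum <- function(x, ...) tidy(x)

#' Test lineage-specific expansion of per-species gene counts
#'
#' Splits a count table into teleost and non-teleost species and runs
#' [wilcoxon_rank_sum()] on the per-species totals (or one group's counts).
#'
#' @param counts `hes_counts` table from [count_table()].
#' @param teleost_species Character vector of species treated as teleosts.
#' @param column Which column to compare (default `"total"`).
#' @return `hes_ranksum` with the compared vectors in
#'   `attr(, "group_values")`.
#' @export
expansion_test <- function(counts, teleost_species, column = "total") {
  is_tel <- counts$species %in% teleost_species
  if (!any(is_tel) || all(is_tel)) {
    abort("need at least one teleost and one non-teleost species")
  }
  x <- counts[[column]][is_tel]
  y <- counts[[column]][!is_tel]
  res <- wilcoxon_rank_sum(x, y)
  attr(res, "group_values") <- list(teleost = x, non_teleost = y)
  res
}
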