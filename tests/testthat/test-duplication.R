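# Tandem clusters, count tables, and the rank-sum expansion test.

test_that("the gap threshold splits chains as expected", {
  loci <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    species = "S", group = "HES1-7", chromosome = "chr1",
    start = c(1e5, 1e5 + 15e3, 1e5 + 75e3),
    end = c(1e5 + 4e3, 1e5 + 19e3, 1e5 + 79e3),
    strand = "+")
  # gaps: 11 kb and 56 kb
  cl <- detect_tandem_clusters(loci, gap_threshold = 40000)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n, 2L)
  expect_equal(cl$members[[1]], c("g1", "g2"))
  expect_error(detect_tandem_clusters(loci, gap_threshold = -1), "positive")
})

test_that("overlapping loci count as gap zero and strand is ignored", {
  loci <- tibble::tibble(
    gene_id = c("a", "b"), species = "S", group = "G", chromosome = "c",
    start = c(100, 500), end = c(1000, 1500), strand = c("+", "-"))
  cl <- detect_tandem_clusters(loci, gap_threshold = 10)
  expect_equal(cl$n, 2L)
  expect_equal(cl$max_gap, 0)
})

test_that("the 13 human loci hold no 40 kb cluster", {
  gt <- name_based_grouping(read_gene_table(
    system.file("extdata", "human_gene_table.tsv", package = "hesfam")))
  loci <- tibble::tibble(gene_id = gt$gene_symbol, species = "Human",
                         group = gt$group, chromosome = gt$chromosome,
                         start = gt$start, end = gt$end, strand = gt$strand)
  expect_equal(nrow(detect_tandem_clusters(loci, 40000)), 0L)
  expect_equal(length(brute_tandem(loci, 40000)), 0L)
})

test_that("chaining matches the brute-force oracle on random loci", {
  for (s in 1:6) {
    loci <- withr::with_seed(300 + s, {
      n <- 150
      tibble::tibble(
        gene_id = paste0("g", seq_len(n)),
        species = sample(c("A", "B"), n, TRUE),
        group = sample(c("G1", "G2"), n, TRUE),
        chromosome = sample(paste0("chr", 1:3), n, TRUE),
        start = sample.int(2e6, n),
        end = 0, strand = "+")
    })
    loci$end <- loci$start + 3000
    cl <- detect_tandem_clusters(loci, gap_threshold = 30000)
    got <- lapply(cl$members, sort)
    got <- got[order(vapply(got, paste, character(1), collapse = ","))]
    expect_equal(got, brute_tandem(loci, 30000))
    # partition: no locus in two clusters
    expect_false(anyDuplicated(unlist(cl$members)) > 0)
    # order invariance
    shuf <- withr::with_seed(s, loci[sample.int(nrow(loci)), ])
    cl2 <- detect_tandem_clusters(shuf, gap_threshold = 30000)
    got2 <- lapply(cl2$members, sort)
    got2 <- got2[order(vapply(got2, paste, character(1), collapse = ","))]
    expect_equal(got2, got)
  }
})

test_that("count tables cross-tabulate species by group with totals", {
  gt <- name_based_grouping(read_gene_table(
    system.file("extdata", "human_gene_table.tsv", package = "hesfam")))
  gt$species <- "Human"
  ct <- count_table(gt[, c("species", "group")])
  expect_equal(unlist(ct[ct$species == "Human",
                         c("HEY1/2/L", "DEC1/2", "HESL", "HES1-7")]),
               c(3L, 2L, 1L, 7L), ignore_attr = TRUE)
  expect_equal(ct$total, 13L)
  empty <- count_table(tibble::tibble(species = character(),
                                      group = character()))
  expect_equal(nrow(empty), 0L)
  expect_s3_class(autoplot(ct), "ggplot")
})

test_that("exact rank-sum enumeration matches hand values", {
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$u_statistic, 0)
  expect_equal(r$p_two_sided, 2 / 6)
  expect_equal(r$method, "exact")
  expect_equal(tidy(r)$p_value, 2 / 6)

  same <- wilcoxon_rank_sum(c(1, 2), c(1, 2))
  expect_equal(same$p_two_sided, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("exact p-values match full permutation enumeration (n <= 7)", {
  cases <- list(
    list(x = c(1, 5, 3), y = c(2, 8)),
    list(x = c(2, 2), y = c(2, 7, 1)),          # ties across groups
    list(x = c(10, 12, 9), y = c(4, 5, 6, 7)),
    list(x = 1, y = c(2, 3, 4)),
    list(x = c(3, 3, 3), y = c(3, 3))           # all tied
  )
  for (cs in cases) {
    expect_equal(wilcoxon_rank_sum(cs$x, cs$y)$p_two_sided,
                 perm_ranksum_p(cs$x, cs$y), tolerance = 1e-12)
  }
})

test_that("tie-free exact p-values agree with the reference implementation", {
  withr::with_seed(414, {
    for (k in 1:10) {
      n1 <- sample(2:4, 1)
      n2 <- sample(2:4, 1)
      v <- sample.int(100, n1 + n2)   # distinct values, no ties
      x <- v[seq_len(n1)]
      y <- v[-seq_len(n1)]
      expect_equal(wilcoxon_rank_sum(x, y)$p_two_sided,
                   stats::wilcox.test(x, y, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  })
})

test_that("the normal approximation tracks the exact tail at 6 vs 6", {
  withr::with_seed(515, {
    for (k in 1:10) {
      v <- sample.int(1000, 12)
      x <- v[1:6]
      y <- v[7:12]
      pe <- wilcoxon_rank_sum(x, y)$p_two_sided
      pn <- wilcoxon_rank_sum(x, y, exact_limit = 0L)$p_two_sided
      expect_lt(abs(pe - pn), 0.02)
    }
  })
})

test_that("doubled teleost counts are detected by the expansion test", {
  counts <- expected_count_table(generator_config())
  teleosts <- c("Zebrafish", "Fugu", "Tetraodon", "Stickleback", "Medaka",
                "Cavefish")
  res <- expansion_test(counts, teleosts)
  expect_lt(res$p_two_sided, 0.05)
  expect_equal(res$n1, 6L)
  vals <- attr(res, "group_values")
  expect_gt(min(vals$teleost), max(vals$non_teleost) - 1)
  expect_error(expansion_test(counts, counts$species), "non-teleost")
})
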