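# Distances, neighbor joining, resampling support, minimum-evolution oracle.

test_that("p-distance matches hand counts under each deletion mode", {
  aln <- tibble::tibble(id = c("a", "b"),
                        aligned = c("AAAA", "AAAT"))
  expect_equal(pdistance(aln, "complete")[1, 2], 0.25)
  ident <- tibble::tibble(id = c("a", "b"), aligned = c("AAAA", "AAAA"))
  expect_equal(pdistance(ident)[1, 2], 0)

  gapped <- tibble::tibble(
    id = c("a", "b", "c"),
    aligned = c("A-CDE", "AAC-E", "TACDE"))
  # pairwise: a/b compare cols 1,3,5 (0 mismatch); a/c cols 2:5 minus col2
  # gap in a -> cols 3,4,5 plus col1: cols 1,3,4,5 -> 1 mismatch? col1 A vs T
  d <- pdistance(gapped, "pairwise")
  expect_equal(d["a", "b"], 0 / 3)
  expect_equal(d["a", "c"], 1 / 4)
  expect_equal(d["b", "c"], 1 / 4)
  # complete deletion drops gapped columns 2 and 4
  dc <- pdistance(gapped, "complete")
  expect_equal(dc["a", "c"], 1 / 3)
  # partial with coverage 0.95 drops the same columns here
  dp <- pdistance(gapped, "partial", coverage = 0.95)
  expect_equal(dp, dc)
})

test_that("p-distance is a semimetric on random gapped alignments", {
  withr::with_seed(31, {
    for (k in 1:10) {
      rows <- vapply(1:5, function(i) {
        s <- strsplit(random_protein(40), "")[[1]]
        s[sample(40, 5)] <- "-"
        paste(s, collapse = "")
      }, character(1))
      aln <- tibble::tibble(id = paste0("s", 1:5), aligned = rows)
      d <- try(pdistance(aln, "pairwise"), silent = TRUE)
      if (inherits(d, "try-error")) next
      expect_equal(d, t(d))
      expect_true(all(diag(d) == 0))
      expect_true(all(d >= 0 & d <= 1))
    }
  })
})

test_that("a pair with no comparable columns is reported by name", {
  aln <- tibble::tibble(id = c("a", "b"), aligned = c("A--A", "-AA-"))
  expect_error(pdistance(aln, "pairwise"), "a and b")
})

test_that("three-taxon NJ solves the closed-form branch lengths", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("a", "b", "c")], c(a = 1, b = 1, c = 3))
})

test_that("NJ reconstructs additive trees exactly", {
  for (s in 1:20) {
    ra <- random_additive(5, seed = 400 + s)
    est <- nj_tree(ra$D)
    expect_true(same_topology(est, ra$tree))
    expect_equal(ape::cophenetic.phylo(est)[rownames(ra$D), colnames(ra$D)],
                 ra$D, tolerance = 1e-8)
  }
})

test_that("NJ agrees with an independent NJ implementation on topology", {
  for (s in 1:10) {
    ra <- random_additive(7, seed = 900 + s)
    D <- ra$D
    noisy <- withr::with_seed(s, {
      N <- D + matrix(runif(length(D), 0, 0.05), nrow(D))
      N <- (N + t(N)) / 2
      diag(N) <- 0
      N
    })
    expect_true(same_topology(nj_tree(noisy), ape::nj(noisy)))
  }
})

test_that("invalid distance matrices are rejected", {
  M <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(nj_tree(M), ">= 3|asymmetric")
  A <- matrix(0, 3, 3)
  A[1, 2] <- 5
  expect_error(nj_tree(A), "asymmetric")
  B <- matrix(c(0, Inf, Inf, 0), 2, 2)
  expect_error(nj_tree(B), "non-finite")
})

test_that("me_brute enumerates topologies and matches NJ on additive data", {
  ra <- random_additive(4, seed = 777)
  me <- me_brute(ra$D)
  expect_equal(attr(me, "n_topologies"), 3L)
  expect_true(same_topology(me, nj_tree(ra$D)))
  expect_error(me_brute(ra$D[1:3, 1:3]), "4 <= n")
})

test_that("ME total length never exceeds the NJ topology's OLS length", {
  for (s in 1:8) {
    ra <- random_additive(5, seed = 50 + s)
    noisy <- withr::with_seed(s, {
      N <- ra$D + matrix(runif(length(ra$D), 0, 0.4), nrow(ra$D))
      N <- (N + t(N)) / 2
      diag(N) <- 0
      N
    })
    me <- me_brute(noisy)
    expect_lte(attr(me, "total_length"),
               ols_tree_length(nj_tree(noisy), noisy) + 1e-9)
  }
})

test_that("resampling support is high for a strongly supported split", {
  block <- function(x, n) paste(rep(x, n), collapse = "")
  aln <- tibble::tibble(
    id = c("a", "b", "c", "d"),
    aligned = c(block("AW", 20), block("AW", 20),
                block("CY", 20), block("CY", 20)))
  tr <- support_resample(aln, n_replicates = 100, seed = 3)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_gte(max(sup, na.rm = TRUE), 95)
})

test_that("support is deterministic given the seed and warns when degenerate", {
  ds <- generate_dataset(small_config(seed = 12))
  mem <- ds$truth[ds$truth$is_member, ][1:6, ]
  seqs <- ds$proteome[match(mem$id, ds$proteome$id), ]
  aln <- progressive_align(tibble::tibble(id = seqs$id,
                                          sequence = seqs$sequence))
  t1 <- support_resample(aln, n_replicates = 30, seed = 8)
  t2 <- support_resample(aln, n_replicates = 30, seed = 8)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))

  flat <- tibble::tibble(id = letters[1:4], aligned = rep("AAAAAA", 4))
  expect_warning(tf <- support_resample(flat, n_replicates = 20, seed = 1),
                 "no variable columns")
  expect_true(all(tf$node.label %in% c("", "100")))
})
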