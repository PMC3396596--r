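# PSSM construction, scanning, empirical significance, membership calls,
# redundancy clustering.

test_that("build_profile implements the pseudocounted log-odds formula", {
  p <- build_profile(c("A", "A", "A", "A", "M", "M", "M", "M") |>
                       vapply(function(x) strrep(x, 5), character(1)),
                     beta = 1)
  # column of 8 residues, 4 A: p(A) = (4 + 0.05) / 9
  expect_equal(unname(p$probs[1, "A"]), (4 + 0.05) / 9)
  # single-residue column example: 4 sequences all A
  p2 <- build_profile(rep("AAAAA", 4), beta = 1)
  expect_equal(unname(p2$probs[1, "A"]), 0.81)
  expect_equal(unname(p2$logodds[1, "A"]), log2(0.81 / 0.05), tolerance = 1e-6)
  # absent residue keeps positive probability (no -Inf scores)
  expect_true(all(is.finite(p2$logodds)))
  expect_equal(unname(p2$probs[1, "W"]), 0.05 / 5)
})

test_that("gappy columns are dropped and degenerate seeds rejected", {
  seed <- c("AC-DEF", "AC-DEF", "A--DEF", "ACWDEF")  # col 3: 75% gaps
  p <- build_profile(seed)
  expect_equal(p$included_columns, c(1, 2, 4, 5, 6))
  expect_error(build_profile(c("AAA", "AAAA")), "unequal")
  expect_error(build_profile(c("---", "---", "---") |>
                               vapply(function(x) strrep(x, 3),
                                      character(1))),
               "gap threshold|columns")
})

test_that("scanning the consensus yields the maximum achievable score", {
  prof <- default_profile("bHLH")
  rec <- tibble::tibble(id = "c",
                        sequence = paste0(strrep("A", 15), prof$consensus,
                                          strrep("A", 15)))
  hits <- scan_profile(rec, prof)
  best <- hits[which.max(hits$score), ]
  expect_equal(best$start, 16L)
  expect_equal(best$end, 15L + prof$length)
  expect_equal(best$score, sum(apply(prof$logodds, 1, max)),
               tolerance = 1e-9)
  expect_false(best$truncated)
})

test_that("two planted non-overlapping copies give two hits", {
  prof <- default_profile("Orange")
  rec <- tibble::tibble(id = "two",
                        sequence = paste0(strrep("A", 10), prof$consensus,
                                          strrep("A", 12), prof$consensus,
                                          strrep("A", 10)))
  hits <- scan_profile(rec, prof)
  strong <- hits[hits$score > 0.8 * max(hits$score), ]
  expect_equal(nrow(strong), 2L)
})

test_that("short sequences yield an empty hit list", {
  prof <- default_profile("bHLH")
  short <- tibble::tibble(id = "s",
                          sequence = strrep("A", ceiling(prof$length / 2) - 1))
  expect_equal(nrow(scan_profile(short, prof)), 0L)
})

test_that("empirical p-values honour their definitional bounds", {
  prof <- default_profile("Orange")
  seqc <- random_protein(120)
  expect_equal(empirical_pvalue(Inf, seqc, prof, 100, seed = 1), 1 / 101)
  expect_equal(empirical_pvalue(-Inf - 0, seqc, prof, 100, seed = 1), 1)
  expect_error(empirical_pvalue(1, seqc, prof, n_shuffles = 50), ">= 100")
  # planted domain is significant
  planted <- paste0(strrep("K", 20), prof$consensus, strrep("K", 20))
  best <- max(scan_profile(planted, prof)$score)
  expect_lte(empirical_pvalue(best, planted, prof, 200, seed = 5), 0.005)
})

test_that("empirical p-values are super-uniform under the null", {
  prof <- default_profile("Orange")
  n_seq <- 500
  alpha <- 0.05
  hits <- withr::with_seed(99, {
    vapply(seq_len(n_seq), function(i) {
      s <- random_protein(60)
      w <- scan_profile(s, prof, score_floor = -Inf)
      best <- max(w$score)
      empirical_pvalue(best, s, prof, n_shuffles = 100,
                       seed = 7000 + i) <= alpha
    }, logical(1))
  })
  expect_lte(mean(hits), alpha + 3 * sqrt(alpha / n_seq))
})

test_that("membership calls recover planted architectures and reasons", {
  ds <- generate_dataset(small_config(seed = 5, mu = 0))
  mem <- call_membership(ds$proteome, default_profile("bHLH"),
                         default_profile("Orange"),
                         n_shuffles = 100, seed = 5)
  joined <- dplyr::left_join(ds$truth, mem, by = "id")
  expect_equal(joined$is_member.y, joined$is_member.x)  # precision & recall 1
  reasons <- joined$reason[!is.na(joined$decoy_type)]
  expected <- c(bhlh_only = "no_orange", orange_only = "no_bhlh",
                random = "no_bhlh", wrong_order = "wrong_order")
  expect_equal(reasons,
               unname(expected[joined$decoy_type[!is.na(joined$decoy_type)]]))
  # members are complete and domain coordinates exact
  m <- joined[joined$is_member.x, ]
  expect_true(all(m$complete))
  expect_equal(m$bhlh_start.y, m$bhlh_start.x)
  expect_equal(m$orange_end.y, m$orange_end.x)
})

test_that("membership is invariant to record order", {
  ds <- generate_dataset(small_config(seed = 6))
  recs <- ds$proteome[1:8, ]
  prof_b <- default_profile("bHLH")
  prof_o <- default_profile("Orange")
  m1 <- call_membership(recs, prof_b, prof_o, n_shuffles = 100, seed = 2)
  m2 <- call_membership(recs[rev(seq_len(nrow(recs))), ], prof_b, prof_o,
                        n_shuffles = 100, seed = 2)
  m2 <- m2[match(m1$id, m2$id), ]
  expect_equal(as.data.frame(m1), as.data.frame(m2))
})

test_that("deduplicate clusters by identity and is idempotent", {
  base <- random_protein(100)
  near <- sub("^(.{10})(.)", "\\1A", base)       # one substitution
  far <- random_protein(100)
  recs <- tibble::tibble(id = c("b", "n", "f"),
                         sequence = c(base, near, far))
  d <- deduplicate(recs)
  expect_equal(sum(d$is_representative), 2L)
  expect_equal(d$cluster_rep[d$id == "n"], d$cluster_rep[d$id == "b"])

  ident <- tibble::tibble(id = c("x", "y"), sequence = c(base, base))
  expect_equal(sum(deduplicate(ident)$is_representative), 1L)

  # 50% identity pair stays apart at threshold 0.9
  half <- paste0(substr(base, 1, 50), random_protein(50))
  two <- tibble::tibble(id = c("p", "q"), sequence = c(base, half))
  expect_equal(sum(deduplicate(two)$is_representative), 2L)

  # idempotence on representatives
  reps <- d[d$is_representative, c("id", "sequence")]
  d2 <- deduplicate(reps)
  expect_true(all(d2$is_representative))
  expect_error(deduplicate(recs, identity_threshold = 0.4), "0.5")
})

test_that("near-duplicates planted among distinct sequences collapse", {
  withr::with_seed(8, {
    s <- vapply(1:3, function(i) random_protein(120), character(1))
    near_dup <- s[1]
    substr(near_dup, 5, 10) <- "AAAAAA"   # ~95% identity to s[1]
    recs <- tibble::tibble(id = paste0("s", 1:5),
                           sequence = c(s, near_dup, random_protein(120)))
  })
  d <- deduplicate(recs)
  expect_equal(sum(d$is_representative), 4L)
})
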