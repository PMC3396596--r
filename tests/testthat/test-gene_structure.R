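# Phase arithmetic and structure-evolution event inference.

test_that("phase strings follow cumulative CDS length mod 3", {
  expect_equal(phases_from_lengths(c(2, 1, 3, 1, 2)), "2-0-0-1")
  expect_equal(phases_from_lengths(c(3, 3, 1, 2)), "0-0-1")
  expect_equal(phases_from_lengths(c(9)), "")   # single-exon gene
})

test_that("compute_phases reads gene models, flags frame and UTR exons", {
  models <- tibble::tibble(
    gene_id = c("g1", "g2"),
    transcript_id = c("g1.t", "g2.t"),
    species = "x", chromosome = "chr1", strand = "+",
    cds = list(
      tibble::tibble(start = c(1, 10, 20, 30, 40),
                     end = c(2, 10, 22, 30, 41)),   # lengths 2,1,3,1,2
      tibble::tibble(start = 1, end = 10)           # one exon, 10 nt
    ),
    utr_exons = c(0L, 1L)
  )
  ph <- compute_phases(models)
  expect_equal(ph$phase_string, c("2-0-0-1", ""))
  expect_equal(ph$in_frame, c(TRUE, FALSE))
  expect_equal(ph$n_exons, c(5L, 1L))
  expect_equal(ph$utr_exons, c(0L, 1L))
})

test_that("phases are invariant under strand mirroring", {
  ds <- generate_dataset(small_config(seed = 21))
  models <- ds$models[1:10, ]
  mirrored <- models
  for (i in seq_len(nrow(mirrored))) {
    seg <- mirrored$cds[[i]]
    # mirror coordinates around a fixed point and flip the strand
    m <- 1e6
    mirrored$cds[[i]] <- tibble::tibble(start = m - seg$end,
                                        end = m - seg$start)
    mirrored$strand[i] <- if (mirrored$strand[i] == "+") "-" else "+"
  }
  expect_equal(compute_phases(mirrored)$phase_string,
               compute_phases(models)$phase_string)
})

test_that("minimal event scripts reproduce the canonical transitions", {
  e1 <- infer_events("0-0-1", "2-0-0-1")
  expect_equal(e1$cost, 1L)
  expect_equal(e1$events$type, "EXON_LOSS_5P")

  e2 <- infer_events("2-0-1", "2-0-0-1")
  expect_equal(e2$cost, 1L)
  expect_equal(e2$events$type, "INTRON_LOSS")
  expect_equal(e2$events$position, 3L)  # the third intron is the one lost

  e3 <- infer_events("2-0-0-1", "2-0-0-1")
  expect_equal(e3$cost, 0L)
  expect_equal(nrow(e3$events), 0L)

  e4 <- infer_events("2-0-0-0-1", "2-0-0-1")
  expect_equal(e4$cost, 1L)
  expect_equal(e4$events$type, "INTRON_GAIN")
})

test_that("scripts replay onto the reference to give the query exactly", {
  withr::with_seed(77, {
    for (k in 1:40) {
      q <- paste(sample(0:2, sample(0:6, 1), replace = TRUE), collapse = "-")
      ev <- infer_events(q, "2-0-0-1")
      expect_false(ev$unalignable)
      expect_equal(apply_events("2-0-0-1", ev$events), q)
    }
  })
})

# Independent oracle: depth-first enumeration of every script up to a cost
# bound, without visited-state pruning.
brute_min_cost <- function(query, reference, max_cost = 3L) {
  q <- strsplit(query, "-")[[1]]
  if (identical(query, "")) q <- character(0)
  ref <- strsplit(reference, "-")[[1]]
  apply1 <- function(p, op) {
    if (op$t == "L5") return(p[-1])
    if (op$t == "L3") return(p[-length(p)])
    if (op$t == "IL") return(p[-op$pos])
    append(p, op$v, after = op$pos)
  }
  ops_for <- function(p) {
    out <- list()
    if (length(p) > 0) {
      out <- c(out, list(list(t = "L5"), list(t = "L3")))
      for (i in seq_along(p)) out <- c(out, list(list(t = "IL", pos = i)))
    }
    for (pos in 0:length(p)) {
      for (v in c("0", "1", "2")) {
        out <- c(out, list(list(t = "IG", pos = pos, v = v)))
      }
    }
    out
  }
  best <- Inf
  rec <- function(p, cost) {
    if (identical(p, q)) {
      best <<- min(best, cost)
      return()
    }
    if (cost >= max_cost || cost >= best) return()
    for (op in ops_for(p)) rec(apply1(p, op), cost + 1L)
  }
  rec(ref, 0L)
  best
}

test_that("inferred cost is minimal against exhaustive enumeration", {
  withr::with_seed(55, {
    cases <- unique(vapply(1:25, function(k) {
      paste(sample(0:2, sample(2:5, 1), replace = TRUE), collapse = "-")
    }, character(1)))
  })
  for (q in cases) {
    oracle <- brute_min_cost(q, "2-0-0-1", max_cost = 3L)
    ev <- infer_events(q, "2-0-0-1")
    if (is.finite(oracle)) {
      expect_equal(ev$cost, as.integer(oracle), info = q)
    } else {
      expect_gte(ev$cost, 3L)
    }
  }
})

test_that("queries beyond the cost bound are flagged unalignable", {
  ev <- infer_events("1-1-1-1-1-1-1", "2-0-0-1", max_cost = 2L)
  expect_true(ev$unalignable)
  expect_true(is.na(ev$cost))
})

test_that("structure_report summarises genes with modal group phases", {
  ds <- generate_dataset(small_config(seed = 22))
  groups <- tibble::tibble(leaf_id = ds$truth$id[ds$truth$is_member],
                           group = ds$truth$group[ds$truth$is_member])
  rep <- structure_report(ds$models, groups)
  expect_equal(nrow(rep), nrow(ds$models))
  tr <- ds$truth[match(rep$gene_id, ds$truth$id), ]
  expect_equal(rep$phase_string, tr$phase_string)
  # HEY-group genes built on the ancestral template need no events
  hey <- rep[rep$group == "HEY1/2/L", ]
  expect_true(all(hey$events == ""))
  expect_equal(unique(hey$group_modal_phase), "2-0-0-1")
  # HES-group genes built on the derived template show one 5' exon loss
  hes <- rep[rep$group == "HES1-7", ]
  expect_true(all(hes$events == "EXON_LOSS_5P@1"))
  expect_equal(unique(hes$group_modal_phase), "0-0-1")
})

test_that("structure diagrams are deterministic and track per gene", {
  models <- tibble::tibble(
    gene_id = "g", transcript_id = "g.t", species = "x",
    chromosome = "chr1", strand = "+",
    cds = list(tibble::tibble(start = c(1, 200), end = c(90, 300))),
    utr_exons = 0L)
  svg <- render_structure_diagram(models)
  expect_identical(svg, render_structure_diagram(models))
  expect_equal(sum(grepl("<rect", svg)), 2L)       # two exon boxes
  expect_equal(sum(grepl("<line", svg)), 1L)       # one intron
  expect_equal(sum(grepl(">0<|>1<|>2<", svg)), 1L) # one phase digit

  ds <- generate_dataset(small_config(seed = 23))
  svg13 <- render_structure_diagram(ds$models[1:13, ])
  expect_equal(sum(grepl("font-family", svg13)), 13L)  # one label per track
  p <- plot_gene_structure(ds$models[1:5, ])
  expect_s3_class(p, "ggplot")
})
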