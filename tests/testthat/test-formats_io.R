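# Readers and writers for FASTA, GFF3, gene tables and Newick.

test_that("read_fasta parses headers, species tags, and validates", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MKV", ">b", "WRPW"), f)
  recs <- read_fasta(f)
  expect_equal(recs$id, c("a", "b"))
  expect_equal(recs$sequence, c("MKV", "WRPW"))
  expect_equal(recs$species, c("unknown", "unknown"))

  writeLines(c(">Zebrafish|ENSDARP00000094981 some desc", "MKVW"), f)
  r <- read_fasta(f)
  expect_equal(r$id, "ENSDARP00000094981")
  expect_equal(r$species, "Zebrafish")
  expect_equal(r$description, "some desc")

  writeLines(c(">a", "MKB?V"), f)   # unknowns map to X
  expect_equal(read_fasta(f, moltype = "protein")$sequence, "MKXXV")

  writeLines(c(">a", "MKV", ">a", "MW"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")
})

test_that("FASTA round-trips 50 random records", {
  withr::with_seed(42, {
    recs <- tibble::tibble(
      id = paste0("id", 1:50),
      species = sample(c("Human", "Zebrafish", "unknown"), 50,
                       replace = TRUE),
      sequence = vapply(1:50, function(i) {
        random_protein(sample(10:80, 1))
      }, character(1)),
      moltype = "protein",
      description = ""
    )
  })
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f)
  back <- read_fasta(f)
  expect_equal(as.data.frame(back), as.data.frame(recs))
})

test_that("read_gff3 groups CDS per transcript in transcription order", {
  f <- withr::local_tempfile(fileext = ".gff3")
  gff <- c("##gff-version 3",
           "chr1\tx\tgene\t101\t206\t.\t+\t.\tID=g1",
           "chr1\tx\tmRNA\t101\t206\t.\t+\t.\tID=t1;Parent=g1",
           "chr1\tx\tCDS\t101\t103\t.\t+\t0\tParent=t1",
           "chr1\tx\tCDS\t201\t206\t.\t+\t0\tParent=t1")
  writeLines(gff, f)
  m <- read_gff3(f)
  expect_equal(m$gene_id, "g1")
  expect_equal(m$cds[[1]]$start, c(101, 201))

  writeLines(gsub("\\t\\+\\t", "\t-\t", gff), f)
  m2 <- read_gff3(f)
  expect_equal(m2$cds[[1]]$start, c(201, 101))  # transcription order reversed
  expect_equal(m2$strand, "-")

  writeLines(c("##gff-version 3",
               "chr1\tx\tCDS\t1\t9\t.\t+\t0\tID=orphan"), f)
  expect_error(read_gff3(f), "Parent")

  writeLines(c("##gff-version 3",
               "chr1\tx\tmRNA\t1\t30\t.\t+\t.\tID=t1",
               "chr1\tx\tCDS\t1\t10\t.\t+\t0\tParent=t1",
               "chr1\tx\tCDS\t5\t20\t.\t+\t0\tParent=t1"), f)
  expect_error(read_gff3(f), "overlapping")

  writeLines(c("chr1\tx\tgene\t1\t2\t.\t+\t.\tID=g"), f)
  expect_error(read_gff3(f), "gff-version")
})

test_that("gene models round-trip through GFF3, including UTR exon counts", {
  ds <- generate_dataset(small_config(seed = 3))
  models <- ds$models[1:20, ]
  models$utr_exons[1] <- 2L
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(models, f)
  back <- read_gff3(f)
  back <- back[match(models$transcript_id, back$transcript_id), ]
  expect_equal(back$gene_id, models$gene_id)
  expect_equal(back$strand, models$strand)
  expect_equal(back$utr_exons, models$utr_exons)
  for (i in seq_len(nrow(models))) {
    expect_equal(as.data.frame(back$cds[[i]]),
                 as.data.frame(models$cds[[i]]))
  }
})

test_that("read_gene_table validates the curated human table", {
  path <- system.file("extdata", "human_gene_table.tsv", package = "hesfam")
  gt <- read_gene_table(path)
  expect_equal(nrow(gt), 13L)
  expect_equal(nrow(attr(gt, "rejected")), 0L)
  hey1 <- gt[gt$gene_symbol == "HEY1", ]
  expect_equal(hey1$protein_length, 308)
  expect_equal(hey1$chromosome, "8")
  expect_equal(hey1$strand, "-")

  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_symbol\tprotein_length\tlocation",
               "GOOD\t100\tChr:1:500:900:1",
               "BAD\t100\tChr:1:900:500:1",
               "UGLY\t100\tnot-a-location"), f)
  gt2 <- read_gene_table(f)
  expect_equal(gt2$gene_symbol, "GOOD")
  rej <- attr(gt2, "rejected")
  expect_setequal(rej$gene_symbol, c("BAD", "UGLY"))
  expect_true("start >= end" %in% rej$reason)
  expect_true("malformed location" %in% rej$reason)
})

test_that("write_newick emits fixed-precision lengths and support labels", {
  star <- ape::read.tree(text = "(a:1,b:1,c:3);")
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(star, f)
  expect_equal(readLines(f), "(a:1.000000,b:1.000000,c:3.000000);")

  t4 <- ape::read.tree(text = "((a:1,b:1):0.5,(c:1,d:1):0.5);")
  t4$node.label <- c("", "98", "77")
  write_newick(t4, f)
  expect_match(readLines(f), "\\)98:", fixed = FALSE)
  back <- read_newick(f)
  expect_true("98" %in% back$node.label)

  dup <- ape::read.tree(text = "(a:1,a:1,b:1);")
  expect_error(write_newick(dup, f), "duplicate")
})

test_that("Newick round-trips 30 random trees with lengths and supports", {
  f <- withr::local_tempfile(fileext = ".nwk")
  for (s in 1:30) {
    tr <- withr::with_seed(1000 + s, {
      t <- ape::rtree(sample(4:12, 1))
      t$node.label <- as.character(sample(50:100, t$Nnode, replace = TRUE))
      t
    })
    write_newick(tr, f)
    back <- read_newick(f)
    expect_true(same_topology(tr, back))
    expect_equal(sort(back$edge.length), sort(tr$edge.length),
                 tolerance = 1e-6)
    expect_setequal(setdiff(back$node.label, ""),
                    setdiff(tr$node.label, ""))
  }
})
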