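#' Read a protein or nucleotide FASTA file into a sequence tibble
#'
#' Headers following the `Species|ID description` convention used throughout
#' the package (and in the figures of comparative gene-family studies) are
#' split into a species tag and a record id. Headers without a `|` yield
#' species `"unknown"` and use the first whitespace-delimited token as the id.
#'
#' Residues outside the declared alphabet are mapped to `X` (protein) or `N`
#' (nucleotide).
#'
#' @param path Path to a FASTA file.
#' @param moltype `"auto"` (default), `"protein"` or `"nucleotide"`.
#' @return A tibble with columns `id`, `species`, `sequence`, `moltype`,
#'   `description`, one row per record in file order.
#' @export
read_fasta <- function(path, moltype = c("auto", "protein", "nucleotide")) {
  moltype <- match.arg(moltype)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(paste0("empty FASTA file: ", path))
  headers <- names(set)
  token <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  has_bar <- grepl("|", token, fixed = TRUE)
  species <- ifelse(has_bar, sub("\\|.*$", "", token), "unknown")
  id <- ifelse(has_bar, sub("^[^|]*\\|", "", token), token)
  if (anyDuplicated(id)) {
    dups <- unique(id[duplicated(id)])
    abort(paste0("duplicate FASTA ids: ", paste(dups, collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) abort("FASTA contains empty sequences")
  if (moltype == "auto") {
    nt_like <- grepl("^[ACGTUN-]+$", seqs)
    moltype <- if (all(nt_like)) "nucleotide" else "protein"
  }
  if (moltype == "protein") {
    clean <- gsub(paste0("[^", paste(AA_ALPHABET, collapse = ""), "X-]"),
                  "X", seqs)
  } else {
    clean <- gsub("U", "T", seqs, fixed = TRUE)
    clean <- gsub("[^ACGTN-]", "N", clean)
  }
  tibble(id = unname(id), species = unname(species),
         sequence = unname(clean), moltype = moltype,
         description = unname(description))
}

#' Write a sequence tibble to FASTA
#'
#' Headers are written as `Species|ID description`; records with species
#' `"unknown"` get a bare `ID` header so that [read_fasta()] round-trips.
#'
#' @param records Tibble with at least `id` and `sequence`; optional
#'   `species`, `description`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  species <- records[["species"]] %||% rep("unknown", nrow(records))
  desc <- records[["description"]] %||% rep("", nrow(records))
  lines <- character(0)
  for (i in seq_len(nrow(records))) {
    head_tok <- if (identical(species[i], "unknown") || !nzchar(species[i])) {
      records$id[i]
    } else {
      paste0(species[i], "|", records$id[i])
    }
    header <- if (nzchar(desc[i])) paste(head_tok, desc[i]) else head_tok
    seq <- records$sequence[i]
    starts <- seq(1L, nchar(seq), by = width)
    lines <- c(lines, paste0(">", header),
               substring(seq, starts, pmin(starts + width - 1L, nchar(seq))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models (gene/mRNA/CDS) from a GFF3 file
#'
#' CDS segments are grouped per transcript via their `Parent` attributes and
#' ordered in transcription direction (descending coordinates on the `-`
#' strand). Coordinates stay 1-based inclusive. Exon features carrying no CDS
#' are counted per transcript as `utr_exons`.
#'
#' @param path Path to a GFF3 file (the `##gff-version 3` directive is
#'   required).
#' @return A gene-model tibble with one row per transcript: `gene_id`,
#'   `transcript_id`, `species`, `chromosome`, `strand`, `cds` (list column
#'   of tibbles with `start`, `end` in transcription order), `utr_exons`.
#' @export
read_gff3 <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^##gff-version\\s+3", first)) {
    abort("missing ##gff-version 3 directive")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  type <- as.character(df$type)
  cds <- df[type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) abort("GFF3 contains no CDS features")
  parents <- cds$Parent
  if (is.null(parents) || any(lengths(parents) == 0L)) {
    abort("CDS feature without Parent")
  }
  mrna <- df[type == "mRNA", , drop = FALSE]
  gene_of <- setNames(
    vapply(mrna$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1)),
    unlist(mrna$ID)
  )
  species_of <- if ("species" %in% names(mrna)) {
    setNames(as.character(mrna$species), unlist(mrna$ID))
  } else {
    character(0)
  }
  exon <- df[type == "exon", , drop = FALSE]

  cds_long <- tibble(
    transcript_id = vapply(parents, function(p) p[[1]], character(1)),
    chromosome = as.character(cds$seqnames),
    strand = as.character(cds$strand),
    start = cds$start, end = cds$end
  )
  out <- cds_long |>
    group_by(.data$transcript_id) |>
    dplyr::group_modify(function(d, key) {
      d <- arrange(d, .data$start)
      if (nrow(d) > 1L && any(d$start[-1] <= d$end[-nrow(d)])) {
        abort(paste0("overlapping CDS in transcript ", key$transcript_id))
      }
      if (d$strand[1] == "-") d <- d[rev(seq_len(nrow(d))), ]
      tibble(chromosome = d$chromosome[1], strand = d$strand[1],
             cds = list(tibble(start = d$start, end = d$end)))
    }) |>
    ungroup()

  # count exons with no CDS overlap (UTR-only exons)
  utr_count <- function(tid, chrom) {
    ex <- exon[vapply(exon$Parent, function(p) tid %in% p, logical(1)), ,
               drop = FALSE]
    if (nrow(ex) == 0L) return(0L)
    seg <- cds_long[cds_long$transcript_id == tid, ]
    sum(vapply(seq_len(nrow(ex)), function(i) {
      !any(ex$start[i] <= seg$end & ex$end[i] >= seg$start)
    }, logical(1)))
  }
  out$utr_exons <- unname(vapply(out$transcript_id, utr_count,
                                 integer(1), chrom = NULL))
  out$gene_id <- ifelse(out$transcript_id %in% names(gene_of),
                        gene_of[out$transcript_id], out$transcript_id)
  out$species <- ifelse(out$transcript_id %in% names(species_of),
                        species_of[out$transcript_id], "unknown")
  select(out, "gene_id", "transcript_id", "species", "chromosome",
         "strand", "cds", "utr_exons")
}

#' Write a gene-model tibble as GFF3
#'
#' Emits gene, mRNA, CDS and exon rows. UTR-only exons (`utr_exons` > 0) are
#' synthesised upstream of the first coding exon so that [read_gff3()]
#' round-trips the count.
#'
#' @param models Gene-model tibble as returned by [read_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    seg <- m$cds[[1]]
    genomic <- arrange(seg, .data$start)
    utr_n <- m[["utr_exons"]] %||% 0L
    utr_n <- if (is.na(utr_n)) 0L else utr_n
    utr <- NULL
    if (utr_n > 0L) {
      # synthetic UTR exons on the 5' side, 100 bp each, 100 bp apart
      if (m$strand == "+") {
        e <- min(genomic$start) - 100L - 200L * (seq_len(utr_n) - 1L)
        utr <- tibble(start = e - 99L, end = e)
      } else {
        s <- max(genomic$end) + 100L + 200L * (seq_len(utr_n) - 1L)
        utr <- tibble(start = s, end = s + 99L)
      }
    }
    all_start <- min(c(genomic$start, utr$start))
    all_end <- max(c(genomic$end, utr$end))
    gid <- m$gene_id
    tid <- m$transcript_id
    lines <- c(
      lines,
      sprintf("%s\thesfam\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              m$chromosome, all_start, all_end, m$strand, gid),
      sprintf("%s\thesfam\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s;species=%s",
              m$chromosome, all_start, all_end, m$strand, tid, gid, m$species)
    )
    exons <- bind_rows(genomic, utr) |> arrange(.data$start)
    lines <- c(lines, sprintf(
      "%s\thesfam\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
      m$chromosome, exons$start, exons$end, m$strand, tid))
    phase_codes <- gff_cds_phases(m$cds[[1]])
    genomic_order <- order(seg$start)
    lines <- c(lines, sprintf(
      "%s\thesfam\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
      m$chromosome, seg$start[genomic_order], seg$end[genomic_order],
      m$strand, phase_codes[genomic_order], tid))
  }
  writeLines(lines, path)
  invisible(path)
}

# GFF3 CDS phase column (bases to skip), from transcription-ordered segments.
gff_cds_phases <- function(seg) {
  lens <- seg$end - seg$start + 1L
  prior <- c(0L, cumsum(lens)[-length(lens)])
  (3L - prior %% 3L) %% 3L
}

#' Read a curated gene table (TSV)
#'
#' Expects the tab-delimited schema of curated HES/HEY gene tables:
#' `gene_symbol`, `ncbi_gene_id`, `full_name`, `ensembl_gene_id`,
#' `ensembl_protein_id`, `protein_length`, and either a single `location`
#' column (`Chr:<chrom>:<start>:<end>:<strand>` or
#' `<chrom>:<start>-<end>:<strand>` with strand +1/-1) or separate
#' `chromosome`, `start`, `end`, `strand` columns.
#'
#' Rows violating invariants (start >= end, non-positive protein length,
#' malformed location, strand outside +1/-1) are dropped; they are reported
#' in the `"rejected"` attribute of the result with a reason each.
#'
#' @param path Path to the TSV file.
#' @return A validated tibble with strand normalised to `+`/`-`; rejected
#'   rows (with `reason`) in `attr(, "rejected")`.
#' @export
read_gene_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         progress = FALSE)
  names(raw) <- tolower(gsub("[^A-Za-z0-9]+", "_", names(raw)))
  need <- c("gene_symbol", "protein_length")
  if (!all(need %in% names(raw))) {
    abort(paste0("gene table missing columns: ",
                 paste(setdiff(need, names(raw)), collapse = ", ")))
  }
  if (!all(c("chromosome", "start", "end", "strand") %in% names(raw))) {
    if (!"location" %in% names(raw)) {
      abort("gene table needs either a location column or chromosome/start/end/strand")
    }
    loc <- parse_location(raw$location)
    raw$chromosome <- loc$chromosome
    raw$start <- loc$start
    raw$end <- loc$end
    raw$strand <- loc$strand
  } else {
    raw$strand <- as.character(raw$strand)
  }
  raw$strand[raw$strand %in% c("+1", "1")] <- "+"
  raw$strand[raw$strand == "-1"] <- "-"

  reason <- rep(NA_character_, nrow(raw))
  bad_loc <- is.na(raw$chromosome) | is.na(raw$start) | is.na(raw$end)
  reason[bad_loc] <- "malformed location"
  coord <- !bad_loc & (raw$start >= raw$end)
  reason[coord] <- "start >= end"
  plen <- is.na(raw$protein_length) | raw$protein_length <= 0
  reason[plen & is.na(reason)] <- "protein_length <= 0"
  strd <- !(raw$strand %in% c("+", "-"))
  reason[strd & is.na(reason)] <- "invalid strand"

  ok <- is.na(reason)
  out <- as_tibble(raw[ok, , drop = FALSE])
  rejected <- as_tibble(raw[!ok, , drop = FALSE])
  rejected$reason <- reason[!ok]
  attr(out, "rejected") <- rejected
  out
}

# Parse "Chr:8:80676248:80680092:-1" / "8:80676248-80680092:-1" location
# strings into chromosome/start/end/strand; unparseable entries become NA.
parse_location <- function(x) {
  x <- gsub("∶", ":", x)        # full-width ratio colon, as printed
  x <- sub("^[Cc]hr:?", "", x)
  m <- regmatches(x, regexec(
    "^([^:]+):([0-9]+)[-:]([0-9]+):?([+-]?1)$", x))
  parsed <- lapply(m, function(g) {
    if (length(g) == 5L) g[-1] else rep(NA_character_, 4L)
  })
  tibble(
    chromosome = vapply(parsed, `[`, character(1), 1L),
    start = suppressWarnings(as.numeric(vapply(parsed, `[`, character(1), 2L))),
    end = suppressWarnings(as.numeric(vapply(parsed, `[`, character(1), 3L))),
    strand = vapply(parsed, `[`, character(1), 4L)
  )
}

#' Write / read phylogenetic trees in Newick format
#'
#' `write_newick()` serialises an `ape::phylo` tree with branch lengths at
#' fixed 6-decimal precision and internal-node support values (from
#' `node.label`) as node labels, so that `read_newick(write_newick(t))`
#' reproduces topology, lengths (to 1e-6) and supports.
#'
#' @param tree An `ape::phylo` object with >= 2 uniquely named leaves.
#' @param path Output (or input) path.
#' @return `write_newick()` returns `path` invisibly; `read_newick()` returns
#'   an `ape::phylo`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) abort("tree must have >= 2 leaves")
  if (anyDuplicated(tree$tip.label)) abort("duplicate leaf names")
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  brlen <- tree$edge.length %||% rep(NA_real_, nrow(tree$edge))
  lab <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    if (!is.null(tree$node.label)) {
      l <- tree$node.label[node - n_tip]
      if (!is.na(l) && nzchar(l)) return(l)
    }
    ""
  }
  render <- function(node) {
    e <- kids[[as.character(node)]]
    if (is.null(e)) return(lab(node))
    parts <- vapply(e, function(i) {
      child <- tree$edge[i, 2]
      s <- render(child)
      if (!is.na(brlen[i])) s <- paste0(s, ":", fmt_brlen(brlen[i]))
      s
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")", lab(node))
  }
  writeLines(paste0(render(root), ";"), path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) abort(paste0("could not parse Newick file: ", path))
  if (anyDuplicated(tree$tip.label)) abort("duplicate leaf names")
  tree
}
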