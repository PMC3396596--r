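# Synthetic dataset generator with known truth.
#
# Emits a proteome (planted dual-domain members plus decoys), gene models
# realising group-specific intron phase templates, genomic loci with planted
# tandem arrays, and a truth table, all deterministically from one seed.

#' Locate the packaged synthetic seed alignments
#'
#' @param domain `"bHLH"` or `"Orange"`.
#' @return Path to the aligned FASTA seed fixture.
#' @export
seed_alignment_path <- function(domain = c("bHLH", "Orange")) {
  domain <- match.arg(domain)
  file <- if (domain == "bHLH") "bhlh_seed_synthetic.fasta"
          else "orange_seed_synthetic.fasta"
  system.file("extdata", file, package = "hesfam", mustWork = TRUE)
}

#' Default profiles built from the packaged seed alignments
#' @param domain `"bHLH"` or `"Orange"`.
#' @return A `profile_model`.
#' @export
default_profile <- function(domain = c("bHLH", "Orange")) {
  domain <- match.arg(domain)
  key <- paste0("profile_", domain)
  if (is.null(the[[key]])) {
    the[[key]] <- build_profile(read_fasta(seed_alignment_path(domain)),
                                name = domain)
  }
  the[[key]]
}

#' Configuration for the synthetic dataset generator
#'
#' Defaults encode the study conditions the package is exercised under: two
#' clades of six species (teleost and non-teleost), the four family groups,
#' teleost per-group counts doubled relative to non-teleost (the expansion
#' pattern under test), within-group substitution rate `mu = 0.05`, one
#' planted 7-gene tandem array in zebrafish, ancestral 2-0-0-1 structure for
#' HEY1/2/L and DEC1/2 versus the first-exon-lost 0-0-1 for HESL and HES1-7,
#' and group-specific C-terminal tetrapeptides with a 10% degenerate-variant
#' rate.
#'
#' @param seed Integer seed; every downstream draw flows from it.
#' @param mu Per-residue substitution probability within a group (0-0.3).
#' @param group_divergence Substitution probability from the family
#'   ancestor to each group ancestor (keeps groups phylogenetically
#'   separable).
#' @param counts_non_teleost,counts_teleost Named per-group gene counts per
#'   species.
#' @param species Species tibble (`name`, `is_teleost`, `n_chromosomes`,
#'   `chrom_length`).
#' @param decoys Named counts per species: `bhlh_only`, `orange_only`,
#'   `random`, `wrong_order`.
#' @param tandem_arrays Tibble of planted arrays (`species`, `group`,
#'   `size`, `gap_min`, `gap_max`).
#' @param tetrapeptides Named map group -> planted motif class (`WRPW`,
#'   `YRPW`, `FRPW`, `ABSENT`).
#' @param degeneracy_prob Probability a planted WRPW/YRPW motif is replaced
#'   by a degenerate W variant.
#' @param structure_templates Named map group -> intron phase string.
#' @param anchor_species Species whose member genes serve as group anchors.
#' @param linker_range,flank_n_range,flank_c_range,intron_range,min_exon_nt
#'   Length parameters (residues / nt).
#' @return List of class `generator_config`.
#' @export
generator_config <- function(
    seed = 17L,
    mu = 0.05,
    group_divergence = 0.25,
    counts_non_teleost = c("HEY1/2/L" = 2L, "DEC1/2" = 1L, "HESL" = 1L,
                           "HES1-7" = 3L),
    counts_teleost = 2L * counts_non_teleost,
    species = NULL,
    decoys = c(bhlh_only = 1L, orange_only = 1L, random = 1L,
               wrong_order = 1L),
    tandem_arrays = tibble(species = "Zebrafish", group = "HES1-7",
                           size = 7L, gap_min = 5000, gap_max = 35000),
    tetrapeptides = c("HEY1/2/L" = "YRPW", "DEC1/2" = "ABSENT",
                      "HESL" = "ABSENT", "HES1-7" = "WRPW"),
    degeneracy_prob = 0.1,
    structure_templates = c("HEY1/2/L" = "2-0-0-1", "DEC1/2" = "2-0-0-1",
                            "HESL" = "0-0-1", "HES1-7" = "0-0-1"),
    anchor_species = "Human",
    linker_range = c(15L, 40L),
    flank_n_range = c(5L, 20L),
    flank_c_range = c(10L, 30L),
    intron_range = c(200L, 1500L),
    min_exon_nt = 30L) {
  if (mu < 0 || mu > 0.3) abort("mu must be in [0, 0.3]")
  if (is.null(species)) {
    species <- tibble(
      name = c("Human", "Mouse", "Chicken", "Lizard", "Frog", "Shark",
               "Zebrafish", "Fugu", "Tetraodon", "Stickleback", "Medaka",
               "Cavefish"),
      is_teleost = rep(c(FALSE, TRUE), each = 6L),
      n_chromosomes = 4L,
      chrom_length = 3e6
    )
  }
  if (any(counts_non_teleost < 0) || any(counts_teleost < 0)) {
    abort("gene counts must be non-negative")
  }
  structure(
    list(seed = as.integer(seed), mu = mu,
         group_divergence = group_divergence,
         counts_non_teleost = counts_non_teleost,
         counts_teleost = counts_teleost,
         species = species, decoys = decoys,
         tandem_arrays = tandem_arrays, tetrapeptides = tetrapeptides,
         degeneracy_prob = degeneracy_prob,
         structure_templates = structure_templates,
         anchor_species = anchor_species,
         linker_range = linker_range, flank_n_range = flank_n_range,
         flank_c_range = flank_c_range, intron_range = intron_range,
         min_exon_nt = min_exon_nt),
    class = "generator_config"
  )
}

DEGENERATE_VARIANTS <- c("VLGW", "VQGW", "AQGW", "GSGW", "AQAW")

sample_from_profile <- function(profile) {
  vapply(seq_len(profile$length), function(j) {
    sample(AA_ALPHABET, 1L, prob = profile$probs[j, ])
  }, character(1))
}

mutate_chars <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a) {
      sample(setdiff(AA_ALPHABET, a), 1L)
    }, character(1))
  }
  chars
}

rand_residues <- function(n, exclude = character(0)) {
  paste(sample(setdiff(AA_ALPHABET, exclude), n, replace = TRUE),
        collapse = "")
}

runif_int <- function(range) {
  if (range[1] >= range[2]) return(as.integer(range[1]))
  as.integer(sample(seq(range[1], range[2]), 1L))
}

# Cumulative CDS cut points realising a phase template exactly.
cuts_for_phases <- function(phases, total, min_exon) {
  n_ex <- length(phases) + 1L
  if (n_ex == 1L) return(integer(0))
  base <- round(total * seq_len(n_ex - 1L) / n_ex)
  cuts <- base + (phases - base) %% 3L
  for (i in seq_along(cuts)) {
    lo <- if (i == 1L) min_exon else cuts[i - 1L] + min_exon
    while (cuts[i] < lo) cuts[i] <- cuts[i] + 3L
  }
  if (total - cuts[length(cuts)] < min_exon) {
    abort("protein too short to realise the phase template")
  }
  as.integer(cuts)
}

# Build a gene model (cds tibble in transcription order) for one gene.
build_gene_model <- function(plen, phases, start_pos, strand, cfg) {
  total <- 3L * plen + 3L
  cuts <- cuts_for_phases(phases, total, cfg$min_exon_nt)
  exon_lens <- diff(c(0L, cuts, total))
  n_int <- length(exon_lens) - 1L
  intron_lens <- if (n_int > 0L) {
    vapply(seq_len(n_int), function(i) runif_int(cfg$intron_range),
           integer(1))
  } else {
    integer(0)
  }
  span <- sum(exon_lens) + sum(intron_lens)
  # offsets of exons along the transcript axis
  offs <- cumsum(c(0L, head(exon_lens, -1L) + intron_lens))
  if (strand == "+") {
    seg <- tibble(start = start_pos + offs,
                  end = start_pos + offs + exon_lens - 1L)
  } else {
    gend <- start_pos + span - 1L
    seg <- tibble(start = gend - offs - exon_lens + 1L,
                  end = gend - offs)
  }
  list(cds = seg, span = span)
}

#' Generate a synthetic dataset with known truth
#'
#' For each planted gene, domain residues are sampled column-wise from the
#' seed profiles (family ancestor), diverged per group
#' (`group_divergence`), then per gene (`mu`); random linkers and flanks
#' are added and the group's C-terminal tetrapeptide appended (or a
#' degenerate variant, with probability `degeneracy_prob`). Gene models
#' realise each group's phase template exactly; tandem-array genes are
#' near-identical copies placed consecutively with sub-threshold gaps,
#' while all other genes are spaced beyond the 40 kb rule. Decoys
#' (single-domain, wrong-order, random) exercise every membership
#' rejection reason. Deterministic (byte-identical outputs) for a fixed
#' config.
#'
#' @param config A [generator_config()].
#' @return List of class `hes_dataset`: `proteome`, `models`, `loci`,
#'   `truth`, `anchors`, `config`.
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  bhlh_prof <- default_profile("bHLH")
  orange_prof <- default_profile("Orange")
  groups <- GROUP_LEVELS
  fam <- list(bhlh = sample_from_profile(bhlh_prof),
              orange = sample_from_profile(orange_prof))
  group_anc <- lapply(setNames(groups, groups), function(g) {
    list(bhlh = mutate_chars(fam$bhlh, cfg$group_divergence),
         orange = mutate_chars(fam$orange, cfg$group_divergence))
  })
  group_tag <- c("HEY1/2/L" = "HEY", "DEC1/2" = "DEC", "HESL" = "HESL",
                 "HES1-7" = "HES")

  proteome <- list()
  truth <- list()
  models <- list()

  make_member <- function(id, species, group, from_base = NULL,
                          base_mu = cfg$mu) {
    if (is.null(from_base)) {
      anc <- group_anc[[group]]
      bh <- mutate_chars(anc$bhlh, cfg$mu)
      oh <- mutate_chars(anc$orange, cfg$mu)
      flank_n <- rand_residues(runif_int(cfg$flank_n_range))
      linker <- rand_residues(runif_int(cfg$linker_range))
      tail_len <- runif_int(cfg$flank_c_range)
      tail <- rand_residues(tail_len, exclude = "W")
      cls <- unname(cfg$tetrapeptides[group])
      observed <- ""
      if (cls %in% c("WRPW", "YRPW", "FRPW")) {
        if (runif(1) < cfg$degeneracy_prob) {
          observed <- sample(DEGENERATE_VARIANTS, 1L)
          cls <- "DEGENERATE_W"
        } else {
          observed <- cls
        }
        protein <- paste0(flank_n, paste(bh, collapse = ""), linker,
                          paste(oh, collapse = ""), tail, observed)
      } else {
        cls <- "ABSENT"
        protein <- paste0(flank_n, paste(bh, collapse = ""), linker,
                          paste(oh, collapse = ""), tail)
      }
      bs <- nchar(flank_n) + 1L
      be <- bs + length(bh) - 1L
      os <- be + nchar(linker) + 1L
      oe <- os + length(oh) - 1L
      list(id = id, species = species, group = group, sequence = protein,
           bhlh_start = bs, bhlh_end = be, orange_start = os,
           orange_end = oe, tetra_class = cls, tetra_observed = observed)
    } else {
      # tandem-array copy: lightly diverged duplicate of the base gene
      chars <- mutate_chars(str_chars(from_base$sequence), base_mu)
      # keep the planted motif intact at the C-terminus
      if (nzchar(from_base$tetra_observed)) {
        keep <- nchar(from_base$sequence) - 3L
        chars[keep:(keep + 3L)] <- str_chars(from_base$tetra_observed)
      }
      out <- from_base
      out$id <- id
      out$sequence <- paste(chars, collapse = "")
      out
    }
  }

  for (si in seq_len(nrow(cfg$species))) {
    sp <- cfg$species$name[si]
    is_tel <- cfg$species$is_teleost[si]
    counts <- if (is_tel) cfg$counts_teleost else cfg$counts_non_teleost
    prefix <- toupper(substr(sp, 1L, 3L))
    chrom_cursor <- setNames(
      rep(10000, cfg$species$n_chromosomes[si]),
      paste0("chr", seq_len(cfg$species$n_chromosomes[si]))
    )
    place_gene <- function(chrom, gap, plen, phases, strand) {
      pos <- chrom_cursor[[chrom]] + gap
      gm <- build_gene_model(plen, phases, as.integer(pos), strand, cfg)
      if (pos + gm$span > cfg$species$chrom_length[si]) {
        abort(paste0("cannot place gene on ", sp, " ", chrom,
                     ": chromosome full"))
      }
      chrom_cursor[[chrom]] <<- pos + gm$span
      gm
    }
    emit <- function(info, chrom, gap, array_id = NA_character_) {
      phases <- parse_phases(cfg$structure_templates[[info$group]])
      strand <- sample(c("+", "-"), 1L)
      gm <- place_gene(chrom, gap, nchar(info$sequence), phases, strand)
      proteome[[length(proteome) + 1L]] <<- tibble(
        id = info$id, species = info$species, sequence = info$sequence,
        moltype = "protein", description = "")
      models[[length(models) + 1L]] <<- tibble(
        gene_id = info$id, transcript_id = paste0(info$id, ".t1"),
        species = info$species, chromosome = chrom, strand = strand,
        cds = list(gm$cds), utr_exons = 0L)
      truth[[length(truth) + 1L]] <<- tibble(
        id = info$id, species = info$species, group = info$group,
        is_member = TRUE, decoy_type = NA_character_,
        bhlh_start = info$bhlh_start, bhlh_end = info$bhlh_end,
        orange_start = info$orange_start, orange_end = info$orange_end,
        phase_string = format_phases(phases),
        planted_events = if (identical(format_phases(phases),
                                       ANCESTRAL_PHASES)) ""
                         else "EXON_LOSS_5P@1",
        tetra_class = info$tetra_class,
        tetra_observed = info$tetra_observed,
        array_id = array_id,
        chromosome = chrom, start = min(gm$cds$start),
        end = max(gm$cds$end), strand = strand)
    }
    for (gi in seq_along(groups)) {
      g <- groups[gi]
      chrom <- paste0("chr", ((gi - 1L) %% cfg$species$n_chromosomes[si]) + 1L)
      n_genes <- counts[[g]]
      for (k in seq_len(n_genes)) {
        info <- make_member(paste0(prefix, "_", group_tag[[g]], k), sp, g)
        emit(info, chrom, gap = runif_int(c(60000L, 120000L)))
      }
      arr <- cfg$tandem_arrays[cfg$tandem_arrays$species == sp &
                               cfg$tandem_arrays$group == g, ]
      if (nrow(arr)) {
        for (ai in seq_len(nrow(arr))) {
          array_id <- paste0(sp, "_", group_tag[[g]], "_array", ai)
          base <- make_member(paste0(prefix, "_", group_tag[[g]], "T1"),
                              sp, g)
          emit(base, chrom, gap = 100000L, array_id = array_id)
          for (k in 2:arr$size[ai]) {
            copy <- make_member(paste0(prefix, "_", group_tag[[g]], "T", k),
                                sp, g, from_base = base, base_mu = 0.01)
            emit(copy, chrom,
                 gap = runif_int(c(arr$gap_min[ai], arr$gap_max[ai])),
                 array_id = array_id)
          }
        }
      }
    }
    # decoys: proteins without gene models
    decoy_seq <- function(type) {
      flank <- function(range) rand_residues(runif_int(range))
      switch(type,
        bhlh_only = paste0(flank(cfg$flank_n_range),
                           paste(mutate_chars(fam$bhlh, cfg$mu),
                                 collapse = ""),
                           rand_residues(runif_int(cfg$flank_c_range),
                                         exclude = "W")),
        orange_only = paste0(flank(cfg$flank_n_range),
                             paste(mutate_chars(fam$orange, cfg$mu),
                                   collapse = ""),
                             rand_residues(runif_int(cfg$flank_c_range),
                                           exclude = "W")),
        wrong_order = paste0(flank(cfg$flank_n_range),
                             paste(mutate_chars(fam$orange, cfg$mu),
                                   collapse = ""),
                             flank(cfg$linker_range),
                             paste(mutate_chars(fam$bhlh, cfg$mu),
                                   collapse = ""),
                             rand_residues(runif_int(cfg$flank_c_range),
                                           exclude = "W")),
        random = rand_residues(runif_int(c(150L, 300L)))
      )
    }
    expected_reason <- c(bhlh_only = "no_orange", orange_only = "no_bhlh",
                         wrong_order = "wrong_order", random = "no_bhlh")
    for (type in names(cfg$decoys)) {
      for (k in seq_len(cfg$decoys[[type]])) {
        id <- paste0(prefix, "_DECOY_", type, k)
        proteome[[length(proteome) + 1L]] <- tibble(
          id = id, species = sp, sequence = decoy_seq(type),
          moltype = "protein", description = "")
        truth[[length(truth) + 1L]] <- tibble(
          id = id, species = sp, group = NA_character_, is_member = FALSE,
          decoy_type = type,
          bhlh_start = NA_integer_, bhlh_end = NA_integer_,
          orange_start = NA_integer_, orange_end = NA_integer_,
          phase_string = NA_character_, planted_events = NA_character_,
          tetra_class = NA_character_, tetra_observed = NA_character_,
          array_id = NA_character_, chromosome = NA_character_,
          start = NA_integer_, end = NA_integer_, strand = NA_character_)
      }
    }
  }
  proteome <- bind_rows(proteome)
  truth <- bind_rows(truth)
  models <- bind_rows(models)
  loci <- truth |>
    filter(.data$is_member) |>
    select("gene_id" = "id", "species", "group", "chromosome", "start",
           "end", "strand")
  anchors <- truth |>
    filter(.data$is_member, .data$species == cfg$anchor_species,
           is.na(.data$array_id)) |>
    select(anchor_id = "id", "group")
  structure(list(proteome = proteome, models = models, loci = loci,
                 truth = truth, anchors = anchors, config = cfg),
            class = "hes_dataset")
}

#' @export
print.hes_dataset <- function(x, ...) {
  cat("<hes_dataset> ", nrow(x$proteome), " sequences (",
      sum(x$truth$is_member), " members, ", sum(!x$truth$is_member),
      " decoys) across ", nrow(x$config$species), " species\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Emits `proteome.fasta`, `models.gff3`, `loci.tsv`, `truth.tsv`,
#' `anchors.tsv`; outputs are byte-identical for identical (config, seed).
#'
#' @param dataset An `hes_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dataset$proteome, file.path(dir, "proteome.fasta"))
  write_gff3(dataset$models, file.path(dir, "models.gff3"))
  readr::write_tsv(dataset$loci, file.path(dir, "loci.tsv"))
  readr::write_tsv(dataset$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(dataset$anchors, file.path(dir, "anchors.tsv"))
  invisible(dir)
}

#' Evolve domain sequences along a guide tree
#'
#' Samples a root sequence column-wise from a profile and substitutes each
#' site independently along each branch with probability
#' `1 - exp(-rate * length)` (to a uniformly chosen different residue);
#' leaves are emitted as records with the leaf name as species tag.
#'
#' @param tree `ape::phylo` guide tree with branch lengths.
#' @param profile A `profile_model` (default: the packaged bHLH profile).
#' @param rate Substitution rate per unit branch length.
#' @param seed Integer seed.
#' @return List: `records` (leaf tibble `id`, `species`, `sequence`),
#'   `root` (root sequence).
#' @export
evolve_on_tree <- function(tree, profile = default_profile("bHLH"),
                           rate = 1, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  tree <- stats::reorder(tree, "cladewise")   # parents before children
  with_seed(seed, {
    root_seq <- sample_from_profile(profile)
    n_tip <- length(tree$tip.label)
    root <- n_tip + 1L
    seqs <- vector("list", n_tip + tree$Nnode)
    seqs[[root]] <- root_seq
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      len <- if (is.null(tree$edge.length)) 0 else tree$edge.length[e]
      p_sub <- 1 - exp(-rate * len)
      seqs[[child]] <- mutate_chars(seqs[[parent]], p_sub)
    }
    records <- tibble(
      id = tree$tip.label,
      species = tree$tip.label,
      sequence = vapply(seq_len(n_tip), function(i) {
        paste(seqs[[i]], collapse = "")
      }, character(1))
    )
    list(records = records, root = paste(root_seq, collapse = ""))
  })
}

#' Expected per-species member counts implied by a generator config
#'
#' The truth-table counts of [generate_dataset()] equal this table exactly
#' (planted genes per group plus tandem-array copies); it lets count-level
#' properties (e.g. the teleost expansion contrast) be evaluated across many
#' configurations without sequence emission.
#'
#' @param config A [generator_config()].
#' @return `hes_counts` tibble (species x group, plus `total`).
#' @export
expected_count_table <- function(config = generator_config()) {
  rows <- list()
  for (si in seq_len(nrow(config$species))) {
    sp <- config$species$name[si]
    counts <- if (config$species$is_teleost[si]) config$counts_teleost
              else config$counts_non_teleost
    for (g in names(counts)) {
      n <- counts[[g]]
      arr <- config$tandem_arrays[config$tandem_arrays$species == sp &
                                  config$tandem_arrays$group == g, ]
      if (nrow(arr)) n <- n + sum(arr$size)
      if (n > 0) {
        rows[[length(rows) + 1L]] <- tibble(
          species = rep(sp, n), group = rep(g, n))
      }
    }
  }
  count_table(bind_rows(rows))
}
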