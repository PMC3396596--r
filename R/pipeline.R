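# End-to-end pipeline: scan -> dedup -> align -> tree -> classify ->
# structure -> motifs -> duplication -> expansion test.

#' Build a pipeline configuration
#'
#' Either point at input files (`proteome`, `gff3`, `anchors`,
#' `gene_table`) or set `synthetic = generator_config(...)` to run on
#' generated data. A configuration with only `gene_table` runs the
#' table-only stages (name-based grouping, count table, tandem scan).
#'
#' @param proteome,gff3,anchors,gene_table,loci Optional input file paths.
#' @param synthetic Optional [generator_config()].
#' @param alpha Membership significance threshold in (0, 1).
#' @param n_shuffles Permutations per record/domain (>= 100).
#' @param identity_threshold Redundancy-clustering identity in (0.5, 1].
#' @param deletion_mode,coverage Gap treatment for distances.
#' @param distance `"pdist"` (default) or `"poisson"`.
#' @param n_replicates Resampling replicates for branch support.
#' @param gap_threshold Tandem-cluster gap rule in bp.
#' @param tetra_window C-terminal search window.
#' @param min_cluster Minimum species-cluster size.
#' @param teleost_species Species treated as teleost in the expansion test;
#'   defaults to the synthetic config's teleost clade when present.
#' @param seed Integer seed for all stochastic stages.
#' @param outdir Optional directory; when set, every stage's artifact is
#'   persisted there as TSV/Newick/JSON plus a manifest.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(proteome = NULL, gff3 = NULL, anchors = NULL,
                            gene_table = NULL, loci = NULL,
                            synthetic = NULL,
                            alpha = 0.01, n_shuffles = 200L,
                            identity_threshold = 0.9,
                            deletion_mode = "partial", coverage = 0.95,
                            distance = c("pdist", "poisson"),
                            n_replicates = 100L,
                            gap_threshold = 40000,
                            tetra_window = 10L,
                            min_cluster = 3L,
                            teleost_species = NULL,
                            seed = 17L, outdir = NULL) {
  structure(
    list(proteome = proteome, gff3 = gff3, anchors = anchors,
         gene_table = gene_table, loci = loci, synthetic = synthetic,
         alpha = alpha, n_shuffles = as.integer(n_shuffles),
         identity_threshold = identity_threshold,
         deletion_mode = deletion_mode, coverage = coverage,
         distance = match.arg(distance),
         n_replicates = as.integer(n_replicates),
         gap_threshold = gap_threshold,
         tetra_window = as.integer(tetra_window),
         min_cluster = as.integer(min_cluster),
         teleost_species = teleost_species,
         seed = as.integer(seed), outdir = outdir),
    class = "pipeline_config"
  )
}

#' Validate a pipeline configuration
#'
#' @param config A [pipeline_config()] (or a list / YAML-parsed config).
#' @return Character vector of problems; empty iff the config is runnable.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  num_in <- function(x, lo, hi) is.numeric(x) && length(x) == 1L &&
    !is.na(x) && x > lo && x < hi
  if (!num_in(config$alpha, 0, 1)) add("alpha must be in (0,1)")
  if (!is.numeric(config$n_shuffles) || config$n_shuffles < 100) {
    add("n_shuffles must be >= 100")
  }
  if (!is.numeric(config$identity_threshold) ||
      config$identity_threshold <= 0.5 || config$identity_threshold > 1) {
    add("identity_threshold must be in (0.5, 1]")
  }
  if (!is.numeric(config$gap_threshold) || config$gap_threshold <= 0) {
    add("gap_threshold must be positive")
  }
  if (!is.numeric(config$n_replicates) || config$n_replicates < 10) {
    add("n_replicates must be >= 10")
  }
  if (!config$deletion_mode %in% c("partial", "pairwise", "complete")) {
    add("deletion_mode must be partial, pairwise or complete")
  }
  has_seq <- !is.null(config$proteome) || !is.null(config$synthetic)
  has_table <- !is.null(config$gene_table)
  if (!has_seq && !has_table) {
    add("need a proteome, a synthetic block, or a gene table")
  }
  for (f in c("proteome", "gff3", "anchors", "gene_table", "loci")) {
    p <- config[[f]]
    if (!is.null(p) && !file.exists(p)) {
      add(paste0(f, " file does not exist: ", p))
    }
  }
  problems
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror the arguments of [pipeline_config()],
#'   with an optional `synthetic:` block passed to [generator_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- NULL
  if (!is.null(y$synthetic)) {
    syn <- do.call(generator_config, y$synthetic)
    y$synthetic <- NULL
  }
  do.call(pipeline_config, c(y, list(synthetic = syn)))
}

#' Run the full family analysis pipeline
#'
#' Stages: identify members by dual-domain scan; remove redundancy; align
#' concatenated domain regions of complete members; build the NJ tree with
#' resampling support; assign groups by anchored clades; compute phases and
#' event scripts from gene models; classify C-terminal tetrapeptides; find
#' conserved blocks; detect tandem clusters; tabulate species-by-group
#' counts; and test teleost expansion. Members with truncated (partial)
#' domains are excluded from the tree but retained in the member table with
#' `complete = FALSE`. With only a gene table, the table-only stages run
#' and the skipped stages are recorded.
#'
#' Identical (inputs, config, seed) give identical reports; persisted data
#' outputs contain no timestamps.
#'
#' @param config A [pipeline_config()].
#' @return List of class `hes_report`: `members`, `representatives`,
#'   `alignment`, `tree`, `groups`, `species_clusters`, `structure`,
#'   `tetrapeptides`, `motif_blocks`, `tandem_clusters`, `counts`,
#'   `expansion`, `skipped`, `params`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  problems <- validate_config(config)
  if (length(problems)) {
    abort(paste0("invalid pipeline config:\n  ",
                 paste(problems, collapse = "\n  ")))
  }
  outdir <- config$outdir
  persist <- function(x, name) {
    if (is.null(outdir)) return(invisible(NULL))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(outdir, name)
    if (inherits(x, "phylo")) {
      write_newick(x, path)
    } else if (is.data.frame(x)) {
      flat <- x
      for (col in names(flat)) {
        if (is.list(flat[[col]])) {
          flat[[col]] <- vapply(flat[[col]], function(v) {
            paste(unlist(v), collapse = ",")
          }, character(1))
        }
      }
      readr::write_tsv(flat, path)
    } else {
      jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
    }
    invisible(NULL)
  }
  report <- list(skipped = character(0))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  # ---- inputs ----
  dataset <- NULL
  records <- NULL
  models <- NULL
  loci <- NULL
  anchors <- NULL
  teleosts <- config$teleost_species
  if (!is.null(config$synthetic)) {
    dataset <- stage("synthetic_data", generate_dataset(config$synthetic))
    if (!is.null(outdir)) write_dataset(dataset, file.path(outdir, "data"))
    records <- dataset$proteome
    models <- dataset$models
    loci <- dataset$loci
    anchors <- dataset$anchors
    if (is.null(teleosts)) {
      teleosts <- dataset$config$species$name[dataset$config$species$is_teleost]
    }
  }
  if (!is.null(config$proteome)) records <- stage("read_proteome",
                                                  read_fasta(config$proteome))
  if (!is.null(config$gff3)) models <- stage("read_gff3",
                                             read_gff3(config$gff3))
  if (!is.null(config$anchors)) {
    anchors <- stage("read_anchors",
                     readr::read_tsv(config$anchors, show_col_types = FALSE))
  }
  if (!is.null(config$loci)) {
    loci <- stage("read_loci",
                  readr::read_tsv(config$loci, show_col_types = FALSE))
  }
  gene_table <- NULL
  if (!is.null(config$gene_table)) {
    gene_table <- stage("read_gene_table", read_gene_table(config$gene_table))
    gene_table <- name_based_grouping(gene_table)
    persist(gene_table, "gene_table_groups.tsv")
    if (is.null(loci)) {
      loci <- tibble(gene_id = gene_table$gene_symbol,
                     species = gene_table[["species"]] %||%
                       rep("unknown", nrow(gene_table)),
                     group = gene_table$group,
                     chromosome = gene_table$chromosome,
                     start = gene_table$start, end = gene_table$end,
                     strand = gene_table$strand)
    }
  }
  report$gene_table <- gene_table

  # ---- sequence stages ----
  groups_tbl <- NULL
  if (!is.null(records)) {
    members <- stage("membership", call_membership(
      records, default_profile("bHLH"), default_profile("Orange"),
      alpha = config$alpha, n_shuffles = config$n_shuffles,
      seed = config$seed))
    member_records <- left_join(
      filter(members, .data$is_member),
      select(records, "id", "sequence"), by = "id")
    dedup <- stage("deduplicate", deduplicate(
      select(member_records, "id", "sequence"),
      identity_threshold = config$identity_threshold))
    members <- left_join(
      members, select(dedup, "id", "cluster_rep"), by = "id")
    report$members <- members
    persist(members, "members.tsv")
    rep_ids <- dedup$id[dedup$is_representative]
    complete_members <- filter(members, .data$is_member, .data$complete,
                               .data$id %in% rep_ids)
    if (nrow(complete_members) >= 3L) {
      domains <- stage("concat_domains",
                       concat_domains(complete_members, records))
      aln <- stage("align", progressive_align(domains))
      report$alignment <- aln
      if (!is.null(outdir)) {
        write_fasta(tibble(id = aln$id, sequence = aln$aligned),
                    file.path(outdir, "alignment.fasta"))
      }
      tree <- stage("tree", support_resample(
        aln, n_replicates = config$n_replicates, seed = config$seed,
        deletion_mode = config$deletion_mode, coverage = config$coverage))
      report$tree <- tree
      persist(tree, "tree.nwk")
      if (!is.null(anchors)) {
        anchors_in <- anchors[anchors$anchor_id %in% tree$tip.label, ]
        groups_tbl <- stage("classify", assign_groups(tree, anchors_in))
        # propagate representative labels to collapsed duplicates
        lookup <- setNames(groups_tbl$group, groups_tbl$leaf_id)
        all_members <- filter(members, .data$is_member)
        groups_tbl <- tibble(
          leaf_id = all_members$id,
          group = unname(lookup[all_members$cluster_rep]),
          method = ifelse(all_members$id %in% names(lookup),
                          groups_tbl$method[match(all_members$id,
                                                  groups_tbl$leaf_id)],
                          "cluster-representative"),
          supporting_clade_size = NA_integer_
        )
        report$groups <- groups_tbl
        persist(groups_tbl, "groups.tsv")
        sp_map <- select(filter(members, .data$is_member), "id", "species")
        report$species_clusters <- stage("species_clusters",
          detect_species_clusters(
            tree, min_size = config$min_cluster,
            species = tibble(leaf_id = sp_map$id, species = sp_map$species)))
        persist(report$species_clusters, "species_clusters.tsv")
      } else {
        report$skipped <- c(report$skipped, "classify (no anchors)")
      }
      report$motif_blocks <- stage("motif_blocks",
                                   find_conserved_blocks(aln))
      persist(select(report$motif_blocks, -"frequencies"),
              "motif_blocks.tsv")
    } else {
      report$skipped <- c(report$skipped,
                          "tree/classify (fewer than 3 complete members)")
    }
    report$tetrapeptides <- stage("tetrapeptides", classify_tetrapeptide(
      filter(records, .data$id %in% members$id[members$is_member]),
      window = config$tetra_window))
    persist(report$tetrapeptides, "tetrapeptides.tsv")
  } else {
    report$skipped <- c(report$skipped,
                        "membership/alignment/tree/motifs (no sequences)")
  }

  # ---- structure ----
  if (!is.null(models)) {
    grp_for_structure <- if (!is.null(groups_tbl)) {
      tibble(leaf_id = groups_tbl$leaf_id, group = groups_tbl$group)
    } else {
      NULL
    }
    # gene ids carry a ".t1" transcript suffix; match on gene ids
    struct_models <- models
    report$structure <- stage("structure",
                              structure_report(struct_models,
                                               grp_for_structure))
    persist(select(report$structure, -any_of("exon_lengths")),
            "structure.tsv")
  } else {
    report$skipped <- c(report$skipped, "structure (no gene models)")
  }

  # ---- duplication & expansion ----
  if (!is.null(loci)) {
    if (!is.null(groups_tbl)) {
      lk <- setNames(groups_tbl$group, groups_tbl$leaf_id)
      loci$group <- ifelse(loci$gene_id %in% names(lk),
                           unname(lk[loci$gene_id]), loci$group)
    }
    report$tandem_clusters <- stage("tandem", detect_tandem_clusters(
      loci, gap_threshold = config$gap_threshold))
    persist(report$tandem_clusters, "tandem_clusters.tsv")
  } else {
    report$skipped <- c(report$skipped, "tandem (no loci)")
  }
  member_sp <- if (!is.null(records) && !is.null(groups_tbl)) {
    m <- filter(report$members, .data$is_member)
    tibble(species = m$species,
           group = unname(setNames(groups_tbl$group,
                                   groups_tbl$leaf_id)[m$id]))
  } else if (!is.null(gene_table) && "species" %in% names(gene_table)) {
    select(gene_table, "species", "group")
  } else if (!is.null(loci) && all(c("species", "group") %in% names(loci))) {
    select(loci, "species", "group")
  } else {
    NULL
  }
  if (!is.null(member_sp)) {
    report$counts <- stage("counts", count_table(member_sp))
    persist(report$counts, "counts.tsv")
    if (!is.null(teleosts) && any(report$counts$species %in% teleosts) &&
        !all(report$counts$species %in% teleosts)) {
      report$expansion <- stage("expansion",
                                expansion_test(report$counts, teleosts))
      persist(tidy(report$expansion), "expansion.tsv")
    } else {
      report$skipped <- c(report$skipped, "expansion (no lineage split)")
    }
  } else {
    report$skipped <- c(report$skipped, "counts (no labeled members)")
  }

  report$params <- config[c("alpha", "n_shuffles", "identity_threshold",
                            "deletion_mode", "coverage", "distance",
                            "n_replicates", "gap_threshold", "tetra_window",
                            "min_cluster", "seed")]
  if (!is.null(outdir)) {
    manifest <- c(report$params,
                  list(stages_skipped = report$skipped,
                       package_version =
                         as.character(utils::packageVersion("hesfam"))))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  class(report) <- "hes_report"
  report
}

#' @export
print.hes_report <- function(x, ...) {
  cat("<hes_report>\n")
  if (!is.null(x$members)) {
    cat("  members: ", sum(x$members$is_member), " of ",
        nrow(x$members), " sequences\n", sep = "")
  }
  if (!is.null(x$groups)) {
    tab <- table(x$groups$group)
    cat("  groups: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  if (!is.null(x$tandem_clusters)) {
    cat("  tandem clusters: ", nrow(x$tandem_clusters), "\n", sep = "")
  }
  if (!is.null(x$expansion)) {
    cat("  expansion test p = ", signif(x$expansion$p_two_sided, 4),
        " (", x$expansion$method, ")\n", sep = "")
  }
  if (length(x$skipped)) {
    cat("  skipped: ", paste(x$skipped, collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}
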