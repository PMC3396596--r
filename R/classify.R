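# Group classification on trees and by gene symbol.

#' Default anchor map: the 13 human HES/HEY genes
#'
#' Maps the human gene symbols to the four canonical family groups:
#' HEY1/HEY2/HEYL to `HEY1/2/L`, BHLHE40/BHLHE41 (DEC1/DEC2) to `DEC1/2`,
#' HELT to `HESL` and HES1..HES7 to `HES1-7`.
#'
#' @return Tibble with `anchor_id`, `group`.
#' @export
default_anchor_map <- function() {
  tibble(
    anchor_id = c("HEY1", "HEY2", "HEYL", "BHLHE40", "BHLHE41", "HELT",
                  paste0("HES", 1:7)),
    group = c(rep("HEY1/2/L", 3), rep("DEC1/2", 2), "HESL",
              rep("HES1-7", 7))
  )
}

# Aliases accepted by name_based_grouping beyond the canonical symbols.
symbol_aliases <- c(DEC1 = "BHLHE40", DEC2 = "BHLHE41", HESL = "HELT")

# Both sides of every edge of an unrooted tree, as a list of leaf-label
# vectors (excluding the full leaf set and the empty set).
tree_clades <- function(tree) {
  all_leaves <- tree$tip.label
  sides <- phylo_bipartitions(tree)
  singles <- as.list(all_leaves)
  clades <- c(unname(sides), lapply(unname(sides), setdiff, x = all_leaves),
              singles,
              lapply(singles, setdiff, x = all_leaves))
  clades[vapply(clades, length, integer(1)) < length(all_leaves)]
}

#' Assign tree leaves to family groups using anchored clades
#'
#' For each non-anchor leaf, the smallest clade (a side of any edge of the
#' unrooted tree) containing the leaf and at least one anchor, such that all
#' anchors inside belong to a single group, determines the group
#' (`method = "clade"`). If every such clade is group-mixed, the leaf takes
#' the group of the anchor at minimum path length (`method =
#' "nearest-anchor"`; ties broken toward the lexicographically smaller
#' anchor id). Anchors keep their own labels (`method = "anchor"`).
#'
#' @param tree `ape::phylo`, unrooted semantics.
#' @param anchors Tibble with `anchor_id`, `group` (see
#'   [default_anchor_map()]); every anchor must be a tree leaf.
#' @return Tibble: `leaf_id`, `group`, `method`, `supporting_clade_size`.
#' @export
assign_groups <- function(tree, anchors = default_anchor_map()) {
  leaves <- tree$tip.label
  missing <- setdiff(anchors$anchor_id, leaves)
  if (length(missing)) {
    abort(paste0("anchors missing from tree: ",
                 paste(missing, collapse = ", ")))
  }
  anchor_group <- setNames(anchors$group, anchors$anchor_id)
  clades <- tree_clades(tree)
  # keep clades whose anchors are single-group
  clade_info <- lapply(clades, function(cl) {
    a <- intersect(cl, anchors$anchor_id)
    if (length(a) == 0L) return(NULL)
    groups <- unique(anchor_group[a])
    list(leaves = cl, size = length(cl),
         group = if (length(groups) == 1L) groups else NA_character_)
  })
  clade_info <- clade_info[!vapply(clade_info, is.null, logical(1))]
  grp_key <- vapply(clade_info, `[[`, character(1), "group")
  grp_key[is.na(grp_key)] <- "~"
  ord <- order(vapply(clade_info, function(x) as.numeric(x$size),
                      numeric(1)), grp_key)
  clade_info <- clade_info[ord]
  pure <- clade_info[!is.na(vapply(clade_info, `[[`, character(1), "group"))]

  path_len <- NULL  # computed lazily for the fallback
  one <- function(leaf) {
    if (leaf %in% anchors$anchor_id) {
      return(tibble(leaf_id = leaf, group = unname(anchor_group[leaf]),
                    method = "anchor", supporting_clade_size = 1L))
    }
    for (ci in pure) {
      if (leaf %in% ci$leaves) {
        return(tibble(leaf_id = leaf, group = ci$group, method = "clade",
                      supporting_clade_size = ci$size))
      }
    }
    if (is.null(path_len)) {
      path_len <<- ape::cophenetic.phylo(tree)
    }
    d <- path_len[leaf, anchors$anchor_id]
    best <- sort(names(d)[d <= min(d) + 1e-12])[1]
    tibble(leaf_id = leaf, group = unname(anchor_group[best]),
           method = "nearest-anchor", supporting_clade_size = NA_integer_)
  }
  bind_rows(lapply(leaves, one))
}

#' Detect species-specific expansion clusters in a tree
#'
#' Reports maximal clades (sides of edges of the unrooted tree) whose
#' leaves all carry one species tag and number at least `min_size`;
#' maximality means no qualifying clade properly contains them.
#'
#' @param tree `ape::phylo` whose leaves carry species tags.
#' @param min_size Minimum cluster size (default 3, so ordinary vertebrate
#'   paralog triplets within one species are not flagged; the clusters of
#'   interest in this family have 5+).
#' @param species Optional tibble `leaf_id`, `species`; by default species
#'   are parsed from `Species|ID` leaf labels.
#' @return Tibble: `species`, `n`, `leaf_ids` (list column), sorted by
#'   decreasing size.
#' @export
detect_species_clusters <- function(tree, min_size = 3L, species = NULL) {
  leaves <- tree$tip.label
  sp <- if (is.null(species)) {
    ifelse(grepl("|", leaves, fixed = TRUE),
           sub("\\|.*$", "", leaves), "unknown")
  } else {
    tb <- setNames(species$species, species$leaf_id)
    unname(tb[leaves])
  }
  names(sp) <- leaves
  clades <- tree_clades(tree)
  qual <- clades[vapply(clades, function(cl) {
    length(cl) >= min_size && length(unique(sp[cl])) == 1L
  }, logical(1))]
  if (length(qual) == 0L) {
    return(tibble(species = character(), n = integer(), leaf_ids = list()))
  }
  keys <- vapply(qual, bipart_key, character(1))
  qual <- qual[!duplicated(keys)]
  maximal <- vapply(seq_along(qual), function(i) {
    !any(vapply(seq_along(qual), function(j) {
      j != i && length(qual[[j]]) > length(qual[[i]]) &&
        all(qual[[i]] %in% qual[[j]])
    }, logical(1)))
  }, logical(1))
  qual <- qual[maximal]
  out <- tibble(
    species = vapply(qual, function(cl) unique(sp[cl]), character(1)),
    n = lengths(qual),
    leaf_ids = lapply(qual, sort)
  )
  arrange(out, desc(.data$n), .data$species)
}

#' Group genes by symbol using the anchor convention
#'
#' Maps gene symbols to the four canonical groups (HEY1/HEY2/HEYL,
#' BHLHE40/BHLHE41 or DEC1/DEC2, HELT/HESL, HES1..HES7); unknown symbols
#' become `"unassigned"`.
#'
#' @param rows Gene-table tibble with a `gene_symbol` column
#'   ([read_gene_table()]).
#' @return The input with an added `group` column.
#' @export
name_based_grouping <- function(rows) {
  map <- default_anchor_map()
  lookup <- setNames(map$group, map$anchor_id)
  sym <- toupper(rows$gene_symbol)
  sym <- ifelse(sym %in% names(symbol_aliases), symbol_aliases[sym], sym)
  mutate(rows, group = ifelse(sym %in% names(lookup),
                              unname(lookup[sym]), "unassigned"))
}
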