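# Plotting: count profiles and exon-intron structure diagrams.

#' Plot a species-by-group count table
#'
#' Stacked per-species bars of member counts by group, the usual display
#' for lineage-expansion comparisons.
#'
#' @param object An `hes_counts` table ([count_table()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hes_counts <- function(object, ...) {
  groups <- setdiff(names(object), c("species", "total"))
  long <- tidyr::pivot_longer(object, cols = all_of(groups),
                              names_to = "group", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$species, y = .data$n, fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "gene count", fill = "group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

# Layout of exon/intron tracks in compressed-nt coordinates. Introns longer
# than `intron_cap` are drawn at the cap and flagged broken (the "//" glyph).
structure_layout <- function(models, membership = NULL, motifs = NULL,
                             intron_cap = 1000) {
  boxes <- list()
  marks <- list()
  for (i in seq_len(nrow(models))) {
    gid <- models$gene_id[i]
    seg <- models$cds[[i]]
    lens <- abs(seg$end - seg$start) + 1L
    ilens <- if (nrow(seg) > 1L) {
      vapply(seq_len(nrow(seg) - 1L), function(k) {
        as.numeric(abs(seg$start[k + 1L] - seg$end[k]) - 1L)
      }, numeric(1))
    } else {
      numeric(0)
    }
    phases <- if (length(lens) > 1L) cumsum(lens)[-length(lens)] %% 3L
              else integer(0)
    x <- 0
    tx_off <- 0   # transcript-axis offset of current exon
    for (k in seq_along(lens)) {
      boxes[[length(boxes) + 1L]] <- tibble(
        gene_id = gid, row = i, type = "exon",
        x0 = x, x1 = x + lens[k], tx0 = tx_off, tx1 = tx_off + lens[k],
        broken = FALSE)
      x <- x + lens[k]
      tx_off <- tx_off + lens[k]
      if (k <= length(ilens)) {
        drawn <- min(ilens[k], intron_cap)
        boxes[[length(boxes) + 1L]] <- tibble(
          gene_id = gid, row = i, type = "intron",
          x0 = x, x1 = x + drawn, tx0 = NA_real_, tx1 = NA_real_,
          broken = ilens[k] > intron_cap)
        marks[[length(marks) + 1L]] <- tibble(
          gene_id = gid, row = i, x = x + drawn / 2,
          label = as.character(phases[k]))
        x <- x + drawn
      }
    }
    # domain overlays from membership calls (protein residues -> CDS nt)
    if (!is.null(membership)) {
      m <- membership[membership$id == gid, , drop = FALSE]
      if (nrow(m) == 1L && isTRUE(m$is_member)) {
        for (dom in c("bhlh", "orange")) {
          rs <- m[[paste0(dom, "_start")]]
          re <- m[[paste0(dom, "_end")]]
          if (is.na(rs)) next
          nt0 <- (rs - 1L) * 3L
          nt1 <- re * 3L
          ex <- bind_rows(boxes)
          ex <- ex[ex$gene_id == gid & ex$type == "exon", ]
          for (b in seq_len(nrow(ex))) {
            lo <- max(nt0, ex$tx0[b])
            hi <- min(nt1, ex$tx1[b])
            if (lo < hi) {
              boxes[[length(boxes) + 1L]] <- tibble(
                gene_id = gid, row = i, type = paste0("domain_", dom),
                x0 = ex$x0[b] + (lo - ex$tx0[b]),
                x1 = ex$x0[b] + (hi - ex$tx0[b]),
                tx0 = lo, tx1 = hi, broken = FALSE)
            }
          }
        }
      }
    }
    if (!is.null(motifs)) {
      mo <- motifs[motifs$id == gid, , drop = FALSE]
      if (nrow(mo) == 1L && mo$class != "ABSENT") {
        marks[[length(marks) + 1L]] <- tibble(
          gene_id = gid, row = i, x = x, label = paste0("*", mo$class))
      }
    }
  }
  list(boxes = bind_rows(boxes), marks = bind_rows(marks))
}

#' Exon-intron structure diagram as a ggplot
#'
#' One track per gene: exon boxes scaled by coding length, intron lines
#' (long introns compressed), intron phase digits at junctions, and domain
#' spans overlaid when membership calls are supplied.
#'
#' @param models Gene-model tibble.
#' @param membership Optional membership tibble ([call_membership()]) for
#'   domain overlays.
#' @param motifs Optional tetrapeptide calls ([classify_tetrapeptide()]).
#' @return A ggplot.
#' @export
plot_gene_structure <- function(models, membership = NULL, motifs = NULL) {
  lay <- structure_layout(models, membership, motifs)
  b <- lay$boxes
  exons <- b[b$type == "exon", ]
  introns <- b[b$type == "intron", ]
  doms <- b[startsWith(b$type, "domain"), ]
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = introns, ggplot2::aes(
      x = .data$x0, xend = .data$x1, y = .data$row, yend = .data$row),
      linewidth = 0.3) +
    ggplot2::geom_rect(data = exons, ggplot2::aes(
      xmin = .data$x0, xmax = .data$x1, ymin = .data$row - 0.25,
      ymax = .data$row + 0.25), fill = "white", colour = "black",
      linewidth = 0.3)
  if (nrow(doms)) {
    p <- p + ggplot2::geom_rect(data = doms, ggplot2::aes(
      xmin = .data$x0, xmax = .data$x1, ymin = .data$row - 0.25,
      ymax = .data$row + 0.25, fill = .data$type)) +
      ggplot2::scale_fill_manual(values = c(domain_bhlh = "firebrick",
                                            domain_orange = "orange"),
                                 labels = c("bHLH", "Orange"),
                                 name = "domain")
  }
  if (nrow(lay$marks)) {
    p <- p + ggplot2::geom_text(data = lay$marks, ggplot2::aes(
      x = .data$x, y = .data$row + 0.38, label = .data$label), size = 2.6)
  }
  p +
    ggplot2::scale_y_reverse(breaks = seq_len(nrow(models)),
                             labels = models$gene_id) +
    ggplot2::labs(x = "compressed nt", y = NULL) +
    ggplot2::theme_minimal()
}

#' Deterministic SVG exon-intron structure diagram
#'
#' Text rendering of the per-gene structure tracks: exon boxes scaled by
#' length, intron lines with a break glyph for compressed long introns,
#' phase digits at junctions, colored domain spans and a tetrapeptide
#' marker. Byte-identical output for fixed input.
#'
#' @inheritParams plot_gene_structure
#' @param px_per_nt Horizontal scale.
#' @return Character vector of SVG lines (one element per line); write with
#'   [writeLines()].
#' @export
render_structure_diagram <- function(models, membership = NULL,
                                     motifs = NULL, px_per_nt = 0.25) {
  lay <- structure_layout(models, membership, motifs)
  b <- lay$boxes
  track_h <- 34
  left <- 150
  width <- ceiling(max(b$x1) * px_per_nt) + left + 40
  height <- nrow(models) * track_h + 20
  px <- function(x) sprintf("%.1f", left + x * px_per_nt)
  yy <- function(row, dy = 0) sprintf("%.1f", row * track_h - 10 + dy)
  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
    width, height))
  fills <- c(exon = "white", domain_bhlh = "#b22222",
             domain_orange = "#ff8c00")
  for (i in seq_len(nrow(models))) {
    out <- c(out, sprintf(
      '<text x="4" y="%s" font-size="10" font-family="monospace">%s</text>',
      yy(i, 4), models$gene_id[i]))
  }
  introns <- b[b$type == "intron", ]
  for (k in seq_len(nrow(introns))) {
    r <- introns[k, ]
    out <- c(out, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black" stroke-width="0.8"/>',
      px(r$x0), yy(r$row), px(r$x1), yy(r$row)))
    if (r$broken) {
      mid <- (r$x0 + r$x1) / 2
      out <- c(out, sprintf(
        '<text x="%s" y="%s" font-size="9" text-anchor="middle">//</text>',
        px(mid), yy(r$row, 3)))
    }
  }
  solid <- b[b$type != "intron", ]
  solid <- solid[order(solid$row, solid$type, solid$x0), ]
  for (k in seq_len(nrow(solid))) {
    r <- solid[k, ]
    out <- c(out, sprintf(
      '<rect x="%s" y="%s" width="%.1f" height="14" fill="%s" stroke="black" stroke-width="0.6"/>',
      px(r$x0), yy(r$row, -7), (r$x1 - r$x0) * px_per_nt,
      fills[[r$type]]))
  }
  if (nrow(lay$marks)) {
    for (k in seq_len(nrow(lay$marks))) {
      r <- lay$marks[k, ]
      out <- c(out, sprintf(
        '<text x="%s" y="%s" font-size="8" text-anchor="middle">%s</text>',
        px(r$x), yy(r$row, -10), r$label))
    }
  }
  c(out, "</svg>")
}
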