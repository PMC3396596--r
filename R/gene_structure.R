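# Exon/intron phase arithmetic and structure-evolution event inference.

#' The ancestral phase string of the family
#'
#' Five coding exons with intron phases 2-0-0-1, the structure of the sponge
#' ancestor and of the HEY1/2/L and DEC1/2 groups.
#' @export
ANCESTRAL_PHASES <- "2-0-0-1"

parse_phases <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  if (length(x) != 1L) abort("phase string must be a single string")
  if (!nzchar(x)) return(integer(0))
  p <- as.integer(strsplit(x, "-", fixed = TRUE)[[1]])
  if (any(is.na(p)) || any(!p %in% 0:2)) abort("phases must be 0, 1 or 2")
  p
}

format_phases <- function(p) paste(p, collapse = "-")

#' Compute intron phase strings from gene models
#'
#' Coding exon lengths are taken from the CDS segments in transcription
#' order; the phase of intron i is the cumulative coding length up to exon i
#' modulo 3 (0: between codons, 1: after the first base, 2: after the
#' second). UTR-only exons do not enter the count and are reported
#' separately. Out-of-frame totals are flagged, not fatal.
#'
#' @param models Gene-model tibble ([read_gff3()]).
#' @return Tibble: `gene_id`, `transcript_id`, `n_exons`, `exon_lengths`
#'   (list column, nt), `total_cds`, `phase_string`, `in_frame`,
#'   `utr_exons`.
#' @export
compute_phases <- function(models) {
  rows <- lapply(seq_len(nrow(models)), function(i) {
    seg <- models$cds[[i]]
    if (nrow(seg) == 0L) abort("gene model without CDS segments")
    lens <- abs(seg$end - seg$start) + 1L
    total <- sum(lens)
    phases <- if (length(lens) > 1L) cumsum(lens)[-length(lens)] %% 3L
              else integer(0)
    tibble(
      gene_id = models$gene_id[i],
      transcript_id = models$transcript_id[i],
      n_exons = length(lens),
      exon_lengths = list(as.integer(lens)),
      total_cds = as.integer(total),
      phase_string = format_phases(phases),
      in_frame = total %% 3L == 0L,
      utr_exons = as.integer((models[["utr_exons"]] %||% rep(0L, nrow(models)))[i])
    )
  })
  bind_rows(rows)
}

#' Phase string from coding exon lengths
#'
#' Convenience wrapper: `phases_from_lengths(c(2,1,3,1,2))` gives
#' `"2-0-0-1"`.
#'
#' @param lengths Coding exon lengths in nt, transcription order.
#' @return Phase string.
#' @export
phases_from_lengths <- function(lengths) {
  if (length(lengths) < 2L) return("")
  format_phases(cumsum(lengths)[-length(lengths)] %% 3L)
}

# The four structure-evolution event types, in tie-break priority order.
EVENT_TYPES <- c("EXON_LOSS_5P", "EXON_LOSS_3P", "INTRON_LOSS", "INTRON_GAIN")

# Apply one event to a phase vector (phases treated as observed labels).
apply_event <- function(p, type, position = NA_integer_, value = NA_integer_) {
  switch(type,
    EXON_LOSS_5P = {
      if (length(p) == 0L) abort("no intron to remove at the 5' end")
      p[-1]
    },
    EXON_LOSS_3P = {
      if (length(p) == 0L) abort("no intron to remove at the 3' end")
      p[-length(p)]
    },
    INTRON_LOSS = {
      if (position < 1L || position > length(p)) abort("bad intron position")
      p[-position]
    },
    INTRON_GAIN = {
      if (position < 0L || position > length(p)) abort("bad insertion point")
      append(p, value, after = position)
    },
    abort(paste0("unknown event type: ", type))
  )
}

#' Replay a structure-event script on a reference phase string
#'
#' @param reference Phase string or integer vector.
#' @param events Event tibble (`type`, `position`, `value`) as produced by
#'   [infer_events()]; positions are interpreted sequentially.
#' @return The resulting phase string.
#' @export
apply_events <- function(reference, events) {
  p <- parse_phases(reference)
  if (!is.null(events)) {
    for (k in seq_len(nrow(events))) {
      p <- apply_event(p, events$type[k], events$position[k],
                       events$value[k])
    }
  }
  format_phases(p)
}

# Candidate events from a state, in canonical tie-break order: 5' exon loss,
# 3' exon loss, intron losses by descending position (so that within a run
# of equal phases the 3'-most intron is the one reported as lost, matching
# the fused-exon reading of such transitions), intron gains by ascending
# position then phase value.
candidate_events <- function(p, min_len, max_len) {
  ev <- list()
  if (length(p) > 0L && length(p) - 1L >= min_len) {
    ev <- c(ev, list(list(type = "EXON_LOSS_5P", position = 1L,
                          value = NA_integer_)),
            list(list(type = "EXON_LOSS_3P", position = length(p),
                      value = NA_integer_)))
    for (i in rev(seq_along(p))) {
      ev <- c(ev, list(list(type = "INTRON_LOSS", position = i,
                            value = NA_integer_)))
    }
  }
  if (length(p) + 1L <= max_len) {
    for (pos in 0:length(p)) {
      for (v in 0:2) {
        ev <- c(ev, list(list(type = "INTRON_GAIN", position = pos,
                              value = as.integer(v))))
      }
    }
  }
  ev
}

#' Infer a minimal structure-evolution event script
#'
#' Finds the minimum-cost script of events (5' exon loss, 3' exon loss,
#' intron loss / exon fusion, intron gain) that transforms the reference
#' phase string into the query, treating phases as observed labels (a 5'
#' exon loss simply drops the first phase, matching the observed
#' 2-0-0-1 to 0-0-1 transition). Breadth-first search with states restricted
#' to lengths within 2 of the band spanned by the query and the reference
#' (a minimal script never needs to leave that range); cost ties are broken
#' by preferring
#' 5' exon loss over 3' exon loss over intron loss over intron gain; among
#' equivalent intron losses (a run of equal phases) the 3'-most intron is
#' reported, and intron gains prefer smaller insertion points.
#'
#' @param query Phase string (or integer vector) of the gene under study.
#' @param reference Phase string of the ancestral structure (default
#'   [ANCESTRAL_PHASES]).
#' @param max_cost Scripts above this cost are not searched (default 6).
#' @return List of class `structure_events`: `events` (tibble `type`,
#'   `position`, `value`), `cost`, `reference`, `query`, `unalignable`.
#' @export
infer_events <- function(query, reference = ANCESTRAL_PHASES, max_cost = 6L) {
  q <- parse_phases(query)
  r <- parse_phases(reference)
  qs <- format_phases(q)
  # States may dip below / rise above the end-point lengths when a value
  # change is realised as intron loss + intron gain; a slack of 2 covers
  # every minimal script over this event set.
  min_len <- max(0L, min(length(q), length(r)) - 2L)
  max_len <- max(length(q), length(r)) + 2L
  script_tibble <- function(script) {
    if (length(script) == 0L) {
      return(tibble(type = character(), position = integer(),
                    value = integer()))
    }
    tibble(
      type = vapply(script, `[[`, character(1), "type"),
      position = vapply(script, `[[`, integer(1), "position"),
      value = vapply(script, `[[`, integer(1), "value")
    )
  }
  result <- function(script, cost, unalignable = FALSE) {
    structure(list(events = if (unalignable) NULL else script_tibble(script),
                   cost = cost, reference = format_phases(r), query = qs,
                   unalignable = unalignable),
              class = "structure_events")
  }
  if (identical(format_phases(r), qs)) return(result(list(), 0L))
  visited <- new.env(parent = emptyenv(), hash = TRUE)
  state_key <- function(p) paste0("p", format_phases(p))
  qkey <- state_key(q)
  assign(state_key(r), TRUE, envir = visited)
  queue <- list(list(state = r, script = list()))
  depth <- 0L
  while (length(queue) && depth < max_cost) {
    depth <- depth + 1L
    budget <- max_cost - depth          # ops left after this one
    next_queue <- vector("list", 0L)
    for (item in queue) {
      for (ev in candidate_events(item$state, min_len, max_len)) {
        new_p <- apply_event(item$state, ev$type, ev$position, ev$value)
        key <- state_key(new_p)
        if (identical(key, qkey)) {
          return(result(c(item$script, list(ev)), depth))
        }
        if (!is.null(visited[[key]])) next
        # at least |length difference| further events are required
        if (abs(length(new_p) - length(q)) > budget) next
        assign(key, TRUE, envir = visited)
        next_queue[[length(next_queue) + 1L]] <-
          list(state = new_p, script = c(item$script, list(ev)))
      }
    }
    queue <- next_queue
  }
  result(NULL, NA_integer_, unalignable = TRUE)
}

#' @export
print.structure_events <- function(x, ...) {
  if (x$unalignable) {
    cat("<structure_events> unalignable: ", x$reference, " -> ", x$query,
        "\n", sep = "")
    return(invisible(x))
  }
  cat("<structure_events> ", x$reference, " -> ", x$query, " (cost ",
      x$cost, ")\n", sep = "")
  if (nrow(x$events)) {
    for (k in seq_len(nrow(x$events))) {
      cat("  ", x$events$type[k], " @ ", x$events$position[k],
          if (!is.na(x$events$value[k])) paste0(" phase ", x$events$value[k]),
          "\n", sep = "")
    }
  } else {
    cat("  (no events)\n")
  }
  invisible(x)
}

format_events <- function(ev) {
  if (is.null(ev) || nrow(ev) == 0L) return("")
  paste(ifelse(ev$type == "INTRON_GAIN",
               paste0(ev$type, "@", ev$position, ":", ev$value),
               paste0(ev$type, "@", ev$position)),
        collapse = ";")
}

#' Per-gene structure report against the ancestral model
#'
#' Computes phases and minimal event scripts for every gene model, joins
#' group assignments, and adds each group's modal phase string.
#'
#' @param models Gene-model tibble.
#' @param groups Optional tibble `leaf_id`, `group` ([assign_groups()]) or
#'   `gene_id`, `group`; matched against gene and transcript ids.
#' @param reference Ancestral phase string (default [ANCESTRAL_PHASES]).
#' @return Tibble: per gene, `gene_id`, `group`, `n_exons`, `phase_string`,
#'   `events` (compact script), `cost`, `unalignable`, `group_modal_phase`.
#' @export
structure_report <- function(models, groups = NULL,
                             reference = ANCESTRAL_PHASES) {
  ph <- compute_phases(models)
  if (!is.null(groups)) {
    key <- names(groups)[1]
    lookup <- setNames(groups$group, groups[[key]])
    grp <- ifelse(ph$gene_id %in% names(lookup), lookup[ph$gene_id],
                  ifelse(ph$transcript_id %in% names(lookup),
                         lookup[ph$transcript_id], NA_character_))
  } else {
    grp <- rep(NA_character_, nrow(ph))
  }
  scripts <- lapply(ph$phase_string, infer_events, reference = reference)
  out <- mutate(
    ph,
    group = unname(grp),
    events = vapply(scripts, function(s) format_events(s$events),
                    character(1)),
    cost = vapply(scripts, function(s) {
      if (s$unalignable) NA_integer_ else s$cost
    }, integer(1)),
    unalignable = vapply(scripts, `[[`, logical(1), "unalignable")
  )
  modal <- out |>
    filter(!is.na(.data$group)) |>
    count(.data$group, .data$phase_string) |>
    group_by(.data$group) |>
    arrange(desc(.data$n), .data$phase_string, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("group", group_modal_phase = "phase_string")
  left_join(out, modal, by = "group") |>
    select("gene_id", "transcript_id", "group", "n_exons", "phase_string",
           "in_frame", "utr_exons", "events", "cost", "unalignable",
           "group_modal_phase")
}
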