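# Orchestration of the screen: RING motif -> transmembrane filter ->
# optional upstream-element annotation, producing one candidate row per
# protein plus a summary, mirroring the published candidate tables.

#' Run the membrane-bound RING-E3 screen
#'
#' Applies the two selection criteria to a proteome: (1) at least one
#' canonical RING-finger motif match and (2) at least `min_tm` predicted
#' transmembrane helices. Each candidate carries the subtype of its canonical
#' (leftmost) match, its helix count and protein length, and any upstream
#' ER-stress element hits.
#'
#' @param proteins Protein tibble (`id`, `sequence`).
#' @param tm Topology tibble ([parse_tmhmm()] or [predict_tm()]). Every
#'   motif-positive protein must be present; missing ids are a hard error,
#'   never silently dropped.
#' @param promoter_hits Optional hit tibble from [scan_upstream()] keyed by
#'   `gene_id` matching protein ids; `NULL` to skip upstream annotation.
#' @param pattern Motif pattern (default [ring_pattern()]).
#' @param min_tm Minimum helix count (default 1).
#' @return An object of class `ring_screen`: list with `candidates` (tibble:
#'   `gene_id`, `subtype`, `ring_start`, `ring_end`, `n_ring`, `n_tm`,
#'   `protein_length`, `upstream_motifs` -- semicolon-joined
#'   `"LABEL,POSITION"` pairs, `"."` if none -- and `notes`, flagging
#'   proteins with matches of both subtypes), `summary` (one-row tibble:
#'   `n_total`, `n_c3h2c3`, `n_c3hc4`, `tm_min`, `tm_max`) and `params`.
#'   Candidates are sorted by subtype then gene id. Use [tidy()] / [glance()]
#'   to extract the pieces.
#' @export
run_screen <- function(proteins, tm, promoter_hits = NULL,
                       pattern = ring_pattern(), min_tm = 1L) {
  matches <- find_ring_motifs(proteins, pattern)
  motif_pos <- unique(matches$protein_id)
  missing_tm <- setdiff(motif_pos, tm$protein_id)
  if (length(missing_tm) > 0) {
    abort(paste0(
      "No transmembrane data for motif-positive protein(s): ",
      paste(missing_tm, collapse = ", ")
    ))
  }
  canonical <- best_match(matches)
  n_ring <- dplyr::count(matches, .data$protein_id, name = "n_ring")
  n_subtypes <- matches |>
    dplyr::distinct(.data$protein_id, .data$subtype) |>
    dplyr::count(.data$protein_id, name = "n_subtypes")

  cand <- canonical |>
    dplyr::select("protein_id", "subtype", ring_start = "start", ring_end = "end") |>
    dplyr::left_join(n_ring, by = "protein_id") |>
    dplyr::left_join(n_subtypes, by = "protein_id") |>
    dplyr::left_join(
      dplyr::select(tm, "protein_id", "n_tm"),
      by = "protein_id"
    ) |>
    dplyr::left_join(
      tibble(protein_id = proteins$id, protein_length = nchar(proteins$sequence)),
      by = "protein_id"
    ) |>
    dplyr::filter(.data$n_tm >= min_tm) |>
    dplyr::mutate(
      gene_id = .data$protein_id,
      notes = ifelse(.data$n_subtypes > 1L, "matches of both subtypes", ""),
      upstream_motifs = serialize_hits(.data$gene_id, promoter_hits)
    ) |>
    dplyr::select(
      "gene_id", "subtype", "ring_start", "ring_end", "n_ring",
      "n_tm", "protein_length", "upstream_motifs", "notes"
    ) |>
    dplyr::arrange(.data$subtype, .data$gene_id)

  summary <- tibble(
    n_total = nrow(cand),
    n_c3h2c3 = sum(cand$subtype == "C3H2C3"),
    n_c3hc4 = sum(cand$subtype == "C3HC4"),
    tm_min = if (nrow(cand) > 0) min(cand$n_tm) else NA_integer_,
    tm_max = if (nrow(cand) > 0) max(cand$n_tm) else NA_integer_
  )
  structure(
    list(
      candidates = cand, summary = summary,
      params = list(pattern = pattern$spec, min_tm = min_tm)
    ),
    class = "ring_screen"
  )
}

serialize_hits <- function(gene_ids, promoter_hits) {
  if (is.null(promoter_hits) || length(gene_ids) == 0) {
    return(rep(".", length(gene_ids)))
  }
  joined <- promoter_hits |>
    dplyr::arrange(dplyr::desc(.data$position)) |> # shallowest (closest to TSS) first
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      s = paste(paste0(.data$label, ",", .data$position), collapse = ";"),
      .groups = "drop"
    )
  out <- unname(setNames(joined$s, joined$gene_id)[gene_ids])
  ifelse(is.na(out), ".", out)
}

#' @export
print.ring_screen <- function(x, ...) {
  s <- x$summary
  cat("<ring_screen>\n")
  cat(sprintf(
    "  %d candidate(s): %d C3H2C3, %d C3HC4; TM helices %s-%s\n",
    s$n_total, s$n_c3h2c3, s$n_c3hc4, s$tm_min, s$tm_max
  ))
  cat(sprintf(
    "  %d with upstream ER-stress element(s)\n",
    sum(x$candidates$upstream_motifs != ".")
  ))
  invisible(x)
}

#' @rdname run_screen
#' @param x A `ring_screen` object.
#' @param ... Unused.
#' @export
tidy.ring_screen <- function(x, ...) x$candidates

#' @rdname run_screen
#' @export
glance.ring_screen <- function(x, ...) x$summary

#' Write / read a candidate table
#'
#' TSV with columns `gene_id`, `subtype`, `upstream_motifs` (semicolon-joined
#' `"LABEL,POSITION"` pairs, `"."` when none), `n_tm`, `protein_length`.
#' Writing then reading is the identity on these columns.
#'
#' @param screen A `ring_screen` object or its candidate tibble.
#' @param path File path.
#' @return `path` invisibly; the reader returns the candidate tibble.
#' @export
write_candidate_table <- function(screen, path) {
  cand <- if (inherits(screen, "ring_screen")) screen$candidates else screen
  cols <- c("gene_id", "subtype", "upstream_motifs", "n_tm", "protein_length")
  readr::write_tsv(dplyr::select(cand, dplyr::all_of(cols)), path)
  invisible(path)
}

#' @rdname write_candidate_table
#' @export
read_candidate_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, col_types = readr::cols(
    gene_id = "c", subtype = "c", upstream_motifs = "c",
    n_tm = "i", protein_length = "i"
  ))
}

#' Serialize upstream hits the way candidate tables print them
#'
#' Joins hit labels and TSS-relative positions as `"LABEL,POSITION"`,
#' semicolon-separated, shallowest hit first (e.g.
#' `"ERSE-I,-506;UPRE,-2303"`).
#'
#' @param hits Hit tibble for one or more genes.
#' @return Named character vector, one entry per gene.
#' @export
format_upstream_motifs <- function(hits) {
  genes <- unique(hits$gene_id)
  setNames(serialize_hits(genes, hits), genes)
}
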