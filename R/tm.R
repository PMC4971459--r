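# Transmembrane-helix counts per protein, from either TMHMM v2 long-format
# output (the tool of record for the screen) or a built-in Kyte-Doolittle
# sliding-window predictor used for synthetic fixtures. Topologies are nested
# tibbles: one row per protein, helices as a list-column of (start, end)
# 1-based inclusive intervals.

# Kyte & Doolittle hydropathy scale; ambiguity codes and '*' score 0
# (neutral), selenocysteine scores as cysteine.
KD_SCALE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2,
  X = 0, B = 0, Z = 0, U = 2.5, `*` = 0
)

tm_topology_tbl <- function(protein_id, helices, source) {
  tibble(
    protein_id = protein_id,
    n_tm = vapply(helices, nrow, 0L),
    helices = helices,
    source = source
  )
}

empty_helices <- function() tibble(start = integer(), end = integer())

#' Parse TMHMM v2 long-format output
#'
#' Reads the standard long format: per-protein header lines
#' `# <id> Number of predicted TMHs:  <n>` and body lines
#' `<id>  TMHMM2.0  TMhelix  <start>  <end>` (1-based inclusive). Other line
#' types (`inside`/`outside`, other `#` comments) are ignored.
#'
#' @param path Path to a TMHMM output file, or a character vector of lines
#'   via `text`.
#' @param text Optional character vector of lines (overrides `path`).
#' @return A topology tibble: `protein_id`, `n_tm`, `helices` (list-column of
#'   tibbles with `start`, `end`), `source = "parsed"`.
#' @export
parse_tmhmm <- function(path = NULL, text = NULL) {
  lines <- text %||% readr::read_lines(path)
  hdr <- stringr::str_match(lines, "^#\\s*(\\S+)\\s+Number of predicted TMHs:\\s*(\\d+)")
  body <- stringr::str_match(lines, "^(\\S+)\\s+\\S+\\s+TMhelix\\s+(\\d+)\\s+(\\d+)")
  ids <- hdr[, 2][!is.na(hdr[, 1])]
  declared <- as.integer(hdr[, 3][!is.na(hdr[, 1])])
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate TMHMM header for: ", ids[duplicated(ids)][1]))
  }
  helix_tbl <- tibble(
    protein_id = body[, 2][!is.na(body[, 1])],
    start = as.integer(body[, 3][!is.na(body[, 1])]),
    end = as.integer(body[, 4][!is.na(body[, 1])])
  )
  unknown <- setdiff(helix_tbl$protein_id, ids)
  if (length(unknown) > 0) {
    abort(paste0("TMhelix lines without header for: ", paste(unique(unknown), collapse = ", ")))
  }
  helices <- purrr::map(ids, function(id) {
    h <- dplyr::arrange(
      dplyr::select(dplyr::filter(helix_tbl, .data$protein_id == id), "start", "end"),
      .data$start
    )
    as_tibble(h)
  })
  found <- vapply(helices, nrow, 0L)
  if (any(found != declared)) {
    bad <- ids[found != declared]
    abort(paste0(
      "Declared TMH count disagrees with TMhelix lines for: ",
      paste(bad, collapse = ", ")
    ))
  }
  tm_topology_tbl(ids, helices, "parsed")
}

#' Write topologies in TMHMM v2 long format
#'
#' Inverse of [parse_tmhmm()]: emits the header and `TMhelix` lines with
#' 1-based inclusive coordinates, so write-then-parse is the identity.
#'
#' @param topologies Topology tibble ([parse_tmhmm()] / [predict_tm()]).
#' @param path Output path; omit to return the lines.
#' @return `path` invisibly, or the character vector of lines when `path` is
#'   `NULL`.
#' @export
write_tmhmm <- function(topologies, path = NULL) {
  lines <- purrr::pmap(topologies, function(protein_id, n_tm, helices, ...) {
    c(
      sprintf("# %s Number of predicted TMHs:  %d", protein_id, n_tm),
      sprintf("%s\tTMHMM2.0\tTMhelix\t%d\t%d", protein_id, helices$start, helices$end)
    )
  })
  lines <- unlist(lines)
  if (is.null(path)) return(lines)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Predict transmembrane helices by sliding-window hydropathy
#'
#' A desk-scale Kyte-Doolittle predictor: residues whose centred
#' `window`-mean hydropathy reaches `threshold` are marked; maximal runs of
#' marked residues are extended by half a window on each side, merged when
#' separated by fewer than `merge_gap` residues, and kept as helices when at
#' least `min_len` residues long. N-terminal hydrophobic stretches (signal
#' peptides) are deliberately counted as helices. Sequences shorter than the
#' window yield zero helices.
#'
#' @param proteins Protein tibble (`id`, `sequence`) or character vector.
#' @param window Odd window width in residues (default 19).
#' @param threshold Mean-hydropathy cutoff on the Kyte-Doolittle scale
#'   (default 1.6).
#' @param min_len Minimum helix length in residues (default 15).
#' @param merge_gap Runs closer than this many residues are merged
#'   (default 5).
#' @return A topology tibble as for [parse_tmhmm()], `source = "predicted"`.
#' @examples
#' predict_tm(c(toy = paste0(strrep("S", 40), strrep("L", 30), strrep("S", 40))))
#' @export
predict_tm <- function(proteins, window = 19L, threshold = 1.6, min_len = 15L,
                       merge_gap = 5L) {
  if (window %% 2L != 1L || window < 5L) abort("`window` must be odd and >= 5")
  if (is.character(proteins)) {
    ids <- names(proteins) %||% paste0("seq", seq_along(proteins))
    proteins <- tibble(id = ids, sequence = unname(proteins))
  }
  helices <- purrr::map(toupper(proteins$sequence), function(s) {
    predict_tm_one(s, window, threshold, min_len, merge_gap)
  })
  tm_topology_tbl(proteins$id, helices, "predicted")
}

predict_tm_one <- function(seq, window, threshold, min_len, merge_gap) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < window) return(empty_helices())
  h <- unname(KD_SCALE[chars])
  h[is.na(h)] <- 0
  half <- (window - 1L) %/% 2L
  win_mean <- stats::filter(h, rep(1 / window, window), sides = 2)
  centres <- which(!is.na(win_mean) & win_mean >= threshold)
  if (length(centres) == 0) return(empty_helices())
  runs <- split(centres, cumsum(c(1L, diff(centres) != 1L)))
  iv <- do.call(rbind, lapply(runs, function(r) {
    c(max(1L, min(r) - half), min(n, max(r) + half))
  }))
  # merge intervals separated by fewer than merge_gap residues
  merged <- list(iv[1, ])
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      last <- merged[[length(merged)]]
      if (iv[i, 1] - last[2] - 1L < merge_gap) {
        merged[[length(merged)]] <- c(last[1], max(last[2], iv[i, 2]))
      } else {
        merged[[length(merged) + 1L]] <- iv[i, ]
      }
    }
  }
  iv <- do.call(rbind, merged)
  keep <- (iv[, 2] - iv[, 1] + 1L) >= min_len
  iv <- iv[keep, , drop = FALSE]
  tibble(start = as.integer(iv[, 1]), end = as.integer(iv[, 2]))
}

#' Hydropathy profile of one protein
#'
#' @param sequence One protein sequence.
#' @param window Odd window width (default 19).
#' @return Tibble with `position` and `hydropathy` (centred window mean; `NA`
#'   within half a window of the ends).
#' @export
hydropathy_profile <- function(sequence, window = 19L) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  h <- unname(KD_SCALE[chars])
  h[is.na(h)] <- 0
  tibble(
    position = seq_along(chars),
    hydropathy = as.numeric(stats::filter(h, rep(1 / window, window), sides = 2))
  )
}

#' Transmembrane filter predicate
#'
#' @param topologies Topology tibble.
#' @param min_count Minimum number of helices (default 1, the screen's
#'   "having transmembrane domain(s)" criterion).
#' @return Logical vector aligned with the rows of `topologies`.
#' @export
passes_tm_filter <- function(topologies, min_count = 1L) {
  topologies$n_tm >= min_count
}
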