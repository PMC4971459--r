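# Variable-gap protein motif matching. Patterns are written in dash notation:
# residue tokens (one letter, or letters joined by "/") alternate with spacer
# tokens ("X2" for exactly two arbitrary residues, "X9-39" for nine to
# thirty-nine). The shipped RING-finger pattern has eight zinc-coordinating
# slots; slot 5 ("C/H") decides the subtype of each individual match.

RING_SPEC <- "C-X2-C-X9-39-C-X1-3-H-X2-3-C/H-X2-C-X9-39-C-X2-C"

# Residues that may fill a coordination slot. Ambiguity codes (X, B, Z, U)
# and '*' never satisfy a slot; they are legal spacer fillers only.
SLOT_RESIDUES <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M", "F",
  "P", "S", "T", "W", "Y", "V"
)

#' Compile a dash-notation protein motif pattern
#'
#' Parses an alternation of residue tokens (a single one-letter code, or
#' several joined by `/` meaning "any of these") and spacer tokens (`Xn` for a
#' fixed gap of n residues, `Xn1-n2` for a bounded variable gap) into a
#' matcher used by [find_ring_motifs()].
#'
#' @param spec Dash-notation pattern string. Must begin and end with a residue
#'   token, and residue tokens must alternate with spacer tokens.
#' @param name Optional pattern name (defaults to `spec`).
#' @return An object of class `motif_pattern`: a list with `slots` (list of
#'   allowed-residue character vectors), `spacers` (list of `c(min, max)`
#'   integer bounds, one fewer than slots), `name` and `spec`.
#' @examples
#' compile_pattern("C-X2-C")
#' ring_pattern() # the canonical RING-finger pattern
#' @export
compile_pattern <- function(spec, name = spec) {
  stopifnot(is.character(spec), length(spec) == 1L)
  # split keeping X9-39 together: tokens are separated by "-" except the "-"
  # inside a spacer range, which sits between two digits after an X.
  tokens <- parse_motif_tokens(spec)
  slots <- list()
  spacers <- list()
  expect_residue <- TRUE
  for (tok in tokens) {
    is_spacer <- stringr::str_detect(tok, "^X\\d")
    if (expect_residue) {
      if (is_spacer) abort(paste0("Malformed pattern: expected residue token, got '", tok, "'"))
      res <- strsplit(tok, "/", fixed = TRUE)[[1]]
      if (!all(res %in% SLOT_RESIDUES) || length(res) == 0) {
        abort(paste0("Malformed residue token '", tok, "'"))
      }
      slots[[length(slots) + 1L]] <- res
    } else {
      if (!is_spacer) {
        abort(paste0("Malformed pattern: missing spacer before residue token '", tok, "'"))
      }
      m <- stringr::str_match(tok, "^X(\\d+)(?:-(\\d+))?$")
      if (is.na(m[1, 1])) abort(paste0("Malformed spacer token '", tok, "'"))
      lo <- as.integer(m[1, 2])
      hi <- if (is.na(m[1, 3])) lo else as.integer(m[1, 3])
      if (lo > hi) abort(paste0("Spacer token '", tok, "' has min > max"))
      spacers[[length(spacers) + 1L]] <- c(lo, hi)
    }
    expect_residue <- !expect_residue
  }
  if (expect_residue) abort("Pattern must end with a residue token")
  if (length(slots) < 2L) abort("Pattern needs at least two residue slots")
  structure(
    list(slots = slots, spacers = spacers, name = name, spec = spec),
    class = "motif_pattern"
  )
}

parse_motif_tokens <- function(spec) {
  if (!nzchar(spec)) abort("Empty pattern")
  # protect the range dash inside "X<digits>-<digits>" before splitting
  protected <- gsub("(X\\d+)-(\\d+)", "\\1:\\2", spec)
  tokens <- strsplit(protected, "-", fixed = TRUE)[[1]]
  if (any(!nzchar(tokens))) abort("Malformed pattern: empty token (check dashes)")
  sub(":", "-", tokens, fixed = TRUE)
}

#' @rdname compile_pattern
#' @export
ring_pattern <- function() {
  compile_pattern(RING_SPEC, name = "RING")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("<motif_pattern> ", x$name, "\n", sep = "")
  cat("  slots:  ", paste(vapply(x$slots, paste, "", collapse = "/"), collapse = " "), "\n", sep = "")
  cat("  spacers:", paste(vapply(x$spacers, function(s) {
    if (s[1] == s[2]) as.character(s[1]) else paste0(s[1], "-", s[2])
  }, ""), collapse = " "), "\n", sep = "")
  invisible(x)
}

# Depth-first enumeration of all coordination-residue assignments for one
# sequence. Candidate positions per slot are precomputed; recursion visits
# them in ascending order, so matches come out in lexicographic order of the
# position tuple without an extra sort.
find_matches_one <- function(seq, pattern) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  stop_at <- match("*", chars)
  if (!is.na(stop_at)) chars <- chars[seq_len(stop_at - 1L)]
  n <- length(chars)
  k <- length(pattern$slots)
  if (n == 0) return(list())
  cand <- lapply(pattern$slots, function(s) which(chars %in% s))
  if (any(lengths(cand) == 0)) return(list())
  out <- list()
  n_out <- 0L
  pos <- integer(k)
  recurse <- function(i) {
    if (i > k) {
      n_out <<- n_out + 1L
      out[[n_out]] <<- pos
      return(invisible())
    }
    b <- pattern$spacers[[i - 1L]]
    lo <- pos[i - 1L] + b[1] + 1L
    hi <- pos[i - 1L] + b[2] + 1L
    for (p in cand[[i]]) {
      if (p < lo) next
      if (p > hi) break
      pos[i] <<- p
      recurse(i + 1L)
    }
    invisible()
  }
  for (p1 in cand[[1]]) {
    pos[1] <- p1
    recurse(2L)
  }
  out[seq_len(n_out)]
}

#' Enumerate RING-finger motif matches in protein sequences
#'
#' Finds every distinct coordination-residue assignment (tuple of slot
#' positions) satisfying the pattern's slot and spacer constraints. All
#' overlapping assignments are reported; screening downstream is done on
#' "at least one match per protein". Scanning stops at the first `*` (stop)
#' character; ambiguity codes never satisfy a coordination slot.
#'
#' @param proteins Tibble with columns `id` and `sequence` (as from
#'   [read_proteins()]), or a single named/unnamed character vector of
#'   sequences.
#' @param pattern A `motif_pattern`, by default the canonical eight-slot
#'   RING-finger pattern [ring_pattern()].
#' @return A tibble with one row per match: `protein_id`, `subtype`
#'   (`C3H2C3` if the fifth coordination slot holds His, `C3HC4` if Cys; `NA`
#'   for patterns without the canonical eight slots), 1-based coordination
#'   positions `pos1`..`posK`, `start`/`end` (1-based inclusive span from
#'   first to last coordination residue), `residues` (the matched slot
#'   characters) and `spacers` (comma-joined inter-slot gap lengths). Rows are
#'   ordered by input protein, then lexicographically by position tuple.
#' @examples
#' seq <- paste0(
#'   "C", "AA", "C", strrep("A", 9), "C", "A", "H", "AA",
#'   "C", "AA", "C", strrep("A", 9), "C", "AA", "C"
#' )
#' find_ring_motifs(tibble::tibble(id = "toy", sequence = seq))
#' @export
find_ring_motifs <- function(proteins, pattern = ring_pattern()) {
  if (is.character(proteins)) {
    ids <- names(proteins) %||% paste0("seq", seq_along(proteins))
    proteins <- tibble(id = ids, sequence = unname(proteins))
  }
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  seqs <- toupper(proteins$sequence)
  validate_protein_sequences(seqs, proteins$id)
  k <- length(pattern$slots)
  res <- purrr::map2(proteins$id, seqs, function(id, s) {
    hits <- find_matches_one(s, pattern)
    if (length(hits) == 0) return(NULL)
    mat <- do.call(rbind, hits)
    colnames(mat) <- paste0("pos", seq_len(k))
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    residues <- apply(mat, 1L, function(p) paste(chars[p], collapse = ""))
    spacer_mat <- mat[, -1L, drop = FALSE] - mat[, -k, drop = FALSE] - 1L
    dplyr::bind_cols(
      tibble(protein_id = id),
      as_tibble(mat),
      tibble(
        start = unname(mat[, 1L]),
        end = unname(mat[, k]),
        residues = residues,
        spacers = apply(spacer_mat, 1L, paste, collapse = ",")
      )
    )
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble(
      protein_id = character(),
      !!!setNames(rep(list(integer()), k), paste0("pos", seq_len(k))),
      start = integer(), end = integer(),
      residues = character(), spacers = character()
    )
  }
  subtype <- if (k == 8L) classify_subtype(out$residues) else rep(NA_character_, nrow(out))
  dplyr::relocate(dplyr::mutate(out, subtype = subtype), "subtype", .after = "protein_id")
}

#' Classify RING-finger matches into C3H2C3 or C3HC4
#'
#' The canonical RING coordinates two zinc ions with eight residues; the
#' fourth is always His. Matches with a second His at the fifth coordination
#' slot are C3H2C3, those with Cys there are C3HC4.
#'
#' @param residues Character vector of eight-character coordination-residue
#'   strings (the `residues` column of [find_ring_motifs()] output), or a
#'   match tibble containing that column.
#' @return Character vector, `"C3H2C3"` or `"C3HC4"` per match.
#' @export
classify_subtype <- function(residues) {
  if (is.data.frame(residues)) residues <- residues$residues
  if (length(residues) == 0) return(character())
  if (any(nchar(residues) != 8L)) {
    abort("Subtype classification needs eight coordination residues per match")
  }
  slot5 <- substr(residues, 5L, 5L)
  if (any(!slot5 %in% c("C", "H"))) {
    abort("Coordination slot 5 outside {C, H}: not a canonical RING match")
  }
  ifelse(slot5 == "H", "C3H2C3", "C3HC4")
}

#' Canonical match per protein
#'
#' Reduces a match table to one row per protein: the lexicographically
#' smallest coordination-position tuple (leftmost start, then shortest
#' spacers). Used to give each gene a single subtype and span in candidate
#' tables.
#'
#' @param matches Match tibble from [find_ring_motifs()].
#' @return Tibble with at most one row per `protein_id`, in first-appearance
#'   protein order.
#' @export
best_match <- function(matches) {
  if (nrow(matches) == 0) return(matches)
  pos_cols <- grep("^pos\\d+$", names(matches), value = TRUE)
  matches |>
    dplyr::mutate(.prot = factor(.data$protein_id, levels = unique(.data$protein_id))) |>
    dplyr::arrange(.data$.prot, !!!rlang::syms(pos_cols)) |>
    dplyr::distinct(.data$.prot, .keep_all = TRUE) |>
    dplyr::select(-".prot")
}

#' Write / read a motif match table as TSV
#'
#' Columns are those of [find_ring_motifs()]; coordination positions and
#' spans are 1-based inclusive.
#'
#' @param matches Match tibble.
#' @param path File path.
#' @return `path` invisibly; `read_ring_tsv()` returns the tibble.
#' @export
write_ring_tsv <- function(matches, path) {
  readr::write_tsv(matches, path)
  invisible(path)
}

#' @rdname write_ring_tsv
#' @export
read_ring_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, col_types = readr::cols(
    protein_id = "c", subtype = "c", residues = "c", spacers = "c",
    .default = "i"
  ))
}
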