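# Independent oracles and small random-input helpers. The oracles
# deliberately use different algorithms from the package: the motif oracle
# enumerates coordination tuples by progressive data-frame joins with
# constraint filtering, and the element oracle compares position by position
# against explicit allowed-base sets (no regular expressions).

# All coordination-position tuples satisfying the pattern, as a matrix with
# one row per tuple, sorted lexicographically.
oracle_ring_positions <- function(seq, pattern = ring_pattern()) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  stop_at <- match("*", chars)
  if (!is.na(stop_at)) chars <- chars[seq_len(stop_at - 1L)]
  k <- length(pattern$slots)
  cand <- lapply(pattern$slots, function(s) which(chars %in% s))
  empty <- matrix(integer(), ncol = k, dimnames = list(NULL, paste0("p", seq_len(k))))
  if (any(lengths(cand) == 0)) return(empty)
  tup <- data.frame(p1 = cand[[1]])
  for (i in seq_len(k - 1L)) {
    nxt <- merge(tup, data.frame(nx = cand[[i + 1L]]))
    gap <- nxt$nx - nxt[[paste0("p", i)]] - 1L
    b <- pattern$spacers[[i]]
    nxt <- nxt[gap >= b[1] & gap <= b[2], , drop = FALSE]
    if (nrow(nxt) == 0) return(empty)
    names(nxt)[names(nxt) == "nx"] <- paste0("p", i + 1L)
    tup <- nxt
  }
  tup <- tup[, paste0("p", seq_len(k)), drop = FALSE]
  tup <- tup[do.call(order, tup), , drop = FALSE]
  m <- as.matrix(tup)
  dimnames(m) <- list(NULL, paste0("p", seq_len(k)))
  m
}

# Position matrix from a find_ring_motifs() tibble, for comparison.
match_positions <- function(matches) {
  pos_cols <- grep("^pos\\d+$", names(matches), value = TRUE)
  m <- as.matrix(matches[pos_cols])
  storage.mode(m) <- "integer"
  dimnames(m) <- list(NULL, paste0("p", seq_along(pos_cols)))
  m
}

# Naive degenerate scanner: position-by-position membership checks.
oracle_scan_elements <- function(sequence, elements = er_stress_elements(),
                                 both_strands = TRUE) {
  sets <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
    D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
    N = c("A", "C", "G", "T", "N")
  )
  comp <- c(
    A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S", W = "W",
    K = "M", M = "K", B = "V", V = "B", D = "H", H = "D", N = "N"
  )
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  L <- length(chars)
  starts_of <- function(pat) {
    pc <- strsplit(pat, "", fixed = TRUE)[[1]]
    m <- length(pc)
    if (L < m) return(integer())
    ok <- rep(TRUE, L - m + 1L)
    for (j in seq_len(m)) {
      ok <- ok & chars[seq_len(L - m + 1L) + j - 1L] %in% sets[[pc[j]]]
    }
    which(ok)
  }
  rows <- list()
  for (kk in seq_len(nrow(elements))) {
    el <- elements$element[kk]
    iu <- elements$iupac[kk]
    for (s in starts_of(iu)) {
      rows[[length(rows) + 1L]] <- data.frame(element = el, strand = "+", position = s - L - 1L)
    }
    if (both_strands) {
      rc <- paste(rev(unname(comp[strsplit(iu, "", fixed = TRUE)[[1]]])), collapse = "")
      for (s in starts_of(rc)) {
        rows[[length(rows) + 1L]] <- data.frame(element = el, strand = "-", position = s - L - 1L)
      }
    }
  }
  out <- do.call(rbind, c(list(data.frame(
    element = character(), strand = character(), position = integer()
  )), rows))
  out <- out[order(out$position, out$element, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Canonical (sorted, unrowname'd) hit frame from scan_upstream() output.
hit_frame <- function(hits) {
  d <- as.data.frame(hits[c("element", "strand", "position")])
  d <- d[order(d$position, d$element, d$strand), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# Random protein with boosted C/H frequency so RING matches actually occur.
rand_protein <- function(n, ch_weight = 6) {
  res <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
           "F", "P", "S", "T", "W", "Y", "V")
  w <- ifelse(res %in% c("C", "H"), ch_weight, 1)
  paste(sample(res, n, replace = TRUE, prob = w / sum(w)), collapse = "")
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Sequence built from a sparse position -> residue map over a filler residue.
seq_from_positions <- function(len, at, filler = "A") {
  chars <- rep(filler, len)
  chars[as.integer(names(at))] <- at
  paste(chars, collapse = "")
}

# The minimal RING instance used in several tests (all-minimal spacers).
minimal_ring_seq <- function(slot5 = "C", filler = "A") {
  paste0(
    "C", strrep(filler, 2), "C", strrep(filler, 9), "C", filler, "H",
    strrep(filler, 2), slot5, strrep(filler, 2), "C", strrep(filler, 9),
    "C", strrep(filler, 2), "C"
  )
}

# A small planted design (subset of the full fixture) for fast screen tests.
small_design <- function() {
  tibble::tibble(
    gene_id = c("G1", "G2", "G3", "G4", "G5", "G6"),
    subtype = c("C3H2C3", "C3H2C3", "C3H2C3", "C3HC4", "C3HC4", "C3HC4"),
    n_tm = c(1L, 2L, 6L, 1L, 3L, 5L),
    length = c(200L, 300L, 617L, 250L, 350L, 435L)
  )
}
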