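# TSS-relative upstream scanning for ER-stress cis-elements. Regions are
# written 5'->3' on the gene's sense strand; the base immediately after the
# last region character is the TSS (+1), so the final base is position -1 and
# there is no position 0. Hits report the sense-strand 5'-most base of the
# matched substring; reverse-orientation hits get a "-r" label suffix.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  # an element 'N' slot accepts any input base including an input 'N';
  # specified element bases never match an input 'N'
  N = c("A", "C", "G", "T", "N")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S", W = "W",
  K = "M", M = "K", B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' The ER-stress cis-element consensus definitions
#'
#' The three elements bound by the unfolded-protein-response transcription
#' factors: ERSE-I (`CCAAT-N9-CCACG/A`, bound by ATF6 with NF-Y), ERSE-II
#' (`ATTGG-N-CCACG`) and UPRE (`TGACGTGG/A`, bound by spliced XBP1), written
#' as IUPAC strings (`R` = A/G, `N` = any base).
#'
#' @return Tibble with columns `element` and `iupac`.
#' @export
er_stress_elements <- function() {
  tibble(
    element = c("ERSE-I", "ERSE-II", "UPRE"),
    iupac = c("CCAATNNNNNNNNNCCACR", "ATTGGNCCACG", "TGACGTGR")
  )
}

iupac_to_regex <- function(iupac) {
  chars <- strsplit(toupper(iupac), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad) > 0) abort(paste0("Unknown IUPAC code: ", paste(bad, collapse = ", ")))
  paste0(vapply(chars, function(ch) {
    s <- IUPAC_SETS[[ch]]
    if (length(s) == 1) s else paste0("[", paste(s, collapse = ""), "]")
  }, ""), collapse = "")
}

revcomp_iupac <- function(iupac) {
  chars <- rev(strsplit(toupper(iupac), "", fixed = TRUE)[[1]])
  paste(unname(IUPAC_COMPLEMENT[chars]), collapse = "")
}

# All (overlapping) 1-based start indices of a degenerate pattern.
degenerate_starts <- function(sequence, iupac) {
  rx <- paste0("(?=", iupac_to_regex(iupac), ")")
  m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer() else as.integer(m)
}

#' Extract TSS-relative upstream regions from a genome
#'
#' For a `+` gene the region is the `window` bases genomically upstream of
#' the TSS (`[tss - window, tss - 1]`, 1-based); for a `-` gene it is
#' `[tss + 1, tss + window]` reverse-complemented. Either way the returned
#' string reads 5'->3' toward the TSS on the gene's sense strand. Regions are
#' truncated at contig edges.
#'
#' @param genome A [Biostrings::DNAStringSet] (see [read_genome()]) or a
#'   named character vector of contig sequences.
#' @param tss Tibble with columns `chrom`, `tss` (1-based coordinate of the
#'   first transcribed base), `strand` (`+`/`-`) and `gene_id`.
#' @param window Upstream window size in nucleotides (default 5000).
#' @return Tibble of promoter regions: `gene_id`, `sequence`, `length`.
#' @export
extract_upstream <- function(genome, tss, window = 5000L) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  stopifnot(window >= 1L)
  contig_len <- setNames(Biostrings::width(genome), names(genome))
  rows <- purrr::pmap(tss, function(chrom, tss, strand, gene_id, ...) {
    if (!chrom %in% names(genome)) {
      abort(paste0("Unknown contig '", chrom, "' for gene ", gene_id))
    }
    len <- contig_len[[chrom]]
    if (tss < 1L || tss > len) {
      abort(paste0("TSS ", tss, " outside contig '", chrom, "' for gene ", gene_id))
    }
    if (strand == "+") {
      from <- max(1L, tss - window)
      to <- tss - 1L
      s <- if (to < from) "" else as.character(Biostrings::subseq(genome[[chrom]], from, to))
    } else if (strand == "-") {
      from <- tss + 1L
      to <- min(len, tss + window)
      s <- if (to < from) {
        ""
      } else {
        as.character(Biostrings::reverseComplement(Biostrings::subseq(genome[[chrom]], from, to)))
      }
    } else {
      abort(paste0("Strand must be '+' or '-' for gene ", gene_id))
    }
    tibble(gene_id = gene_id, sequence = s, length = nchar(s))
  })
  dplyr::bind_rows(rows)
}

#' Scan upstream regions for ER-stress elements
#'
#' Reports every (overlapping) occurrence of each element on the sense
#' strand and, by default, of its reverse complement (reverse-orientation
#' occurrences, labelled with a `-r` suffix as in `UPRE-r`). Positions are
#' TSS-relative: the 5'-most base of the matched substring on the sense
#' strand, with the TSS at +1 and the last upstream base at -1 (no 0). An
#' `N` in the input matches only element `N` slots.
#'
#' @param regions Promoter-region tibble (`gene_id`, `sequence`), e.g. from
#'   [extract_upstream()] or [make_promoter()].
#' @param elements Element definitions, by default [er_stress_elements()].
#' @param both_strands Scan the reverse orientation too? Default `TRUE`.
#' @return Tibble of hits: `gene_id`, `element`, `strand` (`+`/`-`),
#'   `position` (negative, TSS-relative), `matched` (sense-strand substring)
#'   and `label` (element name, `-r`-suffixed for `-` strand), sorted by gene
#'   (input order) then position.
#' @examples
#' region <- make_promoter("g1", plants = tibble::tibble(
#'   element = "UPRE", strand = "+", position = -315
#' ), window = 334, seed = 1)
#' scan_upstream(region)
#' @export
scan_upstream <- function(regions, elements = er_stress_elements(),
                          both_strands = TRUE) {
  hits <- purrr::pmap(regions, function(gene_id, sequence, ...) {
    sequence <- toupper(sequence)
    L <- nchar(sequence)
    per_el <- purrr::pmap(elements, function(element, iupac, ...) {
      w <- nchar(iupac)
      fwd <- degenerate_starts(sequence, iupac)
      out <- tibble(
        gene_id = gene_id, element = element, strand = "+",
        position = fwd - L - 1L,
        matched = stringr::str_sub(sequence, fwd, fwd + w - 1L),
        label = element
      )
      if (both_strands) {
        rev_starts <- degenerate_starts(sequence, revcomp_iupac(iupac))
        out <- dplyr::bind_rows(out, tibble(
          gene_id = gene_id, element = element, strand = "-",
          position = rev_starts - L - 1L,
          matched = stringr::str_sub(sequence, rev_starts, rev_starts + w - 1L),
          label = paste0(element, "-r")
        ))
      }
      out
    })
    dplyr::arrange(dplyr::bind_rows(per_el), .data$position, .data$element, .data$strand)
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    out <- tibble(
      gene_id = character(), element = character(), strand = character(),
      position = integer(), matched = character(), label = character()
    )
  }
  out
}

#' Genes with at least one upstream element hit
#'
#' @param hits Hit tibble from [scan_upstream()].
#' @param genes Optional character vector giving the original gene order
#'   (genes without hits are allowed); defaults to first-appearance order in
#'   `hits`.
#' @return Character vector of gene ids with >= 1 hit, in `genes` order.
#' @export
genes_with_elements <- function(hits, genes = NULL) {
  genes <- genes %||% unique(hits$gene_id)
  intersect(genes, unique(hits$gene_id))
}

#' Serialize promoter hits to TSV / BED6
#'
#' `write_promoter_bed()` needs genomic anchoring: supply the TSS table used
#' for extraction so TSS-relative positions can be mapped back to 0-based
#' half-open genomic intervals. The BED strand column is the element's strand
#' relative to the genome (the gene's strand for `+` hits, its opposite for
#' `-r` hits); the name column is the hit label.
#'
#' @param hits Hit tibble from [scan_upstream()].
#' @param path Output path.
#' @param tss TSS tibble (`chrom`, `tss`, `strand`, `gene_id`).
#' @param elements Element definitions (for element lengths).
#' @return `path`, invisibly.
#' @export
write_promoter_tsv <- function(hits, path) {
  readr::write_tsv(hits, path)
  invisible(path)
}

#' @rdname write_promoter_tsv
#' @export
write_promoter_bed <- function(hits, path, tss, elements = er_stress_elements()) {
  el_len <- setNames(nchar(elements$iupac), elements$element)
  joined <- dplyr::inner_join(hits, tss, by = "gene_id")
  bed <- purrr::pmap(joined, function(gene_id, element, strand.x, position,
                                      label, chrom, tss, strand.y, ...) {
    w <- el_len[[element]]
    if (strand.y == "+") {
      start0 <- tss + position - 1L # 0-based: tss-1 is 0-based TSS
      g_strand <- if (strand.x == "+") "+" else "-"
    } else {
      # sense-strand position p covers genomic [tss - p - w, tss - p - 1] 0-based
      start0 <- tss - position - w
      g_strand <- if (strand.x == "+") "-" else "+"
    }
    tibble(
      chrom = chrom, start = start0, end = start0 + w,
      name = label, score = 0L, strand = g_strand
    )
  })
  readr::write_tsv(dplyr::bind_rows(bed), path, col_names = FALSE)
  invisible(path)
}
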