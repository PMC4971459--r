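# Sequence ingest. Protein FASTA comes in as a tibble (id, description,
# sequence); genomes stay as a Biostrings::DNAStringSet because promoter
# extraction needs random access by contig.

# 20 standard residues plus ambiguity codes and the stop character seen in
# database dumps.
PROTEIN_ALPHABET <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M", "F",
  "P", "S", "T", "W", "Y", "V", "X", "U", "B", "Z", "*"
)

validate_protein_sequences <- function(sequence, id = NULL) {
  bad <- stringr::str_detect(
    sequence,
    paste0("[^", paste(PROTEIN_ALPHABET[PROTEIN_ALPHABET != "*"], collapse = ""), "*]")
  )
  if (any(bad)) {
    who <- if (is.null(id)) which(bad) else id[bad]
    abort(paste0(
      "Invalid protein sequence character(s) in: ",
      paste(utils::head(who, 5), collapse = ", ")
    ))
  }
  if (any(!nzchar(sequence))) {
    who <- if (is.null(id)) which(!nzchar(sequence)) else id[!nzchar(sequence)]
    abort(paste0("Empty protein sequence for: ", paste(head(who, 5), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Read a protein FASTA file into a tibble
#'
#' Sequences are uppercased on ingest and validated against the 20 standard
#' one-letter residue codes plus the ambiguity characters `X`, `U`, `B`, `Z`
#' and the stop character `*`; anything else is an error.
#'
#' @param path Path to a (multi-)FASTA file, wrapped or unwrapped lines.
#' @return A tibble with columns `id` (first whitespace-delimited token of the
#'   header), `description` (remainder of the header, possibly empty) and
#'   `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">p1 a protein", "MCAAC", ">p2", "LLLV"), fa)
#' read_proteins(fa)
#' @export
read_proteins <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  header <- names(aa)
  tbl <- tibble(
    id = stringr::str_extract(header, "^\\S+"),
    description = stringr::str_trim(stringr::str_remove(header, "^\\S+\\s*")),
    sequence = toupper(as.character(aa))
  )
  validate_protein_sequences(tbl$sequence, tbl$id)
  tbl
}

#' Write a protein tibble to FASTA
#'
#' @param proteins Tibble with columns `id`, `sequence` and optionally
#'   `description`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteins <- function(proteins, path) {
  desc <- proteins$description %||% rep("", nrow(proteins))
  hdr <- ifelse(nzchar(desc), paste(proteins$id, desc), proteins$id)
  aa <- Biostrings::AAStringSet(setNames(proteins$sequence, hdr))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read a genome (or promoter set) FASTA as a DNAStringSet
#'
#' @param path Path to a DNA FASTA file.
#' @return A [Biostrings::DNAStringSet] named by the first header token.
#' @export
read_genome <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  names(dna) <- stringr::str_extract(names(dna), "^\\S+")
  dna
}

#' Read a TSS table
#'
#' A BED-like TSV with columns `chrom`, `tss` (1-based genomic coordinate of
#' the first transcribed base), `strand` (`+`/`-`) and `gene_id`.
#'
#' @param path Path to the TSV (with header).
#' @return A tibble with those four columns.
#' @export
read_tss <- function(path) {
  tss <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("chrom", "tss", "strand", "gene_id")
  missing <- setdiff(need, names(tss))
  if (length(missing) > 0) {
    abort(paste0("TSS table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  dplyr::select(tss, dplyr::all_of(need))
}
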