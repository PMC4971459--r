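test_that("upstream extraction respects strand and the no-position-0 convention", {
  genome <- c(chr1 = "AAAAAAAAAACCGGTACGTA")
  plus <- extract_upstream(genome, tibble::tibble(
    chrom = "chr1", tss = 11, strand = "+", gene_id = "g+"
  ), window = 10)
  expect_equal(plus$sequence, "AAAAAAAAAA")

  minus <- extract_upstream(c(chr1 = "ACGTTTTTTT"), tibble::tibble(
    chrom = "chr1", tss = 5, strand = "-", gene_id = "g-"
  ), window = 4)
  expect_equal(minus$sequence, "AAAA") # revcomp of TTTT at bases 6..9
})

test_that("regions truncate at contig edges and the index/position map stays a bijection", {
  contig <- c(chr1 = rand_dna(50))
  withr::local_seed(123)
  r <- extract_upstream(contig, tibble::tibble(
    chrom = "chr1", tss = 21, strand = "+", gene_id = "g"
  ), window = 100)
  expect_equal(r$length, 20)
  # brute force: region index i holds genomic base tss + (i - L - 1)
  chars <- strsplit(contig[["chr1"]], "")[[1]]
  for (i in seq_len(r$length)) {
    pos <- i - r$length - 1L
    expect_equal(substr(r$sequence, i, i), chars[21 + pos])
  }
})

test_that("bad TSS rows fail loudly", {
  genome <- c(chr1 = rand_dna(50))
  expect_error(
    extract_upstream(genome, tibble::tibble(chrom = "chrX", tss = 10, strand = "+", gene_id = "g1")),
    "chrX.*g1"
  )
  expect_error(
    extract_upstream(genome, tibble::tibble(chrom = "chr1", tss = 99, strand = "+", gene_id = "g2")),
    "g2"
  )
})

test_that("a planted UPRE is reported at its TSS-relative position", {
  region <- make_promoter("RNF130", tibble::tibble(
    element = "UPRE", strand = "+", position = -315L
  ), window = 334, seed = 4)
  hits <- scan_upstream(region)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$position, -315L)
  expect_equal(hits$label, "UPRE")
  expect_equal(hits$strand, "+")
})

test_that("reverse-orientation occurrences get the -r label", {
  region <- tibble::tibble(
    gene_id = "g", sequence = paste0(strrep("A", 50), "CCACGTCA", strrep("A", 20)),
    length = 78
  )
  hits <- scan_upstream(region)
  expect_equal(hits$label, "UPRE-r")
  expect_equal(hits$strand, "-")
  expect_equal(hits$position, 51 - 78 - 1)
  expect_equal(hits$matched, "CCACGTCA")
})

test_that("overlapping and nested occurrences are all reported", {
  # a UPRE instance embedded in the ERSE-I nine-base spacer
  inner <- paste0("CCAAT", "TGACGTGGA", "CCACG")
  region <- tibble::tibble(
    gene_id = "g", sequence = paste0(strrep("T", 30), inner, strrep("T", 11)),
    length = 60
  )
  hits <- scan_upstream(region)
  expect_setequal(hits$element, c("ERSE-I", "UPRE"))
})

test_that("input N bases match only element N slots", {
  with_n <- tibble::tibble(
    gene_id = "g",
    sequence = paste0(strrep("T", 20), "CCAAT", "NNNNNNNNN", "CCACG", strrep("T", 10)),
    length = 49
  )
  expect_equal(scan_upstream(with_n)$element, "ERSE-I")
  # N at a specified slot blocks the hit
  blocked <- tibble::tibble(
    gene_id = "g", sequence = paste0(strrep("T", 20), "TGACGTGN", strrep("T", 10)),
    length = 38
  )
  expect_equal(nrow(scan_upstream(blocked)), 0)
})

test_that("the ERSE-I matcher accepts exactly nine bases between half-sites", {
  hits_per_k <- vapply(0:15, function(k) {
    region <- make_promoter("g", window = 300, seed = 100 + k)
    seq <- region$sequence
    probe <- paste0("CCAAT", strrep("T", k), "CCACG")
    substr(seq, 100, 100 + nchar(probe) - 1) <- probe
    nrow(scan_upstream(
      tibble::tibble(gene_id = "g", sequence = seq, length = 300),
      elements = er_stress_elements()[1, ]
    ))
  }, 0L)
  expect_equal(which(hits_per_k == 1) - 1L, 9L)
})

test_that("scanning equals the naive position-by-position oracle", {
  withr::local_seed(17)
  instances <- c("CCAATACGTACGTCCACG", "ATTGGACCACG", "TGACGTGG", "TGACGTGA",
                 "CCACGTCA", "CGTGGTCCAAT")
  for (i in seq_len(100)) {
    L <- sample(600:1200, 1)
    seq <- rand_dna(L)
    for (j in seq_len(sample(0:3, 1))) {
      ins <- sample(instances, 1)
      at <- sample(L - nchar(ins), 1)
      substr(seq, at, at + nchar(ins) - 1) <- ins
    }
    got <- hit_frame(scan_upstream(tibble::tibble(gene_id = "g", sequence = seq, length = L)))
    expect_equal(got, oracle_scan_elements(seq))
  }
})

test_that("scanning a reverse complement swaps strands and remaps positions", {
  withr::local_seed(19)
  el <- er_stress_elements()
  el_len <- stats::setNames(nchar(el$iupac), el$element)
  for (i in 1:20) {
    L <- sample(500:900, 1)
    seq <- rand_dna(L)
    ins <- sample(c("TGACGTGG", "ATTGGACCACG", "CCACGTCA"), 1)
    at <- sample(L - nchar(ins), 1)
    substr(seq, at, at + nchar(ins) - 1) <- ins
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    fwd <- scan_upstream(tibble::tibble(gene_id = "g", sequence = seq, length = L))
    rev <- scan_upstream(tibble::tibble(gene_id = "g", sequence = rc, length = L))
    remapped <- tibble::tibble(
      element = rev$element,
      strand = ifelse(rev$strand == "+", "-", "+"),
      position = -rev$position - L - el_len[rev$element]
    )
    expect_equal(
      hit_frame(fwd),
      hit_frame(tibble::as_tibble(c(list(gene_id = "g"), remapped)))
    )
  }
})

test_that("matched substrings always have the element's defined length", {
  withr::local_seed(23)
  region <- make_promoter("g", tibble::tibble(
    element = c("ERSE-I", "ERSE-II", "UPRE"),
    strand = c("+", "-", "+"),
    position = c(-400L, -200L, -100L)
  ), window = 500)
  hits <- scan_upstream(region)
  el_len <- stats::setNames(nchar(er_stress_elements()$iupac), er_stress_elements()$element)
  expect_equal(nchar(hits$matched), unname(el_len[hits$element]))
})

test_that("genes_with_elements keeps original gene order and lists genes once", {
  expect_equal(
    genes_with_elements(scan_upstream(tibble::tibble(
      gene_id = "g", sequence = strrep("A", 100), length = 100
    ))),
    character(0)
  )
  hrd1 <- make_promoter("HRD1", tibble::tibble(
    element = c("ERSE-I", "UPRE"), strand = "+", position = c(-506L, -2303L)
  ), window = 5000, seed = 31)
  hits <- scan_upstream(hrd1)
  expect_equal(nrow(hits), 2)
  expect_equal(genes_with_elements(hits, c("Z1", "HRD1", "Z2")), "HRD1")
})

test_that("promoter hits serialize to BED with correct genomic anchoring", {
  withr::local_seed(37)
  region <- make_promoter("g", tibble::tibble(
    element = "UPRE", strand = "+", position = -50L
  ), window = 100)
  genome <- c(ctg = paste0(region$sequence, rand_dna(20)))
  tss <- tibble::tibble(chrom = "ctg", tss = 101L, strand = "+", gene_id = "g")
  hits <- scan_upstream(region)
  path <- withr::local_tempfile(fileext = ".bed")
  write_promoter_bed(hits, path, tss)
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name", "score", "strand"),
                         show_col_types = FALSE)
  # the BED interval must slice the planted instance back out of the genome
  expect_equal(substr(genome[["ctg"]], bed$start + 1, bed$end), hits$matched)
  expect_equal(bed$name, "UPRE")
})
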