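# Self-verifying fixture generators. Every generator checks its own
# post-condition with the same pipeline code used for analysis (rejection
# sampling), so planted ground truth is recovered by construction: a planted
# proteome yields exactly the planted candidates, a planted promoter yields
# exactly the planted hits, a noiseless Ct table yields exact folds.
#
# The default fixture transcribes the published candidate tables: 37 genes
# with their motif subtype, TMHMM helix count and protein length, plus the
# eight genes carrying upstream ER-stress elements at their reported
# TSS-relative positions.

# Hydrophilic background residues (Kyte-Doolittle <= -0.4, no C/H so the
# planted coordination tuple is the unique RING match).
BG_RESIDUES <- c("S", "T", "N", "Q", "E", "D", "K", "R", "G", "P")
# Strongly hydrophobic residues for planted membrane-spanning stretches.
TM_RESIDUES <- c("L", "I", "V", "F")
TM_LEN <- 21L # planted transmembrane stretch length (residues)
TM_SEP <- 23L # minimum hydrophilic spacing so predicted helices stay distinct

#' The table-derived fixture specification
#'
#' The default synthetic study design: one protein row per published
#' candidate gene (motif subtype, transmembrane count, protein length), the
#' upstream-element plant list for the eight genes with reported ER-stress
#' elements (reverse orientation for the one `-r` hit), 200 motif-free
#' decoys and a 5000-nt promoter window.
#'
#' @return A list with `proteins` (tibble: `gene_id`, `subtype`, `n_tm`,
#'   `length`), `plants` (tibble: `gene_id`, `element`, `strand`,
#'   `position`), `decoys` and `window`.
#' @export
fixture_spec <- function() {
  proteins <- dplyr::bind_rows(
    tibble(
      gene_id = c(
        "RNF130", "RNF150", "RNF149", "RNF133", "RNF128", "RNF122", "RNF24",
        "RNF13", "RNF167", "ZNRF4", "RNF43", "ZNRF3", "SYVN1", "AMFR",
        "RNF175", "RNF121", "RNF145", "RNF139", "RNF103"
      ),
      subtype = "C3H2C3",
      n_tm = c(2L, 2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L, 1L, 6L, 5L, 5L, 6L, 12L, 12L, 4L),
      length = c(419L, 438L, 400L, 376L, 428L, 155L, 148L, 381L, 350L, 429L,
                 783L, 936L, 617L, 643L, 328L, 327L, 663L, 664L, 685L)
    ),
    tibble(
      gene_id = c(
        "RNF19A", "RNF19B", "RNF5", "RNF185", "RNF170", "RNF186", "RNF152",
        "RNF183", "RNF182", "TRIM59", "TRIM13", "BFAR", "RNF180", "RNFT1",
        "RNF26", "CGRRF1", "MUL1", "RNF217"
      ),
      subtype = "C3HC4",
      n_tm = c(2L, 2L, 2L, 2L, 3L, 2L, 1L, 1L, 2L, 1L, 1L, 3L, 1L, 5L, 4L, 1L, 2L, 1L),
      length = c(838L, 732L, 180L, 192L, 258L, 227L, 203L, 192L, 247L, 403L,
                 407L, 450L, 592L, 435L, 433L, 332L, 352L, 542L)
    )
  )
  plants <- tibble(
    gene_id = c("RNF130", "RNF149", "RNF145", "SYVN1", "SYVN1", "RNF121",
                "RNF19A", "RNF170", "RNF180"),
    element = c("UPRE", "ERSE-I", "ERSE-II", "ERSE-I", "UPRE", "UPRE",
                "UPRE", "UPRE", "ERSE-II"),
    strand = c("+", "+", "+", "+", "+", "+", "-", "+", "+"),
    position = c(-315L, -2586L, -1258L, -506L, -2303L, -2372L, -428L, -627L, -4801L)
  )
  list(proteins = proteins, plants = plants, decoys = 200L, window = 5000L)
}

sample_bg <- function(n) {
  paste(sample(BG_RESIDUES, n, replace = TRUE), collapse = "")
}

minimal_ring_motif <- function(subtype) {
  slot5 <- if (subtype == "C3H2C3") "H" else "C"
  paste0(
    "C", sample_bg(2), "C", sample_bg(9), "C", sample_bg(1), "H", sample_bg(2),
    slot5, sample_bg(2), "C", sample_bg(9), "C", sample_bg(2), "C"
  )
}

#' Generate one protein with a planted RING motif and transmembrane stretches
#'
#' Builds a hydrophilic-background sequence carrying exactly one minimal
#' RING motif of the requested subtype and `n_tm` hydrophobic 21-residue
#' stretches (the first at the N terminus, signal-peptide-like), then
#' verifies by rejection sampling that [find_ring_motifs()] recovers matches
#' of only the requested subtype and [predict_tm()] recovers exactly `n_tm`
#' helices.
#'
#' @param gene_id Protein/gene identifier.
#' @param subtype `"C3H2C3"` or `"C3HC4"`.
#' @param n_tm Number of transmembrane stretches (>= 0).
#' @param length Target sequence length in residues; must accommodate the
#'   motif and the spaced stretches.
#' @param seed Optional integer seed (otherwise the current RNG stream is
#'   used).
#' @param max_tries Rejection-sampling budget (default 10000).
#' @return A one-row protein tibble (`id`, `description`, `sequence`).
#' @export
make_motif_protein <- function(gene_id, subtype = c("C3HC4", "C3H2C3"),
                               n_tm, length, seed = NULL, max_tries = 10000L) {
  subtype <- match.arg(subtype)
  if (!is.null(seed)) withr::local_seed(seed)
  motif_len <- 35L
  required <- motif_len + n_tm * (TM_LEN + TM_SEP)
  if (length < required) {
    abort(paste0(
      "Infeasible spec for ", gene_id, ": length ", length,
      " < required ", required, " (motif + ", n_tm, " spaced TM stretches)"
    ))
  }
  for (try in seq_len(max_tries)) {
    slack <- length - required
    n_gaps <- n_tm + 1L # gaps after motif/TM blocks incl. tail
    extra <- if (slack > 0) {
      as.integer(stats::rmultinom(1, slack, rep(1 / n_gaps, n_gaps)))
    } else {
      rep(0L, n_gaps)
    }
    blocks <- character()
    if (n_tm >= 1L) {
      blocks <- c(blocks, paste(sample(TM_RESIDUES, TM_LEN, replace = TRUE), collapse = ""))
      blocks <- c(blocks, sample_bg(TM_SEP + extra[1]))
    }
    blocks <- c(blocks, minimal_ring_motif(subtype))
    if (n_tm >= 2L) {
      for (i in 2:n_tm) {
        blocks <- c(blocks, sample_bg(TM_SEP + extra[i]))
        blocks <- c(blocks, paste(sample(TM_RESIDUES, TM_LEN, replace = TRUE), collapse = ""))
      }
    }
    blocks <- c(blocks, sample_bg(extra[n_gaps] + if (n_tm == 0L) TM_SEP * 0L else 0L))
    seq <- paste(blocks, collapse = "")
    seq <- substr(seq, 1L, length)
    if (nchar(seq) < length) seq <- paste0(seq, sample_bg(length - nchar(seq)))
    m <- find_ring_motifs(tibble(id = gene_id, sequence = seq))
    if (nrow(m) == 0 || any(m$subtype != subtype)) next
    if (predict_tm(c(seq))$n_tm[1] != n_tm) next
    return(tibble(
      id = gene_id,
      description = paste0("synthetic ", subtype, " n_tm=", n_tm),
      sequence = seq
    ))
  }
  abort(paste0("Rejection budget exhausted for ", gene_id, ": spec likely infeasible"))
}

#' Generate a motif-free decoy protein
#'
#' Uniform-composition sequence over the 20 standard residues, redrawn until
#' it contains no RING-finger match.
#'
#' @param gene_id Identifier.
#' @param length Sequence length.
#' @param seed Optional seed.
#' @param max_tries Rejection budget.
#' @return One-row protein tibble.
#' @export
make_decoy_protein <- function(gene_id, length, seed = NULL, max_tries = 1000L) {
  if (!is.null(seed)) withr::local_seed(seed)
  for (try in seq_len(max_tries)) {
    seq <- paste(sample(SLOT_RESIDUES, length, replace = TRUE), collapse = "")
    if (nrow(find_ring_motifs(tibble(id = gene_id, sequence = seq))) == 0) {
      return(tibble(id = gene_id, description = "synthetic decoy", sequence = seq))
    }
  }
  abort("Could not draw a motif-free decoy")
}

#' Generate the full planted proteome
#'
#' One planted protein per row of the design (default: the table-derived
#' [fixture_spec()]) plus `decoys` motif-free decoys, in shuffled order.
#'
#' @param design Protein design tibble (`gene_id`, `subtype`, `n_tm`,
#'   `length`).
#' @param decoys Number of decoy proteins (default 200).
#' @param decoy_lengths Range of decoy lengths (default 150--500).
#' @param seed Optional seed controlling the whole proteome.
#' @return Protein tibble (`id`, `description`, `sequence`).
#' @export
synth_proteome <- function(design = fixture_spec()$proteins, decoys = 200L,
                           decoy_lengths = c(150L, 500L), seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  planted <- purrr::pmap(design, function(gene_id, subtype, n_tm, length, ...) {
    make_motif_protein(gene_id, subtype, n_tm, length)
  })
  decoy_rows <- purrr::map(seq_len(decoys), function(i) {
    make_decoy_protein(
      sprintf("DECOY%03d", i),
      sample(seq(decoy_lengths[1], decoy_lengths[2]), 1)
    )
  })
  out <- dplyr::bind_rows(planted, decoy_rows)
  out[sample.int(nrow(out)), ]
}

instantiate_iupac <- function(iupac) {
  chars <- strsplit(iupac, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    s <- setdiff(IUPAC_SETS[[ch]], "N")
    if (length(s) == 1) s else sample(s, 1)
  }, ""), collapse = "")
}

#' Generate a promoter region with planted ER-stress elements
#'
#' Draws a uniform-composition background, rejection-checked to be free of
#' all three elements on both strands, then writes each planted element (a
#' random instantiation of its IUPAC consensus; reverse-complemented for `-`
#' strand plants) at the requested TSS-relative position, and verifies that
#' [scan_upstream()] returns exactly the planted hits.
#'
#' @param gene_id Gene identifier.
#' @param plants Tibble (`element`, `strand`, `position`) of plants; may be
#'   empty. Positions are TSS-relative 5'-most bases (negative); planted
#'   intervals must not overlap and must fit in the window.
#' @param window Region length in nucleotides (default 5000).
#' @param elements Element definitions (default [er_stress_elements()]).
#' @param seed Optional seed.
#' @param max_tries Rejection budget.
#' @return One-row region tibble (`gene_id`, `sequence`, `length`).
#' @export
make_promoter <- function(gene_id, plants = NULL, window = 5000L,
                          elements = er_stress_elements(), seed = NULL,
                          max_tries = 200L) {
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.null(plants)) plants <- tibble(element = character(), strand = character(), position = integer())
  el_len <- setNames(nchar(elements$iupac), elements$element)
  if (nrow(plants) > 0) {
    if (any(!plants$element %in% names(el_len))) abort("Unknown element in plants")
    w <- el_len[plants$element]
    if (any(plants$position + w > 0)) {
      abort(paste0("Plant extends past the TSS for ", gene_id))
    }
    if (any(plants$position < -window)) {
      abort(paste0("Plant outside the ", window, "-nt window for ", gene_id))
    }
    iv <- cbind(plants$position, plants$position + w - 1L)
    if (nrow(iv) > 1) {
      o <- order(iv[, 1])
      if (any(iv[o, 1][-1] <= iv[o, 2][-nrow(iv)])) {
        abort(paste0("Overlapping plants for ", gene_id))
      }
    }
  }
  for (try in seq_len(max_tries)) {
    bg <- paste(sample(c("A", "C", "G", "T"), window, replace = TRUE), collapse = "")
    region <- tibble(gene_id = gene_id, sequence = bg, length = window)
    if (nrow(scan_upstream(region, elements)) > 0) next
    seq <- bg
    if (nrow(plants) > 0) {
      for (i in seq_len(nrow(plants))) {
        inst <- instantiate_iupac(elements$iupac[elements$element == plants$element[i]])
        if (plants$strand[i] == "-") {
          inst <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(inst)))
        }
        at <- plants$position[i] + window + 1L # 1-based region index
        substr(seq, at, at + nchar(inst) - 1L) <- inst
      }
    }
    region <- tibble(gene_id = gene_id, sequence = seq, length = window)
    hits <- scan_upstream(region, elements)
    ok <- nrow(hits) == nrow(plants) &&
      (nrow(plants) == 0 || {
        got <- dplyr::arrange(hits[c("element", "strand", "position")], .data$position)
        want <- dplyr::arrange(
          tibble(element = plants$element, strand = plants$strand,
                 position = as.integer(plants$position)),
          .data$position
        )
        identical(as.data.frame(got), as.data.frame(want))
      })
    if (ok) return(region)
  }
  abort(paste0("Rejection budget exhausted planting promoter for ", gene_id))
}

#' Generate planted promoters for a gene panel
#'
#' @param genes Character vector of gene ids (regions are generated for all,
#'   with plants only where listed).
#' @param plants Plant tibble (`gene_id`, `element`, `strand`, `position`),
#'   default from [fixture_spec()].
#' @param window Region length (default 5000).
#' @param seed Optional seed.
#' @return Region tibble, one row per gene.
#' @export
synth_promoters <- function(genes, plants = fixture_spec()$plants,
                            window = 5000L, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  dplyr::bind_rows(purrr::map(genes, function(g) {
    make_promoter(g, plants[plants$gene_id == g, c("element", "strand", "position")],
      window = window
    )
  }))
}

#' Generate a Ct table with known fold effects
#'
#' Each effects row defines one treated sample group: the target gene's Ct is
#' `baseline_ct - log2(true_fold) + N(0, sd)` per replicate, so the true fold
#' relative to the automatically added control sample (`true_fold = 1`) is
#' exact at `sd = 0`. The reference gene is constant across samples up to
#' `ref_sd` noise. Ground truth (including control rows) is attached as
#' attribute `"truth"`.
#'
#' @param effects Tibble with columns `gene`, `condition`, `time_h`,
#'   `true_fold`, `sd`, `n`.
#' @param reference_gene Reference gene name (default `"GAPDH"`).
#' @param baseline_ct Unperturbed target Ct (default 25 cycles).
#' @param reference_ct Reference-gene Ct (default 15 cycles).
#' @param ref_sd Reference-gene noise SD (default 0).
#' @param control_condition Label for the added calibrator sample (default
#'   `"control"`, `time_h = 0`).
#' @param seed Optional seed.
#' @return Long-format Ct tibble (`sample_id`, `condition`, `time_h`,
#'   `gene`, `replicate`, `ct`).
#' @export
make_ct_table <- function(effects, reference_gene = "GAPDH", baseline_ct = 25,
                          reference_ct = 15, ref_sd = 0,
                          control_condition = "control", seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  stopifnot(all(c("gene", "condition", "time_h", "true_fold", "sd", "n") %in% names(effects)))
  if (any(effects$sd < 0) || any(effects$n < 1)) abort("Need sd >= 0 and n >= 1")
  genes <- unique(effects$gene)
  controls <- tibble(
    gene = genes, condition = control_condition, time_h = 0,
    true_fold = 1,
    sd = vapply(genes, function(g) max(effects$sd[effects$gene == g]), 0),
    n = vapply(genes, function(g) max(effects$n[effects$gene == g]), 0)
  )
  all_eff <- dplyr::bind_rows(controls, effects)
  all_eff$sample_id <- paste(all_eff$condition, all_eff$time_h, sep = "_")
  target_rows <- purrr::pmap(all_eff, function(gene, condition, time_h, true_fold,
                                               sd, n, sample_id, ...) {
    tibble(
      sample_id = sample_id, condition = condition, time_h = time_h,
      gene = gene, replicate = seq_len(n),
      ct = baseline_ct - log2(true_fold) + rnorm(n, 0, sd)
    )
  })
  samples <- dplyr::distinct(all_eff[c("sample_id", "condition", "time_h", "n")]) |>
    dplyr::group_by(.data$sample_id, .data$condition, .data$time_h) |>
    dplyr::summarise(n = max(.data$n), .groups = "drop")
  ref_rows <- purrr::pmap(samples, function(sample_id, condition, time_h, n) {
    tibble(
      sample_id = sample_id, condition = condition, time_h = time_h,
      gene = reference_gene, replicate = seq_len(n),
      ct = reference_ct + rnorm(n, 0, ref_sd)
    )
  })
  out <- dplyr::bind_rows(c(target_rows, ref_rows))
  attr(out, "truth") <- all_eff
  out
}

#' Write a complete synthetic fixture to disk
#'
#' Emits plain-text inputs for every pipeline stage: the planted proteome
#' FASTA, its TMHMM-format topology predictions, a promoter "genome" FASTA
#' (one contig per gene: the upstream region followed by 50 downstream
#' bases) with a matching TSS TSV, a long-format Ct TSV, and a ground-truth
#' manifest TSV of the planted design.
#'
#' @param dir Output directory (created if needed).
#' @param spec Fixture specification (default [fixture_spec()]).
#' @param effects Ct effects design; default plants a two-fold induction of
#'   RNFT1 at 6 h under both stressors (sd 0.1, n = 4) with HRD1 (4-fold)
#'   and BiP (20-fold) positive controls.
#' @param seed Integer seed for the whole fixture.
#' @return Named character vector of the files written, invisibly.
#' @export
write_fixture <- function(dir, spec = fixture_spec(), effects = NULL, seed = 1L) {
  withr::local_seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  effects <- effects %||% tidyr::expand_grid(
    gene = c("RNFT1", "HRD1", "BiP"),
    condition = c("Tg", "Tm"),
    time_h = 6
  ) |>
    dplyr::mutate(
      true_fold = c(2, 2, 4, 4, 20, 20)[match(paste(.data$gene, .data$condition),
        paste(rep(c("RNFT1", "HRD1", "BiP"), each = 2), rep(c("Tg", "Tm"), 3))
      )],
      sd = 0.1, n = 4L
    )
  proteome <- synth_proteome(spec$proteins, decoys = spec$decoys)
  topo <- predict_tm(proteome)
  regions <- synth_promoters(spec$proteins$gene_id, spec$plants, window = spec$window)
  downstream <- vapply(seq_len(nrow(regions)), function(i) {
    paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
  }, "")
  contigs <- setNames(paste0(regions$sequence, downstream), regions$gene_id)
  tss <- tibble(
    chrom = regions$gene_id, tss = spec$window + 1L, strand = "+",
    gene_id = regions$gene_id
  )
  ct <- make_ct_table(effects)

  files <- c(
    proteome = file.path(dir, "proteome.fa"),
    tmhmm = file.path(dir, "tmhmm.txt"),
    genome = file.path(dir, "promoters.fa"),
    tss = file.path(dir, "tss.tsv"),
    ct = file.path(dir, "ct.tsv"),
    manifest = file.path(dir, "manifest.tsv")
  )
  write_proteins(proteome, files[["proteome"]])
  write_tmhmm(topo, files[["tmhmm"]])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(contigs), files[["genome"]])
  readr::write_tsv(tss, files[["tss"]])
  readr::write_tsv(ct, files[["ct"]])
  manifest <- dplyr::left_join(
    spec$proteins,
    dplyr::group_by(spec$plants, .data$gene_id) |>
      dplyr::summarise(
        upstream_motifs = paste(paste0(.data$element, ifelse(.data$strand == "-", "-r", ""),
          ",", .data$position
        ), collapse = ";"),
        .groups = "drop"
      ),
    by = "gene_id"
  )
  readr::write_tsv(manifest, files[["manifest"]])
  invisible(files)
}
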