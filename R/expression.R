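# qPCR quantification and the downstream statistical calls. Ct tables are
# long-format tibbles: one row per (sample, gene, replicate) Ct measurement,
# with whatever sample-level metadata (condition, time_h, tissue) rides
# along. Replicates are aggregated as mean Ct before delta-Ct, the standard
# comparative-Ct practice.

check_ct_table <- function(ct) {
  need <- c("sample_id", "gene", "replicate", "ct")
  missing <- setdiff(need, names(ct))
  if (length(missing) > 0) {
    abort(paste0("Ct table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(ct$ct))) abort("Non-finite Ct value(s)")
  invisible(TRUE)
}

#' Comparative-Ct (delta-delta-Ct) fold changes
#'
#' Per sample, `delta_ct` is the mean target Ct minus the mean reference-gene
#' Ct; `ddct` subtracts the calibrator sample's `delta_ct`; the fold change
#' is `2^(-ddct)`. The calibrator's own fold is therefore exactly 1.
#' Replicate-level folds (each target replicate's delta-Ct against the
#' calibrator mean) give the dispersion estimate `fold_sd`.
#'
#' @param ct Long-format Ct tibble with columns `sample_id`, `gene`,
#'   `replicate`, `ct` (plus optional metadata columns, carried through when
#'   constant within sample).
#' @param target Target gene name.
#' @param reference Reference (normaliser) gene name, e.g. `"GAPDH"` or
#'   `"18S"`; must be measured in every sample.
#' @param calibrator Sample id of the calibrator (e.g. the untreated
#'   control).
#' @return A tibble of class `ddct_fold`, one row per sample: `sample_id`,
#'   metadata columns, `n_rep`, `delta_ct`, `ddct`, `fold`, `fold_sd`, and
#'   `rep_folds` (list-column of replicate-level folds). Attributes `target`,
#'   `reference`, `calibrator` record the design.
#' @examples
#' ct <- make_ct_table(
#'   tibble::tibble(gene = "HRD1", condition = "Tg", time_h = 6,
#'                  true_fold = 4, sd = 0, n = 3),
#'   seed = 1
#' )
#' delta_delta_ct(ct, "HRD1", "GAPDH", calibrator = "control_0")
#' @export
delta_delta_ct <- function(ct, target, reference, calibrator) {
  check_ct_table(ct)
  samples <- unique(ct$sample_id)
  if (!calibrator %in% samples) abort(paste0("Calibrator sample '", calibrator, "' not in table"))
  ref <- dplyr::filter(ct, .data$gene == reference)
  tgt <- dplyr::filter(ct, .data$gene == target)
  no_ref <- setdiff(samples, unique(ref$sample_id))
  if (length(no_ref) > 0) {
    abort(paste0(
      "Reference gene '", reference, "' missing in sample(s): ",
      paste(no_ref, collapse = ", ")
    ))
  }
  no_tgt <- setdiff(samples, unique(tgt$sample_id))
  if (length(no_tgt) > 0) {
    abort(paste0(
      "Target gene '", target, "' missing in sample(s): ",
      paste(no_tgt, collapse = ", ")
    ))
  }
  ref_mean <- ref |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(ref_ct = mean(.data$ct), .groups = "drop")
  # sample-level metadata: columns constant within sample
  meta_cols <- setdiff(names(ct), c("gene", "replicate", "ct"))
  meta <- dplyr::distinct(ct[meta_cols])
  meta <- meta[!duplicated(meta$sample_id), , drop = FALSE]

  per_sample <- tgt |>
    dplyr::left_join(ref_mean, by = "sample_id") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_rep = dplyr::n(),
      delta_ct = mean(.data$ct) - .data$ref_ct[1],
      rep_dct = list(.data$ct - .data$ref_ct[1]),
      .groups = "drop"
    )
  cal_dct <- per_sample$delta_ct[per_sample$sample_id == calibrator]
  out <- per_sample |>
    dplyr::mutate(
      ddct = .data$delta_ct - cal_dct,
      fold = 2^(-.data$ddct),
      rep_folds = purrr::map(.data$rep_dct, ~ 2^(-(.x - cal_dct))),
      fold_sd = purrr::map_dbl(.data$rep_folds, ~ if (length(.x) > 1) sd(.x) else NA_real_)
    ) |>
    dplyr::select(-"rep_dct") |>
    dplyr::left_join(meta, by = "sample_id") |>
    dplyr::relocate(dplyr::all_of(setdiff(meta_cols, "sample_id")), .after = "sample_id") |>
    dplyr::arrange(match(.data$sample_id, samples))
  attr(out, "target") <- target
  attr(out, "reference") <- reference
  attr(out, "calibrator") <- calibrator
  class(out) <- c("ddct_fold", class(out))
  out
}

#' Tissue-specificity index (tau) and distribution class
#'
#' `tau = sum(1 - x_i / max(x)) / (n - 1)` over per-tissue mean expression
#' levels: 0 for a uniform profile, 1 for single-tissue expression. Profiles
#' are called `specific` (a single tissue; tau >= `specific`), `selective`
#' (limited tissues; tau >= `selective`) or `ubiquitous` otherwise.
#'
#' @param profile Tibble with columns `tissue` and `fold` (or another value
#'   column named by `value_col`); one row per tissue, >= 5 tissues.
#' @param specific,selective Tau thresholds (defaults 0.95 and 0.85).
#' @param value_col Name of the expression column (default `"fold"`).
#' @return One-row tibble: `tau`, `class` (factor), `top_tissue`.
#' @examples
#' prof <- tibble::tibble(tissue = c("kidney", letters[1:9]),
#'                        fold = c(50, rep(1, 9)))
#' tissue_profile(prof)
#' @export
tissue_profile <- function(profile, specific = 0.95, selective = 0.85,
                           value_col = "fold") {
  stopifnot("tissue" %in% names(profile), value_col %in% names(profile))
  x <- profile[[value_col]]
  if (length(x) < 5) abort("Tissue profile needs >= 5 tissues")
  if (any(x < 0)) abort("Negative expression values")
  if (all(x == 0)) abort("All-zero tissue profile: tau undefined")
  tau <- sum(1 - x / max(x)) / (length(x) - 1)
  cls <- if (tau >= specific) "specific" else if (tau >= selective) "selective" else "ubiquitous"
  tibble(
    tau = tau,
    class = factor(cls, levels = c("specific", "selective", "ubiquitous")),
    top_tissue = profile$tissue[which.max(x)]
  )
}

# Welch-free plain two-group t statistic would be fine here; use stats::t.test
# unless a group has zero variance everywhere, where p degenerates.
safe_p <- function(values, groups) {
  # one-way ANOVA p across groups, handling zero residual variance
  grand <- split(values, groups)
  if (all(vapply(grand, function(v) length(unique(v)) == 1L, TRUE))) {
    warn("Zero within-group variance; ANOVA p treated as exact limiting case")
    means <- vapply(grand, mean, 0)
    return(if (length(unique(means)) == 1L) 1 else 0)
  }
  fit <- aov(values ~ factor(groups))
  summary(fit)[[1]][["Pr(>F)"]][1]
}

safe_pair_p <- function(a, b) {
  if (length(unique(a)) == 1L && length(unique(b)) == 1L) {
    warn("Zero within-group variance; pairwise p treated as exact limiting case")
    return(if (mean(a) == mean(b)) 1 else 0)
  }
  t.test(a, b)$p.value
}

#' ER-stress responsiveness calls from a time-course Ct table
#'
#' For each gene and stressor condition, replicate-level delta-Ct values
#' (target Ct minus the sample's mean reference Ct) are compared across
#' timepoints including the untreated control by one-way ANOVA, followed by
#' two-sided pairwise comparisons of each timepoint against the control with
#' Bonferroni correction (raw p times the number of comparisons, capped at
#' 1). A gene is called responsive when, under **both** conditions, at least
#' one timepoint has adjusted p below `alpha` together with a fold change
#' above 1.
#'
#' @param ct Long-format Ct tibble with columns `sample_id`, `condition`,
#'   `time_h`, `gene`, `replicate`, `ct`.
#' @param genes Genes to test (default: all non-reference genes).
#' @param reference Reference gene (default `"GAPDH"`).
#' @param conditions Stressor conditions required for a responsive call
#'   (default `c("Tg", "Tm")`).
#' @param control Condition label of the untreated calibrator (default
#'   `"control"`); its (single) sample is the ANOVA baseline group and the
#'   fold-change calibrator.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `er_responsiveness`: list with `comparisons`
#'   (tibble: `gene`, `condition`, `time_h`, `fold`, `p_anova`, `p_raw`,
#'   `p_adj`) and `calls` (tibble: `gene`, one logical column per condition,
#'   `responsive`). [tidy()] returns the comparisons, [glance()] the calls.
#' @export
responsiveness <- function(ct, genes = NULL, reference = "GAPDH",
                           conditions = c("Tg", "Tm"), control = "control",
                           alpha = 0.05) {
  check_ct_table(ct)
  stopifnot(all(c("condition", "time_h") %in% names(ct)))
  genes <- genes %||% setdiff(unique(ct$gene), reference)
  present <- unique(ct$condition)
  if (!control %in% present) abort(paste0("Control condition '", control, "' absent"))
  if (length(intersect(conditions, present)) < 1) abort("No stressor condition present")

  ref_mean <- ct |>
    dplyr::filter(.data$gene == reference) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(ref_ct = mean(.data$ct), .groups = "drop")
  if (!setequal(ref_mean$sample_id, unique(ct$sample_id))) {
    abort(paste0("Reference gene '", reference, "' missing in some sample(s)"))
  }

  comparisons <- purrr::map(genes, function(g) {
    dct <- ct |>
      dplyr::filter(.data$gene == g) |>
      dplyr::left_join(ref_mean, by = "sample_id") |>
      dplyr::mutate(dct = .data$ct - .data$ref_ct)
    ctrl <- dplyr::filter(dct, .data$condition == control)
    if (nrow(ctrl) == 0) abort(paste0("No control measurements for gene ", g))
    purrr::map(intersect(conditions, present), function(cond) {
      trt <- dplyr::filter(dct, .data$condition == cond)
      times <- sort(unique(trt$time_h))
      if (length(times) < 1) abort(paste0("No groups for ", g, " under ", cond))
      groups <- c(
        list(control = ctrl$dct),
        setNames(lapply(times, function(t) trt$dct[trt$time_h == t]), times)
      )
      if (length(groups) < 2) abort("Fewer than two groups for ANOVA")
      p_anova <- safe_p(
        unlist(groups),
        rep(names(groups), lengths(groups))
      )
      k <- length(times)
      purrr::map(times, function(t) {
        v <- trt$dct[trt$time_h == t]
        p_raw <- safe_pair_p(v, ctrl$dct)
        tibble(
          gene = g, condition = cond, time_h = t,
          fold = 2^(-(mean(v) - mean(ctrl$dct))),
          p_anova = p_anova, p_raw = p_raw,
          p_adj = min(1, p_raw * k)
        )
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  calls <- comparisons |>
    dplyr::group_by(.data$gene, .data$condition) |>
    dplyr::summarise(
      up = any(.data$p_adj < alpha & .data$fold > 1),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "up", values_fill = FALSE)
  missing_cond <- setdiff(conditions, names(calls))
  for (mc in missing_cond) calls[[mc]] <- FALSE
  calls$responsive <- Reduce(`&`, lapply(conditions, function(cc) calls[[cc]]))
  structure(
    list(comparisons = comparisons, calls = calls,
         params = list(reference = reference, conditions = conditions,
                       control = control, alpha = alpha)),
    class = "er_responsiveness"
  )
}

#' @export
print.er_responsiveness <- function(x, ...) {
  cat("<er_responsiveness> ", nrow(x$calls), " gene(s); responsive: ",
    sum(x$calls$responsive), "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname responsiveness
#' @param x An `er_responsiveness` object.
#' @param ... Unused.
#' @export
tidy.er_responsiveness <- function(x, ...) x$comparisons

#' @rdname responsiveness
#' @export
glance.er_responsiveness <- function(x, ...) x$calls

#' Crystal-violet viability ratios
#'
#' Viability is the assay-well optical density (OD590) over the
#' vehicle-control OD; optionally expressed as fold over the mock
#' (empty-vector) line's ratio.
#'
#' @param od Numeric vector of assay-well OD590 values (> 0).
#' @param vehicle_od Matching vehicle-control OD590 (> 0).
#' @param mock_ratio Optional mock line viability ratio to normalise against
#'   (> 0).
#' @return Numeric vector of (relative) viability ratios.
#' @examples
#' viability(0.3, 0.6, mock_ratio = 0.5) # 1.0
#' @export
viability <- function(od, vehicle_od, mock_ratio = NULL) {
  if (any(od <= 0) || any(vehicle_od <= 0)) abort("Optical densities must be positive")
  ratio <- od / vehicle_od
  if (!is.null(mock_ratio)) {
    if (any(mock_ratio <= 0)) abort("`mock_ratio` must be positive")
    ratio <- ratio / mock_ratio
  }
  ratio
}
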