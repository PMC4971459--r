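tiny_ct <- function(target_cal, target_smp, ref_cal = 15, ref_smp = 15,
                    gene = "G", reference = "GAPDH") {
  tibble::tibble(
    sample_id = rep(c("cal", "smp"), each = 2),
    gene = rep(c(gene, reference), 2),
    replicate = 1L,
    ct = c(target_cal, ref_cal, target_smp, ref_smp)
  )
}

test_that("delta-delta-Ct reproduces its closed forms", {
  # identical delta-Ct in sample and calibrator -> fold 1
  fc <- delta_delta_ct(tiny_ct(25, 25), "G", "GAPDH", "cal")
  expect_equal(fc$fold, c(1, 1))
  # ddCt = -1 -> fold 2; ddCt = +2 -> fold 0.25
  expect_equal(
    delta_delta_ct(tiny_ct(25, 24), "G", "GAPDH", "cal")$fold[2], 2
  )
  expect_equal(
    delta_delta_ct(tiny_ct(25, 27), "G", "GAPDH", "cal")$fold[2], 0.25
  )
  # the calibrator's own fold is identically 1
  expect_equal(fc$fold[fc$sample_id == "cal"], 1)
})

test_that("a missing reference or calibrator is an error", {
  ct <- tiny_ct(25, 24)
  expect_error(delta_delta_ct(ct, "G", "ACTB", "cal"), "ACTB")
  expect_error(delta_delta_ct(ct, "G", "GAPDH", "nope"), "nope")
  no_ref <- dplyr::filter(ct, !(.data$sample_id == "smp" & .data$gene == "GAPDH"))
  expect_error(delta_delta_ct(no_ref, "G", "GAPDH", "cal"), "smp")
})

test_that("planted fold effects are recovered within noise", {
  ct <- make_ct_table(
    tibble::tibble(gene = "G", condition = "Tg", time_h = 6, true_fold = 4, sd = 0.1, n = 4),
    seed = 5
  )
  fc <- delta_delta_ct(ct, "G", "GAPDH", "control_0")
  est <- fc$fold[fc$sample_id == "Tg_6"]
  expect_gt(est, 3.5)
  expect_lt(est, 4.6)
})

test_that("folds are invariant to a constant shift only when applied to both genes", {
  ct <- make_ct_table(
    tibble::tibble(gene = "G", condition = "Tg", time_h = 6, true_fold = 3, sd = 0.05, n = 3),
    seed = 6
  )
  base <- delta_delta_ct(ct, "G", "GAPDH", "control_0")$fold
  both <- dplyr::mutate(ct, ct = .data$ct + ifelse(.data$sample_id == "Tg_6", 1.5, 0))
  expect_equal(delta_delta_ct(both, "G", "GAPDH", "control_0")$fold, base)
  target_only <- dplyr::mutate(
    ct,
    ct = .data$ct + ifelse(.data$sample_id == "Tg_6" & .data$gene == "G", 1.5, 0)
  )
  shifted <- delta_delta_ct(target_only, "G", "GAPDH", "control_0")$fold
  expect_false(isTRUE(all.equal(shifted, base)))
})

test_that("the tau index hits its closed-form extremes and thresholds", {
  one_of_twenty <- tibble::tibble(tissue = paste0("t", 1:20), fold = c(10, rep(0, 19)))
  tp <- tissue_profile(one_of_twenty)
  expect_equal(tp$tau, 1)
  expect_equal(as.character(tp$class), "specific")

  uniform <- tibble::tibble(tissue = paste0("t", 1:10), fold = rep(3, 10))
  tp2 <- tissue_profile(uniform)
  expect_equal(tp2$tau, 0)
  expect_equal(as.character(tp2$class), "ubiquitous")

  # kidney-restricted profile: one tissue at fold 50, the rest near 1
  withr::local_seed(9)
  kidney <- tibble::tibble(
    tissue = c("kidney", paste0("t", 1:19)),
    fold = c(50, exp(rnorm(19, 0, 0.2)))
  )
  expect_equal(as.character(tissue_profile(kidney)$class), "specific")
  expect_equal(tissue_profile(kidney)$top_tissue, "kidney")
})

test_that("degenerate tissue profiles are rejected", {
  expect_error(tissue_profile(tibble::tibble(tissue = paste0("t", 1:8), fold = 0)), "undefined")
  expect_error(tissue_profile(tibble::tibble(tissue = paste0("t", 1:3), fold = 1)), ">= 5")
})

test_that("concentrating expression into fewer tissues never decreases tau", {
  withr::local_seed(14)
  for (i in 1:30) {
    x <- stats::runif(12, 0.1, 10)
    prof <- tibble::tibble(tissue = paste0("t", 1:12), fold = x)
    tau0 <- tissue_profile(prof)$tau
    shrink <- which(x < max(x))[1]
    prof2 <- prof
    prof2$fold[shrink] <- prof2$fold[shrink] * stats::runif(1)
    expect_gte(tissue_profile(prof2)$tau, tau0)
  }
})

test_that("induction under both stressors is required for a responsive call", {
  both <- tidyr::expand_grid(gene = "G", condition = c("Tg", "Tm"), time_h = c(6, 24)) |>
    dplyr::mutate(true_fold = ifelse(.data$time_h == 6, 2, 1), sd = 0.1, n = 4L)
  ct <- make_ct_table(both, seed = 15)
  call <- glance(responsiveness(ct))
  expect_true(call$responsive)

  tg_only <- dplyr::mutate(both, true_fold = ifelse(.data$condition == "Tg", .data$true_fold, 1))
  ct2 <- make_ct_table(tg_only, seed = 16)
  call2 <- glance(responsiveness(ct2))
  expect_true(call2$Tg)
  expect_false(call2$responsive)

  # repression (fold < 1) never counts as responsive
  down <- dplyr::mutate(both, true_fold = ifelse(.data$time_h == 6, 0.25, 1))
  ct3 <- make_ct_table(down, seed = 17)
  expect_false(glance(responsiveness(ct3))$responsive)
})

test_that("Bonferroni adjustment multiplies by the comparison count and caps at 1", {
  eff <- tidyr::expand_grid(gene = "G", condition = c("Tg", "Tm"), time_h = c(3, 6, 24)) |>
    dplyr::mutate(true_fold = 1, sd = 0.2, n = 4L)
  ct <- make_ct_table(eff, seed = 18)
  comp <- tidy(responsiveness(ct))
  expect_equal(comp$p_adj, pmin(1, comp$p_raw * 3))
  expect_true(all(comp$p_adj <= 1))
})

test_that("zero within-group variance degenerates to exact p with a warning", {
  eff <- tidyr::expand_grid(gene = "G", condition = c("Tg", "Tm"), time_h = 6) |>
    dplyr::mutate(true_fold = 2, sd = 0, n = 3L)
  ct <- make_ct_table(eff, seed = 19)
  w <- capture_warnings(r <- responsiveness(ct))
  expect_true(any(grepl("Zero within-group variance", w)))
  comp <- r$comparisons
  expect_equal(comp$p_adj, rep(0, nrow(comp)))
  expect_true(r$calls$responsive)
})

test_that("null tables are rarely called responsive", {
  withr::local_seed(13)
  n_rep <- 150
  false_calls <- 0
  eff <- tidyr::expand_grid(gene = "G", condition = c("Tg", "Tm"), time_h = c(6, 24)) |>
    dplyr::mutate(true_fold = 1, sd = 0.1, n = 4L)
  for (i in seq_len(n_rep)) {
    ct <- make_ct_table(eff)
    if (glance(responsiveness(ct))$responsive) false_calls <- false_calls + 1
  }
  expect_lte(false_calls / n_rep, 0.05)
})

test_that("viability ratios follow the OD arithmetic", {
  expect_equal(viability(0.6, 0.6), 1)
  expect_equal(viability(0.3, 0.6, mock_ratio = 0.5), 1)
  expect_equal(viability(c(0.3, 0.6), 0.6), c(0.5, 1))
  expect_error(viability(0, 0.6), "positive")
  expect_error(viability(0.3, 0.6, mock_ratio = 0), "positive")
})
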