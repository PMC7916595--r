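norm_prof <- function(values, protein = "P1", condition = "wt") {
  migration_profile(protein, condition, values, normalized = TRUE)
}

test_that("peak detection finds local maxima above the height threshold", {
  prof <- norm_prof(c(0, 0.1, 1.0, 0.2, 0.05, 0.5, 0.1))
  peaks <- detect_peaks(prof, min_rel_height = 0.2, smooth = FALSE)
  expect_equal(nrow(peaks), 2L)
  expect_equal(peaks$slice, c(3, 6), tolerance = 0.5)
  expect_true(all(peaks$rel_height <= 1))
  expect_true(all(peaks$rel_height >= 0.2))

  expect_equal(nrow(detect_peaks(norm_prof(rep(0, 8)))), 0L)

  # boundary maxima are allowed: a monotone profile peaks at the last slice
  mono <- norm_prof(seq(0.1, 1.0, length.out = 10))
  peaks <- detect_peaks(mono, smooth = FALSE)
  expect_equal(peaks$slice, 10)

  raw <- migration_profile("P1", "wt", c(0, 5, 1))
  expect_error(detect_peaks(raw), "normalised")
})

test_that("parabolic refinement recovers an off-grid peak centre", {
  # Gaussian band centred between slices
  centre <- 7.4
  x <- dnorm(1:15, centre, 1.2)
  prof <- norm_prof(x / max(x))
  peaks <- detect_peaks(prof, smooth = FALSE)
  expect_equal(nrow(peaks), 1L)
  expect_equal(peaks$slice, centre, tolerance = 0.1)
})

test_that("migration shifts are called by greedy nearest-slice matching", {
  pk <- function(slices) data.frame(slice = slices,
                                    rel_height = rep(1, length(slices)),
                                    mass_kda = NA_real_)
  # respirasome lost, 750 kDa intermediate gained
  sh <- migration_shift(pk(9.5), pk(20.7))
  expect_equal(sh$lost$slice, 9.5)
  expect_equal(sh$gained$slice, 20.7)
  expect_equal(nrow(sh$matched), 0L)

  sh <- migration_shift(pk(c(10, 20)), pk(c(10, 20)))
  expect_equal(nrow(sh$gained) + nrow(sh$lost), 0L)

  # within tolerance: matched, no shift call
  sh <- migration_shift(pk(10.0), pk(10.8), match_tol = 1.5)
  expect_equal(nrow(sh$matched), 1L)
  expect_equal(nrow(sh$gained), 0L)
})

test_that("complex fold changes summarise finite subunit ratios robustly", {
  ann <- data.frame(protein_id = c("S1", "S2", "S3", "S4"),
                    complex_id = "cX", module_id = "",
                    display_order = 1:4)
  ratios <- data.frame(protein_id = c("S1", "S2", "S3"),
                       ratio = c(4, 5, 6), flag = "")
  fc <- complex_fold_change(ratios, ann, "cX")
  expect_equal(fc$median_ratio, 5.0)
  expect_equal(fc$n_finite, 3L)
  expect_identical(fc$status, "ok")

  absent <- data.frame(protein_id = paste0("S", 1:4), ratio = NA_real_,
                       flag = "absent-in-perturbed")
  fc <- complex_fold_change(absent, ann, "cX")
  expect_identical(fc$status, "complex-absent")
  expect_equal(fc$n_absent_perturbed, 4L)
  expect_true(is.na(fc$median_ratio))

  one <- data.frame(protein_id = "S1", ratio = 2, flag = "")
  expect_identical(complex_fold_change(one, ann, "cX")$status, "low-n")
})

test_that("co-migration scores are Pearson correlations with guard rails", {
  a <- norm_prof(c(0, 0.2, 1, 0.4, 0.1, 0.05, 0, 0))
  expect_equal(comigration_score(a, a)$r, 1.0)

  rev_a <- norm_prof(rev(a$values))
  expect_lt(comigration_score(a, rev_a)$r, 1)

  const <- norm_prof(rep(1, 8))
  expect_identical(comigration_score(a, const)$status, "not-a-score")

  tiny_a <- norm_prof(c(1, 0.5, rep(0, 6)))
  tiny_b <- norm_prof(c(0.5, 1, rep(0, 6)))
  expect_identical(comigration_score(tiny_a, tiny_b)$status,
                   "insufficient-support")
})

test_that("heatmap matrices keep values and annotation order", {
  profiles <- list(
    "A::wt" = norm_prof(c(0, 1, 0.5, 0), "A"),
    "B::wt" = norm_prof(c(1, 0.2, 0, 0), "B"))
  ps <- structure(list(profiles = profiles, n_slices = 4), class = "profile_set")
  ann <- data.frame(protein_id = c("B", "A"), complex_id = "cX",
                    module_id = "", display_order = 1:2)
  m <- heatmap_matrix(ps, ann, "wt")
  expect_equal(dim(m), c(2L, 4L))
  expect_identical(rownames(m), c("B", "A"))
  expect_equal(m["A", ], c(slice_1 = 0, slice_2 = 1, slice_3 = 0.5,
                           slice_4 = 0))

  expect_error(heatmap_matrix(ps, ann, "wt", proteins = c("A", "Z")), "Z")

  ann_b <- ann[ann$protein_id == "B", ]
  expect_warning(m2 <- heatmap_matrix(ps, ann_b, "wt"), "unassigned")
  expect_identical(rownames(m2), c("B", "A"))
})

test_that("log2 fold-change summaries divide perturbed by reference means", {
  ann <- data.frame(protein_id = c("A", "B"), complex_id = "cX",
                    module_id = "", display_order = 1:2)
  ab <- data.frame(protein_id = c("A", "A", "B", "B"),
                   condition = c("wt", "KO", "wt", "KO"),
                   abundance = c(100, 25, 40, 40))
  out <- lfq_log2fc_summary(ab, ann, "wt")
  expect_equal(out$log2fc[out$protein_id == "A"], -2.0)
  expect_equal(out$log2fc[out$protein_id == "B"], 0.0)
  expect_error(lfq_log2fc_summary(ab, ann, "nope"), "reference")

  # zeros are flagged, not pseudocounted
  ab0 <- data.frame(protein_id = "A", condition = c("wt", "KO"),
                    abundance = c(10, 0))
  out0 <- lfq_log2fc_summary(ab0, ann, "wt")
  expect_identical(out0$flag, "absent-in-perturbed")
  expect_true(is.na(out0$log2fc))
})

test_that("the default scenario's mitoribosome log2 fold change is ~ -log2(1.75)", {
  run <- default_full_run(101)
  ab <- protein_abundances(run$mapped)
  out <- lfq_log2fc_summary(ab, default_annotation(), "wt")
  mito <- out$log2fc[out$complex_id %in% c("mtLSU", "mtSSU")]
  expect_equal(median(mito, na.rm = TRUE), -log2(1.75), tolerance = 0.1)
})

test_that("scores do not depend on protein input order", {
  run <- default_full_run(101)
  prots <- c("MT-CO1", "COA3", "HIGD2A", "COX5B")
  m1 <- comigration_matrix(run$profiles, prots, "KO")
  m2 <- comigration_matrix(run$profiles, rev(prots), "KO")
  expect_equal(m1, m2[prots, prots])
})
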