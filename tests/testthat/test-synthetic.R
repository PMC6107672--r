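test_that("layouts are deterministic, hit the tm share target, and refuse tiny grids", {
  a <- make_layout(40, 40, 0.3, seed = 1)
  b <- make_layout(40, 40, 0.3, seed = 1)
  expect_identical(a$region, b$region)
  expect_false(identical(a$region, make_layout(40, 40, 0.3, seed = 2)$region))

  big <- make_layout(100, 100, 0.5, seed = 3)
  share <- sum(big$region == "tm") / sum(big$region != "off_tissue")
  expect_gte(share, 0.4)
  expect_lte(share, 0.6)

  expect_error(make_layout(2, 2, 0.3, seed = 1), "too small")
})

test_that("peak panels plant the requested marker structure", {
  pan <- make_peak_panel(50, n_region_markers = 2, n_treatment_markers = 5,
                         seed = 7)
  expect_equal(sum(pan$role == "null"), 43)
  expect_equal(nrow(pan), 50)
  expect_true(all(diff(pan$mz) > 0))
  expect_true(all(pan$base > 0))
  expect_true(all(pan$tm_factor > 0 & pan$tam_group_factor > 0))

  # exact ratio planting
  pan2 <- make_peak_panel(20, 2, 4, ratio_range = c(2, 2), seed = 1)
  f <- pan2$tam_group_factor[pan2$role == "treatment"]
  expect_true(all(abs(f - 2) < 1e-12 | abs(f - 0.5) < 1e-12))

  # default range covers both directions with magnitudes inside [1.5, 4]
  pan3 <- make_peak_panel(50, 10, 5, seed = 5)
  f3 <- pan3$tam_group_factor[pan3$role == "treatment"]
  mag <- pmax(f3, 1 / f3)
  expect_true(all(mag >= 1.5 & mag <= 4))
  expect_true(any(f3 > 1) && any(f3 < 1))

  expect_error(make_peak_panel(5, 4, 4, seed = 1))
})

test_that("noise-free simulation reproduces planted factors exactly", {
  nf <- noise_free_section()
  d <- nf$treated$dataset
  pan <- nf$panel
  lay <- nf$layout
  j_up <- which(pan$role == "treatment" & pan$tam_group_factor > 1)[1]
  tam_rows <- which(lay$region == "tam")
  expect_equal(unique(d$intensities[tam_rows, j_up]),
               pan$base[j_up] * pan$tam_group_factor[j_up])
  tm_rows <- which(lay$region == "tm")
  expect_equal(unique(d$intensities[tm_rows, j_up]), pan$base[j_up])
  # off-tissue carries nothing in the noise-free limit
  expect_true(all(d$intensities[lay$region == "off_tissue", ] == 0))
  # anchors depressed in tm by their planted factor
  j_a <- which(pan$role == "anchor")[1]
  expect_equal(unique(d$intensities[tm_rows, j_a]) /
                 unique(d$intensities[tam_rows, j_a]),
               pan$tm_factor[j_a])
})

test_that("same seed gives bit-identical datasets; parameter errors are caught", {
  lay <- make_layout(15, 15, 0.3, seed = 5, tissue_fraction = 0.6)
  pan <- make_peak_panel(10, 2, 2, seed = 6)
  s1 <- simulate_section(lay, pan, "control", seed = 9)
  s2 <- simulate_section(lay, pan, "control", seed = 9)
  expect_identical(s1$dataset$intensities, s2$dataset$intensities)
  expect_error(simulate_section(lay, pan, "control", seed = 1, noise_sd = -1),
               "negative noise_sd")
})

test_that("planted tam ratio 2 is recovered by the sample mean ratio", {
  lay <- make_layout(40, 40, 0.3, seed = 21, tissue_fraction = 0.7)
  pan <- make_peak_panel(20, 2, 3, ratio_range = c(2, 2), seed = 22)
  tr <- simulate_section(lay, pan, "MSC_TX", seed = 23, cv = 0.3,
                         tic_cv = 0, noise_sd = 0)
  ct <- simulate_section(lay, pan, "control", seed = 24, cv = 0.3,
                         tic_cv = 0, noise_sd = 0)
  tam <- lay$region == "tam"
  expect_gt(sum(tam), 500)
  j <- which(pan$role == "treatment" & pan$tam_group_factor > 1)[1]
  ratio <- mean(tr$dataset$intensities[tam, j]) /
    mean(ct$dataset$intensities[tam, j])
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("treatment markers with ratio >= 1.5 and cv <= 0.5 give AUC > 0.65", {
  for (case in list(list(r = 1.5, cv = 0.5, seed = 31),
                    list(r = 1.5, cv = 0.3, seed = 32),
                    list(r = 2.5, cv = 0.5, seed = 33))) {
    lay <- make_layout(40, 40, 0.3, seed = case$seed, tissue_fraction = 0.7)
    pan <- make_peak_panel(20, 2, 3, ratio_range = c(case$r, case$r),
                           seed = case$seed + 100)
    tr <- simulate_section(lay, pan, "MSC_TX", seed = case$seed + 200,
                           cv = case$cv, tic_cv = 0.2)
    ct <- simulate_section(lay, pan, "control", seed = case$seed + 300,
                           cv = case$cv, tic_cv = 0.2)
    tam <- lay$region == "tam"
    expect_gt(sum(tam), 400)
    fm <- suppressMessages(
      preprocess_batch(list(tr$dataset, ct$dataset)))
    j <- which.min(abs(fm$centers -
                         pan$mz[pan$role == "treatment" & pan$tam_group_factor > 1][1]))
    n1 <- n_pixels(tr$dataset)
    auc <- roc_auc(fm$values[which(tam), j], fm$values[n1 + which(tam), j])
    expect_gt(auc, 0.65)
  }
})

test_that("emulated identification tables carry exact theoretical masses at ppm 0", {
  ref <- reference_peptides()
  tab <- make_id_table(ref, mass_error_sd_ppm = 0, seed = 1)
  expect_equal(nrow(tab), 14)
  expect_setequal(unique(tab$gene_name),
                  c("Col6a1", "Hspa8", "Ca3", "Myl3", "Flnc", "Tnc"))
  theo <- vapply(ref$sequence, monoisotopic_mass, 0, USE.NAMES = FALSE)
  expect_equal(round(tab$experimental_neutral_mass, 4), round(theo, 4))

  # with ppm error, masses move but deterministically per seed
  t1 <- make_id_table(ref, 10, seed = 2)
  t2 <- make_id_table(ref, 10, seed = 2)
  expect_identical(t1$experimental_neutral_mass, t2$experimental_neutral_mass)
  expect_false(any(t1$experimental_neutral_mass == theo))

  empty <- make_id_table(ref[0, ])
  expect_equal(nrow(empty), 0)
})
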