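test_that("baseline removal flattens drift while preserving peak shape", {
  # flat spectrum: nothing but baseline
  expect_true(all(remove_baseline(rep(5, 200), 20) == 0))

  # narrow Gaussian on a linear ramp: peak-local area within 5% of truth,
  # apex position unchanged
  ax <- seq(0, 100, by = 0.1)
  peak <- 50 * exp(-(ax - 50)^2 / (2 * 0.15^2))
  corrected <- remove_baseline(peak + 5 + 0.05 * ax, 20)
  support <- abs(ax - 50) <= 1
  expect_lt(abs(sum(corrected[support]) - sum(peak[support])) / sum(peak[support]),
            0.05)
  expect_equal(which.max(corrected), which.max(peak))

  # already baseline-free input passes through within 1% of total intensity
  again <- remove_baseline(peak, 20)
  expect_lt(sum(abs(again - peak)) / sum(peak), 0.01)

  # centroid datasets are refused
  d <- toy_dataset()
  expect_error(remove_baseline(d, 20), "profile-mode operation")
})

test_that("TIC normalization equalizes spectra to the joint mean TIC", {
  d <- msi_dataset(data.frame(x = 0:1, y = c(0, 0)), mz = c(1000, 1100),
                   intensities = matrix(c(4, 6, 10, 20), 2, byrow = TRUE),
                   mode = "centroid")
  dn <- tic_normalize(d)
  expect_equal(tic(dn), c(20, 20))
  # relative intensities within a spectrum preserved
  expect_equal(dn$intensities[1, 2] / dn$intensities[1, 1], 6 / 4)

  # already equal-TIC input is unchanged
  de <- msi_dataset(data.frame(x = 0:1, y = c(0, 0)), mz = c(1000, 1100),
                    intensities = matrix(c(4, 6, 3, 7), 2, byrow = TRUE),
                    mode = "centroid")
  expect_equal(tic_normalize(de)$intensities, de$intensities)

  # strong per-pixel TIC variation is removed entirely
  lay <- make_layout(15, 15, 0.3, seed = 41, tissue_fraction = 0.7)
  pan <- make_peak_panel(10, 2, 2, seed = 42)
  sim <- simulate_section(lay, pan, "control", seed = 43, tic_cv = 0.5,
                          noise_sd = 0)
  dn2 <- tic_normalize(sim$dataset)
  t2 <- tic(dn2)[tic(sim$dataset) > 0]
  expect_lt(stats::sd(t2) / mean(t2), 1e-9)

  # all-zero spectra are flagged, not divided by zero
  dz <- msi_dataset(data.frame(x = 0:1, y = c(0, 0)), mz = 1000,
                    intensities = matrix(c(0, 10), 2), mode = "centroid")
  dzn <- tic_normalize(dz)
  expect_equal(attr(dzn, "zero_spectra"), 1L)
  expect_true(all(is.finite(dzn$intensities)))
})

test_that("peak detection finds clean peaks, rejects noise, passes centroids through", {
  ax <- seq(900, 1300, by = 0.05)
  y <- 50 * exp(-(ax - 1000)^2 / (2 * 0.2^2)) +
    30 * exp(-(ax - 1200)^2 / (2 * 0.2^2))
  set.seed(1)
  y <- y + abs(rnorm(length(ax), 0, 0.5))
  pk <- detect_peaks(list(mz = ax, intensity = y), "medium", snr = 3)
  expect_equal(length(pk), 2)
  expect_lt(abs(pk[1] - 1000), 0.1)
  expect_lt(abs(pk[2] - 1200), 0.1)

  zero_runs <- 0
  for (s in 1:20) {
    set.seed(s)
    noise <- abs(rnorm(2000))
    p <- detect_peaks(list(mz = seq_len(2000), intensity = noise), "medium", 3)
    zero_runs <- zero_runs + (length(p) == 0)
  }
  expect_gte(zero_runs / 20, 0.95)

  cen <- detect_peaks(list(mz = c(1000, 1200, 1300), intensity = c(5, 0, 2)),
                      mode = "centroid")
  expect_equal(cen, c(1000, 1300))

  expect_error(detect_peaks(list(mz = numeric(0), intensity = numeric(0))),
               "empty spectrum")
})

test_that("interval alignment follows the half-open +/- halfwidth convention", {
  # profile: single point at the center -> column equals that point's value
  d1 <- msi_dataset(data.frame(x = 0, y = 0), mz = c(999, 1000, 1001),
                    intensities = matrix(c(0, 8, 0), 1), mode = "profile")
  fm1 <- align_peaks(d1, 1000, halfwidth = 0.156)
  expect_equal(as.numeric(fm1$values), 8)

  # two spectra with peaks at 1000.00 and 1000.10 land in one column at 1000.05
  d2 <- msi_dataset(data.frame(x = 0:1, y = c(0, 0)),
                    mz = c(1000.00, 1000.10), mode = "centroid",
                    intensities = matrix(c(5, 0, 0, 7), 2, byrow = TRUE))
  fm2 <- align_peaks(d2, 1000.05, halfwidth = 0.156)
  expect_equal(ncol(fm2$values), 1)
  expect_equal(as.numeric(fm2$values), c(5, 7))

  # a peak 0.30 Da from the center is outside the 0.156 halfwidth
  d3 <- msi_dataset(data.frame(x = 0, y = 0), mz = c(1000.30),
                    intensities = matrix(4, 1), mode = "centroid")
  fm3 <- align_peaks(d3, 1000.00, halfwidth = 0.156)
  expect_equal(as.numeric(fm3$values), 0)

  # overlapping centers are merged to the stronger peak, with a message
  d4 <- msi_dataset(data.frame(x = 0, y = 0), mz = c(1000.0, 1000.2),
                    intensities = matrix(c(2, 9), 1), mode = "centroid")
  expect_message(fm4 <- align_peaks(d4, c(1000.0, 1000.2), halfwidth = 0.156),
                 "merged overlapping centers")
  expect_equal(fm4$centers, 1000.2)
})

test_that("alignment output is independent of section processing order", {
  b <- default_batch()
  ds <- b$sim$datasets
  centers <- b$fm$centers
  fm_a <- align_peaks(ds, centers)
  fm_b <- align_peaks(rev(ds), centers)
  key_a <- paste(fm_a$meta$section, fm_a$meta$x, fm_a$meta$y)
  key_b <- paste(fm_b$meta$section, fm_b$meta$x, fm_b$meta$y)
  expect_setequal(key_a, key_b)
  expect_equal(fm_a$values, fm_b$values[match(key_a, key_b), ])
})

test_that("detected peak count is stable across generator seeds", {
  counts <- vapply(c(61, 62, 63), function(s) {
    lay <- make_layout(6, 6, 0.3, seed = s, tissue_fraction = 0.8)
    pan <- make_peak_panel(15, 3, 2, seed = s + 10, mz_range = c(800, 1000))
    sim <- simulate_section(lay, pan, "control", seed = s + 20,
                            mode = "profile", mz_range = c(795, 1005),
                            noise_sd = 0.5)
    fm <- suppressMessages(preprocess_batch(list(sim$dataset)))
    ncol(fm$values)
  }, 0L)
  expect_lte(max(counts), 1.1 * mean(counts))
  expect_gte(min(counts), 0.9 * mean(counts))
})

test_that("feature matrices survive a CSV round-trip", {
  b <- default_batch()
  p <- tempfile(fileext = ".csv")
  write_feature_matrix(b$fm, p)
  fm2 <- read_feature_matrix(p)
  expect_equal(fm2$centers, b$fm$centers)
  expect_equal(unname(fm2$values), unname(b$fm$values), tolerance = 1e-12)
  expect_equal(fm2$meta$section, b$fm$meta$section)
})
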