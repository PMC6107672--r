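test_that("plain-array JSON round-trip is exact and invariants are enforced", {
  d <- toy_dataset()
  p <- tempfile(fileext = ".json")
  write_msi(d, p)
  d2 <- read_msi(p)
  expect_identical(d2$coords, d$coords)
  expect_identical(d2$mz, d$mz)
  expect_identical(d2$intensities, d$intensities)
  expect_identical(d2$mode, "centroid")
  expect_identical(d2$group, "control")

  expect_error(
    msi_dataset(data.frame(x = c(0, 0), y = c(0, 0)), mz = 1000,
                intensities = matrix(1, 2, 1), mode = "centroid"),
    "duplicate pixel"
  )
  expect_error(
    msi_dataset(data.frame(x = 0:1, y = c(0, 0)), mz = 1000,
                intensities = matrix(c(-1, 1), 2, 1), mode = "centroid"),
    "negative intensity"
  )
  expect_error(
    msi_dataset(data.frame(x = 0, y = 0), mz = c(1000, 900),
                intensities = matrix(1:2, 1), mode = "centroid"),
    "not strictly increasing"
  )
})

test_that("imzML round-trips a generated 40x40 cube within float32 tolerance", {
  b <- default_batch()
  d <- b$sim$datasets[[1]]
  p <- tempfile(fileext = ".imzML")
  write_imzml(d, p)
  d2 <- read_imzml(p)
  expect_identical(d2$coords, d$coords)
  expect_equal(d2$mz, d$mz, tolerance = 0)
  rel <- abs(d2$intensities - d$intensities) / pmax(d$intensities, 1)
  expect_lt(max(rel), 1e-6)
  # 64-bit intensities round-trip exactly
  p64 <- tempfile(fileext = ".imzML")
  write_imzml(d, p64, intensity_format = "float64")
  expect_identical(read_imzml(p64)$intensities, d$intensities)
})

test_that("processed-dialect imzML round-trips per-pixel axes", {
  d <- msi_dataset(data.frame(x = 0:1, y = c(0, 0)),
                   mz = list(c(900.5, 1000.25), 950.125),
                   intensities = list(c(10, 20), 5),
                   mode = "centroid", section_id = "proc")
  p <- tempfile(fileext = ".imzML")
  write_imzml(d, p, intensity_format = "float64")
  d2 <- read_imzml(p)
  expect_false(d2$shared_axis)
  expect_equal(d2$mz, d$mz)
  expect_equal(d2$intensities, d$intensities)
})

test_that("an independent imzML parser reads our files and vice versa", {
  d <- toy_dataset()
  p <- tempfile(fileext = ".imzML")
  write_imzml(d, p, intensity_format = "float64")
  out <- system2(python_bin(), c("-c", shQuote(paste0(
    "from pyimzml.ImzMLParser import ImzMLParser\n",
    "p = ImzMLParser('", p, "')\n",
    "print(p.coordinates)\n",
    "for i in range(4):\n",
    "    mz, ii = p.getspectrum(i)\n",
    "    print(list(map(float, mz)), list(map(float, ii)))\n"
  ))), stdout = TRUE, stderr = FALSE)
  expect_true(any(grepl("(1, 1, 1), (2, 1, 1), (1, 2, 1), (2, 2, 1)",
                        out, fixed = TRUE)))
  expect_true(any(grepl("[900.5, 1000.25, 1100.75] [1.0, 2.0, 3.0]",
                        out, fixed = TRUE)))
  expect_true(any(grepl("[10.0, 11.0, 12.0]", out, fixed = TRUE)))

  # reverse direction: a file written by the independent writer
  p2 <- tempfile(fileext = ".imzML")
  status <- system2(python_bin(), c("-c", shQuote(paste0(
    "from pyimzml.ImzMLWriter import ImzMLWriter\n",
    "import numpy as np\n",
    "with ImzMLWriter('", p2, "', mode='processed') as w:\n",
    "    w.addSpectrum(np.array([805.5, 900.0]), np.array([3.0, 4.0]), (1, 1, 1))\n",
    "    w.addSpectrum(np.array([850.25]), np.array([7.0]), (2, 1, 1))\n"
  ))))
  expect_identical(status, 0L)
  d3 <- read_imzml(p2)
  expect_equal(d3$coords, data.frame(x = c(0L, 1L), y = c(0L, 0L)))
  expect_equal(d3$mz[[1]], c(805.5, 900.0))
  expect_equal(d3$intensities[[2]], 7.0)
})

test_that("batch writer emits one file per section plus a complete manifest", {
  b <- default_batch()
  dir <- tempfile()
  man <- write_msi_batch(b$sim$datasets[1:3], dir)
  entries <- jsonlite::read_json(man, simplifyVector = TRUE)
  expect_equal(nrow(entries), 3)
  expect_true(all(file.exists(file.path(dir, entries$file))))
  back <- read_msi_batch(dir)
  expect_equal(length(back), 3)
  expect_equal(back[[2]]$intensities, b$sim$datasets[[2]]$intensities)
  expect_error(write_msi_batch(list(), tempfile()), "nothing to write")
})

test_that("peptide table reader enforces schema and rejects bad residues", {
  p <- tempfile(fileext = ".csv")
  writeLines(c(
    "protein_accession,gene_name,description,sequence,experimental_neutral_mass,score",
    "REF_TNC,Tnc,Tenascin-C,EGDPATINAATEIDAPR,1739.83,60.4",
    "REF_BAD,Bad,Broken,EGDPATINAATEIDAPZ,1000.0,10"
  ), p)
  expect_warning(tab <- read_peptide_ids(p), "invalid residue Z")
  expect_equal(nrow(tab), 1)
  expect_equal(nchar(tab$sequence[1]), 17)
  expect_equal(tab$experimental_neutral_mass[1], 1739.83)
  rej <- attr(tab, "rejected")
  expect_equal(nrow(rej), 1)
  expect_match(rej$reason, "invalid residue Z")

  # header only
  writeLines("protein_accession,gene_name,description,sequence,experimental_neutral_mass,score", p)
  expect_warning(empty <- read_peptide_ids(p), "empty table")
  expect_equal(nrow(empty), 0)

  # missing column
  writeLines(c("protein_accession,sequence", "A,PEPTIDE"), p)
  expect_error(read_peptide_ids(p), "schema error.*gene_name")
})

test_that("ion images honor grid layout, missing pixels and interval sums", {
  d <- msi_dataset(data.frame(x = c(0, 1, 2), y = c(0, 0, 1)),
                   mz = c(1000, 1100), mode = "centroid",
                   intensities = matrix(c(1, 9, 1, 8, 1, 7), 3, byrow = TRUE))
  img <- render_ion_image(d, 1000, 0.2)
  expect_equal(dim(unclass(img)), c(2, 3))
  expect_true(all(img[!is.na(img)] == 1))
  expect_true(is.na(img[2, 1]))  # (0,1) not measured: missing, not zero

  expect_error(render_ion_image(d, 4000, 0.2), "outside axis range")

  # halfwidth spanning two centroids sums them: peaks at 1000.00 and 1000.10
  d3 <- msi_dataset(data.frame(x = 0, y = 0),
                    mz = c(1000.00, 1000.10, 1000.40), mode = "centroid",
                    intensities = matrix(c(2, 5, 11), 1))
  expect_equal(as.numeric(render_ion_image(d3, 1000.05, 0.156)[1, 1]), 7)

  # permutation invariance of storage order
  perm <- c(3, 1, 2)
  dp <- msi_dataset(d$coords[perm, ], d$mz, d$intensities[perm, ],
                    mode = "centroid")
  expect_equal(unclass(render_ion_image(dp, 1000, 0.2)),
               unclass(render_ion_image(d, 1000, 0.2)))
})

test_that("planted tam-only marker shows tam > tm in its ion image", {
  b <- default_batch()
  d <- b$sim$datasets[[1]]  # MSC_TX section
  truth <- b$sim$truths[[1]]
  trt_mz <- b$sim$panel$mz[b$sim$panel$direction %in% "up_in_treated"][1]
  img <- render_ion_image(d, trt_mz, 0.156)
  reg <- matrix(NA_character_, nrow = truth$layout$ny, ncol = truth$layout$nx)
  reg[cbind(d$coords$y + 1, d$coords$x + 1)] <- truth$layout$region
  expect_gt(mean(img[reg == "tam"]), mean(img[reg == "tm"]))
})
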