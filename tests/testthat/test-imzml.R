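# imzML reading and writing.

test_that("processed-mode files round trip within 32-bit float tolerance", {
  ds <- tiny_dataset("processed")
  path <- file.path(withr::local_tempdir(), "a.imzML")
  write_imzml(ds, path)
  got <- read_imzml(path)
  expect_equal(got$coords$x, ds$coords$x)
  expect_equal(got$coords$y, ds$coords$y)
  expect_equal(got$mode, "processed")
  expect_equal(got$pixel_size, 20)
  # m/z stored at 64 bit by default, intensities at 32 bit
  expect_equal(unlist(got$mz), unlist(ds$mz), tolerance = 1e-12)
  expect_equal(unlist(got$intensity), unlist(ds$intensity), tolerance = 1e-6)
})

test_that("continuous-mode files store the shared axis once and round trip", {
  ds <- tiny_dataset("continuous")
  path <- file.path(withr::local_tempdir(), "c.imzML")
  write_imzml(ds, path)
  got <- read_imzml(path)
  expect_equal(got$mode, "continuous")
  expect_equal(got$mz[[1]], ds$mz[[1]], tolerance = 1e-12)
  expect_equal(got$mz[[3]], ds$mz[[1]], tolerance = 1e-12)
  expect_equal(unlist(got$intensity), unlist(ds$intensity), tolerance = 1e-6)
  # shared axis stored once: payload = uuid + axis + n x intensities
  ibd <- file.size(sub("imzML$", "ibd", path))
  expect_equal(ibd, 16 + 3 * 8 + 3 * 3 * 4)
})

test_that("binary payload length matches declared precision", {
  # 1 pixel, 3 peaks, both arrays at 32 bit: 16 uuid + 12 mz + 12 intensity
  ds <- msi_dataset(data.frame(x = 0, y = 0), mz = list(c(100, 200, 300)),
                    intensity = list(c(1, 2, 3)), pixel_size = 10)
  path <- file.path(withr::local_tempdir(), "p.imzML")
  write_imzml(ds, path, mz_precision = 32, intensity_precision = 32)
  expect_equal(file.size(sub("imzML$", "ibd", path)), 16 + 12 + 12)
})

test_that("writes are deterministic and duplicate coordinates are rejected", {
  dir <- withr::local_tempdir()
  ds <- tiny_dataset("processed")
  write_imzml(ds, file.path(dir, "x.imzML"))
  write_imzml(ds, file.path(dir, "y.imzML"))
  expect_identical(readBin(file.path(dir, "x.ibd"), "raw", 1e6),
                   readBin(file.path(dir, "y.ibd"), "raw", 1e6))
  expect_identical(readLines(file.path(dir, "x.imzML")),
                   readLines(file.path(dir, "y.imzML")))
  expect_error(
    msi_dataset(data.frame(x = c(0, 0), y = c(0, 0)),
                mz = list(1, 1), intensity = list(1, 1), pixel_size = 1),
    "duplicate pixel")
  expect_error(write_imzml(
    structure(list(coords = data.frame(x = integer(0), y = integer(0)),
                   mz = list(), intensity = list(), pixel_size = 1,
                   mode = "processed"), class = "msi_dataset"),
    file.path(dir, "e.imzML")), "empty dataset")
})

test_that("malformed or inconsistent files raise named format errors", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "a.imzML")
  write_imzml(tiny_dataset("processed"), path)
  # truncate the XML -> malformed
  bad <- file.path(dir, "bad.imzML")
  writeLines(substr(paste(readLines(path), collapse = "\n"), 1, 300), bad)
  file.copy(sub("imzML$", "ibd", path), sub("imzML$", "ibd", bad))
  expect_error(read_imzml(bad), "malformed XML")
  # corrupt the ibd -> checksum mismatch
  ibd <- sub("imzML$", "ibd", path)
  raw <- readBin(ibd, "raw", file.size(ibd))
  raw[length(raw)] <- as.raw(255)
  writeBin(raw, ibd)
  expect_error(read_imzml(path), "checksum")
})

test_that("peaks closer than the ppm tolerance merge to one axis bin", {
  # 0.5 mDa apart at m/z 281 is ~1.8 ppm; brute-force pairwise check
  mzs <- c(281.2485, 281.2490)
  expect_true(abs(diff(mzs)) / mean(mzs) * 1e6 < 10)
  ds <- msi_dataset(data.frame(x = 0:1, y = c(0, 0)),
                    mz = list(mzs[1], mzs[2]), intensity = list(5, 7),
                    pixel_size = 20, mode = "processed")
  expect_length(common_axis(ds, tol_ppm(10)), 1L)
  expect_length(common_axis(ds, tol_ppm(1)), 2L)
  pm <- pixel_matrix(ds, tol_ppm(10))
  expect_equal(dim(pm$values), c(2L, 1L))
  expect_equal(as.numeric(pm$values), c(5, 7))
})

test_that("files written here parse identically under an independent reader", {
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  dir <- withr::local_tempdir()
  ds <- tiny_dataset("processed")
  path <- file.path(dir, "o.imzML")
  write_imzml(ds, path)
  script <- file.path(dir, "check.py")
  writeLines(c(
    "from pyimzml.ImzMLParser import ImzMLParser",
    "import sys, warnings",
    "warnings.filterwarnings('ignore')",
    sprintf("p = ImzMLParser(r'%s')", path),
    "for i, (x, y, z) in enumerate(p.coordinates):",
    "    mz, ins = p.getspectrum(i)",
    "    print(x, y, ' '.join('%.6f' % v for v in mz),",
    "          ' '.join('%.6f' % v for v in ins))"), script)
  out <- tryCatch(system2(py, script, stdout = TRUE, stderr = FALSE),
                  warning = function(w) NULL, error = function(e) NULL)
  skip_if(is.null(out) || length(out) != 3, "pyimzml unavailable")
  parts <- strsplit(out, " +")
  for (i in 1:3) {
    expect_equal(as.integer(parts[[i]][1:2]),
                 c(ds$coords$x[i] + 1L, ds$coords$y[i] + 1L))
    vals <- as.numeric(parts[[i]][-(1:2)])
    expect_equal(vals, c(ds$mz[[i]], ds$intensity[[i]]), tolerance = 1e-5)
  }
})
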