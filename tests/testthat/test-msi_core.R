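test_that("spectrum invariants are enforced", {
  s <- msi_spectrum(c(756.5514, 778.5357), c(100, 40))
  expect_s3_class(s, "msi_spectrum")
  expect_error(msi_spectrum(c(700, 700), c(1, 1)), "strictly increasing")
  expect_error(msi_spectrum(c(700, 650), c(1, 1)), "strictly increasing")
  expect_error(msi_spectrum(700, c(1, 2)), "lengths differ")
  expect_error(msi_spectrum(c(700, NaN), c(1, 1)), "NA/NaN")
  expect_error(msi_spectrum(700, -1), "non-negative")
  expect_error(msi_spectrum(49.9, 1), "acquisition range")
  expect_error(msi_spectrum(1000.1, 1), "acquisition range")
  expect_silent(msi_spectrum(numeric(0), numeric(0)))
})

test_that("section invariants cover grid bounds and metadata", {
  sp <- list(spec_of(700), spec_of(701))
  expect_error(
    msi_section(sp, data.frame(x = c(1, 5), y = c(1, 1)),
                grid_shape = c(1, 2), section_id = "s"),
    "outside the declared")
  expect_error(
    msi_section(sp, data.frame(x = c(1, 1), y = c(1, 1)),
                grid_shape = c(1, 2), section_id = "s"),
    "duplicated")
  expect_error(
    msi_section(sp, data.frame(x = 1:2, y = c(1, 1)), c(1, 2), "s",
                time_point_h = 12, treatment = "control"),
    "time_point_h")
  expect_error(
    msi_section(sp, data.frame(x = 1:2, y = c(1, 1)), c(1, 2), "s",
                is_blank = TRUE, time_point_h = 8),
    "blank")
  expect_error(msi_section(list(), data.frame(x = integer(0), y = integer(0)),
                           c(1, 1), "s"), "no pixels")
})

test_that("imzML round trip preserves every pixel's peak lists", {
  # minimal single-pixel file
  s1 <- msi_section(list(spec_of(756.5514, 100)),
                    data.frame(x = 1L, y = 1L), c(1, 1), "one")
  p1 <- file.path(tempdir(), "one.imzML")
  write_imzml(s1, p1)
  r1 <- read_imzml(p1)
  expect_equal(r1$spectra[[1]]$mz, 756.5514, tolerance = 1e-9)
  expect_equal(r1$spectra[[1]]$intensity, 100, tolerance = 1e-6)
  expect_equal(length(r1$spectra), 1L)

  # a 3x2 grid with uneven peak counts, one empty pixel
  sp <- list(spec_of(c(100.1, 200.2, 300.3), c(5, 6, 7)),
             spec_of(500.123456, 42.5),
             msi_spectrum(numeric(0), numeric(0)),
             spec_of(c(443.2335, 443.2446), c(1500, 3)),
             spec_of(seq(60, 960, by = 100)),
             spec_of(999.9999, 0.125))
  s2 <- msi_section(sp, expand.grid(x = 1:3, y = 1:2), c(2, 3), "grid",
                    time_point_h = 24, treatment = "BPA")
  p2 <- file.path(tempdir(), "grid.imzML")
  write_imzml(s2, p2)
  r2 <- read_imzml(p2, time_point_h = 24, treatment = "BPA")
  expect_equal(length(r2$spectra), 6L)
  expect_equal(r2$coords, s2$coords)
  expect_equal(r2$grid_shape, s2$grid_shape)
  for (i in seq_along(sp)) {
    expect_equal(r2$spectra[[i]]$mz, sp[[i]]$mz, tolerance = 1e-6)
    if (length(sp[[i]]$intensity))
      expect_lt(max(abs(r2$spectra[[i]]$intensity - sp[[i]]$intensity) /
                      pmax(sp[[i]]$intensity, 1e-12)), 1e-4)
  }
})

test_that("a simulated section survives the file round trip intact", {
  sim <- simulate_section(default_phantom_spec(), 8, "control",
                          seed = 7, acquisition_index = 3)
  path <- file.path(tempdir(), "sim.imzML")
  write_imzml(sim$section, path)
  r <- read_imzml(path, time_point_h = 8, treatment = "control")
  n_in <- vapply(sim$section$spectra, function(s) length(s$mz), integer(1))
  n_out <- vapply(r$spectra, function(s) length(s$mz), integer(1))
  expect_identical(n_out, n_in)  # pixel-wise peak count conservation
  tot_in <- sum(unlist(lapply(sim$section$spectra, `[[`, "intensity")))
  tot_out <- sum(unlist(lapply(r$spectra, `[[`, "intensity")))
  expect_equal(tot_out, tot_in, tolerance = 1e-5)
  mz_in <- unlist(lapply(sim$section$spectra, `[[`, "mz"))
  mz_out <- unlist(lapply(r$spectra, `[[`, "mz"))
  expect_lt(max(abs(mz_in - mz_out)), 1e-6)
})

test_that("reader rejects broken inputs with useful errors", {
  s <- msi_section(list(spec_of(700)), data.frame(x = 1L, y = 1L),
                   c(1, 1), "err")
  path <- file.path(tempdir(), "err.imzML")
  write_imzml(s, path)
  # missing binary companion
  file.rename(sub("imzML$", "ibd", path), sub("imzML$", "ibd.bak", path))
  expect_error(read_imzml(path), "binary companion")
  file.rename(sub("imzML$", "ibd.bak", path), sub("imzML$", "ibd", path))
  # malformed XML
  bad <- file.path(tempdir(), "bad.imzML")
  writeLines("<mzML><unclosed>", bad)
  file.copy(sub("imzML$", "ibd", path), sub("imzML$", "ibd", bad),
            overwrite = TRUE)
  expect_error(read_imzml(bad), "malformed")
  # profile-mode data rejected unless asserted centroided
  prof <- file.path(tempdir(), "prof.imzML")
  txt <- readLines(path)
  txt <- sub('accession="MS:1000127" name="centroid spectrum"',
             'accession="MS:1000128" name="profile spectrum"', txt)
  writeLines(txt, prof)
  file.copy(sub("imzML$", "ibd", path), sub("imzML$", "ibd", prof),
            overwrite = TRUE)
  expect_error(read_imzml(prof), "profile-mode")
  expect_silent(read_imzml(prof, centroided = TRUE))
  expect_error(read_imzml(file.path(tempdir(), "nope.imzML")), "not found")
})

test_that("the written imzML is readable by an independent parser", {
  sp <- list(spec_of(c(104.1075, 443.2335), c(10, 20)),
             spec_of(c(756.5514), c(30)))
  s <- msi_section(sp, data.frame(x = 1:2, y = c(1L, 1L)), c(1, 2), "xval")
  path <- file.path(tempdir(), "xval.imzML")
  write_imzml(s, path)
  out <- suppressWarnings(system2("python", c("-c", shQuote(paste0(
    "from pyimzml.ImzMLParser import ImzMLParser;",
    "p = ImzMLParser('", path, "');",
    "import sys;",
    "mz0, i0 = p.getspectrum(0); mz1, i1 = p.getspectrum(1);",
    "print(len(mz0), len(mz1), round(float(mz0[1]), 4),",
    "round(float(i1[0]), 1), p.coordinates)"))),
    stdout = TRUE, stderr = TRUE))
  line <- out[grepl("^2 1", out)]
  expect_length(line, 1)
  expect_match(line, "443.2335")
  expect_match(line, "30.0")
})

test_that("manifest round trip and study loading preserve metadata", {
  man <- data.frame(section_id = c("a", "blank1"),
                    file = c("a.imzML", "blank1.imzML"),
                    subject_id = c("d1", NA),
                    time_point_h = c(48, NA), treatment = c("BPA", NA),
                    acquisition_index = c(3L, 0L),
                    is_blank = c(FALSE, TRUE))
  path <- file.path(tempdir(), "manifest.yaml")
  write_manifest(man, path)
  man2 <- read_manifest(path)
  expect_equal(man2$section_id, man$section_id)
  expect_equal(man2$time_point_h, man$time_point_h)
  expect_equal(man2$is_blank, man$is_blank)

  dir <- file.path(tempdir(), "mini-study")
  dir.create(dir, showWarnings = FALSE)
  write_imzml(msi_section(list(spec_of(700)), data.frame(x = 1L, y = 1L),
                          c(1, 1), "a"), file.path(dir, "a.imzML"))
  write_imzml(msi_section(list(spec_of(701)), data.frame(x = 1L, y = 1L),
                          c(1, 1), "blank1", is_blank = TRUE),
              file.path(dir, "blank1.imzML"))
  write_manifest(man, file.path(dir, "manifest.yaml"))
  secs <- load_study(file.path(dir, "manifest.yaml"))
  expect_equal(secs[["a"]]$treatment, "BPA")
  expect_equal(secs[["a"]]$time_point_h, 48)
  expect_true(secs[["blank1"]]$is_blank)
})
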