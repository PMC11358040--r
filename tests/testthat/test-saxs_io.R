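test_that("read_dat parses 2- and 3-column files and skips comments", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("0.01 10 1", "0.02 9 1", "0.03 8 1"), f)
  cv <- read_dat(f)
  expect_length(cv$q, 3)
  expect_equal(cv$intensity, c(10, 9, 8))
  expect_equal(cv$sigma, c(1, 1, 1))

  f2 <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("0.01 10", "0.02 9", "0.03 8"), f2)
  expect_null(read_dat(f2)$sigma)

  f3 <- withr::local_tempfile(fileext = ".dat")
  q <- seq(0.01, 0.2, length.out = 100)
  writeLines(c(paste("# comment line", 1:5),
               sprintf("%.6f %.6f %.6f", q, exp(-q), 0.01 + 0 * q)), f3)
  expect_length(read_dat(f3)$q, 100)
})

test_that("read_dat reports malformed input with the offending row", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("0.01 10 1", "0.03 9 1", "0.02 8 1"), f)
  expect_error(read_dat(f), "row 3")

  f2 <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("0.01 10 1", "0.02 oops 1", "0.03 8 1"), f2)
  expect_error(read_dat(f2), "non-numeric")

  expect_error(read_dat(file.path(tempdir(), "no-such-file.dat")),
               "not found")
})

test_that("write_dat/read_dat roundtrip preserves values and metadata", {
  q <- seq(0.012345678, 0.2, length.out = 57)
  cv <- scattering_curve(q, 100 * exp(-q^2 * 31.4159^2 / 3),
                         sigma = 0.01 + q / 7,
                         meta = list(label = "sampleA", time = 0.3,
                                     exposure = 0.3))
  f <- withr::local_tempfile(fileext = ".dat")
  write_dat(cv, f)
  cv2 <- read_dat(f)
  expect_equal(cv2$q, cv$q, tolerance = 1e-9)
  expect_equal(cv2$intensity, cv$intensity, tolerance = 1e-9)
  expect_equal(cv2$sigma, cv$sigma, tolerance = 1e-9)
  expect_equal(cv2$meta$label, "sampleA")
  expect_equal(cv2$meta$time, 0.3)
  # a second roundtrip is exact (values are fixed points of the format)
  f2 <- withr::local_tempfile(fileext = ".dat")
  write_dat(cv2, f2)
  expect_identical(read_dat(f2)$q, cv2$q)
})

test_that("scattering_curve enforces its invariants", {
  expect_error(scattering_curve(c(0.01, 0.02), c(1, 2)), "at least 3")
  expect_error(scattering_curve(c(0.01, 0.02, 0.02), 1:3), "increasing")
  expect_error(scattering_curve(c(-0.01, 0.02, 0.03), 1:3), "positive")
  expect_error(scattering_curve(c(0.01, 0.02, 0.03), 1:3, sigma = c(1, 0, 1)),
               "sigma")
  expect_warning(scattering_curve(c(0.5, 2.5, 3.5), 1:3), "nm")
})

make_toy_plate_dir <- function(n_frames = 10) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  q <- seq(0.01, 0.3, length.out = 30)
  wells <- data.frame(
    well = c("S01", "S02", "M01", "B01"),
    role = c("sample", "sample", "monomer-control", "buffer"),
    compound_id = c("cpdA", "cpdB", "DMSO", "buffer"),
    conc_mM = 0.5, replicate = 1,
    path_pattern = paste0(c("S01", "S02", "M01", "B01"), "_f{frame}.dat"))
  for (i in seq_len(nrow(wells))) {
    for (fr in seq_len(n_frames)) {
      cv <- scattering_curve(q, (i + fr) * exp(-q), sigma = rep(0.1, 30))
      write_dat(cv, file.path(dir, sprintf("%s_f%d.dat", wells$well[i], fr)))
    }
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(wells, manifest, row.names = FALSE)
  list(dir = dir, manifest = manifest, sheet = wells)
}

test_that("load_manifest assembles one ordered series per well", {
  tp <- make_toy_plate_dir()
  res <- load_manifest(tp$manifest)
  expect_length(res$series, 4)
  expect_true(all(vapply(res$series, length, integer(1)) == 10))
  expect_equal(res$series$S01$times, seq(0.3, 3.0, by = 0.3))
  expect_equal(nrow(res$validation), 0)
})

test_that("load_manifest validates schema and reports missing frames", {
  tp <- make_toy_plate_dir()
  bad <- tp$sheet[, setdiff(names(tp$sheet), "role")]
  f <- file.path(tp$dir, "bad.csv")
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(load_manifest(f), "role")

  dup <- rbind(tp$sheet, tp$sheet[1, ])
  f2 <- file.path(tp$dir, "dup.csv")
  utils::write.csv(dup, f2, row.names = FALSE)
  expect_error(load_manifest(f2), "duplicate")

  file.remove(file.path(tp$dir, "S02_f5.dat"))
  res <- load_manifest(tp$manifest, expected_frames = 10)
  expect_equal(res$validation$well, "S02")
  expect_equal(res$validation$frame, 5L)
  expect_length(res$series$S02, 9)
})

test_that("load_manifest is row-order independent", {
  tp <- make_toy_plate_dir()
  res1 <- load_manifest(tp$manifest)
  shuf <- tp$sheet[c(3, 1, 4, 2), ]
  f <- file.path(tp$dir, "shuffled.csv")
  utils::write.csv(shuf, f, row.names = FALSE)
  res2 <- load_manifest(f)
  for (w in names(res1$series)) {
    expect_identical(res1$series[[w]]$curves[[4]]$intensity,
                     res2$series[[w]]$curves[[4]]$intensity)
  }
})

test_that("frame_series requires times and a common grid flag", {
  q <- seq(0.01, 0.1, length.out = 10)
  mk <- function(t, qq = q) scattering_curve(qq, exp(-qq),
                                             meta = list(time = t))
  sr <- frame_series(list(mk(0.3), mk(0.6)))
  expect_true(sr$common_grid)
  sr2 <- frame_series(list(mk(0.3), mk(0.6, q + 1e-4)))
  expect_false(sr2$common_grid)
  expect_error(frame_series(list(mk(0.3), mk(0.3))), "strictly increasing")
  expect_error(frame_series(list(scattering_curve(q, exp(-q)))), "time")
})
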