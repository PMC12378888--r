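make_spec <- function(ni = 40L, nd = 70L, planes = 1L, imag = FALSE,
                      seed = 1L) {
  set.seed(seed)
  data <- array(rnorm(planes * ni * nd), c(planes, ni, nd))
  new_spectrum(data,
               axis_from_carrier(nd, 8000, 600.13, 4.7),
               axis_from_carrier(ni, 2000, 60.81, 118),
               imag_direct = if (imag) array(rnorm(planes * ni * nd),
                                             c(planes, ni, nd)),
               imag_indirect = if (imag) array(rnorm(planes * ni * nd),
                                               c(planes, ni, nd)),
               imag_both = if (imag) array(rnorm(planes * ni * nd),
                                           c(planes, ni, nd)))
}

expect_axis_close <- function(a, b, tol_ppm = 1e-5) {
  expect_equal(a$n_points, b$n_points)
  expect_lt(max(abs(axis_ppm(a) - axis_ppm(b))), tol_ppm)
}

test_that("ft2 write/read round trip is a fixed point at header precision", {
  for (cfg in list(list(imag = FALSE, planes = 1L),
                   list(imag = TRUE, planes = 1L),
                   list(imag = FALSE, planes = 3L))) {
    x <- make_spec(imag = cfg$imag, planes = cfg$planes)
    f1 <- withr::local_tempfile(fileext = ".ft2")
    f2 <- withr::local_tempfile(fileext = ".ft2")
    write_ft2(x, f1)
    y <- read_ft2(f1)
    # float32 storage: one rounding step, then an exact fixed point
    expect_lt(max(abs(y$data - x$data)), 1e-6 * max(abs(x$data)))
    expect_axis_close(y$axis_direct, x$axis_direct)
    expect_axis_close(y$axis_indirect, x$axis_indirect)
    write_ft2(y, f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
    z <- read_ft2(f2)
    expect_identical(z$data, y$data)
    if (cfg$imag) {
      expect_identical(z$imag_direct, y$imag_direct)
      expect_identical(z$imag_indirect, y$imag_indirect)
      expect_identical(z$imag_both, y$imag_both)
    }
    expect_equal(dim(y$data)[1], cfg$planes)
  }
})

test_that("ft2 header parses identically under the independent parser", {
  x <- make_spec()
  f <- withr::local_tempfile(fileext = ".ft2")
  write_ft2(x, f)
  h <- oracle_ft2_header(f)
  expect_equal(h$fltorder, 2.345, tolerance = 1e-6)
  expect_equal(h$dimcount, 2)
  expect_equal(h$size, 70)
  expect_equal(h$specnum, 40)
  expect_equal(h$f3size, 1)
  expect_equal(h$f2sw, 8000, tolerance = 1e-6)
  expect_equal(h$f2obs, 600.13, tolerance = 1e-6)
  expect_equal(h$f2orig, x$axis_direct$origin_hz, tolerance = 1e-6)
  expect_equal(h$f1sw, 2000, tolerance = 1e-6)
  expect_equal(h$f1obs, 60.81, tolerance = 1e-6)
  expect_equal(h$f1orig, x$axis_indirect$origin_hz, tolerance = 1e-6)
})

test_that("ft2 rejects bad files", {
  f <- withr::local_tempfile()
  writeBin(numeric(100), f, size = 4L)
  expect_error(read_ft2(f), "not an ft2 file")
  writeBin(numeric(3000), f, size = 4L)
  expect_error(read_ft2(f), "not an ft2 file")
})

test_that("ucsf round trip handles non-tile-multiple sizes", {
  x <- make_spec(ni = 40L, nd = 70L)          # not a multiple of tile 32
  f1 <- withr::local_tempfile(fileext = ".ucsf")
  f2 <- withr::local_tempfile(fileext = ".ucsf")
  write_ucsf(x, f1, tile = 32L)
  y <- read_ucsf(f1)
  expect_lt(max(abs(y$data - x$data)), 1e-6 * max(abs(x$data)))
  expect_axis_close(y$axis_direct, x$axis_direct)
  expect_axis_close(y$axis_indirect, x$axis_indirect)
  write_ucsf(y, f2, tile = 32L)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("ucsf tile reassembly matches the independent reader", {
  x <- make_spec(ni = 50L, nd = 90L)
  f <- withr::local_tempfile(fileext = ".ucsf")
  write_ucsf(x, f, tile = 32L)
  o <- oracle_ucsf(f)
  expect_equal(o$magic, "UCSF NMR")
  expect_equal(o$ndim, 2L)
  expect_equal(o$a1$n, 50L); expect_equal(o$a2$n, 90L)
  expect_equal(o$matrix, plane_matrix(read_ucsf(f), 1L))
  expect_equal(o$a2$sw, 8000, tolerance = 1e-6)
  expect_equal(o$a1$obs, 60.81, tolerance = 1e-6)
})

test_that("ucsf errors and warnings", {
  f <- withr::local_tempfile()
  writeBin(charToRaw(paste(rep("x", 200), collapse = "")), f)
  expect_error(read_ucsf(f), "not a ucsf file")
  x <- make_spec(imag = TRUE)
  f2 <- withr::local_tempfile(fileext = ".ucsf")
  expect_warning(write_ucsf(x, f2), "imaginary")
  x3 <- make_spec(planes = 2L)
  expect_error(write_ucsf(x3, withr::local_tempfile()), "only 2D")
})

test_that("ft2 and ucsf ppm maps agree for one spectrum", {
  x <- make_spec()
  ff <- withr::local_tempfile(fileext = ".ft2")
  fu <- withr::local_tempfile(fileext = ".ucsf")
  write_ft2(x, ff); write_ucsf(x, fu)
  a <- read_ft2(ff); b <- read_ucsf(fu)
  # float32 headers bound the achievable agreement: 1e-6 ppm on the 1H
  # axis; eps32-limited on the 15N axis (values ~1e2 ppm)
  expect_lt(max(abs(axis_ppm(a$axis_direct) - axis_ppm(b$axis_direct))), 1e-6)
  expect_lt(max(abs(axis_ppm(a$axis_indirect) - axis_ppm(b$axis_indirect))),
            130 * 2^-23 + 1e-6)
})

test_that("Bruker fixture round trip is exact for all encodings", {
  pk <- spread_peaks(3L)
  for (enc in list(c("float64", "little"), c("float64", "big"),
                   c("int32", "little"), c("int32", "big"))) {
    acq <- hsqc_acq(nd = 32L, ni = 8L, data_type = enc[1], byte_order = enc[2])
    pk2 <- pk; pk2$amplitude <- pk2$amplitude * 1e5   # int32 head room
    td <- generate_fid(new_ground_truth(pk2, acquisition = acq, seed = 3L))
    d <- withr::local_tempdir()
    write_bruker_fixture(td, td$meta, file.path(d, "1"), force = TRUE)
    rb <- read_bruker(file.path(d, "1"))
    expect_identical(rb$td$fid, td$fid)
    expect_equal(rb$meta$data_type, enc[1])
    expect_equal(rb$meta$byte_order, enc[2])
    expect_equal(rb$meta$sw_hz, acq$sw_hz)
    expect_equal(rb$meta$obs_mhz, acq$obs_mhz)
    expect_equal(rb$meta$carrier_ppm, acq$carrier_ppm, tolerance = 1e-12)
  }
})

test_that("byte-swapped int32 ser decodes to the same matrix as the oracle", {
  acq <- hsqc_acq(nd = 16L, ni = 4L, data_type = "int32", byte_order = "big")
  pk <- spread_peaks(2L); pk$amplitude <- pk$amplitude * 1e4
  td <- generate_fid(new_ground_truth(pk, acquisition = acq, seed = 9L))
  d <- withr::local_tempdir()
  write_bruker_fixture(td, td$meta, file.path(d, "1"), force = TRUE)
  o <- oracle_bruker_ser(file.path(d, "1", "ser"), td2 = 32L,
                         data_type = "int32", endian = "big")
  rb <- read_bruker(file.path(d, "1"))
  expect_equal(unname(o), unname(rb$td$fid[1L, , ]))
})

test_that("Bruker reader reports structural errors", {
  d <- withr::local_tempdir()
  expect_error(read_bruker(d), "not a Bruker dataset")
  acq <- hsqc_acq(nd = 16L, ni = 4L)
  td <- generate_fid(new_ground_truth(spread_peaks(2L), acquisition = acq))
  write_bruker_fixture(td, td$meta, file.path(d, "1"), force = TRUE)
  # 7 trailing bytes -> inconsistent
  con <- file(file.path(d, "1", "ser"), "ab")
  writeBin(raw(7L), con); close(con)
  expect_error(read_bruker(file.path(d, "1")), "truncated or inconsistent")
})

test_that("pseudo-3D plane count is inferred from the ser size", {
  acq <- hsqc_acq(nd = 16L, ni = 4L)
  tr <- new_ground_truth(spread_peaks(2L), acquisition = acq,
                         plane_scales = c(1, 0.5, 0.25), seed = 2L)
  td <- generate_fid(tr)
  d <- withr::local_tempdir()
  write_bruker_fixture(td, td$meta, file.path(d, "1"), force = TRUE)
  rb <- read_bruker(file.path(d, "1"))
  expect_equal(rb$meta$n_planes, 3L)
  expect_identical(rb$td$fid, td$fid)
})

test_that("totxt reader parses literals exactly and rejects bad dialects", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# F1LEFT = 130.0 ppm. F1RIGHT = 110.0 ppm.",
               "# F2LEFT = 10.0 ppm. F2RIGHT = 6.0 ppm.",
               "# NROWS = 2", "# NCOLS = 3",
               "# row = 0", "1.5", "2.5", "-3.25",
               "# row = 1", "4", "5", "6"), f)
  s <- read_topspin_txt(f)
  expect_equal(plane_matrix(s, 1L), matrix(c(1.5, 2.5, -3.25, 4, 5, 6),
                                           2L, 3L, byrow = TRUE))
  expect_equal(axis_ppm(s$axis_indirect), c(130, 110))
  expect_equal(axis_ppm(s$axis_direct), c(10, 8, 6))
  f2 <- withr::local_tempfile()
  writeLines(c("# NROWS = 2", "# NCOLS = 3"), f2)
  expect_error(read_topspin_txt(f2), "unrecognized totxt dialect")
  f3 <- withr::local_tempfile()
  writeLines(character(), f3)
  expect_error(read_topspin_txt(f3), "empty")
})

test_that("ft2 and totxt written from one source agree to 6 digits", {
  x <- make_spec(ni = 12L, nd = 17L)
  ff <- withr::local_tempfile(fileext = ".ft2")
  ft <- withr::local_tempfile(fileext = ".txt")
  write_ft2(x, ff); write_topspin_txt(x, ft)
  a <- plane_matrix(read_ft2(ff), 1L)
  b <- plane_matrix(read_topspin_txt(ft), 1L)
  expect_lt(max(abs(a - b) / pmax(abs(a), 1e-12)), 1e-6)
})

test_that("nmrpipe_tab peak list round trip with plane heights", {
  ph <- matrix(c(1, 0.5, 0.25, 0.1,
                 1, 0.6, 0.36, 0.2,
                 1, 0.7, 0.49, 0.3), 3L, 4L, byrow = TRUE)
  pk <- new_peaklist(x_ppm = c(8.1234, 7.5, 6.9), y_ppm = c(121.5, 115, 110.2),
                     height = c(1e5, 7e4, 5e4),
                     sigma_x = c(1.2, 1.3, 1.4), gamma_x = c(0.8, 0.7, 0.6),
                     label = c("A10", "G55", "K7"), plane_heights = ph)
  f <- withr::local_tempfile(fileext = ".tab")
  write_peaklist(pk, f, "nmrpipe_tab")
  txt <- readLines(f)
  expect_match(txt[1], "Z_A0 Z_A1 Z_A2 Z_A3")
  y <- read_peaklist(f, "nmrpipe_tab")
  expect_equal(y$x_ppm, pk$x_ppm, tolerance = 1e-4)
  expect_equal(y$y_ppm, pk$y_ppm, tolerance = 1e-4)
  expect_equal(y$label, pk$label)
  expect_equal(as.matrix(y[, c("Z_A0", "Z_A1", "Z_A2", "Z_A3")]),
               ph, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("sparky list round trip; plane heights dropped with warning", {
  pk <- new_peaklist(x_ppm = c(8.1, 7.2), y_ppm = c(120, 111),
                     height = c(2e5, 1e5), label = c("L3HN-N", "V9HN-N"),
                     plane_heights = matrix(1, 2L, 2L))
  f <- withr::local_tempfile(fileext = ".list")
  expect_warning(write_peaklist(pk, f, "sparky_list"), "Z_A")
  y <- read_peaklist(f, "sparky_list")
  expect_equal(y$x_ppm, pk$x_ppm, tolerance = 1e-4)
  expect_equal(y$y_ppm, pk$y_ppm, tolerance = 1e-4)
  expect_equal(y$label, pk$label)
  expect_null(y$Z_A0)
})

test_that("tab files parse by VARS name, not column position", {
  f <- withr::local_tempfile(fileext = ".tab")
  writeLines(c("VARS   HEIGHT Y_PPM X_PPM ASS",
               "FORMAT %e %9.4f %9.4f %s",
               "5.0e+04 115.2000 7.3000 Q2",
               "3.0e+04 108.0000 8.8000 T9"), f)
  y <- read_peaklist(f, "nmrpipe_tab")
  expect_equal(y$x_ppm, c(7.3, 8.8))
  expect_equal(y$y_ppm, c(115.2, 108.0))
  expect_equal(y$height, c(5e4, 3e4))
  expect_equal(y$label, c("Q2", "T9"))
  f2 <- withr::local_tempfile()
  writeLines(c("VARS A B", "1 2"), f2)
  expect_error(read_peaklist(f2, "nmrpipe_tab"), "unrecognized peak list")
})

test_that("nuslist parsing: dedupe, completeness, bounds", {
  f <- withr::local_tempfile()
  writeLines(c("0", "3", "1", "3"), f)
  s <- read_nuslist(f, 8L)
  expect_equal(s$sampled_increments, c(0L, 1L, 3L))
  expect_false(s$complete)
  writeLines(as.character(0:7), f)
  expect_true(read_nuslist(f, 8L)$complete)
  writeLines("12", f)
  expect_error(read_nuslist(f, 8L), "schedule exceeds declared grid")
})
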