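test_that("solvent filter removes DC, keeps off-resonance tones", {
  n <- 256L
  t <- 0:(n - 1L)
  # constant FID is fully captured by the moving average
  expect_lt(max(Mod(solvent_suppress(rep(3 + 2i, n)))), 1e-10)
  # far off-resonance tone: post-FFT peak height changes < 5%
  tone <- exp(2i * pi * 0.25 * t)
  h0 <- max(Mod(fft(tone)))
  h1 <- max(Mod(fft(solvent_suppress(tone))))
  expect_lt(abs(h1 - h0) / h0, 0.05)
  # DC + tone: DC attenuated >= 20x, tone retained
  mix <- 5 + tone
  S <- fft(solvent_suppress(mix))
  expect_lt(Mod(S[1]) / (5 * n), 1 / 20)
  expect_gt(Mod(S[0.25 * n + 1]) / n, 0.95)
  expect_warning(solvent_suppress(c(1 + 0i, 2)), "passthrough")
})

test_that("apodization windows follow their stated formulas", {
  x <- rep(1 + 0i, 3L)
  w <- apodize(x, new_window("sine_bell", off = 0.5, end = 1.0, pow = 1))
  expect_equal(Re(w), c(1, sqrt(2) / 2, sin(pi)), tolerance = 1e-12)
  expect_equal(apodize(x, new_window("exponential", lb_hz = 0)), x)
  expect_equal(apodize(x, new_window("none")), x)
  n <- 64L
  y <- complex(real = rnorm(n), imaginary = rnorm(n))
  lb <- 12
  dwell <- 1 / 8000
  expect_equal(apodize(y, new_window("exponential", lb_hz = lb), dwell),
               y * exp(-pi * lb * (0:(n - 1L)) * dwell))
  expect_error(new_window("sine_bell", off = 0.9, end = 0.2), "off <= end")
})

test_that("zero filling appends zeros to n * 2^folds", {
  x <- complex(real = rnorm(128), imaginary = rnorm(128))
  z <- zero_fill(x, 1L)
  expect_length(z, 256L)
  expect_equal(z[1:128], x)
  expect_true(all(z[129:256] == 0))
  expect_identical(zero_fill(x, 0L), x)
  expect_length(zero_fill(x[1:100], 2L), 400L)
})

test_that("transform_direct: Fourier pair, Parseval, carrier centring", {
  n <- 128L
  f0 <- 0.171875                      # 22/128 cycles/sample, on-grid
  x <- exp(2i * pi * f0 * (0:(n - 1L)))
  s <- transform_direct(x)
  expect_equal(which.max(Mod(s)), as.integer(n / 2 - f0 * n + 1L))
  # Parseval (plain FFT identity, no first-point scaling in this op)
  y <- complex(real = rnorm(n), imaginary = rnorm(n))
  sy <- transform_direct(y)
  expect_equal(sum(Mod(y)^2), sum(Mod(sy)^2) / n)
  # zero frequency maps to the centre index n/2
  expect_equal(which.max(Mod(transform_direct(rep(1 + 0i, n)))), n %/% 2L + 1L)
})

test_that("group delay compensation preserves peak positions", {
  acq <- hsqc_acq(nd = 512L, ni = 8L)
  pk <- spread_peaks(2L); pk$r2_x_hz <- 30
  tr0 <- new_ground_truth(pk, acquisition = acq, seed = 3L)
  trg <- new_ground_truth(pk, acquisition = acq, seed = 3L)
  trg$acquisition$group_delay <- 67.98
  s0 <- process_2d(generate_fid(tr0), scheme = scheme_known())
  s1 <- process_2d(generate_fid(trg), scheme = scheme_known())
  p0 <- refined_max(plane_matrix(s0, 1L))
  p1 <- refined_max(plane_matrix(s1, 1L))
  expect_lt(abs(p0["col"] - p1["col"]), 0.01)
  expect_lt(abs(p0["row"] - p1["row"]), 0.01)
  # circular-shift variant agrees on positions too
  r <- generate_fid(trg)$fid[1L, 1L, ]
  a <- transform_direct(r, group_delay = 67.98, method = "circular_shift")
  b <- transform_direct(generate_fid(tr0)$fid[1L, 1L, ])
  expect_equal(which.max(Mod(a)), which.max(Mod(b)))
})

test_that("indirect quadrature modes recover the signed frequency", {
  pk <- data.frame(x_ppm = 8.2, y_ppm = 112.5, amplitude = 10,
                   r2_x_hz = 18, r2_y_hz = 8)
  pos <- list()
  for (mode in c("states", "states_tppi", "echo_antiecho")) {
    acq <- hsqc_acq(nd = 64L, ni = 32L, acquisition_mode = mode)
    sp <- process_2d(generate_fid(new_ground_truth(pk, acquisition = acq)),
                     scheme = scheme_known())
    ij <- which(sp$data == max(sp$data), arr.ind = TRUE)[1L, ]
    pos[[mode]] <- c(pt_to_ppm(sp$axis_indirect, ij[2] - 1L),
                     pt_to_ppm(sp$axis_direct, ij[3] - 1L))
  }
  for (mode in names(pos)) {
    expect_lt(abs(pos[[mode]][1] - 112.5), 2000 / 64 / 60.81)  # 1 step
    expect_lt(abs(pos[[mode]][2] - 8.2), 8000 / 128 / 600.13)
  }
  expect_error(transform_indirect(matrix(0i, 5L, 4L)), "incomplete quadrature")
})

test_that("states_tppi moves the axial artifact to the spectrum edge", {
  pk <- data.frame(x_ppm = 8.2, y_ppm = 112.5, amplitude = 10,
                   r2_x_hz = 18, r2_y_hz = 8)
  mk <- function(mode) {
    acq <- hsqc_acq(nd = 64L, ni = 32L, acquisition_mode = mode)
    tr <- new_ground_truth(pk, acquisition = acq)
    tr$axial <- list(x_ppm = 4.7, amp = 5, r2_x_hz = 30)
    process_2d(generate_fid(tr), scheme = scheme_known())
  }
  col_of <- function(sp) {
    j <- as.integer(round(ppm_to_pt(sp$axis_direct, 4.7))) + 1L
    abs(plane_matrix(sp, 1L))[, j]
  }
  ax_states <- col_of(mk("states"))       # axial at t1=0 -> centre row
  ax_tppi <- col_of(mk("states_tppi"))    # sign alternation -> edge row
  n1 <- length(ax_states)
  expect_equal(which.max(ax_states), n1 %/% 2L + 1L)
  expect_true(which.max(ax_tppi) %in% c(1L, n1))
})

test_that("apply_phase identities and inverse", {
  x <- complex(real = rnorm(64), imaginary = rnorm(64))
  expect_equal(apply_phase(x, new_phase(0, 0)), x)
  expect_equal(apply_phase(x, new_phase(180, 0)), -x)
  y <- apply_phase(apply_phase(x, new_phase(37, 112)), new_phase(-37, -112))
  expect_lt(max(Mod(y - x)), 1e-12)
  # +360 on p0 is an identity on the phased real part
  expect_equal(Re(apply_phase(x, new_phase(380, 0))),
               Re(apply_phase(x, new_phase(20, 0))))
  expect_error(apply_phase(rnorm(8), new_phase(0, 0)), "imaginary data")
})

test_that("autophase recovers known dephasing and flags flat input", {
  acq <- hsqc_acq(nd = 256L, ni = 16L)
  # perfectly phased spectrum -> (0, 0) within (+-1, +-5) degrees
  tr <- new_ground_truth(spread_peaks(5L), acquisition = acq,
                         noise_sigma = 0.01, seed = 11L)
  sp <- process_2d(generate_fid(tr), scheme = new_scheme(direct_phase = "auto"))
  ph <- attr(sp, "phases")$direct
  expect_lt(abs(ph$p0_deg), 1)
  expect_lt(abs(ph$p1_deg), 5)
  expect_warning(autophase(complex(real = rep(0, 64), imaginary = rep(0, 64))),
                 "low signal")
  expect_error(autophase(rnorm(64)), "imaginary data")
})

test_that("autophase + apply_phase inverts a known dephasing (seeded)", {
  # 1D absorption-mode row with 5 resonances across the window
  n <- 256L
  t <- (0:(n - 1L)) / 8000
  set.seed(21L)
  fid <- Reduce(`+`, lapply(seq(-3000, 3000, length.out = 5), function(f)
    runif(1, 5, 10) * exp((2i * pi * f - 25) * t)))
  fid[1] <- fid[1] * 0.5
  row <- transform_direct(zero_fill(fid, 1L)) +
    complex(real = rnorm(2L * n, 0, 0.05), imaginary = rnorm(2L * n, 0, 0.05))
  for (k in 1:4) {
    set.seed(200 + k)
    p <- new_phase(runif(1, -90, 90), runif(1, -120, 120))
    dephased <- apply_phase(row, p)
    rec <- autophase(dephased)
    expect_lt(abs(((rec$p0_deg + p$p0_deg + 180) %% 360) - 180), 2)
    expect_lt(abs(rec$p1_deg + p$p1_deg), 10)
  }
})

test_that("autophase parameter recovery over seeds", {
  acq <- hsqc_acq(nd = 256L, ni = 8L)
  errs <- matrix(0, 6L, 2L)
  for (k in 1:6) {
    set.seed(100 + k)
    p0 <- runif(1, -60, 60); p1 <- runif(1, -90, 90)
    tr <- new_ground_truth(spread_peaks(5L), acquisition = acq,
                           applied_phase = list(direct = new_phase(p0, p1),
                                                indirect = new_phase(0, 0)),
                           noise_sigma = 0.01, seed = 100 + k)
    sp <- process_2d(generate_fid(tr),
                     scheme = new_scheme(direct_phase = "auto"))
    ph <- attr(sp, "phases")$direct
    errs[k, ] <- c(((ph$p0_deg - p0 + 180) %% 360) - 180, ph$p1_deg - p1)
  }
  expect_lt(max(abs(errs[, 1])), 2)
  expect_lt(max(abs(errs[, 2])), 10)
})

test_that("extract_region slices data and keeps ppm calibration", {
  tr <- new_ground_truth(spread_peaks(3L), acquisition = hsqc_acq())
  sp <- process_2d(generate_fid(tr), scheme = scheme_known())
  full <- extract_region(sp, "direct", -100, 1000)
  expect_equal(full$data, sp$data)
  ex <- extract_region(sp, "direct", 6, 9)
  p_before <- axis_ppm(sp$axis_direct)
  keep <- which(p_before >= 6 & p_before <= 9)
  expect_equal(axis_ppm(ex$axis_direct), p_before[keep])
  expect_equal(ex$data[1, , ], sp$data[1, , keep])
  ex2 <- extract_region(ex, "direct", 6, 9)
  expect_equal(ex2$data, ex$data)                  # idempotent
  expect_error(extract_region(sp, "direct", 100, 200), "does not overlap")
})

test_that("process_2d with windows off equals the direct 2D FFT oracle", {
  acq <- hsqc_acq(nd = 32L, ni = 8L)
  tr <- new_ground_truth(spread_peaks(3L), acquisition = acq,
                         noise_sigma = 0.1, seed = 5L)
  td <- generate_fid(tr)
  sch <- new_scheme(direct_window = new_window("none"),
                    indirect_window = new_window("none"),
                    direct_zf = 0L, indirect_zf = 0L,
                    direct_phase = new_phase(25, 40),
                    indirect_phase = new_phase(-10, 15))
  sp <- process_2d(td, scheme = sch)
  o <- oracle_fft2d(td$fid[1L, , ], 25, 40, -10, 15)
  rel <- function(a, b) max(abs(a - b)) / max(abs(b))
  expect_lt(rel(sp$data[1, , ], o$rr), 1e-9)
  expect_lt(rel(sp$imag_direct[1, , ], o$ri), 1e-9)
  expect_lt(rel(sp$imag_indirect[1, , ], o$ir), 1e-9)
  expect_lt(rel(sp$imag_both[1, , ], o$ii), 1e-9)
})

test_that("Parseval holds through the unwindowed transform chain", {
  x <- complex(real = rnorm(100), imaginary = rnorm(100))
  y <- zero_fill(apodize(x, new_window("none")), 1L)
  s <- transform_direct(y)
  expect_equal(sum(Mod(y)^2), sum(Mod(s)^2) / length(y))
})

test_that("pipeline is linear in the input when the solvent filter is off", {
  acq <- hsqc_acq(nd = 32L, ni = 8L)
  tr <- new_ground_truth(spread_peaks(3L), acquisition = acq, seed = 6L)
  td <- generate_fid(tr)
  td5 <- new_timedomain(td$fid * 5, td$meta)
  s1 <- process_2d(td, scheme = scheme_known())
  s5 <- process_2d(td5, scheme = scheme_known())
  expect_lt(max(abs(s5$data - 5 * s1$data)), 1e-9 * max(abs(s5$data)))
})

test_that("3-peak fixture maxima localize within one digital step", {
  tr <- new_ground_truth(spread_peaks(3L), acquisition = hsqc_acq(),
                         noise_sigma = 0.02, seed = 8L)
  sp <- process_2d(generate_fid(tr), scheme = scheme_known())
  pk <- pick_peaks(sp, threshold_sigma = 8)
  truth <- spread_peaks(3L)
  step_x <- 8000 / sp$axis_direct$n_points / 600.13
  step_y <- 2000 / sp$axis_indirect$n_points / 60.81
  for (j in seq_len(3L)) {
    d <- sqrt(((pk$x_ppm - truth$x_ppm[j]) / step_x)^2 +
              ((pk$y_ppm - truth$y_ppm[j]) / step_y)^2)
    expect_lt(min(d), 1)
  }
})

test_that("first_plane_only and pseudo-3D plane handling", {
  tr <- new_ground_truth(spread_peaks(2L), acquisition = hsqc_acq(nd = 32L, ni = 8L),
                         plane_scales = c(1, 0.5, 0.25, 0.125), seed = 9L)
  td <- generate_fid(tr)
  s1 <- process_2d(td, scheme = scheme_known(first_plane_only = TRUE))
  expect_equal(n_planes(s1), 1L)
  expect_error(process_pseudo3d(td, scheme = scheme_known(first_plane_only = TRUE)),
               "first_plane_only")
  sp <- process_pseudo3d(td, scheme = scheme_known())
  expect_equal(n_planes(sp), 4L)
  # scaled planes give heights in ratio within 1%
  hs <- apply(sp$data, 1L, max)
  expect_equal(hs / hs[1], c(1, 0.5, 0.25, 0.125), tolerance = 0.01)
  # identical planes process identically
  tr2 <- new_ground_truth(spread_peaks(2L), acquisition = hsqc_acq(nd = 32L, ni = 8L),
                          plane_scales = c(1, 1, 1, 1), seed = 10L)
  sp2 <- process_pseudo3d(generate_fid(tr2), scheme = scheme_known())
  for (p in 2:4)
    expect_lt(max(abs(sp2$data[p, , ] - sp2$data[1, , ])),
              1e-12 * max(abs(sp2$data)))
})

test_that("scheme config round trips through its text form", {
  sch <- new_scheme(direct_window = new_window("sine_bell", off = 0.45,
                                               end = 0.98, pow = 1),
                    indirect_window = new_window("exponential", lb_hz = 6),
                    direct_zf = 2L, indirect_zf = 0L, solvent_filter = TRUE,
                    direct_phase = new_phase(12, -34),
                    indirect_phase = new_phase(90, 0),
                    direct_extract = c(6, 9.5), first_plane_only = TRUE)
  f <- withr::local_tempfile(fileext = ".cfg")
  write_scheme_config(sch, f)
  sch2 <- read_scheme_config(f)
  expect_equal(sch2, sch)
  writeLines("direct.bogus = 1", f)
  expect_error(read_scheme_config(f), "unknown config key")
})
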