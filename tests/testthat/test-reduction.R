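test_that("pixel_q matches trigonometric and small-angle oracles", {
  cfg <- instrument_config(sdd = 1.7, wavelength = 6)
  expect_equal(pixel_q(0, cfg), 0)
  expect_equal(pixel_q(0.1, cfg), 0.06152010, tolerance = 1e-7)
  expect_error(pixel_q(-0.01, cfg), "r must be >= 0")
  # small-angle approximation q ~ 2 pi r / (L lambda)
  r <- seq(0.001, 0.05 * 1.7, length.out = 20)
  approxq <- 2 * pi * r / (1.7 * 6)
  expect_true(all(abs(pixel_q(r, cfg) - approxq) / approxq < 0.002))
})

test_that("pixel_q is monotone in r, L and lambda", {
  r <- seq(0.01, 0.5, length.out = 30)
  cfg <- instrument_config(sdd = 1.7)
  expect_true(all(diff(pixel_q(r, cfg)) > 0))
  qL <- sapply(c(1.7, 5, 14.5), function(L)
    pixel_q(0.2, instrument_config(sdd = L)))
  expect_true(all(diff(qL) < 0))
  qlam <- sapply(c(4, 6, 12), function(lam)
    pixel_q(0.2, instrument_config(wavelength = lam, sdd = 1.7)))
  expect_true(all(diff(qlam) < 0))
})

test_that("correct_frame applies the normalization arithmetic", {
  cfg <- instrument_config(sdd = 1.7, detector_shape = c(8, 8),
                           beam_center = c(3.5, 3.5))
  # identity configuration
  counts <- matrix(rpois(64, 50), 8, 8)
  fr <- detector_frame(counts, cfg, monitor = 1)
  expect_equal(correct_frame(fr)$I, counts)
  # hand arithmetic: ((100 - 10) / 2) / 1000 = 0.045
  fr2 <- detector_frame(matrix(100, 8, 8), cfg, monitor = 1000,
                        dark = matrix(10, 8, 8),
                        sensitivity = matrix(2, 8, 8))
  expect_equal(correct_frame(fr2)$I, matrix(0.045, 8, 8))
  expect_equal(correct_frame(fr2)$sigma, matrix(10 / 2 / 1000, 8, 8))
  # doubling the monitor halves intensities exactly
  fr3 <- detector_frame(matrix(100, 8, 8), cfg, monitor = 2000,
                        dark = matrix(10, 8, 8),
                        sensitivity = matrix(2, 8, 8))
  expect_equal(correct_frame(fr3)$I, correct_frame(fr2)$I / 2)
  # shape and validity errors
  expect_error(detector_frame(matrix(1, 4, 4), cfg), "shape")
  expect_error(detector_frame(counts, cfg, monitor = 0), "monitor")
  expect_error(detector_frame(counts, cfg,
                              sensitivity = matrix(0, 8, 8)),
               "sensitivity")
})

test_that("detect_anisotropy classifies uniform and modulated frames", {
  flat <- constant_frame(500)
  res <- detect_anisotropy(flat, q_window = c(0.05, 0.2))
  expect_true(res$isotropic)
  expect_lt(res$score, 0.1)
  # two-fold modulation depth 0.5 at phi0 = 30 degrees; the annulus stays
  # inside the detector's inscribed circle so phi coverage is uniform
  mf <- modulated_frame(0.5, phi0 = 30)
  res <- detect_anisotropy(mf, q_window = c(0.05, 0.15))
  expect_false(res$isotropic)
  expect_equal(res$score, 0.5, tolerance = 0.05)
  expect_lt(min(abs(res$phi0 - 30), abs(res$phi0 - 210)), 5)
  # score invariant under positive scaling (monitor rescales intensity)
  mf2 <- detector_frame(mf$counts, mf$config, monitor = 37)
  res2 <- detect_anisotropy(mf2, q_window = c(0.05, 0.15))
  expect_equal(res2$score, res$score, tolerance = 1e-12)
  expect_error(detect_anisotropy(flat, q_window = c(0.9, 1.0)),
               "empty annulus")
})

test_that("detect_anisotropy matches the generator flag across depths", {
  for (depth in c(0.2, 0.35, 0.6)) {
    res <- detect_anisotropy(modulated_frame(depth, phi0 = 115),
                             q_window = c(0.05, 0.2))
    expect_false(res$isotropic)
  }
  expect_true(detect_anisotropy(modulated_frame(0, phi0 = 0),
                                q_window = c(0.05, 0.2))$isotropic)
})

test_that("sector_reduce reproduces a constant field and conserves counts", {
  fr <- constant_frame(7)
  prof <- sector_reduce(fr)
  expect_true(all(prof$I == 7))
  expect_equal(attr(prof, "label"), "isotropic")
  # count conservation: total pooled counts equal in-range pixel counts
  mf <- modulated_frame(0.4)
  geo <- fibrilsans:::pixel_geometry(mf$config)
  q_bins <- seq(0.02, 0.25, length.out = 40)
  prof <- sector_reduce(mf, q_bins = q_bins)
  breaks <- c(q_bins[1] - diff(q_bins[1:2]) / 2,
              q_bins[-40] + diff(q_bins) / 2,
              q_bins[40] + diff(q_bins[39:40]) / 2)
  inrange <- geo$q >= breaks[1] & geo$q <= breaks[41]
  expect_equal(sum(attr(prof, "provenance")$counts_sum),
               sum(mf$counts[inrange]))
  # two complementary two-fold sectors partition all azimuths
  s1 <- sector_reduce(mf, sector_def(0, 45), q_bins = q_bins)
  s2 <- sector_reduce(mf, sector_def(90, 45), q_bins = q_bins)
  pooled <- sum(attr(s1, "provenance")$counts_sum) +
    sum(attr(s2, "provenance")$counts_sum)
  # diagonal pixels sit exactly on the 45-degree sector boundary and are
  # double-counted by both closed sectors; a few percent of the total
  expect_gte(pooled, sum(mf$counts[inrange]))
  expect_lte((pooled - sum(mf$counts[inrange])) / pooled, 0.05)
  expect_error(sector_reduce(mf, q_bins = c(0.29, 0.3)),
               "no pixels")
})

test_that("sector_reduce equals a brute-force per-pixel loop", {
  gt <- gt_disk()
  cfg <- instrument_config(sdd = 1.7, detector_shape = c(64, 64),
                           beam_center = c(31.5, 31.5),
                           q_range = c(0.01, 0.27))
  fr <- generate_frame(gt, cfg, expected_counts = 2e5, seed = 11)
  cf <- correct_frame(fr)
  q_bins <- seq(0.02, 0.25, length.out = 30)
  sec <- sector_def(0, 25)
  prof <- sector_reduce(cf, sec, q_bins = q_bins)
  # independent naive implementation
  geo <- fibrilsans:::pixel_geometry(cfg)
  nb <- length(q_bins)
  breaks <- c(q_bins[1] - diff(q_bins[1:2]) / 2,
              q_bins[-nb] + diff(q_bins) / 2,
              q_bins[nb] + diff(q_bins[(nb - 1):nb]) / 2)
  acc_I <- acc_V <- acc_Q <- acc_n <- numeric(nb)
  for (i in 1:64) for (j in 1:64) {
    qij <- geo$q[i, j]
    b <- findInterval(qij, breaks, rightmost.closed = TRUE)
    if (b < 1 || b > nb) next
    dphi <- (geo$phi[i, j] - 0 + 90) %% 180 - 90
    if (abs(dphi) > 25) next
    acc_I[b] <- acc_I[b] + cf$I[i, j]
    acc_V[b] <- acc_V[b] + cf$sigma[i, j]^2
    acc_Q[b] <- acc_Q[b] + qij
    acc_n[b] <- acc_n[b] + 1
  }
  nz <- acc_n > 0
  expect_equal(prof$I, acc_I[nz] / acc_n[nz], tolerance = 1e-12)
  expect_equal(prof$q, acc_Q[nz] / acc_n[nz], tolerance = 1e-12)
  expect_equal(prof$sigma, sqrt(acc_V[nz]) / acc_n[nz], tolerance = 1e-12)
})

test_that("isotropic frame reduces identically in both sectors", {
  # aligned vs amorphous sectors on an isotropic Poisson frame agree
  # within propagated errors (reduced chi2 of the difference near 1)
  gt <- decay_series_scenario(seed = 3)$samples[[2]]
  cfg <- instrument_config(sdd = 1.7, q_range = c(0.012, 0.27))
  chis <- sapply(1:5, function(s) {
    fr <- generate_frame(gt, cfg, expected_counts = 5e6, seed = 100 + s)
    cf <- correct_frame(fr)
    a <- sector_reduce(cf, sector_def(0, 25), label = "aligned")
    m <- sector_reduce(cf, sector_def(90, 25), label = "amorphous")
    ia <- attr(a, "provenance")$bin_index
    im <- attr(m, "provenance")$bin_index
    common <- intersect(ia, im)
    z <- (a$I[match(common, ia)] - m$I[match(common, im)]) /
      sqrt(a$sigma[match(common, ia)]^2 + m$sigma[match(common, im)]^2)
    mean(z^2)
  })
  expect_gt(mean(chis), 0.7)
  expect_lt(mean(chis), 1.3)
})

test_that("merge_profiles scales, sorts and spans the union range", {
  q1 <- seq(0.003, 0.04, length.out = 40)
  q2 <- seq(0.012, 0.27, length.out = 60)
  p <- gt_disk()$amorphous
  long <- profile1d(q1, model_intensity(q1, p), rep(0.01, 40),
                    label = "amorphous")
  short <- profile1d(q2, model_intensity(q2, p), rep(0.01, 60),
                     label = "amorphous")
  m <- merge_profiles(long, short)
  # interpolation of the curved model between grid points limits the
  # noiseless scale factor to ~0.1% of unity
  expect_equal(attr(m, "provenance")$merge_scale, 1, tolerance = 0.005)
  expect_equal(range(m$q), c(min(q1), max(q2)))
  expect_true(!is.unsorted(m$q, strictly = TRUE))
  # pre-multiplied short curve: recovered scale factor exactly halves
  short2 <- profile1d(q2, 2 * model_intensity(q2, p), rep(0.01, 60),
                      label = "amorphous")
  m2 <- merge_profiles(long, short2)
  expect_equal(attr(m2, "provenance")$merge_scale,
               attr(m, "provenance")$merge_scale / 2, tolerance = 1e-12)
  expect_equal(m2$I, m$I, tolerance = 1e-9)
  # identical curves: union, scale 1
  m3 <- merge_profiles(long, long)
  expect_equal(attr(m3, "provenance")$merge_scale, 1)
  expect_equal(m3$I, long$I)
  # disjoint ranges error
  expect_error(merge_profiles(
    profile1d(q1, q1 * 0 + 1, q1 * 0, label = "amorphous"),
    profile1d(q2 + 0.3, q2 * 0 + 1, q2 * 0, label = "amorphous")),
    "overlap")
  # label mismatch
  expect_error(merge_profiles(long, profile1d(q2, q2 * 0 + 1, q2 * 0,
                                              label = "aligned")),
               "labels")
})

test_that("frame and profile files round-trip bit-exactly", {
  gt <- gt_disk()
  cfg <- instrument_config(sdd = 1.7, detector_shape = c(16, 16),
                           beam_center = c(7.5, 7.2),
                           q_range = c(0.01, 0.27))
  fr <- generate_frame(gt, cfg, expected_counts = 1e4, seed = 5)
  path <- withr::local_tempfile(fileext = ".frame.txt")
  write_frame(fr, path)
  fr2 <- read_frame(path)
  expect_identical(fr2$counts, fr$counts)
  expect_equal(fr2$monitor, fr$monitor)
  expect_equal(fr2$config$beam_center, cfg$beam_center)
  expect_equal(fr2$sample_id, fr$sample_id)
  prof <- sector_reduce(fr, sector_def(10, 30), label = "aligned")
  p2 <- withr::local_tempfile(fileext = ".dat")
  write_profile(prof, p2)
  prof2 <- read_profile(p2)
  expect_equal(prof2$q, prof$q, tolerance = 1e-15)
  expect_equal(prof2$I, prof$I, tolerance = 1e-15)
  expect_equal(prof2$sigma, prof$sigma, tolerance = 1e-15)
  expect_identical(attr(prof2, "label"), "aligned")
  expect_identical(attr(prof2, "sample_id"), attr(prof, "sample_id"))
})
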