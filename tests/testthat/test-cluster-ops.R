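# Cluster finding, descriptors, calibration and recalibration.

test_that("connectivity follows the Chebyshev-distance definition", {
  fr <- tibble::tibble(layer = 1L, frame = 1L,
                       col = c(10L, 11L, 20L, 22L),
                       row = c(10L, 11L, 20L, 20L),
                       value = c(5L, 5L, 5L, 5L))
  cl8 <- find_clusters(fr, modes = c("1" = "energy"))
  expect_equal(nrow(cl8), 3L)  # diagonal pair joins, distance-2 pair does not
  cl4 <- find_clusters(fr, connectivity = 4, modes = c("1" = "energy"))
  expect_equal(nrow(cl4), 4L)  # rook connectivity splits the diagonal pair
})

test_that("a symmetric 3x3 cluster has its centroid at the central pixel", {
  g <- expand.grid(col = 99:101, row = 49:51)
  fr <- tibble::tibble(layer = 1L, frame = 1L, col = g$col, row = g$row,
                       value = c(1L, 2L, 1L, 2L, 9L, 2L, 1L, 2L, 1L))
  cl <- find_clusters(fr, modes = c("1" = "energy"))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$x, (100 + 0.5) * 0.055 - 7.04, tolerance = 1e-9)
  expect_equal(cl$y, (50 + 0.5) * 0.055 - 7.04, tolerance = 1e-9)
  expect_equal(cl$size, 9L)
  expect_equal(cl$volume, 21)
  expect_equal(cl$n_local_maxima, 1L)
})

test_that("partition equals the brute-force union-find oracle on random frames", {
  set.seed(101)
  for (k in 1:200) {
    n <- sample(5:200, 1)
    fr <- tibble::tibble(layer = 1L, frame = 1L,
                         col = sample(0:59, n, replace = TRUE),
                         row = sample(0:59, n, replace = TRUE),
                         value = sample(1:100, n, replace = TRUE))
    fr <- fr[!duplicated(fr[, c("col", "row")]), ]
    conn <- if (k %% 2) 8 else 4
    px <- label_pixels(fr, connectivity = conn)
    oracle <- oracle_components(fr$col, fr$row, conn)
    expect_identical(partition_signature(px$col, px$row, px$cluster_id),
                     partition_signature(fr$col, fr$row, oracle))
  }
})

test_that("partition and descriptors are invariant under pixel ordering", {
  run <- simulate_run(acquisition = acquisition_spec(frames = 4, seed = 6))
  fr <- run$frames
  set.seed(1); perm <- sample(nrow(fr))
  a <- find_clusters(fr)
  b <- find_clusters(fr[perm, ])
  key <- function(cl) {
    o <- order(cl$layer, cl$frame, round(cl$x, 9), round(cl$y, 9))
    cl[o, c("layer", "frame", "size", "volume", "x", "y", "n_local_maxima")]
  }
  expect_equal(as.data.frame(key(a)), as.data.frame(key(b)), tolerance = 1e-12)
})

test_that("cluster volumes conserve the frame content exactly", {
  run <- med_run()
  cl <- med_clusters()
  expect_equal(sum(cl$volume), sum(as.numeric(run$frames$value)))
  per_frame_cl <- tapply(cl$volume, paste(cl$layer, cl$frame), sum)
  per_frame_px <- tapply(as.numeric(run$frames$value),
                         paste(run$frames$layer, run$frames$frame), sum)
  expect_equal(per_frame_cl[names(per_frame_px)], per_frame_px)
})

test_that("centre-of-mass centroids beat nearest-pixel assignment", {
  lay <- layer_table()
  set.seed(33)
  n <- 250
  x0 <- (sample(80:170, n, TRUE) + runif(n)) * 0.055 - 7.04
  y0 <- (sample(80:170, n, TRUE) + runif(n)) * 0.055 - 7.04
  err <- vapply(seq_len(n), function(i) {
    p <- make_cluster(x0[i], y0[i], 5, lay, 3)
    p$layer <- 3L; p$frame <- 1L
    cl <- find_clusters(p, modes = c("3" = "energy"))
    sqrt((cl$x[1] - x0[i])^2 + (cl$y[1] - y0[i])^2)
  }, 1)
  # sub-pixel property per coordinate: RMS error below pitch/sqrt(12)
  expect_lt(sqrt(mean(err^2) / 2), 0.055 / sqrt(12))
})

test_that("pixel calibration inverts the electronics response", {
  # identity map: calibrated energy = counts (in keV)
  px <- tibble::tibble(layer = 3L, frame = 1L, col = 5L, row = 7L,
                       value = 1234L, cluster_id = 1L)
  ident <- tibble::tibble(col = 5L, row = 7L, a = 1, b = 0, c = 0, t = -1e9)
  out <- apply_pixel_calibration(px, ident)
  expect_equal(out$energy_mev, 1.234, tolerance = 1e-9)
  expect_false(out$calib_flag)
  # counts below the invertible branch are flagged, not inverted
  # hooked response whose only algebraic roots sit at or below the hook
  # threshold: flagged, not inverted
  hook <- tibble::tibble(col = 5L, row = 7L, a = 1, b = 0, c = -500, t = 100)
  low <- px; low$value <- 50L
  out2 <- apply_pixel_calibration(low, hook)
  expect_true(out2$calib_flag)
  expect_true(is.na(out2$energy_mev))
  # counts inverting beyond the 17 MeV calibrated window are flagged
  big <- px; big$value <- 11000L
  wide <- tibble::tibble(col = 5L, row = 7L, a = 0.5, b = 0, c = 0, t = -1e9)
  out3 <- apply_pixel_calibration(big, wide)
  expect_true(out3$calib_flag)
})

test_that("flat-field calibration homogenises the pixel response", {
  lay <- layer_table()
  map <- make_calibration_map(lay, 3)
  gain <- layer_gain_map(lay, 3)
  set.seed(7)
  idx <- cbind(sample(256, 4000, TRUE), sample(256, 4000, TRUE))
  e_kev <- 500
  counts <- round(gain[idx] * e_kev + 2 - 30 / (e_kev - 3))
  raw_cv <- sd(counts) / mean(counts)
  px <- tibble::tibble(layer = 3L, frame = 1L, col = idx[, 1] - 1L,
                       row = idx[, 2] - 1L, value = as.integer(counts),
                       cluster_id = seq_len(nrow(idx)))
  cal <- apply_pixel_calibration(px, map)
  cal_cv <- sd(cal$energy_mev) / mean(cal$energy_mev)
  expect_gt(raw_cv, 0.04)   # the gain field itself
  expect_lt(cal_cv, 0.02)   # homogenised after per-pixel calibration
})

test_that("partial-depletion recalibration recovers depositions within 7%", {
  # identity curve behaves as identity
  ident <- fit_recalibration_curve(seq(0.2, 17, length.out = 400),
                                   seq(0.2, 17, length.out = 400))
  expect_equal(recalibrate_partial_depletion(c(1, 5, 12), ident),
               c(1, 5, 12), tolerance = 1e-3)
  # simulator 10 V response: recovery bias < 7% over the 0.2-17 MeV scan
  lay <- layer_table(bias_voltage = 10)
  map <- make_calibration_map(lay, 3)
  curve <- default_recalibration_curve(lay)
  set.seed(55)
  true_e <- exp(seq(log(0.25), log(16.5), length.out = 25))
  for (e in true_e) {
    meas <- vapply(1:8, function(i) {
      p <- make_cluster(runif(1, -5, 5), runif(1, -5, 5), e, lay, 3)
      p$layer <- 3L; p$frame <- 1L
      sum(apply_pixel_calibration(p, map)$energy_mev, na.rm = TRUE)
    }, 1)
    rec <- suppressWarnings(
      mean(as.numeric(recalibrate_partial_depletion(meas, curve))))
    expect_lt(abs(rec / e - 1), 0.07)
  }
  # out-of-range input is clamped with a warning
  expect_warning(recalibrate_partial_depletion(30, curve), "clamped")
})

test_that("non-monotone recalibration input is rejected", {
  expect_error(fit_recalibration_curve(1:100 / 10, rev(1:100) / 10),
               "monotone")
})

test_that("calibration maps round-trip through CSV", {
  lay <- layer_table()
  map <- make_calibration_map(lay, 3)[1:500, ]
  p <- withr::local_tempfile(fileext = ".csv")
  write_calibration_map(map, p)
  back <- read_calibration_map(p)
  expect_equal(as.data.frame(back), as.data.frame(map), tolerance = 1e-12)
})
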