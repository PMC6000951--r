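# The synthetic-data generator: transport physics, cluster rendering,
# artifact injection, determinism, occupancy.

test_that("zero beam intensity gives empty frames and truth", {
  run <- simulate_run(beam = beam_spec(mean_ions_per_frame = 0),
                      acquisition = acquisition_spec(frames = 5, seed = 3),
                      artifacts = artifact_config(background_per_frame = 0))
  expect_equal(nrow(run$frames), 0L)
  expect_equal(nrow(run$truth), 0L)
})

test_that("identical seeds give identical runs and frame files", {
  a <- simulate_run(acquisition = acquisition_spec(frames = 5, seed = 17))
  b <- simulate_run(acquisition = acquisition_spec(frames = 5, seed = 17))
  expect_identical(as.data.frame(a$frames), as.data.frame(b$frames))
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_frames(a, d1); write_frames(b, d2)
  for (l in 1:5) {
    expect_identical(readLines(file.path(d1, sprintf("layer%d.txt", l))),
                     readLines(file.path(d2, sprintf("layer%d.txt", l))))
  }
})

test_that("hydrogen contamination matches the configured fragmentation rate", {
  tr <- med_run()$truth
  frac_h <- mean(tr$species_out == "hydrogen")
  p <- med_run()$phantom$fragmentation_prob
  se <- sqrt(p * (1 - p) / nrow(tr))
  expect_lt(abs(frac_h - p), 4 * se)
})

test_that("transport is straight and deterministic without stochastic physics", {
  tr <- transport_ion(-2.5, 1.5, 0, 0, 168.3, "helium",
                      phantom_spec(fragmentation_prob = 0), layer_table(),
                      scattering = FALSE, straggling = FALSE)
  expect_equal(tr$exit_x, tr$entry_x)
  expect_equal(tr$exit_x, -2.5)
  expect_equal(tr$y5, 1.5)
  expect_false(tr$stopped)
  # deposition equals the CSDA prediction at the layer-3 residual energy
  expect_equal(tr$dep3, deposition_in_silicon("helium", tr$e_layer3),
               tolerance = 1e-6)
})

test_that("energy bookkeeping: layer-3 energy matches CSDA over the stack", {
  tr <- med_run()$truth
  det <- transport_ion(-2, 0, 0, 0, 168.3, "helium",
                       phantom_spec(fragmentation_prob = 0), layer_table(),
                       scattering = FALSE, straggling = FALSE)
  sel <- tr$species_out == "helium" & tr$alive3 & !is.na(tr$entry_x) &
    tr$entry_x < -1 & tr$x3 < -1   # bulk side, away from the step
  # z-test of the mean against the deterministic prediction
  z <- (mean(tr$e_layer3[sel]) - det$e_layer3) /
    (sd(tr$e_layer3[sel]) / sqrt(sum(sel)))
  expect_lt(abs(z), 4)
  # mean deposition agrees with the Bragg-flank operating point
  expect_equal(mean(tr$dep3[sel]), det$dep3, tolerance = 0.05)
})

test_that("exit-position variance is consistent with Highland composition", {
  n <- 4000
  start <- tibble::tibble(x = 0, y = 0, tx = 0, ty = 0, energy = 168.3,
                          species = "helium")[rep(1, n), ]
  set.seed(8)
  tr <- transport_ions(start, phantom_spec(fragmentation_prob = 0,
                                           step_thickness = 0),
                       layer_table(), straggling = FALSE)
  # analytic oracle: d Var = theta'^2 (L - z)^2 dz with the whole-path log
  # factor, energy updated along depth
  L <- 16.1; nsub <- 200; dz <- L / nsub
  e <- 168.3; var_x <- 0
  full_x <- L * 1.19 / 40.55
  for (i in seq_len(nsub)) {
    e_out <- energy_after("helium", e, "pmma", dz)
    e_mid <- (e + max(e_out, 0.5)) / 2
    th <- highland_sigma("helium", e_mid, "pmma", dz) *
      (1 + 0.038 * log(full_x)) / (1 + 0.038 * log(dz * 1.19 / 40.55))
    z_rem <- L - (i - 0.5) * dz
    var_x <- var_x + th^2 * z_rem^2
    e <- e_out
  }
  expect_equal(var(tr$exit_x) / (var_x * 100), 1, tolerance = 0.10)
})

test_that("cluster rendering: size grows with deposition, quenching at 40 V", {
  lay10 <- layer_table(bias_voltage = 10)
  he <- make_cluster(0.01, 0.02, 5, lay10, 3)
  h <- make_cluster(0.01, 0.02, 1.3, lay10, 3)
  expect_gt(nrow(he), nrow(h))
  expect_gt(nrow(he), 9); expect_lt(nrow(he), 31)
  # single pixel for a tiny deposition exactly at a pixel centre
  # (pixel 128 centre sits at (128 + 0.5) * 0.055 - 7.04 = 0.0275 mm)
  tiny <- make_cluster(0.0275, 0.0275, 0.06, lay10, 3)
  expect_equal(nrow(tiny), 1L)
  expect_equal(tiny$col, 128L)
  expect_equal(tiny$row, 128L)
  # 40 V response: >= 20% deficit at 5 MeV relative to linear
  lay40 <- layer_table(bias_voltage = 40)
  map40 <- make_calibration_map(lay40, 3)
  p <- make_cluster(0.3, -0.2, 5, lay40, 3)
  p$layer <- 3L; p$frame <- 1L
  vol40 <- sum(apply_pixel_calibration(p, map40)$energy_mev, na.rm = TRUE)
  expect_lte(vol40, 0.8 * 5)
  # and approximately linear response below 2 MeV
  p2 <- make_cluster(0.3, -0.2, 1.5, lay40, 3)
  p2$layer <- 3L; p2$frame <- 1L
  vol2 <- sum(apply_pixel_calibration(p2, map40)$energy_mev, na.rm = TRUE)
  expect_equal(vol2, 1.5, tolerance = 0.08)
})

test_that("artifact rates: none when disabled, cropping matches expectation", {
  clean_cfg <- artifact_config(background_per_frame = 0, overshoot_prob = 0,
                               crop_guard_us = 0, overlap_prob = 0)
  a <- simulate_run(acquisition = acquisition_spec(frames = 10, seed = 4),
                    artifacts = clean_cfg)
  expect_false(any(a$truth$cropped))
  expect_false(any(a$truth$overlap_injected))
  expect_false(any(a$truth$overshoot_injected))
  # cropped fraction ~ 2 * guard / frame duration (uniform arrivals)
  tr <- med_run()$truth
  g <- med_run()$artifacts$crop_guard_us
  expected <- 2 * g / 1000
  se <- sqrt(expected * (1 - expected) / nrow(tr))
  expect_lt(abs(mean(tr$cropped) - expected), 4 * se)
})

test_that("injected overlaps produce multi-maximum clusters", {
  run <- simulate_run(acquisition = acquisition_spec(frames = 60, seed = 9),
                      artifacts = artifact_config(background_per_frame = 0,
                                                  overshoot_prob = 0,
                                                  overlap_prob = 0.25))
  cl <- find_clusters(run$frames)
  tr <- run$truth
  en <- cl[cl$mode == "energy", ]
  # locate the injected ions' clusters by truth position (ions inside the
  # sensitive area; companions of out-of-aperture ions render nothing)
  inj <- tr[tr$overlap_injected & tr$alive3 &
              abs(tr$x3) < 6.5 & abs(tr$y3) < 6.5, ]
  hit <- vapply(seq_len(nrow(inj)), function(i) {
    j <- which(en$frame == inj$frame[i])
    d2 <- (en$x[j] - inj$x3[i])^2 + (en$y[j] - inj$y3[i])^2
    j <- j[which.min(d2)]
    min(d2) < 0.3^2 && en$n_local_maxima[j] >= 2
  }, TRUE)
  expect_gt(length(hit), 30)
  expect_gte(mean(hit), 0.95)
})

test_that("occupancy stays below 1% on every layer at default settings", {
  run <- med_run()
  occ <- tapply(rep(1, nrow(run$frames)), run$frames$layer, sum) /
    (run$acquisition$frames * 256^2)
  expect_true(all(occ < 0.01))
})

test_that("helium and hydrogen cluster-volume distributions are separable", {
  cl <- med_clusters()
  tr <- med_run()$truth
  en <- cl[cl$mode == "energy" & !is.na(cl$volume_mev), ]
  # truth-label clusters by nearest uncropped ion impact
  lab <- rep(NA_character_, nrow(en))
  ok_ion <- tr$alive3 & !tr$cropped & !tr$overlap_injected &
    abs(tr$x3) < 6.5 & abs(tr$y3) < 6.5   # fully contained clusters
  for (f in unique(en$frame)) {
    ions <- tr[ok_ion & tr$frame == f, ]
    sel <- which(en$frame == f)
    if (!nrow(ions) || !length(sel)) next
    d <- outer(en$x[sel], ions$x3, "-")^2 + outer(en$y[sel], ions$y3, "-")^2
    j <- apply(d, 1, which.min)
    near <- d[cbind(seq_along(sel), j)] < 0.15^2
    lab[sel[near]] <- ions$species_out[j[near]]
  }
  he <- en$volume_mev[!is.na(lab) & lab == "helium"]
  hy <- en$volume_mev[!is.na(lab) & lab == "hydrogen"]
  expect_gt(length(hy), 50)
  expect_lt(bhattacharyya_overlap(he, hy), 0.05)
})

test_that("alignment run: zero offsets give coincident fluence maxima", {
  run <- simulate_alignment_run(n_ions = 3000, seed = 12)
  cl <- find_clusters(run$frames)
  sol <- estimate_alignment(cl)
  expect_true(all(abs(sol$dx_um) < 27.5))
  expect_true(all(abs(sol$dy_um) < 27.5))
})
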