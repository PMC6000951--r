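# Cleaning cuts, alignment, segment building, matching, association and
# species identification.

test_that("cleaning flags follow the cut definitions and commute", {
  cl <- dplyr::bind_rows(
    constructed_cluster_row(3, 1, 100, 0, 0),                    # clean
    constructed_cluster_row(3, 1, 200, 1, 1),                    # overlap
    constructed_cluster_row(3, 1, 300, 2, 2, volume_mev = 0.1,
                            size = 2),                            # background
    constructed_cluster_row(3, 1, 400, 3, 3),                    # overshoot px
    constructed_cluster_row(1, 1, 500, 4, 4, size = 6),          # clean time
    constructed_cluster_row(1, 1, 600, 5, 5, size = 6))          # tick spread
  cl$n_local_maxima[2] <- 3L
  cl$max_px_mev[4] <- 1.6
  cl$tick_spread[6] <- 7L
  out <- clean_clusters(cl)
  expect_equal(out$flag_overlap, c(F, T, F, F, F, F))
  expect_equal(out$flag_background, c(F, F, T, F, F, F))
  expect_equal(out$flag_overshoot, c(F, F, F, T, F, T))
  expect_equal(out$rejected, c(F, T, T, T, F, T))
  # flags are computed independently: any application order gives the same
  # accepted set
  o1 <- out$rejected
  perm <- c(4, 2, 6, 1, 3, 5)
  o2 <- clean_clusters(cl[perm, ])$rejected[order(perm)]
  expect_identical(o1, o2)
  # a table of only clean clusters has an empty rejected set
  expect_false(any(clean_clusters(cl[c(1, 5), ])$rejected))
})

test_that("simulator-injected overlaps are all flagged overlap", {
  run <- simulate_run(acquisition = acquisition_spec(frames = 40, seed = 14),
                      artifacts = artifact_config(background_per_frame = 0,
                                                  overshoot_prob = 0,
                                                  overlap_prob = 0.3))
  cl <- clean_clusters(find_clusters(run$frames))
  multi <- cl$n_local_maxima >= 2
  expect_true(all(cl$flag_overlap[multi]))
  expect_false(any(cl$flag_overlap[!multi]))
})

test_that("injected layer offsets are recovered within half a pixel", {
  offs <- matrix(c(150, -60, 0, 80, 120,
                   -90, 40, 0, -150, -80), 5, 2)   # up to ~4 pixels
  lay <- layer_table(offsets = offs)
  run <- simulate_alignment_run(layers = lay, n_ions = 10000, seed = 23)
  cl <- find_clusters(run$frames)
  sol <- estimate_alignment(cl)
  want_x <- offs[, 1] - offs[3, 1]
  want_y <- offs[, 2] - offs[3, 2]
  expect_true(all(abs(sol$dx_um - want_x) <= 27.5))
  expect_true(all(abs(sol$dy_um - want_y) <= 27.5))
  # applying the solution leaves sub-pixel residuals
  cl2 <- ionrad:::.apply_alignment(cl, sol)
  resid <- estimate_alignment(cl2)
  expect_true(all(abs(c(resid$dx_um, resid$dy_um)) < 27.5))
})

test_that("alignment estimate is stable when statistics double", {
  run <- simulate_alignment_run(n_ions = 20000, seed = 24)
  cl <- find_clusters(run$frames)
  half <- cl[cl$frame <= max(cl$frame) / 2, ]
  s_half <- estimate_alignment(half)
  s_full <- estimate_alignment(cl)
  d <- c(s_half$dx_um - s_full$dx_um, s_half$dy_um - s_full$dy_um)
  expect_lt(mean(abs(d)), 10)
})

test_that("alignment warns on sparse statistics", {
  run <- simulate_alignment_run(n_ions = 600, seed = 2)
  cl <- find_clusters(run$frames)
  expect_warning(estimate_alignment(cl), "precision")
})

test_that("segments: single clean ion, empty layers, two-ion separation", {
  lay <- layer_table()
  # two well-separated ions sharing one frame and tick
  cl <- dplyr::bind_rows(
    constructed_cluster_row(1, 1, 700, -2.000, 0.5, size = 6),
    constructed_cluster_row(2, 1, 700, -1.990, 0.5, size = 6),
    constructed_cluster_row(1, 1, 700, 3.000, -1.0, size = 6),
    constructed_cluster_row(2, 1, 700, 3.020, -1.0, size = 6))
  cl$cluster_id <- 1:4
  seg <- build_segments(cl, lay, tracker = "front", ref_z = -80.5)
  expect_equal(nrow(seg), 2L)
  seg <- seg[order(seg$x0), ]
  expect_equal(seg$cluster_a, c(1L, 3L))
  expect_equal(seg$cluster_b, c(2L, 4L))   # nearest-position, no swap
  expect_equal(seg$tx, c(0.001, 0.002), tolerance = 1e-9)
  expect_equal(nrow(build_segments(cl[1:2, ][0, ], lay)), 0L)
  # single-ion run: direction matches truth within the tracker resolution
  run <- simulate_run(beam = beam_spec(mean_ions_per_frame = 1, fwhm = 3),
                      acquisition = acquisition_spec(frames = 60, seed = 19),
                      artifacts = artifact_config(background_per_frame = 0,
                                                  overshoot_prob = 0,
                                                  overlap_prob = 0))
  cl2 <- clean_clusters(find_clusters(run$frames))
  seg2 <- build_segments(cl2, lay, tracker = "front", ref_z = -80.5)
  tr <- run$truth
  i <- match(seg2$tick, tr$tick)
  ok <- !is.na(i)
  expect_gt(sum(ok), 20)
  expect_lt(stats::median(abs(seg2$tx[ok] - tr$entry_tx[i][ok])), 0.003)
})

test_that("front/rear matching is species-blind", {
  ev <- med_events()
  tr <- med_run()$truth
  i <- truth_match(ev, tr)
  sp <- tr$species_out[i[!is.na(i)]]
  expect_gt(sum(sp == "hydrogen"), 20)   # fragments are matched too
})

test_that("energy association honours the 220 um boundary exactly", {
  lay <- layer_table()
  pairs <- tibble::tibble(
    frame = c(1L, 2L, 3L),
    f_tick = c(5000L, 5000L, 5000L), r_tick = c(5000L, 5000L, 5000L),
    f_x_ref = 0, f_y_ref = 0, r_x_ref = 0, r_y_ref = 0,
    f_tx = 0, f_ty = 0, r_tx = 0, r_ty = 0,
    f_x0 = 0, f_y0 = 0, f_z0 = -100, r_x0 = c(1, 1, 1), r_y0 = 0, r_z0 = 105)
  # rear track extrapolates to x = 1 at the energy layer (straight, tx = 0)
  en <- dplyr::bind_rows(
    constructed_cluster_row(3, 1, NA, 1.000, 0),          # exactly on point
    constructed_cluster_row(3, 2, NA, 1 + 0.221, 0),      # just outside
    constructed_cluster_row(3, 3, NA, 1 + 0.219, 0))      # just inside
  en$cluster_id <- 1:3
  ev <- associate_energy_cluster(pairs, en, lay)
  expect_equal(ev$status, c("ok", "no_energy", "ok"))
  expect_equal(ev$cluster_id, c(1L, NA, 3L))
  expect_equal(ev$assoc_dist_um[3], 219, tolerance = 1e-6)
})

test_that("association purity exceeds 99% at default occupancy", {
  ev <- med_events()
  tr <- med_run()$truth
  i <- truth_match(ev, tr)
  ok <- ev$status == "ok" & !is.na(i)
  d <- sqrt((ev$x3[ok] - tr$x3[i][ok])^2 + (ev$y3[ok] - tr$y3[i][ok])^2)
  expect_gt(mean(d < 0.15, na.rm = TRUE), 0.99)
})

test_that("species classification reaches 95% on a labelled holdout", {
  ev <- med_events()
  tr <- med_run()$truth
  i <- truth_match(ev, tr)
  ok <- which(ev$status == "ok" & !is.na(i) & !is.na(ev$volume_recal_mev))
  lab <- tr$species_out[i[ok]]
  train <- ok[seq_along(ok) %% 2 == 0]; test <- ok[seq_along(ok) %% 2 == 1]
  b <- fit_species_boundary(ev$volume_recal_mev[train], ev$size[train],
                            tr$species_out[i[train]])
  pred <- classify_species(ev$volume_recal_mev[test], ev$size[test], b)
  expect_gt(mean(pred == tr$species_out[i[test]]), 0.95)
  # the shipped default boundary performs equivalently
  pred0 <- classify_species(ev$volume_recal_mev[test], ev$size[test])
  expect_gt(mean(pred0 == tr$species_out[i[test]]), 0.95)
  # canonical examples
  expect_equal(classify_species(5.1, 20), "helium")
  expect_equal(classify_species(1.0, 6), "hydrogen")
  expect_equal(classify_species(NA_real_, 6), "unknown")
})

test_that("accepted events are pure: one cluster per layer, no flags", {
  run <- med_run()
  cl <- clean_clusters(med_clusters(), cut_config(), run$acquisition)
  ev <- med_events()
  acc <- ev[ev$accepted, ]
  expect_gt(nrow(acc), 1000)
  expect_true(all(acc$species == "helium"))
  expect_true(all(!is.na(acc$cluster_id)))
  expect_false(any(duplicated(acc$cluster_id)))  # one energy cluster per event
  flags <- cl[match(acc$cluster_id, cl$cluster_id), ]
  expect_false(any(flags$rejected))
  guard <- cut_config()$crop_guard_us * 1000 / run$acquisition$tick_ns
  expect_true(all(acc$f_tick > guard &
                    acc$f_tick <= 1e4 - guard))
})

test_that("hydrogen rejection increases the radiograph CNR", {
  run <- med_run()
  rois <- default_rois(run$phantom$step_edge_x)
  ev_all <- build_events(run, identify = FALSE, clusters = med_clusters())
  ev_he <- ev_all[ev_all$status == "ok" & ev_all$species == "helium", ]
  ev_any <- ev_all[ev_all$status == "ok", ]
  img_he <- accumulate_image(
    event_midplane_position(ev_he, run$phantom))
  img_any <- accumulate_image(
    event_midplane_position(ev_any, run$phantom))
  expect_gt(cnr(img_he, rois$step, rois$reference),
            cnr(img_any, rois$step, rois$reference))
})
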