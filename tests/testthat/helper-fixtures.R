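# Shared simulated fixtures, built once per test session and reused across
# files.  Problem sizes are chosen so the whole suite exercises the full
# chain at realistic occupancy while staying desk-scale (see the methods
# vignette for the rationale behind each size).

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

# medium helium imaging run (~12k primaries) for module-level statistics
med_run <- function() fixture("med_run", {
  simulate_run(acquisition = acquisition_spec(frames = 400, seed = 11))
})

med_clusters <- function() fixture("med_clusters", {
  run <- med_run()
  map <- make_calibration_map(run$layers, 3)
  find_clusters(run$frames, calibration = map)
})

med_events <- function() fixture("med_events", {
  build_events(med_run(), clusters = med_clusters())
})

# truth row index for each matched event (frame + arrival tick is unique at
# the simulated occupancy up to rare tick collisions)
truth_match <- function(events, truth) {
  match(paste(events$frame, events$f_tick), paste(truth$frame, truth$tick))
}

# full-dose helium imaging run: the fluence delivering ~450 uGy mean phantom
# dose with the default beam (about 120k primaries)
big_run <- function() fixture("big_run", {
  d <- compute_dose(dose = 450e-6)
  simulate_run(acquisition = acquisition_spec(
    frames = ceiling(d$n_ions / beam_spec()$mean_ions_per_frame), seed = 5))
})

big_stages <- function() fixture("big_stages", {
  stage_comparison(big_run())
})

# matched-dose helium/proton pair (150 uGy each) for the species comparison
hep_pair <- function() fixture("hep_pair", {
  dose <- 150e-6
  d_he <- compute_dose(dose = dose)
  p_beam <- beam_spec(species = "proton", energy_per_nucleon = 168.3)
  d_p <- compute_dose(p_beam, phantom_spec(), dose = dose)
  list(
    he = simulate_run(acquisition = acquisition_spec(
      frames = ceiling(d_he$n_ions / 30), seed = 31)),
    p = simulate_run(beam = p_beam,
                     phantom = phantom_spec(fragmentation_prob = 0),
                     acquisition = acquisition_spec(
                       frames = ceiling(d_p$n_ions / 30), seed = 61)))
})

accepted_midplane <- function(run, identify = TRUE) {
  ev <- build_events(run, identify = identify)
  ev <- event_midplane_position(ev[ev$accepted, ], run$phantom)
  ev[ev$midplane_ok, ]
}

edge_sigma <- function(run, identify = TRUE) {
  ev <- accepted_midplane(run, identify)
  m <- suppressWarnings(mtf_from_esf(
    esf_from_events(ev, run$phantom$step_edge_x, y_half = 3)))
  m$sigma_fit_mm
}

# clean single-ion frames built directly from the renderer, for constructed
# tracking fixtures: one ion per frame at given positions/ticks
constructed_cluster_row <- function(layer, frame, tick, x, y,
                                    volume_mev = 5, size = 15) {
  tibble::tibble(cluster_id = NA_integer_, layer = layer, frame = frame,
                 mode = ifelse(layer == 3, "energy", "time"),
                 size = size, volume = 1000, x = x, y = y,
                 tick = tick, tick_spread = 0L, n_local_maxima = 1L,
                 max_px = 500L, volume_mev = volume_mev,
                 max_px_mev = 0.5, calib_flagged = FALSE)
}
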