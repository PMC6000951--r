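# Run-configuration constructors.  Each returns a validated, classed list (or
# tibble for the layer table); write_run_config()/read_run_config() round-trip
# the whole set through a plain-text file.

#' Beam specification
#'
#' Pencil-beam description. Defaults are the helium imaging beam: 168.3 MeV/u,
#' 10.6 mm FWHM, about 30 ions per 1 ms frame.
#'
#' @param species Ion species (name or [ion_species()]).
#' @param energy_per_nucleon MeV/u.
#' @param fwhm Lateral Gaussian FWHM in mm.
#' @param mean_ions_per_frame Mean Poisson ion count per acquisition frame.
#' @param center Beam axis position `c(x, y)` in mm at the detector plane.
#' @return A `beam_spec` object.
#' @export
beam_spec <- function(species = "helium", energy_per_nucleon = 168.3,
                      fwhm = 10.6, mean_ions_per_frame = 30,
                      center = c(0, 0)) {
  stopifnot(fwhm > 0, mean_ions_per_frame >= 0, length(center) == 2)
  structure(list(species = ion_species(species),
                 energy_per_nucleon = energy_per_nucleon,
                 fwhm = fwhm,
                 mean_ions_per_frame = mean_ions_per_frame,
                 center = as.numeric(center)),
            class = "beam_spec")
}

#' Phantom specification
#'
#' Homogeneous block with a thin transverse step inserted at a given depth.
#' The step occupies the half plane `x > step_edge_x`. Defaults: 161 mm PMMA
#' with a 1 mm air slab exactly at mid-depth, edge at x = 0.
#'
#' @param material Bulk material.
#' @param length Phantom length along the beam in mm.
#' @param step_thickness Step slab thickness in mm (0 disables the step).
#' @param step_material Material inside the step region.
#' @param step_edge_x Transverse edge position in mm; the step replaces the
#'   bulk material for `x > step_edge_x`.
#' @param step_depth_center Depth of the step centre from the upstream face, mm.
#' @param fragmentation_prob Probability that a primary fragments into a
#'   hydrogen ion somewhere inside the phantom (single-point, depth-uniform).
#' @param upstream_z z of the upstream face in mm (beam travels along +z).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(material = "pmma", length = 161,
                         step_thickness = 1, step_material = "air",
                         step_edge_x = 0, step_depth_center = length / 2,
                         fragmentation_prob = 0.13,
                         upstream_z = -length / 2) {
  stopifnot(length > 0, step_thickness >= 0,
            step_depth_center >= 0, step_depth_center <= length,
            fragmentation_prob >= 0, fragmentation_prob <= 1)
  structure(list(material = material(material), length = length,
                 step_thickness = step_thickness,
                 step_material = material(step_material),
                 step_edge_x = step_edge_x,
                 step_depth_center = step_depth_center,
                 fragmentation_prob = fragmentation_prob,
                 upstream_z = upstream_z),
            class = "phantom_spec")
}

#' Detector layer table
#'
#' One row per layer. Layers 1-2 form the front tracker (time mode), layer 3
#' the energy detector at the isocenter, layers 4-5 the rear tracker (time
#' mode). 300 um silicon sensors, 55 um pixels, 256 x 256 pixels, readout chip
#' water-equivalent budget behind each sensor.
#'
#' @param z Layer z positions in mm (must be strictly increasing, phantom
#'   between layers 2 and 3).
#' @param bias_voltage Sensor bias in V (10 = partially depleted linear-deficit
#'   response, 40 = fully depleted with high-energy quenching); applies to the
#'   energy layer.
#' @param threshold Per-pixel detection threshold in keV.
#' @param readout_wet Water-equivalent thickness of the thinned readout chip
#'   and services behind each sensor, mm.
#' @param gain_sd Relative sd of the per-pixel gain field.
#' @param gain_seed Integer seed from which per-layer pixel gain maps are
#'   generated (deterministic).
#' @param offsets 5 x 2 matrix of true lateral layer offsets (dx, dy) in um,
#'   recovered by [estimate_alignment()].
#' @return A tibble of class `ionrad_layers`.
#' @export
layer_table <- function(z = c(-100, -90, 95, 105, 115),
                        bias_voltage = 10, threshold = 8, readout_wet = 0.4,
                        gain_sd = 0.05, gain_seed = 20210401,
                        offsets = matrix(0, 5, 2)) {
  stopifnot(length(z) == 5, all(diff(z) > 0), nrow(offsets) == 5)
  tibble::new_tibble(tibble::tibble(
    layer = 1:5,
    z = as.numeric(z),
    mode = c("time", "time", "energy", "time", "time"),
    sensor_um = 300,
    pitch_um = 55,
    n_pixels = 256L,
    readout_wet_mm = readout_wet,
    bias_v = bias_voltage,
    threshold_kev = threshold,
    gain_sd = gain_sd,
    gain_seed = as.integer(gain_seed) + 0:4,
    offset_x_um = as.numeric(offsets[, 1]),
    offset_y_um = as.numeric(offsets[, 2])
  ), class = "ionrad_layers")
}

#' Acquisition specification
#'
#' Frame timing and digitisation. 1 ms frames, 100 ns arrival-time ticks,
#' 14-bit counters saturating at 11810 counts, 260 +/- 40 us digitisation time.
#'
#' @param frames Number of frames to acquire.
#' @param seed Integer RNG seed for the whole simulated run.
#' @param frame_ms Frame (shutter) duration in ms.
#' @param tick_ns Arrival-time quantisation in ns.
#' @param digitization_us_mean,digitization_us_sd Cluster digitisation time, us.
#' @param counter_max Counter saturation value.
#' @return An `acquisition_spec` object.
#' @export
acquisition_spec <- function(frames = 100, seed = 1, frame_ms = 1,
                             tick_ns = 100, digitization_us_mean = 260,
                             digitization_us_sd = 40, counter_max = 11810) {
  stopifnot(frames >= 0, frame_ms > 0, tick_ns > 0, counter_max > 1)
  structure(list(frames = as.integer(frames), seed = as.integer(seed),
                 frame_ms = frame_ms, tick_ns = tick_ns,
                 digitization_us_mean = digitization_us_mean,
                 digitization_us_sd = digitization_us_sd,
                 counter_max = as.integer(counter_max)),
            class = "acquisition_spec")
}

#' Artifact configuration
#'
#' Rates of the signal-degradation classes injected into simulated frames:
#' light radiation background, overshoot signals on high pixel depositions,
#' temporally cropped clusters at the frame edges, and overlapping clusters.
#' Setting every rate to zero leaves the frames clean.
#'
#' @param background_per_frame Mean count of small background clusters
#'   (photons/electrons, 1-2 pixels) per frame per layer.
#' @param overshoot_prob Probability that a cluster containing a pixel above
#'   `overshoot_pixel_mev` develops an overshoot artifact.
#' @param overshoot_pixel_mev Pixel deposition (MeV) above which overshoot can
#'   occur.
#' @param crop_guard_us Ions arriving within this window of the frame start or
#'   end are only partially digitised in the energy detector.
#' @param overlap_prob Probability per ion of being merged with a companion
#'   cluster on the energy layer (two local maxima in one connected region).
#' @return An `artifact_config` object.
#' @export
artifact_config <- function(background_per_frame = 30, overshoot_prob = 0.25,
                            overshoot_pixel_mev = 1.0, crop_guard_us = 65,
                            overlap_prob = 0.02) {
  stopifnot(background_per_frame >= 0, overshoot_prob >= 0, overshoot_prob <= 1,
            crop_guard_us >= 0, overlap_prob >= 0, overlap_prob <= 1)
  structure(list(background_per_frame = background_per_frame,
                 overshoot_prob = overshoot_prob,
                 overshoot_pixel_mev = overshoot_pixel_mev,
                 crop_guard_us = crop_guard_us,
                 overlap_prob = overlap_prob),
            class = "artifact_config")
}

#' Cleaning and matching cut configuration
#'
#' Defaults follow the processing chain: clean clusters are time coherent
#' (tick spread <= 1), the energy-association radius is four 55 um pitches
#' (220 um), the time-matching window one 100 ns tick, and the temporal-crop
#' guard matches the simulator's digitisation model.
#'
#' @param max_tick_spread Maximum arrival-tick spread within one time-mode
#'   cluster.
#' @param crop_guard_us Arrival window at either frame edge flagged as
#'   temporally cropped.
#' @param energy_association_radius_um Maximum distance between the
#'   extrapolated rear track and the energy cluster centroid.
#' @param time_match_window Maximum tick difference for cluster/segment
#'   matching.
#' @param background_volume_max_mev Clusters below this calibrated volume with
#'   size <= 2 pixels are flagged as light background.
#' @param overshoot_pixel_energy_mev Any calibrated pixel above this value
#'   flags the cluster as overshoot.
#' @return A `cut_config` object.
#' @export
cut_config <- function(max_tick_spread = 1, crop_guard_us = 65,
                       energy_association_radius_um = 220,
                       time_match_window = 1,
                       background_volume_max_mev = 0.3,
                       overshoot_pixel_energy_mev = 1.0) {
  stopifnot(max_tick_spread > 0, crop_guard_us > 0,
            energy_association_radius_um > 0, time_match_window > 0,
            background_volume_max_mev > 0, overshoot_pixel_energy_mev > 0)
  structure(list(max_tick_spread = max_tick_spread,
                 crop_guard_us = crop_guard_us,
                 energy_association_radius_um = energy_association_radius_um,
                 time_match_window = time_match_window,
                 background_volume_max_mev = background_volume_max_mev,
                 overshoot_pixel_energy_mev = overshoot_pixel_energy_mev),
            class = "cut_config")
}

#' Imaging plane specification
#'
#' The mid-phantom projection plane and image binning (220 um pixels).
#'
#' @param z_position Plane z in mm (default: phantom mid-depth for the default
#'   geometry, z = 0).
#' @param pixel_pitch Image bin pitch in um.
#' @param extent Half-extent of the image in mm (square, centred on the axis).
#' @return An `imaging_plane_spec` object.
#' @export
imaging_plane_spec <- function(z_position = 0, pixel_pitch = 220, extent = 7) {
  stopifnot(pixel_pitch > 0, extent > 0)
  structure(list(z_position = z_position, pixel_pitch = pixel_pitch,
                 extent = extent),
            class = "imaging_plane_spec")
}

#' Per-pixel gain field of a layer
#'
#' Deterministically regenerates the multiplicative gain map of one layer from
#' its `gain_seed` (log-normal, relative sd `gain_sd`).
#'
#' @param layers A [layer_table()].
#' @param layer Layer index 1-5.
#' @return A 256 x 256 matrix (column = detector column + 1).
#' @export
layer_gain_map <- function(layers, layer) {
  row <- layers[layers$layer == layer, ]
  n <- row$n_pixels
  rng <- .saved_rng(row$gain_seed)
  m <- matrix(exp(stats::rnorm(n * n, 0, row$gain_sd)), n, n)
  .restore_rng(rng)
  m
}

# evaluate RNG-dependent code under a local seed without touching the
# caller's RNG stream
.saved_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible()
}
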