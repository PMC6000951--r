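# Synthetic-data generator: CSDA + Highland transport of single ions through
# the five-layer geometry, Gaussian charge-cloud cluster rendering with the
# bias-voltage response models, and injection of the artifact classes the
# processing chain removes (background, overshoot, temporal cropping,
# overlapping clusters).

HALF_AREA_MM <- 7.04      # sensitive half-width: 256 * 55 um / 2
PITCH_MM <- 0.055

# charge-cloud width model: sigma = sigma0(bias) + k * sqrt(deposited energy);
# higher bias collects faster -> smaller clusters
.cloud_sigma_mm <- function(dep_mev, bias_v) {
  sigma0 <- ifelse(bias_v >= 40, 0.020, 0.028)
  sigma0 + 0.0096 * sqrt(pmax(dep_mev, 0))
}

# energy-detector response to the cluster deposition.
# 40 V (full depletion): linear up to 2 MeV, then a saturating rational branch
# (quenching; >= 20% deficit at 5 MeV). 10 V (partial depletion): linear with
# slope 0.6, invertible by recalibrate_partial_depletion().
.bias_response <- function(e_mev, bias_v) {
  if (bias_v >= 40) {
    ifelse(e_mev <= 2, e_mev, 2 + (e_mev - 2) / (1 + (e_mev - 2) / 5))
  } else {
    0.6 * e_mev
  }
}

# per-pixel electronics response: counts = a*E + b - c/(E - t), E in keV.
# a carries the pixel gain field; b, c, t are the global surrogate constants.
PIXEL_RESP_B <- 2
PIXEL_RESP_C <- 30
PIXEL_RESP_T <- 3

.pixel_counts <- function(e_kev, gain) {
  gain * e_kev + PIXEL_RESP_B - PIXEL_RESP_C / (e_kev - PIXEL_RESP_T)
}

.species_cols <- function(species) {
  ions <- lapply(species, ion_species)
  list(Z = vapply(ions, `[[`, 1L, "charge_number"),
       A = vapply(ions, `[[`, 1L, "mass_number"),
       m = vapply(ions, `[[`, 0, "mass_per_nucleon"))
}

# one thin-slab transport step, vectorised over ions; modifies energy,
# position and direction; thickness in mm.  `mat` may be a single material or
# a character vector per ion (used for the step slab).
.step_slab <- function(st, mat, thickness_mm, scattering, straggling,
                       corr_x_over_x0 = NULL) {
  alive <- st$alive & st$energy > 0
  if (!any(alive) || thickness_mm <= 0) {
    st$x <- st$x + st$tx * thickness_mm
    st$y <- st$y + st$ty * thickness_mm
    return(st)
  }
  mats <- if (inherits(mat, "material")) list(mat) else lapply(unique(mat), material)
  mat_id <- if (inherits(mat, "material")) rep(1L, length(st$x)) else match(mat, unique(mat))
  # straight drift with the entry slope; the scattering displacement term
  # below carries the correlated in-slab deflection
  st$x <- st$x + st$tx * thickness_mm
  st$y <- st$y + st$ty * thickness_mm
  e_in <- st$energy
  e_out <- e_in
  for (sp in unique(st$species[alive])) {
    for (mi in seq_along(mats)) {
      idx <- which(alive & st$species == sp & mat_id == mi)
      if (!length(idx)) next
      e_out[idx] <- energy_after(sp, e_in[idx], mats[[mi]], thickness_mm / 10)
      if (straggling) {
        ion <- ion_species(sp)
        sig <- bohr_straggling_sigma(ion, mats[[mi]], thickness_mm / 10) /
          ion$mass_number
        e_out[idx] <- pmax(e_out[idx] + stats::rnorm(length(idx), 0, sig), 0)
      }
      if (scattering) {
        e_mid <- pmax((e_in[idx] + pmax(e_out[idx], E_CUTOFF)) / 2, E_CUTOFF)
        th0 <- highland_sigma(sp, e_mid, mats[[mi]], thickness_mm / 10)
        if (!is.null(corr_x_over_x0)) {
          # sub-slab of a thick object: the Highland log factor must be taken
          # for the whole path, else composed variance underestimates
          slab_x <- thickness_mm / 10 * mats[[mi]]$density /
            mats[[mi]]$radiation_length
          th0 <- th0 * (1 + 0.038 * log(corr_x_over_x0)) /
            (1 + 0.038 * log(slab_x))
        }
        n <- length(idx)
        for (d in c("x", "y")) {
          z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
          st[[d]][idx] <- st[[d]][idx] +
            thickness_mm * th0 * (z1 / sqrt(12) + z2 / 2)
          st[[paste0("t", d)]][idx] <- st[[paste0("t", d)]][idx] + z2 * th0
        }
      }
    }
  }
  dead <- alive & e_out <= 0
  st$energy <- ifelse(alive, e_out, st$energy)
  st$alive[dead] <- FALSE
  st$stopped[dead] <- TRUE
  st
}

.drift_air <- function(st, dz_mm, straggling) {
  if (dz_mm <= 0) return(st)
  st <- .step_slab(st, material("air"), dz_mm, scattering = FALSE,
                   straggling = FALSE)
  st
}

#' Transport ions through the imaging geometry
#'
#' Piecewise-straight CSDA transport with Highland multiple-scattering kicks
#' (correlated angle/offset thick-slab sampling), Bohr energy-loss straggling,
#' and single-point helium-to-hydrogen fragmentation inside the phantom.
#' Returns one truth row per ion with per-layer impact positions, directions
#' and sensor energy depositions.
#'
#' @param start Tibble with one row per ion: `x`, `y` (mm), `tx`, `ty`
#'   (slopes dx/dz, dy/dz), `energy` (MeV/u), `species` (character), and
#'   optionally `ion_id`, `frame`, `arrival_us`.
#' @param phantom A [phantom_spec()], or `NULL` for a phantom-free geometry.
#' @param layers A [layer_table()].
#' @param scattering,straggling Logical switches for the stochastic physics;
#'   disabling both makes trajectories straight and depositions deterministic.
#' @param n_substeps Number of sub-slabs per phantom half (scattering
#'   composition accuracy).
#' @return A tibble (the truth table): per-ion entry/exit state at the phantom
#'   faces, per-layer `x<l>`, `y<l>`, `tx<l>`, `ty<l>`, `dep<l>` (MeV) and
#'   `alive<l>`, residual energy `e_layer3` (MeV/u), `species_out`,
#'   `frag_depth` and `stopped`.
#' @export
transport_ions <- function(start, phantom, layers,
                           scattering = TRUE, straggling = TRUE,
                           n_substeps = 8) {
  n <- nrow(start)
  st <- list(
    x = start$x, y = start$y, tx = start$tx, ty = start$ty,
    energy = start$energy, species = start$species,
    alive = rep(TRUE, n), stopped = rep(FALSE, n)
  )
  truth <- tibble::tibble(
    ion_id = start[["ion_id"]] %||% seq_len(n),
    frame = start[["frame"]] %||% rep(1L, n),
    arrival_us = start[["arrival_us"]] %||% rep(0, n),
    species_in = start$species
  )
  frag_depth <- rep(NA_real_, n)
  if (!is.null(phantom) && phantom$fragmentation_prob > 0) {
    u <- stats::runif(n)
    frag <- u < phantom$fragmentation_prob & start$species == "helium"
    frag_depth[frag] <- stats::runif(sum(frag), 0, phantom$length)
  }

  z_now <- min(layers$z) - 5
  rec_layer <- function(st, l) {
    row <- layers[l, ]
    dep <- rep(0, n)
    alive <- st$alive
    for (sp in unique(st$species[alive])) {
      idx <- which(alive & st$species == sp)
      if (!length(idx)) next
      dep[idx] <- deposition_in_silicon(sp, st$energy[idx], row$sensor_um)
      if (straggling) {
        ion <- ion_species(sp)
        sig <- bohr_straggling_sigma(ion, "silicon", row$sensor_um * 1e-4)
        dep[idx] <- pmax(dep[idx] + stats::rnorm(length(idx), 0, sig), 0)
      }
    }
    list(x = ifelse(alive, st$x, NA_real_), y = ifelse(alive, st$y, NA_real_),
         tx = ifelse(alive, st$tx, NA_real_), ty = ifelse(alive, st$ty, NA_real_),
         dep = ifelse(alive, dep, 0), alive = alive,
         energy = ifelse(alive, st$energy, 0))
  }

  cross_layer <- function(st, l) {
    row <- layers[l, ]
    st <- .step_slab(st, material("silicon"), row$sensor_um / 1000,
                     scattering, straggling)
    if (row$readout_wet_mm > 0) {
      st <- .step_slab(st, material("water"), row$readout_wet_mm,
                       scattering, straggling)
    }
    st
  }

  do_phantom <- function(st) {
    L <- phantom$length
    t_step <- phantom$step_thickness
    s0 <- phantom$step_depth_center - t_step / 2
    s1 <- phantom$step_depth_center + t_step / 2
    corr <- L / 10 * phantom$material$density /
      phantom$material$radiation_length
    run_block <- function(st, from, to, depth0) {
      if (to <= from) return(st)
      nb <- max(1L, ceiling((to - from) / (L / (2 * n_substeps))))
      dt <- (to - from) / nb
      for (b in seq_len(nb)) {
        d_here <- depth0 + (b - 1) * dt
        conv <- which(!is.na(frag_depth) & frag_depth <= d_here &
                        st$species == "helium" & st$alive)
        if (length(conv)) {
          st$species[conv] <- "proton"  # hydrogen fragment, same E/u
          remaining <- pmax(L - d_here, 1)
          kick <- 3 * highland_sigma("proton", pmax(st$energy[conv], E_CUTOFF),
                                     phantom$material, remaining / 10)
          st$tx[conv] <- st$tx[conv] + stats::rnorm(length(conv), 0, kick)
          st$ty[conv] <- st$ty[conv] + stats::rnorm(length(conv), 0, kick)
        }
        st <- .step_slab(st, phantom$material, dt, scattering, straggling,
                         corr_x_over_x0 = corr)
      }
      st
    }
    st <- run_block(st, 0, s0, 0)
    if (t_step > 0) {
      in_step <- st$x > phantom$step_edge_x
      mats <- ifelse(in_step, phantom$step_material$name, phantom$material$name)
      st <- .step_slab(st, mats, t_step, scattering, straggling,
                       corr_x_over_x0 = corr)
    }
    st <- run_block(st, s1, L, s1)
    # fragmentations drawn in the last sub-slab convert at the exit face
    conv <- which(!is.na(frag_depth) & st$species == "helium" & st$alive)
    if (length(conv)) {
      st$species[conv] <- "proton"
      kick <- 3 * highland_sigma("proton", pmax(st$energy[conv], E_CUTOFF),
                                 phantom$material, 0.5)
      st$tx[conv] <- st$tx[conv] + stats::rnorm(length(conv), 0, kick)
      st$ty[conv] <- st$ty[conv] + stats::rnorm(length(conv), 0, kick)
    }
    st
  }

  per_layer <- vector("list", 5)
  entry <- exit <- NULL
  phantom_done <- is.null(phantom)
  for (l in 1:5) {
    z_target <- layers$z[l]
    if (!phantom_done && !is.null(phantom) && phantom$upstream_z < z_target) {
      st <- .drift_air(st, phantom$upstream_z - z_now, straggling)
      z_now <- phantom$upstream_z
      entry <- list(x = st$x, y = st$y, tx = st$tx, ty = st$ty, e = st$energy)
      st <- do_phantom(st)
      z_now <- z_now + phantom$length
      exit <- list(x = st$x, y = st$y, tx = st$tx, ty = st$ty, e = st$energy)
      phantom_done <- TRUE
    }
    st <- .drift_air(st, z_target - z_now, straggling)
    z_now <- z_target
    per_layer[[l]] <- rec_layer(st, l)
    st <- cross_layer(st, l)
    z_now <- z_now  # layer thickness is negligible in z bookkeeping
  }
  # hydrogen conversion: species recorded as "proton" internally for physics,
  # reported as hydrogen
  truth$species_out <- ifelse(st$species %in% c("proton", "hydrogen"),
                              "hydrogen", st$species)
  truth$frag_depth <- frag_depth
  truth$stopped <- st$stopped
  if (is.null(entry)) entry <- list(x = rep(NA_real_, n), y = NA_real_,
                                    tx = NA_real_, ty = NA_real_, e = NA_real_)
  if (is.null(exit)) exit <- entry
  truth$entry_x <- entry$x; truth$entry_y <- entry$y
  truth$entry_tx <- entry$tx; truth$entry_ty <- entry$ty
  truth$exit_x <- exit$x; truth$exit_y <- exit$y
  truth$exit_tx <- exit$tx; truth$exit_ty <- exit$ty
  for (l in 1:5) {
    pl <- per_layer[[l]]
    truth[[paste0("x", l)]] <- pl$x
    truth[[paste0("y", l)]] <- pl$y
    truth[[paste0("tx", l)]] <- pl$tx
    truth[[paste0("ty", l)]] <- pl$ty
    truth[[paste0("dep", l)]] <- pl$dep
    truth[[paste0("alive", l)]] <- pl$alive
  }
  truth$e_layer3 <- per_layer[[3]]$energy
  truth
}

#' Transport a single ion (convenience wrapper)
#'
#' @inheritParams transport_ions
#' @param x,y,tx,ty,energy,species Initial state of the ion upstream of the
#'   first layer.
#' @return A one-row truth tibble; see [transport_ions()].
#' @export
transport_ion <- function(x, y, tx, ty, energy, species, phantom, layers, ...) {
  transport_ions(tibble::tibble(x = x, y = y, tx = tx, ty = ty,
                                energy = energy, species = species),
                 phantom, layers, ...)
}

# fraction of the cloud falling into pixels at offsets -4..4 around the centre
# pixel, separable Gaussian; returns the long-format pixel list above threshold
.render_layer <- function(hits, layer_row, acq, gain) {
  if (!nrow(hits)) {
    return(tibble::tibble(frame = integer(), col = integer(), row = integer(),
                          value = integer(), hit_id = integer()))
  }
  pitch <- layer_row$pitch_um / 1000
  px <- (hits$x + HALF_AREA_MM) / pitch - 0.5   # cloud centre, pixel units
  py <- (hits$y + HALF_AREA_MM) / pitch - 0.5
  c0 <- round(px); r0 <- round(py)
  sig <- .cloud_sigma_mm(hits$dep, layer_row$bias_v) / pitch
  offs <- -4:4
  n <- nrow(hits); k <- length(offs)
  fx <- matrix(unlist(lapply(offs, function(j)
    stats::pnorm((c0 + j + 0.5 - px) / sig) -
      stats::pnorm((c0 + j - 0.5 - px) / sig))), n, k)
  fy <- matrix(unlist(lapply(offs, function(j)
    stats::pnorm((r0 + j + 0.5 - py) / sig) -
      stats::pnorm((r0 + j - 0.5 - py) / sig))), n, k)
  e_cl_kev <- hits$e_meas_kev
  idx <- rep(seq_len(n), times = k * k)
  jx <- rep(rep(seq_len(k), each = n), times = k)
  jy <- rep(seq_len(k), each = n * k)
  e_px <- e_cl_kev[idx] * fx[cbind(idx, jx)] * fy[cbind(idx, jy)]
  col <- c0[idx] + offs[jx]
  row <- r0[idx] + offs[jy]
  keep <- e_px >= layer_row$threshold_kev & col >= 0 & col <= 255 &
    row >= 0 & row <= 255
  col <- col[keep]; row <- row[keep]; e_px <- e_px[keep]; idx <- idx[keep]
  if (layer_row$mode == "energy") {
    g <- gain[cbind(col + 1L, row + 1L)]
    value <- round(.pixel_counts(e_px, g))
    value <- pmin(pmax(value, 1), acq$counter_max)
  } else {
    value <- hits$tick[idx]
  }
  tibble::tibble(frame = hits$frame[idx], col = as.integer(col),
                 row = as.integer(row), value = as.integer(value),
                 hit_id = hits$hit_id[idx])
}

#' Render the pixel cluster of a single impact
#'
#' The 2-D Gaussian charge-cloud model of one ion hitting one layer: the cloud
#' width grows with deposited energy and shrinks with bias voltage; pixels
#' above threshold receive energy counts (energy mode, with the bias response
#' and counter saturation) or the arrival-time tick (time mode).
#'
#' @param x,y Impact position in mm (layer-local frame).
#' @param deposited_mev Energy deposited in the sensor, MeV.
#' @param layers A [layer_table()].
#' @param layer Layer index.
#' @param tick Arrival-time tick (time mode value).
#' @param acquisition An [acquisition_spec()].
#' @param gain Optional 256 x 256 gain matrix; default: the layer's own field.
#' @return Tibble of pixel hits (`col`, `row`, `value`); empty below threshold.
#' @export
make_cluster <- function(x, y, deposited_mev, layers, layer, tick = 1,
                         acquisition = acquisition_spec(), gain = NULL) {
  row <- layers[layers$layer == layer, ]
  gain <- gain %||% layer_gain_map(layers, layer)
  e_meas <- .bias_response(deposited_mev, row$bias_v) * 1000
  hits <- tibble::tibble(x = x, y = y, dep = deposited_mev,
                         e_meas_kev = e_meas, tick = tick,
                         frame = 1L, hit_id = seq_along(x))
  .render_layer(hits, row, acquisition, gain)[c("col", "row", "value")]
}

#' Inject detector artifacts into rendered frames
#'
#' Adds, at the configured rates: light-background 1-2 pixel clusters;
#' overshoot distortions on clusters containing a pixel above the overshoot
#' deposition (wide arrival-tick spread in time mode, distorted counts in
#' energy mode); and merged companion clusters (overlaps, two local maxima).
#' Temporal cropping is applied during rendering (it scales the digitised
#' energy), so this function handles the additive/distorting classes.
#'
#' @param frames Frames tibble from the renderer (internal pixel table with
#'   `layer`, `frame`, `col`, `row`, `value`, `hit_id`).
#' @param truth Truth table (used to locate eligible clusters).
#' @param layers,acquisition,artifacts Run configuration objects.
#' @return Frames tibble with artifacts applied.
#' @keywords internal
.inject_background <- function(frames, layers, acquisition, artifacts, n_frames) {
  if (artifacts$background_per_frame <= 0) return(frames)
  out <- list(frames)
  for (l in 1:5) {
    row <- layers[l, ]
    n_bg <- stats::rpois(n_frames, artifacts$background_per_frame)
    tot <- sum(n_bg)
    if (!tot) next
    fr <- rep(seq_len(n_frames), n_bg)
    col <- sample.int(256, tot, replace = TRUE) - 1L
    rw <- sample.int(256, tot, replace = TRUE) - 1L
    if (row$mode == "energy") {
      val <- as.integer(round(stats::runif(tot, row$threshold_kev, 200)))
    } else {
      val <- as.integer(sample.int(floor(acquisition$frame_ms * 1e6 /
                                           acquisition$tick_ns), tot,
                                   replace = TRUE))
    }
    second <- stats::runif(tot) < 0.4
    dcol <- ifelse(stats::runif(tot) < 0.5, 1L, 0L)
    drow <- 1L - dcol
    bg <- tibble::tibble(
      layer = l, frame = fr, col = col, row = rw, value = val,
      hit_id = NA_integer_)
    bg2 <- bg[second, ]
    if (nrow(bg2)) {
      bg2$col <- pmin(bg2$col + dcol[second], 255L)
      bg2$row <- pmin(bg2$row + drow[second], 255L)
      if (row$mode == "energy")
        bg2$value <- as.integer(round(stats::runif(nrow(bg2),
                                                   row$threshold_kev, 70)))
      bg <- dplyr::bind_rows(bg, bg2)
    }
    out[[length(out) + 1]] <- bg
  }
  dplyr::bind_rows(out)
}

.apply_overshoot <- function(frames, layers, acquisition, artifacts,
                             eligible_hit_ids) {
  if (artifacts$overshoot_prob <= 0 || !length(eligible_hit_ids)) {
    return(list(frames = frames, hit_ids = integer()))
  }
  chosen <- eligible_hit_ids[stats::runif(length(eligible_hit_ids)) <
                               artifacts$overshoot_prob]
  if (!length(chosen)) return(list(frames = frames, hit_ids = integer()))
  mode_of <- stats::setNames(layers$mode, layers$layer)
  affected <- frames$hit_id %in% chosen
  idx <- which(affected)
  if (length(idx)) {
    is_energy <- mode_of[as.character(frames$layer[idx])] == "energy"
    # energy mode: a random subset of pixels gets multiplied counts
    en <- idx[is_energy]
    if (length(en)) {
      boost <- stats::runif(length(en)) < 0.4
      frames$value[en[boost]] <- pmin(
        as.integer(round(frames$value[en[boost]] *
                           stats::runif(sum(boost), 2, 6))),
        acquisition$counter_max)
    }
    # time mode: anomalous tick spread
    tm <- idx[!is_energy]
    if (length(tm)) {
      jit <- stats::runif(length(tm)) < 0.6
      frames$value[tm[jit]] <- pmax(
        frames$value[tm[jit]] +
          as.integer(sample(c(-1, 1), sum(jit), replace = TRUE) *
                       sample(2:12, sum(jit), replace = TRUE)), 1L)
    }
  }
  list(frames = frames, hit_ids = chosen)
}

#' Simulate a full imaging run
#'
#' Generates per-layer sparse pixel frames and the matching ground-truth table
#' for a pencil-beam acquisition: Poisson ion counts per frame, Gaussian beam
#' profile, CSDA + Highland + straggling transport with fragmentation,
#' charge-cloud cluster rendering with the bias-voltage response models,
#' temporal cropping of ions arriving near the frame edges, and the additive
#' artifact classes of [artifact_config()]. Identical seeds give identical
#' output.
#'
#' @param beam A [beam_spec()].
#' @param phantom A [phantom_spec()] or `NULL`.
#' @param layers A [layer_table()].
#' @param acquisition An [acquisition_spec()] (holds `frames` and `seed`).
#' @param artifacts An [artifact_config()].
#' @param scattering,straggling Physics switches (see [transport_ions()]).
#' @return An `ionrad_run`: list with `frames` (tibble: `layer`, `frame`,
#'   `col`, `row`, `value`) carrying the layer table and acquisition as
#'   attributes, and `truth` (one row per primary ion, including the artifact
#'   bookkeeping columns `cropped`, `crop_factor`, `overlap_injected`,
#'   `overshoot_injected`).
#' @export
simulate_run <- function(beam = beam_spec(), phantom = phantom_spec(),
                         layers = layer_table(),
                         acquisition = acquisition_spec(),
                         artifacts = artifact_config(),
                         scattering = TRUE, straggling = TRUE) {
  set.seed(acquisition$seed)
  n_frames <- acquisition$frames
  n_per_frame <- stats::rpois(n_frames, beam$mean_ions_per_frame)
  n <- sum(n_per_frame)
  empty_truth <- tibble::tibble(ion_id = integer())
  if (n == 0) {
    fr <- tibble::tibble(layer = integer(), frame = integer(), col = integer(),
                         row = integer(), value = integer())
    return(.new_run(fr, empty_truth, layers, acquisition, beam, phantom,
                    artifacts))
  }
  sigma_beam <- beam$fwhm / (2 * sqrt(2 * log(2)))
  frame_us <- acquisition$frame_ms * 1000
  start <- tibble::tibble(
    ion_id = seq_len(n),
    frame = rep(seq_len(n_frames), n_per_frame),
    x = stats::rnorm(n, beam$center[1], sigma_beam),
    y = stats::rnorm(n, beam$center[2], sigma_beam),
    tx = 0, ty = 0,
    energy = beam$energy_per_nucleon,
    species = beam$species$name,
    arrival_us = stats::runif(n, 0, frame_us)
  )
  truth <- transport_ions(start, phantom, layers,
                          scattering = scattering, straggling = straggling)
  tick_us <- acquisition$tick_ns / 1000
  truth$tick <- as.integer(floor(truth$arrival_us / tick_us)) + 1L

  # temporal cropping: ions arriving within the guard window of either frame
  # edge get a partially digitised energy signal
  g <- artifacts$crop_guard_us
  truth$cropped <- truth$arrival_us < g | truth$arrival_us > frame_us - g
  truth$crop_factor <- ifelse(truth$cropped, stats::runif(n, 0.2, 0.8), 1)

  # overlap injection: a companion deposit merged with the ion's energy-layer
  # cluster, displaced by 2.5-3.5 pixels -> two local maxima in one region
  truth$overlap_injected <- stats::runif(n) < artifacts$overlap_prob &
    truth$alive3

  gains <- lapply(1:5, function(l) layer_gain_map(layers, l))
  all_px <- vector("list", 5)
  for (l in 1:5) {
    row <- layers[l, ]
    al <- truth[[paste0("alive", l)]] & truth[[paste0("dep", l)]] > 0
    hits <- tibble::tibble(
      x = truth[[paste0("x", l)]][al] - row$offset_x_um / 1000,
      y = truth[[paste0("y", l)]][al] - row$offset_y_um / 1000,
      dep = truth[[paste0("dep", l)]][al],
      tick = truth$tick[al],
      frame = truth$frame[al],
      hit_id = truth$ion_id[al]
    )
    if (row$mode == "energy") {
      hits$e_meas_kev <- .bias_response(hits$dep, row$bias_v) * 1000 *
        truth$crop_factor[al]
      ov <- truth$overlap_injected[al]
      if (any(ov)) {
        comp <- hits[ov, ]
        ang <- stats::runif(nrow(comp), 0, 2 * pi)
        rad <- stats::runif(nrow(comp), 3.2, 4.2) * row$pitch_um / 1000
        comp$x <- comp$x + cos(ang) * rad
        comp$y <- comp$y + sin(ang) * rad
        comp$dep <- comp$dep * 0.9
        comp$e_meas_kev <- comp$e_meas_kev * 0.9
        hits <- dplyr::bind_rows(hits, comp)
      }
    } else {
      hits$e_meas_kev <- hits$dep * 1000
    }
    px <- .render_layer(hits, row, acquisition, gains[[l]])
    px$layer <- l
    all_px[[l]] <- px
  }
  frames <- dplyr::bind_rows(all_px)

  # overshoot eligibility: the cluster contains a pixel whose true deposition
  # exceeds the configured level (charge-sharing peak fraction x deposition)
  peak_frac <- function(dep, bias) {
    s <- .cloud_sigma_mm(dep, bias) / PITCH_MM
    (2 * stats::pnorm(0.5 / s) - 1)^2
  }
  elig <- unique(unlist(lapply(1:5, function(l) {
    row <- layers[l, ]
    al <- truth[[paste0("alive", l)]]
    dep <- truth[[paste0("dep", l)]]
    truth$ion_id[al & dep * peak_frac(dep, row$bias_v) >
                   artifacts$overshoot_pixel_mev]
  })))
  os <- .apply_overshoot(frames, layers, acquisition, artifacts, elig)
  frames <- os$frames
  truth$overshoot_injected <- truth$ion_id %in% os$hit_ids

  frames <- .inject_background(frames, layers, acquisition, artifacts, n_frames)
  # one entry per pixel per frame: coincident depositions add their counts in
  # energy mode (charge sums) and keep the earliest tick in time mode
  energy_layers <- layers$layer[layers$mode == "energy"]
  frames <- .merge_coincident(frames, energy_layers, acquisition$counter_max,
                              n_frames)
  .new_run(frames, truth, layers, acquisition, beam, phantom, artifacts)
}

# resolve multiple depositions landing on the same pixel of the same frame:
# counts add (saturating) in energy mode, the earliest tick wins in time mode
.merge_coincident <- function(frames, energy_layers, counter_max, n_frames) {
  nf <- max(n_frames, 1L)
  key <- (((frames$layer - 1) * nf + (frames$frame - 1)) * 256 +
            frames$col) * 256 + frames$row
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  keep <- frames[!dup, ]
  if (any(dup)) {
    dd <- frames[dup, ]; dk <- key[dup]
    en <- dd$layer %in% energy_layers
    parts <- list(keep)
    if (any(en)) {
      sub <- dd[en, ]; k <- dk[en]
      o <- order(k); sub <- sub[o, ]; k <- k[o]
      first <- !duplicated(k)
      out <- sub[first, ]
      out$value <- as.integer(pmin(rowsum(sub$value, k)[, 1], counter_max))
      parts[[length(parts) + 1]] <- out
    }
    if (any(!en)) {
      sub <- dd[!en, ]; k <- dk[!en]
      o <- order(k, sub$value); sub <- sub[o, ]; k <- k[o]
      parts[[length(parts) + 1]] <- sub[!duplicated(k), ]
    }
    keep <- dplyr::bind_rows(parts)
  }
  key2 <- (((keep$layer - 1) * nf + (keep$frame - 1)) * 256 +
             keep$col) * 256 + keep$row
  out <- keep[order(key2), ]
  out$value <- as.integer(out$value)
  out
}

.new_run <- function(frames, truth, layers, acquisition, beam, phantom,
                     artifacts) {
  frames <- tibble::as_tibble(frames)
  attr(frames, "layers") <- layers
  attr(frames, "acquisition") <- acquisition
  class(frames) <- c("ionrad_frames", class(frames))
  structure(list(frames = frames, truth = truth, layers = layers,
                 acquisition = acquisition, beam = beam, phantom = phantom,
                 artifacts = artifacts),
            class = "ionrad_run")
}

#' @export
print.ionrad_run <- function(x, ...) {
  cat(sprintf("<ionrad_run> %d primaries, %d frames, %d pixel hits\n",
              nrow(x$truth), x$acquisition$frames, nrow(x$frames)))
  invisible(x)
}

#' Simulate a phantom-free alignment run
#'
#' Narrow-beam, high-statistics acquisition with the phantom removed, used to
#' determine the per-layer lateral offsets: on each layer the beam centroid is
#' the point of maximum fluence, and differences to the reference layer give
#' the alignment solution. Defaults follow the alignment procedure: 4.9 mm
#' FWHM beam at the highest energy, 220.5 MeV/u.
#'
#' @param layers A [layer_table()] (its `offset_*_um` columns are the true
#'   offsets to be recovered).
#' @param n_ions Number of ions to acquire.
#' @param beam Alignment beam.
#' @param seed RNG seed.
#' @return An `ionrad_run` (see [simulate_run()]).
#' @export
simulate_alignment_run <- function(layers = layer_table(), n_ions = 10000,
                                   beam = beam_spec(energy_per_nucleon = 220.5,
                                                    fwhm = 4.9),
                                   seed = 1) {
  frames <- max(1L, ceiling(n_ions / beam$mean_ions_per_frame))
  acq <- acquisition_spec(frames = frames, seed = seed)
  simulate_run(beam = beam, phantom = NULL, layers = layers,
               acquisition = acq,
               artifacts = artifact_config(background_per_frame = 0,
                                           overshoot_prob = 0,
                                           overlap_prob = 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
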