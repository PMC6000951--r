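# Mid-plane radiograph formation: connection-line positioning of each
# accepted ion at the imaging plane, per-bin channel accumulation, and the
# imaging-dose bookkeeping.

#' Mid-plane position of accepted events
#'
#' The front segment is extrapolated to the upstream phantom face and the
#' rear segment back-extrapolated to the downstream face; the straight
#' connection line between the two surface points is evaluated at the imaging
#' plane. Events whose surface points fall outside the detector aperture are
#' excluded with a reason.
#'
#' @param events Event table from [build_events()] (needs `f_x_ref` etc. at
#'   the phantom faces).
#' @param phantom A [phantom_spec()].
#' @param plane An [imaging_plane_spec()].
#' @return `events` with `x_mid`, `y_mid` (mm) and `midplane_ok`.
#' @export
event_midplane_position <- function(events, phantom,
                                    plane = imaging_plane_spec()) {
  z_up <- phantom$upstream_z
  z_dn <- phantom$upstream_z + phantom$length
  stopifnot(plane$z_position >= z_up, plane$z_position <= z_dn)
  f <- (plane$z_position - z_up) / (z_dn - z_up)
  ev <- events
  ev$x_mid <- ev$f_x_ref + (ev$r_x_ref - ev$f_x_ref) * f
  ev$y_mid <- ev$f_y_ref + (ev$r_y_ref - ev$f_y_ref) * f
  lim <- HALF_AREA_MM
  ev$midplane_ok <- abs(ev$f_x_ref) <= lim & abs(ev$f_y_ref) <= lim &
    abs(ev$r_x_ref) <= lim & abs(ev$r_y_ref) <= lim
  ev
}

#' Accumulate a multi-channel radiograph
#'
#' Bins events on the imaging plane (each event wholly assigned to the bin
#' containing its point — no splatting) and accumulates per-bin channels:
#' ion count, mean and SD of the deposited energy, mean front/rear angle
#' change and mean cluster size. Order-independent accumulators make the
#' image invariant under permutation of the event stream.
#'
#' @param events Event table with position columns and channel sources.
#' @param plane An [imaging_plane_spec()].
#' @param x,y Names of the position columns (mm).
#' @param energy Name of the deposited-energy column.
#' @return An `ionrad_radiograph`: tibble with `ix`, `iy`, bin centres
#'   `x`, `y`, `count`, `mean_energy`, `sd_energy`, `mean_angle`,
#'   `mean_size`; grid metadata in attributes. Channels are defined only
#'   where `count > 0` (empty bins carry no rows).
#' @export
accumulate_image <- function(events, plane = imaging_plane_spec(),
                             x = "x_mid", y = "y_mid",
                             energy = "volume_recal_mev") {
  pitch <- plane$pixel_pitch / 1000
  ext <- plane$extent
  ev <- events
  xi <- ev[[x]]; yi <- ev[[y]]
  keep <- !is.na(xi) & !is.na(yi) & abs(xi) < ext & abs(yi) < ext &
    !is.na(ev[[energy]])
  ev <- ev[keep, ]; xi <- xi[keep]; yi <- yi[keep]
  n_bins <- ceiling(2 * ext / pitch)
  ix <- pmin(floor((xi + ext) / pitch), n_bins - 1)
  iy <- pmin(floor((yi + ext) / pitch), n_bins - 1)
  bin <- ix * n_bins + iy
  e <- ev[[energy]]
  ang <- if (all(c("f_tx", "r_tx") %in% names(ev))) {
    sqrt((ev$f_tx - ev$r_tx)^2 + (ev$f_ty - ev$r_ty)^2)
  } else rep(NA_real_, nrow(ev))
  siz <- if ("size" %in% names(ev)) ev$size else rep(NA_real_, nrow(ev))
  cnt <- unname(rowsum(rep(1, length(bin)), bin)[, 1])
  s1 <- unname(rowsum(e, bin)[, 1])
  s2 <- unname(rowsum(e^2, bin)[, 1])
  sa <- unname(rowsum(ang, bin)[, 1])
  ss <- unname(rowsum(as.numeric(siz), bin)[, 1])
  ub <- sort(unique(bin))
  mean_e <- s1 / cnt
  sd_e <- sqrt(pmax(s2 / cnt - mean_e^2, 0) * cnt / pmax(cnt - 1, 1))
  sd_e[cnt < 2] <- NA_real_
  out <- tibble::tibble(
    ix = ub %/% n_bins, iy = ub %% n_bins,
    x = (ub %/% n_bins + 0.5) * pitch - ext,
    y = (ub %% n_bins + 0.5) * pitch - ext,
    count = as.integer(cnt),
    mean_energy = mean_e, sd_energy = sd_e,
    mean_angle = sa / cnt, mean_size = ss / cnt)
  attr(out, "plane") <- plane
  attr(out, "n_bins") <- n_bins
  class(out) <- c("ionrad_radiograph", class(out))
  out
}

#' Radiograph channel as a matrix
#'
#' @param x An `ionrad_radiograph`.
#' @param channel Channel column name.
#' @param ... Unused.
#' @return Square matrix (x along rows); empty bins are `NA`.
#' @export
as.matrix.ionrad_radiograph <- function(x, channel = "mean_energy", ...) {
  n <- attr(x, "n_bins")
  m <- matrix(NA_real_, n, n)
  m[cbind(x$ix + 1, x$iy + 1)] <- x[[channel]]
  m
}

#' Write a radiograph to disk
#'
#' One 32-bit float TIFF per channel (when the tiff package is available)
#' plus a CSV of the bin table and a YAML sidecar with the grid metadata.
#'
#' @param image An `ionrad_radiograph`.
#' @param path Base path (without extension).
#' @param channels Channels to export.
#' @return Invisibly, the written paths.
#' @export
write_radiograph <- function(image, path,
                             channels = c("mean_energy", "count")) {
  paths <- paste0(path, ".csv")
  readr::write_csv(as.data.frame(image), paths)
  plane <- attr(image, "plane")
  meta <- paste0(path, "_meta.yaml")
  writeLines(yaml::as.yaml(list(z_position = plane$z_position,
                                pixel_pitch_um = plane$pixel_pitch,
                                extent_mm = plane$extent,
                                n_bins = attr(image, "n_bins"))), meta)
  paths <- c(paths, meta)
  if (requireNamespace("tiff", quietly = TRUE)) {
    for (ch in channels) {
      m <- as.matrix(image, ch)
      m[is.na(m)] <- 0
      rng <- max(abs(m), 1e-12)
      p <- paste0(path, "_", ch, ".tif")
      tiff::writeTIFF(m / rng, p, bits.per.sample = 32L)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Imaging dose of a run
#'
#' Per-slab dose accumulation through the phantom: the beam's central-axis
#' fluence (particles/cm^2) times the local mass stopping power, integrated
#' over depth. In inverse mode (`dose` given) returns the fluence and primary
#' count achieving the requested mean phantom dose.
#'
#' @param beam A [beam_spec()].
#' @param phantom A [phantom_spec()].
#' @param n_ions Number of primaries (converted to central fluence through
#'   the Gaussian beam area); alternatively give `fluence` directly.
#' @param fluence Central-axis fluence in cm^-2.
#' @param dose Target mean phantom dose in Gy (inverse mode).
#' @param n_slabs Depth resolution.
#' @return A `dose_report`: list with `fluence_cm2`, `n_ions`,
#'   `mean_dose_gy`, and the per-slab `profile` tibble (`depth_mm`,
#'   `energy_mev_u`, `dose_gy`).
#' @export
compute_dose <- function(beam = beam_spec(), phantom = phantom_spec(),
                         n_ions = NULL, fluence = NULL, dose = NULL,
                         n_slabs = 50) {
  sigma_cm <- beam$fwhm / (2 * sqrt(2 * log(2))) / 10
  area_cm2 <- 2 * pi * sigma_cm^2
  if (is.null(fluence)) {
    fluence <- if (!is.null(n_ions)) n_ions / area_cm2 else 1
  }
  L_cm <- phantom$length / 10
  edges <- seq(0, L_cm, length.out = n_slabs + 1)
  mids <- (utils::head(edges, -1) + utils::tail(edges, -1)) / 2
  e_mid <- energy_after(beam$species, beam$energy_per_nucleon,
                        phantom$material, mids)
  ok <- e_mid > 0
  s <- rep(0, n_slabs)
  s[ok] <- mass_stopping_power(beam$species, e_mid[ok], phantom$material)
  dose_slab <- fluence * s * GY_PER_MEV_G
  mean_dose <- mean(dose_slab)
  if (!is.null(dose)) {
    scale <- dose / mean_dose
    return(compute_dose(beam, phantom, fluence = fluence * scale,
                        n_slabs = n_slabs))
  }
  structure(list(
    fluence_cm2 = fluence,
    n_ions = fluence * area_cm2,
    mean_dose_gy = mean_dose,
    profile = tibble::tibble(depth_mm = mids * 10, energy_mev_u = e_mid,
                             dose_gy = dose_slab)),
    class = "dose_report")
}

#' @export
print.dose_report <- function(x, ...) {
  cat(sprintf(
    "<dose_report> fluence %.3g /cm2 (%.0f primaries), mean phantom dose %.3g uGy\n",
    x$fluence_cm2, x$n_ions, x$mean_dose_gy * 1e6))
  invisible(x)
}
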