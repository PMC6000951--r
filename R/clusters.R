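# Cluster analysis: connected-component labelling of sparse pixel frames,
# cluster descriptors (volume, size, sub-pixel centroid, time statistics,
# local maxima), per-pixel energy calibration and the partial-depletion
# recalibration of the cluster volume.

# global numeric pixel key, unique across (layer, frame, col, row)
.pixel_key <- function(layer, frame, col, row, n_frames) {
  (((layer - 1) * n_frames + (frame - 1)) * 256 + col) * 256 + row
}

#' Label pixels into clusters
#'
#' Partitions the hit pixels of every frame into connected components
#' (default 8-connectivity), vectorised across all frames and layers at once.
#'
#' @param frames Frames tibble (`layer`, `frame`, `col`, `row`, `value`).
#' @param connectivity 8 (default, corner pixels connect) or 4.
#' @return The input with a `cluster_id` column (unique across the table).
#' @export
label_pixels <- function(frames, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  n <- nrow(frames)
  if (!n) return(dplyr::mutate(frames, cluster_id = integer()))
  nf <- max(frames$frame)
  shifts <- list(c(1, 0), c(0, 1))
  if (connectivity == 8) shifts <- c(shifts, list(c(1, 1), c(1, -1)))
  out <- frames
  out$cluster_id <- NA_integer_
  offset <- 0L
  # one graph per layer keeps the peak graph size bounded on large runs
  for (l in sort(unique(frames$layer))) {
    li <- which(frames$layer == l)
    sub <- frames[li, ]
    key <- .pixel_key(1L, sub$frame, sub$col, sub$row, nf)
    edges <- lapply(shifts, function(s) {
      nb <- .pixel_key(1L, sub$frame, sub$col + s[1], sub$row + s[2], nf)
      j <- match(nb, key)
      # neighbour must exist and stay inside the pixel matrix (the key is
      # positional, so an out-of-range column would alias another frame)
      ok <- !is.na(j) & sub$col + s[1] >= 0 & sub$col + s[1] <= 255 &
        sub$row + s[2] >= 0 & sub$row + s[2] <= 255
      cbind(which(ok), j[ok])
    })
    e <- do.call(rbind, edges)
    g <- igraph::make_empty_graph(length(li), directed = FALSE)
    if (nrow(e)) g <- igraph::add_edges(g, t(e))
    comp <- igraph::components(g)
    out$cluster_id[li] <- as.integer(comp$membership) + offset
    offset <- offset + comp$no
    rm(g, e, edges, key)
  }
  out
}

# local-maximum representative count per cluster: a candidate pixel dominates
# (>=) all 8 neighbours; adjacent equal-valued candidates (plateaus) merge
# and count once
.n_local_maxima <- function(px, nf) {
  key <- .pixel_key(px$layer, px$frame, px$col, px$row, nf)
  ord <- order(key)
  skey <- key[ord]
  val_of <- px$value[ord]
  lookup <- function(dc, dr) {
    nb <- .pixel_key(px$layer, px$frame, px$col + dc, px$row + dr, nf)
    j <- findInterval(nb, skey)
    v <- rep(-Inf, nrow(px))
    hit <- j > 0 & skey[pmax(j, 1)] == nb
    v[hit] <- val_of[j[hit]]
    v
  }
  cand <- rep(TRUE, nrow(px))
  for (dc in -1:1) for (dr in -1:1) {
    if (dc == 0 && dr == 0) next
    cand <- cand & px$value >= lookup(dc, dr)
  }
  # plateau merge: connected equal-value candidates count once
  sub <- px[cand, ]
  if (!nrow(sub)) return(stats::setNames(integer(0), character(0)))
  ck <- .pixel_key(sub$layer, sub$frame, sub$col, sub$row, nf)
  edges <- list()
  for (s in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    nb <- .pixel_key(sub$layer, sub$frame, sub$col + s[1], sub$row + s[2], nf)
    j <- match(nb, ck)
    ok <- !is.na(j) & sub$value == sub$value[ifelse(is.na(j), 1, j)]
    edges[[length(edges) + 1]] <- cbind(which(ok), j[ok])
  }
  e <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(nrow(sub), directed = FALSE)
  if (nrow(e)) g <- igraph::add_edges(g, t(e))
  plateau <- igraph::components(g)$membership
  rep_px <- !duplicated(plateau)
  counts <- table(sub$cluster_id[rep_px])
  counts
}

#' Apply per-pixel energy calibration
#'
#' Inverts each pixel's electronics response `counts = a E + b - c/(E - t)`
#' (E in keV) to a calibrated pixel energy. Pixels whose counts fall outside
#' the invertible branch (at or below the hook threshold) are flagged and get
#' `NA` energy; clusters containing such pixels are flagged overshoot
#' downstream.
#'
#' @param pixels Labelled pixel tibble (energy-mode rows; see
#'   [label_pixels()]).
#' @param map Calibration map tibble (`col`, `row`, `a`, `b`, `c`, `t`), one
#'   row per pixel, e.g. from [make_calibration_map()].
#' @return `pixels` with `energy_mev` and `calib_flag` columns.
#' @export
apply_pixel_calibration <- function(pixels, map) {
  idx <- match(pixels$col * 256 + pixels$row, map$col * 256 + map$row)
  if (anyNA(idx)) stop("calibration map does not cover all pixels",
                       call. = FALSE)
  a <- map$a[idx]; b <- map$b[idx]; cc <- map$c[idx]; tt <- map$t[idx]
  y <- pixels$value
  # solve a E^2 + (b - y - a t) E - ((b - y) t + c) = 0, branch E > t
  B <- b - y - a * tt
  C <- -((b - y) * tt + cc)
  disc <- B^2 - 4 * a * C
  ok <- disc >= 0
  e_kev <- rep(NA_real_, length(y))
  e_kev[ok] <- (-B[ok] + sqrt(disc[ok])) / (2 * a[ok])
  # invertible branch: above the hook threshold, inside the calibrated
  # deposition window (0-17 MeV per pixel)
  ok <- ok & e_kev > tt & e_kev <= 17000
  out <- pixels
  out$energy_mev <- ifelse(ok, e_kev / 1000, NA_real_)
  out$calib_flag <- !ok
  out
}

#' Calibration map of a simulated layer
#'
#' The per-pixel response parameters the simulator used for a layer: linear
#' gain `a` from the layer's gain field plus the global offset/hook surrogate
#' constants. Stored and exchanged as CSV via [write_calibration_map()].
#'
#' @param layers A [layer_table()].
#' @param layer Layer index (default 3, the energy detector).
#' @return Tibble `col`, `row`, `a`, `b`, `c`, `t` covering all 65536 pixels.
#' @export
make_calibration_map <- function(layers, layer = 3) {
  g <- layer_gain_map(layers, layer)
  grid <- expand.grid(col = 0:255, row = 0:255)
  tibble::tibble(col = grid$col, row = grid$row,
                 a = as.numeric(g[cbind(grid$col + 1, grid$row + 1)]),
                 b = PIXEL_RESP_B, c = PIXEL_RESP_C, t = PIXEL_RESP_T)
}

#' @rdname make_calibration_map
#' @param map Calibration map tibble.
#' @param path CSV path.
#' @export
write_calibration_map <- function(map, path) {
  readr::write_csv(map, path)
  invisible(path)
}

#' @rdname make_calibration_map
#' @export
read_calibration_map <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(col = "i", row = "i"))
}

#' Find clusters and compute descriptors
#'
#' Labels connected components and reduces them to one row per cluster:
#' volume (summed counts), size, value-weighted sub-pixel centroid in mm
#' (uniform weights in time mode, where values are arrival ticks), arrival
#' tick and tick spread (time mode), number of plateau-merged local maxima,
#' and — when a calibration map is supplied — the calibrated cluster energy
#' and peak calibrated pixel.
#'
#' @param frames Frames tibble; modes are taken from the `layers` attribute,
#'   the `modes` attribute set by [decode_frames()], or `modes`.
#' @param connectivity Passed to [label_pixels()].
#' @param calibration Optional calibration map for the energy layer(s).
#' @param modes Optional named character vector layer -> mode.
#' @return Tibble with one row per cluster: `cluster_id`, `layer`, `frame`,
#'   `mode`, `size`, `volume`, `x`, `y`, `tick`, `tick_spread`,
#'   `n_local_maxima`, `max_px`, and calibrated `volume_mev`, `max_px_mev`,
#'   `calib_flagged` where applicable.
#' @export
find_clusters <- function(frames, connectivity = 8, calibration = NULL,
                          modes = NULL) {
  if (is.null(modes)) {
    lt <- attr(frames, "layers")
    modes <- if (!is.null(lt)) stats::setNames(lt$mode, lt$layer)
    else attr(frames, "modes")
  }
  if (is.null(modes)) stop("layer modes unknown; pass `modes`", call. = FALSE)
  px <- label_pixels(frames, connectivity)
  if (!nrow(px)) {
    return(tibble::tibble(cluster_id = integer(), layer = integer(),
                          frame = integer(), mode = character(),
                          size = integer(), volume = numeric(),
                          x = numeric(), y = numeric(), tick = integer(),
                          tick_spread = integer(), n_local_maxima = integer(),
                          max_px = integer()))
  }
  nf <- max(px$frame)
  px$mode <- unname(modes[as.character(px$layer)])
  cid <- px$cluster_id
  n_cl <- max(cid)
  # positions in mm (pixel centre convention)
  xm <- (px$col + 0.5) * PITCH_MM - HALF_AREA_MM
  ym <- (px$row + 0.5) * PITCH_MM - HALF_AREA_MM
  w <- ifelse(px$mode == "energy", px$value, 1)
  size <- tabulate(cid, n_cl)
  volume <- unname(rowsum(as.numeric(px$value), cid)[, 1])
  wsum <- unname(rowsum(w, cid)[, 1])
  cx <- unname(rowsum(w * xm, cid)[, 1]) / wsum
  cy <- unname(rowsum(w * ym, cid)[, 1]) / wsum
  # per-cluster min/max value via sort trick
  o <- order(cid, px$value)
  vmin <- px$value[o][!duplicated(cid[o])]
  vmax <- px$value[o][rev(!duplicated(rev(cid[o])))]
  first_of <- !duplicated(cid)
  out <- tibble::tibble(
    cluster_id = cid[first_of], layer = px$layer[first_of],
    frame = px$frame[first_of], mode = px$mode[first_of])
  out <- out[order(out$cluster_id), ]
  out$size <- size
  out$volume <- volume
  out$x <- cx
  out$y <- cy
  is_time <- out$mode == "time"
  out$tick <- ifelse(is_time, vmin, NA_integer_)
  out$tick_spread <- ifelse(is_time, vmax - vmin, NA_integer_)
  nlm <- .n_local_maxima(px, nf)
  out$n_local_maxima <- 0L
  out$n_local_maxima[as.integer(names(nlm))] <- as.integer(nlm)
  out$max_px <- vmax
  if (!is.null(calibration)) {
    en <- px[px$mode == "energy", ]
    if (nrow(en)) {
      en <- apply_pixel_calibration(en, calibration)
      ecid <- en$cluster_id
      ok <- !is.na(en$energy_mev)
      vsum <- rowsum(ifelse(ok, en$energy_mev, 0), ecid)
      # max calibrated pixel via sort trick
      o2 <- order(ecid, en$energy_mev, na.last = FALSE)
      pmax_mev <- en$energy_mev[o2][rev(!duplicated(rev(ecid[o2])))]
      flagged <- unname(rowsum(as.numeric(en$calib_flag), ecid)[, 1]) > 0
      ids <- sort(unique(ecid))
      out$volume_mev <- NA_real_
      out$max_px_mev <- NA_real_
      out$calib_flagged <- FALSE
      out$volume_mev[ids] <- unname(vsum[, 1])
      out$max_px_mev[ids] <- pmax_mev
      out$calib_flagged[ids] <- flagged
    } else {
      out$volume_mev <- NA_real_
      out$max_px_mev <- NA_real_
      out$calib_flagged <- FALSE
    }
  }
  out
}

#' Fit the partial-depletion recalibration curve
#'
#' At 10 V the sensor is only partially depleted and the measured cluster
#' volume underestimates the deposition. The recalibration maps measured to
#' true deposition with a monotone spline fitted to a simulator-generated
#' (measured, true) scan and refined with one residual-correction iteration.
#'
#' @param measured,true Paired deposition scan in MeV (measured = calibrated
#'   cluster volume; true = deposited energy).
#' @return A `recal_curve` object (monotone mapping), usable in
#'   [recalibrate_partial_depletion()].
#' @export
fit_recalibration_curve <- function(measured, true) {
  o <- order(measured)
  m <- measured[o]; tr <- true[o]
  # pool into ~40 quantile knots, enforce monotonicity
  br <- unique(stats::quantile(m, probs = seq(0, 1, length.out = 41)))
  g <- cut(m, br, include.lowest = TRUE)
  mk <- tapply(m, g, mean); tk <- tapply(tr, g, mean)
  keep <- !is.na(mk)
  mk <- mk[keep]; tk <- tk[keep]
  if (length(mk) < 3 || stats::cor(mk, tk) <= 0) {
    stop("non-monotone recalibration curve", call. = FALSE)
  }
  tk <- stats::isoreg(mk, tk)$yf
  dup <- duplicated(tk)
  f1 <- stats::splinefun(mk[!dup], tk[!dup], method = "hyman")
  # one refinement iteration: absorb the residual bias of the first pass
  pred <- f1(m)
  ratio_k <- as.numeric(tapply(tr / pmax(pred, 1e-9), g, mean)[keep])
  f_res <- stats::approxfun(mk, ratio_k, rule = 2)
  structure(list(f = f1, res = f_res, range = range(mk)),
            class = "recal_curve")
}

#' Recalibrate the cluster volume for partial depletion
#'
#' Applies a monotone recalibration curve to measured cluster volumes
#' (MeV-equivalent after per-pixel calibration). Inputs outside the curve's
#' fitted range are clamped with a warning.
#'
#' @param volume Measured cluster volume(s), MeV.
#' @param curve A `recal_curve` from [fit_recalibration_curve()], or a
#'   two-column data frame (measured, true) to fit on the fly.
#' @return Recalibrated deposition in MeV, with attribute `clamped` (logical
#'   vector) when any input was out of range.
#' @export
recalibrate_partial_depletion <- function(volume, curve) {
  if (is.data.frame(curve)) {
    curve <- fit_recalibration_curve(curve[[1]], curve[[2]])
  }
  stopifnot(inherits(curve, "recal_curve"))
  clamped <- volume < curve$range[1] | volume > curve$range[2]
  v <- pmin(pmax(volume, curve$range[1]), curve$range[2])
  out <- curve$f(v) * curve$res(v)
  if (any(clamped)) {
    warning(sum(clamped), " volume(s) outside the recalibration range; clamped")
    attr(out, "clamped") <- clamped
  }
  out
}

#' Default recalibration curve for a layer configuration
#'
#' Builds the (measured, true) deposition scan for the energy layer by
#' rendering single clusters at depositions spanning 0.2-17 MeV through the
#' layer's response and calibration, then fits the monotone recalibration
#' curve. Deterministic; cached per layer configuration.
#'
#' @param layers A [layer_table()].
#' @param layer Energy layer index.
#' @param n_rep Clusters per scan energy.
#' @return A `recal_curve`.
#' @export
default_recalibration_curve <- function(layers, layer = 3, n_rep = 24) {
  key <- paste(layer, layers$bias_v[layer], layers$threshold_kev[layer],
               layers$gain_seed[layer], layers$gain_sd[layer], n_rep,
               sep = "|")
  cached <- .range_cache[[paste0("recal|", key)]]
  if (!is.null(cached)) return(cached)
  rng <- .saved_rng(42L)
  on.exit(.restore_rng(rng))
  energies <- exp(seq(log(0.2), log(17), length.out = 48))
  gain <- layer_gain_map(layers, layer)
  map <- make_calibration_map(layers, layer)
  truth <- rep(energies, each = n_rep)
  xs <- stats::runif(length(truth), -5, 5)
  ys <- stats::runif(length(truth), -5, 5)
  measured <- vapply(seq_along(truth), function(i) {
    p <- make_cluster(xs[i], ys[i], truth[i], layers, layer, gain = gain)
    if (!nrow(p)) return(NA_real_)
    p$layer <- layer; p$frame <- 1L
    cal <- apply_pixel_calibration(p, map)
    sum(cal$energy_mev, na.rm = TRUE)
  }, 1)
  ok <- !is.na(measured) & measured > 0
  curve <- fit_recalibration_curve(measured[ok], truth[ok])
  .range_cache[[paste0("recal|", key)]] <- curve
  curve
}
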