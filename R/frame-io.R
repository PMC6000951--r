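# Plain-text sparse frame files: one file per layer with
#   # layer <i> mode <time|energy>
#   # frame <k> t0 <us>
#   <col> <row> <value>
# lines; lossless round trip with the simulator output.

#' Write sparse frame files
#'
#' One plain-text file per layer (`layer<i>.txt`), sparse triplets with layer
#' and frame headers; every frame of the acquisition gets a header even when
#' empty, so the round trip preserves frame count.
#'
#' @param run An `ionrad_run` from [simulate_run()], or a frames tibble
#'   carrying `layers` and `acquisition` attributes.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_frames <- function(run, dir) {
  frames <- if (inherits(run, "ionrad_run")) run$frames else run
  layers <- attr(frames, "layers")
  acq <- attr(frames, "acquisition")
  stopifnot(!is.null(layers), !is.null(acq))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  frame_us <- acq$frame_ms * 1000
  paths <- character(5)
  for (l in 1:5) {
    row <- layers[l, ]
    sub <- frames[frames$layer == l, ]
    lines <- c(sprintf("# layer %d mode %s", l, row$mode))
    split_f <- split(sub, factor(sub$frame, levels = seq_len(acq$frames)))
    body <- unlist(lapply(seq_len(acq$frames), function(k) {
      s <- split_f[[k]]
      c(sprintf("# frame %d t0 %g", k, (k - 1) * frame_us),
        if (nrow(s)) sprintf("%d %d %d", s$col, s$row, s$value))
    }))
    paths[l] <- file.path(dir, sprintf("layer%d.txt", l))
    writeLines(c(lines, body), paths[l])
  }
  invisible(paths)
}

#' Decode sparse frame files
#'
#' Reads frame files written by [write_frames()] (or by compatible hardware
#' export). Malformed lines, out-of-range pixel indices and values above the
#' counter dynamic range raise parse errors naming the offending line.
#'
#' @param paths Character vector of frame files, or a directory containing
#'   `layer*.txt`.
#' @param counter_max Maximum admissible pixel value (saturation contract).
#' @return Frames tibble (`layer`, `frame`, `col`, `row`, `value`) with
#'   attributes `modes` (per layer), `n_frames` and `t0` (per frame, us).
#' @export
decode_frames <- function(paths, counter_max = 11810) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- sort(list.files(paths, pattern = "^layer[0-9]+\\.txt$",
                             full.names = TRUE))
  }
  if (!length(paths)) stop("no frame files found", call. = FALSE)
  out <- list()
  modes <- c()
  t0 <- c()
  n_frames <- 0L
  for (p in paths) {
    txt <- readLines(p)
    hdr <- grepl("^#", txt)
    m <- regmatches(txt[1], regexec("^# layer ([0-9]+) mode (time|energy)$",
                                    txt[1]))[[1]]
    if (length(m) != 3) {
      stop(sprintf("%s:1: malformed layer header", p), call. = FALSE)
    }
    layer <- as.integer(m[2]); modes[as.character(layer)] <- m[3]
    frame_hdr <- grepl("^# frame ", txt)
    fm <- regmatches(txt[frame_hdr],
                     regexec("^# frame ([0-9]+) t0 ([0-9.eE+-]+)$",
                             txt[frame_hdr]))
    bad <- which(lengths(fm) != 3)
    if (length(bad)) {
      stop(sprintf("%s:%d: malformed frame header", p,
                   which(frame_hdr)[bad[1]]), call. = FALSE)
    }
    f_ids <- vapply(fm, function(z) as.integer(z[2]), 1L)
    f_t0 <- vapply(fm, function(z) as.numeric(z[3]), 1)
    n_frames <- max(n_frames, f_ids, 0L)
    t0[as.character(f_ids)] <- f_t0
    data_ln <- which(!hdr & nzchar(trimws(txt)))
    if (length(data_ln)) {
      fields <- strsplit(trimws(txt[data_ln]), "[[:space:]]+")
      nf <- lengths(fields)
      if (any(nf != 3)) {
        stop(sprintf("%s:%d: expected 'col row value'", p,
                     data_ln[which(nf != 3)[1]]), call. = FALSE)
      }
      v <- suppressWarnings(as.integer(unlist(fields)))
      if (anyNA(v)) {
        stop(sprintf("%s:%d: non-integer field", p,
                     data_ln[ceiling(which(is.na(v))[1] / 3)]), call. = FALSE)
      }
      v <- matrix(v, ncol = 3, byrow = TRUE)
      # frame id for each data line: last frame header above it
      fh_pos <- which(frame_hdr)
      frame_of <- f_ids[findInterval(data_ln, fh_pos)]
      if (anyNA(frame_of)) {
        stop(sprintf("%s:%d: pixel data before first frame header", p,
                     data_ln[1]), call. = FALSE)
      }
      bad_idx <- v[, 1] < 0 | v[, 1] > 255 | v[, 2] < 0 | v[, 2] > 255
      if (any(bad_idx)) {
        stop(sprintf("%s:%d: pixel index out of range", p,
                     data_ln[which(bad_idx)[1]]), call. = FALSE)
      }
      if (any(v[, 3] < 1 | v[, 3] > counter_max)) {
        stop(sprintf("%s:%d: value outside [1, %d]", p,
                     data_ln[which(v[, 3] < 1 | v[, 3] > counter_max)[1]],
                     counter_max), call. = FALSE)
      }
      out[[length(out) + 1]] <- tibble::tibble(
        layer = layer, frame = frame_of, col = v[, 1], row = v[, 2],
        value = v[, 3])
    }
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    res <- tibble::tibble(layer = integer(), frame = integer(),
                          col = integer(), row = integer(), value = integer())
  }
  res <- res[order(res$layer, res$frame, res$col, res$row), ]
  attr(res, "modes") <- modes
  attr(res, "n_frames") <- n_frames
  attr(res, "t0") <- t0
  res
}

#' Round-trippable run-configuration file
#'
#' Serialises the beam, phantom, layer table, acquisition, artifact and cut
#' configuration to a structured YAML text file, and reads it back into the
#' same objects.
#'
#' @param config Named list with any of `beam`, `phantom`, `layers`,
#'   `acquisition`, `artifacts`, `cuts`.
#' @param path File path.
#' @return `read_run_config()` returns the named list of rebuilt objects.
#' @export
write_run_config <- function(config, path) {
  ser <- list()
  if (!is.null(config$beam)) {
    b <- config$beam
    ser$beam <- list(species = b$species$name,
                     energy_per_nucleon = b$energy_per_nucleon, fwhm = b$fwhm,
                     mean_ions_per_frame = b$mean_ions_per_frame,
                     center = b$center)
  }
  if (!is.null(config$phantom)) {
    p <- config$phantom
    ser$phantom <- list(material = p$material$name, length = p$length,
                        step_thickness = p$step_thickness,
                        step_material = p$step_material$name,
                        step_edge_x = p$step_edge_x,
                        step_depth_center = p$step_depth_center,
                        fragmentation_prob = p$fragmentation_prob,
                        upstream_z = p$upstream_z)
  }
  if (!is.null(config$layers)) {
    ser$layers <- lapply(as.list(as.data.frame(config$layers)), identity)
  }
  for (nm in c("acquisition", "artifacts", "cuts")) {
    if (!is.null(config[[nm]])) ser[[nm]] <- unclass(config[[nm]])
  }
  writeLines(yaml::as.yaml(ser), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  ser <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(ser$beam)) out$beam <- do.call(beam_spec, ser$beam)
  if (!is.null(ser$phantom)) out$phantom <- do.call(phantom_spec, ser$phantom)
  if (!is.null(ser$layers)) {
    lt <- tibble::as_tibble(ser$layers)
    out$layers <- layer_table(z = lt$z, bias_voltage = lt$bias_v[1],
                              threshold = lt$threshold_kev[1],
                              readout_wet = lt$readout_wet_mm[1],
                              gain_sd = lt$gain_sd[1],
                              gain_seed = lt$gain_seed[1],
                              offsets = cbind(lt$offset_x_um, lt$offset_y_um))
  }
  if (!is.null(ser$acquisition)) out$acquisition <-
      do.call(acquisition_spec, ser$acquisition)
  if (!is.null(ser$artifacts)) out$artifacts <-
      do.call(artifact_config, ser$artifacts)
  if (!is.null(ser$cuts)) out$cuts <- do.call(cut_config, ser$cuts)
  out
}
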