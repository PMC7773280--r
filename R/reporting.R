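# Per-frame metrics, smoothing, and visual output: event overlays on the
# z-stack, maximum-intensity projections, and static event-review patches.

#' Centred simple moving average
#'
#' The window is truncated at the series boundaries, so the output has the
#' same length as the input and a constant series maps to itself.
#'
#' @param series numeric vector (non-empty).
#' @param window window size (>= 1).
#' @return Numeric vector, same length as `series`.
#' @export
moving_average <- function(series, window = 5L) {
  if (!length(series)) stop("empty series")
  if (window < 1L) stop("window must be >= 1")
  n <- length(series)
  h1 <- (window - 1L) %/% 2L
  h2 <- window - 1L - h1
  cs <- cumsum(c(0, series))
  lo <- pmax(seq_len(n) - h1, 1L)
  hi <- pmin(seq_len(n) + h2, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# default palette: fusion green, fission red, depolarisation blue
mel_palette <- function() {
  list(fusion = c(0, 1, 0), fission = c(1, 0, 0), depolarisation = c(0, 0.4, 1))
}

# solid marker ball, anisotropy-aware: radius (voxels) in-plane, scaled by
# dy/dz along z so the physical radius matches
marker_offsets <- function(radius, spacing) {
  rz <- max(radius * spacing[2] / spacing[1], 1e-6)
  r <- ceiling(c(rz, radius, radius))
  g <- expand.grid(dz = -r[1]:r[1], dy = -r[2]:r[2], dx = -r[3]:r[3])
  keep <- (g$dz / rz)^2 + (g$dy / radius)^2 + (g$dx / radius)^2 <= 1
  as.matrix(g[keep, , drop = FALSE])
}

#' Superimpose event markers on a frame as an RGB stack
#'
#' The grayscale frame is replicated into three channels (scaled to
#' `[0, 1]`) and a solid colour ball is drawn at each event location
#' (fusion green, fission red, depolarisation blue by default). Voxels
#' outside the marker balls keep identical channels.
#'
#' @param frame a [voxel_grid()] (normally the normalised Frame 1).
#' @param events event data frame with voxel coordinates on `frame`'s grid.
#' @param radius in-plane marker radius in voxels.
#' @param palette named list of RGB triplets in `[0, 1]` per event type.
#' @return A 4D numeric array `(z, y, x, channel)` in `[0, 1]`.
#' @export
render_overlay <- function(frame, events, radius = 2,
                           palette = mel_palette()) {
  d <- dim(frame$data)
  g <- frame$data / max(frame$intensity_range[2], 1e-12)
  rgb <- array(g, dim = c(d, 3))
  if (!is.null(events) && nrow(events)) {
    off <- marker_offsets(radius, frame$spacing)
    for (i in seq_len(nrow(events))) {
      ctr <- round(c(events$z_vox[i], events$y_vox[i], events$x_vox[i])) + 1L
      if (any(ctr < 1L) || any(ctr > d)) stop("event location out of bounds")
      col <- palette[[events$event_type[i]]]
      vox <- sweep(off, 2, ctr, "+")
      ok <- vox[, 1] >= 1L & vox[, 1] <= d[1] & vox[, 2] >= 1L &
        vox[, 2] <= d[2] & vox[, 3] >= 1L & vox[, 3] <= d[3]
      vox <- vox[ok, , drop = FALSE]
      for (ch in 1:3) rgb[cbind(vox, ch)] <- col[ch]
    }
  }
  rgb
}

#' Maximum-intensity projection over z
#'
#' @param x a [voxel_grid()], a 3D array, or a 4D `(z, y, x, channel)` array.
#' @return A `(y, x)` matrix, or `(y, x, channel)` array for RGB input.
#' @export
max_intensity_projection <- function(x) {
  a <- if (is_voxel_grid(x)) x$data else x
  if (length(dim(a)) == 3L) return(apply(a, c(2, 3), max))
  apply(a, c(2, 3, 4), max)
}

#' Write an RGB overlay stack as TIFF
#' @param rgb 4D `(z, y, x, channel)` array in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_overlay_tiff <- function(rgb, path) {
  d <- dim(rgb)
  pages <- lapply(seq_len(d[1]), function(z) {
    array(rgb[z, , , ], dim = c(d[2], d[3], d[4]))
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

# crop window centred on `ctr` (1-based), clamped so it stays inside [1, n]
clamp_window <- function(ctr, half, n) {
  w <- min(2L * half + 1L, n)
  lo <- max(1L, min(ctr - half, n - w + 1L))
  lo:(lo + w - 1L)
}

#' Export event-centred review patches
#'
#' For one event, crops Frame 1 and Frame 2 around the event location and
#' produces tinted versions in which the participating structures are
#' highlighted (red/green) on the frame where the pair lives: Frame 1 for
#' fusion, Frame 2 for fission, Frame 1 for depolarisation. Optionally
#' writes each z-slice of every patch as PNG.
#'
#' @param event one-row event data frame (grid coordinates of the processed
#'   frames).
#' @param frame1,frame2 normalised [voxel_grid()]s.
#' @param s1,s2 the frames' `mel_structure_set`s.
#' @param half_size half window size in voxels (in-plane; z is scaled by the
#'   spacing anisotropy, minimum 1).
#' @param dir optional output directory for per-slice PNGs.
#' @return List with `frame1`, `frame2` (grayscale crops) and
#'   `frame1_tinted`, `frame2_tinted` (RGB crops), plus the crop index
#'   ranges, invisibly when `dir` is given.
#' @export
export_event_patches <- function(event, frame1, frame2, s1, s2,
                                 half_size = 15L, dir = NULL) {
  stopifnot(nrow(event) == 1L)
  d <- dim(frame1$data)
  ctr <- round(c(event$z_vox, event$y_vox, event$x_vox)) + 1L
  if (any(ctr < 1L) || any(ctr > d)) stop("event location out of bounds")
  hz <- max(1L, as.integer(round(half_size * frame1$spacing[2] /
                                   frame1$spacing[1])))
  zi <- clamp_window(ctr[1], hz, d[1])
  yi <- clamp_window(ctr[2], half_size, d[2])
  xi <- clamp_window(ctr[3], half_size, d[3])
  mx <- max(frame1$intensity_range[2], 1e-12)
  crop1 <- frame1$data[zi, yi, xi, drop = FALSE] / mx
  crop2 <- frame2$data[zi, yi, xi, drop = FALSE] / mx
  tint <- function(crop, labels_crop, ids) {
    rgb <- array(crop, dim = c(dim(crop), 3))
    cols <- list(c(1, 0.2, 0.2), c(0.2, 1, 0.2))
    for (k in seq_along(ids)) {
      sel <- which(labels_crop == ids[k], arr.ind = TRUE)
      if (nrow(sel)) {
        col <- cols[[((k - 1L) %% 2L) + 1L]]
        for (ch in 1:3) {
          rgb[cbind(sel, ch)] <- 0.5 * rgb[cbind(sel, ch)] + 0.5 * col[ch]
        }
      }
    }
    rgb
  }
  ids1 <- parse_labels(event$labels_frame1)
  ids2 <- parse_labels(event$labels_frame2)
  lab1 <- s1$labels[zi, yi, xi, drop = FALSE]
  lab2 <- s2$labels[zi, yi, xi, drop = FALSE]
  out <- list(
    frame1 = crop1, frame2 = crop2,
    frame1_tinted = if (event$event_type != "fission") tint(crop1, lab1, ids1)
                    else array(crop1, dim = c(dim(crop1), 3)),
    frame2_tinted = if (event$event_type == "fission") tint(crop2, lab2, ids2)
                    else array(crop2, dim = c(dim(crop2), 3)),
    z = zi, y = yi, x = xi)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    base <- sprintf("f%03d_%s", event$frame_index, event$event_type)
    for (nm in c("frame1", "frame2", "frame1_tinted", "frame2_tinted")) {
      a <- out[[nm]]
      for (zz in seq_len(dim(a)[1])) {
        img <- if (length(dim(a)) == 3L) a[zz, , ] else
          array(a[zz, , , ], dim = dim(a)[2:4])
        png::writePNG(pmin(pmax(img, 0), 1),
                      file.path(dir, sprintf("%s_%s_z%02d.png", base, nm, zz)))
      }
    }
  }
  out
}

parse_labels <- function(s) {
  if (!nzchar(s)) return(integer(0))
  as.integer(strsplit(s, ";", fixed = TRUE)[[1]])
}
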