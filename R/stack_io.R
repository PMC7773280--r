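#' Read a time-lapse of z-stacks from TIFF
#'
#' Accepts either a single multi-page TIFF holding all frames
#' (pages ordered frame-major: frame 1 slices z1..zZ, frame 2 slices, ...)
#' or a directory of per-frame multi-page TIFFs (one file per frame, sorted
#' by file name). Intensities are read bit-exactly (`as.is`), never rescaled.
#'
#' Voxel spacing and the frame/slice split are taken, in order of precedence,
#' from (1) the explicit arguments, (2) a sidecar `<file>.meta.yaml` written
#' by [write_timelapse()], (3) ImageJ-style TIFF metadata (an ImageDescription
#' with `spacing=`/`slices=`/`frames=` plus x/y resolution in pixels per
#' micrometre). If no source yields a spacing, an error is raised.
#'
#' @param path a TIFF file or a directory of per-frame TIFF files.
#' @param spacing_override optional `(dz, dy, dx)` in micrometres; wins over
#'   any file metadata.
#' @param n_frames optional frame count for a single multi-page file whose
#'   metadata does not state it.
#' @param frame_interval seconds between consecutive frames (metadata in
#'   a sidecar wins over the default).
#' @return A [time_lapse()] object.
#' @export
read_timelapse <- function(path, spacing_override = NULL, n_frames = NULL,
                           frame_interval = 10) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (!length(files)) stop("no TIFF files found in directory: ", path)
    metas <- lapply(files, read_tiff_stack)
    dims <- lapply(metas, function(m) dim(m$data))
    if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
      stop("inconsistent dimensions across frame files")
    spacing <- resolve_spacing(spacing_override, sidecar_meta(files[[1]]),
                               metas[[1]]$meta)
    fi <- resolve_interval(frame_interval, sidecar_meta(files[[1]]))
    frames <- lapply(metas, function(m)
      voxel_grid(m$data, spacing, intensity_range = m$intensity_range))
    return(time_lapse(frames, fi))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  st <- read_tiff_stack(path)
  side <- sidecar_meta(path)
  spacing <- resolve_spacing(spacing_override, side, st$meta)
  fi <- resolve_interval(frame_interval, side)
  nt <- n_frames %||% side$frames %||% st$meta$frames %||% 1L
  nt <- as.integer(nt)
  nz_total <- dim(st$data)[1]
  if (nz_total %% nt != 0L)
    stop("page count ", nz_total, " is not divisible by n_frames ", nt)
  nz <- nz_total %/% nt
  frames <- lapply(seq_len(nt), function(t) {
    sl <- st$data[((t - 1L) * nz + 1L):(t * nz), , , drop = FALSE]
    voxel_grid(sl, spacing, intensity_range = st$intensity_range)
  })
  time_lapse(frames, fi)
}

#' Write a time-lapse to a multi-page TIFF (plus a metadata sidecar)
#'
#' Pages are written frame-major. Intensities are quantised to the grid's
#' integer `intensity_range` (8 or 16 bit); a `<file>.meta.yaml` sidecar
#' records spacing, slice/frame counts and the frame interval so that
#' [read_timelapse()] round-trips exactly.
#'
#' @param tl a [time_lapse()] object.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_timelapse <- function(tl, path) {
  stopifnot(inherits(tl, "mel_timelapse"))
  g1 <- tl$frames[[1]]
  maxv <- g1$intensity_range[2]
  bits <- if (maxv <= 255) 8L else 16L
  denom <- 2^bits - 1
  pages <- list()
  for (f in tl$frames) {
    d <- dim(f$data)
    for (z in seq_len(d[1])) {
      pg <- round(pmin(pmax(f$data[z, , ], 0), denom)) / denom
      pages[[length(pages) + 1L]] <- matrix(pg, d[2], d[3])
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  meta <- list(
    frames = length(tl$frames),
    slices = dim(g1$data)[1],
    spacing = as.numeric(g1$spacing),
    frame_interval = tl$frame_interval,
    intensity_range = as.numeric(g1$intensity_range),
    unit = "micron")
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".meta.yaml")

sidecar_meta <- function(path) {
  sp <- sidecar_path(path)
  if (file.exists(sp)) yaml::read_yaml(sp) else NULL
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Read one multi-page TIFF into a (z, y, x) array, keeping raw integers,
# and parse whatever ImageJ-style metadata the tags carry.
read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d2 <- dim(pages[[1]])[1:2]
  if (!all(vapply(pages, function(p) identical(dim(p)[1:2], d2), logical(1))))
    stop("inconsistent dimensions across TIFF pages")
  nz <- length(pages)
  a <- array(0, dim = c(nz, d2[1], d2[2]))
  for (z in seq_len(nz)) a[z, , ] <- pages[[z]]
  at <- attributes(pages[[1]])
  bits <- at$bits.per.sample %||% 16L
  meta <- parse_imagej_meta(at)
  list(data = a, meta = meta, intensity_range = c(0, 2^bits - 1))
}

# ImageJ writes "key=value" lines into ImageDescription and pixels-per-unit
# into the resolution tags; spacing= is the z-step in the stated unit.
parse_imagej_meta <- function(at) {
  out <- list()
  desc <- at$description
  if (!is.null(desc) && nzchar(desc)) {
    kv <- strsplit(strsplit(desc, "\n", fixed = TRUE)[[1]], "=", fixed = TRUE)
    for (p in kv) {
      if (length(p) == 2L) out[[trimws(p[1])]] <- trimws(p[2])
    }
  }
  meta <- list()
  if (!is.null(out$frames)) meta$frames <- as.integer(out$frames)
  if (!is.null(out$slices)) meta$slices <- as.integer(out$slices)
  dz <- if (!is.null(out$spacing)) as.numeric(out$spacing) else NA_real_
  xr <- at$x.resolution %||% NA_real_
  yr <- at$y.resolution %||% NA_real_
  if (is.finite(dz) && is.finite(xr) && is.finite(yr) && xr > 0 && yr > 0)
    meta$spacing <- c(dz, 1 / yr, 1 / xr)
  meta
}

resolve_spacing <- function(override, sidecar, embedded) {
  if (!is.null(override)) {
    s <- as.numeric(override)
    if (length(s) != 3L || any(s <= 0)) stop("spacing_override must be (dz, dy, dx) > 0")
    return(s)
  }
  if (!is.null(sidecar$spacing)) return(as.numeric(sidecar$spacing))
  if (!is.null(embedded$spacing)) return(as.numeric(embedded$spacing))
  stop("no voxel spacing available: supply spacing_override or file metadata")
}

resolve_interval <- function(default, sidecar) {
  as.numeric(sidecar$frame_interval %||% default)
}

#' Write detected events to CSV
#'
#' One row per event with both physical (micrometre) and voxel coordinates,
#' ordered deterministically by frame, event type, then location. Participant
#' label lists are `;`-separated.
#'
#' @param events an event table as returned by [detect_events()] (possibly
#'   row-bound over frame pairs), or an empty data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  cols <- c("frame_index", "event_type", "z_um", "y_um", "x_um",
            "z_vox", "y_vox", "x_vox", "labels_frame1", "labels_frame2")
  if (is.null(events) || !nrow(events)) {
    events <- empty_events()
  } else {
    stopifnot(all(cols %in% names(events)))
    events <- events[order(events$frame_index, events$event_type,
                           events$z_um, events$y_um, events$x_um), cols]
  }
  utils::write.csv(format_num_df(events[, cols]), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# fixed-precision numeric formatting so re-runs are byte-identical
format_num_df <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.6f", df[[nm]])
  }
  df
}

empty_events <- function() {
  data.frame(frame_index = integer(), event_type = character(),
             z_um = numeric(), y_um = numeric(), x_um = numeric(),
             z_vox = numeric(), y_vox = numeric(), x_vox = numeric(),
             labels_frame1 = character(), labels_frame2 = character(),
             stringsAsFactors = FALSE)
}

#' Read an event table written by [write_event_table()]
#' @param path CSV path.
#' @return A data frame of events.
#' @export
read_event_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(labels_frame1 = "character",
                                       labels_frame2 = "character"))
  df
}

#' Write per-frame-pair network metrics to CSV
#' @param metrics data frame of per-pair metrics (see [run_pipeline()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(metrics, path) {
  utils::write.csv(format_num_df(metrics), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
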