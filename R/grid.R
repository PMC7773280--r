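#' A single 3D intensity frame with physical voxel spacing
#'
#' The fundamental container of the package: one z-stack stored as a numeric
#' array indexed `[z, y, x]` together with its physical voxel spacing in
#' micrometres. Voxel indices are 0-based in all user-facing coordinates
#' (tables, event locations); internally R's 1-based indexing is used.
#' The physical coordinate of a voxel is its 0-based index times the spacing,
#' i.e. voxel centres sit on integer multiples of the spacing.
#'
#' @param data 3D numeric array, dimensions `(z, y, x)`, each >= 1.
#' @param spacing numeric length-3 `(dz, dy, dx)` in micrometres, all > 0.
#' @param intensity_range numeric length-2, the representable intensity range
#'   (e.g. `c(0, 255)` for 8-bit data). Defaults to `c(0, max(data))` when the
#'   data have a positive maximum, else `c(0, 1)`.
#' @return An object of class `mel_voxel_grid`.
#' @export
voxel_grid <- function(data, spacing, intensity_range = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3D array (z, y, x)")
  if (any(dim(data) < 1L)) stop("all data dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (dz, dy, dx)")
  if (is.null(intensity_range)) {
    mx <- suppressWarnings(max(data))
    intensity_range <- c(0, if (is.finite(mx) && mx > 0) mx else 1)
  }
  intensity_range <- as.numeric(intensity_range)
  if (length(intensity_range) != 2L || intensity_range[2] <= intensity_range[1])
    stop("intensity_range must be (min, max) with max > min")
  structure(
    list(data = data, spacing = spacing, intensity_range = intensity_range),
    class = "mel_voxel_grid")
}

#' @export
print.mel_voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mel_voxel_grid> %d x %d x %d (z,y,x), spacing %.4g/%.4g/%.4g um, range [%g, %g]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$intensity_range[1], x$intensity_range[2]))
  invisible(x)
}

is_voxel_grid <- function(x) inherits(x, "mel_voxel_grid")

#' An ordered sequence of z-stack frames
#'
#' @param frames list of [voxel_grid()] objects, all with identical dimensions
#'   and spacing.
#' @param frame_interval time between consecutive frames in seconds (> 0).
#' @return An object of class `mel_timelapse`.
#' @export
time_lapse <- function(frames, frame_interval = 10) {
  if (!length(frames) || !all(vapply(frames, is_voxel_grid, logical(1))))
    stop("frames must be a non-empty list of voxel_grid objects")
  d1 <- dim(frames[[1]]$data)
  s1 <- frames[[1]]$spacing
  for (f in frames) {
    if (!identical(dim(f$data), d1)) stop("inconsistent dimensions across frames")
    if (max(abs(f$spacing - s1)) > 1e-9) stop("inconsistent spacing across frames")
  }
  frame_interval <- as.numeric(frame_interval)
  if (!is.finite(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  structure(list(frames = frames, frame_interval = frame_interval),
            class = "mel_timelapse")
}

#' @export
print.mel_timelapse <- function(x, ...) {
  d <- dim(x$frames[[1]]$data)
  cat(sprintf("<mel_timelapse> %d frames of %d x %d x %d (z,y,x), interval %g s\n",
              length(x$frames), d[1], d[2], d[3], x$frame_interval))
  invisible(x)
}

#' @export
length.mel_timelapse <- function(x) length(x$frames)

#' Run configuration for event detection
#'
#' Collects every tunable of the pipeline with the defaults used throughout
#' the package. In-plane smoothing `sigma2d` is sensible between 0.5 and 1.5
#' pixels and the per-structure 3D blur `sigma3d` between 0.2 and 0.5 pixels
#' (both merely guidance, not enforced); a warning is emitted outside those
#' ranges.
#'
#' @param k_skip non-negative integer; number of intermediate frames skipped
#'   between Frame 1 and Frame 2 when pairing a time-lapse.
#' @param sigma2d in-plane Gaussian blur width in pixels applied per z-slice
#'   during normalisation.
#' @param sigma3d in-plane width (pixels) of the per-structure 3D blur; the
#'   z component is scaled by `dy/dz` so the physical blur radius is
#'   comparable across the anisotropic axes.
#' @param upscale_factor in-plane bilinear upscale factor (>= 1).
#' @param saturation_pct percentage of voxels clipped at each intensity tail
#'   by the contrast stretch.
#' @param min_voxels connected structures smaller than this many voxels
#'   (counted on the upscaled grid) are discarded as noise.
#' @param distance_threshold_um maximum feasible movement of a structure
#'   (micrometres) over a 10 s frame interval; scaled internally by
#'   `(frame_interval / 10) * (k_skip + 1)`.
#' @param pct_high relative overlap percentage strictly above which an
#'   association counts as "high".
#' @param blur_support_eps relative intensity (fraction of the per-structure
#'   blurred maximum) above which a voxel belongs to the blurred support.
#' @param deconvolve logical; run Richardson-Lucy deconvolution first.
#' @param psf_sigma optional `(z, y, x)` Gaussian PSF widths in voxels for
#'   deconvolution; when `NULL` they are derived from `na`, `lambda_nm`,
#'   `refractive_index` and the grid spacing.
#' @param rl_iterations Richardson-Lucy iteration count.
#' @param na,lambda_nm,refractive_index optics used to derive a PSF when
#'   `psf_sigma` is not given (numerical aperture, emission wavelength in nm,
#'   immersion refractive index).
#' @param third_structure_mode `"segment"` (default) samples the whole
#'   segment between a candidate pair for intervening structures;
#'   `"midpoint"` checks only the midway voxel.
#' @param seed integer seed for any stochastic stage (deconvolution and the
#'   deterministic core use none; kept for synthetic-data workflows).
#' @return An object of class `mel_config` (a named list).
#' @export
mel_config <- function(k_skip = 0L,
                       sigma2d = 1.0,
                       sigma3d = 0.25,
                       upscale_factor = 1.5,
                       saturation_pct = 0.3,
                       min_voxels = 40L,
                       distance_threshold_um = 1.0,
                       pct_high = 50,
                       blur_support_eps = 1e-3,
                       deconvolve = FALSE,
                       psf_sigma = NULL,
                       rl_iterations = 10L,
                       na = 1.46,
                       lambda_nm = 561,
                       refractive_index = 1.518,
                       third_structure_mode = c("segment", "midpoint"),
                       seed = 1L) {
  k_skip <- as.integer(k_skip)
  if (is.na(k_skip) || k_skip < 0L) stop("k_skip must be a non-negative integer")
  if (upscale_factor < 1) stop("upscale_factor must be >= 1")
  if (min_voxels < 0) stop("min_voxels must be >= 0")
  if (!(pct_high > 0 && pct_high < 100)) stop("pct_high must lie in (0, 100)")
  if (saturation_pct < 0 || saturation_pct >= 50)
    stop("saturation_pct must lie in [0, 50)")
  if (sigma2d < 0.5 || sigma2d > 1.5)
    warning("sigma2d outside the recommended range [0.5, 1.5] pixels")
  if (sigma3d < 0.2 || sigma3d > 0.5)
    warning("sigma3d outside the recommended range [0.2, 0.5] pixels")
  structure(list(
    k_skip = k_skip,
    sigma2d = sigma2d,
    sigma3d = sigma3d,
    upscale_factor = upscale_factor,
    saturation_pct = saturation_pct,
    min_voxels = as.integer(min_voxels),
    distance_threshold_um = distance_threshold_um,
    pct_high = pct_high,
    blur_support_eps = blur_support_eps,
    deconvolve = isTRUE(deconvolve),
    psf_sigma = psf_sigma,
    rl_iterations = as.integer(rl_iterations),
    na = na, lambda_nm = lambda_nm, refractive_index = refractive_index,
    third_structure_mode = match.arg(third_structure_mode),
    seed = as.integer(seed)), class = "mel_config")
}

#' Read a run configuration from YAML
#'
#' The YAML keys mirror the arguments of [mel_config()]; unknown keys are an
#' error so typos do not silently fall back to defaults.
#'
#' @param path path to a YAML file.
#' @return A `mel_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(mel_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(mel_config, vals)
}

# Effective distance threshold in micrometres for a given acquisition:
# the per-10 s budget scaled by the physical time separating the two frames.
effective_distance_um <- function(cfg, frame_interval = 10) {
  cfg$distance_threshold_um * (frame_interval / 10) * (cfg$k_skip + 1)
}

# Gaussian PSF sigma (z, y, x) in voxels, either user-supplied or derived
# from the optics via the usual widefield approximations
# sigma_xy = 0.21 * lambda / NA, sigma_z = 0.66 * lambda * n / NA^2.
psf_sigma_vox <- function(cfg, spacing) {
  if (!is.null(cfg$psf_sigma)) {
    s <- as.numeric(cfg$psf_sigma)
    if (length(s) != 3L || any(s < 0)) stop("psf_sigma must be (z, y, x) >= 0")
    return(s)
  }
  lam_um <- cfg$lambda_nm / 1000
  sxy_um <- 0.21 * lam_um / cfg$na
  sz_um <- 0.66 * lam_um * cfg$refractive_index / cfg$na^2
  c(sz_um / spacing[1], sxy_um / spacing[2], sxy_um / spacing[3])
}
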