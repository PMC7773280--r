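# ---- separable Gaussian filtering ------------------------------------------
# Blur is implemented as banded-matrix multiplies along each axis (BLAS does
# the heavy lifting). Rows of the band matrix are renormalised at the array
# boundary, which makes the filter constant-preserving.

gauss_band_matrix <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  offs <- -r:r
  w <- exp(-offs^2 / (2 * sigma^2))
  K <- matrix(0, n, n)
  idx <- seq_len(n)
  for (k in seq_along(offs)) {
    j <- idx + offs[k]
    ok <- j >= 1L & j <= n
    K[cbind(idx[ok], j[ok])] <- K[cbind(idx[ok], j[ok])] + w[k]
  }
  K / rowSums(K)
}

# Blur a (z, y, x) array along one axis (1 = z, 2 = y, 3 = x).
blur_along <- function(a, sigma, axis) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  K <- gauss_band_matrix(d[axis], sigma)
  if (axis == 1L) {
    dim(a) <- c(d[1], d[2] * d[3])
    a <- K %*% a
  } else if (axis == 2L) {
    a <- aperm(a, c(2, 1, 3))
    dim(a) <- c(d[2], d[1] * d[3])
    a <- K %*% a
    dim(a) <- c(d[2], d[1], d[3])
    a <- aperm(a, c(2, 1, 3))
  } else {
    dim(a) <- c(d[1] * d[2], d[3])
    a <- a %*% t(K)
  }
  dim(a) <- d
  a
}

# Full 3D Gaussian blur with per-axis sigmas (z, y, x), in voxel units.
blur_3d <- function(a, sigma_zyx) {
  a <- blur_along(a, sigma_zyx[3], 3L)
  a <- blur_along(a, sigma_zyx[2], 2L)
  blur_along(a, sigma_zyx[1], 1L)
}

# Per-slice 2D blur: smooth within each micrograph, never across z.
blur_2d_slices <- function(a, sigma) {
  a <- blur_along(a, sigma, 3L)
  blur_along(a, sigma, 2L)
}

# ---- bilinear in-plane upscaling -------------------------------------------

# Interpolation weights mapping output pixel centres onto input pixel centres.
bilinear_weights <- function(n_in, factor) {
  n_out <- ceiling(n_in * factor)
  u <- (seq_len(n_out) - 0.5) / factor + 0.5
  u <- pmin(pmax(u, 1), n_in)
  i0 <- pmin(floor(u), n_in - 1L)
  if (n_in == 1L) i0 <- rep(1L, n_out)
  w <- u - i0
  list(n_out = n_out, i0 = as.integer(i0),
       i1 = as.integer(pmin(i0 + 1L, n_in)), w = w)
}

# Upscale each z-slice of a (z, y, x) array by `factor` (bilinear); z untouched.
upscale_bilinear <- function(a, factor) {
  if (factor == 1) return(a)
  d <- dim(a)
  wy <- bilinear_weights(d[2], factor)
  wx <- bilinear_weights(d[3], factor)
  out <- array(0, dim = c(d[1], wy$n_out, wx$n_out))
  for (z in seq_len(d[1])) {
    s <- a[z, , ]
    s <- s[wy$i0, , drop = FALSE] * (1 - wy$w) + s[wy$i1, , drop = FALSE] * wy$w
    s <- s[, wx$i0, drop = FALSE] * rep(1 - wx$w, each = wy$n_out) +
      s[, wx$i1, drop = FALSE] * rep(wx$w, each = wy$n_out)
    out[z, , ] <- s
  }
  out
}

# ---- contrast stretch -------------------------------------------------------

# Clip `pct` percent of voxels at each intensity tail, then rescale linearly
# to [0, intensity_max]. A constant input maps to all zeros by definition so
# degenerate inputs pass through the pipeline.
contrast_stretch <- function(a, pct, intensity_max) {
  q <- stats::quantile(a, c(pct / 100, 1 - pct / 100), names = FALSE)
  # effectively-constant input (within float round-off of the upstream
  # filters) maps to zeros rather than amplifying numerical noise
  if (q[2] - q[1] <= 1e-9 * max(abs(q[2]), 1)) return(array(0, dim = dim(a)))
  out <- (a - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  out * intensity_max
}

# ---- Richardson-Lucy deconvolution -----------------------------------------

# Classic multiplicative Richardson-Lucy update with a (symmetric) Gaussian
# PSF; convolution reuses the separable blur above.
richardson_lucy <- function(a, sigma_zyx, iterations) {
  eps <- 1e-12
  obs <- pmax(a, 0)
  est <- pmax(a, eps)
  for (i in seq_len(iterations)) {
    ratio <- obs / pmax(blur_3d(est, sigma_zyx), eps)
    est <- est * blur_3d(ratio, sigma_zyx)
  }
  est
}

# ---- normalisation ----------------------------------------------------------

#' Normalise a raw z-stack frame
#'
#' Applies, in order: optional Richardson-Lucy deconvolution, in-plane
#' bilinear upscaling (z untouched; dy and dx divided by the factor),
#' per-slice 2D Gaussian smoothing, and a contrast stretch that clips
#' `saturation_pct` percent of voxels at each tail and rescales to the
#' frame's full intensity range.
#'
#' @param raw a [voxel_grid()].
#' @param cfg a [mel_config()].
#' @return A normalised `mel_voxel_grid` on the upscaled grid.
#' @export
normalise_frame <- function(raw, cfg = mel_config()) {
  stopifnot(is_voxel_grid(raw))
  a <- raw$data
  if (cfg$deconvolve)
    a <- richardson_lucy(a, psf_sigma_vox(cfg, raw$spacing), cfg$rl_iterations)
  a <- upscale_bilinear(a, cfg$upscale_factor)
  a <- blur_2d_slices(a, cfg$sigma2d)
  a <- contrast_stretch(a, cfg$saturation_pct, raw$intensity_range[2])
  spacing <- c(raw$spacing[1], raw$spacing[2:3] / cfg$upscale_factor)
  voxel_grid(a, spacing, intensity_range = raw$intensity_range)
}

# ---- automatic hysteresis thresholds ---------------------------------------

#' Automatic low/high hysteresis thresholds from the intensity histogram
#'
#' Builds a 256-bin histogram of the normalised intensities, smooths it with
#' a centred 5-bin moving average, locates the dominant peak in the lower
#' half of the intensity range (the background mode) and sets the low
#' threshold at the first local minimum after that peak — the edge of the
#' background valley. The high threshold is the halfway point between the
#' low threshold and the maximum observed intensity.
#'
#' @param norm a normalised [voxel_grid()] (>= 2 distinct intensities).
#' @param n_bins,smooth_window histogram resolution and smoothing window.
#' @return Named numeric `c(low, high)`.
#' @export
auto_hysteresis_thresholds <- function(norm, n_bins = 256L, smooth_window = 5L) {
  v <- as.numeric(norm$data)
  mn <- min(v); mx <- max(v)
  if (!(mx > mn)) stop("no background/foreground separation: constant image")
  counts <- tabulate(pmin(pmax(
    findInterval(v, seq(mn, mx, length.out = n_bins + 1L),
                 rightmost.closed = TRUE), 1L), n_bins), nbins = n_bins)
  sm <- moving_average(counts, smooth_window)
  centres <- mn + (seq_len(n_bins) - 0.5) * (mx - mn) / n_bins
  half <- max(1L, n_bins %/% 2L)
  peak <- which.max(sm[seq_len(half)])
  low <- NA_real_
  for (b in seq.int(peak + 1L, n_bins - 1L)) {
    if (sm[b] <= sm[b - 1L] && sm[b] <= sm[b + 1L]) {
      low <- centres[b]
      break
    }
  }
  if (!is.finite(low))
    stop("no background/foreground separation: no histogram valley found")
  high <- low + (mx - low) / 2
  c(low = low, high = high)
}

# ---- binarisation ----------------------------------------------------------

#' Hysteresis binarisation with small-structure removal
#'
#' Foreground is every voxel strictly above `high`, plus voxels in
#' `[low, high]` that connect (26-connectivity, through voxels `>= low`) to
#' a voxel above `high`. Connected components with fewer than `min_voxels`
#' voxels are then deleted.
#'
#' @param norm a normalised [voxel_grid()].
#' @param low,high hysteresis thresholds (`low < high`).
#' @param min_voxels minimum surviving component size in voxels.
#' @return A logical `(z, y, x)` array.
#' @export
binarise <- function(norm, low, high, min_voxels = 40L) {
  stopifnot(low < high)
  d <- dim(norm$data)
  mask <- .hysteresis_mask_3d(as.numeric(norm$data), as.integer(d), low, high)
  if (min_voxels > 0L) {
    lab <- .cc_label_3d(mask, as.integer(d))
    nmax <- max(lab)
    if (nmax > 0L) {
      sizes <- tabulate(lab, nbins = nmax)
      small <- which(sizes < min_voxels)
      if (length(small)) mask[lab %in% small] <- FALSE
    }
  }
  mask
}

# ---- structure sets ---------------------------------------------------------

# coordinates (z, y, x; 1-based) of TRUE voxels / positive labels, in
# raster-scan order of the linear index
which_coords <- function(idx, d) {
  z <- (idx - 1L) %% d[1] + 1L
  r <- (idx - 1L) %/% d[1]
  y <- r %% d[2] + 1L
  x <- r %/% d[2] + 1L
  cbind(z = z, y = y, x = x)
}

# 6-neighbour surface voxels: a labelled voxel with any face neighbour that
# carries a different label (or lies outside the volume) is an edge voxel.
edge_mask_6 <- function(lab) {
  d <- dim(lab)
  fg <- lab > 0L
  e <- array(FALSE, d)
  # volume boundary: every foreground voxel on an outer face is an edge
  e[c(1, d[1]), , ] <- fg[c(1, d[1]), , , drop = FALSE]
  e[, c(1, d[2]), ] <- e[, c(1, d[2]), , drop = FALSE] |
    fg[, c(1, d[2]), , drop = FALSE]
  e[, , c(1, d[3])] <- e[, , c(1, d[3]), drop = FALSE] |
    fg[, , c(1, d[3]), drop = FALSE]
  mark <- function(ia, ib) {
    # ia/ib: index lists of two face-adjacent slabs along one axis
    dif <- lab[ia[[1]], ia[[2]], ia[[3]], drop = FALSE] !=
      lab[ib[[1]], ib[[2]], ib[[3]], drop = FALSE]
    e[ia[[1]], ia[[2]], ia[[3]]] <<- e[ia[[1]], ia[[2]], ia[[3]], drop = FALSE] |
      (fg[ia[[1]], ia[[2]], ia[[3]], drop = FALSE] & dif)
    e[ib[[1]], ib[[2]], ib[[3]]] <<- e[ib[[1]], ib[[2]], ib[[3]], drop = FALSE] |
      (fg[ib[[1]], ib[[2]], ib[[3]], drop = FALSE] & dif)
  }
  if (d[1] > 1L) mark(list(2:d[1], 1:d[2], 1:d[3]),
                      list(1:(d[1] - 1L), 1:d[2], 1:d[3]))
  if (d[2] > 1L) mark(list(1:d[1], 2:d[2], 1:d[3]),
                      list(1:d[1], 1:(d[2] - 1L), 1:d[3]))
  if (d[3] > 1L) mark(list(1:d[1], 1:d[2], 2:d[3]),
                      list(1:d[1], 1:d[2], 1:(d[3] - 1L)))
  e
}

#' Label a binary stack and derive all per-structure arrays
#'
#' Connected components (26-connectivity) are labelled 1..N in raster-scan
#' order of each component's first voxel. For every structure the function
#' derives its voxel count, unweighted centroid, surface (edge) voxels, and
#' its blurred support: the voxels where the 3D-Gaussian-blurred indicator of
#' the structure exceeds `blur_support_eps` times its maximum. The blur is
#' anisotropic — sigma in z is scaled by `dy/dz` so the physical radius is
#' comparable across axes. Because overlap accounting must conserve volume,
#' supports are made disjoint: a structure keeps all of its own labelled
#' voxels, and any contested unlabelled voxel is assigned to the structure
#' with the largest blurred intensity there (ties to the lower label).
#'
#' @param mask logical `(z, y, x)` array (output of [binarise()]).
#' @param spacing `(dz, dy, dx)` of the (upscaled) grid in micrometres.
#' @param cfg a [mel_config()] (uses `sigma3d` and `blur_support_eps`).
#' @return An object of class `mel_structure_set` with fields `labels`
#'   (integer array), `support` (integer array of disjoint blurred supports),
#'   `n_structures`, `volumes`, `centroids` (N x 3, 1-based voxel coords),
#'   `edges` (list of integer matrices), `gar` (per-structure blurred crops
#'   with their bounding boxes, kept as diagnostic weights) and `spacing`.
#' @export
build_structure_set <- function(mask, spacing, cfg = mel_config()) {
  d <- dim(mask)
  labels <- .cc_label_3d(as.logical(mask), as.integer(d))
  n <- max(labels)
  sigma <- c(cfg$sigma3d * spacing[2] / spacing[1], cfg$sigma3d, cfg$sigma3d)
  pad <- pmax(1L, ceiling(3 * sigma))
  support <- array(0L, d)
  edges_arr <- edge_mask_6(labels)
  volumes <- integer(n)
  centroids <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("z", "y", "x")))
  edges <- vector("list", n)
  gar <- vector("list", n)
  if (n > 0L) {
    idx <- which(labels > 0L)
    lab_at <- labels[idx]
    co <- which_coords(idx, d)
    ord <- order(lab_at)
    lab_sorted <- lab_at[ord]
    co_sorted <- co[ord, , drop = FALSE]
    idx_sorted <- idx[ord]
    bounds <- c(0L, cumsum(tabulate(lab_sorted, nbins = n)))
    volumes <- diff(bounds)
    # contested-voxel resolution bookkeeping
    sup_idx <- vector("list", n)
    sup_w <- vector("list", n)
    for (i in seq_len(n)) {
      rows <- (bounds[i] + 1L):bounds[i + 1L]
      ci <- co_sorted[rows, , drop = FALSE]
      centroids[i, ] <- colMeans(ci)
      ei <- idx_sorted[rows][edges_arr[idx_sorted[rows]]]
      edges[[i]] <- which_coords(ei, d)
      # blurred indicator on a padded bounding box
      lo <- pmax(apply(ci, 2, min) - pad, 1L)
      hi <- pmin(apply(ci, 2, max) + pad, d)
      box <- array(0, dim = hi - lo + 1L)
      box[cbind(ci[, 1] - lo[1] + 1L, ci[, 2] - lo[2] + 1L,
                ci[, 3] - lo[3] + 1L)] <- 1
      g <- blur_3d(box, sigma)
      gar[[i]] <- list(bbox_min = lo, values = g)
      keep <- which(g > cfg$blur_support_eps * max(g))
      kco <- which_coords(keep, dim(g))
      gz <- kco[, 1] + lo[1] - 1L
      gy <- kco[, 2] + lo[2] - 1L
      gx <- kco[, 3] + lo[3] - 1L
      sup_idx[[i]] <- gz + d[1] * (gy - 1L + d[2] * (gx - 1L))
      sup_w[[i]] <- g[keep]
    }
    # own voxels always win; otherwise highest blurred weight, ties to the
    # lower label
    vox <- unlist(sup_idx, use.names = FALSE)
    lab_of <- rep.int(seq_len(n), lengths(sup_idx))
    w <- unlist(sup_w, use.names = FALSE)
    w[labels[vox] == lab_of] <- Inf
    ordv <- order(vox, -w, lab_of)
    first <- !duplicated(vox[ordv])
    support[vox[ordv][first]] <- lab_of[ordv][first]
  }
  structure(list(labels = labels, support = support, n_structures = n,
                 volumes = as.integer(volumes), centroids = centroids,
                 edges = edges, gar = gar, spacing = as.numeric(spacing)),
            class = "mel_structure_set")
}

#' @export
print.mel_structure_set <- function(x, ...) {
  cat(sprintf("<mel_structure_set> %d structures, %d foreground voxels\n",
              x$n_structures, sum(x$volumes)))
  invisible(x)
}

#' Voxel coordinates of one labelled structure
#' @param ss a `mel_structure_set`.
#' @param i structure label (1..N).
#' @return Integer matrix of `(z, y, x)` coordinates (1-based).
#' @export
structure_voxels <- function(ss, i) {
  which_coords(which(ss$labels == i), dim(ss$labels))
}

#' Run the full pre-processing chain on one raw frame
#'
#' Normalisation, automatic threshold selection, hysteresis binarisation and
#' structure-set construction in one call; the result feeds
#' [compare_frames()] and [detect_events()].
#'
#' @param raw a raw [voxel_grid()].
#' @param cfg a [mel_config()].
#' @return An object of class `mel_frame`: `norm` (normalised grid),
#'   `thresholds`, `mask`, and `structures`.
#' @export
preprocess_frame <- function(raw, cfg = mel_config()) {
  norm <- normalise_frame(raw, cfg)
  th <- auto_hysteresis_thresholds(norm)
  mask <- binarise(norm, th["low"], th["high"], cfg$min_voxels)
  ss <- build_structure_set(mask, norm$spacing, cfg)
  structure(list(norm = norm, thresholds = th, mask = mask, structures = ss),
            class = "mel_frame")
}

#' @export
print.mel_frame <- function(x, ...) {
  cat(sprintf("<mel_frame> thresholds [%.3g, %.3g], %d structures\n",
              x$thresholds["low"], x$thresholds["high"],
              x$structures$n_structures))
  invisible(x)
}
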