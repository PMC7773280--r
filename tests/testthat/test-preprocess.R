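test_that("normalisation preserves constants and scales the grid as specified", {
  g <- voxel_grid(array(7, c(4, 16, 16)), c(0.5, 0.1, 0.1),
                  intensity_range = c(0, 255))
  out <- normalise_frame(g, mel_config())
  # constant input: upscale/blur preserve the constant, stretch maps it to 0
  expect_equal(dim(out$data), c(4, 24, 24))
  expect_true(all(out$data == 0))
  expect_equal(out$spacing, c(0.5, 0.1 / 1.5, 0.1 / 1.5))
})

test_that("contrast stretch clips exactly the percentile tails (sorted-list oracle)", {
  set.seed(42)
  d <- c(6, 20, 20)
  v <- stats::rlnorm(prod(d), 3, 0.4)
  # plant a 0.3% block of extreme outliers at the top
  v[seq_len(ceiling(0.003 * length(v)))] <- max(v) * 50
  g <- voxel_grid(array(v, d), c(0.5, 0.1, 0.1), intensity_range = c(0, 255))
  cfg <- mel_config(upscale_factor = 1, sigma2d = 0.5, saturation_pct = 0.3)
  suppressWarnings(out <- normalise_frame(g, mel_config(
    upscale_factor = 1, sigma2d = 1e-9, saturation_pct = 0.3)))
  expect_equal(as.numeric(out$data), or_stretch(v, 0.3, 255), tolerance = 1e-9)
  # the outlier block saturates at the new maximum
  expect_true(all(out$data[seq_len(ceiling(0.003 * length(v)))] == 255))
})

test_that("bilinear upscaling hits ceil(n * factor) and preserves linear ramps", {
  d <- c(2, 16, 16)
  ramp <- array(rep(seq(0, 150, length.out = 16), each = 2 * 16), d) # ramp in x
  g <- voxel_grid(ramp, c(0.5, 0.1, 0.1), intensity_range = c(0, 255))
  suppressWarnings(out <- normalise_frame(g, mel_config(
    upscale_factor = 1.5, sigma2d = 1e-9, saturation_pct = 0)))
  expect_equal(dim(out$data), c(2, 24, 24))
  # a linear ramp stays monotone and (away from clamped borders) linear
  prof <- out$data[1, 12, ]
  expect_true(all(diff(prof) >= 0))
  expect_equal(diff(prof[4:21]), rep(diff(prof[4:5]), 17), tolerance = 1e-6)
})

test_that("automatic thresholds follow the valley/midpoint rule", {
  d <- c(16, 16, 16)
  # two-value image: 99% background at 0, 1% objects at 200
  a <- array(0, d)
  a[seq_len(round(0.01 * prod(d)))] <- 200
  g <- voxel_grid(a, c(0.5, 0.1, 0.1), intensity_range = c(0, 255))
  th <- auto_hysteresis_thresholds(g)
  # derived from the smoothed 256-bin histogram: the first all-zero bin
  # after the background spike is bin 4, whose centre is 3.5 * 200 / 256
  expect_equal(unname(th["low"]), 3.5 * 200 / 256, tolerance = 1e-9)
  expect_equal(unname(th["high"]), th[["low"]] + (200 - th[["low"]]) / 2)
  expect_true(th["low"] > 0 && th["low"] < 200)
  # constant image: no separation
  expect_error(auto_hysteresis_thresholds(zero_grid()), "separation")
})

test_that("thresholds land in the valley of a bimodal intensity mixture", {
  set.seed(7)
  d <- c(12, 24, 24)
  n <- prod(d)
  v <- c(stats::rnorm(round(0.9 * n), 20, 4),
         stats::rnorm(n - round(0.9 * n), 200, 12))
  v <- pmin(pmax(v, 0), 255)
  g <- voxel_grid(array(v, d), c(0.5, 0.1, 0.1), intensity_range = c(0, 255))
  th <- auto_hysteresis_thresholds(g)
  # brute-force scan of the same smoothed histogram for its global valley
  counts <- tabulate(pmin(pmax(findInterval(
    v, seq(min(v), max(v), length.out = 257), rightmost.closed = TRUE),
    1L), 256L), nbins = 256L)
  sm <- stats::filter(counts, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- 0
  centres <- min(v) + (seq_len(256) - 0.5) * (max(v) - min(v)) / 256
  inter <- centres > 20 & centres < 200
  valley <- centres[inter][which.min(sm[inter])]
  expect_gt(th["low"], 20)
  expect_lt(th["low"], 200)
  expect_lt(abs(th[["low"]] - valley), 40) # same valley region
  expect_equal(unname(th["high"]), th[["low"]] + (max(v) - th[["low"]]) / 2)
})

test_that("hysteresis keeps connected mid-intensity halos and drops isolated specks", {
  d <- c(10, 24, 24)
  a <- array(0, d)
  a <- put_box(a, 4:6, 8:12, 8:12, 250)   # core above high
  a <- put_box(a, 4:6, 13:15, 8:12, 150)  # halo in [low, high], attached
  a <- put_box(a, 4:6, 20:22, 20:22, 150) # isolated speck in [low, high]
  g <- voxel_grid(a, c(0.5, 0.1, 0.1), intensity_range = c(0, 255))
  m <- binarise(g, low = 100, high = 200, min_voxels = 0)
  expect_true(all(m[4:6, 8:15, 8:12]))
  expect_false(any(m[4:6, 20:22, 20:22]))
  expect_identical(unclass(m), or_hysteresis(a, 100, 200))
})

test_that("binarisation matches the reachability oracle on random volumes", {
  for (seed in 1:6) {
    d <- c(12, 16, 16)
    f <- or_smooth_field(d, seed)
    img <- (f - min(f)) / (max(f) - min(f)) * 255
    low <- unname(stats::quantile(img, 0.75))
    high <- unname(stats::quantile(img, 0.92))
    g <- voxel_grid(img, c(0.5, 0.1, 0.1), intensity_range = c(0, 255))
    expect_identical(unclass(binarise(g, low, high, min_voxels = 0)),
                     or_hysteresis(img, low, high))
  }
})

test_that("raising either threshold never adds foreground voxels", {
  d <- c(12, 16, 16)
  for (seed in 1:4) {
    f <- or_smooth_field(d, seed)
    img <- (f - min(f)) / (max(f) - min(f)) * 255
    g <- voxel_grid(img, c(0.5, 0.1, 0.1), intensity_range = c(0, 255))
    m0 <- binarise(g, 120, 180, min_voxels = 10)
    expect_true(all(binarise(g, 140, 180, min_voxels = 10) <= m0))
    expect_true(all(binarise(g, 120, 200, min_voxels = 10) <= m0))
  }
})

test_that("the small-structure filter removes components below the cutoff", {
  d <- c(8, 20, 20)
  a <- array(0, d)
  a <- put_box(a, 3, 2:4, 2:14, 250)  # 1 x 3 x 13 = 39 voxels
  a <- put_box(a, 6, 10:13, 2:11, 250) # 1 x 4 x 10 = 40 voxels
  g <- voxel_grid(a, c(0.5, 0.1, 0.1), intensity_range = c(0, 255))
  m <- binarise(g, 100, 200, min_voxels = 40)
  expect_false(any(m[3, , ]))
  expect_equal(sum(m), 40)
})

test_that("labelling matches the brute-force flood-fill oracle on random masks", {
  for (seed in 1:10) {
    mask <- or_random_mask(c(16, 16, 16), seed)
    ss <- build_structure_set(mask, c(0.5, 0.1, 0.1), mel_config())
    expect_identical(or_canonical(ss$labels), or_label_key(mask))
  }
})

test_that("structure sets report volumes, centroids and surfaces correctly", {
  d <- c(12, 24, 24)
  mask <- array(FALSE, d)
  mask[3:7, 3:7, 3:7] <- TRUE     # 5^3 cube
  mask[9:10, 15:18, 15:20] <- TRUE # 2 x 4 x 6 box
  ss <- build_structure_set(mask, c(0.5, 0.1, 0.1), mel_config())
  expect_equal(ss$n_structures, 2L)
  expect_equal(sort(ss$volumes), c(48L, 125L))
  cube_lab <- ss$labels[5, 5, 5]
  expect_equal(unname(ss$centroids[cube_lab, ]), c(5, 5, 5))
  # all 6-connected surface voxels of a 5^3 cube: 125 - 27 interior = 98
  expect_equal(nrow(ss$edges[[cube_lab]]), 98L)
  # neighbour-scan oracle for the surface
  cnt <- 0L
  for (z in 3:7) for (y in 3:7) for (x in 3:7) {
    nb <- rbind(c(z - 1, y, x), c(z + 1, y, x), c(z, y - 1, x),
                c(z, y + 1, x), c(z, y, x - 1), c(z, y, x + 1))
    if (any(!mask[nb])) cnt <- cnt + 1L
  }
  expect_equal(nrow(ss$edges[[cube_lab]]), cnt)
  # per-label volumes partition the foreground
  expect_equal(sum(ss$volumes), sum(mask))
  # labelling is deterministic
  ss2 <- build_structure_set(mask, c(0.5, 0.1, 0.1), mel_config())
  expect_identical(ss$labels, ss2$labels)
})

test_that("blurred supports contain their structures and stay disjoint", {
  for (seed in c(2, 5)) {
    mask <- or_random_mask(c(12, 16, 16), seed, frac = 0.15)
    suppressWarnings(cfg <- mel_config(sigma3d = 0.5))
    ss <- build_structure_set(mask, c(0.5, 0.1, 0.1), cfg)
    for (i in seq_len(ss$n_structures)) {
      own <- ss$labels == i
      expect_true(all(ss$support[own] == i)) # support superset of voxel set
    }
    # supports partition: one label per voxel by construction
    expect_true(all(ss$support[mask] > 0))
  }
})

test_that("richardson-lucy sharpening leaves planted events detectable", {
  sc <- make_event_scene(n_fusion = 1, n_fission = 0, n_depol = 1,
                         dim = c(32, 64, 64), radius = 3, gap = 8,
                         noise = "none", psf_sigma = c(0.5, 0.8, 0.8),
                         seed = 3)
  r <- render_scene(sc, seed = 3)
  cfg_on <- mel_config(deconvolve = TRUE, psf_sigma = c(0.5, 0.8, 0.8),
                       rl_iterations = 5L)
  for (cfg in list(mel_config(), cfg_on)) {
    res <- detect_events(r$timelapse$frames[[1]], r$timelapse$frames[[2]], cfg)
    m <- evaluate_detection(res$events, r$truth, 3, sc$spacing)
    expect_equal(m$recall, c(1, 1, 1))
    expect_equal(m$precision, c(1, 1, 1))
  }
})
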