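# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use different algorithms from the package internals
# (iterative label/reachability propagation instead of stack-based flood
# fill; hand-coded sorted-percentile interpolation instead of quantile()).

# 26-neighbour index matrix over the foreground voxels `idx` (linear,
# 1-based) of a volume with dimensions d; entries are positions within idx,
# NA where the neighbour is background or outside.
or_neighbours <- function(idx, d) {
  co <- arrayInd(idx, d)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  look <- rep(NA_integer_, prod(d))
  look[idx] <- seq_along(idx)
  nb <- matrix(NA_integer_, length(idx), nrow(offs))
  for (k in seq_len(nrow(offs))) {
    z <- co[, 1] + offs[k, 1]
    y <- co[, 2] + offs[k, 2]
    x <- co[, 3] + offs[k, 3]
    ok <- z >= 1 & z <= d[1] & y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
    lin <- z + d[1] * (y - 1) + d[1] * d[2] * (x - 1)
    nb[ok, k] <- look[lin[ok]]
  }
  nb
}

# Connected components by iterative minimum-label propagation; returns an
# array where every foreground voxel carries the minimum linear index of
# its component (a canonical labelling independent of scan order).
or_label_key <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  key <- array(0, d)
  if (!length(idx)) return(key)
  nb <- or_neighbours(idx, d)
  look <- rep(NA_integer_, prod(d))
  look[idx] <- seq_along(idx)
  lab <- as.numeric(idx)
  ok <- !is.na(nb)
  repeat {
    m <- matrix(Inf, length(idx), ncol(nb))
    m[ok] <- lab[nb[ok]]
    cand <- do.call(pmin, c(list(lab), asplit(m, 2)))
    # pointer jumping: adopt the representative's own current label
    cand <- pmin(cand, cand[look[cand]])
    if (identical(cand, lab)) break
    lab <- cand
  }
  key[idx] <- lab
  key
}

# map an arbitrary labelling to the same canonical form as or_label_key
or_canonical <- function(labels) {
  key <- array(0, dim(labels))
  idx <- which(labels > 0)
  if (!length(idx)) return(key)
  mins <- tapply(idx, labels[idx], min)
  key[idx] <- as.numeric(mins[as.character(labels[idx])])
  key
}

# hysteresis support by iterative reachability over voxels >= low, seeded
# at voxels > high
or_hysteresis <- function(img, low, high) {
  d <- dim(img)
  idx <- which(img >= low)
  out <- array(FALSE, d)
  if (!length(idx)) return(out)
  reach <- img[idx] > high
  nb <- or_neighbours(idx, d)
  repeat {
    nbre <- matrix(FALSE, length(idx), ncol(nb))
    ok <- !is.na(nb)
    nbre[ok] <- reach[nb[ok]]
    new <- reach | rowSums(nbre) > 0
    if (identical(new, reach)) break
    reach <- new
  }
  out[idx[reach]] <- TRUE
  out
}

# type-7 percentile by hand from the sorted values
or_quantile7 <- function(v, p) {
  s <- sort(v)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
}

# percentile-clipping contrast stretch straight from the definition
or_stretch <- function(v, pct, maxv) {
  qlo <- or_quantile7(v, pct / 100)
  qhi <- or_quantile7(v, 1 - pct / 100)
  out <- (v - qlo) / (qhi - qlo)
  pmin(pmax(out, 0), 1) * maxv
}

# smooth random scalar field (nearest-neighbour box smoothing, repeated)
or_smooth_field <- function(d, seed, times = 2) {
  set.seed(seed)
  a <- array(stats::rnorm(prod(d)), d)
  for (t in seq_len(times)) {
    for (ax in 1:3) {
      n <- d[ax]
      if (n < 3) next
      il <- c(1, seq_len(n - 1))
      ir <- c(seq_len(n - 1) + 1, n)
      a <- switch(ax,
                  (a[il, , , drop = FALSE] + a + a[ir, , , drop = FALSE]) / 3,
                  (a[, il, , drop = FALSE] + a + a[, ir, , drop = FALSE]) / 3,
                  (a[, , il, drop = FALSE] + a + a[, , ir, drop = FALSE]) / 3)
    }
  }
  a
}

# a blocky random binary mask with a controllable foreground fraction
or_random_mask <- function(d, seed, frac = 0.2) {
  f <- or_smooth_field(d, seed)
  f > stats::quantile(f, 1 - frac)
}

# small all-zero grid helper
zero_grid <- function(d = c(8, 16, 16), spacing = c(0.5, 0.1, 0.1)) {
  voxel_grid(array(0, d), spacing, intensity_range = c(0, 255))
}

# drop a rectangular blob of `value` into an array
put_box <- function(a, z, y, x, value = 250) {
  a[z, y, x] <- value
  a
}

# brute-force triple-loop overlap count between two support label fields
or_overlap <- function(sup1, sup2, n1, n2) {
  V <- matrix(0L, n1 + 1L, n2 + 1L, dimnames = list(0:n1, 0:n2))
  for (x in 0:n1) {
    for (y in 0:n2) {
      V[x + 1L, y + 1L] <- sum(sup1 == x & sup2 == y)
    }
  }
  V
}
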