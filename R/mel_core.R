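# The event-detection core: structures of Frame 1 and Frame 2 are associated
# by the voxel overlap of their blurred supports, candidate fusion partners
# (within Frame 1) and fission partners (within Frame 2) are collected by
# back-and-forth matching, and candidates are filtered on physical distance,
# intervening structures and relative overlap percentage.

#' Voxel-overlap matrix between two frames' structures
#'
#' Entry `V[x+1, y+1]` counts the voxels where the blurred support of
#' structure `x` in Frame 1 intersects the blurred support of structure `y`
#' in Frame 2; row and column 0 hold the overlap with background. Because
#' each frame's supports are disjoint by construction, every row `x >= 1`
#' sums exactly to the support volume of `x` (and columns mirror this).
#'
#' @param s1,s2 `mel_structure_set`s on identical grids.
#' @return Integer matrix of dimension `(N1 + 1) x (N2 + 1)` with dimnames
#'   `0..N1` / `0..N2`, class `mel_overlap`.
#' @export
compute_overlap_matrix <- function(s1, s2) {
  if (!identical(dim(s1$labels), dim(s2$labels)))
    stop("structure sets are on different grids")
  n1 <- s1$n_structures
  n2 <- s2$n_structures
  V <- matrix(0L, n1 + 1L, n2 + 1L, dimnames = list(0:n1, 0:n2))
  code <- s1$support + (n1 + 1L) * s2$support # pairs both labels in one int
  tab <- tabulate(code + 1L, nbins = (n1 + 1L) * (n2 + 1L))
  V[] <- tab
  class(V) <- c("mel_overlap", class(V))
  V
}

#' Forward/backward association lists from an overlap matrix
#'
#' `forward[[x]]` lists the Frame-2 structures whose support overlaps
#' structure `x` of Frame 1; `backward[[y]]` is the mirror. Background is
#' never associated.
#'
#' @param V an overlap matrix from [compute_overlap_matrix()].
#' @return A list with elements `forward` and `backward` (lists of integer
#'   vectors), class `mel_assoc`.
#' @export
build_associations <- function(V) {
  n1 <- nrow(V) - 1L
  n2 <- ncol(V) - 1L
  inner <- V[-1L, -1L, drop = FALSE]
  forward <- lapply(seq_len(n1), function(x) unname(which(inner[x, ] > 0L)))
  backward <- lapply(seq_len(n2), function(y) unname(which(inner[, y] > 0L)))
  structure(list(forward = forward, backward = backward), class = "mel_assoc")
}

#' Back-and-forth structure matching
#'
#' For each structure in Frame 1, follow its associations into Frame 2 and
#' back: every other Frame-1 structure reached this way is a fusion
#' candidate partner. The mirrored walk (Frame 2 -> Frame 1 -> Frame 2)
#' yields fission candidate partners. Both partner lists are symmetric.
#'
#' @param assoc a `mel_assoc` from [build_associations()].
#' @return List with `W1` (per Frame-1 structure, fusion partners) and `W2`
#'   (per Frame-2 structure, fission partners).
#' @export
back_and_forth_matching <- function(assoc) {
  W1 <- lapply(seq_along(assoc$forward), function(a) {
    back <- unlist(assoc$backward[assoc$forward[[a]]], use.names = FALSE)
    sort(unique(back[back != a]))
  })
  W2 <- lapply(seq_along(assoc$backward), function(b) {
    fwd <- unlist(assoc$forward[assoc$backward[[b]]], use.names = FALSE)
    sort(unique(fwd[fwd != b]))
  })
  list(W1 = W1, W2 = W2)
}

#' Relative percentage overlap of associated structures
#'
#' For each structure, the overlap volume with every associated structure in
#' the other frame is normalised by the combined overlap volume over all its
#' associations, giving percentages that sum to 100 per non-empty list.
#'
#' @param V overlap matrix.
#' @param assoc association lists.
#' @return List with `P1` and `P2`; each element is a named numeric vector
#'   (names = partner labels in the other frame).
#' @export
compute_overlap_percentages <- function(V, assoc) {
  P1 <- lapply(seq_along(assoc$forward), function(x) {
    ys <- assoc$forward[[x]]
    if (!length(ys)) return(stats::setNames(numeric(0), character(0)))
    v <- as.numeric(V[x + 1L, ys + 1L])
    stats::setNames(100 * v / sum(v), ys)
  })
  P2 <- lapply(seq_along(assoc$backward), function(y) {
    xs <- assoc$backward[[y]]
    if (!length(xs)) return(stats::setNames(numeric(0), character(0)))
    v <- as.numeric(V[xs + 1L, y + 1L])
    stats::setNames(100 * v / sum(v), xs)
  })
  list(P1 = P1, P2 = P2)
}

#' Shortest distance and midway point between two structures
#'
#' The minimum anisotropic Euclidean distance (micrometres) over all pairs of
#' surface voxels of the two structures, with the midway point of the
#' minimising voxel pair as the candidate event location. Distance ties are
#' broken by the lexicographically smallest voxel pair, which makes the
#' geometry deterministic.
#'
#' @param edges_a,edges_b integer matrices of `(z, y, x)` surface voxels
#'   (1-based), both non-empty.
#' @param spacing `(dz, dy, dx)` in micrometres.
#' @return List with `d_um`, `p_vox` (midway point, 1-based possibly
#'   half-integer), and the minimising voxels `a_vox`, `b_vox`.
#' @export
compute_pair_geometry <- function(edges_a, edges_b, spacing) {
  if (!nrow(edges_a) || !nrow(edges_b)) stop("empty edge set")
  res <- .min_edge_distance(edges_a, edges_b, as.numeric(spacing))
  list(d_um = res$d_um, p_vox = (res$a + res$b) / 2,
       a_vox = res$a, b_vox = res$b)
}

#' Depolarisation events: Frame-1 structures with no Frame-2 association
#'
#' A structure whose support overlaps nothing in Frame 2 (background only)
#' has lost its fluorescence signal and is reported as a depolarisation at
#' its unweighted centre of mass.
#'
#' @param assoc association lists.
#' @param s1 Frame-1 `mel_structure_set`.
#' @param frame_index index of Frame 1 in the time-lapse (1-based).
#' @return Event data frame (possibly empty).
#' @export
detect_depolarisation <- function(assoc, s1, frame_index = 1L) {
  gone <- which(lengths(assoc$forward) == 0L)
  if (!length(gone)) return(empty_events())
  loc <- s1$centroids[gone, , drop = FALSE]
  make_events(frame_index, "depolarisation", loc, s1$spacing,
              labels_f1 = as.character(gone), labels_f2 = rep("", length(gone)))
}

# assemble an event data frame from 1-based voxel locations
make_events <- function(frame_index, type, loc_vox, spacing,
                        labels_f1, labels_f2) {
  loc0 <- loc_vox - 1 # 0-based voxel coordinates
  data.frame(frame_index = as.integer(frame_index), event_type = type,
             z_um = loc0[, 1] * spacing[1], y_um = loc0[, 2] * spacing[2],
             x_um = loc0[, 3] * spacing[3],
             z_vox = loc0[, 1], y_vox = loc0[, 2], x_vox = loc0[, 3],
             labels_frame1 = labels_f1, labels_frame2 = labels_f2,
             stringsAsFactors = FALSE)
}

# unordered candidate pairs (a < b) from a symmetric partner list
candidate_pairs <- function(W) {
  out <- list()
  for (a in seq_along(W)) {
    bs <- W[[a]]
    bs <- bs[bs > a]
    if (length(bs)) out[[length(out) + 1L]] <- cbind(a = a, b = bs)
  }
  if (!length(out)) return(matrix(integer(0), 0, 2,
                                  dimnames = list(NULL, c("a", "b"))))
  do.call(rbind, out)
}

# TRUE when a structure other than `allowed` lies on the straight segment
# between two voxels (labels sampled at `step`-voxel increments)
third_structure_on_segment <- function(labels, from, to, allowed, step = 0.5) {
  delta <- to - from
  len <- sqrt(sum(delta^2))
  if (len == 0) return(FALSE)
  ts <- seq(0, 1, by = step / len)
  pts <- cbind(round(from[1] + ts * delta[1]),
               round(from[2] + ts * delta[2]),
               round(from[3] + ts * delta[3]))
  labs <- labels[pts]
  any(labs != 0L & labs != allowed[1] & labs != allowed[2])
}

#' Filter candidate pairs and classify fusion/fission events
#'
#' An unordered candidate pair survives when (1) the shortest distance
#' between the two structures does not exceed the distance threshold, (2) no
#' third structure lies between them (segment sampling by default), and
#' (3) both members share a common structure in the other frame with which
#' each has a relative overlap percentage strictly above `pct_high`
#' (high/low and low/low combinations are ignored). Each surviving pair
#' yields exactly one event at the pair's midway point; a structure with
#' several surviving partners produces one event per pair. Fusion pairs live
#' in Frame 1, fission pairs in Frame 2; both are attributed to Frame 1's
#' index since they state what Frame 1 is about to do.
#'
#' @param W partner lists from [back_and_forth_matching()].
#' @param P percentage lists from [compute_overlap_percentages()].
#' @param assoc association lists.
#' @param s1,s2 the two frames' structure sets.
#' @param cfg a [mel_config()].
#' @param distance_um effective distance threshold in micrometres.
#' @param frame_index index of Frame 1 in the time-lapse.
#' @return Event data frame with fusion and fission rows.
#' @export
filter_and_classify <- function(W, P, assoc, s1, s2, cfg = mel_config(),
                                distance_um = cfg$distance_threshold_um,
                                frame_index = 1L) {
  fuse <- classify_pairs(W$W1, P$P1, assoc$forward, s1, cfg, distance_um)
  fiss <- classify_pairs(W$W2, P$P2, assoc$backward, s2, cfg, distance_um)
  rows <- list()
  if (nrow(fuse$pairs)) {
    rows[[1]] <- make_events(
      frame_index, "fusion", fuse$loc, s1$spacing,
      labels_f1 = paste(fuse$pairs[, 1], fuse$pairs[, 2], sep = ";"),
      labels_f2 = fuse$targets)
  }
  if (nrow(fiss$pairs)) {
    rows[[length(rows) + 1L]] <- make_events(
      frame_index, "fission", fiss$loc, s2$spacing,
      labels_f1 = fiss$targets,
      labels_f2 = paste(fiss$pairs[, 1], fiss$pairs[, 2], sep = ";"))
  }
  if (!length(rows)) return(empty_events())
  do.call(rbind, rows)
}

# shared pair-filtering logic for one direction; `side_assoc` maps this
# frame's structures to their partners in the other frame
classify_pairs <- function(Wside, Pside, side_assoc, ss, cfg, distance_um) {
  pairs <- candidate_pairs(Wside)
  keep <- logical(nrow(pairs))
  loc <- matrix(numeric(0), 0, 3)
  targets <- character(0)
  if (nrow(pairs)) {
    locs <- matrix(NA_real_, nrow(pairs), 3)
    for (i in seq_len(nrow(pairs))) {
      a <- pairs[i, 1]; b <- pairs[i, 2]
      geom <- compute_pair_geometry(ss$edges[[a]], ss$edges[[b]], ss$spacing)
      if (geom$d_um > distance_um) next
      if (cfg$third_structure_mode == "segment") {
        if (third_structure_on_segment(ss$labels, geom$a_vox, geom$b_vox,
                                       c(a, b))) next
      } else {
        mid <- round(geom$p_vox)
        lab_mid <- ss$labels[matrix(mid, 1)]
        if (lab_mid != 0L && lab_mid != a && lab_mid != b) next
      }
      common <- intersect(side_assoc[[a]], side_assoc[[b]])
      common <- common[Pside[[a]][as.character(common)] > cfg$pct_high &
                       Pside[[b]][as.character(common)] > cfg$pct_high]
      if (!length(common)) next
      keep[i] <- TRUE
      locs[i, ] <- geom$p_vox
      targets <- c(targets, paste(sort(common), collapse = ";"))
    }
    loc <- locs[keep, , drop = FALSE]
  }
  list(pairs = pairs[keep, , drop = FALSE], loc = loc, targets = targets)
}

#' Compare two pre-processed frames and emit located events
#'
#' The core chain on already pre-processed frames: overlap matrix,
#' associations, back-and-forth matching, overlap percentages,
#' depolarisation detection and pair filtering. Useful when sliding along a
#' time-lapse, where each frame serves once as Frame 2 and once as Frame 1.
#'
#' @param pre1,pre2 `mel_frame` objects from [preprocess_frame()].
#' @param cfg a [mel_config()].
#' @param frame_interval seconds between the two frames (before skipping);
#'   scales the distance threshold.
#' @param frame_index index of Frame 1 in the time-lapse.
#' @return An object of class `mel_result`: `events` (data frame),
#'   `n_structures`, `total_volume_vox`, `average_volume_vox`,
#'   `frame_index`, plus the intermediate `V`, `assoc`, `W`, `P`.
#' @export
compare_frames <- function(pre1, pre2, cfg = mel_config(),
                           frame_interval = 10, frame_index = 1L) {
  s1 <- pre1$structures
  s2 <- pre2$structures
  V <- compute_overlap_matrix(s1, s2)
  assoc <- build_associations(V)
  W <- back_and_forth_matching(assoc)
  P <- compute_overlap_percentages(V, assoc)
  dist_um <- effective_distance_um(cfg, frame_interval)
  ev <- rbind(
    filter_and_classify(W, P, assoc, s1, s2, cfg, dist_um, frame_index),
    detect_depolarisation(assoc, s1, frame_index))
  ev <- ev[order(ev$frame_index, ev$event_type, ev$z_um, ev$y_um, ev$x_um), ]
  rownames(ev) <- NULL
  n <- s1$n_structures
  tot <- sum(s1$volumes)
  structure(list(
    frame_index = as.integer(frame_index), events = ev, n_structures = n,
    total_volume_vox = tot,
    average_volume_vox = if (n > 0) tot / n else 0,
    V = V, assoc = assoc, W = W, P = P), class = "mel_result")
}

#' @export
print.mel_result <- function(x, ...) {
  tb <- table(factor(x$events$event_type,
                     levels = c("fusion", "fission", "depolarisation")))
  cat(sprintf(
    "<mel_result> frame %d: %d fusion, %d fission, %d depolarisation; %d structures (mean volume %.1f vox)\n",
    x$frame_index, tb["fusion"], tb["fission"], tb["depolarisation"],
    x$n_structures, x$average_volume_vox))
  invisible(x)
}

#' Detect mitochondrial events between two raw frames
#'
#' End-to-end detection for one frame pair: both frames are pre-processed
#' (normalised, thresholded, binarised, segmented) and then compared. Running
#' the same pair in reversed order swaps the roles of fusion and fission
#' (depolarisation excluded — structure appearance is deliberately not an
#' event class).
#'
#' @param frame1,frame2 raw [voxel_grid()]s on identical grids.
#' @param cfg a [mel_config()].
#' @param frame_interval seconds separating the two frames.
#' @param frame_index index of `frame1` in its time-lapse.
#' @return A `mel_result`; see [compare_frames()].
#' @export
detect_events <- function(frame1, frame2, cfg = mel_config(),
                          frame_interval = 10, frame_index = 1L) {
  if (!identical(dim(frame1$data), dim(frame2$data)))
    stop("frames are on different grids")
  if (max(abs(frame1$spacing - frame2$spacing)) > 1e-9)
    stop("frames have different spacing")
  compare_frames(preprocess_frame(frame1, cfg), preprocess_frame(frame2, cfg),
                 cfg, frame_interval, frame_index)
}
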