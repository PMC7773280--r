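---
title: "Localising mitochondrial fission, fusion and depolarisation events in 3D"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localising mitochondrial fission, fusion and depolarisation events in 3D}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melr)
```

## The problem

Mitochondria form a dynamic network that continuously remodels through
fission (one structure separating into two), fusion (two structures joining
into one) and, under stress, depolarisation — the loss of membrane potential
that makes a structure disappear from a potential-dependent dye channel such
as TMRE. Live-cell confocal time-lapses of this network are 3D z-stacks
(typically a 0.5 µm z-step and ~0.1 µm pixels at 100x magnification)
acquired every ~10 s. Counting and, crucially, *localising* these events by
eye across a whole cell volume is impractical; `melr` automates it
deterministically, frame pair by frame pair.

Between two frames — Frame 1 at time *t* and Frame 2 at time *t* + Δ —
the package answers three questions: which Frame-1 structures are about to
fuse, which Frame-2 structures have just arisen by fission, and which
Frame-1 structures vanish entirely. Each detected event is assigned a 3D
location: the midway point between the two participating structures, or the
centre of mass of a vanishing one.

## The detection procedure

### Pre-processing

Each frame passes through four stages, in this fixed order:

1. **Deconvolution** (optional, off by default): Richardson–Lucy with a
   Gaussian PSF. The PSF width is either given directly (`psf_sigma`) or
   derived from the optics via σ~xy~ = 0.21 λ/NA and
   σ~z~ = 0.66 λ n/NA². Detection must not *depend* on this stage — the
   test suite exercises planted-event recovery with it both on and off.
2. **In-plane upscaling** by 1.5 (bilinear, per slice; z untouched). This
   reduces the chance that two adjacent but separate structures fuse during
   binarisation. Spacing is divided accordingly, so physical geometry is
   preserved.
3. **2D Gaussian smoothing** per slice (σ~2D~ = 1 pixel by default;
   useful range ≈ 0.5–1.5) to suppress noise before thresholding.
4. **Contrast stretching** clipping `saturation_pct` (default 0.3 %) of
   voxels at *each* intensity tail and rescaling linearly to the frame's
   intensity range. A constant frame is defined to map to all zeros, so
   degenerate inputs pass through the pipeline rather than erroring.

### Automatic hysteresis thresholds

Binarisation uses dual-threshold hysteresis: voxels above the high
threshold are object seeds; voxels between the thresholds join the object
only if connected (26-connectivity) to a seed through voxels at or above
the low threshold. The thresholds are chosen from the intensity histogram:
256 bins, smoothed with a centred 5-bin moving average. The low threshold
sits at the *edge of the background valley* — operationalised as the first
local minimum after the dominant peak in the lower half of the intensity
range (ties resolved to the lowest intensity). The high threshold is the
halfway point between the low threshold and the maximum observed intensity.

The "valley edge" could in principle mean the far (signal-side) boundary of
the valley instead; we fix the near-side first-local-minimum reading,
unit-test it as the module's contract, and expose the histogram resolution
and smoothing window as arguments for users who need to deviate. A frame
with no detectable valley (constant or unimodal histogram) raises an error
rather than guessing.

After binarisation, connected components smaller than `min_voxels`
(default 40, counted on the upscaled grid — equivalent to a blob of about
0.6 µm diameter at the default geometry) are removed as binarised noise.

### Per-structure arrays

Components are labelled 1..N in raster-scan order of each component's first
voxel, which makes labelling deterministic. For every structure we derive:

* its voxel set, volume and unweighted centroid;
* its **surface**: voxels with at least one 6-neighbour outside the
  structure. (On a binary stack, Canny-style edge detection degenerates to
  exactly this surface test, without gradient or non-maximum-suppression
  parameters.)
* its **blurred support**: the region where the 3D-Gaussian-blurred
  indicator of the structure exceeds `blur_support_eps` (10⁻³) of its
  maximum. The blur (σ~3D~ = 0.25 pixel in-plane; useful range 0.2–0.5) is
  anisotropic — σ~z~ is scaled by dy/dz so the physical radius is
  comparable across axes despite the coarse z-step. Blurring slightly
  inflates structures and is what lets moving structures still overlap
  across frames.

One numerical decision matters here. Supports of nearby structures within
a frame can overlap, which would break the conservation property that each
structure's overlap counts sum to its support volume. We therefore make
supports disjoint: a structure always keeps its own labelled voxels, and a
contested unlabelled voxel is assigned to the structure with the largest
blurred intensity there (ties to the lower label). This watershed-like
assignment retains the full blurred weights for diagnostics while making
overlap accounting exact.

### Association and back-and-forth matching

The overlap matrix V counts, for every Frame-1 structure x and Frame-2
structure y, the voxels their blurred supports share (row and column 0 are
the background). From V we read off association lists in both directions,
and collect candidate *pairs* by back-and-forth matching: from a Frame-1
structure, follow its associations into Frame 2 and back — every other
Frame-1 structure reached is a fusion candidate partner. The mirrored walk
gives fission candidate partners in Frame 2. Structures whose forward
association list is empty depolarise.

### Filtering

Candidate pairs are pruned by three independent filters:

* **Distance**: the shortest surface-to-surface distance (anisotropic
  Euclidean, in µm, computed from the edge voxel sets) must not exceed the
  movement budget. No published value exists for this budget; we default to
  1 µm per 10 s and scale it linearly with the actual time separation,
  `frame_interval/10 × (k_skip + 1)`. Ties in the minimising voxel pair are
  broken lexicographically so the event location is deterministic.
* **Intervening structure**: the straight segment between the minimising
  edge voxels is sampled at half-voxel steps; if any sample lands in a
  third labelled structure, the pair is discarded. This suppresses the
  classic false positive of two structures that each fuse with a structure
  lying *between* them. A midpoint-only variant
  (`third_structure_mode = "midpoint"`) is kept for comparison; segment
  sampling subsumes it.
* **Relative overlap percentage**: each structure's overlap volumes are
  normalised over its association list, giving percentages that sum to
  100. A pair becomes an event only if both members share a *common*
  partner structure in the other frame with which each has a relative
  overlap strictly above `pct_high` (default 50 %; empirically the shares
  are either very high or very low, so the split is insensitive). High/low
  and low/low combinations are ignored. The alternative reading — each
  member merely needing *some* high-percentage association — is rejected
  because it would pair structures that fuse with different targets.

Each surviving unordered pair yields exactly one event at the pair's
midway point. When n > 2 structures fuse into one target, all surviving
pairs are emitted (one location per pair): the pipeline is pair-native
(candidate lists, distances and midpoints are all pair-indexed), so the
per-pair reading of "separate locations for each" is the consistent one.
Fission events are located in Frame-2 geometry but attributed to Frame 1's
index — they state what Frame 1 is about to do. Depolarisations are placed
at the unweighted (binary) centroid of the vanished structure.

Time-reversal is an exact duality: running a pair in reversed order swaps
fusion and fission with identical locations and participants. Structure
*appearance* is deliberately not an event class, so depolarisation has no
mirror.

## Per-frame metrics and reporting

For every frame pair the package reports the Frame-1 structure count and
their combined and average volume (voxels), and smooths event-count series
with a centred five-frame simple moving average (window truncated at the
series boundaries). Overlays replicate the grayscale stack to RGB and draw
a solid colour ball per event — green for fusion, red for fission, blue
for depolarisation, radius 2 voxels in-plane scaled by the anisotropy in z
— plus maximum-intensity projections. For manual review, event-centred
crops of both frames are exported with the participating structures
tinted (on Frame 1 for fusion, Frame 2 for fission); interactive 3D
navigation is out of scope.

## The synthetic-data generator

Real recordings of this kind are not redistributable, so the package ships
a first-class scene generator that emulates the acquisition it targets:
bright tubular/blob structures (ellipsoids and capsules) on a dark
background, 0.5 µm z-steps with 0.1 µm pixels, an optical Gaussian blur,
and Poisson shot noise plus Gaussian read noise over a small constant
offset (defaults: background 8, read-noise σ 2, unit photon gain, peak
intensity 200 on an 8-bit scale — the high signal-to-noise regime of a
TMRE-style stain). Scenes are scripted: structures split (leaving a gap),
merge (closing one), vanish, or drift, and every scripted event is recorded
as ground truth at an exactly known location (the gap midpoint, or the
vanished structure's centroid). Rendering is deterministic given a seed.

`make_event_scene()` places fusing pairs, fission parents, vanishing and
static blobs on a jittered, widely separated lattice. Its default geometry
— blob radii of 0.4 µm in-plane and 1 µm axially, 0.8 µm event gaps —
keeps planted events inside the 1 µm movement budget while the gaps stay
cleanly resolvable after optical and detector blur. That resolvability is a
real constraint, not a convenience: on a noiseless render the automatic low
threshold settles very close to zero, so a 0.6 µm gap under a ~0.18 µm
effective blur can leave an above-threshold bridge and binarise as one
structure. The same geometry *with* realistic noise separates fine, because
the background raises the threshold. This mirrors the bridging
false-positive mode of real data and is why clean fixtures in the test
suite use the 0.8 µm gap.

Three dedicated fixtures probe the known failure modes: a sub-threshold
intensity bridge between near-touching structures (no event must fire), a
small structure moving beyond the distance budget (a false depolarisation
*is* expected — a documented limitation of overlap matching, matching the
low validated accuracy of depolarisation calls on real data), and the
A–C–B geometry where two structures fuse with an in-between third (the
segment filter must keep A–C and C–B but suppress A–B).

What passing on these scenes does **not** show: performance on dense,
entangled mitochondrial networks, genuine motility (our drift is rigid and
small), photobleaching, or focus drift. On real data a substantial fraction
of raw detections are false positives that require manual review — the
synthetic results bound the algorithmic, not the biological, error.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations to desk
scale: full-size clean scenes are 64×128×128 voxels with 3 fusion, 3
fission and 2 depolarisation events each (recovery must be perfect with
locations within 3 voxels); duality, null-stability and threshold-sweep
checks run on 32×64×64 scenes; oracle-equivalence checks on random 32³
volumes against independent iterative flood-fill/reachability
implementations. Tie-breaks (nearest-pair selection, support contests,
histogram minima) are all resolved deterministically, and re-running the
pipeline on identical input produces byte-identical tables.

Known limitations, beyond those of the generator: events are detected per
frame pair with no tracking across longer windows (a kiss-and-run therefore
scores one fusion then one fission, by design); small fast structures can
masquerade as depolarisation; binarisation bridges can create false
fusion/fission pairs, which the distance and intervening-structure filters
only partially remove; and the valley-edge threshold rule assumes a
bimodal intensity histogram — images without a clear background mode are
rejected rather than segmented badly.
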