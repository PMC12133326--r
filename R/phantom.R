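#' Specification of a synthetic vascular phantom
#'
#' Describes a 3D grayscale volume emulating high-resolution phase-contrast
#' tomography of lung biopsy tissue: tubular vessels consisting of a wall and
#' an interior lumen with distinct intensity peaks, embedded in a background
#' whose intensity histogram substantially overlaps the vessel histogram.
#' Vessels are grown as random-walk centerline tubes; `tortuosity` in
#' `[0, 1]` scales the angular deviation of successive centerline steps
#' (0 gives straight tubes).
#'
#' Default intensities (arbitrary units): background 0.35, wall 0.55,
#' lumen 0.75, with per-class Gaussian noise sd 0.12 — close enough that the
#' class histograms overlap heavily, as observed in real sparsely-labeled
#' tissue volumes, while remaining learnable.
#'
#' @param shape integer length-3, voxels per axis (z, y, x); all >= 8.
#' @param n_vessels number of vessels to grow (>= 0).
#' @param radius_range numeric length-2, min/max outer tube radius in voxels;
#'   the max must be below half the smallest volume extent.
#' @param wall_thickness wall thickness in voxels (lumen radius =
#'   outer radius - wall_thickness, floored at 0.5).
#' @param intensity_means named numeric: `background`, `wall`, `lumen` means.
#' @param intensity_sd per-class noise standard deviation (> 0); scalar or
#'   named like `intensity_means`.
#' @param tortuosity curvature parameter in `[0, 1]`.
#' @param seed integer; identical spec + seed gives bit-identical output.
#' @return an object of class `vssl_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L),
                         n_vessels = 4L,
                         radius_range = c(3, 6),
                         wall_thickness = 1.5,
                         intensity_means = c(background = 0.35, wall = 0.55, lumen = 0.75),
                         intensity_sd = 0.12,
                         tortuosity = 0.2,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stopf("shape must be 3 axes, each >= 8 voxels")
  if (length(radius_range) != 2L || radius_range[1] > radius_range[2] ||
      radius_range[1] <= 0)
    stopf("radius_range must be an increasing positive pair")
  if (radius_range[2] >= min(shape) / 2)
    stopf("degenerate spec: max vessel radius %.1f >= half the smallest extent (%d/2)",
          radius_range[2], min(shape))
  if (is.null(names(intensity_means)))
    names(intensity_means) <- c("background", "wall", "lumen")
  if (length(intensity_sd) == 1L)
    intensity_sd <- setNames(rep(intensity_sd, 3), names(intensity_means))
  if (any(intensity_sd <= 0)) stopf("intensity_sd must be > 0")
  if (tortuosity < 0 || tortuosity > 1) stopf("tortuosity must lie in [0, 1]")
  if (n_vessels < 0) stopf("n_vessels must be >= 0")
  structure(list(shape = shape, n_vessels = as.integer(n_vessels),
                 radius_range = as.numeric(radius_range),
                 wall_thickness = as.numeric(wall_thickness),
                 intensity_means = intensity_means, intensity_sd = intensity_sd,
                 tortuosity = as.numeric(tortuosity), seed = as.integer(seed)),
            class = "vssl_phantom_spec")
}

#' Rasterize a tube along a centerline
#'
#' Stamps spheres of the given radius at each centerline point; the union is
#' the voxelized tube.  This is the rasterizer [generate_phantom()] uses for
#' every vessel, exposed so tube geometry can be pinned directly (e.g. a
#' straight axis-aligned cylinder of radius r and length L covers close to
#' pi * r^2 * L voxels).
#'
#' @param shape volume shape (z, y, x).
#' @param centerline n x 3 matrix of (z, y, x) coordinates, 1-based voxel
#'   space.
#' @param radius tube outer radius in voxels.
#' @return integer 0/1 array of shape `shape`.
#' @export
vessel_tube_mask <- function(shape, centerline, radius) {
  mask <- array(0L, dim = shape)
  r <- ceiling(radius)
  off <- as.matrix(expand.grid(dz = -r:r, dy = -r:r, dx = -r:r))
  off <- off[rowSums(off^2) <= radius^2, , drop = FALSE]
  for (i in seq_len(nrow(centerline))) {
    pts <- sweep(off, 2, round(centerline[i, ]), "+")
    keep <- pts[, 1] >= 1 & pts[, 1] <= shape[1] &
            pts[, 2] >= 1 & pts[, 2] <= shape[2] &
            pts[, 3] >= 1 & pts[, 3] <= shape[3]
    p <- pts[keep, , drop = FALSE]
    if (nrow(p)) mask[p] <- 1L
  }
  mask
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# Random-walk centerline: unit steps whose direction deviates from the
# previous one by an angle controlled by tortuosity; 0 keeps it straight.
walk_centerline <- function(start, direction, n_steps, tortuosity, shape) {
  pts <- matrix(NA_real_, nrow = n_steps, ncol = 3)
  pos <- start
  dir <- direction / sqrt(sum(direction^2))
  for (i in seq_len(n_steps)) {
    pts[i, ] <- pos
    if (tortuosity > 0) {
      dir <- dir + tortuosity * 0.5 * rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
    }
    pos <- pos + dir
    if (any(pos < 1 - 2 | pos > shape + 2)) { pts <- pts[seq_len(i), , drop = FALSE]; break }
  }
  pts[!is.na(pts[, 1]), , drop = FALSE]
}

#' Generate a synthetic vascular phantom
#'
#' Draws `n_vessels` random-walk tube vessels, each with an outer wall and an
#' interior lumen, then samples voxel intensities per class
#' (background / wall / lumen) from Gaussians given by the spec.  The returned
#' dense mask marks wall plus lumen — everything inside the outer vessel wall.
#' Output is a pure function of the spec (including its seed).
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [new_volume()]), `labels` (dense
#'   [new_labels()], all slices annotated), and `lumen` (0/1 array, the lumen
#'   subset of the mask).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "vssl_phantom_spec"))
  stream <- rng_stream(spec$seed)
  shape <- spec$shape
  with_stream(stream, {
    vessel <- array(0L, dim = shape)
    lumen <- array(0L, dim = shape)
    for (v in seq_len(spec$n_vessels)) {
      radius <- runif(1, spec$radius_range[1], spec$radius_range[2])
      start <- c(runif(1, 1, shape[1]), runif(1, 1, shape[2]), runif(1, 1, shape[3]))
      dir <- random_unit_vector()
      n_steps <- max(shape) * 2L
      cl <- walk_centerline(start, dir, n_steps, spec$tortuosity, shape)
      vessel <- pmax(vessel, vessel_tube_mask(shape, cl, radius))
      lum_r <- max(radius - spec$wall_thickness, 0.5)
      lumen <- pmax(lumen, vessel_tube_mask(shape, cl, lum_r))
    }
    lumen <- lumen * vessel
    wall <- vessel - lumen
    n <- prod(shape)
    vol <- array(rnorm(n, spec$intensity_means[["background"]],
                       spec$intensity_sd[["background"]]), dim = shape)
    wall_noise <- rnorm(n, spec$intensity_means[["wall"]], spec$intensity_sd[["wall"]])
    lumen_noise <- rnorm(n, spec$intensity_means[["lumen"]], spec$intensity_sd[["lumen"]])
    vol[wall == 1L] <- wall_noise[wall == 1L]
    vol[lumen == 1L] <- lumen_noise[lumen == 1L]
    list(volume = new_volume(vol),
         labels = new_labels(array(as.numeric(vessel), dim = shape)),
         lumen = lumen)
  })
}

#' Slice-cadence annotation policy
#'
#' Emulates the practice of manually labeling every k-th slice of a volume and
#' optionally interpolating labels for the slices in between.
#'
#' @param cadence annotate every k-th slice (k >= 1); the first slice is always
#'   annotated.
#' @param interpolate fill non-annotated slices by nearest-neighbour shape
#'   interpolation between annotated slices.
#' @param completeness fraction of vessel voxels retained per annotated slice,
#'   in `[0, 1]` (1 = full annotation; lower values emulate partial labeling).
#' @return an object of class `vssl_annotation_policy`.
#' @export
annotation_policy <- function(cadence = 5L, interpolate = FALSE, completeness = 1) {
  if (cadence < 1) stopf("cadence must be >= 1")
  if (completeness < 0 || completeness > 1) stopf("completeness must lie in [0, 1]")
  structure(list(cadence = as.integer(cadence), interpolate = isTRUE(interpolate),
                 completeness = as.numeric(completeness)),
            class = "vssl_annotation_policy")
}

#' Sparsify a dense label mask to slice-cadence annotation
#'
#' Keeps labels on every k-th z-slice (optionally thinned to `completeness`),
#' zeroes the rest, and — if `interpolate` — refills the in-between slices by
#' copying the nearest annotated slice's labels (nearest-neighbour shape
#' interpolation).  With cadence 1, completeness 1 and no interpolation, the
#' output equals the input.  Output is a pure function of
#' `(labels, policy, seed)`.
#'
#' @param labels dense [new_labels()] or binary 3D array.
#' @param policy an [annotation_policy()].
#' @param seed seed for the completeness subsampling (unused when
#'   `completeness = 1`).
#' @return a [new_labels()] whose `annotated_slices` marks the cadence slices.
#' @export
sparsify_annotation <- function(labels, policy, seed = 0L) {
  stopifnot(inherits(policy, "vssl_annotation_policy"))
  mask <- as_mask_array(labels)
  if (!is_binary(mask)) stopf("mask must be binary")
  nz <- dim(mask)[1]
  if (policy$cadence > nz)
    stopf("cadence %d exceeds the number of slices (%d)", policy$cadence, nz)
  ann_idx <- seq(1L, nz, by = policy$cadence)
  annotated <- rep(FALSE, nz); annotated[ann_idx] <- TRUE
  out <- array(0, dim = dim(mask))
  stream <- rng_stream(seed)
  for (z in ann_idx) {
    sl <- mask[z, , ]
    if (policy$completeness < 1) {
      on <- which(sl == 1)
      keep <- with_stream(stream, {
        n_keep <- round(length(on) * policy$completeness)
        if (length(on)) sample(on, n_keep) else integer(0)
      })
      sl[] <- 0; sl[keep] <- 1
    }
    out[z, , ] <- sl
  }
  if (policy$interpolate && length(ann_idx) > 0L) {
    for (z in seq_len(nz)) {
      if (!annotated[z]) {
        nearest <- ann_idx[which.min(abs(ann_idx - z))]
        out[z, , ] <- out[nearest, , ]
      }
    }
  }
  new_labels(out, annotated_slices = annotated)
}
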