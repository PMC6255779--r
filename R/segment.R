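#' Extract a spherical volume of interest around a nodule
#'
#' Crops the bounding box of the spherical VOI centred on `center_mm` with
#' diameter `d + 1.5` mm for spheres and `d + 6.5` mm for spiked spheres,
#' and returns the in-VOI sphere mask; voxels outside the sphere are
#' excluded from clustering downstream.
#'
#' @param volume an [image_volume].
#' @param center_mm VOI centre (mm).
#' @param nodule a [nodule_spec] (determines the VOI diameter).
#' @return A list with `volume` (cropped [image_volume]) and `voi`
#'   ([binary_mask] of the in-VOI sphere on the cropped grid).
#' @export
extract_voi <- function(volume, center_mm, nodule) {
  stopifnot(inherits(volume, "image_volume"), inherits(nodule, "nodule_spec"))
  D <- voi_diameter(nodule)
  ax <- grid_axes(volume)
  idx <- lapply(1:3, function(a)
    which(ax[[a]] >= center_mm[a] - D / 2 - volume$spacing[a] / 2 &
          ax[[a]] <= center_mm[a] + D / 2 + volume$spacing[a] / 2))
  if (any(lengths(idx) == 0))
    stop("VOI lies entirely outside the volume", call. = FALSE)
  full <- vapply(1:3, function(a)
    length(idx[[a]]) >= floor(D / volume$spacing[a]), TRUE)
  if (!all(full) &&
      (ax[[1]][1] > center_mm[1] - D / 2 || max(ax[[1]]) < center_mm[1] + D / 2 ||
       ax[[2]][1] > center_mm[2] - D / 2 || max(ax[[2]]) < center_mm[2] + D / 2 ||
       ax[[3]][1] > center_mm[3] - D / 2 || max(ax[[3]]) < center_mm[3] + D / 2))
    warning("VOI extends beyond the volume; clipped")
  sub <- volume$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  dim(sub) <- vapply(idx, length, 1L)
  xs <- ax[[1]][idx[[1]]]; ys <- ax[[2]][idx[[2]]]; zs <- ax[[3]][idx[[3]]]
  r2 <- outer(outer((xs - center_mm[1])^2, (ys - center_mm[2])^2, "+"),
              (zs - center_mm[3])^2, "+")
  voi <- r2 <= (D / 2)^2
  origin <- c(xs[1], ys[1], zs[1])
  list(volume = image_volume(sub, volume$spacing, origin),
       voi = binary_mask(voi, volume$spacing, origin))
}

#' Two-cluster intensity threshold (1-D k-means)
#'
#' Partitions the VOI intensities into two clusters by Lloyd iteration
#' initialised at the minimum and maximum value (deterministic and
#' order-independent in 1-D). The foreground is the cluster with the higher
#' mean; the returned threshold is the midpoint of the final cluster means,
#' which always lies strictly between them.
#'
#' @param voi_values numeric vector of intensities (>= 2 distinct values).
#' @return A list with `threshold_hu`, `foreground` (logical selector
#'   aligned with `voi_values`) and `means` (the two cluster means,
#'   ascending).
#' @export
#' @examples
#' two_cluster_threshold(c(rep(-580, 100), rep(-110, 50)))$threshold_hu
two_cluster_threshold <- function(voi_values) {
  x <- as.numeric(voi_values)
  if (length(unique(x)) < 2)
    stop("degenerate input: need >= 2 distinct values", call. = FALSE)
  km <- kmeans(x, centers = matrix(c(min(x), max(x))), algorithm = "Lloyd",
               iter.max = 200)
  means <- sort(as.numeric(km$centers))
  hi <- which.max(km$centers)
  list(threshold_hu = mean(means), foreground = km$cluster == hi,
       means = means)
}

#' Keep only the component connected to the centre
#'
#' Retains the 26-connected component containing the voxel nearest
#' `center_mm`. If that voxel is background, the component of the nearest
#' foreground voxel within a 1-voxel radius is used; if there is none, an
#' empty mask is returned with a warning.
#'
#' @param mask a [binary_mask].
#' @param center_mm physical point (mm).
#' @return A [binary_mask] on the same grid.
#' @export
keep_connected_to_center <- function(mask, center_mm) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$values)
  if (!any(mask$values)) return(mask)
  ijk <- round(mm_to_index(mask, center_mm))
  ijk <- pmin(pmax(ijk, 0), d - 1)
  seed <- ijk[1] + d[1] * (ijk[2] + d[2] * ijk[3])
  if (!mask$values[seed + 1]) {
    # search the 26-neighbourhood for the nearest foreground voxel
    off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    off <- off[order(rowSums(off^2)), , drop = FALSE]
    found <- FALSE
    for (r in seq_len(nrow(off))) {
      q <- ijk + off[r, ]
      if (any(q < 0) || any(q > d - 1)) next
      s <- q[1] + d[1] * (q[2] + d[2] * q[3])
      if (mask$values[s + 1]) { seed <- s; found <- TRUE; break }
    }
    if (!found) {
      warning("no foreground voxel near the centre; returning empty mask")
      return(binary_mask(array(FALSE, d), mask$spacing, mask$origin))
    }
  }
  comp <- cpp_component_from_seed(as.logical(mask$values), d, as.integer(seed))
  binary_mask(array(comp, d), mask$spacing, mask$origin)
}

#' Segment a nodule with triplicate centre perturbation
#'
#' For each repeat, the seed centre is perturbed by a seeded uniform offset
#' within +/- one voxel per axis (repeat 1 is unperturbed), then the chain
#' VOI extraction -> two-cluster threshold -> connectivity filter is run.
#' Downstream volume and Dice reports average over the repeats, mirroring
#' triplicate manual seeding.
#'
#' @param volume an [image_volume] (a reconstructed/simulated acquisition).
#' @param center_mm nominal nodule centre (mm).
#' @param nodule a [nodule_spec].
#' @param repeats number of repeats (default 3).
#' @param perturb_mm per-axis perturbation bound (mm); default one voxel of
#'   `volume`.
#' @param seed integer seed for the perturbations.
#' @return A list of `segmentation_result` objects, each with elements
#'   `mask`, `center_used_mm`, `voi_diameter_mm`, `threshold_hu`,
#'   `repeat_index`.
#' @export
segment_nodule <- function(volume, center_mm, nodule, repeats = 3,
                           perturb_mm = NULL, seed = 1) {
  stopifnot(inherits(volume, "image_volume"), inherits(nodule, "nodule_spec"))
  if (is.null(perturb_mm)) perturb_mm <- volume$spacing
  perturb_mm <- rep_len(as.numeric(perturb_mm), 3)
  offsets <- local_seed(seed, {
    m <- matrix(0, nrow = repeats, ncol = 3)
    if (repeats > 1)
      for (r in 2:repeats) m[r, ] <- runif(3, -1, 1) * perturb_mm
    m
  })
  lapply(seq_len(repeats), function(r) {
    ctr <- center_mm + offsets[r, ]
    voi <- extract_voi(volume, ctr, nodule)
    inside <- voi$voi$values
    th <- two_cluster_threshold(voi$volume$values[inside])
    arr <- array(FALSE, dim(inside))
    arr[inside] <- th$foreground
    m <- binary_mask(arr, voi$volume$spacing, voi$volume$origin)
    m <- keep_connected_to_center(m, ctr)
    structure(list(mask = m, center_used_mm = ctr,
                   voi_diameter_mm = voi_diameter(nodule),
                   threshold_hu = th$threshold_hu, repeat_index = r),
              class = "segmentation_result")
  })
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> repeat %d: %d voxels (%.3f mm^3), VOI %.1f mm, threshold %.1f HU\n",
              x$repeat_index, sum(x$mask$values),
              sum(x$mask$values) * prod(x$mask$spacing),
              x$voi_diameter_mm, x$threshold_hu))
  invisible(x)
}
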