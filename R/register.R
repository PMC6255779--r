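#' Upsample a mask to an isotropic grid
#'
#' Cubic interpolation of the 0/1 field followed by re-binarisation at 0.5,
#' onto an isotropic grid of `target_mm` (default 0.14 mm, a common choice
#' fine enough for both 0.25 mm and 0.625 mm slice spacings). Physical
#' extent is preserved. Masks from different reconstruction grids land on
#' comparable grids, making voxel counts and overlaps commensurable.
#'
#' @param mask a [binary_mask].
#' @param target_mm isotropic target spacing (mm), > 0.
#' @return A [binary_mask] on the isotropic grid.
#' @export
upsample_isotropic <- function(mask, target_mm = 0.14) {
  stopifnot(inherits(mask, "binary_mask"))
  if (target_mm <= 0) stop("`target_mm` must be > 0", call. = FALSE)
  if (all(abs(mask$spacing - target_mm) < 1e-12)) return(mask)
  vol <- image_volume(array(as.double(mask$values), dim(mask$values)),
                      mask$spacing, mask$origin)
  out <- resample(vol, rep(target_mm, 3), method = "cubic")
  binary_mask(out$values >= 0.5, out$spacing, out$origin)
}

# Resample a mask onto the grid of `target` (same-orientation grids),
# cubic interpolation of the 0/1 field, re-binarised at 0.5.
resample_mask_to_grid <- function(mask, target, method = "cubic") {
  g <- as_grid(target)
  v <- array(as.double(mask$values), dim(mask$values))
  dims <- dim(v)
  m <- if (method == "linear") 0L else 1L
  for (a in 1:3) {
    pos <- (g$origin[a] + (seq_len(g$shape[a]) - 1) * g$spacing[a] -
            mask$origin[a]) / mask$spacing[a]
    v <- cpp_resample_axis(as.double(v), dims, a, pos, m)
    dims[a] <- g$shape[a]
  }
  binary_mask(array(v >= 0.5, dims), g$spacing, g$origin)
}

#' Rigidly rotate a mask about its centroid
#'
#' Rotation about the x, then y, then z axis by the given angles, on an
#' isotropic grid; the 0/1 field is sampled with trilinear interpolation
#' and re-binarised at 0.5.
#'
#' @param mask a [binary_mask] with isotropic spacing.
#' @param angles_deg rotations about the x, y and z axes (degrees).
#' @return The rotated [binary_mask] on the same grid.
#' @export
rotate_mask <- function(mask, angles_deg) {
  stopifnot(inherits(mask, "binary_mask"))
  if (diff(range(mask$spacing)) > 1e-9)
    stop("`mask` must be on an isotropic grid (see upsample_isotropic)",
         call. = FALSE)
  angles_deg <- rep_len(as.numeric(angles_deg), 3)
  if (any(!is.finite(angles_deg))) stop("angles must be finite", call. = FALSE)
  if (all(angles_deg == 0)) return(mask)
  d <- dim(mask$values)
  if (!any(mask$values)) return(mask)
  R <- rotation_matrix(angles_deg)
  idx <- which(mask$values)
  ijk <- arrayInd(idx, d) - 1
  centroid <- mask$origin + colMeans(ijk) * mask$spacing
  ax <- grid_axes(mask)
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  q <- sweep(sweep(pts, 2, centroid) %*% R, 2, centroid, "+")  # inverse map
  coords <- sweep(sweep(q, 2, mask$origin), 2, mask$spacing, "/")
  v <- cpp_trilinear(as.double(mask$values), d, coords, 0)
  binary_mask(array(v >= 0.5, d), mask$spacing, mask$origin)
}

# Combined rotation: about x, then y, then z. Returns the matrix mapping
# output-space offsets to input-space offsets (inverse rotation, for use as
# p_in = c + (p_out - c) %*% R).
rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])), c(0, sin(a[1]), cos(a[1])))
  Ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
  Rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
  fw <- Rz %*% Ry %*% Rx
  # for row-vector points p %*% R with R = t(fw^-1) = fw (orthonormal): use
  # p_in = p_out %*% fw gives the inverse rotation applied to row vectors
  fw
}

# 1-D/2-D integer cross-correlation shift via FFT; returns the shift to
# apply to `b` so it best overlays `a`. Ties break toward the smallest
# shift magnitude.
xcorr_shift <- function(a, b) {
  da <- dim(a)
  if (is.null(da)) { a <- matrix(a, ncol = 1); b <- matrix(b, ncol = 1); da <- dim(a) }
  n <- 2 * da
  ap <- matrix(0, n[1], n[2]); bp <- matrix(0, n[1], n[2])
  ap[seq_len(da[1]), seq_len(da[2])] <- a
  bp[seq_len(da[1]), seq_len(da[2])] <- b
  cc <- Re(fft(fft(ap) * Conj(fft(bp)), inverse = TRUE)) / prod(n)
  # index (i, j) corresponds to shift ((i-1) mod n, ...) mapped to signed
  sft <- function(i, nn) ifelse(i - 1 > nn / 2, i - 1 - nn, i - 1)
  best <- max(cc)
  cand <- which(cc >= best - 1e-9 * abs(best), arr.ind = TRUE)
  sx <- sft(cand[, 1], n[1]); sy <- sft(cand[, 2], n[2])
  ord <- order(sx^2 + sy^2, abs(sx), abs(sy), sx, sy)
  c(sx[ord[1]], sy[ord[1]])
}

#' In-plane translation alignment by 2-D cross-correlation
#'
#' The integer in-plane shift maximising the 2-D cross-correlation of the
#' two axial mid-slices, plus a through-plane shift from 1-D correlation of
#' the per-slice voxel counts. Ties break toward the smallest shift
#' magnitude. Both masks must share an isotropic grid.
#'
#' @param mask,reference [binary_mask] objects on the same grid.
#' @return A `registration_params` list with `angles_deg = c(0, 0, 0)` and
#'   `shift_vox` (the integer shift to apply to `mask`).
#' @export
align_translation_xcorr <- function(mask, reference) {
  stopifnot(inherits(mask, "binary_mask"), inherits(reference, "binary_mask"))
  if (!same_grid(mask, reference))
    stop("masks must share one grid", call. = FALSE)
  if (!any(mask$values) || !any(reference$values))
    stop("degenerate input: empty mask", call. = FALSE)
  d <- dim(mask$values)
  mid <- floor(d[3] / 2) + 1
  s_xy <- xcorr_shift(reference$values[, , mid] * 1.0, mask$values[, , mid] * 1.0)
  ca <- apply(reference$values, 3, sum)
  cb <- apply(mask$values, 3, sum)
  s_z <- xcorr_shift(ca, cb)[1]
  structure(list(angles_deg = c(0, 0, 0),
                 shift_vox = as.integer(c(s_xy, s_z))),
            class = "registration_params")
}

# integer translation of a mask (no wraparound; vacated voxels FALSE)
apply_shift <- function(mask, shift_vox) {
  d <- dim(mask$values)
  out <- array(FALSE, d)
  src <- lapply(1:3, function(a) {
    s <- shift_vox[a]
    list(src = max(1, 1 - s):min(d[a], d[a] - s),
         dst = max(1, 1 + s):min(d[a], d[a] + s))
  })
  if (all(vapply(src, function(u) length(u$src) > 0, TRUE)))
    out[src[[1]]$dst, src[[2]]$dst, src[[3]]$dst] <-
      mask$values[src[[1]]$src, src[[2]]$src, src[[3]]$src]
  binary_mask(out, mask$spacing, mask$origin)
}

#' Register a segmentation to its reference mask
#'
#' Three-step rigid registration: (1) both masks are brought onto the
#' reference's isotropic grid (cubic upsampling, re-binarised at 0.5);
#' (2) the mask is rotated either by configured angles or by the best of a
#' coordinate-wise search over +/- `search$range_deg` in `search$step_deg`
#' steps maximising post-shift Dice; (3) the mask is shifted by integer
#' voxels per [align_translation_xcorr]. The unrotated, unshifted candidate
#' is always scored too, so a search never returns a lower Dice than the
#' unregistered upsampled pair.
#'
#' @param mask a [binary_mask] (any grid).
#' @param reference a [binary_mask]; its upsampled grid defines the output.
#' @param angles_deg fixed rotation angles (degrees), or `NULL`.
#' @param search `NULL`, `TRUE` (defaults: range 10 deg, step 2 deg), or a
#'   list with `range_deg` and `step_deg`.
#' @param target_mm isotropic working resolution (mm).
#' @return The registered [binary_mask] on the reference's isotropic grid,
#'   with attribute `"registration"` (a `registration_params` with the
#'   angles and shift used, plus the achieved Dice).
#' @export
register_to_reference <- function(mask, reference, angles_deg = NULL,
                                  search = NULL, target_mm = 0.14) {
  stopifnot(inherits(mask, "binary_mask"), inherits(reference, "binary_mask"))
  ref_iso <- upsample_isotropic(reference, target_mm)
  mov <- resample_mask_to_grid(mask, ref_iso)
  if (!any(mov$values) || !any(ref_iso$values))
    stop("degenerate input: empty mask after resampling", call. = FALSE)

  score <- function(m) {
    p <- align_translation_xcorr(m, ref_iso)
    shifted <- apply_shift(m, p$shift_vox)
    list(mask = shifted, params = p,
         dice = dice_coefficient(ref_iso, shifted)$value)
  }
  baseline_dice <- dice_coefficient(ref_iso, mov)$value

  if (!is.null(angles_deg)) {
    m <- rotate_mask(mov, angles_deg)
    best <- score(m)
    best$params$angles_deg <- rep_len(as.numeric(angles_deg), 3)
  } else if (!is.null(search) && !isFALSE(search)) {
    if (isTRUE(search)) search <- list()
    rng <- if (is.null(search$range_deg)) 10 else search$range_deg
    stp <- if (is.null(search$step_deg)) 2 else search$step_deg
    angles <- c(0, 0, 0)
    best <- score(mov)
    best$params$angles_deg <- angles
    # coordinate-wise sweep over the angle grid, one axis at a time
    for (axis in 1:3) {
      for (a in seq(-rng, rng, by = stp)) {
        cand_angles <- angles
        cand_angles[axis] <- a
        cand <- score(rotate_mask(mov, cand_angles))
        if (cand$dice > best$dice + 1e-12) {
          best <- cand
          best$params$angles_deg <- cand_angles
          angles <- cand_angles
        }
      }
    }
  } else {
    best <- score(mov)
    best$params$angles_deg <- c(0, 0, 0)
  }
  if (best$dice < baseline_dice) {
    best <- list(mask = mov,
                 params = structure(list(angles_deg = c(0, 0, 0),
                                         shift_vox = c(0L, 0L, 0L)),
                                    class = "registration_params"),
                 dice = baseline_dice)
  }
  out <- best$mask
  best$params$dice <- best$dice
  attr(out, "registration") <- best$params
  out
}
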