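#' Volumetric image and binary mask containers
#'
#' An `image_volume` is a 3-D scalar field in Hounsfield Units (HU) with
#' anisotropic voxel spacing; a `binary_mask` is a 3-D logical field sharing
#' the same geometry model. Both use the voxel-centre convention: the
#' physical coordinate (mm) of voxel `(i, j, k)` (0-based) is
#' `origin + c(i, j, k) * spacing`. Array dimension 1 is x, 2 is y, 3 is z.
#'
#' @param values 3-D numeric array (HU) for volumes, logical (or 0/1) array
#'   for masks.
#' @param spacing numeric length-3, per-axis voxel size in mm; all > 0.
#' @param origin numeric length-3, physical position (mm) of the centre of
#'   voxel (0, 0, 0).
#' @return An object of class `image_volume` or `binary_mask`: a list with
#'   elements `values`, `spacing`, `origin`.
#' @export
#' @examples
#' v <- image_volume(array(-875, c(4, 4, 2)), spacing = c(0.5, 0.5, 1))
#' dim(v$values)
image_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array", call. = FALSE)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite lengths (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite coordinates (mm)", call. = FALSE)
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values)))
    stop("`values` must be finite (no NA/NaN/Inf)", call. = FALSE)
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @rdname image_volume
#' @export
binary_mask <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array", call. = FALSE)
  if (is.numeric(values)) {
    if (!all(values %in% c(0, 1)))
      stop("numeric mask values must be 0/1", call. = FALSE)
    values <- array(as.logical(values), dim(values))
  }
  if (!is.logical(values) || anyNA(values))
    stop("`values` must be logical without NA", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite lengths (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite coordinates (mm)", call. = FALSE)
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "binary_mask")
}

#' Create a uniformly filled volume
#'
#' @param shape integer length-3 grid size (voxels per axis).
#' @param spacing numeric length-3 voxel size in mm.
#' @param fill_hu HU value to fill with.
#' @param origin physical position (mm) of the first voxel centre.
#' @return An [image_volume].
#' @export
#' @examples
#' g <- make_grid(c(10, 10, 10), c(1, 1, 1), fill_hu = -875)
make_grid <- function(shape, spacing, fill_hu = -875, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || anyNA(shape) || any(shape < 1L))
    stop("`shape` must be 3 integers >= 1", call. = FALSE)
  image_volume(array(as.double(fill_hu), shape), spacing, origin)
}

# Accept an image_volume / binary_mask / list(shape, spacing, origin) as a
# geometry descriptor and normalise it.
as_grid <- function(grid) {
  if (inherits(grid, "image_volume") || inherits(grid, "binary_mask"))
    return(list(shape = dim(grid$values), spacing = grid$spacing,
                origin = grid$origin))
  if (is.list(grid) && all(c("shape", "spacing") %in% names(grid))) {
    origin <- if (is.null(grid$origin)) c(0, 0, 0) else grid$origin
    return(list(shape = as.integer(grid$shape),
                spacing = as.numeric(grid$spacing),
                origin = as.numeric(origin)))
  }
  stop("`grid` must be an image_volume, binary_mask or list(shape, spacing[, origin])",
       call. = FALSE)
}

# Physical coordinates of voxel centres along each axis.
grid_axes <- function(x) {
  g <- as_grid(x)
  lapply(1:3, function(a) g$origin[a] + (seq_len(g$shape[a]) - 1) * g$spacing[a])
}

voxel_volume_mm3 <- function(x) prod(as_grid(x)$spacing)

same_grid <- function(a, b, tol = 1e-6) {
  ga <- as_grid(a); gb <- as_grid(b)
  identical(ga$shape, gb$shape) && all(abs(ga$spacing - gb$spacing) < tol)
}

# mm -> continuous 0-based voxel index
mm_to_index <- function(grid, p_mm) {
  g <- as_grid(grid)
  (p_mm - g$origin) / g$spacing
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  HU range [%.1f, %.1f], origin (%s) mm\n",
              min(x$values), max(x$values),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, spacing %s mm, %d foreground (%.3f mm^3)\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              sum(x$values), sum(x$values) * prod(x$spacing)))
  invisible(x)
}
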