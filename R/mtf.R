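#' Average the slices of a wire volume
#'
#' Mean across z on the in-plane grid, reducing noise by ~1/sqrt(n) for n
#' independent-noise slices.
#'
#' @param volume an [image_volume].
#' @return A `plane_image`: list with `values` (matrix), `spacing` and
#'   `origin` (in-plane, mm).
#' @export
average_slices <- function(volume) {
  stopifnot(inherits(volume, "image_volume"))
  d <- dim(volume$values)
  vals <- if (d[3] == 1) volume$values[, , 1]
          else rowMeans(volume$values, dims = 2)
  structure(list(values = vals, spacing = volume$spacing[1:2],
                 origin = volume$origin[1:2]), class = "plane_image")
}

#' @export
print.plane_image <- function(x, ...) {
  cat(sprintf("<plane_image> %d x %d pixels @ %s mm\n", nrow(x$values),
              ncol(x$values), paste(signif(x$spacing, 4), collapse = " x ")))
  invisible(x)
}

#' Locate the wire centre with sub-pixel precision
#'
#' Starts from the intensity-weighted centroid of the pixels above
#' background + half the maximum excess, then refines it with a few
#' fixed-point iterations of the excess-weighted centroid over a circular
#' window (`window_mm`), which removes the truncation bias of the
#' half-maximum threshold.
#'
#' @param image a `plane_image` (see [average_slices]).
#' @param window_mm radius of the refinement window (mm); default 12
#'   pixels.
#' @return Length-2 centre (mm).
#' @export
estimate_wire_center <- function(image, window_mm = NULL) {
  stopifnot(inherits(image, "plane_image"))
  if (is.null(window_mm)) window_mm <- 12 * min(image$spacing)
  v <- image$values
  bg <- min(v)
  excess <- v - bg
  mx <- max(excess)
  if (mx <= 0) stop("no wire found: image has no positive contrast", call. = FALSE)
  thr <- mx / 2
  sel <- which(excess > thr, arr.ind = TRUE)
  w <- excess[excess > thr]
  xs <- image$origin[1] + (seq_len(nrow(v)) - 1) * image$spacing[1]
  ys <- image$origin[2] + (seq_len(ncol(v)) - 1) * image$spacing[2]
  ctr <- c(sum(xs[sel[, 1]] * w), sum(ys[sel[, 2]] * w)) / sum(w)
  for (i in 1:3) {
    r2 <- outer((xs - ctr[1])^2, (ys - ctr[2])^2, "+")
    win <- r2 <= window_mm^2
    ww <- excess[win]
    px <- outer(xs, rep(1, length(ys)))[win]
    py <- outer(rep(1, length(xs)), ys)[win]
    ctr <- c(sum(px * ww), sum(py * ww)) / sum(ww)
  }
  ctr
}

#' Subtract the image background
#'
#' Background is the mean over pixels farther than `exclusion_radius_mm`
#' from the wire centre; it is subtracted everywhere, so the far field has
#' exactly zero mean by construction.
#'
#' @param image a `plane_image`.
#' @param center length-2 centre (mm).
#' @param exclusion_radius_mm radius excluded from the background estimate.
#' @return The background-subtracted `plane_image` (attribute
#'   `"background_hu"` records the subtracted level).
#' @export
subtract_background <- function(image, center, exclusion_radius_mm) {
  stopifnot(inherits(image, "plane_image"))
  r <- pixel_radii(image, center)
  far <- r > exclusion_radius_mm
  if (!any(far))
    stop("exclusion region covers the whole image", call. = FALSE)
  bg <- mean(image$values[far])
  out <- image
  out$values <- image$values - bg
  attr(out, "background_hu") <- bg
  out
}

pixel_radii <- function(image, center) {
  xs <- image$origin[1] + (seq_len(nrow(image$values)) - 1) * image$spacing[1]
  ys <- image$origin[2] + (seq_len(ncol(image$values)) - 1) * image$spacing[2]
  sqrt(outer((xs - center[1])^2, (ys - center[2])^2, "+"))
}

#' Radial intensity profile around the wire
#'
#' Pixels are binned by distance to the centre (default bin width: a
#' quarter pixel) and averaged per bin. With `abscissa = "mean_radius"`
#' (default) each bin is reported at the mean radius of its contributing
#' pixels, which removes the first-order bias of sparse annuli near the
#' centre, and empty bins simply contribute no point; with
#' `abscissa = "bin_center"` bins sit at their centres and empty bins are
#' linearly interpolated from their neighbours. The profile is truncated
#' at the inscribed circle radius so every annulus is fully sampled.
#'
#' @param image a `plane_image` (background-subtracted).
#' @param center length-2 centre (mm).
#' @param bin_width_mm radial bin width (mm); default `pixel / 4`.
#' @param abscissa `"mean_radius"` or `"bin_center"`.
#' @return A `radial_profile`: list with `radii_mm` (strictly increasing),
#'   `values_hu` and `bin_width_mm`.
#' @export
radial_profile <- function(image, center, bin_width_mm = NULL,
                           abscissa = c("mean_radius", "bin_center")) {
  stopifnot(inherits(image, "plane_image"))
  abscissa <- match.arg(abscissa)
  if (is.null(bin_width_mm)) bin_width_mm <- min(image$spacing) / 4
  if (bin_width_mm <= 0) stop("`bin_width_mm` must be > 0", call. = FALSE)
  r <- pixel_radii(image, center)
  xs <- image$origin[1] + (seq_len(nrow(image$values)) - 1) * image$spacing[1]
  ys <- image$origin[2] + (seq_len(ncol(image$values)) - 1) * image$spacing[2]
  rmax <- min(center[1] - xs[1], max(xs) - center[1],
              center[2] - ys[1], max(ys) - center[2])
  nb <- floor(rmax / bin_width_mm)
  if (nb < 2) stop("image too small for the requested bin width", call. = FALSE)
  bin <- floor(r / bin_width_mm) + 1
  keep <- bin <= nb
  means <- tapply(image$values[keep], bin[keep], mean)
  if (abscissa == "mean_radius") {
    radii <- as.numeric(tapply(r[keep], bin[keep], mean))
    vals <- as.numeric(means)
  } else {
    vals <- rep(NA_real_, nb)
    vals[as.integer(names(means))] <- means
    radii <- (seq_len(nb) - 0.5) * bin_width_mm
    if (anyNA(vals)) {
      ok <- !is.na(vals)
      vals <- approx(radii[ok], vals[ok], radii, rule = 2)$y
    }
  }
  structure(list(radii_mm = radii, values_hu = as.numeric(vals),
                 bin_width_mm = bin_width_mm), class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("<radial_profile> %d bins of %.4f mm, r in [%.4f, %.4f] mm, peak %.2f HU\n",
              length(x$radii_mm), x$bin_width_mm, min(x$radii_mm),
              max(x$radii_mm), max(x$values_hu)))
  invisible(x)
}

#' Order-0 Hankel transform of a radial profile
#'
#' `MTF(f) = |2 pi * integral p(r) J0(2 pi f r) r dr|`, evaluated by
#' trapezoidal quadrature. The profile is spline-interpolated onto a grid
#' `oversample` times finer than its bins to control quadrature error
#' against the oscillating Bessel kernel; the spline uses an even (mirror)
#' extension about r = 0, since a radial function has zero slope there,
#' which extrapolates the unobserved peak correctly. Frequencies are
#' handled internally in LP/mm and reported in LP/cm. A profile whose tail
#' exceeds 5% of its peak triggers a truncation-bias warning.
#'
#' @param profile a `radial_profile`.
#' @param freq_grid_lp_cm frequency grid (LP/cm) starting at 0.
#' @param oversample spline refinement factor for the quadrature grid.
#' @return An `mtf_curve`: list with `frequencies_lp_cm` and `modulation`.
#' @export
hankel_mtf <- function(profile, freq_grid_lp_cm = seq(0, 40, by = 0.1),
                       oversample = 4) {
  stopifnot(inherits(profile, "radial_profile"))
  peak <- max(abs(profile$values_hu))
  ntail <- max(3, ceiling(0.05 * length(profile$values_hu)))
  tail_level <- max(abs(utils::tail(profile$values_hu, ntail)))
  if (peak > 0 && tail_level > 0.05 * peak)
    warning("profile tail exceeds 5% of peak; MTF may be truncation-biased")
  rr <- profile$radii_mm
  vv <- profile$values_hu
  mirror <- rr > profile$bin_width_mm / 8  # avoid duplicating a point at ~0
  r0 <- c(-rev(rr[mirror]), rr)
  p0 <- c(rev(vv[mirror]), vv)
  rf <- seq(0, max(rr), by = profile$bin_width_mm / max(1, oversample))
  pf <- spline(r0, p0, xout = rf)$y
  dr <- diff(rf)
  f_mm <- freq_grid_lp_cm / 10
  mod <- vapply(f_mm, function(f) {
    y <- pf * besselJ(2 * pi * f * rf, 0) * rf
    abs(2 * pi * sum((y[-1] + y[-length(y)]) / 2 * dr))
  }, 0)
  structure(list(frequencies_lp_cm = freq_grid_lp_cm, modulation = mod),
            class = "mtf_curve")
}

#' Finite-wire (Nickoloff) correction
#'
#' Divides the measured modulation by the transform of the wire's own disk
#' cross-section, `2 J1(pi d f) / (pi d f)` (f in LP/mm, d in mm), removing
#' the wire size from the estimate. Frequencies at or beyond the disk
#' transform's first null are dropped with a warning.
#'
#' @param curve an `mtf_curve`.
#' @param wire_diameter_mm wire diameter (mm), > 0.
#' @return The corrected `mtf_curve`.
#' @export
wire_correction <- function(curve, wire_diameter_mm) {
  stopifnot(inherits(curve, "mtf_curve"))
  if (wire_diameter_mm <= 0) stop("`wire_diameter_mm` must be > 0", call. = FALSE)
  u <- pi * wire_diameter_mm * curve$frequencies_lp_cm / 10
  first_null <- 3.8317059702075  # first zero of J1
  ok <- u < first_null
  if (!all(ok)) {
    warning("frequencies at/beyond the wire transform's first null dropped")
    curve$frequencies_lp_cm <- curve$frequencies_lp_cm[ok]
    curve$modulation <- curve$modulation[ok]
    u <- u[ok]
  }
  divisor <- ifelse(u == 0, 1, 2 * besselJ(u, 1) / u)
  curve$modulation <- curve$modulation / divisor
  curve
}

# Transfer function of the square sampling aperture (pixel box), averaged
# over direction; used to remove the renderer's area-integrating aperture.
aperture_divisor <- function(frequencies_lp_cm, pixel_mm, n_theta = 64) {
  th <- seq(0, pi / 4, length.out = n_theta)
  sinc <- function(x) ifelse(abs(x) < 1e-12, 1, sin(x) / x)
  vapply(frequencies_lp_cm / 10, function(f) {
    a <- pi * pixel_mm * f
    mean(sinc(a * cos(th)) * sinc(a * sin(th)))
  }, 0)
}

#' Pixel-aperture correction
#'
#' The image pixels integrate the signal over their square area, so the
#' measured transform carries the known aperture transfer function
#' `sinc(pi a fx) sinc(pi a fy)` on top of the system blur. Two removal
#' routes are provided. [deconvolve_pixel_aperture] divides the image's
#' discrete Fourier transform by the separable sinc before radial
#' averaging, which also restores the circular symmetry the radial binning
#' relies on; this is the route [estimate_mtf] uses by default.
#' [aperture_correction] instead divides the finished curve by the
#' direction-averaged aperture transform.
#'
#' @param curve an `mtf_curve`.
#' @param pixel_mm in-plane pixel size (mm).
#' @param n_theta quadrature points for the direction average.
#' @return The corrected `mtf_curve` / `plane_image`.
#' @export
aperture_correction <- function(curve, pixel_mm, n_theta = 64) {
  stopifnot(inherits(curve, "mtf_curve"))
  if (pixel_mm <= 0) stop("`pixel_mm` must be > 0", call. = FALSE)
  curve$modulation <- curve$modulation /
    aperture_divisor(curve$frequencies_lp_cm, pixel_mm, n_theta)
  curve
}

#' @rdname aperture_correction
#' @param image a `plane_image` (background-subtracted).
#' @export
deconvolve_pixel_aperture <- function(image) {
  stopifnot(inherits(image, "plane_image"))
  v <- image$values
  n1 <- nrow(v); n2 <- ncol(v)
  sinc <- function(x) ifelse(abs(x) < 1e-12, 1, sin(x) / x)
  dft_freqs <- function(n, dx)
    c(0:floor(n / 2), -((ceiling(n / 2) - 1):1))[seq_len(n)] / (n * dx)
  fx <- dft_freqs(n1, image$spacing[1])
  fy <- dft_freqs(n2, image$spacing[2])
  H <- outer(sinc(pi * image$spacing[1] * fx), sinc(pi * image$spacing[2] * fy))
  out <- image
  out$values <- Re(fft(fft(v) / H, inverse = TRUE)) / (n1 * n2)
  out
}

#' Normalise an MTF to unity at zero frequency
#'
#' @param curve an `mtf_curve` whose first frequency is 0.
#' @return The normalised `mtf_curve` (`modulation[1] == 1`).
#' @export
normalize_mtf <- function(curve) {
  stopifnot(inherits(curve, "mtf_curve"))
  m0 <- curve$modulation[1]
  if (!is.finite(m0) || m0 <= 0)
    stop("degenerate input: modulation at zero frequency must be > 0",
         call. = FALSE)
  curve$modulation <- curve$modulation / m0
  curve
}

#' MTF cutoff frequency
#'
#' First downward crossing of `level`, linearly interpolated between the
#' bracketing samples. `level = 1` returns 0.
#'
#' @param curve a normalised `mtf_curve` starting at 1.
#' @param level fraction in (0, 1], e.g. 0.5 or 0.1.
#' @return Cutoff frequency in LP/cm.
#' @export
mtf_cutoff <- function(curve, level) {
  stopifnot(inherits(curve, "mtf_curve"))
  if (level <= 0 || level > 1) stop("`level` must be in (0, 1]", call. = FALSE)
  if (level == 1) return(0)
  m <- curve$modulation
  f <- curve$frequencies_lp_cm
  below <- which(m < level)
  below <- below[below > 1]
  if (length(below) == 0)
    stop("no cutoff: curve never falls below ", level, call. = FALSE)
  i <- below[1]
  f[i - 1] + (level - m[i - 1]) / (m[i] - m[i - 1]) * (f[i] - f[i - 1])
}

#' Options for the MTF estimation chain
#'
#' @param bin_width_mm radial bin width; `NULL` = pixel / 4.
#' @param freq_grid_lp_cm frequency grid (LP/cm).
#' @param oversample quadrature refinement factor in [hankel_mtf].
#' @param exclusion_radius_factor background exclusion radius as a multiple
#'   of the wire diameter.
#' @param pixel_aperture how to remove the square sampling aperture of the
#'   pixel grid: `"image"` (frequency-domain deconvolution before radial
#'   averaging, the default), `"curve"` (divide the finished curve), or
#'   `"none"`. `TRUE`/`FALSE` map to `"image"`/`"none"`.
#' @param abscissa radial-profile abscissa, see [radial_profile].
#' @param n_theta direction-average quadrature points (curve route).
#' @return A list of options for [estimate_mtf].
#' @export
mtf_options <- function(bin_width_mm = NULL,
                        freq_grid_lp_cm = seq(0, 40, by = 0.1),
                        oversample = 4, exclusion_radius_factor = 10,
                        pixel_aperture = "image", abscissa = "mean_radius",
                        n_theta = 64) {
  if (isTRUE(pixel_aperture)) pixel_aperture <- "image"
  if (isFALSE(pixel_aperture)) pixel_aperture <- "none"
  pixel_aperture <- match.arg(pixel_aperture, c("image", "curve", "none"))
  list(bin_width_mm = bin_width_mm, freq_grid_lp_cm = freq_grid_lp_cm,
       oversample = oversample,
       exclusion_radius_factor = exclusion_radius_factor,
       pixel_aperture = pixel_aperture, abscissa = abscissa,
       n_theta = n_theta)
}

#' Estimate the in-plane MTF from a wire-phantom volume
#'
#' Full chain: slice averaging, wire-centre estimation, background
#' subtraction, radial profile, order-0 Hankel transform, finite-wire
#' (Nickoloff) correction, optional pixel-aperture correction,
#' normalisation, and 50%/10% cutoff extraction.
#'
#' @param volume an [image_volume] of the wire phantom.
#' @param wire_diameter_mm physical wire diameter (mm).
#' @param options see [mtf_options].
#' @return An `mtf_estimate`: list with `curve` (normalised `mtf_curve`),
#'   `cutoff_50_lp_cm`, `cutoff_10_lp_cm`, `center_mm`, `background_hu`.
#' @export
estimate_mtf <- function(volume, wire_diameter_mm, options = mtf_options()) {
  img <- average_slices(volume)
  ctr <- estimate_wire_center(img)
  img <- subtract_background(img, ctr,
                             options$exclusion_radius_factor * wire_diameter_mm)
  if (identical(options$pixel_aperture, "image") ||
      isTRUE(options$pixel_aperture)) {
    bg <- attr(img, "background_hu")
    img <- deconvolve_pixel_aperture(img)
    attr(img, "background_hu") <- bg
  }
  prof <- radial_profile(img, ctr, options$bin_width_mm,
                         abscissa = if (is.null(options$abscissa)) "mean_radius"
                                    else options$abscissa)
  curve <- hankel_mtf(prof, options$freq_grid_lp_cm, options$oversample)
  curve <- wire_correction(curve, wire_diameter_mm)
  if (identical(options$pixel_aperture, "curve"))
    curve <- aperture_correction(curve, min(img$spacing), options$n_theta)
  curve <- normalize_mtf(curve)
  c50 <- tryCatch(mtf_cutoff(curve, 0.5), error = function(e) NA_real_)
  c10 <- tryCatch(mtf_cutoff(curve, 0.1), error = function(e) NA_real_)
  structure(list(curve = curve, cutoff_50_lp_cm = c50, cutoff_10_lp_cm = c10,
                 center_mm = ctr,
                 background_hu = attr(img, "background_hu")),
            class = "mtf_estimate")
}

#' @export
print.mtf_estimate <- function(x, ...) {
  cat(sprintf("<mtf_estimate> 50%% cutoff %.2f LP/cm, 10%% cutoff %.2f LP/cm\n",
              x$cutoff_50_lp_cm, x$cutoff_10_lp_cm))
  invisible(x)
}

#' @export
plot.mtf_curve <- function(x, xlab = "Spatial frequency (LP/cm)",
                           ylab = "Modulation", type = "l", ...) {
  plot(x$frequencies_lp_cm, x$modulation, xlab = xlab, ylab = ylab,
       type = type, ...)
  abline(h = 0.5, lty = 3)
  abline(h = 0.1, lty = 2)
  invisible(x)
}

#' @export
plot.mtf_estimate <- function(x, ...) {
  plot(x$curve, ...)
  invisible(x)
}
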