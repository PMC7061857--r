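#' Convert 8-bit pixel values to absorbance
#'
#' Brightfield pixel values are converted to optical density with
#' \code{A = log10(255 / pv)}, treating the unattenuated sensor reading (255)
#' as the blank. Fully dark pixels (\code{pv = 0}) are clipped to 1 so the
#' absorbance saturates at \code{log10(255) ~ 2.407} instead of diverging.
#'
#' @param pv numeric vector of pixel values in \[0, 255\].
#' @return numeric vector of absorbances (unitless optical density).
#' @examples
#' pixel_to_absorbance(c(255, 26, 0))
#' @export
pixel_to_absorbance <- function(pv) {
  if (any(!is.finite(pv)) || any(pv < 0) || any(pv > 255))
    stopf("pixel values must lie in [0, 255]")
  log10(255 / pmax(pv, 1))
}

#' Render absorbance as an 8-bit pixel value
#'
#' Inverse of [pixel_to_absorbance()]: \code{pv = round(255 * 10^-A)}.
#'
#' @param A numeric vector of absorbances (>= 0).
#' @return integer pixel values in \[0, 255\].
#' @export
absorbance_to_pixel <- function(A) {
  if (any(!is.finite(A)) || any(A < 0)) stopf("absorbance must be finite and >= 0")
  as.integer(round(255 * 10^(-A)))
}

#' CIE 1931 2-degree colour matching functions
#'
#' Analytic multi-lobe Gaussian fits to the standard observer (Wyman, Sloan
#' and Shirley 2013), accurate to within about 1\% of the tabulated observer —
#' ample for hue readouts of smooth absorbance spectra.
#'
#' @param wl numeric vector of wavelengths (nm).
#' @return matrix with columns \code{x}, \code{y}, \code{z}.
#' @export
cie_cmf <- function(wl) {
  lobe <- function(wl, mu, s1, s2) {
    t <- (wl - mu) * ifelse(wl < mu, 1 / s1, 1 / s2)
    exp(-0.5 * t^2)
  }
  x <- 0.362 * lobe(wl, 442.0, 1 / 0.0624, 1 / 0.0374) +
    1.056 * lobe(wl, 599.8, 1 / 0.0264, 1 / 0.0323) -
    0.065 * lobe(wl, 501.1, 1 / 0.0490, 1 / 0.0382)
  y <- 0.821 * lobe(wl, 568.8, 1 / 0.0213, 1 / 0.0247) +
    0.286 * lobe(wl, 530.9, 1 / 0.0613, 1 / 0.0322)
  z <- 1.217 * lobe(wl, 437.0, 1 / 0.0845, 1 / 0.0278) +
    0.681 * lobe(wl, 459.0, 1 / 0.0385, 1 / 0.0725)
  cbind(x = x, y = y, z = z)
}

## XYZ (rows) -> linear sRGB, D65 white.
.xyz2rgb <- matrix(c(
  3.2406, -1.5372, -0.4986,
  -0.9689, 1.8758, 0.0415,
  0.0557, -0.2040, 1.0570
), nrow = 3, byrow = TRUE)

.srgb_gamma <- function(u) {
  u <- clamp(u, 0, 1)
  ifelse(u <= 0.0031308, 12.92 * u, 1.055 * u^(1 / 2.4) - 0.055)
}

#' Construct an absorbance spectrum
#'
#' @param wavelength_nm strictly increasing wavelengths (nm).
#' @param absorbance non-negative finite absorbances, same length.
#' @return object of class `spectrum` (data.frame with a `lambda_max`
#'   attribute).
#' @export
absorbance_spectrum <- function(wavelength_nm, absorbance) {
  if (length(wavelength_nm) != length(absorbance))
    stopf("wavelength and absorbance must have equal length")
  if (any(diff(wavelength_nm) <= 0)) stopf("wavelengths must be strictly increasing")
  if (any(!is.finite(absorbance)) || any(absorbance < 0))
    stopf("absorbance must be finite and non-negative")
  s <- data.frame(wavelength_nm = wavelength_nm, absorbance = absorbance)
  class(s) <- c("spectrum", "data.frame")
  attr(s, "lambda_max") <- wavelength_nm[which.max(absorbance)]
  s
}

#' Hue of an absorbance spectrum
#'
#' Converts an absorbance spectrum to its perceived transmitted colour:
#' transmittance \code{T = 10^-A} is integrated against the CIE 1931
#' 2-degree observer under the chosen illuminant, the tristimulus values are
#' white-point normalised (von Kries in XYZ), converted to gamma-encoded
#' sRGB with out-of-gamut clipping, and finally to HSV. A flat spectrum maps
#' exactly to the white point. Samples with saturation below
#' `achromatic_threshold` carry no meaningful hue and are flagged achromatic.
#'
#' @param s an [absorbance_spectrum()]; must cover 380--780 nm.
#' @param illuminant `"E"` (equal energy, default) or a numeric vector of
#'   relative spectral power on the same grid as `s`.
#' @param achromatic_threshold saturation below which hue is undefined.
#' @return list of class `color_sample`: `hue` (degrees, NA if achromatic),
#'   `saturation`, `value`, `achromatic`, `XYZ`.
#' @export
spectrum_to_hue <- function(s, illuminant = "E", achromatic_threshold = 0.05) {
  wl <- s$wavelength_nm
  if (min(wl) > 380 || max(wl) < 780)
    stopf("spectrum must cover the visible range 380-780 nm (got %g-%g)", min(wl), max(wl))
  if (is.character(illuminant)) {
    if (!identical(illuminant, "E")) stopf("unknown illuminant '%s'", illuminant)
    I <- rep(1, length(wl))
  } else {
    if (length(illuminant) != length(wl)) stopf("illuminant grid mismatch")
    I <- illuminant
  }
  Tr <- 10^(-s$absorbance)
  cmf <- cie_cmf(wl)
  dw <- c(diff(wl), wl[length(wl)] - wl[length(wl) - 1])
  XYZ <- colSums(cmf * I * Tr * dw)
  white <- colSums(cmf * I * dw)
  XYZn <- XYZ / white # von Kries: illuminant white -> unit white
  rgb_lin <- as.vector(.xyz2rgb %*% (XYZn * c(0.95047, 1, 1.08883)))
  rgb <- .srgb_gamma(rgb_lin)
  hsv <- rgb2hsv(rgb[1], rgb[2], rgb[3], maxColorValue = 1)
  achrom <- hsv[2, 1] < achromatic_threshold
  structure(list(
    hue = if (achrom) NA_real_ else hsv[1, 1] * 360,
    saturation = hsv[2, 1], value = hsv[3, 1],
    achromatic = achrom, XYZ = XYZ
  ), class = "color_sample")
}

#' Circular mean of hue angles
#'
#' @param hue_deg numeric vector of hues in degrees; NAs dropped.
#' @return mean hue in \[0, 360).
#' @export
circular_mean_hue <- function(hue_deg) {
  h <- hue_deg[is.finite(hue_deg)] * pi / 180
  if (!length(h)) return(NA_real_)
  (atan2(mean(sin(h)), mean(cos(h))) * 180 / pi) %% 360
}

#' Per-point hue of an RGB section image
#'
#' Measures HSV colour at circular points (mean RGB over each point's pixels,
#' then HSV), and summarises chromatic points by their circular mean hue.
#'
#' @param img 8-bit RGB array (h x w x 3).
#' @param points data.frame with columns `x`, `y` (pixel centres).
#' @param area_px pixels per circular point (default 12).
#' @param achromatic_threshold saturation cut-off below which a point is
#'   achromatic.
#' @return list with `points` (data.frame of hue, saturation, value,
#'   achromatic), `summary_hue` and `achromatic` flag for the summary.
#' @export
region_hue <- function(img, points, area_px = 12, achromatic_threshold = 0.05) {
  off <- circle_offsets(area_px)
  h <- dim(img)[1]; w <- dim(img)[2]
  res <- lapply(seq_len(nrow(points)), function(i) {
    xs <- round(points$x[i]) + off$dx; ys <- round(points$y[i]) + off$dy
    if (any(xs < 1 | xs > w | ys < 1 | ys > h)) stopf("point %d outside image", i)
    idx <- cbind(ys, xs)
    m <- c(mean(img[, , 1][idx]), mean(img[, , 2][idx]), mean(img[, , 3][idx]))
    hsv <- rgb2hsv(m[1], m[2], m[3], maxColorValue = 255)
    data.frame(hue = hsv[1, 1] * 360, saturation = hsv[2, 1], value = hsv[3, 1],
               achromatic = hsv[2, 1] < achromatic_threshold)
  })
  pts <- do.call(rbind, res)
  chrom <- !pts$achromatic
  list(points = pts,
       summary_hue = if (any(chrom)) circular_mean_hue(pts$hue[chrom]) else NA_real_,
       achromatic = !any(chrom))
}

#' Stain vector from a target hue
#'
#' Builds the unit optical-density direction of a stain whose transmitted
#' colour has the given hue at a reference saturation and value. This is the
#' Beer--Lambert single-stain model: pixel OD is this direction scaled by the
#' local stain amount.
#'
#' @param hue_deg target hue in degrees.
#' @param saturation,value reference HSV coordinates of the rendered stain.
#' @return unit-length, non-negative numeric vector of per-channel OD.
#' @export
stain_vector <- function(hue_deg, saturation = 0.8, value = 0.5) {
  col <- col2rgb(hsv(hue_deg %% 360 / 360, saturation, value)) / 255
  od <- -log10(pmax(col[, 1], 1e-4))
  od / sqrt(sum(od^2))
}

#' Two-stain colour deconvolution with a fixed primary
#'
#' Unmixes an 8-bit RGB image into a fixed primary stain density and a
#' data-driven complementary density. Pixels are converted to optical density
#' (\code{log10(255/pv)} per channel, zeros clipped to 1); the complementary
#' vector is the component of the image's mean OD direction orthogonal to the
#' primary, normalised and clamped non-negative. Densities follow by linear
#' least-squares unmixing.
#'
#' @param img 8-bit RGB array.
#' @param primary unit OD direction of the fixed stain (see [stain_vector()]).
#' @param min_od pixels with OD norm below this are excluded from the mean OD
#'   direction estimate.
#' @param collinear_tol residual norm below which the image's mean OD
#'   direction is considered collinear with the primary (single-stain
#'   image): the in-plane complement is then undefined.
#' @param fallback if TRUE (default), a collinear image falls back to the
#'   grey-axis complement (component of equal-channel OD orthogonal to the
#'   primary) with a warning — the complementary density is then ~0
#'   everywhere, as it should be for a single-stain image. If FALSE,
#'   collinearity is a hard error with a diagnostic.
#' @param clamp_negative zero out negative complement components (breaks
#'   exact orthogonality and unmixing; off by default).
#' @return list: `primary_density`, `complementary_density` (matrices),
#'   `complementary_vector`, `complementary_hue` (hue of the complementary
#'   vector's transmittance rendering at unit density).
#' @export
color_deconvolve <- function(img, primary, min_od = 0.05,
                             collinear_tol = 5e-3, fallback = TRUE,
                             clamp_negative = FALSE) {
  stopifnot(length(dim(img)) == 3L)
  p <- primary / sqrt(sum(primary^2))
  od <- array(log10(255 / pmax(img, 1)), dim = dim(img))
  odm <- cbind(as.vector(od[, , 1]), as.vector(od[, , 2]), as.vector(od[, , 3]))
  nrm <- sqrt(rowSums(odm^2))
  sel <- nrm > min_od
  if (!any(sel)) stopf("image carries no optical density above %g", min_od)
  mdir <- colMeans(odm[sel, , drop = FALSE])
  mdir <- mdir / sqrt(sum(mdir^2))
  comp <- mdir - sum(mdir * p) * p
  if (sqrt(sum(comp^2)) < collinear_tol) {
    if (!fallback)
      stopf("primary stain is nearly collinear with the mean OD direction (residual norm %.2g); cannot construct a complementary channel", sqrt(sum(comp^2)))
    warning("mean OD direction collinear with the primary; using the grey-axis complement")
    comp <- rep(1 / sqrt(3), 3) - sum(rep(1 / sqrt(3), 3) * p) * p
  }
  comp <- comp / sqrt(sum(comp^2))
  ## a strictly positive primary admits no non-negative orthogonal vector, so
  ## clamping is opt-in: it trades exact orthogonality (and unmixing
  ## exactness) for a physically non-negative complement
  clamped <- FALSE
  if (clamp_negative && any(comp < 0)) {
    clamped <- TRUE
    comp <- pmax(comp, 0)
    comp <- comp / sqrt(sum(comp^2))
  }
  M <- cbind(p, comp)
  coefs <- solve(crossprod(M), t(M)) # 2 x 3 unmixing matrix
  dens <- odm %*% t(coefs)
  h <- dim(img)[1]
  Tr <- clamp(10^(-comp), 0, 1) # negative components clip to full transmittance
  hsvc <- rgb2hsv(Tr[1], Tr[2], Tr[3], maxColorValue = 1)
  list(
    primary_density = matrix(dens[, 1], h),
    complementary_density = matrix(dens[, 2], h),
    complementary_vector = comp,
    complementary_clamped = clamped,
    complementary_hue = hsvc[1, 1] * 360
  )
}
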