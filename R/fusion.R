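# Two-channel normalization and Gaussian high/low-pass fusion, CNR
# measurement, kernel-size-for-target-CNR search, and dose-kernel fitting.

#' Normalize an image to a tissue pair
#'
#' Affine rescale so the mean over `roi_low` becomes 0 and the mean over
#' `roi_high` becomes 1. If the channel has inverted contrast (the
#' nominally high tissue reads lower), the gain is negative and the
#' channels end up on a common scale by construction.
#'
#' @param recon a `bct_recon` (or plain matrix with `pixel_mm` given).
#' @param roi_low,roi_high single-row ROI data frames (columns `cx_mm`,
#'   `cy_mm`, `r_mm`).
#' @param pixel_mm pixel size when `recon` is a bare matrix.
#' @return Rescaled object of the same kind.
#' @export
normalize_pair <- function(recon, roi_low, roi_high, pixel_mm = NULL) {
  vals <- if (inherits(recon, "bct_recon")) recon$values else recon
  if (is.null(pixel_mm)) pixel_mm <- recon$pixel_mm
  n <- nrow(vals)
  m_lo <- mean(vals[roi_mask(roi_low, n, pixel_mm)])
  m_hi <- mean(vals[roi_mask(roi_high, n, pixel_mm)])
  if (isTRUE(all.equal(m_lo, m_hi))) stop("ROI means are equal")
  out <- (vals - m_lo) / (m_hi - m_lo)
  if (inherits(recon, "bct_recon")) {
    recon$values <- out
    recon
  } else out
}

#' Fuse attenuation and phase channels
#'
#' \eqn{fused = G_\sigma * att + (dpc - G_\sigma * dpc)}: the low-pass part
#' of the attenuation image (where its noise power is lowest) is summed
#' with the high-pass part of the phase image (where differential-phase
#' noise is lowest). Both inputs must be normalized to the same tissue
#' pair. The Gaussian filtering is periodic-FFT with exact unit DC gain,
#' so fusing an image with itself returns it exactly.
#'
#' @param att,dpc normalized `bct_recon` objects (or matrices) on the same
#'   grid.
#' @param sigma_px shared Gaussian kernel sigma in pixels.
#' @return Fused image of the same kind as `att` (channel `"fused"`).
#' @export
fuse <- function(att, dpc, sigma_px) {
  a <- if (inherits(att, "bct_recon")) att$values else att
  d <- if (inherits(dpc, "bct_recon")) dpc$values else dpc
  stopifnot(all(dim(a) == dim(d)), sigma_px >= 0)
  f <- gaussian_blur(a, sigma_px) + (d - gaussian_blur(d, sigma_px))
  if (inherits(att, "bct_recon")) {
    att$values <- f
    att$channel <- "fused"
    att
  } else f
}

#' Contrast-to-noise ratio between two ROIs
#'
#' \eqn{CNR = |m_A - m_B| / \sqrt{(v_A + v_B)/2}} with pooled per-ROI
#' variances.
#'
#' @param recon a `bct_recon` or matrix.
#' @param roiA,roiB single-row ROI data frames.
#' @param pixel_mm pixel size for bare matrices.
#' @return CNR (dimensionless).
#' @export
cnr <- function(recon, roiA, roiB, pixel_mm = NULL) {
  vals <- if (inherits(recon, "bct_recon")) recon$values else recon
  if (is.null(pixel_mm)) pixel_mm <- recon$pixel_mm
  n <- nrow(vals)
  a <- vals[roi_mask(roiA, n, pixel_mm)]
  b <- vals[roi_mask(roiB, n, pixel_mm)]
  if (length(a) < 25 || length(b) < 25) {
    stop("each ROI must contain at least 25 pixels")
  }
  abs(mean(a) - mean(b)) / sqrt((stats::var(a) + stats::var(b)) / 2)
}

#' Gaussian kernel FWHM required to reach a target CNR
#'
#' Blurs the image isotropically and searches (bracketing followed by
#' bisection) for the smallest kernel whose CNR between the two ROIs
#' reaches the target. Larger kernels trade resolution for noise: the
#' returned FWHM is the resolution limit at this dose. Returns 0 when the
#' unblurred image already meets the target and `NA` when no kernel up to
#' `max_fwhm_mm` does.
#'
#' @param recon a `bct_recon` or matrix.
#' @param roiA,roiB single-row ROI data frames.
#' @param target target CNR (default 5, the Rose criterion).
#' @param pixel_mm pixel size for bare matrices.
#' @param max_fwhm_mm largest kernel tried (default: the smaller ROI
#'   radius).
#' @param tol_px bisection tolerance in pixels.
#' @return FWHM in mm (0, positive, or `NA`).
#' @export
kernel_for_cnr <- function(recon, roiA, roiB, target = 5, pixel_mm = NULL,
                           max_fwhm_mm = NULL, tol_px = 0.05) {
  vals <- if (inherits(recon, "bct_recon")) recon$values else recon
  if (is.null(pixel_mm)) pixel_mm <- recon$pixel_mm
  if (is.null(max_fwhm_mm)) max_fwhm_mm <- min(roiA$r_mm, roiB$r_mm)
  fwhm_factor <- 2 * sqrt(2 * log(2))
  cnr_at <- function(sigma_px) {
    img <- if (sigma_px > 0) gaussian_blur(vals, sigma_px) else vals
    cnr(img, roiA, roiB, pixel_mm = pixel_mm)
  }
  if (cnr_at(0) >= target) return(0)
  hi <- 0.5
  max_sigma <- max_fwhm_mm / pixel_mm / fwhm_factor
  while (cnr_at(hi) < target) {
    hi <- hi * 2
    if (hi > max_sigma) return(NA_real_)
  }
  lo <- hi / 2
  while (hi - lo > tol_px) {
    mid <- (lo + hi) / 2
    if (cnr_at(mid) >= target) hi <- mid else lo <- mid
  }
  hi * fwhm_factor * pixel_mm
}

#' First-degree fit of kernel size versus dose
#'
#' Least-squares line through (dose, FWHM) points for one system and
#' tissue pair; the fitted line, rather than the individual noisy kernels,
#' defines the rendering kernel at each dose.
#'
#' @param dose_mGy dose levels.
#' @param fwhm_mm measured kernel sizes (NA rows are dropped).
#' @return Object of class `bct_dose_kernel_fit`: `slope`, `intercept`,
#'   `points`, and `predict(dose)` via [predict_kernel()].
#' @export
dose_kernel_fit <- function(dose_mGy, fwhm_mm) {
  keep <- is.finite(dose_mGy) & is.finite(fwhm_mm)
  stopifnot(sum(keep) >= 2)
  fit <- stats::lm(fwhm_mm[keep] ~ dose_mGy[keep])
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 points = data.frame(dose_mGy = dose_mGy[keep],
                                     fwhm_mm = fwhm_mm[keep])),
            class = "bct_dose_kernel_fit")
}

#' Predict the kernel size from a dose-kernel fit
#' @param fit a `bct_dose_kernel_fit`.
#' @param dose_mGy dose levels.
#' @return FWHM in mm.
#' @export
predict_kernel <- function(fit, dose_mGy) {
  fit$intercept + fit$slope * dose_mGy
}

#' Crossing dose of two dose-kernel lines
#'
#' Dose at which two systems deliver equal resolution at the target CNR.
#'
#' @param fit_a,fit_b `bct_dose_kernel_fit` objects.
#' @return Dose in mGy (may be negative or infinite if the lines do not
#'   cross at a physical dose).
#' @export
crossing_dose <- function(fit_a, fit_b) {
  if (fit_a$slope == fit_b$slope) return(Inf)
  (fit_b$intercept - fit_a$intercept) / (fit_a$slope - fit_b$slope)
}

#' Radially averaged noise power spectrum
#'
#' @param img matrix (noise field; the mean is removed).
#' @param n_bins number of radial frequency bins.
#' @return Data frame `freq` (cycles/pixel) and `power`.
#' @export
radial_nps <- function(img, n_bins = 24) {
  n <- nrow(img)
  F2 <- Mod(stats::fft(img - mean(img)))^2 / length(img)
  fx <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1) / n
  fr <- sqrt(outer(fx^2, fx^2, `+`))
  breaks <- seq(0, 0.5, length.out = n_bins + 1)
  bin <- cut(fr, breaks, include.lowest = TRUE)
  data.frame(freq = (breaks[-1] + breaks[-length(breaks)]) / 2,
             power = as.numeric(tapply(F2, bin, mean)))
}
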