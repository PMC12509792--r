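# Procedural breast phantom: adipose disc, band-pass-noise fibroglandular
# texture, a large tumor region, and small tumor inserts embedded in both
# adipose and fibroglandular surroundings, with evaluation ROIs.
#
# Label codes: 0 background (air), 1 adipose, 2 fibroglandular, 3 tumor.

PHANTOM_LABELS <- c(background = 0, adipose = 1, fibroglandular = 2,
                    tumor = 3)

# separable FFT Gaussian blur with periodic boundary; the transfer function
# is the exact DFT of a sampled, wrapped Gaussian, so blur(sigma = 0) is the
# identity and the DC gain is exactly 1 for any sigma
gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  blur1 <- function(n) {
    x <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)
    k <- exp(-x^2 / (2 * sigma_px^2))
    Re(stats::fft(k / sum(k)))
  }
  kr <- blur1(nrow(img)); kc <- blur1(ncol(img))
  Re(stats::fft(stats::fft(img) * outer(kr, kc), inverse = TRUE)) /
    length(img)
}

#' Build a procedural breast phantom
#'
#' A 2D central-slice phantom: an adipose disc of the requested diameter, a
#' fibroglandular compartment generated by thresholding two-scale band-pass
#' filtered white noise (threshold set by quantile so the glandular area
#' fraction hits its target), one large tumor region, and small tumor
#' inserts of the given radii placed once in a pure-adipose pocket and once
#' in a solid fibroglandular island. When the diameter changes, all
#' structural length scales follow it while the insert radii stay fixed in
#' millimetres. Deterministic for a fixed seed.
#'
#' @param diameter_cm phantom diameter, 6-20 cm.
#' @param pixel_mm grid pixel size in mm.
#' @param insert_radii_mm radii of the small tumor inserts (each must be at
#'   least two pixels).
#' @param seed integer seed for the texture noise.
#' @param glandular_fraction target fibroglandular area fraction of the
#'   disc (before tumor insertion), default 0.4.
#' @return Object of class `bct_phantom`: integer label matrix plus
#'   `pixel_mm`, `diameter_cm`, `materials` (label-to-material map), `rois`
#'   (data frame of named circular ROIs in mm, origin at the centre) and
#'   `seed`.
#' @export
#' @examples
#' ph <- build_phantom(12, 0.5, insert_radii_mm = 1, seed = 1)
#' table(ph$labels) / length(ph$labels)
build_phantom <- function(diameter_cm = 12, pixel_mm = 0.1,
                          insert_radii_mm = c(1, 0.5, 0.25), seed = 1,
                          glandular_fraction = 0.4) {
  stopifnot(diameter_cm >= 6, diameter_cm <= 20, pixel_mm > 0)
  if (any(insert_radii_mm < 2 * pixel_mm)) {
    stop("insert radii must be at least two pixels")
  }
  R_mm <- diameter_cm * 10 / 2
  n <- 2 * ceiling(R_mm * 1.04 / pixel_mm) + 1
  ax <- (seq_len(n) - (n + 1) / 2) * pixel_mm
  X <- matrix(ax, n, n); Y <- matrix(ax, n, n, byrow = TRUE)
  rr <- sqrt(X^2 + Y^2)
  disc <- rr <= R_mm
  lab <- matrix(PHANTOM_LABELS["background"], n, n)
  lab[disc] <- PHANTOM_LABELS["adipose"]

  # fibroglandular texture: band-pass filtered white noise, thresholded at
  # the quantile that yields the target glandular area of the whole disc
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  noise <- matrix(stats::rnorm(n * n), n, n)
  s_fine <- (diameter_cm * 10 / 120) / pixel_mm    # ~1 mm at 12 cm
  s_coarse <- (diameter_cm * 10 / 24) / pixel_mm   # ~5 mm at 12 cm
  bp <- gaussian_blur(noise, s_fine) - gaussian_blur(noise, s_coarse)
  core <- disc & rr <= 0.85 * R_mm                 # keep an adipose rim
  target_px <- glandular_fraction * sum(disc)
  if (target_px > sum(core)) stop("glandular fraction too large for core")
  thr <- stats::quantile(bp[core], 1 - target_px / sum(core))
  lab[core & bp > thr] <- PHANTOM_LABELS["fibroglandular"]

  paint <- function(lab, cx, cy, r, value) {
    lab[(X - cx)^2 + (Y - cy)^2 <= r^2] <- value
    lab
  }
  # large tumor region
  r_tum <- 0.12 * R_mm
  tum_c <- 0.45 * R_mm * c(cos(-pi / 4), sin(-pi / 4))
  lab <- paint(lab, tum_c[1], tum_c[2], r_tum, PHANTOM_LABELS["tumor"])

  # solid fibroglandular island and pure adipose pocket hosting the small
  # inserts, plus homogeneous reference pads for large-ROI measurements;
  # pads are painted before the inserts so they can never overwrite them
  s_max <- max(insert_radii_mm)
  r_pocket <- max(4 * s_max, 5)
  fg_c <- 0.45 * R_mm * c(cos(3 * pi / 4), sin(3 * pi / 4))
  ad_c <- 0.45 * R_mm * c(cos(-3 * pi / 4), sin(-3 * pi / 4))
  lab <- paint(lab, fg_c[1], fg_c[2], r_pocket,
               PHANTOM_LABELS["fibroglandular"])
  lab <- paint(lab, ad_c[1], ad_c[2], r_pocket, PHANTOM_LABELS["adipose"])
  ref_r <- 0.6 * r_tum
  fg_ref <- 0.55 * R_mm * c(cos(pi / 2), sin(pi / 2))
  ad_ref <- 0.62 * R_mm * c(1, 0)
  lab <- paint(lab, fg_ref[1], fg_ref[2], ref_r * 1.3,
               PHANTOM_LABELS["fibroglandular"])
  lab <- paint(lab, ad_ref[1], ad_ref[2], ref_r * 1.3,
               PHANTOM_LABELS["adipose"])

  rois <- list()
  add_roi <- function(name, cx, cy, r, tissue) {
    rois[[length(rois) + 1]] <<- data.frame(
      name = name, cx_mm = cx, cy_mm = cy, r_mm = r, tissue = tissue)
  }
  ring <- 2.2 * s_max
  for (k in seq_along(insert_radii_mm)) {
    r_i <- insert_radii_mm[k]
    th <- 2 * pi * (k - 1) / max(length(insert_radii_mm), 3)
    off <- ring * c(cos(th), sin(th))
    for (surround in c("adipose", "fibroglandular")) {
      ctr <- (if (surround == "adipose") ad_c else fg_c) + off
      lab <- paint(lab, ctr[1], ctr[2], r_i, PHANTOM_LABELS["tumor"])
      add_roi(sprintf("insert_%s_%g", surround, r_i), ctr[1], ctr[2],
              0.7 * r_i, "tumor")
    }
  }
  add_roi("surround_adipose", ad_c[1], ad_c[2], 0.9 * s_max, "adipose")
  add_roi("surround_fibroglandular", fg_c[1], fg_c[2], 0.9 * s_max,
          "fibroglandular")
  # large reference ROIs for normalization and CNR measurement
  add_roi("tumor_ref", tum_c[1], tum_c[2], ref_r, "tumor")
  add_roi("adipose_ref", ad_ref[1], ad_ref[2], ref_r, "adipose")
  add_roi("fibroglandular_ref", fg_ref[1], fg_ref[2], ref_r,
          "fibroglandular")

  structure(list(
    labels = lab, pixel_mm = pixel_mm, diameter_cm = diameter_cm,
    materials = c("adipose", "fibroglandular", "tumor"),
    rois = do.call(rbind, rois), seed = seed,
    glandular_fraction = glandular_fraction),
    class = "bct_phantom")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' @export
print.bct_phantom <- function(x, ...) {
  fr <- mean(x$labels == PHANTOM_LABELS["fibroglandular"]) /
    mean(x$labels != PHANTOM_LABELS["background"])
  cat(sprintf(paste0("<bct_phantom> %g cm, %g mm pixels (%d x %d), ",
                     "glandular fraction %.2f, %d ROIs\n"),
              x$diameter_cm, x$pixel_mm, nrow(x$labels), ncol(x$labels),
              fr, nrow(x$rois)))
  invisible(x)
}

#' Glandular area fraction of a phantom
#' @param phantom a `bct_phantom`.
#' @return Fibroglandular pixels over disc pixels.
#' @export
glandular_fraction <- function(phantom) {
  inside <- phantom$labels != PHANTOM_LABELS["background"]
  sum(phantom$labels == PHANTOM_LABELS["fibroglandular"]) / sum(inside)
}

#' Per-pixel attenuation and refraction maps at one energy
#'
#' @param phantom a `bct_phantom`.
#' @param E_keV energy in keV.
#' @return List with `mu` (1/cm) and `delta` (dimensionless) matrices;
#'   background pixels are zero (air).
#' @export
material_maps <- function(phantom, E_keV) {
  stopifnot(inherits(phantom, "bct_phantom"), length(E_keV) == 1)
  mu_map <- matrix(0, nrow(phantom$labels), ncol(phantom$labels))
  de_map <- mu_map
  for (name in phantom$materials) {
    m <- bct_material(name)
    sel <- phantom$labels == PHANTOM_LABELS[name]
    mu_map[sel] <- mu(m, E_keV)
    de_map[sel] <- delta(m, E_keV)
  }
  list(mu = mu_map, delta = de_map)
}

# pixel mask of a circular ROI on an arbitrary centred grid
roi_mask <- function(roi, n, pixel_mm) {
  ax <- (seq_len(n) - (n + 1) / 2) * pixel_mm
  X <- matrix(ax, n, n); Y <- matrix(ax, n, n, byrow = TRUE)
  (X - roi$cx_mm)^2 + (Y - roi$cy_mm)^2 <= roi$r_mm^2
}

#' Save a phantom as a TIFF label image with a JSON sidecar
#'
#' @param phantom a `bct_phantom`.
#' @param path output TIFF path; the sidecar gets extension `.json`.
#' @export
write_phantom <- function(phantom, path) {
  tiff::writeTIFF(phantom$labels / max(PHANTOM_LABELS), path,
                  bits.per.sample = 8)
  side <- sub("\\.tiff?$", ".json", path)
  jsonlite::write_json(list(
    pixel_mm = phantom$pixel_mm, diameter_cm = phantom$diameter_cm,
    materials = phantom$materials, seed = phantom$seed,
    labels = as.list(PHANTOM_LABELS),
    rois = phantom$rois), side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
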