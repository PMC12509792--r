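# shared fixtures built in code

# uniform single-material disc phantom (material name = label 1)
disc_phantom <- function(material = "water", diameter_cm = 6,
                         pixel_mm = 0.25) {
  R_mm <- diameter_cm * 10 / 2
  n <- 2 * ceiling(R_mm * 1.04 / pixel_mm) + 1
  ax <- (seq_len(n) - (n + 1) / 2) * pixel_mm
  rr <- sqrt(outer(ax^2, ax^2, `+`))
  lab <- matrix(0L, n, n)
  lab[rr <= R_mm] <- 1L
  structure(list(labels = lab, pixel_mm = pixel_mm,
                 diameter_cm = diameter_cm, materials = material,
                 rois = NULL, seed = 0), class = "bct_phantom")
}

empty_phantom <- function(diameter_cm = 6, pixel_mm = 0.25) {
  ph <- disc_phantom("water", diameter_cm, pixel_mm)
  ph$labels[] <- 0L
  ph
}

# monochromatic single-bin spectrum at E0
mono_spectrum <- function(E0) {
  gibct::spectrum(E0, 1, kvp = E0 + 0.5)
}

# plain sinogram container for phase-stepping tests
psc_inputs <- function(n_px, trans = 1, dpc = 0, vis = 0.23, red = NULL) {
  structure(list(transmission = matrix(trans, n_px, 1),
                 dpc = matrix(dpc, n_px, 1),
                 visibility = matrix(vis, n_px, 1),
                 reduction = red),
            class = "bct_sinograms")
}

# small fast geometry for reconstruction tests
test_geometry <- function(det_pixel_mm = 0.4, n_proj = 360, fov_cm = 6.5) {
  fan_geometry(0.896, 0.546, det_pixel_mm = det_pixel_mm, n_proj = n_proj,
               fov_cm = fov_cm)
}

# centre patch mean of a reconstruction
centre_mean <- function(recon, half = 5) {
  n <- nrow(recon$values)
  c0 <- (n + 1) / 2
  mean(recon$values[(c0 - half):(c0 + half), (c0 - half):(c0 + half)])
}
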