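# End-to-end workflows: the design grid search and the in-silico
# simulation/evaluation study, with YAML-configurable entry points used by
# the command-line scripts in inst/cli.

#' Resolution/runtime profiles for the simulation chain
#'
#' `"full"` mirrors the nominal acquisition (200 um detector pixels, 1000
#' projections); `"ci"` is a reduced-scale profile for routine testing
#' (coarser grids, fewer projections) that preserves every modelling step.
#'
#' @param name `"full"` or `"ci"`.
#' @return List of profile parameters.
#' @export
simulation_profile <- function(name = c("ci", "full")) {
  name <- match.arg(name)
  if (name == "full") {
    list(name = "full", det_pixel_mm = 0.2, n_proj = 1000, recon_n = 512,
         phantom_pixel_mm = 0.1, n_steps = 5,
         insert_radii_mm = c(1, 0.5, 0.25), step_factor = 0.5)
  } else {
    list(name = "ci", det_pixel_mm = 0.6, n_proj = 320, recon_n = 220,
         phantom_pixel_mm = 0.5, n_steps = 5,
         insert_radii_mm = 1, step_factor = 1)
  }
}

# per-channel normalization to a tissue pair: the higher-valued tissue maps
# to 1, the lower to 0 (channel-wise, so inverse-contrast channels still
# land on [0, 1])
normalize_to_pair <- function(recon, rois, tissue_a, tissue_b) {
  ra <- rois[rois$name == paste0(tissue_a, "_ref"), ]
  rb <- rois[rois$name == paste0(tissue_b, "_ref"), ]
  vals <- recon$values
  n <- nrow(vals)
  ma <- mean(vals[roi_mask(ra, n, recon$pixel_mm)])
  mb <- mean(vals[roi_mask(rb, n, recon$pixel_mm)])
  if (ma >= mb) normalize_pair(recon, rb, ra) else normalize_pair(recon, ra, rb)
}

# fusion kernel selection: minimize the variance of the fused image over a
# homogeneous reference patch (proxy for the integrated noise power
# spectrum) on a geometric sigma grid
choose_fusion_sigma <- function(att, dpc, roi, sigma_grid = NULL) {
  if (is.null(sigma_grid)) sigma_grid <- exp(seq(log(0.5), log(8),
                                                 length.out = 10))
  n <- nrow(att$values)
  mask <- roi_mask(roi, n, att$pixel_mm)
  v <- vapply(sigma_grid, function(s) {
    stats::var(fuse(att, dpc, s)$values[mask])
  }, numeric(1))
  sigma_grid[which.min(v)]
}

#' Simulate and evaluate one system over dose levels
#'
#' Runs the complete in-silico chain for a benchmark system: forward
#' projection, dose-budgeted Poisson phase stepping (or plain counting for
#' the gratingless system), signal retrieval, FBP of both channels, fusion
#' (grating systems), and the kernel-size-for-target-CNR analysis for each
#' tissue pair.
#'
#' @param system a `bct_system`.
#' @param phantom a `bct_phantom`.
#' @param doses_mGy dose levels in mGy.
#' @param seed integer seed for the noise.
#' @param profile list from [simulation_profile()].
#' @param pairs list of 2-vectors of tissue names to evaluate.
#' @param target_cnr CNR target for the kernel search.
#' @param keep_images also return the reconstructed images.
#' @return List: `report` (data frame with one row per dose, pair and
#'   channel: CNR of the raw image, kernel FWHM to reach the target, and
#'   the phase-noise-floor flag) and `images` (when requested).
#' @export
evaluate_system <- function(system, phantom, doses_mGy, seed = 1,
                            profile = simulation_profile("ci"),
                            pairs = list(c("adipose", "fibroglandular"),
                                         c("adipose", "tumor"),
                                         c("fibroglandular", "tumor")),
                            target_cnr = 5, keep_images = FALSE) {
  system$det_pixel_mm <- profile$det_pixel_mm
  system$n_proj <- profile$n_proj
  geom <- fan_geometry(system$source_to_sample, system$d_sens,
                       det_pixel_mm = profile$det_pixel_mm,
                       n_proj = profile$n_proj,
                       fov_cm = phantom$diameter_cm)
  sinos <- project_sinograms(phantom, system, geom,
                             step_factor = profile$step_factor)
  recon_px <- phantom$diameter_cm * 10 * 1.06 / profile$recon_n
  rows <- list(); images <- list()
  for (di in seq_along(doses_mGy)) {
    dose <- doses_mGy[di]
    n_steps <- if (system$gratingless) 1 else profile$n_steps
    budget <- photons_for_dose(dose, sinos$spectrum, phantom$diameter_cm,
                               geom, profile$n_proj, n_steps, system)
    run_seed <- seed + 1000 * di
    if (system$gratingless) {
      old <- .Random.seed_save(); set.seed(run_seed)
      counts <- array(stats::rpois(length(sinos$transmission),
                                   sinos$transmission *
                                     budget$counts_per_step),
                      dim(sinos$transmission))
      .Random.seed_restore(old)
      trans <- counts / budget$counts_per_step
      att <- fbp(pmax(trans, 1e-12), geom, "ramlak",
                 recon_n = profile$recon_n, recon_pixel_mm = recon_px)
      channels <- list(attenuation = att)
      floor_ok <- NA
    } else {
      psc <- simulate_phase_stepping(sinos, budget$counts_per_step,
                                     n_steps, seed = run_seed)
      ret <- retrieve(psc)
      att <- fbp(pmax(ret$transmission, 1e-12), geom, "ramlak",
                 recon_n = profile$recon_n, recon_pixel_mm = recon_px)
      dpc <- fbp(ret$dpc, geom, "hilbert", recon_n = profile$recon_n,
                 recon_pixel_mm = recon_px,
                 p2_um = system$geometry$p2_um)
      channels <- list(attenuation = att, refraction = dpc)
      floor_ok <- phase_noise_floor_ok(mean(sinos$visibility),
                                       budget$counts_per_step, n_steps)
    }
    for (pair in pairs) {
      roiA <- phantom$rois[phantom$rois$name == paste0(pair[1], "_ref"), ]
      roiB <- phantom$rois[phantom$rois$name == paste0(pair[2], "_ref"), ]
      ch_eval <- list(attenuation =
                        normalize_to_pair(channels$attenuation,
                                          phantom$rois, pair[1], pair[2]))
      if (!system$gratingless) {
        dpc_n <- normalize_to_pair(channels$refraction, phantom$rois,
                                   pair[1], pair[2])
        sig <- choose_fusion_sigma(ch_eval$attenuation, dpc_n, roiA)
        ch_eval$fused <- fuse(ch_eval$attenuation, dpc_n, sig)
      }
      for (ch_name in names(ch_eval)) {
        img <- ch_eval[[ch_name]]
        rows[[length(rows) + 1]] <- data.frame(
          system = system$name, dose_mGy = dose,
          pair = paste(pair, collapse = "/"), channel = ch_name,
          cnr_raw = cnr(img, roiA, roiB),
          fwhm_mm = kernel_for_cnr(img, roiA, roiB, target = target_cnr),
          counts_per_step = budget$counts_per_step,
          phase_floor_ok = floor_ok)
      }
    }
    if (keep_images) images[[as.character(dose)]] <- channels
  }
  list(report = do.call(rbind, rows), images = images)
}

#' Run the design grid search workflow
#'
#' Enumerates the feasible space and writes, per imaging task, the
#' CNRD-versus-voltage curve of the best design at each voltage.
#'
#' @param config list (or path to a YAML file) with optional entries
#'   `space` (arguments of [search_space()]), `constraints` (arguments of
#'   [constraint_set()]), `tasks` (data frame or list with
#'   `breast_diameter_cm`, `malignancy_radius_mm`), `dose_exponent`,
#'   `out_dir`.
#' @return Invisible list with `designs`, `counts` and the per-task best
#'   curves; files are written when `out_dir` is set.
#' @export
run_gridsearch <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  space <- do.call(search_space, config$space %||% list())
  cs <- do.call(constraint_set, config$constraints %||% list())
  tasks <- config$tasks %||% expand.grid(breast_diameter_cm = c(9, 14, 18),
                                         malignancy_radius_mm =
                                           c(0.25, 0.5, 0.75))
  q <- config$dose_exponent %||% 0.5
  designs <- enumerate_feasible(space, cs)
  counts <- c(per_design = nrow(designs),
              per_tuple = sum(designs$n_L),
              per_design_g0_only = count_feasible(space, cs,
                                                  check_g2 = FALSE),
              per_tuple_g0_only = count_feasible(space, cs, "per_tuple",
                                                 check_g2 = FALSE))
  curves <- list()
  for (i in seq_len(nrow(tasks))) {
    task <- task_spec(tasks$breast_diameter_cm[i],
                      tasks$malignancy_radius_mm[i], dose_exponent = q)
    key <- sprintf("t%g_r%g", task$t_cm, task$r_mm)
    curves[[key]] <- best_per_voltage(designs, task, space$kvp,
                                      constraints = cs)
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(designs, file.path(config$out_dir,
                                        "feasible_designs.csv"),
                     row.names = FALSE)
    jsonlite::write_json(as.list(counts),
                         file.path(config$out_dir, "counts.json"),
                         auto_unbox = TRUE)
    for (key in names(curves)) {
      utils::write.csv(curves[[key]],
                       file.path(config$out_dir,
                                 paste0("cnrd_curve_", key, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(list(designs = designs, counts = counts, curves = curves))
}

#' Run the in-silico simulation workflow
#'
#' Builds (or reuses) a phantom, simulates each requested system at each
#' dose, and writes the kernel/CNR evaluation report.
#'
#' @param config list (or YAML path) with optional entries `systems`
#'   (names among `gi_bct`, `optica_2023`, `ab_ct`), `doses_mGy`,
#'   `diameter_cm`, `seed`, `profile` (`"ci"` or `"full"`), `out_dir`,
#'   `write_images`.
#' @return Invisible combined report data frame.
#' @export
run_simulation <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  systems <- benchmark_systems()[config$systems %||%
                                   c("gi_bct", "optica_2023", "ab_ct")]
  doses <- config$doses_mGy %||% c(5, 10, 20, 50, 100)
  seed <- config$seed %||% 1
  profile <- simulation_profile(config$profile %||% "ci")
  phantom <- build_phantom(config$diameter_cm %||% 12,
                           profile$phantom_pixel_mm,
                           insert_radii_mm = profile$insert_radii_mm,
                           seed = seed)
  reports <- list()
  for (sys in systems) {
    res <- evaluate_system(sys, phantom, doses, seed = seed,
                           profile = profile,
                           keep_images = isTRUE(config$write_images))
    reports[[sys$name]] <- res$report
    if (isTRUE(config$write_images) && !is.null(config$out_dir)) {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      for (dose in names(res$images)) {
        for (ch in names(res$images[[dose]])) {
          img <- res$images[[dose]][[ch]]$values
          rng <- range(img)
          tiff::writeTIFF((img - rng[1]) / max(diff(rng), 1e-12),
                          file.path(config$out_dir,
                                    sprintf("%s_%smGy_%s.tiff",
                                            gsub("[^A-Za-z0-9]", "_",
                                                 sys$name), dose, ch)))
        }
      }
    }
  }
  report <- do.call(rbind, reports)
  rownames(report) <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report, file.path(config$out_dir, "evaluation.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(seed = seed, profile = profile$name,
                              doses_mGy = doses),
                         file.path(config$out_dir, "run_config.json"),
                         auto_unbox = TRUE)
  }
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
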