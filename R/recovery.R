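#' Desk-scale synthetic parameter-recovery experiment
#'
#' Runs the whole validation loop on a synthetic root system with known
#' ground truth: generate a 10-root system, scan it from three viewpoints at
#' 120 degrees with 2 mm range noise, sweep QSM reconstruction over the
#' 18-value PatchDiam grid, fit interpolation lines per trait, intersect each
#' with the true trait value, brute-force refine around each optimum (5
#' models per candidate) and build a 20-model ensemble at the selected
#' PatchDiam, summarized by median and 5th/95th percentiles.
#'
#' The traits calibrated are total root length (m), total root volume (dm^3)
#' and the number of first-order roots. The default scene is a desk-scale
#' system (taproot 0.8 m, first-order roots 0.45-0.7 m) scanned at an angular
#' step giving roughly 2 mm point spacing, sized so the ~160 reconstructions
#' complete in minutes; `scene = "study"` uses the full field-scale
#' dimensions (1.2 m taproot, roots to 1.1 m).
#'
#' @param seed base seed; the generator, scanner and all reconstruction seeds
#'   derive from it deterministically.
#' @param scene `"desk"` (default) or `"study"`.
#' @param grid PatchDiam grid, mm.
#' @param n_sweep_seeds replicate models per grid value.
#' @param n_refine models per refinement candidate.
#' @param n_models ensemble size.
#' @param angular_step_deg scanner angular step; default 0.025 for the desk
#'   scene, 0.05 for the study scene.
#' @param config a [qsm_config()].
#' @return list with `truth` (trait references), `cloud_size`,
#'   `spacing_mm`, `sweep` (the [sweep_patchdiam()] result), and per trait:
#'   interpolation line, optimum, selected PatchDiam, ensemble summaries and
#'   relative recovery error of the ensemble median.
#' @export
recovery_experiment <- function(seed = 1L, scene = c("desk", "study"),
                                grid = default_patchdiam_grid(),
                                n_sweep_seeds = 3L, n_refine = 5L,
                                n_models = 20L, angular_step_deg = NULL,
                                config = qsm_config()) {
  scene <- match.arg(scene)
  seed <- as.integer(seed)
  spec <- if (scene == "desk") {
    root_system_spec(taproot_depth = 0.8, taproot_radius = 0.055,
                     n_first = 10L, first_radius = c(0.015, 0.026),
                     first_length = c(0.45, 0.7), second_per_first = 0.7,
                     third_per_second = 0.4, seed = seed)
  } else {
    root_system_spec(n_first = 10L, seed = seed)
  }
  if (is.null(angular_step_deg))
    angular_step_deg <- if (scene == "desk") 0.025 else 0.05
  truth <- generate_system(spec)
  tt <- truth_traits(truth,
                     min_proximal_diam = config$min_proximal_diam_cm,
                     depth_threshold = config$depth_threshold_m)
  refs <- c(length = unname(tt$totals["length_m"]),
            volume = unname(tt$totals["volume_dm3"]),
            number = tt$by_order$number[match(1L, tt$by_order$order)])
  scanner <- scanner_spec(range_m = if (scene == "desk") 4 else 4.5,
                          angular_step_deg = angular_step_deg,
                          seed = seed + 500L)
  cloud <- scan_system(truth, scanner)
  dens <- estimate_density(cloud, probe_patch_diam = 30, seed = seed)

  sweep_seeds <- seed * 10L + seq_len(n_sweep_seeds)
  sw <- sweep_patchdiam(cloud, grid = grid, seeds = sweep_seeds,
                        config = config, number_order = 1L)
  traits <- list()
  for (tr in c("length", "volume", "number")) {
    line <- fit_interpolation(sw, tr)
    opt <- suppressWarnings(intersect_reference(line, refs[[tr]], sw$grid))
    # The intersection is only meaningful when the line actually describes
    # the trait's response (the calibration protocol presupposes strong
    # linear fits). When the fit is poor (R^2 < 0.5) or the intersection
    # leaves the swept range, fall back to the grid value whose mean trait
    # is empirically closest to the reference; the brute-force refinement
    # still probes around whichever optimum is chosen.
    if (!opt$in_grid || !is.finite(opt$optimum) || line$r2 < 0.5)
      opt$optimum <- sw$means$patch_diam[
        which.min(abs(sw$means[[tr]] - refs[[tr]]))]
    re <- refine_and_ensemble(cloud, opt$optimum, refs[[tr]], trait = tr,
                              n_refine = n_refine, n_models = n_models,
                              seed = seed, config = config,
                              number_order = 1L)
    med <- re$summaries[tr, "median"]
    traits[[tr]] <- list(line = line, optimum = opt$optimum,
                         selected_patch_diam = re$selected_patch_diam,
                         summaries = re$summaries,
                         n_ensemble_models = nrow(re$models),
                         reference = refs[[tr]],
                         median = med,
                         rel_error = med / refs[[tr]] - 1)
  }
  list(truth = refs, truth_system = truth, cloud_size = nrow(cloud$points),
       spacing_mm = dens$median_spacing_mm, sweep = sw, traits = traits,
       seed = seed, scene = scene)
}
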