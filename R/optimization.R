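#' The default PatchDiam grid (mm)
#'
#' The 18-value grid swept during calibration:
#' 5, 7.5, 10, 12.5, 15, 17.5, 20, 25, 30, 35, 40, 45, 50, 60, 70, 80, 90,
#' 100 mm.
#' @export
default_patchdiam_grid <- function() {
  c(5, 7.5, 10, 12.5, 15, 17.5, 20, 25, 30, 35, 40, 45, 50, 60, 70, 80, 90,
    100)
}

#' Sweep QSM reconstruction over a PatchDiam grid
#'
#' Builds one QSM per (grid value, seed), computes total traits (length m,
#' volume dm^3, number of roots) and stores per-model values plus the mean
#' per grid value. Grid values where every replicate fails are flagged and
#' excluded with a warning.
#'
#' @param cloud a [root_cloud()] with frame set.
#' @param grid PatchDiam values, mm; strictly increasing, positive.
#' @param seeds one seed per replicate model at each grid value.
#' @param config a [qsm_config()].
#' @param number_order if given, the "number" trait counts only roots of
#'   this order (e.g. 1 for first-order roots); default counts all coarse
#'   roots.
#' @return object of class `sweep_result`: `models` (per-model data.frame),
#'   `means` (per grid value), `grid`, `seeds`, `number_order`.
#' @export
sweep_patchdiam <- function(cloud, grid = default_patchdiam_grid(),
                            seeds = 1:3, config = qsm_config(),
                            number_order = NULL) {
  if (length(grid) == 0L || any(grid <= 0) || is.unsorted(grid,
                                                          strictly = TRUE))
    stop("`grid` must be positive and strictly increasing", call. = FALSE)
  rows <- list()
  for (gi in seq_along(grid)) {
    for (si in seq_along(seeds)) {
      tr <- tryCatch({
        qsm <- build_qsm(cloud, grid[gi], seed = seeds[si], config = config)
        t <- compute_traits(qsm,
                            min_proximal_diam = config$min_proximal_diam_cm,
                            depth_threshold = config$depth_threshold_m,
                            include_taproot = config$include_taproot)
        num <- if (is.null(number_order)) unname(t$totals["number"]) else
          t$by_order$number[match(number_order, t$by_order$order)]
        data.frame(patch_diam = grid[gi], seed = seeds[si],
                   length = unname(t$totals["length_m"]),
                   volume = unname(t$totals["volume_dm3"]),
                   number = num %||% 0,
                   n_patches = qsm$provenance$n_patches)
      }, error = function(e) {
        warning(sprintf("QSM failed at PatchDiam %.1f mm (seed %d): %s",
                        grid[gi], seeds[si], conditionMessage(e)),
                call. = FALSE)
        NULL
      })
      if (!is.null(tr)) rows[[length(rows) + 1L]] <- tr
    }
  }
  models <- do.call(rbind, rows)
  if (is.null(models) || nrow(models) == 0L)
    stop("all QSM reconstructions failed", call. = FALSE)
  means <- do.call(rbind, lapply(split(models, models$patch_diam),
                                 function(d) data.frame(
    patch_diam = d$patch_diam[1], length = mean(d$length),
    volume = mean(d$volume), number = mean(d$number),
    n_patches = mean(d$n_patches), n_models = nrow(d))))
  means <- means[order(means$patch_diam), ]
  rownames(means) <- NULL
  structure(list(models = models, means = means, grid = grid, seeds = seeds,
                 number_order = number_order),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d grid values x %d seeds\n",
              length(x$grid), length(x$seeds)))
  print(x$means, row.names = FALSE)
  invisible(x)
}

#' Straight-line interpolation of a swept trait
#'
#' Ordinary least-squares line of the per-grid-value mean trait on
#' PatchDiam.
#'
#' @param sweep a [sweep_patchdiam()] result.
#' @param trait `"length"`, `"volume"` or `"number"`.
#' @return list with `intercept`, `slope`, `r2`.
#' @export
fit_interpolation <- function(sweep, trait = c("length", "volume",
                                               "number")) {
  trait <- match.arg(trait)
  d <- sweep$means[is.finite(sweep$means[[trait]]), ]
  if (nrow(d) < 2L)
    stop("need at least 2 valid grid points to fit a line", call. = FALSE)
  if (stats::sd(d[[trait]]) < 1e-12)
    stop("degenerate fit: trait has zero variance across the grid",
         call. = FALSE)
  fit <- stats::lm(d[[trait]] ~ d$patch_diam)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       r2 = summary(fit)$r.squared)
}

#' Optimum PatchDiam by intersection with a reference trait value
#'
#' Solves `reference = intercept + slope * x` for x. An intersection outside
#' the swept grid hull is returned with a warning and flagged.
#'
#' @param line list with `intercept` and `slope` (from
#'   [fit_interpolation()]).
#' @param reference_value reference trait value (same units as the sweep).
#' @param grid optional grid for the in-hull check.
#' @return list with `optimum` (mm) and `in_grid`.
#' @export
intersect_reference <- function(line, reference_value, grid = NULL) {
  if (!is.finite(line$slope) || line$slope == 0)
    stop("no intersection: interpolation line has zero slope", call. = FALSE)
  x <- (reference_value - line$intercept) / line$slope
  in_grid <- TRUE
  if (!is.null(grid)) {
    in_grid <- x >= min(grid) && x <= max(grid)
    if (!in_grid)
      warning(sprintf("optimum %.1f mm lies outside the swept grid [%g, %g]",
                      x, min(grid), max(grid)), call. = FALSE)
  }
  list(optimum = x, in_grid = in_grid)
}

#' Ensemble percentile summary
#'
#' Median (50th), 5th and 95th percentiles with linear interpolation between
#' order statistics (quantile type 7).
#'
#' @param values numeric vector of per-model trait values.
#' @return named vector `median`, `p5`, `p95`.
#' @export
ensemble_summary <- function(values) {
  q <- stats::quantile(values, c(0.5, 0.05, 0.95), type = 7, names = FALSE)
  c(median = q[1], p5 = q[2], p95 = q[3])
}

#' Brute-force refinement and model ensemble at an optimum PatchDiam
#'
#' Evaluates `n_refine` replicate QSMs at each candidate PatchDiam around the
#' interpolated optimum (`optimum * candidates`), selects the candidate whose
#' mean trait is closest to the reference value, then builds `n_models` QSMs
#' at the selected value with distinct seeds and summarizes each trait by
#' median, 5th and 95th percentiles.
#'
#' @param cloud a [root_cloud()].
#' @param optimum interpolated optimum PatchDiam, mm.
#' @param reference_value reference value of `trait` used to pick the
#'   refinement candidate.
#' @param trait trait driving the refinement.
#' @param n_refine models per refinement candidate.
#' @param n_models ensemble size at the selected PatchDiam.
#' @param candidates candidate multipliers around the optimum.
#' @param seed base seed; replicate seeds are derived deterministically.
#' @param config a [qsm_config()].
#' @param number_order passed to [sweep_patchdiam()].
#' @return list: `selected_patch_diam`, `refinement` (candidate means),
#'   `models` (per-model ensemble traits), `summaries` (median/p5/p95 per
#'   trait).
#' @export
refine_and_ensemble <- function(cloud, optimum, reference_value,
                                trait = c("length", "volume", "number"),
                                n_refine = 5L, n_models = 20L,
                                candidates = c(0.9, 1.0, 1.1), seed = 1L,
                                config = qsm_config(), number_order = NULL) {
  trait <- match.arg(trait)
  .assert_scalar_pos(optimum, "optimum")
  cand <- optimum * candidates
  ref_means <- numeric(length(cand))
  for (ci in seq_along(cand)) {
    sw <- sweep_patchdiam(cloud, grid = cand[ci],
                          seeds = seed + 100L * ci + seq_len(n_refine),
                          config = config, number_order = number_order)
    ref_means[ci] <- sw$means[[trait]][1]
  }
  sel <- cand[which.min(abs(ref_means - reference_value))]
  ens <- sweep_patchdiam(cloud, grid = sel,
                         seeds = seed + 10000L + seq_len(n_models),
                         config = config, number_order = number_order)
  summaries <- rbind(
    length = ensemble_summary(ens$models$length),
    volume = ensemble_summary(ens$models$volume),
    number = ensemble_summary(ens$models$number))
  list(selected_patch_diam = sel,
       refinement = data.frame(patch_diam = cand, mean = ref_means),
       models = ens$models, summaries = summaries)
}

#' Agreement regression between reference and predicted traits
#'
#' OLS regression of the reference (digitized) trait values on the predicted
#' (TLS ensemble mean) values across root systems, with the variance
#' explained and the two-sided p-value of the slope.
#'
#' @param reference_values per-system reference trait values.
#' @param predicted_means per-system predicted trait means.
#' @return list: `slope`, `intercept`, `r2`, `p`.
#' @export
agreement_regression <- function(reference_values, predicted_means) {
  if (length(reference_values) != length(predicted_means))
    stop("reference and predicted vectors must have equal length",
         call. = FALSE)
  if (length(reference_values) < 3L)
    stop("need at least 3 root systems", call. = FALSE)
  fit <- stats::lm(reference_values ~ predicted_means)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = s$r.squared, p = unname(s$coefficients[2, 4]))
}
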