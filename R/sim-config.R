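#' Simulation configuration for synthetic chip images
#'
#' Collects every tunable of the synthetic image generator in one validated
#' object. Intensities are arbitrary camera units (the analysis never relies
#' on absolute values); geometry is in um and converted with the layout's
#' pixel size at render time.
#'
#' Defaults emulate the study conditions of a hepatoma (H4-II-EC3) chip:
#' spheroid equivalent diameters 72.9 +/- 18.6 um, about 85% spheroids /
#' 9% aggregates / 6% cell units, ~20 detectable nuclei per spheroid
#' (130k nuclei over ~6000 spheroids), a 5% dead-cell fraction placed
#' edge-biased (r/R ~ 0.8), a 16% BrdU-positive fraction enriched at
#' r/R 0.8-1, ALB peak amplitudes flat up to r/R = 0.4 then rising towards
#' the rim, and a dome-shaped out-of-focus background
#' `a (r/R)^3 + b (r/R)^2 + c` from the volume effect.
#'
#' @param background fluorescence background level.
#' @param bf_background bright-field background level.
#' @param noise_sd additive Gaussian read-noise sd (0 = noise-free).
#' @param poisson_noise if TRUE, Poisson shot noise is applied after the
#'   Gaussian component.
#' @param blur_sigma_px global PSF blur applied to bright-field renders (px).
#' @param rim_width_px half-width of the dark anchor rim (px).
#' @param speckle_sd bright-field texture contrast inside objects.
#' @param nuclei_per_spheroid mean nucleus count for a 73-um spheroid
#'   (scaled with projected area for other sizes).
#' @param nucleus_sigma_um Gaussian sigma of a rendered nucleus (um);
#'   converted with the layout's pixel size at render time.
#' @param cell_radial_exponent exponent of the planted radial cell-density
#'   law: r/R is drawn as U^(1/e). e = 2 is uniform in the disk; the default
#'   1.4 packs nuclei more densely in the core, so nearest-neighbour
#'   distances grow towards the rim.
#' @param cell_min_separation_um minimum distance between planted nuclei
#'   (um); nuclei are physical objects and cannot overlap.
#' @param dead_fraction fraction of cells planted dead.
#' @param dead_bias placement of dead cells: `"edge"` (r/R ~ Beta(8, 2),
#'   mean 0.8), `"core"` (Beta(2, 8)) or `"uniform"`.
#' @param brdu_fraction overall BrdU-positive fraction.
#' @param brdu_edge_boost multiplicative enrichment of BrdU+ probability at
#'   r/R >= 0.8.
#' @param dapi_amplitude,dead_amplitude mean spot amplitudes (log-normal,
#'   cv `amp_cv`).
#' @param brdu_ratio_neg,brdu_ratio_pos mean BrdU/DAPI amplitude ratio of
#'   negative and positive nuclei.
#' @param amp_cv log-normal coefficient of variation of spot amplitudes.
#' @param dapi_diffuse amplitude of the diffuse (out-of-focus) component
#'   filling the spheroid footprint in the nuclear channel; this is what
#'   makes whole-spheroid masks recoverable by thresholding.
#' @param alb_profile function of r/R in `[0, 1]` giving the mean ALB peak
#'   amplitude at that radial position.
#' @param dome_coeffs numeric `c(a, b, c)` of the out-of-focus background
#'   `a x^3 + b x^2 + c` in x = r/R over the spheroid footprint.
#' @param diameter_mean_um,diameter_sd_um spheroid equivalent-diameter
#'   distribution (truncated normal, > 41 um).
#' @param class_probs probabilities of planting a spheroid / aggregate /
#'   cell unit at an anchor.
#' @param frame_interval_min,duration_h time-lapse cadence and span.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(background = 20,
                       bf_background = 200,
                       noise_sd = 2,
                       poisson_noise = FALSE,
                       blur_sigma_px = 1,
                       rim_width_px = 1.5,
                       speckle_sd = 12,
                       nuclei_per_spheroid = 20,
                       nucleus_sigma_um = 3.2,
                       cell_radial_exponent = 1.4,
                       cell_min_separation_um = 7,
                       dead_fraction = 0.05,
                       dead_bias = c("edge", "core", "uniform"),
                       brdu_fraction = 0.16,
                       brdu_edge_boost = 1.5,
                       dapi_amplitude = 80,
                       dead_amplitude = 90,
                       brdu_ratio_neg = 0.2,
                       brdu_ratio_pos = 0.8,
                       amp_cv = 0.15,
                       dapi_diffuse = 40,
                       alb_profile = function(rr) 60 * (1 + 0.8 * pmax(rr - 0.4, 0) / 0.6),
                       dome_coeffs = c(a = -5, b = -20, c = 40),
                       diameter_mean_um = 72.9,
                       diameter_sd_um = 18.6,
                       class_probs = c(spheroid = 0.85, aggregate = 0.09, unit = 0.06),
                       frame_interval_min = 20,
                       duration_h = 23) {
  dead_bias <- match.arg(dead_bias)
  stopifnot(
    noise_sd >= 0, speckle_sd >= 0, blur_sigma_px >= 0,
    dead_fraction >= 0, dead_fraction <= 1,
    brdu_fraction >= 0, brdu_fraction <= 1,
    length(dome_coeffs) == 3,
    abs(sum(class_probs) - 1) < 1e-6,
    is.function(alb_profile)
  )
  if ((duration_h * 60) %% frame_interval_min != 0) {
    abort("`frame_interval_min` must divide `duration_h` evenly.")
  }
  structure(
    list(
      background = background, bf_background = bf_background,
      noise_sd = noise_sd, poisson_noise = poisson_noise,
      blur_sigma_px = blur_sigma_px, rim_width_px = rim_width_px,
      speckle_sd = speckle_sd,
      nuclei_per_spheroid = nuclei_per_spheroid,
      nucleus_sigma_um = nucleus_sigma_um,
      cell_radial_exponent = cell_radial_exponent,
      cell_min_separation_um = cell_min_separation_um,
      dead_fraction = dead_fraction, dead_bias = dead_bias,
      brdu_fraction = brdu_fraction, brdu_edge_boost = brdu_edge_boost,
      dapi_amplitude = dapi_amplitude, dead_amplitude = dead_amplitude,
      brdu_ratio_neg = brdu_ratio_neg, brdu_ratio_pos = brdu_ratio_pos,
      amp_cv = amp_cv, dapi_diffuse = dapi_diffuse,
      alb_profile = alb_profile,
      dome_coeffs = setNames(as.numeric(dome_coeffs), c("a", "b", "c")),
      diameter_mean_um = diameter_mean_um, diameter_sd_um = diameter_sd_um,
      class_probs = class_probs,
      frame_interval_min = frame_interval_min, duration_h = duration_h
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> noise sd %.1f | blur %.1f px | %g nuclei/spheroid | dead %.0f%% (%s) | BrdU+ %.0f%%\n",
    x$noise_sd, x$blur_sigma_px, x$nuclei_per_spheroid,
    100 * x$dead_fraction, x$dead_bias, 100 * x$brdu_fraction
  ))
  invisible(x)
}

#' Write / read a simulation configuration as YAML
#'
#' The `alb_profile` function is stored as deparsed R code and re-parsed on
#' read, so configurations round-trip.
#'
#' @param cfg a [sim_config()].
#' @param path file path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns a `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$alb_profile <- paste(deparse(x$alb_profile), collapse = "\n")
  x$class_probs <- as.list(x$class_probs)
  x$dome_coeffs <- as.list(x$dome_coeffs)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$alb_profile <- eval(parse(text = x$alb_profile))
  x$class_probs <- unlist(x$class_probs)
  x$dome_coeffs <- unlist(x$dome_coeffs)
  do.call(sim_config, x)
}
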