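# Shape descriptors, object classification, formation-kinetics fits.

#' Shape index (circularity)
#'
#' `ShI = 4 * pi * A / P^2`: 1 for a perfect circle, approaching 0 for a
#' line. Vectorised over area and perimeter (any consistent units).
#'
#' @param area object area.
#' @param perimeter object perimeter.
#' @return numeric shape index (unclipped).
#' @examples
#' shape_index(pi * 5^2, 2 * pi * 5) # circle -> 1
#' shape_index(4^2, 4 * 4)           # square -> pi/4
#' @export
shape_index <- function(area, perimeter) {
  4 * pi * area / perimeter^2
}

#' Equivalent diameter
#'
#' Diameter of the disk with the same area as the object:
#' `D = 2 * sqrt(A / pi)`.
#'
#' @param area_um2 area in um^2 (or any squared unit).
#' @return diameter in the corresponding linear unit.
#' @export
equivalent_diameter <- function(area_um2) {
  2 * sqrt(area_um2 / pi)
}

#' Morphometry of a binary mask
#'
#' Area (pixel count), perimeter (smoothed marching-squares contour, see
#' [mask_perimeter()]), equivalent diameter and shape index, in physical
#' units. The reported `shape_index` is clipped to `[0, 1]` (digitisation
#' can overshoot 1 slightly for near-perfect disks); the raw value is kept
#' in `shape_index_raw`. Masks thinner than ~2 px measure near 0 and
#' trigger a warning.
#'
#' @param mask logical (or 0/1) matrix.
#' @param pixel_size_um calibration (um/px).
#' @return one-row tibble: `area_px`, `area_um2`, `perimeter_um`,
#'   `diameter_um`, `shape_index`, `shape_index_raw`.
#' @export
measure_mask <- function(mask, pixel_size_um = 1) {
  area_px <- sum(mask != 0)
  if (area_px == 0) {
    return(tibble(area_px = 0, area_um2 = 0, perimeter_um = 0,
                  diameter_um = 0, shape_index = NA_real_,
                  shape_index_raw = NA_real_))
  }
  p_px <- mask_perimeter(mask)
  shi_raw <- shape_index(area_px, p_px)
  if (shi_raw < 0.1) {
    warn("Near-degenerate mask: shape index below 0.1.")
  }
  tibble(
    area_px = area_px,
    area_um2 = area_px * pixel_size_um^2,
    perimeter_um = p_px * pixel_size_um,
    diameter_um = equivalent_diameter(area_px * pixel_size_um^2),
    shape_index = min(max(shi_raw, 0), 1),
    shape_index_raw = shi_raw
  )
}

#' Classify objects into units, aggregates and spheroids
#'
#' Morphological sorting rules: objects with equivalent diameter below 9 um
#' or failing the focus filter are discarded; 9-40 um are cell units; above
#' 40 um, shape index below 0.5 marks a cell aggregate and above 0.5 a
#' spheroid. Boundary conventions: D = 40 um is a unit, ShI = 0.5 an
#' aggregate.
#'
#' @param diameter_um equivalent diameter (um), vectorised.
#' @param shi shape index, vectorised.
#' @param focus_kept logical from the focus filter (recycled).
#' @return factor with levels `discarded`, `unit`, `aggregate`, `spheroid`.
#' @examples
#' classify_object(c(72.9, 50, 8, 20), c(0.8, 0.3, 0.9, 0.9))
#' @export
classify_object <- function(diameter_um, shi, focus_kept = TRUE) {
  n <- max(length(diameter_um), length(shi))
  diameter_um <- rep_len(diameter_um, n)
  shi <- rep_len(shi, n)
  focus_kept <- rep_len(focus_kept, n)
  out <- rep("discarded", n)
  ok <- focus_kept & diameter_um >= 9
  out[ok & diameter_um <= 40] <- "unit"
  out[ok & diameter_um > 40 & shi < 0.5] <- "aggregate"
  out[ok & diameter_um > 40 & shi >= 0.5] <- "spheroid"
  factor(out, levels = c("discarded", "unit", "aggregate", "spheroid"))
}

# Single-trace exponential relaxation fit. Returns coef list or NULL.
fit_relaxation_one <- function(t, a) {
  if (length(t) < 6 || sd(a) == 0 || !all(is.finite(a))) return(NULL)
  a_inf0 <- max(min(a), 1e-9)
  a00 <- a[which.min(t)]
  if (a00 <= a_inf0) a00 <- a_inf0 * 1.5
  tau0 <- diff(range(t)) / 3
  fit <- tryCatch(
    minpack.lm::nlsLM(
      a ~ a_inf + (a0 - a_inf) * exp(-t / tau),
      start = list(a_inf = a_inf0, a0 = a00, tau = tau0),
      lower = c(a_inf = 0, a0 = 0, tau = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  co <- coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((a - mean(a))^2)
  list(a_inf = co[["a_inf"]], a0 = co[["a0"]], tau = co[["tau"]],
       r_squared = 1 - ss_res / ss_tot)
}

#' Fit spheroid-formation kinetics
#'
#' Per-trace least-squares fit of the exponential relaxation
#' `A(t) = A_inf + (A0 - A_inf) * exp(-t / tau)` (Levenberg-Marquardt).
#' Non-convergent traces are retained with `converged = FALSE` and `NA`
#' parameters. Because it is unstated whether a population's characteristic
#' time should come from per-trace fits or from a single fit to the pooled
#' median trace, [glance()] reports both: `tau_median` (median of per-trace
#' tau) and `tau_pooled` (fit to the per-time-point median area).
#'
#' @param traces tibble with columns `trace_id`, `t_h` and `area_um2`
#'   (or `area_norm`), e.g. from [simulate_formation()].
#' @param area name of the area column to fit.
#' @return object of class `formation_fit`; see [tidy.formation_fit()] and
#'   [glance.formation_fit()].
#' @export
fit_formation <- function(traces, area = "area_um2") {
  stopifnot(all(c("trace_id", "t_h", area) %in% names(traces)))
  fits <- traces |>
    group_by(.data$trace_id) |>
    group_split() |>
    purrr::map(function(d) {
      f <- fit_relaxation_one(d$t_h, d[[area]])
      if (is.null(f)) {
        tibble(trace_id = d$trace_id[1], tau_h = NA_real_, a0 = NA_real_,
               a_inf = NA_real_, r_squared = NA_real_, converged = FALSE)
      } else {
        tibble(trace_id = d$trace_id[1], tau_h = f$tau, a0 = f$a0,
               a_inf = f$a_inf, r_squared = f$r_squared, converged = TRUE)
      }
    }) |>
    list_rbind()

  med <- traces |>
    group_by(.data$t_h) |>
    summarise(area_med = median(.data[[area]]), .groups = "drop")
  pooled <- fit_relaxation_one(med$t_h, med$area_med)

  structure(
    list(fits = fits, data = traces, area_col = area,
         pooled = pooled),
    class = "formation_fit"
  )
}

#' @export
print.formation_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<formation_fit> %d traces (%d converged) | median tau %.2f h | pooled tau %.2f h\n",
    g$n_traces, g$n_converged, g$tau_median, g$tau_pooled
  ))
  invisible(x)
}

#' Tidy a formation fit
#'
#' @param x a [fit_formation()] result.
#' @param ... unused.
#' @return tibble of per-trace parameters (`trace_id`, `tau_h`, `a0`,
#'   `a_inf`, `r_squared`, `converged`).
#' @export
tidy.formation_fit <- function(x, ...) x$fits

#' One-row summary of a formation fit
#'
#' @param x a [fit_formation()] result.
#' @param ... unused.
#' @return tibble with `n_traces`, `n_converged`, `tau_median`, `tau_iqr`,
#'   `tau_pooled`, `r_squared_median`.
#' @export
glance.formation_fit <- function(x, ...) {
  ok <- x$fits$converged
  tibble(
    n_traces = nrow(x$fits),
    n_converged = sum(ok),
    tau_median = median(x$fits$tau_h[ok]),
    tau_iqr = stats::IQR(x$fits$tau_h[ok]),
    tau_pooled = if (is.null(x$pooled)) NA_real_ else x$pooled$tau,
    r_squared_median = median(x$fits$r_squared[ok])
  )
}
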