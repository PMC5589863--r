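#' Simulate spheroid-formation traces
#'
#' Projected area of a compacting aggregate relaxes exponentially from `a0`
#' to `a_inf` with characteristic time `tau_h`; the shape index rises
#' monotonically towards ~1 on the same clock. Observation noise is
#' multiplicative with coefficient of variation `noise_cv`. A small
#' log-normal per-trace spread on tau (`tau_cv`, median-preserving) emulates
#' the biological heterogeneity visible across anchors; set it to 0 for
#' strictly identical kinetics.
#'
#' @param tau_h characteristic formation time (h). Default 11 h
#'   (hepatoma-like); mesenchymal stem cells compact faster (~4 h).
#' @param t_grid_h sampling times (h); the default is every 20 min over 23 h.
#' @param a0_um2,a_inf_um2 initial and plateau projected areas (um^2);
#'   defaults give a 3:1 compaction onto a ~71 um spheroid.
#' @param noise_cv multiplicative observation noise cv.
#' @param n_traces number of anchors simulated.
#' @param tau_cv per-trace log-normal spread of tau (median preserved).
#' @param shi0,shi_inf initial and plateau shape index.
#' @param seed RNG seed.
#' @return tibble with `trace_id`, `t_h`, `area_um2`, `area_norm`
#'   (area/area at t0), `shi`, and the per-trace `tau_true_h`.
#' @examples
#' tr <- simulate_formation(n_traces = 5, noise_cv = 0, tau_cv = 0, seed = 1)
#' @export
simulate_formation <- function(tau_h = 11,
                               t_grid_h = seq(0, 23, by = 1 / 3),
                               a0_um2 = 12000,
                               a_inf_um2 = 4000,
                               noise_cv = 0.03,
                               n_traces = 150,
                               tau_cv = 0.08,
                               shi0 = 0.35,
                               shi_inf = 0.96,
                               seed = 1) {
  if (!length(t_grid_h)) abort("`t_grid_h` must contain at least one time point.")
  stopifnot(tau_h > 0, a0_um2 > a_inf_um2, a_inf_um2 > 0, noise_cv >= 0)
  withr::with_seed(as.integer(seed), {
    ln_sd <- sqrt(log(1 + tau_cv^2))
    taus <- tau_h * rlnorm(n_traces, 0, ln_sd) # median = tau_h
    purrr::map(seq_len(n_traces), function(i) {
      mu <- a_inf_um2 + (a0_um2 - a_inf_um2) * exp(-t_grid_h / taus[i])
      area <- mu * (1 + rnorm(length(t_grid_h), 0, noise_cv))
      shi_mu <- shi_inf - (shi_inf - shi0) * exp(-t_grid_h / taus[i])
      shi <- pmin(shi_mu * (1 + rnorm(length(t_grid_h), 0, noise_cv / 2)), 1.05)
      tibble(
        trace_id = i,
        t_h = t_grid_h,
        area_um2 = area,
        area_norm = area / area[1],
        shi = shi,
        tau_true_h = taus[i]
      )
    }) |> list_rbind()
  })
}

#' Simulate a single-spheroid ALB field with volume-effect dome
#'
#' Builds one spheroid crop in the ALB (FITC) channel: a dome-shaped
#' out-of-focus background `a (r/R)^3 + b (r/R)^2 + c` over a disk of radius
#' `radius_px`, plus planted intracellular ALB peaks whose true amplitudes
#' follow `peak_profile(r/R)`. The returned truth table is the oracle for the
#' background-correction pipeline.
#'
#' @param radius_px spheroid radius in pixels (>= 10).
#' @param peak_profile function of r/R giving the mean peak amplitude.
#' @param dome_coeffs numeric `c(a, b, c)` of the dome polynomial.
#' @param n_peaks number of planted peaks.
#' @param peak_sigma_px Gaussian sigma of a rendered peak.
#' @param amp_cv log-normal amplitude spread (0 = exact profile).
#' @param background camera offset outside the spheroid.
#' @param radial_exponent placement law, as in [sim_config()].
#' @param min_separation_px minimum distance between planted peaks.
#' @param seed RNG seed.
#' @return list with `image`, `mask` (logical disk), `peaks` (tibble:
#'   `row_px`, `col_px`, `r_over_R`, `amplitude`), `center` (row, col),
#'   `radius_px`, `dome_coeffs`.
#' @export
simulate_alb_field <- function(radius_px = 40,
                               peak_profile = function(rr) rep(60, length(rr)),
                               dome_coeffs = c(a = -5, b = -20, c = 40),
                               n_peaks = 25,
                               peak_sigma_px = 2.5,
                               amp_cv = 0,
                               background = 5,
                               radial_exponent = 1.4,
                               min_separation_px = 7,
                               seed = 1) {
  if (radius_px < 10) abort("`radius_px` must be at least 10.")
  dome_coeffs <- setNames(as.numeric(dome_coeffs), c("a", "b", "c"))
  withr::with_seed(as.integer(seed), {
    n <- 2 * ceiling(radius_px) + 21
    ctr <- (n + 1) / 2
    rows <- matrix(seq_len(n), n, n)
    cols <- t(rows)
    rr_px <- sqrt((rows - ctr)^2 + (cols - ctr)^2)
    mask <- rr_px <= radius_px
    rr <- rr_px / radius_px
    img <- matrix(background, n, n)
    img[mask] <- background + dome_coeffs[["c"]] +
      dome_coeffs[["b"]] * rr[mask]^2 + dome_coeffs[["a"]] * rr[mask]^3

    peaks <- tibble(row_px = numeric(0), col_px = numeric(0),
                    r_over_R = numeric(0), amplitude = numeric(0))
    if (n_peaks > 0) {
      # Rejection-sample peak centres with a minimum separation.
      pr <- numeric(0); pc <- numeric(0)
      tries <- 0
      while (length(pr) < n_peaks && tries < 200 * n_peaks) {
        tries <- tries + 1
        rho <- runif(1)^(1 / radial_exponent) * 0.92
        th <- runif(1, 0, 2 * pi)
        r0 <- ctr + rho * radius_px * sin(th)
        c0 <- ctr + rho * radius_px * cos(th)
        if (!length(pr) ||
            min((pr - r0)^2 + (pc - c0)^2) >= min_separation_px^2) {
          pr <- c(pr, r0); pc <- c(pc, c0)
        }
      }
      rrp <- sqrt((pr - ctr)^2 + (pc - ctr)^2) / radius_px
      ln_sd <- sqrt(log(1 + amp_cv^2))
      amp <- peak_profile(rrp) *
        (if (amp_cv > 0) rlnorm(length(pr), -ln_sd^2 / 2, ln_sd) else 1)
      img <- add_spots(img, pr, pc, amp, peak_sigma_px)
      peaks <- tibble(row_px = pr, col_px = pc, r_over_R = rrp, amplitude = amp)
    }
    list(image = img, mask = mask, peaks = peaks,
         center = c(row = ctr, col = ctr), radius_px = radius_px,
         dome_coeffs = dome_coeffs)
  })
}
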