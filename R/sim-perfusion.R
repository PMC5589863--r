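# Perfusion and co-culture truth generators.

#' Spatial drug-exposure schedule of a perfused chamber
#'
#' Three horizontal bands across the chamber height: region I (top) is
#' continuously drug-exposed, region II (middle) intermittently with the
#' stated half-period, region III (bottom) never.
#'
#' @param chamber_h_um chamber height (um).
#' @param band_fracs fractions of the height for regions I, II, III
#'   (top to bottom; must sum to 1).
#' @param half_period_h half-period of the intermittent exposure in region
#'   II (h).
#' @return object of class `region_schedule`: list with a `regions` tibble
#'   (`region`, `y_min_um`, `y_max_um`) and `half_period_h`.
#' @export
region_schedule <- function(chamber_h_um,
                            band_fracs = c(1, 1, 1) / 3,
                            half_period_h = 1) {
  if (length(band_fracs) != 3 || any(band_fracs <= 0) ||
      abs(sum(band_fracs) - 1) > 1e-8) {
    abort("`band_fracs` must be 3 positive fractions summing to 1.")
  }
  cuts <- chamber_h_um * cumsum(c(0, band_fracs))
  structure(
    list(
      regions = tibble(
        region = factor(c("I", "II", "III"), levels = c("I", "II", "III")),
        y_min_um = cuts[1:3],
        y_max_um = cuts[2:4]
      ),
      half_period_h = half_period_h,
      chamber_h_um = chamber_h_um
    ),
    class = "region_schedule"
  )
}

#' Is a region drug-exposed at time t?
#'
#' @param schedule a [region_schedule()].
#' @param region `"I"`, `"II"` or `"III"` (vectorised).
#' @param t_h time (h), vectorised.
#' @return logical.
#' @export
region_exposed <- function(schedule, region, t_h) {
  phase <- (t_h %/% schedule$half_period_h) %% 2 == 0
  out <- rep(FALSE, max(length(region), length(t_h)))
  region <- rep_len(as.character(region), length(out))
  phase <- rep_len(phase, length(out))
  out[region == "I"] <- TRUE
  out[region == "II"] <- phase[region == "II"]
  out
}

#' Simulate death kinetics under region-resolved drug perfusion
#'
#' Builds a chip truth via [simulate_chip()] (with no pre-existing dead
#' cells), assigns every anchor to a perfusion region, and plants two death
#' mechanisms on top:
#'
#' * a fast mechanism confined to a random "early-dying" subset of spheroids
#'   in each region (`early_fracs`), whose cells die at `fast_rate` cells/h
#'   starting at a random time in the first 2 h, at edge-biased positions
#'   (r/R ~ 0.8);
#' * a slow mechanism in region I only, switching on at `slow_onset_h`, which
#'   kills `slow_rate` cells per spheroid per hour across all its spheroids,
#'   at positions whose mean r/R drifts inward at `inward_rate` per hour.
#'
#' With the defaults the planted phenomenology is: region II accumulates dead
#' cells ~2x faster than region III, region I matches region II until the
#' onset and then breaks upward ~4-fold, and the mean dead-cell r/R is ~0.8
#' everywhere except region I where it drifts inward. Deaths are permanent,
#' so every per-region count series is non-decreasing.
#'
#' @param layout a [chip_layout()].
#' @param cfg a [sim_config()]; its `dead_fraction` is ignored (deaths come
#'   from the planted mechanisms).
#' @param schedule a [region_schedule()]; defaults to thirds of the chamber.
#' @param early_fracs named fractions of early-dying spheroids per region.
#' @param fast_rate cells/h killed in an early-dying spheroid.
#' @param slow_rate cells/spheroid/h killed by the slow mechanism (region I).
#' @param baseline_rate spontaneous cells/spheroid/h dying in every region
#'   (edge-positioned), the slow constant trickle seen without drug.
#' @param slow_onset_h onset of the slow mechanism (h).
#' @param inward_rate inward drift of the slow-mechanism death position
#'   (r/R units per hour).
#' @param duration_h experiment duration (h).
#' @param frame_interval_min imaging cadence (min).
#' @param seed RNG seed.
#' @return object of class `perfusion_truth`: the underlying `chip_truth`
#'   plus `schedule`, `spheroids` (anchor -> region), a `cells` table with
#'   `death_time_h` (NA = survives) and death position columns,
#'   `early_spheroids` (anchor ids of the planted early-dying subset), and
#'   `frame_times_h`.
#' @export
simulate_perfusion <- function(layout,
                               cfg = sim_config(dead_fraction = 0,
                                                frame_interval_min = 30,
                                                duration_h = 10),
                               schedule = region_schedule(layout$chamber_h_um),
                               early_fracs = c(I = 0.19, II = 0.21, III = 0.094),
                               fast_rate = 12,
                               slow_rate = 0.6,
                               baseline_rate = 0.02,
                               slow_onset_h = 5,
                               inward_rate = 0.08,
                               duration_h = cfg$duration_h,
                               frame_interval_min = cfg$frame_interval_min,
                               seed = 1) {
  stopifnot(inherits(schedule, "region_schedule"))
  if (any(diff(schedule$regions$y_min_um) <= 0)) {
    abort("Regions must be disjoint, ordered bands.")
  }
  truth <- simulate_chip(
    layout,
    cfg = do.call(sim_config, utils::modifyList(
      strip_config(cfg), list(dead_fraction = 0)
    )),
    seed = seed
  )
  withr::with_seed(derive_seed(seed, 97L), {
    sph <- truth$objects
    sph$region <- assign_regions(sph, schedule)$region
    cells <- truth$cells
    cells$death_time_h <- NA_real_
    cells$death_r_over_R <- NA_real_

    early_all <- integer(0)
    for (reg in c("I", "II", "III")) {
      ids <- sph$anchor_id[sph$region == reg]
      # the early-dying fractions are counts of affected *spheroids*; units
      # and aggregates are not candidates
      sph_ids <- sph$anchor_id[sph$region == reg & sph$class == "spheroid"]
      n_early <- round(early_fracs[[reg]] * length(sph_ids))
      early <- sample_vec(sph_ids, n_early)
      early_all <- c(early_all, early)
      for (aid in early) {
        idx <- which(cells$anchor_id == aid & is.na(cells$death_time_h))
        t0 <- runif(1, 0, 1.5)
        # fast mechanism: Poisson death events at fast_rate until exhaustion
        n_events <- min(length(idx), rpois(1, fast_rate * (duration_h - t0) * 0.9))
        if (n_events < 1) next
        times <- sort(t0 + cumsum(stats::rexp(n_events, fast_rate)))
        times <- times[times <= duration_h]
        if (!length(times)) next
        victims <- sample_vec(idx, length(times))
        cells$death_time_h[victims] <- times
        cells$death_r_over_R[victims] <-
          draw_dead_rr(length(times), "edge") * 0.95
      }
      if (baseline_rate > 0) {
        for (aid in ids) {
          n_bg <- rpois(1, baseline_rate * duration_h)
          if (n_bg < 1) next
          alive_idx <- which(cells$anchor_id == aid & is.na(cells$death_time_h))
          n_bg <- min(n_bg, length(alive_idx))
          if (n_bg < 1) next
          times <- sort(runif(n_bg, 0, duration_h))
          victims <- sample_vec(alive_idx, n_bg)
          cells$death_time_h[victims] <- times
          cells$death_r_over_R[victims] <- draw_dead_rr(n_bg, "edge") * 0.95
        }
      }
      if (reg == "I" && slow_rate > 0) {
        for (aid in ids) {
          n_slow <- rpois(1, slow_rate * max(0, duration_h - slow_onset_h))
          if (n_slow < 1) next
          alive_idx <- which(cells$anchor_id == aid & is.na(cells$death_time_h))
          n_slow <- min(n_slow, length(alive_idx))
          if (n_slow < 1) next
          times <- sort(runif(n_slow, slow_onset_h, duration_h))
          victims <- sample_vec(alive_idx, n_slow)
          mu <- pmax(0.15, 0.8 - inward_rate * (times - slow_onset_h))
          cells$death_time_h[victims] <- times
          cells$death_r_over_R[victims] <-
            pmin(0.95, pmax(0, rnorm(n_slow, mu, 0.08)))
        }
      }
    }

    # Move dying cells to their death position (radial draw, random angle),
    # so rendered dead spots sit where the death mechanism places them.
    dying <- which(!is.na(cells$death_time_h))
    if (length(dying)) {
      obj <- truth$objects[match(cells$anchor_id[dying], truth$objects$anchor_id), ]
      th <- runif(length(dying), 0, 2 * pi)
      cells$row_px[dying] <- obj$row_px +
        cells$death_r_over_R[dying] * obj$radius_px * sin(th)
      cells$col_px[dying] <- obj$col_px +
        cells$death_r_over_R[dying] * obj$radius_px * cos(th)
      cells$r_over_R[dying] <- cells$death_r_over_R[dying]
      amp_ln <- sqrt(log(1 + truth$cfg$amp_cv^2))
      cells$dead_amp[dying] <- truth$cfg$dead_amplitude *
        rlnorm(length(dying), -amp_ln^2 / 2, amp_ln)
    }

    out <- truth
    out$cells <- cells
    out$spheroids <- sph[, c("anchor_id", "region", "row_px", "col_px",
                             "radius_px", "diameter_um")]
    out$schedule <- schedule
    out$early_spheroids <- sort(early_all)
    out$frame_times_h <- seq(0, duration_h, by = frame_interval_min / 60)
    class(out) <- c("perfusion_truth", "chip_truth")
    out
  })
}

strip_config <- function(cfg) {
  x <- unclass(cfg)
  x[!names(x) %in% c()] # keep all; sim_config() revalidates
}

#' Cell table of a perfusion truth at one time point
#'
#' Cells whose `death_time_h` is at or before `t_h` are marked dead (their
#' TRITC amplitude becomes visible); the rest are alive. Feed the result to
#' [render_chip()] to get the frame's rasters.
#'
#' @param truth a `perfusion_truth`.
#' @param t_h frame time (h).
#' @return the truth's `cells` tibble with `alive` updated for time `t_h`.
#' @export
perfusion_frame_cells <- function(truth, t_h) {
  cells <- truth$cells
  cells$alive <- is.na(cells$death_time_h) | cells$death_time_h > t_h
  cells$dead_amp <- ifelse(cells$alive, 0, cells$dead_amp)
  cells
}

#' Simulate a co-culture chip with endothelial cores
#'
#' Each anchor receives a hetero-spheroid formed from a mixing ratio of
#' endothelial cells (TRITC-labelled) and hepatoma cells. Endothelial cells
#' self-organise into one or more internal cores: at high mixing ratios a
#' single, central, large core; at low ratios several smaller, more
#' peripheral cores. Planted rules: expected core count
#' `1 + Poisson(2.2 (1 - ratio)^2)`, mean core-centre distance
#' `0.55 (1 - ratio)` in r/R, and total core cross-section proportional to
#' the ratio.
#'
#' @param layout a [chip_layout()].
#' @param cfg a [sim_config()].
#' @param ratios endothelial mixing ratios to plant; anchors are assigned to
#'   ratios in contiguous row-major blocks (emulating sequential loading).
#' @param seed RNG seed.
#' @return a `chip_truth` with an extra `cores` tibble (`anchor_id`,
#'   `ratio`, `core_id`, `row_px`, `col_px`, `core_radius_px`,
#'   `dist_over_R`, `amplitude`).
#' @export
simulate_coculture <- function(layout,
                               cfg = sim_config(dead_fraction = 0),
                               ratios = c(0, 0.1, 0.2, 0.3, 0.5, 0.7, 0.8),
                               seed = 1) {
  truth <- simulate_chip(layout, cfg, seed = seed)
  withr::with_seed(derive_seed(seed, 131L), {
    obj <- truth$objects
    ratio <- ratios[pmin(length(ratios),
                         1 + (seq_len(nrow(obj)) - 1) %/%
                           ceiling(nrow(obj) / length(ratios)))]
    obj$baec_ratio <- ratio
    cores <- purrr::map(seq_len(nrow(obj)), function(i) {
      r <- ratio[i]
      if (r <= 0) return(NULL)
      n_core <- 1 + rpois(1, 2.2 * (1 - r)^2)
      R <- obj$radius_px[i]
      # split the total endothelial cross-section (ratio * spheroid area)
      # across cores
      w <- rlnorm(n_core, 0, 0.25)
      area <- r * pi * R^2 * 0.8 * w / sum(w)
      rad <- sqrt(area / pi)
      d_rr <- pmin(0.8, pmax(0, rnorm(n_core, 0.55 * (1 - r), 0.1)))
      th <- runif(n_core, 0, 2 * pi)
      tibble(
        anchor_id = obj$anchor_id[i],
        ratio = r,
        core_id = seq_len(n_core),
        row_px = obj$row_px[i] + d_rr * R * sin(th),
        col_px = obj$col_px[i] + d_rr * R * cos(th),
        core_radius_px = rad,
        dist_over_R = d_rr,
        amplitude = 80
      )
    }) |> list_rbind()
    truth$objects <- obj
    truth$cores <- cores
    truth
  })
}
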