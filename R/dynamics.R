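# Region-resolved death kinetics under drug perfusion; co-culture cores.

#' Assign anchors to perfusion regions
#'
#' Labels each anchor by the horizontal band containing its centre. An
#' anchor sitting exactly on a boundary goes to the upper band (smaller y)
#' and is reported.
#'
#' @param anchors tibble with `y_um` (or `row_px` + `pixel_size_um`).
#' @param schedule a [region_schedule()].
#' @param pixel_size_um used when only pixel coordinates are present.
#' @return `anchors` with a `region` factor added; attribute
#'   `boundary_anchors` lists ids assigned by the boundary rule.
#' @export
assign_regions <- function(anchors, schedule, pixel_size_um = 1) {
  stopifnot(inherits(schedule, "region_schedule"))
  y <- if ("y_um" %in% names(anchors)) {
    anchors$y_um
  } else {
    px_to_um(anchors$row_px, pixel_size_um)
  }
  reg <- schedule$regions
  cuts <- c(reg$y_min_um[1], reg$y_max_um)
  idx <- findInterval(y, cuts, rightmost.closed = TRUE, left.open = TRUE)
  # left.open: y exactly on an internal boundary falls in the lower interval
  # index, i.e. the upper band (smaller y).
  idx[y <= cuts[1]] <- 1L
  on_boundary <- y %in% cuts[2:3]
  anchors$region <- reg$region[pmin(pmax(idx, 1L), 3L)]
  if (any(on_boundary)) {
    ids <- if ("anchor_id" %in% names(anchors)) {
      anchors$anchor_id[on_boundary]
    } else {
      which(on_boundary)
    }
    inform(sprintf("%d anchor(s) on a region boundary assigned to the upper band.",
                   sum(on_boundary)))
    attr(anchors, "boundary_anchors") <- ids
  }
  anchors
}

#' Mean dead cells per spheroid over time
#'
#' For each region and frame, the number of dead-cell peaks divided by the
#' number of spheroids in the region. Input is a long table of dead-cell
#' detections per frame (from peak detection on the dead channel, or the
#' simulator truth): since the dead stain persists, each frame's detections
#' are the cumulative dead population.
#'
#' @param dead_peaks tibble with `t_h`, `anchor_id` (one row per dead cell
#'   visible at that frame).
#' @param spheroids tibble with `anchor_id`, `region`.
#' @param frame_times_h frame times; defaults to the times present.
#' @return tibble `region`, `t_h`, `n_dead`, `n_spheroids`, `n_dead_mean`.
#'   Regions with no spheroids yield `NaN` series and a warning.
#' @export
death_series <- function(dead_peaks, spheroids, frame_times_h = NULL) {
  stopifnot(all(c("anchor_id", "region") %in% names(spheroids)))
  frame_times_h <- frame_times_h %||% sort(unique(dead_peaks$t_h))
  n_reg <- spheroids |> count(.data$region, name = "n_spheroids")
  if (any(!levels(spheroids$region) %in% n_reg$region)) {
    warn("Region(s) without spheroids: their series are NaN.")
  }
  dead_peaks <- dead_peaks |>
    left_join(spheroids[, c("anchor_id", "region")], by = "anchor_id")
  grid <- tidyr::expand_grid(
    region = factor(levels(spheroids$region), levels(spheroids$region)),
    t_h = frame_times_h
  )
  counts <- dead_peaks |>
    count(.data$region, .data$t_h, name = "n_dead")
  grid |>
    left_join(counts, by = c("region", "t_h")) |>
    mutate(n_dead = dplyr::coalesce(.data$n_dead, 0L)) |>
    left_join(n_reg, by = "region") |>
    mutate(n_dead_mean = .data$n_dead / .data$n_spheroids)
}

#' Per-spheroid viability trajectories and final distribution
#'
#' One viability series per spheroid, the final-frame histogram summary per
#' region, and the count of spheroids whose viability ever drops below
#' `threshold` (the "died" count per region).
#'
#' @param viab tibble with `spheroid_id`, `region`, `t_h`, `viability`
#'   (percent). Needs at least 2 frames.
#' @param threshold viability threshold (percent) defining a dead spheroid.
#' @return object of class `viability_trajectories`: list with
#'   `trajectories`, `final` (last-frame values), `summary` (per-region
#'   final mean/sd and `n_crossed`).
#' @export
viability_trajectories <- function(viab, threshold = 50) {
  stopifnot(all(c("spheroid_id", "region", "t_h", "viability") %in% names(viab)))
  if (length(unique(viab$t_h)) < 2) abort("Need at least 2 frames.")
  t_end <- max(viab$t_h)
  final <- viab |> filter(.data$t_h == t_end)
  crossed <- viab |>
    group_by(.data$region, .data$spheroid_id) |>
    summarise(crossed = min(.data$viability) < threshold, .groups = "drop")
  summary <- crossed |>
    group_by(.data$region) |>
    summarise(n_spheroids = n(), n_crossed = sum(.data$crossed),
              .groups = "drop") |>
    left_join(
      final |>
        group_by(.data$region) |>
        summarise(final_mean = mean(.data$viability),
                  final_sd = sd(.data$viability), .groups = "drop"),
      by = "region"
    )
  structure(
    list(trajectories = viab, final = final, summary = summary,
         threshold = threshold),
    class = "viability_trajectories"
  )
}

#' @export
print.viability_trajectories <- function(x, ...) {
  cat("<viability_trajectories>\n")
  print(x$summary)
  invisible(x)
}

#' Mean radial position of dead cells over time
#'
#' Average r/R of the dead-cell peaks visible at each frame, per region;
#' frames with no dead cells in a region give `NaN`.
#'
#' @param dead_peaks tibble with `t_h`, `r_over_R` and either `region` or
#'   `anchor_id`.
#' @param spheroids optional `anchor_id` -> `region` map (needed when
#'   `dead_peaks` has no `region`).
#' @return tibble `region`, `t_h`, `n_dead`, `mean_r_over_R_dead`.
#' @export
mean_dead_radial <- function(dead_peaks, spheroids = NULL) {
  if (!"region" %in% names(dead_peaks)) {
    stopifnot(!is.null(spheroids))
    dead_peaks <- dead_peaks |>
      left_join(spheroids[, c("anchor_id", "region")], by = "anchor_id")
  }
  dead_peaks |>
    group_by(.data$region, .data$t_h) |>
    summarise(n_dead = n(),
              mean_r_over_R_dead = mean(.data$r_over_R),
              .groups = "drop")
}

#' Detect endothelial cores inside a hetero-spheroid
#'
#' Otsu threshold on the TRITC crop restricted to the spheroid mask,
#' connected components above a minimum size, per-core centroid distances to
#' the spheroid centre normalised by R, and the spheroid's total
#' background-subtracted TRITC signal.
#'
#' @param tritc_crop TRITC (endothelial label) crop.
#' @param mask spheroid mask (from the nuclei channel).
#' @param center_row,center_col,radius_px spheroid centre and equivalent
#'   radius.
#' @param pixel_size_um calibration.
#' @param min_core_diameter_um smallest core retained.
#' @param background camera background to subtract for the total signal.
#' @return list with `n_cores`, `cores` (tibble: `core_id`, `row_px`,
#'   `col_px`, `area_px`, `dist_over_R`), `total_signal`.
#' @export
detect_cores <- function(tritc_crop, mask, center_row, center_col, radius_px,
                         pixel_size_um = 1, min_core_diameter_um = 8,
                         background = NULL) {
  vals <- tritc_crop
  vals[!mask] <- NA
  bg <- background %||% mean(tritc_crop[!mask])
  ot <- otsu_threshold(vals[is.finite(vals)])
  empty <- list(n_cores = 0L,
                cores = tibble(core_id = integer(0), row_px = numeric(0),
                               col_px = numeric(0), area_px = numeric(0),
                               dist_over_R = numeric(0)),
                total_signal = sum(pmax(tritc_crop[mask] - bg, 0)))
  # guard: a mask with no endothelial label has only noise above Otsu; ask
  # for real contrast between classes
  if (!is.finite(ot$threshold)) return(empty)
  inside <- mask & tritc_crop > ot$threshold
  if (!any(inside)) return(empty)
  # require the upper class to stand off the in-mask background
  lo <- tritc_crop[mask & tritc_crop <= ot$threshold]
  if (length(lo) > 10 &&
      mean(tritc_crop[inside]) - mean(lo) < 4 * sd(lo)) {
    return(empty)
  }
  labels <- EBImage::bwlabel(as_ebimage(inside * 1))
  labels <- matrix(as.integer(labels), nrow(tritc_crop), ncol(tritc_crop))
  min_area <- pi * (min_core_diameter_um / 2 / pixel_size_um)^2
  tab <- tabulate(labels[labels > 0])
  keep <- which(tab >= min_area)
  if (!length(keep)) return(empty)
  labels <- relabel_sequential(labels, keep)
  cores <- purrr::map(seq_along(keep), function(l) {
    m <- labels == l
    ctr <- mask_centroid(m)
    tibble(core_id = l, row_px = ctr[["row"]], col_px = ctr[["col"]],
           area_px = sum(m),
           dist_over_R = sqrt((ctr[["row"]] - center_row)^2 +
                                (ctr[["col"]] - center_col)^2) / radius_px)
  }) |> list_rbind()
  list(n_cores = nrow(cores), cores = cores,
       total_signal = sum(pmax(tritc_crop[mask] - bg, 0)))
}
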