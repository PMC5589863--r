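# Single-cell and per-spheroid fluorescence cytometry.

#' Local fluorescence background of an anchor
#'
#' Mean intensity of the crop pixels that belong to no object. If fewer
#' than `min_free_fraction` of the pixels are object-free the anchor cannot
#' provide a stable estimate; the supplied `fallback` (e.g. a chip-wide
#' background) is returned with `flagged = TRUE`.
#'
#' @param crop numeric matrix.
#' @param labels integer label matrix (0 = background); `NULL` means no
#'   objects.
#' @param min_free_fraction minimum object-free pixel fraction.
#' @param fallback value to use when the anchor is (nearly) fully covered.
#' @return list with `background` and `flagged`.
#' @export
local_background <- function(crop, labels = NULL, min_free_fraction = 0.1,
                             fallback = NULL) {
  free <- if (is.null(labels)) rep(TRUE, length(crop)) else labels == 0
  if (mean(free) < min_free_fraction) {
    return(list(background = fallback %||% mean(crop), flagged = TRUE))
  }
  list(background = mean(crop[free]), flagged = FALSE)
}

#' Background-subtracted object signal
#'
#' Mean fluorescence over the object mask minus the anchor's local
#' background. Unstained objects legitimately measure ~0.
#'
#' @param mask logical matrix.
#' @param crop numeric matrix.
#' @param background scalar from [local_background()].
#' @return numeric signal.
#' @export
object_signal <- function(mask, crop, background) {
  if (!any(mask)) abort("Mask is empty.")
  mean(crop[mask]) - background
}

#' Per-spheroid viability from the dead stain
#'
#' `viability (%) = 100 * (object area - dead pixels) / object area`, where
#' dead pixels are mask pixels whose dead-channel intensity exceeds the
#' per-anchor threshold (from [segment_fluorescence()] on the dead channel).
#'
#' @param mask logical object mask.
#' @param dead_crop dead-channel (TRITC) crop.
#' @param dead_threshold intensity threshold; `NA` (undefined threshold on a
#'   signal-free crop) counts zero dead pixels.
#' @return one-row tibble: `object_area`, `dead_pixels`, `viability`.
#' @export
viability <- function(mask, dead_crop, dead_threshold) {
  area <- sum(mask)
  if (area == 0) abort("Mask is empty.")
  dead <- if (is.na(dead_threshold)) 0L else sum(dead_crop[mask] > dead_threshold)
  tibble(
    object_area = area,
    dead_pixels = dead,
    viability = 100 * (area - dead) / area
  )
}

#' Detect single-cell fluorescence peaks
#'
#' Local maxima of the Gaussian-smoothed crop, restricted to the object mask
#' (dilated by 2 px so boundary nuclei are kept), with prominence measured
#' against a wide-Gaussian local baseline, and greedy non-maximum
#' suppression at `min_separation_px`. Two emitters closer than the
#' separation merge into one reported peak.
#'
#' @param crop numeric matrix.
#' @param mask optional logical mask (whole crop if `NULL`).
#' @param min_separation_px suppression radius (~2 nucleus radii).
#' @param min_prominence minimum height above the local baseline; `NULL`
#'   auto-selects `max(6 * noise sd, 10% of the crop's dynamic range)`.
#' @param smooth_sigma_px detection smoothing.
#' @param baseline_radius_px radius of the grayscale-opening structuring
#'   element used as the local baseline (top-hat); structures wider than
#'   this survive the opening and so have ~zero prominence (which is what
#'   keeps the smooth out-of-focus dome from gating in), while sharp peaks
#'   keep their full height.
#' @return tibble: `row_px`, `col_px`, `value` (smoothed intensity),
#'   `prominence`.
#' @export
detect_peaks <- function(crop, mask = NULL,
                         min_separation_px = 6,
                         min_prominence = NULL,
                         smooth_sigma_px = 1,
                         baseline_radius_px = 2 * min_separation_px) {
  s1 <- gaussian_blur(crop, smooth_sigma_px)
  s2 <- tophat_baseline(s1, baseline_radius_px)
  prom <- s1 - s2
  if (is.null(min_prominence)) {
    # noise sd from the horizontal first difference of the raw crop, plus a
    # floor at 10% of the crop's dynamic range so residual baseline error on
    # smooth structures cannot gate in
    noise_sd <- mad(diff(as.numeric(crop))) / sqrt(2)
    min_prominence <- max(6 * noise_sd, 0.1 * diff(range(crop)), 1e-9)
  }
  allowed <- if (is.null(mask)) {
    matrix(TRUE, nrow(crop), ncol(crop))
  } else {
    m <- EBImage::dilate(as_ebimage(mask * 1), EBImage::makeBrush(5, "disc"))
    as_matrix_img(m) > 0
  }
  cand <- which(local_maxima_3x3(s1) & prom > min_prominence & allowed,
                arr.ind = TRUE)
  if (!nrow(cand)) {
    return(tibble(row_px = numeric(0), col_px = numeric(0),
                  value = numeric(0), prominence = numeric(0)))
  }
  sc <- s1[cand]
  keep <- greedy_nms(cand[, 1], cand[, 2], sc, min_separation_px)
  tibble(
    row_px = cand[keep, 1],
    col_px = cand[keep, 2],
    value = s1[cand[keep, , drop = FALSE]],
    prominence = prom[cand[keep, , drop = FALSE]]
  ) |> arrange(.data$row_px, .data$col_px)
}

#' Attach radial coordinates to peaks
#'
#' `r/R` with `r` the distance to the spheroid centroid and `R = D/2` the
#' equivalent radius. Values slightly above 1 are legitimate for peaks in
#' boundary pixels of irregular masks.
#'
#' @param peaks tibble with `row_px`, `col_px`.
#' @param center_row,center_col spheroid centroid (crop coordinates).
#' @param radius_px equivalent radius R in pixels.
#' @return `peaks` with `r_over_R` added.
#' @export
peak_radial <- function(peaks, center_row, center_col, radius_px) {
  peaks$r_over_R <- sqrt((peaks$row_px - center_row)^2 +
                           (peaks$col_px - center_col)^2) / radius_px
  peaks
}

#' Mean k-nearest-neighbour distance per cell
#'
#' Euclidean 2-D distances between nuclei within each spheroid; each cell
#' gets the mean distance to its `k` nearest neighbours, in um. Spheroids
#' with fewer than `k + 1` nuclei are skipped and counted in the
#' `skipped_spheroids` attribute.
#'
#' @param nuclei tibble with `row_px`, `col_px` and a grouping column.
#' @param k neighbours per cell.
#' @param pixel_size_um calibration.
#' @param group name of the spheroid id column.
#' @return `nuclei` with `mean_knn_um` added (NA rows dropped), attribute
#'   `skipped_spheroids`.
#' @export
nn_distances <- function(nuclei, k = 3, pixel_size_um = 1,
                         group = "spheroid_id") {
  stopifnot(group %in% names(nuclei))
  parts <- split(nuclei, nuclei[[group]])
  skipped <- 0L
  out <- purrr::map(parts, function(d) {
    if (nrow(d) < k + 1) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    dm <- as.matrix(dist(cbind(d$row_px, d$col_px)))
    diag(dm) <- Inf
    d$mean_knn_um <- unname(apply(dm, 1, function(r) {
      mean(sort(r)[seq_len(k)])
    })) * pixel_size_um
    d
  }) |> list_rbind()
  attr(out, "skipped_spheroids") <- skipped
  out
}

#' Decile gating of a distance (or any) distribution
#'
#' Flags values below the first decile and above the last decile
#' (quantile type 7). With `n` a multiple of 10, exactly `n/10` values fall
#' strictly below the first decile.
#'
#' @param x numeric vector.
#' @return factor with levels `below_d1`, `mid`, `above_d9`.
#' @export
gate_deciles <- function(x) {
  q <- quantile(x, c(0.1, 0.9), type = 7, names = FALSE)
  factor(
    ifelse(x < q[1], "below_d1", ifelse(x > q[2], "above_d9", "mid")),
    levels = c("below_d1", "mid", "above_d9")
  )
}

#' Volume-effect correction of ALB peak amplitudes (one spheroid)
#'
#' Wide-field images of a fluorescent sphere carry out-of-focus light that
#' brightens the centre. The spheroid's own background is estimated by
#' least-squares fitting `a x^3 + b x^2 + c` (x = r/R) to mask pixels
#' farther than `exclusion_radius_px` from every peak; each peak's raw
#' amplitude is corrected by subtracting the background at its r/R, then
#' scaled by the background at the centre (`1/c`) to damp inter-spheroid
#' variability. Spheroids whose fit fails or returns `c <= 0` are excluded
#' and flagged.
#'
#' @param peaks tibble with `row_px`, `col_px`, `r_over_R` and raw
#'   amplitudes in `value`.
#' @param crop ALB-channel crop.
#' @param mask spheroid mask.
#' @param center_row,center_col,radius_px spheroid centroid and equivalent
#'   radius.
#' @param exclusion_radius_px pixels closer than this to any peak are
#'   excluded from the background fit.
#' @param background camera/anchor background already present under the
#'   spheroid (subtracted before fitting).
#' @param min_fit_pixels minimum number of background pixels for a fit.
#' @return list with `peaks` (adds `corrected`, `scaled`), `coefficients`
#'   (a, b, c), `excluded` flag.
#' @export
correct_alb <- function(peaks, crop, mask,
                        center_row, center_col, radius_px,
                        exclusion_radius_px = 4,
                        background = 0,
                        min_fit_pixels = 30) {
  idx <- which(mask, arr.ind = TRUE)
  rr <- sqrt((idx[, 1] - center_row)^2 + (idx[, 2] - center_col)^2) / radius_px
  vals <- crop[idx] - background
  if (nrow(peaks)) {
    d2min <- rep(Inf, nrow(idx))
    for (i in seq_len(nrow(peaks))) {
      d2 <- (idx[, 1] - peaks$row_px[i])^2 + (idx[, 2] - peaks$col_px[i])^2
      d2min <- pmin(d2min, d2)
    }
    free <- d2min > exclusion_radius_px^2
  } else {
    free <- rep(TRUE, nrow(idx))
  }
  if (sum(free) < min_fit_pixels) {
    return(list(peaks = peaks, coefficients = c(a = NA, b = NA, c = NA),
                excluded = TRUE))
  }
  fit <- tryCatch(
    lm(v ~ I(x^2) + I(x^3), data = list(v = vals[free], x = rr[free])),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(peaks = peaks, coefficients = c(a = NA, b = NA, c = NA),
                excluded = TRUE))
  }
  co <- coef(fit)
  cc <- unname(co[1]); bb <- unname(co[2]); aa <- unname(co[3])
  if (!is.finite(cc) || cc <= 0) {
    return(list(peaks = peaks, coefficients = c(a = aa, b = bb, c = cc),
                excluded = TRUE))
  }
  bg_at <- function(x) cc + bb * x^2 + aa * x^3
  pk <- peaks
  pk$corrected <- (pk$value - background) - bg_at(pk$r_over_R)
  pk$scaled <- pk$corrected / cc
  list(peaks = pk, coefficients = c(a = aa, b = bb, c = cc),
       excluded = FALSE)
}

#' Chip-level ALB normalisation
#'
#' Final stage of the ALB chain: each peak's background-corrected, centre-
#' scaled amplitude is divided by the chip-wide mean, so the chip mean of
#' the normalised amplitudes is exactly 1 and spheroids from different chips
#' become comparable. Peaks from excluded spheroids (flagged fits) do not
#' enter the mean and get `NA`.
#'
#' @param peaks tibble with a `scaled` column and optionally an `excluded`
#'   flag column.
#' @return `peaks` with `normalized` added.
#' @export
normalize_alb <- function(peaks) {
  use <- if ("excluded" %in% names(peaks)) !peaks$excluded else rep(TRUE, nrow(peaks))
  m <- mean(peaks$scaled[use])
  peaks$normalized <- ifelse(use, peaks$scaled / m, NA_real_)
  peaks
}

#' Gate BrdU-positive nuclei from the BrdU/DAPI ratio histogram
#'
#' The per-nucleus BrdU/DAPI amplitude ratio is split automatically with
#' Otsu's criterion; the upper class is BrdU+. When the ratio histogram is
#' effectively unimodal (the two-class split explains less than
#' `bimodality_min` of the variance) the gate falls back to mean + 2 sd and
#' the result is flagged.
#'
#' @param brdu_amp,dapi_amp per-nucleus amplitudes (same length, >= 20 for a
#'   stable histogram — shorter inputs are accepted with a warning).
#' @param bimodality_min minimum Otsu between/total variance ratio for the
#'   automatic gate.
#' @return list with `positive` (logical), `fraction`, `threshold`,
#'   `method` ("otsu" or "fallback").
#' @export
gate_brdu <- function(brdu_amp, dapi_amp, bimodality_min = 0.75) {
  stopifnot(length(brdu_amp) == length(dapi_amp))
  if (length(brdu_amp) < 20) {
    warn("Fewer than 20 nuclei; the ratio histogram may be unstable.")
  }
  ratio <- brdu_amp / dapi_amp
  ot <- otsu_threshold(ratio)
  if (is.finite(ot$threshold) && isTRUE(ot$eta >= bimodality_min)) {
    th <- ot$threshold
    method <- "otsu"
  } else {
    th <- mean(ratio) + 2 * sd(ratio)
    method <- "fallback"
  }
  pos <- ratio > th
  list(positive = pos, fraction = mean(pos), threshold = th, method = method)
}

#' Whole-frame (2-D culture) analysis
#'
#' The monolayer mode: the same fluorescence routines applied to the full
#' frame, without anchor detection, focus-variance filtering or
#' morphological sorting, returning a single ratio per image.
#'
#' * `mode = "viability"`: objects are thresholded on `reference_crop`
#'   (cell stain); the ratio is the live-pixel fraction of the object area
#'   given the dead channel `stain_crop`.
#' * `mode = "brdu"`: nuclei are detected on `reference_crop` (DAPI); the
#'   ratio is the BrdU+ fraction after [gate_brdu()] on amplitudes read
#'   from `stain_crop` (BrdU) and `reference_crop`.
#'
#' @param stain_crop dead- or BrdU-channel frame.
#' @param reference_crop cell- or DAPI-channel frame.
#' @param mode `"viability"` or `"brdu"`.
#' @param min_separation_px peak separation for nucleus detection.
#' @param ... passed to [detect_peaks()] in BrdU mode.
#' @return one-row tibble: `mode`, `ratio` (percent), `n` (pixels or
#'   nuclei).
#' @export
analyze_2d <- function(stain_crop, reference_crop,
                       mode = c("viability", "brdu"),
                       min_separation_px = 6, ...) {
  mode <- match.arg(mode)
  if (mode == "viability") {
    seg <- segment_fluorescence(reference_crop)
    mask <- seg$labels > 0
    if (!any(mask)) return(tibble(mode = mode, ratio = NA_real_, n = 0L))
    th <- segment_fluorescence(stain_crop)$threshold
    v <- viability(mask, stain_crop, th)
    tibble(mode = mode, ratio = v$viability, n = v$object_area)
  } else {
    pk <- detect_peaks(reference_crop, min_separation_px = min_separation_px,
                       ...)
    if (nrow(pk) < 2) return(tibble(mode = mode, ratio = NA_real_, n = nrow(pk)))
    bg_ref <- local_background(reference_crop,
                               segment_fluorescence(reference_crop)$labels)
    bg_stn <- local_background(stain_crop,
                               segment_fluorescence(stain_crop)$labels)
    s_stain <- gaussian_blur(stain_crop, 1)
    dapi_amp <- pk$value - bg_ref$background
    brdu_amp <- s_stain[cbind(pk$row_px, pk$col_px)] - bg_stn$background
    g <- gate_brdu(brdu_amp, dapi_amp)
    tibble(mode = mode, ratio = 100 * g$fraction, n = nrow(pk))
  }
}
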