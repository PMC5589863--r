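# Object segmentation inside anchor crops.
#
# Bright field: objects have textured interiors, so the Sobel gradient
# magnitude is high inside them and near zero over the flat droplet
# background. The gradient map is smoothed, thresholded (Otsu), cleaned by
# closing + hole filling, restricted to a circular zone that excludes the
# anchor rim, and touching objects are split by a watershed on the distance
# map. Fluorescence: per-anchor automatic (Otsu) threshold + connected
# components.

label_stats <- function(labels, pixel_size_um, bf_crop = NULL) {
  labs <- sort(setdiff(unique(as.integer(labels)), 0L))
  rows <- purrr::map(labs, function(l) {
    mask <- labels == l
    ctr <- mask_centroid(mask)
    m <- measure_mask(mask, pixel_size_um)
    m$label <- l
    m$row_centroid <- ctr[["row"]]
    m$col_centroid <- ctr[["col"]]
    if (!is.null(bf_crop)) m$focus_variance <- var(bf_crop[mask])
    m
  })
  out <- list_rbind(rows)
  if (!nrow(out)) {
    out <- tibble(area_px = numeric(0), area_um2 = numeric(0),
                  perimeter_um = numeric(0), diameter_um = numeric(0),
                  shape_index = numeric(0), shape_index_raw = numeric(0),
                  label = integer(0), row_centroid = numeric(0),
                  col_centroid = numeric(0))
    if (!is.null(bf_crop)) out$focus_variance <- numeric(0)
  }
  out
}

relabel_sequential <- function(labels, keep) {
  out <- matrix(0L, nrow(labels), ncol(labels))
  for (i in seq_along(keep)) out[labels == keep[i]] <- i
  out
}

#' Segment bright-field anchor crops (gradient + watershed)
#'
#' @param crop numeric matrix, at least 32x32 px.
#' @param pixel_size_um calibration (um/px).
#' @param center_row,center_col centre of the exclusion geometry (defaults
#'   to the crop centre, i.e. the anchor centre when the crop came from
#'   [crop_anchor()]).
#' @param exclusion_radius_px radius of the circular zone within which
#'   objects are accepted; everything outside (the anchor rim and beyond) is
#'   discarded. Defaults to the whole crop (`Inf`); pass the anchor's
#'   inscribed-circle radius minus a rim allowance when the crop contains
#'   the rim.
#' @param min_diameter_um smallest equivalent diameter retained (um).
#' @param watershed_tolerance `h`-minima depth for the distance-map
#'   watershed that splits touching objects (px).
#' @param smooth_sigma_px pre-smoothing of the gradient map (px).
#' @return list with `labels` (integer matrix) and `objects` (tibble of
#'   per-object morphometry incl. `focus_variance` over the crop).
#' @export
segment_brightfield <- function(crop,
                                pixel_size_um = 1,
                                center_row = (nrow(crop) + 1) / 2,
                                center_col = (ncol(crop) + 1) / 2,
                                exclusion_radius_px = Inf,
                                min_diameter_um = 9,
                                watershed_tolerance = 2,
                                smooth_sigma_px = 1) {
  if (nrow(crop) < 32 || ncol(crop) < 32) {
    abort("Bright-field crop must be at least 32x32 pixels.")
  }
  g <- sobel_magnitude(gaussian_blur(crop, smooth_sigma_px))
  ot <- otsu_threshold(g)
  if (!is.finite(ot$threshold)) {
    return(list(labels = matrix(0L, nrow(crop), ncol(crop)),
                objects = label_stats(matrix(0L, 1, 1), pixel_size_um, crop)))
  }
  support <- g > ot$threshold
  if (is.finite(exclusion_radius_px)) {
    rows <- matrix(seq_len(nrow(crop)), nrow(crop), ncol(crop))
    cols <- matrix(seq_len(ncol(crop)), nrow(crop), ncol(crop), byrow = TRUE)
    support <- support &
      ((rows - center_row)^2 + (cols - center_col)^2 <= exclusion_radius_px^2)
  }
  kern <- EBImage::makeBrush(3, "box")
  sup_img <- as_ebimage(support * 1)
  sup_img <- EBImage::closing(sup_img, kern)
  sup_img <- EBImage::fillHull(sup_img)
  # the boundary gradient bleeds ~2 px outward (Sobel support + smoothing);
  # erode by the same amount so areas are unbiased
  sup_img <- EBImage::erode(sup_img, EBImage::makeBrush(5, "disc"))
  dm <- EBImage::distmap(sup_img)
  labels <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  labels <- matrix(as.integer(labels), nrow(crop), ncol(crop))

  min_area_px <- pi * (min_diameter_um / 2 / pixel_size_um)^2
  tab <- tabulate(labels[labels > 0])
  keep <- which(tab >= min_area_px)
  labels <- relabel_sequential(labels, keep)
  list(labels = labels,
       objects = label_stats(labels, pixel_size_um, crop))
}

#' Segment a fluorescence crop by automatic thresholding
#'
#' Per-anchor Otsu threshold on the crop, connected components above the
#' threshold (holes filled), small components removed. The chosen threshold
#' is returned with the result; a crop with zero dynamic range yields no
#' objects and an `NA` threshold with `threshold_defined = FALSE`.
#'
#' @param crop numeric matrix.
#' @param pixel_size_um calibration (um/px).
#' @param min_diameter_um smallest equivalent diameter retained (um).
#' @param bf_crop optional registered bright-field crop; when given, each
#'   object's bright-field `focus_variance` is reported (used by
#'   [focus_filter()]).
#' @param pre_smooth_sigma_px Gaussian smoothing applied before the
#'   threshold is chosen and applied (px); merges punctate nuclei into the
#'   diffuse object signal.
#' @return list with `labels`, `objects`, `threshold`, `threshold_defined`.
#' @export
segment_fluorescence <- function(crop,
                                 pixel_size_um = 1,
                                 min_diameter_um = 9,
                                 bf_crop = NULL,
                                 pre_smooth_sigma_px = 2) {
  # smoothing at the nucleus scale merges bright punctate nuclei into the
  # diffuse object signal, so the automatic threshold separates object from
  # background instead of splitting off the brightest spots
  sm <- gaussian_blur(crop, pre_smooth_sigma_px)
  ot <- otsu_threshold(sm)
  if (!is.finite(ot$threshold)) {
    labels <- matrix(0L, nrow(crop), ncol(crop))
    return(list(labels = labels,
                objects = label_stats(labels, pixel_size_um, bf_crop),
                threshold = NA_real_, threshold_defined = FALSE))
  }
  # apply the split halfway between the background class mean and the
  # object class's lower decile (a robust object-edge level): the raw Otsu
  # value is dragged upward by bright nuclei when the object class is small
  # and long-tailed, which trims the object rim
  above <- sm[sm > ot$threshold]
  th <- (mean(sm[sm <= ot$threshold]) +
           quantile(above, 0.1, names = FALSE, type = 7)) / 2
  support <- sm > th
  sup_img <- EBImage::fillHull(as_ebimage(support * 1))
  labels <- EBImage::bwlabel(sup_img)
  labels <- matrix(as.integer(labels), nrow(crop), ncol(crop))
  min_area_px <- pi * (min_diameter_um / 2 / pixel_size_um)^2
  tab <- tabulate(labels[labels > 0])
  keep <- which(tab >= min_area_px)
  labels <- relabel_sequential(labels, keep)
  list(labels = labels,
       objects = label_stats(labels, pixel_size_um, bf_crop),
       threshold = th, threshold_defined = TRUE)
}

#' Select the spheroid of interest
#'
#' The largest object in an anchor is the spheroid of interest (pre-fusion
#' frames can hold several forming aggregates). Ties are broken by the
#' smaller label, deterministically, and reported.
#'
#' @param objects per-object tibble (needs `area_px` and `label`).
#' @return the selected row (one-row tibble).
#' @export
select_primary_object <- function(objects) {
  if (!nrow(objects)) abort("No objects to select from.")
  best <- objects[objects$area_px == max(objects$area_px), , drop = FALSE]
  if (nrow(best) > 1) {
    inform(sprintf("Area tie between labels %s; keeping label %d.",
                   paste(best$label, collapse = ", "), min(best$label)))
    best <- best[which.min(best$label), , drop = FALSE]
  }
  best
}

#' Focus filter from bright-field variance
#'
#' In-focus objects show strong bright-field texture; out-of-focus ones are
#' washed out. The bright-field intensity variance over the object mask is
#' compared with `min_variance`; objects below it are discarded.
#'
#' @param mask logical matrix (object mask), or a precomputed variance via
#'   `variance`.
#' @param bf_crop registered bright-field crop.
#' @param min_variance discard threshold (intensity^2); 0 keeps everything.
#' @param variance optional precomputed variance (skips `mask`/`bf_crop`).
#' @return list with `keep` (logical) and `variance`.
#' @export
focus_filter <- function(mask = NULL, bf_crop = NULL, min_variance = 10,
                         variance = NULL) {
  if (is.null(variance)) {
    if (is.null(mask) || is.null(bf_crop)) {
      abort("Provide `mask` and `bf_crop`, or `variance`.")
    }
    if (!any(mask)) abort("Mask is empty.")
    v <- var(bf_crop[mask])
    variance <- if (is.na(v)) 0 else v
  }
  list(keep = variance >= min_variance, variance = variance)
}
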