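# Anchor-array detection and tracking.
#
# Anchors appear as dark hexagonal rims in bright field. Detection is a
# matched filter: the gradient magnitude of the image (rim + object texture
# light up) is correlated with a zero-mean hexagonal template; response
# maxima above mean + k*sd, non-maximum-suppressed at half a pitch, are the
# anchor centres.

#' Hexagonal matched-filter template
#'
#' Regular hexagon (two vertices on the horizontal axis) inscribed in a
#' square of side `anchor_diameter_px`, returned zero-mean and unit-norm for
#' matched filtering. The raw binary mask is available as
#' `attr(x, "mask")`; its fill fraction is the hexagon/square area ratio
#' 3*sqrt(3)/8 ~ 0.6495.
#'
#' @param anchor_diameter_px vertex-to-vertex diameter in pixels (>= 5).
#' @param orientation_deg hexagon rotation (degrees).
#' @return numeric matrix (odd side), class `hex_template`.
#' @export
build_hex_template <- function(anchor_diameter_px, orientation_deg = 0) {
  if (anchor_diameter_px < 5) {
    abort("`anchor_diameter_px` must be at least 5 pixels.")
  }
  side <- as.integer(round(anchor_diameter_px))
  if (side %% 2 == 0) side <- side + 1L
  ctr <- (side + 1) / 2
  dr <- outer(seq_len(side) - ctr, rep(1, side))
  dc <- t(dr)
  depth <- hex_signed_depth(dr, dc, anchor_diameter_px / 2, orientation_deg)
  mask <- depth >= 0
  tmpl <- mask - mean(mask)
  tmpl <- tmpl / sqrt(sum(tmpl^2))
  structure(tmpl, mask = mask, depth = depth,
            diameter_px = anchor_diameter_px,
            class = c("hex_template", "matrix", "array"))
}

#' Detect anchors by matched filtering
#'
#' Correlates the Sobel gradient magnitude of `image` (or the raw image if
#' `use_gradient = FALSE`) with the zero-mean hexagon template, thresholds
#' the response at `mean + threshold_nsd * sd`, and keeps 3x3 local maxima
#' after greedy non-maximum suppression at radius `pitch_px / 2`. A flat
#' image yields an empty table, not an error.
#'
#' @param image numeric matrix (bright-field frame).
#' @param template a [build_hex_template()].
#' @param pitch_px lattice pitch in pixels.
#' @param pixel_size_um calibration for the physical-unit columns.
#' @param threshold_nsd response threshold in sd units above the mean.
#' @param use_gradient correlate the gradient magnitude (default) or the
#'   mean-subtracted intensity.
#' @param rim_width_px half-width of the dark rim band assumed by the
#'   gradient-space kernel (px).
#' @return tibble with `anchor_id` (row-major order), `row_px`, `col_px`,
#'   `row_um`, `col_um` (= y_um, x_um), `score`.
#' @export
detect_anchors <- function(image, template, pitch_px,
                           pixel_size_um = 1,
                           threshold_nsd = 3,
                           use_gradient = TRUE,
                           rim_width_px = 1.5) {
  stopifnot(is.matrix(image))
  if (nrow(image) <= nrow(template) || ncol(image) <= ncol(template)) {
    abort("`image` must be larger than the template.")
  }
  empty <- tibble(anchor_id = integer(0), row_px = numeric(0),
                  col_px = numeric(0), row_um = numeric(0),
                  col_um = numeric(0), score = numeric(0))
  s <- sd(image)
  if (!is.finite(s) || s == 0) return(empty)

  if (use_gradient) {
    # Matched filter in gradient space. The anchor appears as a dark rim
    # band along the hexagon boundary, so the image's gradient magnitude
    # carries a double ring at +/- the band half-width; the kernel is the
    # gradient magnitude of that band (from the template's signed-depth
    # map), zero-meaned and normalised like the template itself.
    feat <- sobel_magnitude(image)
    band <- (abs(attr(template, "depth")) < rim_width_px) * 1
    kern <- sobel_magnitude(gaussian_blur(band, 1))
    kern <- kern - mean(kern)
    kern <- kern / sqrt(sum(kern^2))
  } else {
    feat <- image - mean(image)
    kern <- unclass(template)
  }
  resp <- EBImage::filter2(feat, kern, boundary = "replicate")
  rm(feat)
  resp <- matrix(as.numeric(resp), nrow(image), ncol(image))
  thr <- mean(resp) + threshold_nsd * sd(resp)
  cand <- which(local_maxima_3x3(resp) & resp > thr, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  sc <- resp[cand]
  keep <- greedy_nms(cand[, 1], cand[, 2], sc, pitch_px / 2)
  rows <- cand[keep, 1]
  cols <- cand[keep, 2]
  # sub-pixel refinement: 1-D parabola through the response at the maximum
  # and its two neighbours, per axis
  refine <- function(r, c) {
    dr <- dc <- 0
    if (r > 1 && r < nrow(resp)) {
      y <- resp[(r - 1):(r + 1), c]
      den <- y[1] - 2 * y[2] + y[3]
      if (den < 0) dr <- 0.5 * (y[1] - y[3]) / den
    }
    if (c > 1 && c < ncol(resp)) {
      y <- resp[r, (c - 1):(c + 1)]
      den <- y[1] - 2 * y[2] + y[3]
      if (den < 0) dc <- 0.5 * (y[1] - y[3]) / den
    }
    c(r + max(-0.5, min(0.5, dr)), c + max(-0.5, min(0.5, dc)))
  }
  sub <- purrr::map2(rows, cols, refine)
  rows <- map_dbl(sub, 1)
  cols <- map_dbl(sub, 2)
  o <- order(round(rows / (pitch_px * sqrt(3) / 4)), cols)
  tibble(
    anchor_id = seq_along(keep),
    row_px = rows[o],
    col_px = cols[o],
    row_um = px_to_um(rows[o], pixel_size_um),
    col_um = px_to_um(cols[o], pixel_size_um),
    score = sc[keep][o]
  )
}

#' Track anchors across time-lapse frames
#'
#' Nearest-neighbour assignment of detections to active tracks, gated at
#' `gate_px` (use half a pitch). A track missing in a frame stays active and
#' resumes when a detection reappears within the gate; the gap is recorded.
#' Each track id appears at most once per frame; when two detections compete
#' for one track the closer wins.
#'
#' @param sites_per_frame a list of detection tibbles (one per frame, as
#'   from [detect_anchors()]), or a single tibble with a `frame` column.
#' @param gate_px assignment gate in pixels.
#' @return tibble of all detections with stable `anchor_id`, `frame`, and a
#'   `gap` flag marking re-appearances after a missed frame.
#' @export
track_anchors <- function(sites_per_frame, gate_px) {
  if (is.data.frame(sites_per_frame)) {
    stopifnot("frame" %in% names(sites_per_frame))
    sites_per_frame <- split(sites_per_frame, sites_per_frame$frame)
  }
  if (!length(sites_per_frame)) abort("Need at least one frame.")

  tracks_row <- numeric(0)
  tracks_col <- numeric(0)
  tracks_last <- integer(0)
  out <- vector("list", length(sites_per_frame))
  for (f in seq_along(sites_per_frame)) {
    det <- sites_per_frame[[f]]
    det <- det[order(det$row_px, det$col_px), , drop = FALSE]
    ids <- integer(nrow(det))
    gaps <- logical(nrow(det))
    used <- logical(length(tracks_row))
    if (nrow(det) && length(tracks_row)) {
      d2 <- outer(det$row_px, tracks_row, "-")^2 +
        outer(det$col_px, tracks_col, "-")^2
      # greedy globally-closest assignment
      repeat {
        if (all(!is.finite(d2)) || min(d2, na.rm = TRUE) >= gate_px^2) break
        k <- arrayInd(which.min(d2), dim(d2))
        i <- k[1]; j <- k[2]
        ids[i] <- j
        gaps[i] <- tracks_last[j] < f - 1L
        used[j] <- TRUE
        d2[i, ] <- Inf
        d2[, j] <- Inf
      }
    }
    new <- which(ids == 0L)
    if (length(new)) {
      ids[new] <- length(tracks_row) + seq_along(new)
      tracks_row <- c(tracks_row, det$row_px[new])
      tracks_col <- c(tracks_col, det$col_px[new])
      tracks_last <- c(tracks_last, rep(f - 1L, length(new)))
    }
    tracks_row[ids] <- det$row_px
    tracks_col[ids] <- det$col_px
    tracks_last[ids] <- f
    det$anchor_id <- ids
    det$frame <- f
    det$gap <- gaps
    out[[f]] <- det
  }
  list_rbind(out) |> arrange(.data$frame, .data$anchor_id) |> as_tibble()
}

#' Crop a per-anchor subimage
#'
#' Extracts a square window of half-size `radius_px + margin_px` around the
#' anchor centre, clipped to the image. The returned offsets map crop
#' coordinates back to the full frame: `full = crop + offset`.
#'
#' @param image numeric matrix.
#' @param row_px,col_px anchor centre (pixels).
#' @param radius_px nominal anchor radius (pixels).
#' @param margin_px extra margin (pixels).
#' @return list with `crop` (matrix), `row_offset`, `col_offset`, and the
#'   centre in crop coordinates (`center_row`, `center_col`).
#' @export
crop_anchor <- function(image, row_px, col_px, radius_px, margin_px = 0) {
  half <- radius_px + margin_px
  r0 <- floor(row_px - half)
  r1 <- ceiling(row_px + half)
  c0 <- floor(col_px - half)
  c1 <- ceiling(col_px + half)
  if (r1 < 1 || c1 < 1 || r0 > nrow(image) || c0 > ncol(image)) {
    abort("Crop window does not intersect the image.")
  }
  r0 <- max(1L, r0); c0 <- max(1L, c0)
  r1 <- min(nrow(image), r1); c1 <- min(ncol(image), c1)
  list(
    crop = image[r0:r1, c0:c1, drop = FALSE],
    row_offset = r0 - 1L,
    col_offset = c0 - 1L,
    center_row = row_px - (r0 - 1L),
    center_col = col_px - (c0 - 1L)
  )
}
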