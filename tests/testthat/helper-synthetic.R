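# Shared fixtures, all generated in code.

PX <- 1.29                       # um per pixel, 10x objective
ANCHOR_D_PX <- 250 / PX
PITCH_PX <- 680 / PX

small_layout <- function(w = 3000, h = 2600, px = PX) {
  chip_layout(chamber_w_um = w, chamber_h_um = h, pixel_size_um = px)
}

# Rasterised disk mask with margin.
disk_mask <- function(r_px, pad = 5) {
  n <- 2 * ceiling(r_px) + 2 * pad + 1
  ctr <- (n + 1) / 2
  rows <- matrix(seq_len(n), n, n)
  cols <- t(rows)
  (rows - ctr)^2 + (cols - ctr)^2 <= r_px^2
}

# Planted-ellipse mask of a truth object inside a crop window.
truth_object_mask <- function(obj, crop_dim, row_offset, col_offset) {
  rows <- matrix(seq_len(crop_dim[1]), crop_dim[1], crop_dim[2]) + row_offset
  cols <- matrix(seq_len(crop_dim[2]), crop_dim[1], crop_dim[2],
                 byrow = TRUE) + col_offset
  dr <- rows - obj$row_px
  dc <- cols - obj$col_px
  ca <- cos(obj$angle_rad)
  sa <- sin(obj$angle_rad)
  u <- dc * ca + dr * sa
  v <- -dc * sa + dr * ca
  (u / obj$semi_major_px)^2 + (v / obj$semi_minor_px)^2 <= 1
}

iou <- function(a, b) sum(a & b) / sum(a | b)

# Greedy truth matching: detected vs planted positions within tol_px.
match_points <- function(det_r, det_c, true_r, true_c, tol_px) {
  if (!length(det_r) || !length(true_r)) {
    return(list(tp = 0, fp = length(det_r), fn = length(true_r)))
  }
  d <- sqrt(outer(det_r, true_r, "-")^2 + outer(det_c, true_c, "-")^2)
  tp <- 0
  while (is.finite(min(d)) && min(d) <= tol_px) {
    k <- arrayInd(which.min(d), dim(d))
    tp <- tp + 1
    d[k[1], ] <- Inf
    d[, k[2]] <- Inf
  }
  list(tp = tp, fp = length(det_r) - tp, fn = length(true_r) - tp)
}

# Textured disk on a flat background (bright-field-like), for segmentation
# tests that need hand-placed objects.
textured_disk_image <- function(n, centers, r_px, bg = 200, level = 140,
                                speckle = 12, seed = 1) {
  withr::with_seed(seed, {
    img <- matrix(bg, n, n)
    rows <- matrix(seq_len(n), n, n)
    cols <- t(rows)
    for (i in seq_len(nrow(centers))) {
      inside <- (rows - centers[i, 1])^2 + (cols - centers[i, 2])^2 <= r_px[i]^2
      img[inside] <- level + rnorm(sum(inside), 0, speckle)
    }
    spherochip:::gaussian_blur(img, 1)
  })
}
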