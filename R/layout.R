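#' Hexagonal anchor lattice for an anchored-droplet chip
#'
#' Builds the geometry of a culture chamber whose floor carries a hexagonal
#' array of droplet anchors. Anchors sit on a triangular (hexagonally packed)
#' lattice: rows parallel to the chamber width, spaced `pitch * sqrt(3)/2`,
#' with every other row offset by half a pitch. Only anchors lying fully
#' inside the chamber (centre at least one anchor radius from every wall) are
#' kept, which reproduces the designed density of about 500 anchors per
#' 2 cm^2 at the default 680 um pitch.
#'
#' @param pitch_um centre-to-centre anchor spacing (um). One droplet diameter.
#' @param chamber_w_um,chamber_h_um chamber width (x, along columns) and
#'   height (y, along rows), um.
#' @param orientation_deg rotation of the lattice about the chamber centre.
#' @param anchor_diameter_um vertex-to-vertex diameter of the hexagonal
#'   anchors (um).
#' @param pixel_size_um image calibration used whenever the layout is
#'   rendered or detections are mapped to physical units (um per pixel).
#' @return An object of class `chip_layout`: a list with the geometry fields
#'   and `$anchors`, a tibble with one row per anchor
#'   (`anchor_id`, `x_um`, `y_um`, `row_px`, `col_px`), sorted row-major
#'   (top-left to bottom-right).
#' @examples
#' layout <- chip_layout(pitch_um = 680, chamber_w_um = 20000,
#'                       chamber_h_um = 10000)
#' nrow(layout$anchors) # ~500
#' @export
chip_layout <- function(pitch_um = 680,
                        chamber_w_um = 20000,
                        chamber_h_um = 10000,
                        orientation_deg = 0,
                        anchor_diameter_um = 250,
                        pixel_size_um = 1.29) {
  if (!is.numeric(pitch_um) || length(pitch_um) != 1 || !is.finite(pitch_um) ||
      pitch_um <= 0) {
    abort("`pitch_um` must be a single positive number.")
  }
  if (pitch_um <= anchor_diameter_um) {
    abort("`pitch_um` must exceed `anchor_diameter_um`.")
  }
  if (chamber_w_um <= 0 || chamber_h_um <= 0) {
    abort("Chamber dimensions must be positive.")
  }

  row_step <- pitch_um * sqrt(3) / 2
  margin <- anchor_diameter_um / 2

  # Generate over a bounding box large enough to cover the rotated chamber,
  # rotate about the chamber centre, then clip.
  half_diag <- sqrt(chamber_w_um^2 + chamber_h_um^2) / 2
  n_rows <- ceiling(2 * half_diag / row_step) + 2
  n_cols <- ceiling(2 * half_diag / pitch_um) + 2
  k <- seq(-n_rows, n_rows)
  pts <- purrr::map(k, function(ki) {
    x <- seq(-n_cols, n_cols) * pitch_um + (ki %% 2) * pitch_um / 2
    cbind(x = x, y = ki * row_step)
  })
  pts <- do.call(rbind, pts)

  th <- orientation_deg * pi / 180
  xr <- pts[, "x"] * cos(th) - pts[, "y"] * sin(th) + chamber_w_um / 2
  yr <- pts[, "x"] * sin(th) + pts[, "y"] * cos(th) + chamber_h_um / 2

  inside <- xr >= margin & xr <= chamber_w_um - margin &
    yr >= margin & yr <= chamber_h_um - margin
  xs <- xr[inside]
  ys <- yr[inside]
  o <- order(round(ys / row_step), xs)
  anchors <- tibble(
    anchor_id = seq_along(xs),
    x_um = xs[o],
    y_um = ys[o],
    row_px = um_to_px(ys[o], pixel_size_um),
    col_px = um_to_px(xs[o], pixel_size_um)
  )

  layout <- structure(
    list(
      pitch_um = pitch_um,
      anchor_diameter_um = anchor_diameter_um,
      chamber_w_um = chamber_w_um,
      chamber_h_um = chamber_h_um,
      orientation_deg = orientation_deg,
      pixel_size_um = pixel_size_um,
      anchors = anchors
    ),
    class = "chip_layout"
  )
  layout
}

#' @export
print.chip_layout <- function(x, ...) {
  cat(sprintf(
    "<chip_layout> %d anchors | pitch %.0f um | chamber %.0f x %.0f um | %.2f um/px\n",
    nrow(x$anchors), x$pitch_um, x$chamber_w_um, x$chamber_h_um, x$pixel_size_um
  ))
  invisible(x)
}

#' Expected anchor capacity of a chamber
#'
#' Closed-form hexagonal packing density: one site per
#' `sqrt(3)/2 * pitch^2` of chamber area, i.e. `2 A / (sqrt(3) pitch^2)`.
#'
#' @param chamber_w_um,chamber_h_um chamber dimensions (um).
#' @param pitch_um lattice pitch (um).
#' @return expected number of sites (not rounded).
#' @export
lattice_capacity <- function(chamber_w_um, chamber_h_um, pitch_um) {
  2 * chamber_w_um * chamber_h_um / (sqrt(3) * pitch_um^2)
}

#' Image dimensions of a rendered chip
#'
#' @param layout a [chip_layout()].
#' @return integer c(rows, cols).
#' @export
layout_dim <- function(layout) {
  c(
    rows = as.integer(ceiling(layout$chamber_h_um / layout$pixel_size_um)),
    cols = as.integer(ceiling(layout$chamber_w_um / layout$pixel_size_um))
  )
}

#' Cell-encapsulation loading arithmetic
#'
#' Bookkeeping for the droplet loading mix: a cell suspension is combined
#' with a liquid agarose stock, and the resulting mix is dispersed into
#' droplets of fixed volume. Returns the final cell concentration, the final
#' agarose content, and the expected cell count per droplet
#' (volume x concentration).
#'
#' @param n_cells cells in the suspension aliquot.
#' @param cell_suspension_ul volume of the cell aliquot (uL).
#' @param agarose_stock_ul volume of agarose stock added (uL).
#' @param agarose_stock_pct agarose stock concentration (% w/v).
#' @param droplet_volume_nl droplet volume (nL).
#' @return one-row tibble with `cell_concentration_per_ml`,
#'   `agarose_final_pct`, `cells_per_droplet`.
#' @examples
#' loading_mix() # 12e6 cells/mL, 0.9% agarose, ~200 cells per 16 nL droplet
#' @export
loading_mix <- function(n_cells = 1.2e6,
                        cell_suspension_ul = 70,
                        agarose_stock_ul = 30,
                        agarose_stock_pct = 3,
                        droplet_volume_nl = 16) {
  total_ul <- cell_suspension_ul + agarose_stock_ul
  conc_per_ml <- n_cells / (total_ul * 1e-3)
  tibble(
    cell_concentration_per_ml = conc_per_ml,
    agarose_final_pct = agarose_stock_pct * agarose_stock_ul / total_ul,
    cells_per_droplet = conc_per_ml * droplet_volume_nl * 1e-6
  )
}
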