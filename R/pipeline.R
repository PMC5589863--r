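#' End-to-end multiscale cytometry of one chip
#'
#' Runs the full analysis on registered whole-chip images: anchor detection
#' (matched filter on bright field), per-anchor cropping, object
#' segmentation (automatic threshold on the nuclear channel when available,
#' bright-field gradient + watershed otherwise), selection of the spheroid
#' of interest, morphometry + focus filtering + classification, and the
#' single-cell layer (nuclei peaks, dead-cell peaks and viability, ALB peaks
#' with volume-effect correction and chip-level normalisation).
#'
#' @param images named list of matrices; `brightfield` is required, `dapi`,
#'   `fitc` (ALB), `tritc` (dead stain) optional.
#' @param pixel_size_um calibration (um/px).
#' @param anchor_diameter_um,pitch_um chip geometry.
#' @param min_focus_variance focus-filter threshold (bright-field intensity
#'   variance).
#' @param peak_min_separation_um minimum nucleus separation for peak
#'   detection.
#' @param alb_exclusion_um exclusion radius around ALB peaks for the
#'   background fit.
#' @param anchors optional precomputed anchor table (skips detection).
#' @return object of class `chip_analysis`: list of tibbles `anchors`,
#'   `objects` (per-anchor primary object with class), `cells` (per-peak
#'   rows for nuclei/dead/alb with `r_over_R` and normalised ALB), and
#'   `spheroids` (per-spheroid viability, nucleus and dead counts, ALB
#'   background fit).
#' @export
analyze_chip <- function(images,
                         pixel_size_um = 1.29,
                         anchor_diameter_um = 250,
                         pitch_um = 680,
                         min_focus_variance = 10,
                         peak_min_separation_um = 8,
                         alb_exclusion_um = 5,
                         anchors = NULL) {
  stopifnot("brightfield" %in% names(images))
  bf <- images$brightfield
  anchor_d_px <- anchor_diameter_um / pixel_size_um
  pitch_px <- pitch_um / pixel_size_um
  if (is.null(anchors)) {
    tmpl <- build_hex_template(anchor_d_px)
    anchors <- detect_anchors(bf, tmpl, pitch_px, pixel_size_um)
  }
  if (!nrow(anchors)) {
    abort("No anchors detected.")
  }
  crop_half <- anchor_d_px / 2 + 4
  # accept objects only inside the anchor's inscribed circle, clear of the rim
  excl_r <- anchor_d_px / 2 * sqrt(3) / 2 - 4
  sep_px <- max(3, peak_min_separation_um / pixel_size_um)

  per_anchor <- purrr::map(seq_len(nrow(anchors)), function(i) {
    a <- anchors[i, ]
    bf_cr <- crop_anchor(bf, a$row_px, a$col_px, crop_half)
    crops <- purrr::map(images[setdiff(names(images), "brightfield")],
                        function(im) crop_anchor(im, a$row_px, a$col_px,
                                                 crop_half)$crop)
    seg_channel <- if ("dapi" %in% names(crops)) "dapi" else
      if ("fitc" %in% names(crops)) "fitc" else "brightfield"
    seg <- if (seg_channel == "brightfield") {
      segment_brightfield(bf_cr$crop, pixel_size_um,
                          center_row = bf_cr$center_row,
                          center_col = bf_cr$center_col,
                          exclusion_radius_px = excl_r)
    } else {
      segment_fluorescence(crops[[seg_channel]], pixel_size_um,
                           bf_crop = bf_cr$crop)
    }
    if (!nrow(seg$objects)) {
      return(list(object = NULL, cells = NULL, spheroid = NULL))
    }
    primary <- suppressMessages(select_primary_object(seg$objects))
    mask <- seg$labels == primary$label
    fv <- if ("focus_variance" %in% names(primary)) {
      primary$focus_variance
    } else {
      var(bf_cr$crop[mask])
    }
    keep <- focus_filter(variance = fv,
                         min_variance = min_focus_variance)$keep
    cls <- classify_object(primary$diameter_um, primary$shape_index, keep)
    R_px <- primary$diameter_um / 2 / pixel_size_um

    obj <- tibble(
      anchor_id = a$anchor_id,
      class = as.character(cls),
      area_um2 = primary$area_um2,
      diameter_um = primary$diameter_um,
      shape_index = primary$shape_index,
      focus_variance = fv,
      row_px = primary$row_centroid + bf_cr$row_offset,
      col_px = primary$col_centroid + bf_cr$col_offset,
      x_um = px_to_um(primary$col_centroid + bf_cr$col_offset, pixel_size_um),
      y_um = px_to_um(primary$row_centroid + bf_cr$row_offset, pixel_size_um),
      radius_px = R_px
    )
    if (cls != "spheroid") {
      return(list(object = obj, cells = NULL, spheroid = NULL))
    }

    cell_rows <- list()
    n_nuclei <- NA_integer_
    if ("dapi" %in% names(crops)) {
      pk <- detect_peaks(crops$dapi, mask, min_separation_px = sep_px) |>
        peak_radial(primary$row_centroid, primary$col_centroid, R_px)
      n_nuclei <- nrow(pk)
      if (nrow(pk)) {
        cell_rows$dapi <- pk |> mutate(channel = "dapi")
      }
    }
    n_dead <- NA_integer_
    viab <- NULL
    if ("tritc" %in% names(crops)) {
      seg_dead <- segment_fluorescence(crops$tritc, pixel_size_um)
      # the threshold is only meaningful when it stands clear of the robust
      # background level; otherwise Otsu has split noise and nothing here is
      # dead
      dead_th <- seg_dead$threshold
      if (!is.na(dead_th) &&
          dead_th <= median(crops$tritc) + 4 * mad(crops$tritc)) {
        dead_th <- NA_real_
      }
      viab <- viability(mask, crops$tritc, dead_th)
      pk <- detect_peaks(crops$tritc, mask, min_separation_px = sep_px) |>
        peak_radial(primary$row_centroid, primary$col_centroid, R_px)
      n_dead <- nrow(pk)
      if (nrow(pk)) {
        cell_rows$tritc <- pk |> mutate(channel = "tritc")
      }
    }
    alb_fit <- NULL
    if ("fitc" %in% names(crops)) {
      bg <- local_background(crops$fitc, seg$labels)
      pk <- detect_peaks(crops$fitc, mask, min_separation_px = sep_px) |>
        peak_radial(primary$row_centroid, primary$col_centroid, R_px)
      alb_fit <- correct_alb(pk, crops$fitc, mask,
                             primary$row_centroid, primary$col_centroid, R_px,
                             exclusion_radius_px = alb_exclusion_um / pixel_size_um,
                             background = bg$background)
      if (nrow(alb_fit$peaks)) {
        cell_rows$fitc <- alb_fit$peaks |>
          mutate(channel = "fitc", excluded = alb_fit$excluded)
      }
    }
    cells <- if (length(cell_rows)) {
      list_rbind(purrr::map(cell_rows, function(d) {
        d$row_px <- d$row_px + bf_cr$row_offset
        d$col_px <- d$col_px + bf_cr$col_offset
        d
      })) |> mutate(anchor_id = a$anchor_id)
    } else {
      NULL
    }
    sph <- tibble(
      anchor_id = a$anchor_id,
      diameter_um = primary$diameter_um,
      shape_index = primary$shape_index,
      n_nuclei = n_nuclei,
      n_dead = n_dead,
      viability = if (is.null(viab)) NA_real_ else viab$viability,
      dead_pixels = if (is.null(viab)) NA_integer_ else viab$dead_pixels,
      alb_a = if (is.null(alb_fit)) NA_real_ else alb_fit$coefficients[["a"]],
      alb_b = if (is.null(alb_fit)) NA_real_ else alb_fit$coefficients[["b"]],
      alb_c = if (is.null(alb_fit)) NA_real_ else alb_fit$coefficients[["c"]],
      alb_excluded = if (is.null(alb_fit)) NA else alb_fit$excluded
    )
    list(object = obj, cells = cells, spheroid = sph)
  })

  objects <- list_rbind(purrr::compact(purrr::map(per_anchor, "object")))
  cells <- list_rbind(purrr::compact(purrr::map(per_anchor, "cells")))
  spheroids <- list_rbind(purrr::compact(purrr::map(per_anchor, "spheroid")))
  if (nrow(cells) && "scaled" %in% names(cells)) {
    is_alb <- cells$channel == "fitc"
    alb <- cells[is_alb, , drop = FALSE]
    alb$excluded <- alb$excluded | is.na(alb$scaled)
    alb <- normalize_alb(alb)
    cells$normalized <- NA_real_
    cells$normalized[is_alb] <- alb$normalized
  }
  structure(
    list(anchors = anchors, objects = objects, cells = cells,
         spheroids = spheroids, pixel_size_um = pixel_size_um),
    class = "chip_analysis"
  )
}

#' @export
print.chip_analysis <- function(x, ...) {
  cat(sprintf(
    "<chip_analysis> %d anchors | %d objects (%d spheroids) | %d cell peaks\n",
    nrow(x$anchors), nrow(x$objects),
    sum(x$objects$class == "spheroid"),
    if (is.null(x$cells)) 0L else nrow(x$cells)
  ))
  invisible(x)
}

#' Write the analysis tables as CSV
#'
#' @param analysis a `chip_analysis`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_chip_analysis <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(analysis$anchors, file.path(dir, "anchors.csv"),
                   row.names = FALSE)
  utils::write.csv(analysis$objects, file.path(dir, "objects.csv"),
                   row.names = FALSE)
  if (!is.null(analysis$cells) && nrow(analysis$cells)) {
    utils::write.csv(analysis$cells, file.path(dir, "cells.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(analysis$spheroids, file.path(dir, "spheroids.csv"),
                   row.names = FALSE)
  invisible(dir)
}
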