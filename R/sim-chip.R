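# Synthetic chip truth generation and rendering.
#
# simulate_chip() draws the ground truth (objects, cells, amplitudes) from a
# single RNG stream; render_chip() turns a truth table into an image for one
# channel, deterministically given the truth's seed.

# Shape index of an ellipse with axis ratio q (Ramanujan perimeter).
ellipse_shape_index <- function(q) {
  a <- 1
  b <- q
  A <- pi * a * b
  P <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  4 * pi * A / P^2
}

rtrunc_norm <- function(n, mean, sd, lower, upper = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

draw_dead_rr <- function(n, bias) {
  switch(bias,
    edge = rbeta(n, 8, 2),
    core = rbeta(n, 2, 8),
    uniform = sqrt(runif(n))
  )
}

#' Simulate the ground truth of one chip
#'
#' Plants one cell structure per anchor (spheroid, aggregate or cell unit,
#' drawn from `cfg$class_probs`) with the configured size, shape and nucleus
#' statistics, plus per-cell alive/dead and BrdU states and fluorescence
#' amplitudes. All stochastic draws flow from one generator seeded with
#' `seed`, so identical `(layout, cfg, seed)` give identical truth.
#'
#' @param layout a [chip_layout()].
#' @param cfg a [sim_config()].
#' @param seed integer RNG seed.
#' @return An object of class `chip_truth`: list with `layout`, `cfg`,
#'   `seed`, and tibbles `objects` (one row per anchor-level object) and
#'   `cells` (one row per planted cell, with true `r_over_R`, alive/dead and
#'   BrdU flags and channel amplitudes).
#' @export
simulate_chip <- function(layout, cfg = sim_config(), seed = 1) {
  stopifnot(inherits(layout, "chip_layout"), inherits(cfg, "sim_config"))
  px <- layout$pixel_size_um
  withr::with_seed(as.integer(seed), {
    an <- layout$anchors
    n_anchor <- nrow(an)
    cls <- sample(names(cfg$class_probs), n_anchor, replace = TRUE,
                  prob = cfg$class_probs)

    d_um <- numeric(n_anchor)
    q <- numeric(n_anchor)
    d_um[cls == "spheroid"] <-
      rtrunc_norm(sum(cls == "spheroid"), cfg$diameter_mean_um,
                  cfg$diameter_sd_um, lower = 41)
    q[cls == "spheroid"] <- runif(sum(cls == "spheroid"), 0.88, 1)
    d_um[cls == "aggregate"] <-
      rtrunc_norm(sum(cls == "aggregate"), 65, 15, lower = 41)
    q[cls == "aggregate"] <- runif(sum(cls == "aggregate"), 0.12, 0.25)
    d_um[cls == "unit"] <-
      rtrunc_norm(sum(cls == "unit"), 22, 6, lower = 10, upper = 39)
    q[cls == "unit"] <- runif(sum(cls == "unit"), 0.7, 1)

    jit <- matrix(rnorm(2 * n_anchor, 0, 5), ncol = 2) # um, settling jitter
    x_um <- an$x_um + jit[, 1]
    y_um <- an$y_um + jit[, 2]
    R_px <- (d_um / 2) / px
    a_px <- R_px / sqrt(q)
    b_px <- R_px * sqrt(q)
    angle <- runif(n_anchor, 0, pi)

    objects <- tibble(
      anchor_id = an$anchor_id,
      class = cls,
      x_um = x_um,
      y_um = y_um,
      row_px = um_to_px(y_um, px),
      col_px = um_to_px(x_um, px),
      diameter_um = d_um,
      radius_px = R_px,
      semi_major_px = a_px,
      semi_minor_px = b_px,
      angle_rad = angle,
      shi_true = ellipse_shape_index(q)
    )

    # Cells: count scales with projected area; radial placement follows the
    # configured density law (denser core).
    n_cells <- pmax(1L, rpois(n_anchor,
                              cfg$nuclei_per_spheroid * (d_um / 72.9)^2))
    min_sep_px <- cfg$cell_min_separation_um / px
    cells <- purrr::map(seq_len(n_anchor), function(i) {
      nc <- n_cells[i]
      rr <- runif(nc)^(1 / cfg$cell_radial_exponent) * 0.95
      dead <- runif(nc) < cfg$dead_fraction
      rr[dead] <- draw_dead_rr(sum(dead), cfg$dead_bias) * 0.95
      ca <- cos(angle[i]); sa <- sin(angle[i])
      dr <- numeric(nc); dc <- numeric(nc)
      # place cells at their drawn radius with a physical minimum spacing
      # between nuclei (angles re-drawn a bounded number of times)
      for (j in seq_len(nc)) {
        for (try in 1:25) {
          theta <- runif(1, 0, 2 * pi)
          u <- rr[j] * a_px[i] * cos(theta)
          v <- rr[j] * b_px[i] * sin(theta)
          dcj <- u * ca - v * sa
          drj <- u * sa + v * ca
          if (j == 1 ||
              min((dr[seq_len(j - 1)] - drj)^2 +
                    (dc[seq_len(j - 1)] - dcj)^2) >= min_sep_px^2) break
        }
        dr[j] <- drj
        dc[j] <- dcj
      }
      tibble(
        anchor_id = an$anchor_id[i],
        row_px = objects$row_px[i] + dr,
        col_px = objects$col_px[i] + dc,
        r_over_R = sqrt(dr^2 + dc^2) / R_px[i],
        alive = !dead,
        # a nucleus cannot out-span its object: cap the rendered footprint
        nucleus_sigma_um = min(cfg$nucleus_sigma_um, d_um[i] / 3.5)
      )
    }) |> list_rbind()
    cells$cell_id <- seq_len(nrow(cells))

    # BrdU status: probability proportional to the radial enrichment weight,
    # scaled so the chip-wide mean equals cfg$brdu_fraction.
    w <- 1 + (cfg$brdu_edge_boost - 1) * (cells$r_over_R >= 0.8)
    p_brdu <- pmin(1, cfg$brdu_fraction * w / mean(w))
    cells$brdu <- runif(nrow(cells)) < p_brdu

    ln_sd <- sqrt(log(1 + cfg$amp_cv^2))
    cells$dapi_amp <- cfg$dapi_amplitude * rlnorm(nrow(cells), -ln_sd^2 / 2, ln_sd)
    cells$alb_amp <- cfg$alb_profile(pmin(cells$r_over_R, 1)) *
      rlnorm(nrow(cells), -ln_sd^2 / 2, ln_sd)
    ratio <- ifelse(cells$brdu, cfg$brdu_ratio_pos, cfg$brdu_ratio_neg)
    cells$brdu_amp <- cells$dapi_amp * ratio * rlnorm(nrow(cells), -ln_sd^2 / 2, ln_sd)
    cells$dead_amp <- ifelse(cells$alive, 0,
                             cfg$dead_amplitude * rlnorm(nrow(cells), -ln_sd^2 / 2, ln_sd))

    structure(
      list(layout = layout, cfg = cfg, seed = as.integer(seed),
           objects = objects, cells = cells),
      class = "chip_truth"
    )
  })
}

#' @export
print.chip_truth <- function(x, ...) {
  cat(sprintf(
    "<chip_truth> seed %d | %d objects (%d spheroids) | %d cells (%.1f%% dead)\n",
    x$seed, nrow(x$objects), sum(x$objects$class == "spheroid"),
    nrow(x$cells), 100 * mean(!x$cells$alive)
  ))
  invisible(x)
}

channel_index <- function(channel) {
  match(channel, c("brightfield", "dapi", "fitc", "tritc", "brdu"))
}

# Normalised ellipse radius of pixel offsets (dr, dc) for an object row.
ellipse_rho <- function(dr, dc, obj) {
  ca <- cos(obj$angle_rad)
  sa <- sin(obj$angle_rad)
  u <- dc * ca + dr * sa
  v <- -dc * sa + dr * ca
  sqrt((u / obj$semi_major_px)^2 + (v / obj$semi_minor_px)^2)
}

#' Render one channel of a synthetic chip
#'
#' Turns a [simulate_chip()] truth object into an intensity raster.
#' Bright field shows dark hexagonal anchor rims and textured object
#' interiors on a bright background; fluorescence channels render each
#' emitter as a Gaussian spot of its planted amplitude, on top of the
#' channel-specific diffuse components (spheroid footprint in DAPI, the
#' out-of-focus dome in FITC/ALB). Noise is applied last. Rendering is
#' deterministic given the truth's seed: the same truth and channel always
#' produce a bit-identical raster.
#'
#' @param truth a `chip_truth`.
#' @param channel one of `"brightfield"`, `"dapi"`, `"fitc"`, `"tritc"`,
#'   `"brdu"`.
#' @param cells optional replacement cell table (e.g. a time-lapse frame
#'   subset); defaults to `truth$cells`.
#' @return numeric intensity matrix (rows x cols per [layout_dim()]).
#' @export
render_chip <- function(truth,
                        channel = c("brightfield", "dapi", "fitc", "tritc", "brdu"),
                        cells = NULL) {
  stopifnot(inherits(truth, "chip_truth"))
  channel <- match.arg(channel)
  cfg <- truth$cfg
  layout <- truth$layout
  cells <- cells %||% truth$cells
  dm <- layout_dim(layout)

  out_of_bounds <- cells$row_px < 0.5 | cells$row_px > dm[["rows"]] + 0.5 |
    cells$col_px < 0.5 | cells$col_px > dm[["cols"]] + 0.5
  if (any(out_of_bounds)) {
    abort(paste0(
      "Emitters outside the image bounds: cell_id ",
      paste(utils::head(cells$cell_id[out_of_bounds], 10), collapse = ", ")
    ))
  }

  withr::with_seed(derive_seed(truth$seed, channel_index(channel)), {
    img <- switch(channel,
      brightfield = render_brightfield(truth, dm),
      dapi = render_fluor(truth, dm, cells, cells$dapi_amp, diffuse = TRUE),
      fitc = render_fluor(truth, dm, cells[cells$alive, , drop = FALSE],
                          cells$alb_amp[cells$alive], dome = TRUE),
      brdu = render_fluor(truth, dm, cells, cells$brdu_amp),
      tritc = render_tritc(truth, dm, cells)
    )
    if (cfg$noise_sd > 0) {
      img <- img + rnorm(length(img), 0, cfg$noise_sd)
    }
    if (isTRUE(cfg$poisson_noise)) {
      img <- matrix(rpois(length(img), pmax(img, 0)), dm[["rows"]], dm[["cols"]])
    }
    img
  })
}

object_window <- function(obj, pad, dm) {
  r0 <- max(1L, floor(obj$row_px - pad))
  r1 <- min(dm[["rows"]], ceiling(obj$row_px + pad))
  c0 <- max(1L, floor(obj$col_px - pad))
  c1 <- min(dm[["cols"]], ceiling(obj$col_px + pad))
  if (r0 > r1 || c0 > c1) return(NULL)
  list(rows = r0:r1, cols = c0:c1)
}

render_brightfield <- function(truth, dm) {
  cfg <- truth$cfg
  layout <- truth$layout
  px <- layout$pixel_size_um
  img <- matrix(cfg$bf_background, dm[["rows"]], dm[["cols"]])

  hex_R <- (layout$anchor_diameter_um / 2) / px
  rim_level <- cfg$bf_background * 0.35
  for (i in seq_len(nrow(layout$anchors))) {
    a <- layout$anchors[i, ]
    w <- object_window(list(row_px = a$row_px, col_px = a$col_px),
                       hex_R + 3, dm)
    if (is.null(w)) next
    dr <- outer(w$rows - a$row_px, rep(1, length(w$cols)))
    dc <- outer(rep(1, length(w$rows)), w$cols - a$col_px)
    depth <- hex_signed_depth(dr, dc, hex_R, layout$orientation_deg)
    rim <- abs(depth) < cfg$rim_width_px
    blk <- img[w$rows, w$cols]
    blk[rim] <- rim_level
    img[w$rows, w$cols] <- blk
  }

  obj_level <- cfg$bf_background * 0.7
  for (i in seq_len(nrow(truth$objects))) {
    obj <- truth$objects[i, ]
    w <- object_window(obj, obj$semi_major_px + 2, dm)
    if (is.null(w)) next
    dr <- outer(w$rows - obj$row_px, rep(1, length(w$cols)))
    dc <- outer(rep(1, length(w$rows)), w$cols - obj$col_px)
    rho <- ellipse_rho(dr, dc, obj)
    inside <- rho <= 1
    ns <- sum(inside)
    if (!ns) next
    blk <- img[w$rows, w$cols]
    blk[inside] <- obj_level + rnorm(ns, 0, cfg$speckle_sd) -
      0.15 * cfg$bf_background * (rho[inside] > 0.85)
    img[w$rows, w$cols] <- blk
  }
  gaussian_blur(img, cfg$blur_sigma_px)
}

render_fluor <- function(truth, dm, cells, amps, diffuse = FALSE, dome = FALSE) {
  cfg <- truth$cfg
  img <- matrix(cfg$background, dm[["rows"]], dm[["cols"]])
  if (diffuse || dome) {
    dome_c <- cfg$dome_coeffs
    for (i in seq_len(nrow(truth$objects))) {
      obj <- truth$objects[i, ]
      w <- object_window(obj, obj$semi_major_px + 2, dm)
      if (is.null(w)) next
      dr <- outer(w$rows - obj$row_px, rep(1, length(w$cols)))
      dc <- outer(rep(1, length(w$rows)), w$cols - obj$col_px)
      rho <- ellipse_rho(dr, dc, obj)
      inside <- rho <= 1
      if (!any(inside)) next
      blk <- img[w$rows, w$cols]
      add <- if (dome) {
        dome_c[["c"]] + dome_c[["b"]] * rho[inside]^2 +
          dome_c[["a"]] * rho[inside]^3
      } else {
        cfg$dapi_diffuse * (1 - 0.2 * rho[inside]^4)
      }
      blk[inside] <- blk[inside] + add
      img[w$rows, w$cols] <- blk
    }
  }
  if (nrow(cells)) {
    sig <- (cells$nucleus_sigma_um %||% cfg$nucleus_sigma_um) /
      truth$layout$pixel_size_um
    img <- add_spots(img, cells$row_px, cells$col_px, amps, sig)
  }
  img
}

render_tritc <- function(truth, dm, cells) {
  cfg <- truth$cfg
  img <- matrix(cfg$background, dm[["rows"]], dm[["cols"]])
  dead <- cells[!cells$alive, , drop = FALSE]
  if (nrow(dead)) {
    sig <- (dead$nucleus_sigma_um %||% cfg$nucleus_sigma_um) /
      truth$layout$pixel_size_um
    img <- add_spots(img, dead$row_px, dead$col_px, dead$dead_amp, sig)
  }
  # Co-culture endothelial cores, when planted (see simulate_coculture()).
  if (!is.null(truth$cores) && nrow(truth$cores)) {
    for (i in seq_len(nrow(truth$cores))) {
      co <- truth$cores[i, ]
      w <- object_window(co, co$core_radius_px + 3, dm)
      if (is.null(w)) next
      dr <- outer(w$rows - co$row_px, rep(1, length(w$cols)))
      dc <- outer(rep(1, length(w$rows)), w$cols - co$col_px)
      d <- sqrt(dr^2 + dc^2)
      img[w$rows, w$cols] <- img[w$rows, w$cols] +
        co$amplitude / (1 + exp((d - co$core_radius_px) / 0.8))
    }
  }
  img
}

#' Write / read image stacks as multi-page TIFF
#'
#' Images are stored as 16-bit TIFF pages after scaling by `scale`
#' (intensity units per full range); `read_image_tiff()` inverts the
#' scaling. One page per image (position or frame).
#'
#' @param images a matrix or list of matrices.
#' @param path output file.
#' @param max_intensity full-scale intensity mapped to the 16-bit maximum.
#' @return `write_image_tiff()`: `path`, invisibly. `read_image_tiff()`:
#'   list of matrices.
#' @export
write_image_tiff <- function(images, path, max_intensity = 4096) {
  if (is.matrix(images)) images <- list(images)
  pages <- lapply(images, function(m) pmin(pmax(m / max_intensity, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path, max_intensity = 4096) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(m) {
    if (length(dim(m)) == 3) m <- m[, , 1]
    m * max_intensity
  })
}

# CSV writers that round-trip doubles exactly (%.17g formatting).
precise_write_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write / read ground-truth tables
#'
#' Persists a `chip_truth` as plain-text artefacts: `objects.csv`,
#' `cells.csv`, `layout.yaml`, `config.yaml` and `seed.yaml`. Numeric
#' columns are written with 17 significant digits so tables round-trip
#' losslessly.
#'
#' @param truth a `chip_truth`.
#' @param dir output directory (created if needed).
#' @return `write_chip_truth()`: `dir`, invisibly; `read_chip_truth()`:
#'   a `chip_truth` (without re-simulating).
#' @export
write_chip_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  precise_write_csv(truth$objects, file.path(dir, "objects.csv"))
  precise_write_csv(truth$cells, file.path(dir, "cells.csv"))
  if (!is.null(truth$cores)) {
    precise_write_csv(truth$cores, file.path(dir, "cores.csv"))
  }
  lay <- truth$layout
  yaml::write_yaml(list(
    pitch_um = lay$pitch_um, anchor_diameter_um = lay$anchor_diameter_um,
    chamber_w_um = lay$chamber_w_um, chamber_h_um = lay$chamber_h_um,
    orientation_deg = lay$orientation_deg, pixel_size_um = lay$pixel_size_um
  ), file.path(dir, "layout.yaml"))
  write_sim_config(truth$cfg, file.path(dir, "config.yaml"))
  yaml::write_yaml(list(seed = truth$seed), file.path(dir, "seed.yaml"))
  invisible(dir)
}

#' @rdname write_chip_truth
#' @export
read_chip_truth <- function(dir) {
  lay <- yaml::read_yaml(file.path(dir, "layout.yaml"))
  layout <- do.call(chip_layout, lay)
  cfg <- read_sim_config(file.path(dir, "config.yaml"))
  seed <- yaml::read_yaml(file.path(dir, "seed.yaml"))$seed
  truth <- list(
    layout = layout, cfg = cfg, seed = as.integer(seed),
    objects = as_tibble(utils::read.csv(file.path(dir, "objects.csv"))),
    cells = as_tibble(utils::read.csv(file.path(dir, "cells.csv")))
  )
  core_path <- file.path(dir, "cores.csv")
  if (file.exists(core_path)) {
    truth$cores <- as_tibble(utils::read.csv(core_path))
  }
  structure(truth, class = "chip_truth")
}
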