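make_spheroid_truth <- function(lay, d_um = 80, seed = 3, noise_sd = 0) {
  tr <- simulate_chip(lay, sim_config(noise_sd = noise_sd), seed = seed)
  tr$objects$class <- "spheroid"
  tr$objects$diameter_um <- d_um
  tr$objects$radius_px <- d_um / 2 / PX
  tr$objects$semi_major_px <- tr$objects$radius_px
  tr$objects$semi_minor_px <- tr$objects$radius_px
  tr
}

test_that("bright-field segmentation recovers a planted spheroid", {
  lay <- small_layout(1400, 1400)
  tr <- make_spheroid_truth(lay, d_um = 80)
  bf <- render_chip(tr, "brightfield")
  a <- lay$anchors[1, ]
  cr <- crop_anchor(bf, a$row_px, a$col_px, ANCHOR_D_PX / 2 + 4)
  seg <- segment_brightfield(cr$crop, PX, cr$center_row, cr$center_col,
                             exclusion_radius_px = ANCHOR_D_PX / 2 * sqrt(3) / 2 - 4)
  expect_equal(nrow(seg$objects), 1)
  expect_lt(abs(seg$objects$area_um2 - pi * 40^2) / (pi * 40^2), 0.05)
  expect_lt(abs(seg$objects$diameter_um - 80), 2 * PX)
  expect_gt(seg$objects$shape_index, 0.95)
  expect_error(segment_brightfield(matrix(1, 20, 20)), "32x32")
})

test_that("an empty anchor segments to zero objects", {
  lay <- small_layout(1400, 1400)
  tr <- simulate_chip(lay, sim_config(noise_sd = 0), seed = 3)
  tr$objects <- tr$objects[0, ]
  tr$cells <- tr$cells[0, ]
  bf <- render_chip(tr, "brightfield")
  a <- lay$anchors[1, ]
  cr <- crop_anchor(bf, a$row_px, a$col_px, ANCHOR_D_PX / 2 + 4)
  seg <- segment_brightfield(cr$crop, PX, cr$center_row, cr$center_col,
                             exclusion_radius_px = ANCHOR_D_PX / 2 * sqrt(3) / 2 - 4)
  expect_equal(nrow(seg$objects), 0)
})

test_that("two separated aggregates yield at least two objects, and the
           largest is selected as the spheroid of interest", {
  img <- textured_disk_image(200, centers = rbind(c(70, 70), c(140, 140)),
                             r_px = c(25, 15))
  seg <- segment_brightfield(img, PX)
  expect_gte(nrow(seg$objects), 2)
  primary <- select_primary_object(seg$objects)
  expect_equal(primary$area_px, max(seg$objects$area_px))

  # tie-break: equal areas -> lower label, with a message
  objs <- tibble::tibble(label = c(2L, 1L), area_px = c(500, 500))
  expect_message(sel <- select_primary_object(objs), "tie")
  expect_equal(sel$label, 1L)
  expect_error(select_primary_object(objs[0, ]), "No objects")
})

test_that("fluorescence segmentation thresholds a bimodal crop correctly", {
  withr::with_seed(5, {
    n <- 150
    crop <- matrix(rnorm(n^2, 100, 10), n, n)
    mask <- disk_mask(35, pad = 39) # 149 x 149
    mask <- rbind(mask, FALSE)[, seq_len(n - 1)]
    mask <- cbind(mask, FALSE)[seq_len(n), ]
    crop[mask] <- rnorm(sum(mask), 300, 10)
  })
  seg <- segment_fluorescence(crop, pixel_size_um = 1)
  expect_gt(seg$threshold, 150)
  expect_lt(seg$threshold, 250)
  expect_equal(nrow(seg$objects), 1)
  expect_lt(abs(seg$objects$area_px - sum(mask)) / sum(mask), 0.05)

  # robustness: perturbing the threshold by +/-5% leaves the object set intact
  sm <- spherochip:::gaussian_blur(crop, 2)
  for (f in c(0.95, 1.05)) {
    alt <- sm > seg$threshold * f
    expect_gt(iou(alt, seg$labels > 0), 0.95)
  }
})

test_that("zero-dynamic-range crops yield no objects and an undefined threshold", {
  seg <- segment_fluorescence(matrix(42, 60, 60))
  expect_equal(nrow(seg$objects), 0)
  expect_true(is.na(seg$threshold))
  expect_false(seg$threshold_defined)
})

test_that("segmentation commutes with intensity rescaling", {
  img <- textured_disk_image(150, centers = rbind(c(75, 75)), r_px = 30)
  s1 <- segment_brightfield(img, PX)
  s2 <- segment_brightfield(img * 3.7, PX)
  expect_equal(s1$labels, s2$labels)

  withr::with_seed(5, f <- matrix(rnorm(101^2, 100, 10), 101, 101))
  f[disk_mask(25, pad = 25)] <- 300
  f1 <- segment_fluorescence(f)
  f2 <- segment_fluorescence(f * 0.01)
  expect_equal(f1$labels, f2$labels)
})

test_that("focus filter discards low-variance (out-of-focus) objects", {
  mask <- disk_mask(15)
  withr::with_seed(8, {
    sharp <- matrix(140, nrow(mask), ncol(mask))
    sharp[mask] <- 140 + rnorm(sum(mask), 0, 12)
  })
  blurred <- spherochip:::gaussian_blur(sharp, 6)

  expect_false(focus_filter(mask, matrix(100, nrow(mask), ncol(mask)),
                            min_variance = 1)$keep)
  f_sharp <- focus_filter(mask, sharp, min_variance = 10)
  f_blur <- focus_filter(mask, blurred, min_variance = 10)
  expect_true(f_sharp$keep)
  expect_gt(f_sharp$variance, f_blur$variance)
  expect_true(focus_filter(mask, blurred, min_variance = 0)$keep)
})

test_that("planted objects are segmented with IoU >= 0.8 for >= 95% of objects", {
  lay <- small_layout(5000, 3500)
  tr <- simulate_chip(lay, sim_config(noise_sd = 2), seed = 21)
  dapi <- render_chip(tr, "dapi")
  ious <- vapply(seq_len(nrow(tr$objects)), function(i) {
    o <- tr$objects[i, ]
    cr <- crop_anchor(dapi, lay$anchors$row_px[i], lay$anchors$col_px[i],
                      ANCHOR_D_PX / 2 + 4)
    seg <- segment_fluorescence(cr$crop, PX)
    if (!nrow(seg$objects)) return(0)
    primary <- suppressMessages(select_primary_object(seg$objects))
    truth_mask <- truth_object_mask(o, dim(cr$crop), cr$row_offset,
                                    cr$col_offset)
    iou(seg$labels == primary$label, truth_mask)
  }, numeric(1))
  expect_gte(mean(ious >= 0.8), 0.95)
})
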