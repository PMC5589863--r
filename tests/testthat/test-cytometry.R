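test_that("local background is the mean of object-free pixels", {
  crop <- matrix(100, 80, 80)
  labels <- matrix(0L, 80, 80)
  labels[30:50, 30:50] <- 1L
  crop[labels == 1] <- 500
  expect_equal(local_background(crop, labels)$background, 100)
  expect_equal(local_background(crop, NULL)$background, mean(crop))

  withr::with_seed(1, noisy <- matrix(rnorm(6400, 100, 5), 80, 80))
  expect_lt(abs(local_background(noisy, labels)$background - 100), 1)

  full <- matrix(1L, 80, 80)
  lb <- local_background(crop, full, fallback = 77)
  expect_true(lb$flagged)
  expect_equal(lb$background, 77)
})

test_that("object signal subtracts the local background", {
  mask <- matrix(FALSE, 40, 40)
  mask[10:20, 10:20] <- TRUE
  crop <- matrix(100, 40, 40)
  crop[mask] <- 300
  expect_equal(object_signal(mask, crop, 100), 200)
  expect_equal(object_signal(mask, matrix(100, 40, 40), 100), 0)
  expect_error(object_signal(matrix(FALSE, 4, 4), crop, 0), "empty")

  # planted amplitude ladder preserves rank order
  amps <- c(20, 50, 90, 140)
  sig <- vapply(amps, function(a) {
    cc <- matrix(100, 40, 40)
    cc[mask] <- 100 + a
    object_signal(mask, cc, 100)
  }, numeric(1))
  expect_equal(order(sig), order(amps))
})

test_that("viability follows the dead-pixel formula exactly", {
  mask <- matrix(FALSE, 40, 40)
  mask[1:25, 1:40] <- TRUE # 1000 px
  dead <- matrix(0, 40, 40)
  dead[1:5, 1:10] <- 100   # 50 px above threshold
  v <- viability(mask, dead, 50)
  expect_equal(v$viability, 95)
  expect_equal(v$dead_pixels, 50L)
  expect_equal(viability(mask, matrix(0, 40, 40), 50)$viability, 100)
  expect_equal(viability(mask, dead, NA)$viability, 100)
  expect_error(viability(matrix(FALSE, 4, 4), dead, 50), "empty")
  # identity: viability + dead fraction = 100
  expect_equal(v$viability + 100 * v$dead_pixels / v$object_area, 100)
})

test_that("peak detection finds planted nuclei and suppresses close pairs", {
  withr::with_seed(1, {
    img <- matrix(5, 120, 120)
    rows <- numeric(0); cols <- numeric(0)
    while (length(rows) < 30) {
      r <- runif(1, 15, 105); c <- runif(1, 15, 105)
      if (!length(rows) || min((rows - r)^2 + (cols - c)^2) >= 81) {
        rows <- c(rows, r); cols <- c(cols, c)
      }
    }
  })
  img <- spherochip:::add_spots(img, rows, cols, 80, 2.5)
  pk <- detect_peaks(img, min_separation_px = 6)
  m <- match_points(pk$row_px, pk$col_px, rows, cols, tol_px = 1)
  expect_equal(m$tp, 30)
  expect_equal(m$fp, 0)

  # a uniform disk has no peaks
  flat <- matrix(0, 81, 81)
  flat[disk_mask(25, pad = 15)] <- 100
  expect_equal(nrow(detect_peaks(spherochip:::gaussian_blur(flat, 1))), 0)

  # two emitters 2 px apart merge under an 8 px separation
  pair <- spherochip:::add_spots(matrix(0, 60, 60), c(30, 32), c(30, 30), 50, 2)
  expect_equal(nrow(detect_peaks(pair, min_separation_px = 8)), 1)
})

test_that("radial coordinates come from centroid and equivalent radius", {
  pk <- tibble::tibble(row_px = c(50, 50, 80), col_px = c(50, 80, 50))
  out <- peak_radial(pk, 50, 50, 30)
  expect_equal(out$r_over_R, c(0, 1, 1))
})

test_that("3-NN distances: closed form, skipping, and decile gates", {
  nuc <- tibble::tibble(spheroid_id = 1, row_px = c(0, 0, 1, 1),
                        col_px = c(0, 1, 0, 1))
  nn <- nn_distances(nuc, k = 3)
  expect_equal(nn$mean_knn_um, rep((2 + sqrt(2)) / 3, 4))

  few <- tibble::tibble(spheroid_id = c(1, 1, 1, 2, 2, 2, 2),
                        row_px = rnorm(7), col_px = rnorm(7))
  nn2 <- nn_distances(few, k = 3)
  expect_equal(attr(nn2, "skipped_spheroids"), 1L)
  expect_equal(unique(nn2$spheroid_id), 2)

  g <- gate_deciles(1:100)
  expect_equal(sum(g == "below_d1"), 10)
  expect_equal(sum(g == "above_d9"), 10)
})

test_that("cells are sparser near the spheroid edge in planted chips", {
  lay <- small_layout(5000, 3500)
  tr <- simulate_chip(lay, sim_config(nuclei_per_spheroid = 40), seed = 13)
  nuc <- tr$cells
  nuc$spheroid_id <- nuc$anchor_id
  nn <- nn_distances(nuc, k = 3, pixel_size_um = PX)
  gate <- gate_deciles(nn$mean_knn_um)
  med_dense <- median(nn$r_over_R[gate == "below_d1"])
  med_sparse <- median(nn$r_over_R[gate == "above_d9"])
  expect_gt(med_sparse, med_dense)
})

test_that("volume-effect correction flattens a flat profile under a dome", {
  f <- simulate_alb_field(40, peak_profile = function(rr) rep(60, length(rr)),
                          n_peaks = 25, seed = 2)
  pk <- detect_peaks(f$image, f$mask, min_separation_px = 5)
  pk <- peak_radial(pk, f$center[["row"]], f$center[["col"]], f$radius_px)
  ca <- correct_alb(pk, f$image, f$mask, f$center[["row"]], f$center[["col"]],
                    f$radius_px, background = 5)
  expect_false(ca$excluded)
  expect_equal(nrow(ca$peaks), 25)
  expect_lt(sd(ca$peaks$corrected) / mean(ca$peaks$corrected), 0.05)
  # fitted background reproduces the planted dome shape
  expect_lt(abs(ca$coefficients[["c"]] - 40) / 40, 0.25)
})

test_that("a planted radial ALB rise is recovered after correction", {
  prof <- function(rr) 30 * (1 + 2 * pmax(rr - 0.2, 0) / 0.8)
  f <- simulate_alb_field(40, peak_profile = prof, n_peaks = 30, seed = 5)
  pk <- detect_peaks(f$image, f$mask, min_separation_px = 5)
  pk <- peak_radial(pk, f$center[["row"]], f$center[["col"]], f$radius_px)
  ca <- correct_alb(pk, f$image, f$mask, f$center[["row"]], f$center[["col"]],
                    f$radius_px, background = 5)
  lo <- ca$peaks$r_over_R < 0.35
  hi <- ca$peaks$r_over_R > 0.8
  ratio <- mean(ca$peaks$corrected[hi]) / mean(ca$peaks$corrected[lo])
  planted <- mean(prof(ca$peaks$r_over_R[hi])) / mean(prof(ca$peaks$r_over_R[lo]))
  expect_gt(ratio, 2)
  expect_lt(abs(ratio - planted) / planted, 0.25)
})

test_that("correction preserves amplitude ranks at equal radius and the
           chip normalisation identity", {
  # peaks at the same r/R: subtracting the radially symmetric dome is a
  # constant shift, so ranks are unchanged
  f <- simulate_alb_field(50, n_peaks = 0, seed = 1)
  ctr <- f$center
  th <- seq(0, 2 * pi - 0.5, length.out = 8)
  pk <- tibble::tibble(
    row_px = ctr[["row"]] + 30 * sin(th),
    col_px = ctr[["col"]] + 30 * cos(th),
    value = c(10, 50, 30, 90, 20, 70, 40, 60) + 40 # on top of dome-ish level
  )
  pk <- peak_radial(pk, ctr[["row"]], ctr[["col"]], f$radius_px)
  ca <- correct_alb(pk, f$image, f$mask, ctr[["row"]], ctr[["col"]],
                    f$radius_px, background = 5)
  expect_equal(order(ca$peaks$corrected), order(pk$value))

  normd <- normalize_alb(dplyr::mutate(ca$peaks, excluded = FALSE))
  expect_equal(mean(normd$normalized), 1, tolerance = 1e-12)

  # flagged spheroids are excluded from the chip mean and get NA
  two <- dplyr::bind_rows(
    dplyr::mutate(ca$peaks, excluded = FALSE),
    dplyr::mutate(ca$peaks, excluded = TRUE)
  )
  n2 <- normalize_alb(two)
  expect_true(all(is.na(n2$normalized[two$excluded])))
  expect_equal(mean(n2$normalized[!two$excluded]), 1, tolerance = 1e-12)
})

test_that("background fits degenerate inputs are flagged, not fatal", {
  f <- simulate_alb_field(40, n_peaks = 0)
  pk <- tibble::tibble(row_px = numeric(0), col_px = numeric(0),
                       value = numeric(0), r_over_R = numeric(0))
  tiny_mask <- f$mask & FALSE
  tiny_mask[45:47, 45:47] <- TRUE
  ca <- correct_alb(pk, f$image, tiny_mask, f$center[["row"]],
                    f$center[["col"]], f$radius_px)
  expect_true(ca$excluded)
})

test_that("BrdU gating recovers planted fractions and radial bias", {
  withr::with_seed(4, {
    n <- 1000
    pos <- runif(n) < 0.16
    dapi <- 80 * rlnorm(n, 0, 0.15)
    brdu <- dapi * ifelse(pos, 0.8, 0.2) * rlnorm(n, 0, 0.25)
  })
  g <- gate_brdu(brdu, dapi)
  expect_equal(g$method, "otsu")
  expect_lt(abs(g$fraction - mean(pos)), 0.02)

  # all-negative population goes through the fallback and gates ~nothing
  withr::with_seed(5, neg <- dapi * 0.2 * rlnorm(n, 0, 0.25))
  gn <- gate_brdu(neg, dapi)
  expect_equal(gn$method, "fallback")
  expect_lt(gn$fraction, 0.05)

  # planted radial enrichment at the rim is preserved by the gate
  lay <- small_layout(5000, 3500)
  tr <- simulate_chip(lay, sim_config(nuclei_per_spheroid = 40,
                                      brdu_edge_boost = 2), seed = 3)
  gc <- gate_brdu(tr$cells$brdu_amp, tr$cells$dapi_amp)
  rim <- tr$cells$r_over_R >= 0.8
  core <- tr$cells$r_over_R <= 0.5
  expect_gt(mean(gc$positive[rim]), mean(gc$positive[core]))
})

test_that("whole-frame 2-D analysis returns single ratios", {
  # planted ~30% BrdU+ field
  withr::with_seed(2, {
    n0 <- 300
    fr <- matrix(20, 900, 900)
    rows <- runif(n0, 20, 880); cols <- runif(n0, 20, 880)
    keep <- spherochip:::greedy_nms(rows, cols, runif(n0), 12)
    rows <- rows[keep]; cols <- cols[keep]
    n <- length(rows)
    pos <- runif(n) < 0.3
    dapi_amp <- 80 * rlnorm(n, 0, 0.15)
    dapi <- spherochip:::add_spots(fr, rows, cols, dapi_amp, 2.5) +
      rnorm(length(fr), 0, 2)
    brdu <- spherochip:::add_spots(fr, rows, cols,
                                   dapi_amp * ifelse(pos, 0.8, 0.2) *
                                     rlnorm(n, 0, 0.2), 2.5) +
      rnorm(length(fr), 0, 2)
  })
  r <- analyze_2d(brdu, dapi, "brdu")
  expect_lt(abs(r$ratio - 100 * mean(pos)), 2)

  # viability mode: no dead pixels -> 100%
  live <- matrix(20, 300, 300)
  live[100:200, 100:200] <- 150
  v <- analyze_2d(matrix(20, 300, 300), live, "viability")
  expect_equal(v$ratio, 100)
})

test_that("anchored and 2-D paths agree on a single-anchor viability crop", {
  lay <- small_layout(1400, 1400)
  tr <- simulate_chip(lay, sim_config(noise_sd = 1, dead_fraction = 0.15),
                      seed = 6)
  dapi <- render_chip(tr, "dapi")
  tritc <- render_chip(tr, "tritc")
  a <- lay$anchors[1, ]
  crd <- crop_anchor(dapi, a$row_px, a$col_px, ANCHOR_D_PX / 2 + 4)
  crt <- crop_anchor(tritc, a$row_px, a$col_px, ANCHOR_D_PX / 2 + 4)

  seg <- segment_fluorescence(crd$crop, PX)
  primary <- suppressMessages(select_primary_object(seg$objects))
  th <- segment_fluorescence(crt$crop, PX)$threshold
  anchored <- viability(seg$labels == primary$label, crt$crop, th)$viability
  twod <- analyze_2d(crt$crop, crd$crop, "viability")$ratio
  expect_lt(abs(anchored - twod), 1)
})
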