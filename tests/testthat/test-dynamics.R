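# Shared perfusion fixture at the study's scale (~130 spheroids per region).
perfusion_fixture <- function(seed = 5) {
  lay <- chip_layout(chamber_w_um = 20000, chamber_h_um = 8000,
                     pixel_size_um = PX)
  pf <- simulate_perfusion(lay, seed = seed)
  frames <- pf$frame_times_h
  dead <- purrr::map(frames, function(t) {
    cells <- perfusion_frame_cells(pf, t)
    d <- cells[!cells$alive, c("anchor_id", "r_over_R")]
    d$t_h <- t
    d
  }) |> purrr::list_rbind()
  list(layout = lay, pf = pf, dead = dead, frames = frames)
}

fx <- perfusion_fixture()

test_that("anchors partition into bands; boundaries go to the upper band", {
  lay <- fx$layout
  sch <- region_schedule(lay$chamber_h_um)
  reg <- assign_regions(lay$anchors, sch)
  counts <- table(reg$region)
  # equal bands: counts near a third of the lattice each
  expect_true(all(abs(counts - nrow(lay$anchors) / 3) <=
                    nrow(lay$anchors) / 10))
  expect_equal(sum(counts), nrow(lay$anchors))

  # an anchor exactly on the internal boundary is assigned to the upper band
  cut1 <- sch$regions$y_max_um[1]
  on_edge <- tibble::tibble(anchor_id = 1L, y_um = cut1)
  expect_message(r <- assign_regions(on_edge, sch), "upper band")
  expect_equal(as.character(r$region), "I")
  below <- assign_regions(tibble::tibble(anchor_id = 1L, y_um = cut1 + 1), sch)
  expect_equal(as.character(below$region), "II")
})

test_that("region spheroid counts equal the planted assignment", {
  # independent re-derivation from anchor y-coordinates
  sch <- fx$pf$schedule
  y <- fx$pf$spheroids$row_px # px at PX um/px
  y_um <- (y - 0.5) * PX
  manual <- cut(y_um, c(-Inf, sch$regions$y_max_um[1:2], Inf),
                labels = c("I", "II", "III"))
  expect_equal(as.character(fx$pf$spheroids$region), as.character(manual))
})

test_that("death series: conservation, monotonicity, zero case", {
  ds <- death_series(fx$dead, fx$pf$spheroids, fx$frames)
  # conservation: per-frame sum over regions equals chip-wide dead count
  per_frame <- tapply(ds$n_dead, ds$t_h, sum)
  chip <- table(factor(fx$dead$t_h, levels = fx$frames))
  expect_equal(as.numeric(per_frame), as.numeric(chip))
  # permanent deaths: every region series is non-decreasing
  for (reg in c("I", "II", "III")) {
    expect_true(all(diff(ds$n_dead_mean[ds$region == reg]) >= 0))
  }
  # no deaths -> flat zero series
  none <- death_series(fx$dead[0, ], fx$pf$spheroids, fx$frames)
  expect_true(all(none$n_dead_mean == 0))
})

test_that("intermittent exposure doubles the death rate over the control", {
  # final N_dead_mean ratio II/III, averaged over three generator seeds to
  # estimate the planted ratio (single chips scatter by ~+/-0.2)
  ratios <- vapply(c(5, 6, 7), function(sd_) {
    f <- if (sd_ == 5) fx else perfusion_fixture(sd_)
    ds <- death_series(f$dead, f$pf$spheroids, f$frames)
    fin <- ds[ds$t_h == max(f$frames), ]
    fin$n_dead_mean[fin$region == "II"] / fin$n_dead_mean[fin$region == "III"]
  }, numeric(1))
  expect_gt(mean(ratios), 1.7)
  expect_lt(mean(ratios), 2.3)
})

test_that("continuous exposure shows a rate break after the slow onset", {
  ds <- death_series(fx$dead, fx$pf$spheroids, fx$frames)
  slope <- function(reg, t0, t1) {
    s <- ds[ds$region == reg & ds$t_h >= t0 & ds$t_h <= t1, ]
    unname(coef(lm(n_dead_mean ~ t_h, s))[2])
  }
  post_I <- slope("I", 5.5, 9.5)
  post_II <- slope("II", 5.5, 9.5)
  pre_gap <- abs(slope("I", 2, 5) - slope("II", 2, 5))
  # before onset region I tracks region II; after, it breaks sharply upward
  expect_gt(post_I, 3 * max(post_II, 0.02))
  expect_gt(post_I / max(slope("I", 3.5, 5), 0.02), 1.5)
  expect_lt(pre_gap, 0.25)

  # changepoint of a two-segment fit, estimated after the fast transient
  # has settled (t >= 3), lands near the planted onset
  s_late <- ds[ds$region == "I" & ds$t_h >= 3, ]
  cand <- seq(4, 8.5, 0.5)
  sse <- vapply(cand, function(b) {
    x1 <- pmin(s_late$t_h, b)
    x2 <- pmax(s_late$t_h - b, 0)
    sum(resid(lm(s_late$n_dead_mean ~ x1 + x2))^2)
  }, numeric(1))
  expect_lt(abs(cand[which.min(sse)] - 5), 1.6)
})

test_that("viability trajectories count the planted early-dying spheroids", {
  pf <- fx$pf
  totals <- table(pf$cells$anchor_id)
  viab <- purrr::map(fx$frames, function(t) {
    cells <- perfusion_frame_cells(pf, t)
    alive <- tapply(cells$alive, cells$anchor_id, mean)
    tibble::tibble(spheroid_id = as.integer(names(alive)),
                   t_h = t, viability = 100 * as.numeric(alive))
  }) |> purrr::list_rbind()
  viab <- dplyr::left_join(
    viab, dplyr::rename(pf$spheroids[, c("anchor_id", "region")],
                        spheroid_id = "anchor_id"),
    by = "spheroid_id"
  )
  # restrict to spheroid-class anchors: cell units hold 1-5 cells, where a
  # couple of spontaneous deaths swing the cell-fraction viability wildly
  sph_ids <- pf$objects$anchor_id[pf$objects$class == "spheroid"]
  vt <- viability_trajectories(viab[viab$spheroid_id %in% sph_ids, ],
                               threshold = 50)
  early_sph <- intersect(pf$early_spheroids, sph_ids)
  planted <- table(pf$spheroids$region[match(early_sph,
                                             pf$spheroids$anchor_id)])
  # early diers lose essentially all cells, so each crosses the threshold;
  # the slow mechanism (~15% of cells) does not push survivors below 50%
  for (reg in c("II", "III")) {
    expect_equal(vt$summary$n_crossed[vt$summary$region == reg],
                 unname(planted[reg]))
  }
  expect_gte(vt$summary$n_crossed[vt$summary$region == "I"],
             unname(planted["I"]))
  # region I: lower final mean and wider spread than the control
  s <- vt$summary
  expect_lt(s$final_mean[s$region == "I"], s$final_mean[s$region == "III"])
  expect_gt(s$final_sd[s$region == "I"], s$final_sd[s$region == "III"])

  # degenerate all-alive region: flat histogram at 100%
  flat <- tibble::tibble(spheroid_id = rep(1:5, each = 2),
                         region = factor("III", c("I", "II", "III")),
                         t_h = rep(c(0, 1), 5), viability = 100)
  vt0 <- viability_trajectories(flat)
  expect_equal(vt0$summary$n_crossed, 0L)
  expect_equal(vt0$summary$final_sd, 0)
})

test_that("dead cells appear at the rim and drift inward only under
           continuous exposure", {
  mdr <- mean_dead_radial(fx$dead, fx$pf$spheroids)
  early <- mdr[mdr$t_h <= 2 & mdr$n_dead > 3, ]
  expect_lt(abs(mean(early$mean_r_over_R_dead) - 0.8), 0.1)
  sl <- function(reg) {
    s <- mdr[mdr$region == reg & mdr$t_h >= 1, ]
    unname(coef(lm(mean_r_over_R_dead ~ t_h, s))[2])
  }
  expect_lt(sl("I"), -0.002)
  expect_lt(abs(sl("III")), 0.003)

  # single dead cell at the centroid -> mean r/R 0
  one <- tibble::tibble(t_h = 1, r_over_R = 0,
                        region = factor("I", c("I", "II", "III")))
  expect_equal(mean_dead_radial(one)$mean_r_over_R_dead, 0)
})

test_that("endothelial cores are detected with their planted geometry", {
  # single central core
  n <- 121; ctr <- 61; R <- 45
  mask <- disk_mask(R, pad = (n - 2 * R - 1) / 2)[1:n, 1:n]
  mk_core <- function(centers, radius) {
    img <- matrix(20, n, n)
    rows <- matrix(seq_len(n), n, n); cols <- t(rows)
    for (i in seq_len(nrow(centers))) {
      d <- sqrt((rows - centers[i, 1])^2 + (cols - centers[i, 2])^2)
      img <- img + 80 / (1 + exp((d - radius) / 0.8))
    }
    img
  }
  central <- mk_core(rbind(c(ctr, ctr)), 12)
  dc <- detect_cores(central, mask, ctr, ctr, R)
  expect_equal(dc$n_cores, 1L)
  expect_lt(dc$cores$dist_over_R, 0.05)

  # three off-centre cores at known distances
  offs <- rbind(c(ctr - 22, ctr), c(ctr + 14, ctr - 18), c(ctr + 10, ctr + 24))
  three <- mk_core(offs, 8)
  d3 <- detect_cores(three, mask, ctr, ctr, R)
  expect_equal(d3$n_cores, 3L)
  truth_d <- sqrt((offs[, 1] - ctr)^2 + (offs[, 2] - ctr)^2) / R
  expect_equal(sort(d3$cores$dist_over_R), sort(truth_d), tolerance = 0.05)

  # no endothelial signal -> zero cores
  d0 <- detect_cores(matrix(20, n, n) + 0.01 * matrix(rnorm(n^2), n, n),
                     mask, ctr, ctr, R)
  expect_equal(d0$n_cores, 0L)
})

test_that("core count and position follow the planted mixing-ratio trend", {
  lay <- small_layout(6000, 4100)
  cc <- simulate_coculture(lay, seed = 3)
  tritc <- render_chip(cc, "tritc")
  dapi <- render_chip(cc, "dapi")
  res <- purrr::map(seq_len(nrow(cc$objects)), function(i) {
    o <- cc$objects[i, ]
    crt <- crop_anchor(tritc, o$row_px, o$col_px, ANCHOR_D_PX / 2 + 4)
    crd <- crop_anchor(dapi, o$row_px, o$col_px, ANCHOR_D_PX / 2 + 4)
    seg <- segment_fluorescence(crd$crop, PX)
    if (!nrow(seg$objects)) return(NULL)
    pr <- suppressMessages(select_primary_object(seg$objects))
    dc <- detect_cores(crt$crop, seg$labels == pr$label, pr$row_centroid,
                       pr$col_centroid, pr$diameter_um / 2 / PX, PX)
    tibble::tibble(ratio = o$baec_ratio, n_cores = dc$n_cores,
                   mean_dist = mean(dc$cores$dist_over_R),
                   signal = dc$total_signal)
  }) |> purrr::list_rbind()
  agg <- res |>
    dplyr::group_by(ratio) |>
    dplyr::summarise(n = mean(n_cores), d = mean(mean_dist, na.rm = TRUE),
                     s = mean(signal), .groups = "drop")
  expect_equal(agg$n[agg$ratio == 0], 0)
  hi <- agg[agg$ratio >= 0.7, ]
  lo <- agg[agg$ratio > 0 & agg$ratio <= 0.2, ]
  expect_lt(mean(hi$n), mean(lo$n))       # fewer cores at high ratio
  expect_lt(mean(hi$d), mean(lo$d))       # more central cores at high ratio
  expect_gt(cor(agg$ratio, agg$s), 0.9)   # signal tracks the mixing ratio
})
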