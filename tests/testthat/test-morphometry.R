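test_that("shape index closed forms: circle 1, square pi/4", {
  for (r in c(1, 5, 72.9 / 2)) {
    expect_equal(shape_index(pi * r^2, 2 * pi * r), 1)
  }
  for (s in c(1, 40)) {
    expect_equal(shape_index(s^2, 4 * s), pi / 4)
  }
})

test_that("rasterised disks measure near-analytic perimeter and ShI", {
  for (r in c(10, 20, 30, 50)) {
    m <- measure_mask(disk_mask(r), pixel_size_um = 1)
    expect_lt(abs(m$perimeter_um - 2 * pi * r) / (2 * pi * r), 0.015)
    expect_lt(abs(m$shape_index_raw - 1), 0.02)
    expect_lt(abs(m$diameter_um - 2 * r), 1)
  }
  # 1-px-wide mask: ShI near 0 with a warning
  line <- matrix(FALSE, 10, 80)
  line[5, 10:70] <- TRUE
  expect_warning(m <- measure_mask(line), "degenerate")
  expect_lt(m$shape_index, 0.1)
})

test_that("ShI is invariant under rotation and integer scaling", {
  # elliptical mask, axes 29 x 18 px
  m <- matrix(FALSE, 70, 90)
  rows <- matrix(seq_len(70), 70, 90)
  cols <- matrix(seq_len(90), 70, 90, byrow = TRUE)
  m[((rows - 35) / 18)^2 + ((cols - 45) / 29)^2 <= 1] <- TRUE
  s0 <- measure_mask(m)$shape_index_raw
  s90 <- measure_mask(t(m)[ncol(m):1, ])$shape_index_raw
  expect_lt(abs(s0 - s90), 0.03)
  big <- m[rep(seq_len(nrow(m)), each = 2), rep(seq_len(ncol(m)), each = 2)]
  expect_lt(abs(measure_mask(big)$shape_index_raw - s0), 0.03)
})

test_that("equivalent diameter inverts area", {
  expect_equal(equivalent_diameter(pi * 36.45^2), 72.9)
  expect_equal(equivalent_diameter(1), 2 / sqrt(pi))
  d80 <- measure_mask(disk_mask(40 / PX), pixel_size_um = PX)$diameter_um
  expect_lt(abs(d80 - 80), 2 * PX)
})

test_that("object classification follows the morphological sorting rules", {
  expect_equal(as.character(classify_object(72.9, 0.8)), "spheroid")
  expect_equal(as.character(classify_object(50, 0.3)), "aggregate")
  expect_equal(as.character(classify_object(8, 0.9)), "discarded")
  expect_equal(as.character(classify_object(20, 0.9)), "unit")
  expect_equal(as.character(classify_object(72.9, 0.8, focus_kept = FALSE)),
               "discarded")
  # boundary conventions: D = 40 um -> unit; ShI = 0.5 -> aggregate
  expect_equal(as.character(classify_object(40, 0.9)), "unit")
  expect_equal(as.character(classify_object(40.001, 0.499)), "aggregate")
  expect_equal(as.character(classify_object(40.001, 0.5)), "spheroid")
  expect_equal(as.character(classify_object(9, 0.9)), "unit")

  # totality: every input maps to exactly one class, never NA
  grid <- expand.grid(d = c(0, 5, 9, 20, 40, 41, 100),
                      shi = c(0, 0.3, 0.5, 0.7, 1),
                      keep = c(TRUE, FALSE))
  cls <- classify_object(grid$d, grid$shi, grid$keep)
  expect_false(any(is.na(cls)))
  expect_equal(length(cls), nrow(grid))
})

test_that("formation fit recovers noise-free kinetics exactly", {
  tr <- simulate_formation(tau_h = 11, noise_cv = 0, tau_cv = 0,
                           n_traces = 3, seed = 1)
  # relaxation-time identity: A(tau) - A_inf = (A0 - A_inf)/e
  one <- tr[tr$trace_id == 1, ]
  a_tau <- approx(one$t_h, one$area_um2, xout = 11)$y
  expect_equal(a_tau - 4000, (12000 - 4000) / exp(1), tolerance = 1e-3)

  fit <- fit_formation(tr)
  td <- tidy(fit)
  expect_true(all(td$converged))
  expect_equal(td$tau_h, rep(11, 3), tolerance = 0.01)
  expect_equal(glance(fit)$tau_pooled, 11, tolerance = 0.01)
})

test_that("constant traces fail gracefully and are retained", {
  flat <- tibble::tibble(trace_id = 1, t_h = seq(0, 23, 0.5),
                         area_um2 = 5000)
  fit <- fit_formation(flat)
  expect_false(tidy(fit)$converged)
  expect_true(is.na(tidy(fit)$tau_h))
  expect_equal(nrow(tidy(fit)), 1)
})

test_that("faster-compacting populations fit shorter characteristic times", {
  g11 <- glance(fit_formation(simulate_formation(tau_h = 11, n_traces = 40,
                                                 seed = 42)))
  g4 <- glance(fit_formation(simulate_formation(tau_h = 4, n_traces = 40,
                                                seed = 42)))
  expect_lt(g4$tau_median, g11$tau_median)
  expect_lt(abs(g4$tau_median - 4) / 4, 0.15)
})

test_that("noise-free formation renders have monotone ShI before noise", {
  tr <- simulate_formation(noise_cv = 0, tau_cv = 0, n_traces = 2, seed = 1)
  for (id in unique(tr$trace_id)) {
    shi <- tr$shi[tr$trace_id == id]
    expect_true(all(diff(shi) >= -1e-9))
    expect_lt(max(shi), 1.01)
  }
})
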