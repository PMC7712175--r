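test_that("COP is the force-weighted centroid of the cell positions", {
  cells <- square_cells(100)
  equal <- tibble::tibble(time_s = 0:1, f1 = 5, f2 = 5, f3 = 5, f4 = 5)
  traj <- compute_cop(equal, cells)
  expect_equal(traj$ml_mm, c(0, 0))
  expect_equal(traj$ap_mm, c(0, 0))

  solo <- tibble::tibble(time_s = 0, f1 = 7, f2 = 0, f3 = 0, f4 = 0)
  traj <- compute_cop(solo, cells)
  expect_equal(c(traj$ml_mm, traj$ap_mm), c(-100, 100))

  # hand-computed: weights (2,1,1,0) on corners (-100,100),(100,100),(100,-100),(-100,-100)
  w <- tibble::tibble(time_s = 0, f1 = 2, f2 = 1, f3 = 1, f4 = 0)
  traj <- compute_cop(w, cells)
  expect_equal(c(traj$ml_mm, traj$ap_mm), c(0, 50))

  # brute-force oracle on random cases
  withr::with_seed(99, {
    for (i in 1:25) {
      pos <- matrix(runif(8, -150, 150), 4, 2)
      while (nrow(unique(pos)) < 4) pos <- matrix(runif(8, -150, 150), 4, 2)
      f <- matrix(runif(12, 0.1, 50), 3, 4)
      forces <- tibble::tibble(time_s = 0:2, f1 = f[, 1], f2 = f[, 2],
                               f3 = f[, 3], f4 = f[, 4])
      got <- compute_cop(forces, pos)
      for (s in 1:3) {
        expect_equal(got$ml_mm[s], sum(f[s, ] * pos[, 1]) / sum(f[s, ]),
                     tolerance = 1e-12)
        expect_equal(got$ap_mm[s], sum(f[s, ] * pos[, 2]) / sum(f[s, ]),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("COP computation rejects degenerate force input", {
  cells <- square_cells()
  zero <- tibble::tibble(time_s = 0:1, f1 = c(1, 0), f2 = c(1, 0),
                         f3 = c(1, 0), f4 = c(1, 0))
  err <- expect_error(compute_cop(zero, cells), class = "balancemdc_degenerate")
  expect_match(conditionMessage(err), "index 2")
  neg <- tibble::tibble(time_s = 0, f1 = -1, f2 = 1, f3 = 1, f4 = 1)
  expect_error(compute_cop(neg, cells), class = "balancemdc_invalid_spec")
  expect_error(compute_cop(tibble::tibble(time_s = 0, f1 = 1, f2 = 1, f3 = 1, f4 = 1),
                           cells[c(1, 1, 2, 3), ]),
               class = "balancemdc_invalid_spec")
})

test_that("mean speed is path length over elapsed time", {
  expect_equal(mean_speed(constant_traj()), 0)
  seg <- make_traj(c(0, 2), c(0, 6), c(0, 8)) # 10 mm in 2 s
  expect_equal(mean_speed(seg), 5)
  # circle of radius r at angular rate omega: speed -> r * omega as fs grows
  r <- 10; omega <- 2 * pi
  expect_equal(mean_speed(circle_traj(r, omega, fs = 1000)), r * omega,
               tolerance = 0.01)
  expect_error(mean_speed(make_traj(0, 0, 0)),
               class = "balancemdc_insufficient_data")
})

test_that("RMS position is the radial RMS about the mean point", {
  expect_equal(rms_position(constant_traj(ml = 3, ap = -2)), 0)
  circ <- circle_traj(r = 7, fs = 512)
  expect_equal(rms_position(circ), 7, tolerance = 1e-3)
  two <- make_traj(c(0, 1), c(-1, 1), c(0, 0))
  expect_equal(rms_position(two), 1)
})

test_that("sway area: 95% ellipse closed form and convex hull", {
  flat <- make_traj(0:4 / 10, 0:4, 2 * (0:4)) # collinear
  expect_equal(sway_area(flat, "ellipse95"), 0)
  expect_error(sway_area(flat, "convex_hull"), class = "balancemdc_degenerate")

  sq <- make_traj(0:3 / 10, c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(sway_area(sq, "convex_hull"), 0.01) # 1 mm^2

  # isotropic Gaussian cloud of SD s: ellipse area -> pi * chi2(0.95) * s^2
  s <- 10
  cloud <- withr::with_seed(31, {
    make_traj(seq_len(20000) / 100, rnorm(20000, 0, s), rnorm(20000, 0, s))
  })
  expect_equal(sway_area(cloud), pi * qchisq(0.95, 2) * s^2 / 100,
               tolerance = 0.05)
})

test_that("directional range is max minus min of the coordinate", {
  expect_equal(directional_range(constant_traj(), "AP"), 0)
  tr <- make_traj(c(0, 1), c(0, 0), c(-3, 7))
  expect_equal(directional_range(tr, "AP"), 10)
  w <- wander_traj(seed = 4)
  expect_equal(directional_range(w, "ML"), max(w$ml_mm) - min(w$ml_mm))
  expect_equal(directional_range(w, "AP"), max(w$ap_mm) - min(w$ap_mm))
})

test_that("COP limits are start-referenced directional maxima, floored at zero", {
  geom <- los_geometry(80)
  still <- constant_traj(n = 5, ml = 12, ap = -4) # offset start, never moves
  expect_equal(cop_limits(still, geom)$limit_mm, rep(0, 8))

  fwd <- make_traj(c(0, 1, 2), c(0, 0, 0), c(0, 80, 0))
  lims <- cop_limits(fwd, geom)
  expect_equal(lims$limit_mm[lims$direction == "Forward"], 80)
  expect_equal(lims$limit_mm[lims$direction == "Forward-rightward"],
               80 * cos(pi / 4), tolerance = 1e-12)
  expect_equal(lims$limit_mm[lims$direction == "Backward"], 0)
})

test_that("default success score is the out-and-back path-efficiency ratio", {
  fgeom <- los_geometry(80)[1, ] # Forward only
  straight <- make_traj(0:2, c(0, 0, 0), c(0, 10, 0), target_dir = "Forward")
  expect_equal(success_scores(straight, fgeom)$success_pct, 100)

  still <- make_traj(0:2, c(0, 0, 0), c(0, 0, 0), target_dir = "Forward")
  expect_equal(success_scores(still, fgeom)$success_pct, 0)

  meander <- make_traj(0:4, rep(0, 5), c(0, 10, 0, 10, 0), target_dir = "Forward")
  expect_equal(success_scores(meander, fgeom)$success_pct, 50)

  # pluggable scorer
  expect_equal(
    success_scores(straight, fgeom, scorer = function(phase, ux, uy) 42)$success_pct,
    42)
  expect_error(success_scores(make_traj(0:1, 0:1, 0:1), fgeom),
               class = "balancemdc_config")
})

test_that("extract_variables returns the task's full panel", {
  static <- extract_variables(constant_traj(n = 6), "RSEO")
  expect_equal(static$variable,
               c("COP mean speed", "RMS", "Area", "AP disp.", "ML disp."))
  expect_equal(static$value, rep(0, 5))
  expect_equal(static$units, c("mm/s", "mm", "cm^2", "mm", "mm"))

  spec <- los_spec(radius_target_mm = 80, dwell_s = 2)
  vars <- extract_variables(gen_los_trajectory(spec), "LOS", geom = los_geometry(80))
  expect_equal(nrow(vars), 21)
  dirs <- c("Forward", "Forward-rightward", "Rightward", "Backward-rightward",
            "Backward", "Backward-leftward", "Leftward", "Forward-leftward")
  expect_equal(vars$variable,
               c("COP mean speed", "RMS", "Area", "AP disp.", "ML disp.",
                 paste0("Lim.COP.", dirs), paste0("Success.", dirs)))
  lims <- vars$value[6:13]
  expect_equal(lims, rep(80, 8), tolerance = 1e-12)
  expect_true(all(vars$value >= 0))
  expect_true(all(vars$value[14:21] >= 0 & vars$value[14:21] <= 100))
  expect_error(extract_variables(gen_los_trajectory(spec), "LOS"),
               class = "balancemdc_config")
})

test_that("metrics transform correctly under scaling, translation and time dilation", {
  geom <- los_geometry(80)
  for (seed in 1:4) {
    tr <- wander_traj(n = 150, seed = seed)
    cc <- 2.5
    scaled <- make_traj(tr$time_s, cc * tr$ml_mm, cc * tr$ap_mm)
    expect_equal(rms_position(scaled), cc * rms_position(tr))
    expect_equal(mean_speed(scaled), cc * mean_speed(tr))
    expect_equal(directional_range(scaled, "AP"), cc * directional_range(tr, "AP"))
    expect_equal(sway_area(scaled), cc^2 * sway_area(tr))
    expect_equal(cop_limits(scaled, geom)$limit_mm, cc * cop_limits(tr, geom)$limit_mm)

    shifted <- make_traj(tr$time_s, tr$ml_mm + 40, tr$ap_mm - 15)
    expect_equal(rms_position(shifted), rms_position(tr))
    expect_equal(mean_speed(shifted), mean_speed(tr))
    expect_equal(sway_area(shifted), sway_area(tr))
    expect_equal(directional_range(shifted, "ML"), directional_range(tr, "ML"))
    expect_equal(cop_limits(shifted, geom)$limit_mm, cop_limits(tr, geom)$limit_mm)

    k <- 3
    slow <- make_traj(k * tr$time_s, tr$ml_mm, tr$ap_mm)
    expect_equal(mean_speed(slow), mean_speed(tr) / k)
  }
})

test_that("low-pass filtering attenuates high-frequency noise but keeps slow sway", {
  t <- seq(0, 10, by = 1 / 40)
  slow <- sin(2 * pi * 0.3 * t)
  noisy <- slow + withr::with_seed(8, rnorm(length(t), 0, 0.5))
  tr <- make_traj(t, noisy, noisy)
  sm <- lowpass_cop(tr, cutoff_hz = 2)
  expect_lt(mean((sm$ml_mm - slow)^2), mean((noisy - slow)^2) / 4)
  expect_error(lowpass_cop(tr, cutoff_hz = 50), class = "balancemdc_invalid_spec")
})
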