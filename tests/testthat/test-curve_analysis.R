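flat_curve <- function(level = 0, n = 2000, noise_sd = 0, z_max = 20,
                       seed = 1) {
  withr::with_seed(seed, {
    z <- seq(0, z_max, length.out = n)
    force_curve(z, rep(level, n) + rnorm(n, 0, noise_sd),
                curve_metadata(source_id = "flat"), corrected = TRUE)
  })
}

test_that("baseline estimate is exact on constant input and robust to noise", {
  cv <- flat_curve(level = 0.30)
  bl <- estimate_baseline(cv, tail_fraction = 0.2)
  expect_equal(bl$level, 0.30)
  expect_equal(bl$noise_sd, 0)

  # adhesion well confined to z < 5, flat zero tail
  z <- seq(0, 20, by = 0.01)
  f <- ifelse(z < 5, -sin(pi * z / 5), 0)
  bl2 <- estimate_baseline(force_curve(z, f, corrected = TRUE))
  expect_equal(bl2$level, 0)

  bln <- estimate_baseline(flat_curve(0, noise_sd = 0.05, seed = 5))
  expect_lt(abs(bln$noise_sd - 0.05) / 0.05, 0.15)

  expect_error(estimate_baseline(flat_curve(n = 70), tail_fraction = 0.2),
               "insufficient baseline")
  expect_error(estimate_baseline(flat_curve(), tail_fraction = 0.7),
               "tail_fraction")
})

test_that("origin is the first baseline crossing, linearly interpolated", {
  # crossing exactly at a sample
  z <- seq(0, 20, by = 0.1)
  f <- 12.4 - z  # crosses 0 at z = 12.4, a grid point
  expect_equal(find_origin(force_curve(z, f, corrected = TRUE), 0), 12.4)

  # midpoint interpolation between (-0.1 at 3.0) and (+0.1 at 3.2)
  z2 <- c(seq(0, 3.0, by = 0.05), seq(3.2, 20, by = 0.05))
  f2 <- approx(c(0, 3.0, 3.2, 20), c(-3, -0.1, 0.1, 0.1), xout = z2)$y
  expect_equal(find_origin(force_curve(z2, f2, corrected = TRUE), 0), 3.1)

  # first crossing in retraction order wins over later ones
  z3 <- seq(0, 20, by = 0.01)
  f3 <- cos(z3)  # many crossings, first at pi/2
  expect_equal(find_origin(force_curve(z3, f3, corrected = TRUE), 0),
               pi / 2, tolerance = 1e-4)

  expect_error(find_origin(flat_curve(level = 1), 0), "no crossing")
})

test_that("Savitzky-Golay derivative reproduces polynomials and flags bad params", {
  z <- seq(0, 1, by = 0.001)
  lin <- force_curve(z, 2 * z, corrected = TRUE)
  d <- smooth_derivative(lin, window = 21, polyorder = 3)
  interior <- 21:(length(z) - 21)
  expect_equal(d[interior], rep(2, length(interior)), tolerance = 1e-9)

  quad <- force_curve(z, z^2, corrected = TRUE)
  d2 <- smooth_derivative(quad, window = 11, polyorder = 2)
  expect_equal(d2[interior], 2 * z[interior], tolerance = 1e-6)

  const <- flat_curve(level = 1)
  expect_equal(max(abs(smooth_derivative(const))), 0, tolerance = 1e-10)

  expect_error(smooth_derivative(lin, window = 20), "odd")
  expect_error(smooth_derivative(lin, window = 3, polyorder = 5), "polyorder")
  expect_error(smooth_derivative(flat_curve(n = 64), window = 101), "exceeds")
})

test_that("discontinuity detection finds real steps and ignores smooth decay", {
  z <- seq(0, 20, by = 0.01)
  smooth <- force_curve(z, -exp(-z / 3), corrected = TRUE)
  ev <- detect_discontinuities(smooth, noise_sd = 0.001)
  expect_equal(NROW(ev), 0)

  st <- simulate_staircase(3, step_height = 0.4, noise_sd = 0.02, seed = 7)
  bl <- estimate_baseline(st$curve)
  ev3 <- detect_discontinuities(st$curve, noise_sd = bl$noise_sd, window = 21)
  expect_equal(NROW(ev3), 3)
  half_window <- 21 / 2 * 0.01
  expect_true(all(abs(sort(ev3$z_position) - sort(st$truth$z_steps)) <=
                    half_window))
  expect_true(all(ev3$force_jump > 0))
  expect_true(all(ev3$post_force > ev3$pre_force))

  # a step no larger than the noise floor is not an event
  st1 <- simulate_staircase(1, step_height = 0.02, noise_sd = 0.02, seed = 8)
  ev1 <- detect_discontinuities(st1$curve, noise_sd = 0.02, window = 21)
  expect_equal(NROW(ev1), 0)
})

test_that("detachment point is the last event with its pre-rupture force", {
  ev <- data.frame(z_position = c(2.0, 5.5, 9.1),
                   force_jump = c(0.5, 0.4, 0.3),
                   pre_force = c(-1.0, -0.8, -0.3),
                   post_force = c(-0.5, -0.4, 0.0))
  det <- find_detachment_point(ev, baseline_level = 0)
  expect_equal(det$z_det, 9.1)
  expect_equal(det$f_det, -0.3)
  expect_equal(find_detachment_point(ev[2, ], 0)$z_det, 5.5)
  expect_error(find_detachment_point(ev[0, ], 0), "no detachment")
})

test_that("detachment work matches closed-form polygon areas", {
  # zero force -> zero work
  expect_equal(compute_detachment_work(flat_curve(0), z_det = 10), 0)

  # triangle well: 0 -> -1 nN at 1 um -> 0 at 2 um gives 1 fJ
  tri <- polyline_curve(c(0, 1, 2), c(0, -1, 0))
  expect_equal(compute_detachment_work(tri, z_det = 2), 1.0,
               tolerance = 1e-12)

  # random polylines against the shoelace oracle
  withr::with_seed(11, {
    for (i in 1:25) {
      p <- random_adhesion_polyline()
      cv <- polyline_curve(p$z, p$f)
      W <- compute_detachment_work(cv, z_det = max(p$z))
      expect_equal(W, polygon_work(p$z, p$f), tolerance = 1e-9)
    }
  })

  expect_error(compute_detachment_work(tri, z_det = 5), "beyond")
  expect_error(compute_detachment_work(tri, z_det = -1), "> 0")
})

test_that("full analysis recovers simulated work and is deterministic", {
  cfg <- test_simconfig()
  sim <- synthesize_retract_curve(cfg, 12L, seed = 21)
  res <- analyze_curve(sim$curve)
  expect_false(res$flagged)
  expect_lt(abs(res$work - sim$truth$W) / sim$truth$W, 0.05)
  expect_gt(res$z_det, 0)
  expect_true(all(res$events$z_position <= res$z_det))
  expect_equal(res$z_det, max(res$events$z_position))
  expect_gte(res$max_adhesion, abs(res$f_det) - 1e-9)

  res2 <- analyze_curve(sim$curve)
  expect_identical(res, res2)
})

test_that("noise-only curves are flagged, not dropped", {
  res <- analyze_curve(flat_curve(0, noise_sd = 0.02, seed = 3))
  expect_true(res$flagged)
  expect_match(res$flag_reason, "no detachment|no crossing")
  df <- results_to_df(list(res))
  expect_equal(nrow(df), 1)
  expect_true(is.na(df$work_fJ))
})

test_that("analysis is invariant to force offsets and equivariant to scalings", {
  cfg <- test_simconfig()
  sim <- synthesize_retract_curve(cfg, 8L, seed = 31)
  base <- analyze_curve(sim$curve)

  shifted <- force_curve(sim$curve$z, sim$curve$force + 0.7,
                         sim$curve$metadata, corrected = TRUE)
  res_s <- analyze_curve(shifted)
  expect_equal(res_s$work, base$work, tolerance = 1e-9)
  expect_equal(res_s$z_det, base$z_det, tolerance = 1e-9)
  expect_equal(NROW(res_s$events), NROW(base$events))

  cF <- 3.5
  scaled_f <- force_curve(sim$curve$z, sim$curve$force * cF,
                          sim$curve$metadata, corrected = TRUE)
  res_f <- analyze_curve(scaled_f)
  expect_equal(res_f$work, base$work * cF, tolerance = 1e-6)
  expect_equal(sort(res_f$events$force_jump),
               sort(base$events$force_jump) * cF, tolerance = 1e-6)

  cZ <- 2
  scaled_z <- force_curve(sim$curve$z * cZ, sim$curve$force,
                          sim$curve$metadata, corrected = TRUE)
  res_z <- analyze_curve(scaled_z)
  expect_equal(res_z$work, base$work * cZ, tolerance = 1e-6)
  expect_equal(res_z$z_det, base$z_det * cZ, tolerance = 1e-6)
})

test_that("uncorrected curves are bend-corrected when analysing separation", {
  cfg <- test_simconfig()
  sim <- synthesize_retract_curve(cfg, 8L, seed = 41)
  k <- sim$curve$metadata$spring_constant
  # build the raw piezo curve whose correction reproduces the separation
  z_piezo <- sim$curve$z + (sim$curve$force / k) * 1e-3
  raw <- force_curve(z_piezo, sim$curve$force, sim$curve$metadata,
                     corrected = FALSE)
  res_raw <- analyze_curve(raw, analysis_params(distance = "separation"))
  res_sep <- analyze_curve(sim$curve)
  expect_equal(res_raw$work, res_sep$work, tolerance = 1e-6)
  # piezo mode analyses the raw coordinate unchanged
  res_piezo <- analyze_curve(raw, analysis_params(distance = "piezo"))
  expect_false(res_piezo$flagged)
})
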