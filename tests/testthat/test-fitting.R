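# build a results table directly in the CSV schema
fake_results <- function(variable, values, works) {
  n <- length(works)
  df <- data.frame(
    source_id = sprintf("c%03d.txt", seq_len(n)),
    approach_speed_um_s = 10, retract_speed_um_s = 10,
    delay_time_s = 45, setpoint_nN = 1,
    delay_mode = "constant_height",
    work_fJ = works, z_det_um = 10, f_det_nN = -0.5,
    n_events = 5L, max_adhesion_nN = 1,
    stringsAsFactors = FALSE
  )
  df[[variable]] <- values
  df
}

test_that("aggregation groups, sorts and summarises per condition", {
  withr::with_seed(55, {
    speeds <- rep(c(10, 1, 25), each = 10)
    works <- rnorm(30, 50, 5)
    df <- fake_results("retract_speed_um_s", speeds, works)
    s <- aggregate_by_condition(df, "v_r")
    expect_equal(nrow(s), 3)
    expect_equal(s$value, c(1, 10, 25))  # sorted ascending
    expect_equal(s$n_curves, rep(10L, 3))
    expect_equal(s$mean_W[1], mean(works[speeds == 1]))
    expect_equal(sum(s$n_curves), 30)   # counts conserved
  })
})

test_that("hand-computed group statistics match on a toy table", {
  df <- fake_results("delay_time_s", c(1, 1, 1, 15, 15, 15),
                     c(2, 4, 6, 10, 20, 30))
  s <- aggregate_by_condition(df, "tau")
  expect_equal(s$mean_W, c(4, 20))
  expect_equal(s$median_W, c(4, 20))
  expect_equal(s$sd_W, c(2, 10))
  expect_false(any(s$degenerate))

  # single-curve group: sd 0 and degenerate flag
  s1 <- aggregate_by_condition(
    fake_results("delay_time_s", c(1, 15, 15), c(3, 1, 5)), "tau")
  expect_equal(s1$sd_W, c(0, sd(c(1, 5))))
  expect_identical(s1$degenerate, c(TRUE, FALSE))
})

test_that("flagged curves are excluded from aggregation", {
  df <- fake_results("delay_time_s", c(1, 1, 15, 15), c(2, 4, 10, 20))
  df$flagged <- c(FALSE, TRUE, FALSE, FALSE)
  df$work_fJ[2] <- NA
  s <- aggregate_by_condition(df, "tau")
  expect_equal(s$n_curves, c(1L, 2L))
  expect_equal(s$mean_W, c(2, 15))
  expect_warning(aggregate_by_condition(df[0, ], "tau"), "no unflagged")
})

test_that("noiseless model data are recovered to numerical precision", {
  # delay model at the published parameters over the studied dwell times
  tau <- c(1, 15, 30, 45, 60, 120)
  s <- data.frame(value = tau, mean_W = model_W_delay(tau, 0.05, 1.72))
  f <- fit_model(s, "delay")
  expect_equal(f$A, 0.05, tolerance = 1e-6)
  expect_equal(f$B, 1.72, tolerance = 1e-6)

  F0 <- c(1, 10, 30)
  s2 <- data.frame(value = F0, mean_W = model_W_setpoint(F0, 0.42, 5.13))
  f2 <- fit_model(s2, "setpoint")
  expect_equal(f2$A, 0.42, tolerance = 1e-6)
  expect_equal(f2$B, 5.13, tolerance = 1e-6)

  v <- c(1, 2.5, 10, 25, 50)
  s3 <- data.frame(value = v, mean_W = model_W_approach(v, 2.0, 27.0))
  f3 <- fit_model(s3, "approach")
  expect_equal(f3$A, 2.0, tolerance = 1e-6)
  expect_equal(f3$B, 27.0, tolerance = 1e-5)

  s4 <- data.frame(value = v, mean_W = model_W_retract(v, 0.21, 5.0))
  f4 <- fit_model(s4, "retract")
  expect_equal(f4$A, 0.21, tolerance = 1e-6)
  expect_equal(f4$B, 5.0, tolerance = 1e-5)
})

test_that("fits are unbiased under condition-mean noise", {
  # noise on condition means as from 50 curves/condition with sd 5 fJ
  tau <- c(1, 15, 30, 45, 60, 120)
  truth <- model_W_delay(tau, 0.05, 1.72)
  Bs <- withr::with_seed(77, {
    vapply(1:200, function(i) {
      s <- data.frame(value = tau,
                      mean_W = truth + rnorm(6, 0, 5 / sqrt(50)))
      fit_model(s, "delay")$B
    }, numeric(1))
  })
  se_of_mean <- sd(Bs) / sqrt(length(Bs))
  expect_lt(abs(mean(Bs) - 1.72), 3 * se_of_mean)
})

test_that("fits are invariant to point order and duplication", {
  tau <- c(1, 15, 30, 45, 60, 120)
  s <- data.frame(value = tau,
                  mean_W = model_W_delay(tau, 0.3, 1.5) +
                    c(0.4, -0.2, 0.1, -0.3, 0.2, -0.1))
  f <- fit_model(s, "delay")
  f_rev <- fit_model(s[6:1, ], "delay")
  expect_equal(f_rev$A, f$A, tolerance = 1e-6)
  expect_equal(f_rev$B, f$B, tolerance = 1e-6)
  f_dup <- fit_model(rbind(s, s), "delay")
  expect_equal(f_dup$A, f$A, tolerance = 1e-6)
  expect_equal(f_dup$B, f$B, tolerance = 1e-6)
})

test_that("underdetermined and degenerate fits error informatively", {
  s <- data.frame(value = c(1, 15), mean_W = c(2, 25))
  expect_error(fit_model(s, "delay"), "at least 3")
  dm <- data.frame(value = c("constant_force", "constant_height"),
                   mean_W = c(10, 5))
  expect_error(fit_model(dm, "delay"), "numeric")
})

test_that("inverse-variance weighting uses group precision and drops degenerates", {
  tau <- c(1, 15, 30, 45, 60)
  s <- data.frame(value = tau, mean_W = model_W_delay(tau, 1, 2),
                  sd_W = c(1, 1, 1, 1, 0), n_curves = c(10, 10, 10, 10, 1))
  expect_warning(f <- fit_model(s, "delay", weighting = "inverse_variance"),
                 "degenerate")
  expect_equal(f$n_points, 4)
  expect_equal(f$B, 2, tolerance = 1e-6)
})

test_that("free-exponent power fit recovers a known exponent", {
  x <- c(1, 10, 30)
  pw <- fit_power_law(x, 5.13 * x^(2 / 3))
  expect_equal(pw$p, 2 / 3, tolerance = 1e-8)
  expect_equal(pw$C, 5.13, tolerance = 1e-6)
})

test_that("bootstrap CI is deterministic, degenerate-safe, and calibrated", {
  expect_equal(unname(bootstrap_condition_ci(rep(3.5, 20), seed = 9)),
               c(3.5, 3.5))
  v <- withr::with_seed(12, rnorm(30, 50, 8))
  ci1 <- bootstrap_condition_ci(v, seed = 4)
  ci2 <- bootstrap_condition_ci(v, seed = 4)
  expect_identical(ci1, ci2)
  expect_warning(ci0 <- bootstrap_condition_ci(c(1, 2)), "degenerate")
  expect_equal(unname(ci0), c(1, 2))

  # coverage of the 95% interval over seeded Gaussian replicates
  hits <- withr::with_seed(13, {
    vapply(1:500, function(i) {
      x <- rnorm(30, 100, 10)
      ci <- bootstrap_condition_ci(x, n_boot = 400, seed = i)
      ci[1] <= 100 && 100 <= ci[2]
    }, logical(1))
  })
  expect_lt(abs(mean(hits) - 0.95), 0.03)
})
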