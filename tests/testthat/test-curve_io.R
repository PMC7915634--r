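test_that("ccfs-txt round trip preserves samples and metadata exactly", {
  withr::with_seed(101, {
    for (rep in 1:5) {
      n <- sample(100:500, 1)
      z <- sort(runif(n, 0, 50))
      z <- z + seq_len(n) * 1e-9  # enforce strict monotonicity
      f <- rnorm(n, 0, 0.5)
      md <- curve_metadata(approach_speed = runif(1, 1, 50),
                           retract_speed = runif(1, 1, 50),
                           delay_time = runif(1, 0, 120),
                           setpoint = runif(1, 1, 30),
                           delay_mode = sample(c("constant_height",
                                                 "constant_force"), 1),
                           spring_constant = runif(1, 0.01, 0.1),
                           source_id = "roundtrip.txt")
      cv <- force_curve(z, f, md, corrected = TRUE)
      path <- withr::local_tempfile(fileext = ".txt")
      write_curve_file(cv, path)
      cv2 <- read_curve_file(path)
      expect_identical(cv2$z, cv$z)
      expect_identical(cv2$force, cv$force)
      for (fld in c("approach_speed", "retract_speed", "delay_time",
                    "setpoint", "delay_mode", "spring_constant"))
        expect_identical(cv2$metadata[[fld]], md[[fld]])
    }
  })
})

test_that("approach segment survives the round trip", {
  z <- seq(0, 10, by = 0.1)
  cv <- force_curve(z, -exp(-z), approach = cbind(z = z, force = exp(-z)),
                    corrected = FALSE)
  path <- withr::local_tempfile(fileext = ".txt")
  write_curve_file(cv, path)
  cv2 <- read_curve_file(path)
  expect_equal(cv2$approach[, "force"], exp(-z))
  expect_false(cv2$corrected)
})

test_that("missing header metadata gets baseline defaults with a warning", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# setpoint_nN: 10", "# segment: retract",
               sprintf("%g\t%g", seq(0, 10, 0.1), rep(0, 101))), path)
  expect_warning(cv <- read_curve_file(path), "defaults applied")
  expect_equal(cv$metadata$setpoint, 10)
  expect_equal(cv$metadata$approach_speed, 10)
  expect_equal(cv$metadata$delay_time, 45)
  expect_equal(cv$metadata$delay_mode, "constant_height")
  expect_match(cv$metadata$extra$defaults_applied, "approachSpeed_um_s")
})

test_that("non-numeric data produces a format error citing the line", {
  path <- withr::local_tempfile(fileext = ".txt")
  lines <- c("# segment: retract", sprintf("%g\t%g", seq(0, 9.9, 0.1), 0))
  lines[42] <- "3.7\toops"
  writeLines(lines, path)
  expect_error(read_curve_file(path), "line 42")
})

test_that("curves with NaN samples are refused", {
  z <- seq(0, 10, by = 0.1)
  expect_error(force_curve(z, c(NaN, rep(0, length(z) - 1))), "finite")
  expect_error(force_curve(z[c(1, 1:100)], rep(0, 101)), "increasing")
  expect_error(force_curve(1:10, 1:10), "64 samples")
})

test_that("bending correction is the identity at zero force and shifts by F/k", {
  z <- seq(0, 10, by = 0.1)
  expect_identical(correct_bending(z, rep(0, length(z)), 0.03), z)
  sep <- correct_bending(z, rep(1, length(z)), 0.03)
  expect_equal(sep - z, rep(-1 / 0.03 * 1e-3, length(z)), tolerance = 1e-12)
  expect_equal(abs(sep[1] - z[1]), 0.03333, tolerance = 1e-3)
  expect_error(correct_bending(z, rep(0, length(z)), -1), "positive")
})

test_that("bending correction reduces the apparent slope of a stiff contact ramp", {
  # force rising linearly with piezo position in contact
  z <- seq(0, 1, by = 0.001)
  s <- 50  # nN per um of piezo travel
  f <- s * z
  sep <- correct_bending(z, f, 0.1)
  # separation per unit force grows, so force per unit separation shrinks
  slope_corrected <- coef(lm(f ~ sep))[2]
  expect_lt(abs(coef(lm(f ~ z))[2] - s), 1e-9)
  expect_gt(slope_corrected, s)  # steeper vs separation: ramp compressed
})

test_that("scan_folder loads valid files and skips corrupt ones", {
  dir <- withr::local_tempdir()
  z <- seq(0, 10, by = 0.1)
  for (i in 1:4)
    write_curve_file(force_curve(z, -exp(-z) + i * 0,
                                 curve_metadata(source_id = paste0(i))),
                     file.path(dir, sprintf("c%d.txt", i)))
  writeLines("not a curve at all", file.path(dir, "corrupt.txt"))
  expect_warning(curves <- scan_folder(dir), "skipping")
  expect_length(curves, 4)
  expect_equal(attr(curves, "skipped"), 1L)
  expect_equal(attr(curves, "skipped_files"), "corrupt.txt")

  empty <- withr::local_tempdir()
  expect_warning(none <- scan_folder(empty), "no curve files")
  expect_length(none, 0)
})

test_that("results CSV has the exact schema, sorted rows, and >= 9 digits", {
  cfg <- test_simconfig()
  sims <- lapply(c(5L, 3L), function(n)
    synthesize_retract_curve(cfg, n, seed = 400 + n))
  res <- lapply(sims, function(s) analyze_curve(s$curve))
  res[[1]]$metadata$source_id <- "zzz.txt"
  res[[2]]$metadata$source_id <- "aaa.txt"
  path <- withr::local_tempfile(fileext = ".csv")
  export_results_csv(res, path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  expect_identical(names(df),
                   c("source_id", "approach_speed_um_s", "retract_speed_um_s",
                     "delay_time_s", "setpoint_nN", "delay_mode", "work_fJ",
                     "z_det_um", "f_det_nN", "n_events", "max_adhesion_nN"))
  expect_identical(df$source_id, c("aaa.txt", "zzz.txt"))
  expect_equal(df$work_fJ[2], res[[1]]$work, tolerance = 1e-9)

  # empty input: header-only CSV
  hdr_only <- withr::local_tempfile(fileext = ".csv")
  export_results_csv(list(), hdr_only)
  expect_equal(nrow(read.csv(hdr_only)), 0)
})
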