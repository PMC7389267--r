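test_that("written curves round-trip through the TSV dialect", {
  cv <- synthesize_curve(events = data.frame(distance_nm = 50, force_pN = 80),
                         seed = 11, curve_id = "rt")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_curve(cv, path)
  cv2 <- read_curve(path)

  expect_s3_class(cv2, "force_curve")
  expect_equal(nrow(cv2), nrow(cv))
  expect_equal(cv2$force_pN, cv$force_pN, tolerance = 1e-9)
  expect_equal(cv2$height_nm, cv$height_nm, tolerance = 1e-9)
  expect_equal(cv2$time_s, cv$time_s, tolerance = 1e-9)
  expect_identical(cv2$segment, cv$segment)
  m <- curve_meta(cv2)
  expect_equal(m$spring_constant_pN_per_nm, 10)
  expect_equal(m$retract_speed_um_per_s, 1)
  expect_equal(m$temperature_K, 293.15)
  expect_identical(m$curve_id, "rt")
})

test_that("random curves round-trip (property)", {
  for (i in 1:20) {
    cv <- synthesize_curve(
      events = if (i %% 2 == 0) data.frame(distance_nm = 20 + 10 * i,
                                           force_pN = 30 + 5 * i) else NULL,
      noise_sigma = i %% 4, retract_speed = 1 + (i %% 5),
      spring_constant = 5 + i, seed = 100 + i,
      curve_id = paste0("prop", i))
    path <- withr::local_tempfile(fileext = ".tsv")
    write_curve(cv, path)
    cv2 <- read_curve(path)
    expect_equal(cv2$force_pN, cv$force_pN, tolerance = 1e-9)
    expect_equal(curve_meta(cv2)$spring_constant_pN_per_nm, 5 + i)
  }
})

test_that("missing mandatory header keys are reported by name", {
  cv <- synthesize_curve(seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_curve(cv, path)
  lines <- readLines(path)
  writeLines(lines[!grepl("spring_constant_pN_per_nm", lines)], path)
  expect_error(read_curve(path), "spring_constant_pN_per_nm")
})

test_that("curve validation rejects bad input", {
  s <- data.frame(segment = rep("retract", 20), time_s = c(2, 1, 3:20),
                  height_nm = 1:20, force_pN = 0)
  expect_error(force_curve(s, 10, 1), "strictly increasing")
  s$time_s <- 1:20
  expect_error(force_curve(s, -1, 1), "spring_constant")
  expect_error(force_curve(s, 10, 0), "retract_speed")
  expect_warning(force_curve(s, 0.5, 1), "outside the expected range")
  # a curve without retract samples cannot be written
  s_app <- transform(s, segment = "approach")
  cv <- force_curve(s_app, 10, 1)
  expect_error(write_curve(cv, withr::local_tempfile()), "no retract")
})

test_that("baseline correction removes tilt and offset", {
  cv <- flat_curve(noise_sigma = 5, seed = 21, tilt = 0.05, offset = 20)
  bc <- correct_baseline(cv)
  retract <- bc[bc$segment == "retract", ]
  far <- tail(retract[order(retract$time_s), ], 300)
  expect_lt(abs(mean(far$force_pN)), 0.5)
  expect_true(curve_meta(bc)$baseline_corrected)
})

test_that("baseline correction is idempotent and preserves noise", {
  cv <- flat_curve(noise_sigma = 5, seed = 22)
  b1 <- correct_baseline(cv)
  b2 <- correct_baseline(b1)
  expect_equal(b2$force_pN, b1$force_pN, tolerance = 1e-6)
  retract <- b1[b1$segment == "retract", ]
  expect_equal(sd(tail(retract$force_pN, 300)), 5, tolerance = 0.6)
})

test_that("baseline window auto-shrinks around far-field excursions", {
  cv <- flat_curve(noise_sigma = 3, seed = 23)
  # plant a deep excursion inside the far-field tail window
  retract_idx <- which(cv$segment == "retract")
  tail_idx <- tail(retract_idx, 100)[40:50]
  cv$force_pN[tail_idx] <- cv$force_pN[tail_idx] - 80
  expect_warning(bc <- correct_baseline(cv), "auto-shrunk")
  retract <- bc[bc$segment == "retract", ]
  clean_far <- tail(retract$force_pN, 300)
  clean_far <- clean_far[abs(clean_far) < 30]
  expect_lt(abs(mean(clean_far)), 1)
})

test_that("contact point is recovered and translation-equivariant", {
  cv <- flat_curve(noise_sigma = 5, seed = 24)
  bc <- correct_baseline(cv)
  h0 <- find_contact_point(bc)
  expect_lt(abs(h0 - 0), 2)

  shifted <- bc
  shifted$height_nm <- shifted$height_nm + 100
  h1 <- find_contact_point(shifted)
  expect_equal(h1 - h0, 100, tolerance = 1e-6)
})

test_that("noise-only approach raises a no-contact error", {
  cv <- flat_curve(noise_sigma = 5, seed = 25)
  bc <- correct_baseline(cv)
  flat <- bc[bc$segment == "retract" & bc$height_nm > 0, ]
  # build an approach with no contact ramp at all (pure noise)
  noise_app <- flat
  noise_app$segment <- "approach"
  both <- rbind(as.data.frame(noise_app), as.data.frame(flat))
  cv2 <- force_curve(both, 10, 1)
  cv2 <- correct_baseline(cv2)
  expect_error(find_contact_point(cv2), "no contact")
})

test_that("grid index round-trips", {
  m <- synthesize_map(n_rows = 4, n_cols = 4, background_p = 0.5, seed = 9)
  grid <- m$grid
  grid$curve_path <- paste0(grid$curve_id, ".tsv")
  path <- withr::local_tempfile(fileext = ".csv")
  write_grid_index(grid, path)
  g2 <- read_grid_index(path)
  expect_equal(attr(g2, "n_rows"), 4L)
  expect_identical(g2$curve_id, grid$curve_id)
  # duplicate pixels are rejected
  expect_error(force_volume_grid(rbind(grid[1, ], grid[1, ]), 4, 4),
               "at most one")
})
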