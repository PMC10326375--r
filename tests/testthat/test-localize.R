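test_that("blank frames produce no localizations", {
  frames <- replicate(3, matrix(rnorm(48 * 48, 100, 5), 48, 48), simplify = FALSE)
  set.seed(1)
  locs <- localize_stack(frames, threshold_k = 6)
  expect_identical(nrow(locs), 0L)
})

test_that("a noiseless Gaussian spot is localized to sub-pixel accuracy", {
  f <- matrix(10, 64, 64)
  f <- aggquant:::render_gaussians(f, 20.3, 40.7, 800, 1.1)
  locs <- localize_stack(list(f), threshold_k = 3, pixel_nm = 100)
  expect_identical(nrow(locs), 1L)
  expect_lt(abs(locs$x_nm / 100 - 20.3), 0.1)
  expect_lt(abs(locs$y_nm / 100 - 40.7), 0.1)
  expect_equal(locs$sigma_nm / 100, 1.1, tolerance = 0.05)
})

test_that("localization count tracks the simulated ON-event count", {
  p <- sr_sim_params(canvas_size = 320L, camera_size = 64L, scale_factor = 5L,
                     n_frames = 150L, n_structures = 4L,
                     length_distribution = c(60, 10), n_fiducials = 1L,
                     seed = 13)
  st <- simulate_blinking_stack(simulate_structures(p), p)
  locs <- localize_stack(st, threshold_k = 5, pixel_nm = 100)
  # spot amplitudes are N(300, 60), so the dimmest tail of true events sits
  # below the 5-sigma candidate threshold; recall of ~3/4 is expected
  expected <- nrow(st$on_events) + p$n_frames  # structure events + fiducial
  expect_gt(nrow(locs), 0.7 * expected)
  expect_lt(nrow(locs), 1.15 * expected)
})

test_that("fiducial tracks are found by persistence and drift is recovered", {
  p <- sr_sim_params(canvas_size = 320L, camera_size = 64L, scale_factor = 5L,
                     n_frames = 200L, n_structures = 3L,
                     length_distribution = c(50, 10), n_fiducials = 2L,
                     drift_per_frame = 0.05, seed = 14)
  st <- simulate_blinking_stack(simulate_structures(p), p)
  locs <- localize_stack(st, threshold_k = 5, pixel_nm = 100)
  fid <- find_fiducials(locs, n_frames = p$n_frames)
  expect_identical(length(unique(fid$track)), 2L)
  dc <- correct_drift(locs, n_frames = p$n_frames)
  est <- attr(dc, "drift")
  rms <- sqrt(mean((est$dx_nm / 100 - st$drift$dx_px)^2 +
                     (est$dy_nm / 100 - st$drift$dy_px)^2))
  expect_lt(rms, 0.5)
  # fiducial localizations are removed, structure localizations kept
  expect_lt(nrow(dc), nrow(locs))
})

test_that("drift correction is exact for noise-free shared-drift localizations", {
  set.seed(71)
  n_frames <- 50L
  drift <- cumsum(sample(c(-10, 0, 10), n_frames, replace = TRUE))
  drift <- drift - drift[1]
  fid <- tibble::tibble(frame = 0:(n_frames - 1),
                        x_nm = 3000 + drift, y_nm = 2000,
                        intensity = 10, sigma_nm = 100)
  # sparse structure localizations sharing the same drift (blinking sites
  # must not themselves look like fiducials)
  sparse <- seq(0L, n_frames - 1L, by = 3L)
  pts <- tibble::tibble(frame = sparse,
                        x_nm = 1000 + drift[sparse + 1L], y_nm = 800,
                        intensity = 1, sigma_nm = 100)
  locs <- dplyr::mutate(dplyr::bind_rows(fid, pts),
                        id = dplyr::row_number(), .before = 1)
  class(locs) <- c("agg_localizations", class(locs))
  attr(locs, "pixel_nm") <- 100
  dc <- correct_drift(locs, n_frames = n_frames, smooth_window = 1L)
  expect_identical(nrow(dc), length(sparse))  # fiducial rows removed
  expect_equal(dc$x_nm, rep(1000, length(sparse)), tolerance = 1e-9)
  expect_equal(dc$y_nm, rep(800, length(sparse)), tolerance = 1e-9)
})

test_that("two fiducials with identical motion correct like one", {
  n_frames <- 30L
  drift <- cumsum(rep(3, n_frames)); drift <- drift - drift[1]
  mk_fid <- function(x0) tibble::tibble(frame = 0:(n_frames - 1),
                                        x_nm = x0 + drift, y_nm = 500,
                                        intensity = 10, sigma_nm = 100)
  sparse <- seq(0L, n_frames - 1L, by = 2L)
  pts <- tibble::tibble(frame = sparse, x_nm = 100 + drift[sparse + 1L],
                        y_nm = 900, intensity = 1, sigma_nm = 100)
  one <- dplyr::mutate(dplyr::bind_rows(mk_fid(4000), pts),
                       id = dplyr::row_number(), .before = 1)
  two <- dplyr::mutate(dplyr::bind_rows(mk_fid(4000), mk_fid(7000), pts),
                       id = dplyr::row_number(), .before = 1)
  for (d in list(one, two)) class(d) <- c("agg_localizations", class(d))
  c1 <- correct_drift(one, n_frames = n_frames, smooth_window = 1L)
  c2 <- correct_drift(two, n_frames = n_frames, smooth_window = 1L)
  expect_equal(c1$x_nm, c2$x_nm, tolerance = 1e-9)
})

test_that("no fiducial leaves localizations unchanged with a warning", {
  pts <- tibble::tibble(id = 1:4, frame = c(0L, 5L, 9L, 12L),
                        x_nm = c(1, 2, 3, 4) * 100, y_nm = 100,
                        intensity = 1, sigma_nm = 100)
  class(pts) <- c("agg_localizations", class(pts))
  expect_warning(dc <- correct_drift(pts, n_frames = 20L), "skipped")
  expect_equal(dc$x_nm, pts$x_nm)
})

test_that("localization tables round-trip through the native CSV dialect", {
  locs <- tibble::tibble(id = 1:3, frame = c(0L, 0L, 2L),
                         x_nm = c(100.5, 220.25, 330),
                         y_nm = c(50, 60, 70.125),
                         intensity = c(1000, 2000, 1500),
                         sigma_nm = c(110, 120, 115))
  path <- withr::local_tempfile(fileext = ".csv")
  write_localizations(locs, path)
  back <- read_localizations(path, dialect = "native")
  expect_equal(back$x_nm, locs$x_nm)
  expect_equal(back$frame, locs$frame)
  expect_equal(back$intensity, locs$intensity)
})

test_that("ThunderSTORM and GDSC dialects are parsed into nm fields", {
  ts <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    '"id","frame","x [nm]","y [nm]","sigma [nm]","intensity [photon]"',
    "1,1,1050.2,2300.8,150.1,850.5",
    "2,3,980.4,2210.0,140.9,700.25"
  ), ts)
  locs <- read_localizations(ts)
  expect_equal(locs$x_nm, c(1050.2, 980.4))
  expect_equal(locs$frame, c(1L, 3L))
  expect_equal(locs$intensity, c(850.5, 700.25))

  gd <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Frame,X,Y,Signal", "2,10.5,20.25,900"), gd)
  locs2 <- read_localizations(gd, pixel_nm = 100)
  expect_equal(locs2$x_nm, 1050)
  expect_equal(locs2$y_nm, 2025)

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("frame,x_nm,y_nm", empty)
  expect_identical(nrow(read_localizations(empty)), 0L)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,x_nm", "1,2"), bad)
  expect_error(read_localizations(bad, dialect = "native"), "y_nm")
})
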