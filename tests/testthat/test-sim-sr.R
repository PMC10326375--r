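# small canvas/camera geometry keeps these fast; physics parameters stay at
# their defaults
small_params <- function(..., n_frames = 60L) {
  sr_sim_params(canvas_size = 320L, camera_size = 64L, scale_factor = 5L,
                n_frames = n_frames, ...)
}

test_that("geometry invariants are enforced", {
  expect_error(sr_sim_params(canvas_size = 2400L), "canvas_size")
  expect_error(sr_sim_params(on_probability = 0), "on_probability")
  expect_error(sr_sim_params(fiducial_intensity_factor = 0),
               "fiducial_intensity_factor")
})

test_that("line structures record the exact end-to-end length in nm", {
  p <- small_params(structure_type = "line", n_structures = 1L,
                    length_distribution = c(100, 1e-9), seed = 2)
  tr <- simulate_structures(p)
  # 100 canvas px at 20 nm per canvas px
  expect_equal(tr$structures$true_length_nm, 2000, tolerance = 1e-6)
  expect_equal(tr$super_res_pixel_nm, 20)
  # the stroke is one pixel wide and fully inside the canvas
  pix <- tr$occupied[[1]]
  expect_true(all(pix >= 0 & pix <= 319))
})

test_that("zero structures give an empty occupied set", {
  tr <- simulate_structures(small_params(n_structures = 0L, seed = 1))
  expect_identical(nrow(tr$structures), 0L)
  expect_length(tr$occupied, 0)
})

test_that("sampled line lengths follow the configured distribution", {
  p <- sr_sim_params(n_structures = 50L, length_distribution = c(100, 20),
                     seed = 31)
  tr <- simulate_structures(p)
  mean_px <- mean(tr$structures$true_length_nm) / 20
  expect_lt(abs(mean_px - 100), 3 * 20 / sqrt(50))
})

test_that("dot structures report their diameter as true length", {
  p <- small_params(structure_type = "dot", n_structures = 20L,
                    dot_diameter_distribution = c(3, 0.3), seed = 4)
  tr <- simulate_structures(p)
  expect_equal(mean(tr$structures$true_length_nm), 3 * 20, tolerance = 6)
  expect_true(all(tr$structures$n_occupied_px >= 1))
})

test_that("the stack has the configured number of frames and sparse blinking", {
  p <- small_params(n_structures = 3L, length_distribution = c(40, 5),
                    n_fiducials = 1L, seed = 6)
  st <- simulate_blinking_stack(simulate_structures(p), p)
  expect_identical(dim(st$frames)[3], 60L)
  expect_identical(nrow(st$drift), 60L)
  # ON events per site ~ Binomial(n_frames, p)
  n_sites <- sum(st$truth$structures$n_occupied_px)
  expected <- n_sites * p$n_frames * p$on_probability
  expect_lt(abs(nrow(st$on_events) - expected), 4 * sqrt(expected) + 2)
})

test_that("without structures and fiducials every frame is pure background", {
  p <- small_params(n_structures = 0L, n_fiducials = 0L, seed = 7)
  st <- simulate_blinking_stack(simulate_structures(p), p)
  expect_equal(mean(st$frames), 200, tolerance = 1)
  expect_equal(sd(st$frames), 20, tolerance = 1)
})

test_that("fiducials render every frame at five times the mean spot peak", {
  p <- small_params(n_structures = 4L, length_distribution = c(60, 5),
                    n_fiducials = 1L, drift_per_frame = 0,
                    n_frames = 150L, seed = 8)
  st <- simulate_blinking_stack(simulate_structures(p), p)
  fx <- round(st$fiducials$x_px[1]); fy <- round(st$fiducials$y_px[1])
  fid_peak <- mean(apply(st$frames[(fy - 1):(fy + 3), (fx - 1):(fx + 3), ],
                         3, max)) - p$background[1]
  # spot peaks measured the same way around each ON event
  ev <- st$on_events
  spot_peaks <- vapply(seq_len(nrow(ev)), function(i) {
    r <- round(ev$y_px[i]) + 1; c <- round(ev$x_px[i]) + 1
    max(st$frames[max(1, r - 2):min(64, r + 2),
                  max(1, c - 2):min(64, c + 2), ev$frame[i] + 1]) - p$background[1]
  }, numeric(1))
  expect_equal(fid_peak / mean(spot_peaks), 5, tolerance = 0.25)
  # fiducial visible in every frame
  mins <- apply(st$frames[(fy):(fy + 2), (fx):(fx + 2), ], 3, max)
  expect_true(all(mins > p$background[1] + 5 * p$background[2]))
})

test_that("with zero drift the drift trace is identically zero", {
  p <- small_params(n_structures = 2L, length_distribution = c(40, 5),
                    drift_per_frame = 0, seed = 9)
  st <- simulate_blinking_stack(simulate_structures(p), p)
  expect_true(all(st$drift$dx_px == 0 & st$drift$dy_px == 0))
})

test_that("the drift trace is a cumulative one-axis random walk from zero", {
  p <- small_params(n_structures = 1L, length_distribution = c(40, 5),
                    drift_per_frame = 0.05, seed = 10)
  st <- simulate_blinking_stack(simulate_structures(p), p)
  d <- st$drift
  expect_equal(d$dx_px[1], 0); expect_equal(d$dy_px[1], 0)
  steps <- cbind(diff(d$dx_px), diff(d$dy_px))
  # one axis moves per frame, by 0 or +/- the step size
  expect_true(all(rowSums(abs(steps) > 1e-9) <= 1))
  expect_true(all(abs(steps) < 1e-9 | abs(abs(steps) - 0.05) < 1e-9))
})

test_that("simulation output writes stack, truth and drift files", {
  dir <- withr::local_tempdir()
  p <- small_params(n_structures = 2L, length_distribution = c(40, 5),
                    n_frames = 5L, seed = 12)
  st <- simulate_blinking_stack(simulate_structures(p), p)
  paths <- write_sr_simulation(st, dir)
  expect_true(all(file.exists(paths$path)))
  back <- read_image_stack(file.path(dir, "sr_stack.tif"))
  expect_length(back, 5L)
})
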