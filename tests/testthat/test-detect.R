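test_that("top-hat flattens constant frames and smooth gradients but keeps spots", {
  expect_true(all(tophat_background_suppress(matrix(7, 32, 32), 5) == 0))
  # isolated dot on flat offset survives within 1% of its height
  f <- fixture_dot_frame(64, rbind(c(32, 32)), amplitude = 1000, sigma = 2,
                         offset = 500)
  th <- tophat_background_suppress(f, 7)
  expect_gt(max(th), 0.99 * 1000)
  # wide smooth gradient is suppressed far below its range
  g <- outer(seq(0, 500, length.out = 64), seq(0, 500, length.out = 64), "+")
  tg <- tophat_background_suppress(g, 7)
  expect_lt(max(tg), 0.2 * diff(range(g)))
  expect_error(tophat_background_suppress(f, -1), "radius")
})

test_that("detection kernels are normalized as band-pass and low-pass filters", {
  pr <- detection_params(kernel = "ricker")
  pg <- detection_params(kernel = "gaussian")
  kr <- aggquant:::make_kernel("ricker", pr$kernel_width)
  kg <- aggquant:::make_kernel("gaussian", pg$kernel_width)
  expect_equal(sum(kr), 0, tolerance = 1e-12)
  expect_equal(sum(kg), 1, tolerance = 1e-12)
  # delta impulse reproduces the kernel
  f <- matrix(0, 33, 33); f[17, 17] <- 1
  conv <- kernel_convolve(f, pr)
  ctr <- conv[(17 - 6):(17 + 6), (17 - 6):(17 + 6)]
  expect_equal(ctr, kr[, ], tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("white noise through the zero-sum Ricker kernel has near-zero mean", {
  set.seed(42)
  f <- matrix(rnorm(64 * 64, 100, 10), 64, 64)
  conv <- kernel_convolve(f, detection_params(kernel = "ricker"))
  expect_lt(abs(mean(conv)), 0.5)
})

test_that("matched filtering peaks at the dot center and matches direct convolution", {
  f <- fixture_dot_frame(32, rbind(c(15, 15)), amplitude = 100, sigma = 1.5)
  p <- detection_params(kernel = "ricker", kernel_width = 1.5)
  conv <- kernel_convolve(f, p)
  expect_equal(which.max(conv), which(row(f) == 16 & col(f) == 16))
  oracle <- brute_convolve(f, aggquant:::make_kernel("ricker", 1.5))
  expect_equal(conv, oracle, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("histogram thresholding keeps only strong outliers and is monotone in k", {
  expect_false(any(threshold_mask(matrix(5, 16, 16), 2)))
  set.seed(1)
  f <- matrix(rnorm(64 * 64), 64, 64)
  f[20, 20] <- mean(f) + 10 * sd(f)
  m <- threshold_mask(f, 2)
  expect_true(m[20, 20])
  m4 <- threshold_mask(f, 4)
  expect_true(all(which(m4) %in% which(m)))
})

test_that("morphological cleaning removes specks, keeps blocks, and has an identity", {
  m <- matrix(FALSE, 32, 32)
  m[5, 5] <- TRUE              # isolated pixel
  m[10:19, 10:19] <- TRUE      # solid block
  cleaned <- morphological_clean(m, 1)
  expect_false(cleaned[5, 5])
  expect_true(all(cleaned[10:19, 10:19]))
  expect_identical(morphological_clean(m, 0), m)
})

test_that("component labeling matches a brute-force flood fill", {
  for (seed in 1:4) {
    set.seed(seed)
    mask <- matrix(runif(48 * 48) < 0.25, 48, 48)
    lab <- label_components(mask)
    oracle <- brute_label_components(mask)
    expect_identical(canonical_labels(as.vector(lab)),
                     canonical_labels(as.vector(oracle)))
    # label conservation: footprints tile the mask exactly
    expect_identical(sum(lab > 0), sum(mask))
  }
})

test_that("a single centered dot is detected once with sub-pixel centroid accuracy", {
  p <- dl_sim_params(n_dots = 1, peak_sd = 0, seed = 2)
  s <- simulate_dl(p, centers = rbind(c(256, 256)))
  parts <- detect_spots(s$noisy, detection_params())
  expect_identical(attr(parts, "n_particles"), 1L)
  expect_lt(abs(parts$x_px - 256), 1)
  expect_lt(abs(parts$y_px - 256), 1)
  expect_gt(parts$integrated_intensity, 0)
})

test_that("a pure-noise field yields no detections", {
  s <- simulate_dl(dl_sim_params(n_dots = 0, seed = 8))
  expect_identical(attr(detect_spots(s$noisy), "n_particles"), 0L)
})

test_that("edge margins exclude particles near the border in both modes", {
  f <- fixture_dot_frame(100, rbind(c(3, 50), c(50, 50)), amplitude = 3000,
                         sigma = 2, offset = 0)
  noisy <- f + matrix(rnorm(1e4, 100, 5), 100, 100)
  fixed <- detect_spots(noisy, detection_params(kernel = "ricker", edge_margin = 5))
  expect_identical(attr(fixed, "n_particles"), 1L)
  expect_true(all(fixed$x_px >= 5 & fixed$x_px <= 94))
  frac <- detect_spots(noisy, detection_params(kernel = "gaussian"))
  expect_true(all(frac$x_px >= attr(frac, "edge_margin_px")))
})

test_that("counting accuracy follows the symmetric formula", {
  expect_equal(counting_accuracy(300, 300), 100)
  expect_equal(counting_accuracy(270, 300), 90)
  expect_equal(counting_accuracy(330, 300), 90)
  expect_lt(counting_accuracy(700, 300), 0)
  expect_error(counting_accuracy(10, 0), "n_simulated")
})

test_that("counting accuracy does not degrade from very low to high snr", {
  acc <- function(snr) {
    s <- simulate_dl(dl_sim_params(n_dots = 150, snr = snr, seed = 21))
    counting_accuracy(attr(detect_spots(s$noisy), "n_particles"),
                      attr(s$truth, "true_count"))
  }
  expect_gte(acc(4), acc(0.25))
})
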