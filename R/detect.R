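#' Spot-detection parameters
#'
#' Two presets are idiomatic: the Ricker-wavelet detector (`kernel =
#' "ricker"`, fixed 5 px edge margin) and the Gaussian-kernel variant
#' (`kernel = "gaussian"`, fractional 2% edge margin), mirroring the two
#' families of spot counters used for single-molecule pull-down images.
#'
#' @param kernel `"ricker"` (zero-sum Mexican-hat band-pass) or `"gaussian"`.
#' @param kernel_width Kernel sigma in px; defaults 1.5 (ricker) / 2
#'   (gaussian).
#' @param threshold_k Threshold multiplier `k`: pixels above
#'   `mean + k * sd` of the convolved image are kept. Default 2.
#' @param erosion_size Half-width of the square structuring element used for
#'   the morphological opening that removes small bright specks; 0 disables.
#' @param edge_margin_mode `"fixed_pixels"` (margin of `edge_margin` px) or
#'   `"fraction"` (margin of `edge_fraction` of each side).
#' @param edge_margin Margin in px for `"fixed_pixels"` mode (default 5).
#' @param edge_fraction Fractional margin per side for `"fraction"` mode
#'   (default 0.02).
#' @param tophat_radius Disc radius of the top-hat background suppression
#'   (px); must exceed the largest expected spot radius.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(kernel = c("ricker", "gaussian"),
                             kernel_width = NULL,
                             threshold_k = 2,
                             erosion_size = 1L,
                             edge_margin_mode = NULL,
                             edge_margin = 5L,
                             edge_fraction = 0.02,
                             tophat_radius = 7L) {
  kernel <- match.arg(kernel)
  if (is.null(kernel_width)) {
    kernel_width <- if (kernel == "ricker") 1.5 else 2
  }
  if (is.null(edge_margin_mode)) {
    edge_margin_mode <- if (kernel == "ricker") "fixed_pixels" else "fraction"
  }
  edge_margin_mode <- match.arg(edge_margin_mode, c("fixed_pixels", "fraction"))
  check_number(kernel_width, "kernel_width", min = 1e-6)
  check_number(threshold_k, "threshold_k", min = 1e-12)
  check_number(erosion_size, "erosion_size", min = 0, integer = TRUE)
  check_number(edge_margin, "edge_margin", min = 0, integer = TRUE)
  check_number(edge_fraction, "edge_fraction", min = 0, max = 0.5)
  check_number(tophat_radius, "tophat_radius", min = 1, integer = TRUE)
  structure(
    list(
      kernel = kernel, kernel_width = kernel_width,
      threshold_k = threshold_k, erosion_size = as.integer(erosion_size),
      edge_margin_mode = edge_margin_mode,
      edge_margin = as.integer(edge_margin), edge_fraction = edge_fraction,
      tophat_radius = as.integer(tophat_radius)
    ),
    class = "detection_params"
  )
}

#' White top-hat background suppression
#'
#' Subtracts the morphological opening with a disc of the given radius from
#' the image, flattening slowly varying background while preserving features
#' smaller than the disc. Output is non-negative.
#'
#' @param frame Numeric matrix.
#' @param radius Disc radius in px; choose larger than the largest expected
#'   spot radius.
#' @return Filtered matrix of the same shape.
#' @export
tophat_background_suppress <- function(frame, radius = 7) {
  check_frame(frame)
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0) {
    abort("`radius` must be a single positive number.")
  }
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  # work on a unit scale: EBImage grayscale morphology expects [0, 1]
  lo <- min(frame); hi <- max(frame)
  if (hi == lo) return(matrix(0, nrow(frame), ncol(frame)))
  unit <- (frame - lo) / (hi - lo)
  opened <- EBImage::opening(unit, brush)
  out <- (unit - opened) * (hi - lo)
  out[out < 0] <- 0
  out
}

# build the 2-D detection kernel; Ricker sums to 0, Gaussian to 1
make_kernel <- function(kernel, sigma) {
  r <- ceiling(4 * sigma)
  ax <- -r:r
  d2 <- outer(ax^2, ax^2, "+")
  if (kernel == "gaussian") {
    k <- exp(-d2 / (2 * sigma^2))
    k / sum(k)
  } else {
    k <- (1 - d2 / (2 * sigma^2)) * exp(-d2 / (2 * sigma^2))
    k - mean(k)  # enforce exact zero sum on the truncated support
  }
}

#' Convolve a frame with the detection kernel
#'
#' Linear convolution with a zero-lag-normalized kernel: the Ricker wavelet
#' integrates to zero (band-pass matched filter for spot-sized features), the
#' Gaussian to one (low-pass smoothing).
#'
#' @param frame Numeric matrix (typically top-hat filtered).
#' @param params A [detection_params()] object.
#' @return Convolved matrix, same shape.
#' @export
kernel_convolve <- function(frame, params = detection_params()) {
  check_frame(frame)
  stopifnot(inherits(params, "detection_params"))
  k <- make_kernel(params$kernel, params$kernel_width)
  EBImage::filter2(frame, k, boundary = "replicate")
}

#' Histogram threshold of a convolved frame
#'
#' Pools every pixel of the convolved image into one histogram and keeps
#' pixels strictly above `mean + threshold_k * sd`. A constant frame yields
#' an empty mask.
#'
#' @param conv_frame Numeric matrix.
#' @param threshold_k Positive multiplier of the pixel-histogram SD.
#' @return Logical matrix mask.
#' @export
threshold_mask <- function(conv_frame, threshold_k = 2) {
  check_frame(conv_frame)
  check_number(threshold_k, "threshold_k", min = 1e-12)
  if (!all(is.finite(conv_frame))) abort("`conv_frame` must be finite.")
  mu <- mean(conv_frame)
  s <- sd(conv_frame)
  conv_frame > (mu + threshold_k * s)
}

#' Morphological cleaning of a detection mask
#'
#' Erosion followed by dilation (opening) with a square structuring element
#' of side `2 * erosion_size + 1`, removing isolated bright specks smaller
#' than the element. `erosion_size = 0` is the identity.
#'
#' @param mask Logical matrix.
#' @param erosion_size Non-negative integer half-width.
#' @return Logical matrix.
#' @export
morphological_clean <- function(mask, erosion_size = 1L) {
  if (!is.matrix(mask)) abort("`mask` must be a matrix.")
  check_number(erosion_size, "erosion_size", min = 0, integer = TRUE)
  mask <- mask != 0
  if (erosion_size == 0L) return(mask)
  brush <- matrix(1L, 2L * erosion_size + 1L, 2L * erosion_size + 1L)
  storage.mode(mask) <- "numeric"
  out <- EBImage::opening(mask, brush)
  out > 0.5
}

#' Label 8-connected components of a mask
#'
#' @param mask Logical matrix.
#' @return Integer matrix of labels (0 = background), numbered in row-major
#'   discovery order.
#' @export
label_components <- function(mask) {
  if (!is.matrix(mask)) abort("`mask` must be a matrix.")
  cpp_label_components(mask != 0)
}

#' Detect diffraction-limited spots in a frame
#'
#' Full counting pipeline: white top-hat background suppression, matched
#' filtering with a Ricker or Gaussian kernel, pixel-histogram thresholding
#' at `mean + k * sd`, morphological opening, 8-connected labeling, and edge
#' exclusion. Integrated intensity per particle is the sum of raw counts over
#' its footprint minus a local background (median of an annulus around the
#' particle).
#'
#' Multi-frame stacks are averaged to a single frame before detection.
#'
#' @param frame Numeric matrix, or a stack (list / 3-D array) that will be
#'   averaged.
#' @param params A [detection_params()] object.
#' @return A tibble of class `agg_particles`, one row per detected particle:
#'   `particle`, `x_px`, `y_px` (0-based centroid), `area_px`,
#'   `integrated_intensity`. The spot count and the applied edge margin are
#'   stored as attributes `n_particles` and `edge_margin_px`.
#' @export
detect_spots <- function(frame, params = detection_params()) {
  if (!is.matrix(frame)) frame <- average_stack(frame)
  check_frame(frame)
  stopifnot(inherits(params, "detection_params"))

  filtered <- tophat_background_suppress(frame, params$tophat_radius)
  conv <- kernel_convolve(filtered, params)
  mask <- threshold_mask(conv, params$threshold_k)
  mask <- morphological_clean(mask, params$erosion_size)
  labels <- label_components(mask)

  margin <- if (params$edge_margin_mode == "fixed_pixels") {
    params$edge_margin
  } else {
    ceiling(params$edge_fraction * nrow(frame))
  }

  n_lab <- max(labels)
  rows <- vector("list", n_lab)
  keep <- 0L
  nr <- nrow(frame); nc <- ncol(frame)
  if (n_lab > 0) {
    idx_all <- which(labels > 0)
    lab_vec <- labels[idx_all]
    ord <- order(lab_vec)
    idx_all <- idx_all[ord]; lab_vec <- lab_vec[ord]
    splits <- split(idx_all, lab_vec)
    for (lab in seq_len(n_lab)) {
      idx <- splits[[as.character(lab)]]
      rr <- ((idx - 1L) %% nr)        # 0-based row (y)
      cc <- ((idx - 1L) %/% nr)       # 0-based col (x)
      w <- filtered[idx]
      if (sum(w) <= 0) w <- rep(1, length(idx))
      cx <- sum(cc * w) / sum(w)
      cy <- sum(rr * w) / sum(w)
      if (cx < margin || cx > nc - 1 - margin ||
          cy < margin || cy > nr - 1 - margin) next
      # local background: median of an annulus around the particle
      fp_radius <- sqrt(length(idx) / pi)
      bg <- annulus_median(frame, cx, cy, fp_radius + 2, 3)
      keep <- keep + 1L
      rows[[keep]] <- tibble(
        particle = keep, x_px = cx, y_px = cy,
        area_px = length(idx),
        integrated_intensity = sum(frame[idx] - bg)
      )
    }
  }
  out <- if (keep) dplyr::bind_rows(rows[seq_len(keep)]) else
    tibble(particle = integer(), x_px = numeric(), y_px = numeric(),
           area_px = integer(), integrated_intensity = numeric())
  attr(out, "n_particles") <- keep
  attr(out, "edge_margin_px") <- margin
  class(out) <- c("agg_particles", class(out))
  out
}

# median intensity in an annulus centered at (cx, cy), 0-based coords
annulus_median <- function(frame, cx, cy, inner, width) {
  nr <- nrow(frame); nc <- ncol(frame)
  outer_r <- inner + width
  r0 <- max(0, floor(cy - outer_r)); r1 <- min(nr - 1, ceiling(cy + outer_r))
  c0 <- max(0, floor(cx - outer_r)); c1 <- min(nc - 1, ceiling(cx + outer_r))
  rows <- r0:r1; cols <- c0:c1
  d2 <- outer((rows - cy)^2, (cols - cx)^2, "+")
  sel <- d2 >= inner^2 & d2 <= outer_r^2
  vals <- frame[rows + 1, cols + 1, drop = FALSE][sel]
  if (!length(vals)) return(median(frame))
  median(vals)
}

#' Counting accuracy against a known ground truth
#'
#' `Accuracy = (1 - |N_measured - N_simulated| / N_simulated) * 100`.
#' Symmetric in over- and under-counting; can be negative for gross
#' over-counting.
#'
#' @param n_measured,n_simulated Spot counts; `n_simulated` must be > 0.
#' @return Accuracy in percent.
#' @export
counting_accuracy <- function(n_measured, n_simulated) {
  if (any(n_simulated <= 0)) abort("`n_simulated` must be > 0.")
  (1 - abs(n_measured - n_simulated) / n_simulated) * 100
}

#' @export
print.agg_particles <- function(x, ...) {
  cat(sprintf("<agg_particles> %d particles (edge margin %d px)\n",
              attr(x, "n_particles"), attr(x, "edge_margin_px")))
  NextMethod()
}

#' @rdname detect_spots
#' @param x An `agg_particles` tibble.
#' @param ... Unused.
#' @export
glance.agg_particles <- function(x, ...) {
  tibble(
    n_particles = attr(x, "n_particles"),
    median_intensity = if (nrow(x)) median(x$integrated_intensity) else NA_real_,
    median_area_px = if (nrow(x)) median(x$area_px) else NA_real_
  )
}
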