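#' Parameters for the diffraction-limited aggregate simulator
#'
#' Defaults reproduce the validation conditions for spot counting: Gaussian
#' dots of 7-10 px diameter with peak intensities of 3000 +/- 600 counts on a
#' normally distributed baseline of 2000 +/- 200 counts in a 512 x 512 field.
#' The signal-to-noise ratio of a field is defined as mean dot peak intensity
#' divided by mean baseline background intensity; `snr` is a convenience that
#' sets `peak_mean = snr * baseline_mean`.
#'
#' @param image_size Pixels per side of the square field (>= 32).
#' @param n_dots Number of dots to place.
#' @param dot_diameter_range Length-2 numeric, low/high dot diameter in px.
#' @param peak_mean,peak_sd Normal distribution of dot peak intensities
#'   (counts).
#' @param baseline_mean,baseline_sd Normal per-pixel baseline noise (counts).
#' @param illumination Add an additive, centered 2-D Gaussian illumination
#'   component (bright center, dim margins)?
#' @param illumination_amplitude Peak amplitude of the illumination component
#'   (counts); default a quarter of the baseline mean.
#' @param illumination_sigma Width of the illumination Gaussian (px).
#' @param gaussian_mask Multiply dot signal by a centered Gaussian mask with
#'   mean 1, emulating a Gaussian-shaped excitation beam (used in SNR tests).
#' @param snr Optional signal-to-noise ratio; overrides `peak_mean`.
#' @param seed Optional RNG seed; identical parameters and seed give
#'   bit-identical images.
#' @return A list of class `dl_sim_params`.
#' @export
dl_sim_params <- function(image_size = 512L,
                          n_dots = 300L,
                          dot_diameter_range = c(7, 10),
                          peak_mean = 3000,
                          peak_sd = 600,
                          baseline_mean = 2000,
                          baseline_sd = 200,
                          illumination = FALSE,
                          illumination_amplitude = 0.25 * baseline_mean,
                          illumination_sigma = image_size / 2,
                          gaussian_mask = FALSE,
                          snr = NULL,
                          seed = NULL) {
  if (!is.null(snr)) {
    check_number(snr, "snr", min = 0)
    peak_mean <- snr * baseline_mean
  }
  check_number(image_size, "image_size", min = 32, integer = TRUE)
  check_number(n_dots, "n_dots", min = 0, integer = TRUE)
  if (length(dot_diameter_range) != 2L || diff(dot_diameter_range) < 0 ||
      any(dot_diameter_range <= 0)) {
    abort("`dot_diameter_range` must be positive with low <= high.")
  }
  check_number(peak_mean, "peak_mean", min = 0)
  check_number(peak_sd, "peak_sd", min = 0)
  check_number(baseline_mean, "baseline_mean", min = 0)
  check_number(baseline_sd, "baseline_sd", min = 0)
  check_number(illumination_amplitude, "illumination_amplitude", min = 0)
  check_number(illumination_sigma, "illumination_sigma", min = 0)
  structure(
    list(
      image_size = as.integer(image_size),
      n_dots = as.integer(n_dots),
      dot_diameter_range = as.numeric(dot_diameter_range),
      peak_mean = peak_mean, peak_sd = peak_sd,
      baseline_mean = baseline_mean, baseline_sd = baseline_sd,
      illumination = isTRUE(illumination),
      illumination_amplitude = illumination_amplitude,
      illumination_sigma = illumination_sigma,
      gaussian_mask = isTRUE(gaussian_mask),
      seed = seed
    ),
    class = "dl_sim_params"
  )
}

#' Simulate a diffraction-limited field of dot-like aggregates
#'
#' Places `n_dots` isotropic Gaussian dots at uniformly random positions on a
#' blank field. Each dot's diameter is drawn uniformly from
#' `dot_diameter_range` and rendered with `sigma = diameter / 4`, so ~95% of
#' its mass lies within the stated diameter. Dots are placed so they lie
#' fully inside the field. The noisy image adds per-pixel normal baseline
#' noise and, optionally, an additive centered Gaussian illumination gradient;
#' with `gaussian_mask = TRUE` the dot signal is first modulated by a centered
#' Gaussian mask normalized to mean 1.
#'
#' The ground-truth dot count (`true_count`) is obtained by prominence-based
#' maxima counting on the ideal image (prominence threshold 1), so dots that
#' merge into a single peak count once.
#'
#' @param params A [dl_sim_params()] object.
#' @param centers Optional 2-column matrix of dot centers (0-based px) to use
#'   instead of random placement (for constructed fixtures).
#' @return A list of class `dl_simulation` with elements `ideal` (matrix),
#'   `noisy` (matrix), and `truth`, a tibble with columns `x_px`, `y_px`,
#'   `diameter_px`, `peak_intensity` plus attribute `true_count`.
#' @export
simulate_dl <- function(params = dl_sim_params(), centers = NULL) {
  stopifnot(inherits(params, "dl_sim_params"))
  with_seed(params$seed, {
    n <- params$n_dots
    size <- params$image_size
    diam <- if (n) runif(n, params$dot_diameter_range[1], params$dot_diameter_range[2]) else numeric()
    # dots drawn fully inside the field
    margin <- ceiling(max(params$dot_diameter_range) / 2) + 1
    if (is.null(centers)) {
      cx <- if (n) runif(n, margin, size - 1 - margin) else numeric()
      cy <- if (n) runif(n, margin, size - 1 - margin) else numeric()
    } else {
      stopifnot(nrow(centers) == n)
      cx <- centers[, 1]; cy <- centers[, 2]
    }
    peaks <- if (n) rnorm(n, params$peak_mean, params$peak_sd) else numeric()
    peaks <- pmax(peaks, 0)

    ideal <- matrix(0, size, size)
    ideal <- render_gaussians(ideal, cx, cy, peaks, diam / 4)

    signal <- ideal
    if (params$gaussian_mask) {
      g <- pixel_grid(size, size)
      m <- exp(-(((g$x - (size - 1) / 2)^2 + (g$y - (size - 1) / 2)^2) /
                   (2 * (size / 2)^2)))
      signal <- signal * (m / mean(m))
    }
    noisy <- signal +
      matrix(rnorm(size * size, params$baseline_mean, params$baseline_sd), size, size)
    if (params$illumination) {
      g <- pixel_grid(size, size)
      noisy <- noisy + params$illumination_amplitude *
        exp(-(((g$x - (size - 1) / 2)^2 + (g$y - (size - 1) / 2)^2) /
                (2 * params$illumination_sigma^2)))
    }

    truth <- tibble(
      x_px = cx, y_px = cy,
      diameter_px = diam, peak_intensity = peaks
    )
    attr(truth, "true_count") <- count_true_maxima(ideal, prominence = 1)
    structure(
      list(ideal = ideal, noisy = noisy, truth = truth, params = params),
      class = "dl_simulation"
    )
  })
}

#' Count ground-truth maxima by prominence
#'
#' Counts local maxima whose prominence (height above the highest saddle
#' connecting them to a higher maximum) strictly exceeds a threshold,
#' following the "find maxima" convention used to count ground-truth dots:
#' overlapping dots that merge into one peak count once, and a constant image
#' has no maxima. Plateaus are broken in row-major scan order.
#'
#' @param frame Numeric matrix (typically the ideal, noise-free image).
#' @param prominence Positive prominence threshold; ground truth uses 1.
#' @return Integer count of prominent maxima.
#' @export
count_true_maxima <- function(frame, prominence = 1) {
  check_frame(frame)
  check_number(prominence, "prominence")
  if (prominence <= 0) abort("`prominence` must be > 0.")
  cpp_count_prominent_maxima(frame, prominence)
}

#' Write a diffraction-limited simulation to disk
#'
#' Writes 16-bit TIFFs for the ideal and noisy frames plus a ground-truth CSV
#' (`x_px`, `y_px`, `diameter_px`, `peak_intensity`, `frame`).
#'
#' @param sim A `dl_simulation` from [simulate_dl()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Tibble of written paths, invisibly.
#' @export
write_dl_simulation <- function(sim, dir, prefix = "fov") {
  stopifnot(inherits(sim, "dl_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_ideal <- file.path(dir, paste0(prefix, "_ideal.tif"))
  p_noisy <- file.path(dir, paste0(prefix, "_noisy.tif"))
  p_truth <- file.path(dir, paste0(prefix, "_truth.csv"))
  write_image_stack(sim$ideal, p_ideal)
  write_image_stack(sim$noisy, p_noisy)
  readr::write_csv(dplyr::mutate(sim$truth, frame = 0L), p_truth)
  invisible(tibble(kind = c("ideal", "noisy", "truth"),
                   path = c(p_ideal, p_noisy, p_truth)))
}

#' @export
print.dl_simulation <- function(x, ...) {
  cat(sprintf(
    "<dl_simulation> %d x %d px, %d dots (true maxima count: %d)\n",
    nrow(x$ideal), ncol(x$ideal), x$params$n_dots,
    attr(x$truth, "true_count")
  ))
  invisible(x)
}
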