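#' Parameters for the super-resolution (blinking-stack) simulator
#'
#' Ground-truth structures (round dots or straight lines) are rasterized on a
#' fine canvas; every occupied canvas pixel is a potential blinking site that
#' turns ON independently each frame. ON sites are rendered as Gaussian spots
#' on the coarser camera image at canvas coordinates divided by
#' `scale_factor`, with normal background, always-on fiducial markers at
#' `fiducial_intensity_factor` times the mean spot intensity, and a
#' cumulative random-walk stage drift.
#'
#' Defaults emulate a DNA-PAINT acquisition: 2500 px canvas imaged onto a
#' 500 px camera (scale 5), 1000 frames, sparse blinking
#' (`on_probability = 0.005`), a 1.1 camera-px PSF, spot peak amplitudes of
#' 300 +/- 60 counts on a 200 +/- 30 count background (about 10 nm
#' localization precision), two fiducials at 5x the mean spot intensity, and
#' a 0.02 camera-px/frame drift step. At the default 100 nm camera pixel, one
#' canvas pixel spans 20 nm.
#'
#' @param canvas_size Canvas pixels per side; must equal
#'   `camera_size * scale_factor`.
#' @param camera_size Camera pixels per side.
#' @param scale_factor Integer canvas-to-camera scale (canvas coords are
#'   divided by this).
#' @param n_frames Number of frames (>= 1).
#' @param structure_type `"line"` or `"dot"`.
#' @param n_structures Number of structures.
#' @param length_distribution `c(mean, sd)` of line lengths, canvas px.
#' @param dot_diameter_distribution `c(mean, sd)` of dot diameters, canvas px.
#' @param on_probability Per-site per-frame ON probability (0 < p < 1).
#' @param spot_intensity `c(mean, sd)` of Gaussian spot peak amplitudes
#'   (counts).
#' @param background `c(mean, sd)` of per-pixel normal background (counts).
#' @param psf_sigma_px Camera-space PSF sigma (px).
#' @param n_fiducials Number of always-on fiducial markers.
#' @param fiducial_intensity_factor Fiducial amplitude as a multiple of the
#'   mean spot amplitude (> 0, default 5).
#' @param drift_per_frame Drift random-walk step size (camera px); each frame
#'   steps by -d, 0, or +d on one randomly chosen axis.
#' @param camera_pixel_nm Physical camera pixel size (nm).
#' @param seed Optional RNG seed.
#' @return A list of class `sr_sim_params`.
#' @export
sr_sim_params <- function(canvas_size = 2500L,
                          camera_size = 500L,
                          scale_factor = 5L,
                          n_frames = 1000L,
                          structure_type = c("line", "dot"),
                          n_structures = 50L,
                          length_distribution = c(100, 37.5),
                          dot_diameter_distribution = c(1.5, 0.25),
                          on_probability = 0.005,
                          spot_intensity = c(300, 60),
                          background = c(200, 30),
                          psf_sigma_px = 1.1,
                          n_fiducials = 2L,
                          fiducial_intensity_factor = 5,
                          drift_per_frame = 0.02,
                          camera_pixel_nm = 100,
                          seed = NULL) {
  structure_type <- match.arg(structure_type)
  check_number(canvas_size, "canvas_size", min = 10, integer = TRUE)
  check_number(camera_size, "camera_size", min = 2, integer = TRUE)
  check_number(scale_factor, "scale_factor", min = 1, integer = TRUE)
  if (canvas_size != camera_size * scale_factor) {
    abort("`canvas_size` must equal `camera_size * scale_factor`.")
  }
  check_number(n_frames, "n_frames", min = 1, integer = TRUE)
  check_number(n_structures, "n_structures", min = 0, integer = TRUE)
  check_number(on_probability, "on_probability", min = 1e-12, max = 1 - 1e-12)
  check_number(n_fiducials, "n_fiducials", min = 0, integer = TRUE)
  check_number(fiducial_intensity_factor, "fiducial_intensity_factor", min = 1e-12)
  check_number(drift_per_frame, "drift_per_frame", min = 0)
  check_number(psf_sigma_px, "psf_sigma_px", min = 1e-6)
  check_number(camera_pixel_nm, "camera_pixel_nm", min = 1e-6)
  stopifnot(length(length_distribution) == 2L, length_distribution[2] >= 0,
            length(dot_diameter_distribution) == 2L,
            dot_diameter_distribution[2] >= 0,
            length(spot_intensity) == 2L, length(background) == 2L)
  structure(
    list(
      canvas_size = as.integer(canvas_size),
      camera_size = as.integer(camera_size),
      scale_factor = as.integer(scale_factor),
      n_frames = as.integer(n_frames),
      structure_type = structure_type,
      n_structures = as.integer(n_structures),
      length_distribution = as.numeric(length_distribution),
      dot_diameter_distribution = as.numeric(dot_diameter_distribution),
      on_probability = on_probability,
      spot_intensity = as.numeric(spot_intensity),
      background = as.numeric(background),
      psf_sigma_px = psf_sigma_px,
      n_fiducials = as.integer(n_fiducials),
      fiducial_intensity_factor = fiducial_intensity_factor,
      drift_per_frame = drift_per_frame,
      camera_pixel_nm = camera_pixel_nm,
      seed = seed
    ),
    class = "sr_sim_params"
  )
}

# Bresenham line rasterization between 0-based integer canvas endpoints
bresenham <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx - dy
  n <- dx + dy + 1L
  xs <- integer(n); ys <- integer(n)
  i <- 0L
  repeat {
    i <- i + 1L
    xs[i] <- x0; ys[i] <- y0
    if (x0 == x1 && y0 == y1) break
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x0 <- x0 + sx }
    if (e2 < dx) { err <- err + dx; y0 <- y0 + sy }
  }
  cbind(x = xs[seq_len(i)], y = ys[seq_len(i)])
}

#' Generate ground-truth super-resolution structures
#'
#' Rasterizes `n_structures` dot- or line-shaped structures fully inside the
#' canvas and records their exact true lengths: a line's length is the
#' Euclidean end-to-end distance of its endpoints, a dot's length is its
#' diameter. Lines are 1-px-wide Bresenham strokes with normally distributed
#' lengths and uniform orientations; dots are filled discs with normally
#' distributed diameters. Structures that cannot fit are resampled (up to
#' 1000 attempts, then an error).
#'
#' @param params An [sr_sim_params()] object.
#' @return A list of class `sr_ground_truth`: `structures` (tibble with
#'   `structure`, `type`, `true_length_nm`, `n_occupied_px`, anchor
#'   coordinates), `occupied` (list of per-structure integer matrices of
#'   occupied canvas pixels), `super_res_pixel_nm`, `camera_pixel_nm`, and
#'   the generating `params`.
#' @export
simulate_structures <- function(params = sr_sim_params()) {
  stopifnot(inherits(params, "sr_sim_params"))
  with_seed(params$seed, {
    n <- params$n_structures
    size <- params$canvas_size
    px_nm <- params$camera_pixel_nm / params$scale_factor
    occupied <- vector("list", n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      if (params$structure_type == "line") {
        ok <- FALSE
        for (try in seq_len(1000L)) {
          len <- rnorm(1, params$length_distribution[1], params$length_distribution[2])
          if (len < 1 || len > size - 2) next
          theta <- runif(1, 0, pi)
          dx <- len * cos(theta); dy <- len * sin(theta)
          x0 <- runif(1, 0, size - 1 - abs(dx)) + max(0, -dx)
          y0 <- runif(1, 0, size - 1 - abs(dy)) + max(0, -dy)
          x1 <- x0 + dx; y1 <- y0 + dy
          if (min(x0, x1) >= 0 && max(x0, x1) <= size - 1 &&
              min(y0, y1) >= 0 && max(y0, y1) <= size - 1) { ok <- TRUE; break }
        }
        if (!ok) abort("Cannot fit a line structure inside the canvas.")
        pix <- bresenham(round(x0), round(y0), round(x1), round(y1))
        true_len <- sqrt((x1 - x0)^2 + (y1 - y0)^2) * px_nm
        anchor <- c((x0 + x1) / 2, (y0 + y1) / 2)
      } else {
        ok <- FALSE
        for (try in seq_len(1000L)) {
          d <- rnorm(1, params$dot_diameter_distribution[1],
                     params$dot_diameter_distribution[2])
          if (d >= 1 && d <= size - 6) { ok <- TRUE; break }
        }
        if (!ok) abort("Cannot fit a dot structure inside the canvas.")
        r <- d / 2
        cx <- runif(1, r + 1, size - 2 - r); cy <- runif(1, r + 1, size - 2 - r)
        # occupied pixels: centers within r of the continuous dot center
        gx <- floor(cx - r):ceiling(cx + r)
        gy <- floor(cy - r):ceiling(cy + r)
        g <- expand.grid(x = gx, y = gy)
        keep <- (g$x - cx)^2 + (g$y - cy)^2 <= r^2 + 1e-9
        if (!any(keep)) keep[which.min((g$x - cx)^2 + (g$y - cy)^2)] <- TRUE
        pix <- cbind(x = g$x[keep], y = g$y[keep])
        true_len <- d * px_nm
        anchor <- c(cx, cy)
      }
      occupied[[i]] <- pix
      rows[[i]] <- tibble(
        structure = i, type = params$structure_type,
        anchor_x_px = anchor[1], anchor_y_px = anchor[2],
        true_length_nm = true_len, n_occupied_px = nrow(pix)
      )
    }
    structures <- if (n) dplyr::bind_rows(rows) else
      tibble(structure = integer(), type = character(),
             anchor_x_px = numeric(), anchor_y_px = numeric(),
             true_length_nm = numeric(), n_occupied_px = integer())
    structure(
      list(
        structures = structures, occupied = occupied,
        super_res_pixel_nm = px_nm, camera_pixel_nm = params$camera_pixel_nm,
        params = params
      ),
      class = "sr_ground_truth"
    )
  })
}

#' Simulate a blinking super-resolution image stack
#'
#' For each frame, every occupied canvas pixel turns ON independently with
#' `on_probability`; each ON site is rendered as a Gaussian spot on the
#' camera image at its canvas coordinates divided by `scale_factor`, shifted
#' by the frame's cumulative drift. Normal background is added, and
#' `n_fiducials` always-on sites are rendered each frame at
#' `fiducial_intensity_factor` times the mean spot amplitude. The drift trace
#' is a cumulative random walk stepping by `-d, 0, +d` on one random axis per
#' frame and is stored for validation of drift correction.
#'
#' @param truth An `sr_ground_truth` from [simulate_structures()].
#' @param params The same [sr_sim_params()] object (defaults to the one
#'   stored in `truth`).
#' @param seed Optional seed for the blinking/noise stage; defaults to
#'   `params$seed + 1` when `params$seed` is set.
#' @return A list of class `sr_stack`: `frames` (H x W x n_frames array,
#'   counts), `drift` (tibble `frame`, `dx_px`, `dy_px` in camera px),
#'   `on_events` (tibble `frame`, `x_px`, `y_px` camera coords before drift,
#'   `structure`), `fiducials` (tibble `fiducial`, `x_px`, `y_px`), and
#'   `truth`.
#' @export
simulate_blinking_stack <- function(truth, params = truth$params, seed = NULL) {
  stopifnot(inherits(truth, "sr_ground_truth"), inherits(params, "sr_sim_params"))
  if (is.null(seed)) seed <- if (!is.null(params$seed)) params$seed + 1L else NULL
  with_seed(seed, {
    cam <- params$camera_size
    nf <- params$n_frames
    sites <- if (length(truth$occupied)) do.call(rbind, truth$occupied) else
      matrix(numeric(), ncol = 2)
    site_struct <- rep(seq_along(truth$occupied),
                       vapply(truth$occupied, nrow, integer(1)))
    n_sites <- nrow(sites)

    # drift: cumulative random walk, one axis per frame
    step_axis <- sample(c("x", "y"), nf, replace = TRUE)
    step_sign <- sample(c(-1, 0, 1), nf, replace = TRUE)
    ddx <- ifelse(step_axis == "x", step_sign * params$drift_per_frame, 0)
    ddy <- ifelse(step_axis == "y", step_sign * params$drift_per_frame, 0)
    ddx[1] <- 0; ddy[1] <- 0   # first frame is the reference
    drift <- tibble(frame = seq_len(nf) - 1L,
                    dx_px = cumsum(ddx), dy_px = cumsum(ddy))

    # fiducials: fixed camera positions away from the border
    fid <- tibble(
      fiducial = seq_len(params$n_fiducials),
      x_px = runif(params$n_fiducials, 0.1 * cam, 0.9 * cam),
      y_px = runif(params$n_fiducials, 0.1 * cam, 0.9 * cam)
    )
    fid_amp <- params$fiducial_intensity_factor * params$spot_intensity[1]

    frames <- array(0, dim = c(cam, cam, nf))
    ev <- vector("list", nf)
    for (f in seq_len(nf)) {
      img <- matrix(rnorm(cam * cam, params$background[1], params$background[2]),
                    cam, cam)
      if (n_sites) {
        on <- which(runif(n_sites) < params$on_probability)
        if (length(on)) {
          x_cam <- sites[on, 1] / params$scale_factor
          y_cam <- sites[on, 2] / params$scale_factor
          amp <- pmax(rnorm(length(on), params$spot_intensity[1],
                            params$spot_intensity[2]), 0)
          img <- render_gaussians(img, x_cam + drift$dx_px[f],
                                  y_cam + drift$dy_px[f], amp,
                                  params$psf_sigma_px)
          ev[[f]] <- tibble(frame = f - 1L, x_px = x_cam, y_px = y_cam,
                            structure = site_struct[on])
        }
      }
      if (nrow(fid)) {
        img <- render_gaussians(img, fid$x_px + drift$dx_px[f],
                                fid$y_px + drift$dy_px[f],
                                fid_amp, params$psf_sigma_px)
      }
      frames[, , f] <- img
    }
    on_events <- dplyr::bind_rows(ev)
    if (!nrow(on_events) && !is.data.frame(on_events)) {
      on_events <- tibble(frame = integer(), x_px = numeric(),
                          y_px = numeric(), structure = integer())
    }
    structure(
      list(frames = frames, drift = drift, on_events = on_events,
           fiducials = fid, truth = truth, params = params),
      class = "sr_stack"
    )
  })
}

#' Write a super-resolution simulation to disk
#'
#' Writes the multi-frame 16-bit TIFF stack, a ground-truth CSV
#' (`structure`, `type`, `true_length_nm`, `n_occupied_px`) and a drift CSV
#' (`frame`, `dx_px`, `dy_px`).
#'
#' @param stack An `sr_stack` from [simulate_blinking_stack()].
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Tibble of written paths, invisibly.
#' @export
write_sr_simulation <- function(stack, dir, prefix = "sr") {
  stopifnot(inherits(stack, "sr_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_tif <- file.path(dir, paste0(prefix, "_stack.tif"))
  p_truth <- file.path(dir, paste0(prefix, "_truth.csv"))
  p_drift <- file.path(dir, paste0(prefix, "_drift.csv"))
  write_image_stack(stack$frames, p_tif)
  readr::write_csv(
    dplyr::select(stack$truth$structures, "structure", "type",
                  "true_length_nm", "n_occupied_px"),
    p_truth
  )
  readr::write_csv(stack$drift, p_drift)
  invisible(tibble(kind = c("stack", "truth", "drift"),
                   path = c(p_tif, p_truth, p_drift)))
}

#' @export
print.sr_stack <- function(x, ...) {
  cat(sprintf(
    "<sr_stack> %d x %d px x %d frames, %d structures, %d fiducials\n",
    dim(x$frames)[1], dim(x$frames)[2], dim(x$frames)[3],
    nrow(x$truth$structures), nrow(x$fiducials)
  ))
  invisible(x)
}
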