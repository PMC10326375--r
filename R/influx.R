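#' Average an image stack into a single frame
#'
#' @param stack A list of frames, a 3-D array, or a single matrix.
#' @return The per-pixel arithmetic mean frame.
#' @export
average_stack <- function(stack) {
  frames <- stack_to_frames(stack)
  if (!length(frames)) abort("Cannot average an empty stack.")
  Reduce(`+`, frames) / length(frames)
}

#' Align two frames by integer-pixel cross-correlation
#'
#' Finds the integer shift (within `max_shift` px on each axis) that
#' maximizes the cross-correlation of the mean-subtracted frames, and
#' translates the moving frame by that shift, filling exposed rows/columns
#' with the frame median. Flat (zero-variance) inputs return shift (0, 0)
#' with a warning flag.
#'
#' @param reference,moving Numeric matrices of identical shape.
#' @param max_shift Maximum |shift| searched per axis (px).
#' @return List with `aligned` (the moving frame translated back into the
#'   reference's coordinates), `shift` (`c(dx, dy)`: the detected
#'   displacement of `moving` relative to `reference`, x = column axis), and
#'   `flat` (logical flag).
#' @export
align_by_crosscorr <- function(reference, moving, max_shift = 20L) {
  check_frame(reference, "reference"); check_frame(moving, "moving")
  if (!all(dim(reference) == dim(moving))) abort("Frames must have identical shapes.")
  check_number(max_shift, "max_shift", min = 0, integer = TRUE)
  if (sd(reference) == 0 || sd(moving) == 0) {
    return(list(aligned = moving, shift = c(dx = 0L, dy = 0L), flat = TRUE))
  }
  a <- reference - mean(reference)
  b <- moving - mean(moving)
  # circular cross-correlation via FFT; peak restricted to the search window
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  nr <- nrow(cc); nc <- ncol(cc)
  shifts_r <- c(0:(nr - 1)); shifts_r[shifts_r > nr / 2] <- shifts_r[shifts_r > nr / 2] - nr
  shifts_c <- c(0:(nc - 1)); shifts_c[shifts_c > nc / 2] <- shifts_c[shifts_c > nc / 2] - nc
  ok <- outer(abs(shifts_r) <= max_shift, abs(shifts_c) <= max_shift, "&")
  cc[!ok] <- -Inf
  best <- which.max(cc)
  # detected displacement of `moving` relative to `reference`
  dy <- -shifts_r[((best - 1L) %% nr) + 1L]
  dx <- -shifts_c[((best - 1L) %/% nr) + 1L]
  aligned <- translate_frame(moving, -dx, -dy, fill = median(moving))
  list(aligned = aligned, shift = c(dx = dx, dy = dy), flat = FALSE)
}

# integer translation; positive dx moves content toward larger column index
translate_frame <- function(frame, dx, dy, fill = 0) {
  nr <- nrow(frame); nc <- ncol(frame)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dy; src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1 & src_r <= nr; ok_c <- src_c >= 1 & src_c <= nc
  out[which(ok_r), which(ok_c)] <- frame[src_r[ok_r], src_c[ok_c]]
  out
}

#' Locate liposomes in the ionomycin frame
#'
#' A maximum filter (grayscale dilation over a square window) identifies
#' local peaks; only peaks above `background + threshold` are retained, where
#' background is the frame median. Peaks closer than the window size are
#' merged into the brighter one.
#'
#' @param frame Numeric matrix (averaged ionomycin frame).
#' @param threshold Non-negative intensity threshold above background.
#' @param window Odd window size of the maximum filter (px).
#' @return Tibble with `x_px`, `y_px` (0-based integer peak positions) and
#'   `peak_intensity`.
#' @export
find_liposome_peaks <- function(frame, threshold, window = 5L) {
  check_frame(frame)
  check_number(threshold, "threshold", min = 0)
  check_number(window, "window", min = 1, integer = TRUE)
  if (window %% 2L == 0L) abort("`window` must be odd.")
  lo <- min(frame); hi <- max(frame)
  if (hi == lo) {
    return(tibble(x_px = integer(), y_px = integer(), peak_intensity = numeric()))
  }
  unit <- (frame - lo) / (hi - lo)
  mx <- EBImage::dilate(unit, matrix(1L, window, window)) * (hi - lo) + lo
  bg <- median(frame)
  is_peak <- (frame >= mx - 1e-9) & (frame > bg + threshold)
  idx <- which(is_peak)
  if (!length(idx)) {
    return(tibble(x_px = integer(), y_px = integer(), peak_intensity = numeric()))
  }
  nr <- nrow(frame)
  peaks <- tibble(
    x_px = (idx - 1L) %/% nr, y_px = (idx - 1L) %% nr,
    peak_intensity = frame[idx]
  )
  peaks <- dplyr::arrange(peaks, dplyr::desc(.data$peak_intensity))
  # merge peaks closer than the window size, keeping the brighter one
  kept <- logical(0); kx <- numeric(0); ky <- numeric(0); sel <- integer(0)
  for (i in seq_len(nrow(peaks))) {
    if (!length(kx) ||
        all(pmax(abs(kx - peaks$x_px[i]), abs(ky - peaks$y_px[i])) >= window)) {
      kx <- c(kx, peaks$x_px[i]); ky <- c(ky, peaks$y_px[i]); sel <- c(sel, i)
    }
  }
  peaks[sel, ]
}

#' Per-liposome calcium influx
#'
#' For each liposome peak, integrates the blank, sample, and ionomycin frames
#' over a disc of radius 3 px and applies
#' `%Influx = (F_sample - F_blank) / (F_ionomycin - F_blank) * 100`.
#' Records whose ionomycin-minus-blank denominator falls below `floor_counts`
#' are flagged invalid rather than divided.
#'
#' @param f_blank,f_sample,f_ionomycin Aligned, averaged frames (identical
#'   shapes).
#' @param peaks Tibble of peaks from [find_liposome_peaks()] on the
#'   ionomycin frame.
#' @param radius_px Disc radius for intensity integration (default 3 px:
#'   pixels whose center lies within 3.0 px, 29 pixels).
#' @param floor_counts Minimum |I_ionomycin - I_blank| for a valid record.
#' @param clip Clip influx to the 0-100 range? Off by default: negative or
#'   greater-than-100 values are biologically meaningful noise.
#' @return A tibble of class `agg_influx`: `x_px`, `y_px`, `I_blank`,
#'   `I_sample`, `I_ionomycin`, `influx_percent`, `valid`.
#' @export
measure_influx <- function(f_blank, f_sample, f_ionomycin, peaks,
                           radius_px = 3, floor_counts = 10, clip = FALSE) {
  check_frame(f_blank, "f_blank"); check_frame(f_sample, "f_sample")
  check_frame(f_ionomycin, "f_ionomycin")
  if (!all(dim(f_blank) == dim(f_sample)) ||
      !all(dim(f_blank) == dim(f_ionomycin))) {
    abort("The three frames must have identical shapes.")
  }
  n <- nrow(peaks)
  disc <- disc_offsets(radius_px)
  nr <- nrow(f_blank); nc <- ncol(f_blank)
  res <- purrr::map_dfr(seq_len(n), function(i) {
    rr <- peaks$y_px[i] + disc$dy; cc <- peaks$x_px[i] + disc$dx
    ok <- rr >= 0 & rr < nr & cc >= 0 & cc < nc
    idx <- (rr[ok]) + (cc[ok]) * nr + 1L
    ib <- sum(f_blank[idx]); is <- sum(f_sample[idx]); ii <- sum(f_ionomycin[idx])
    valid <- abs(ii - ib) >= floor_counts
    influx <- if (valid) (is - ib) / (ii - ib) * 100 else NA_real_
    if (valid && clip) influx <- min(max(influx, 0), 100)
    tibble(
      x_px = peaks$x_px[i], y_px = peaks$y_px[i],
      I_blank = ib, I_sample = is, I_ionomycin = ii,
      influx_percent = influx, valid = valid
    )
  })
  if (n == 0) {
    res <- tibble(x_px = integer(), y_px = integer(), I_blank = numeric(),
                  I_sample = numeric(), I_ionomycin = numeric(),
                  influx_percent = numeric(), valid = logical())
  }
  class(res) <- c("agg_influx", class(res))
  res
}

# integer pixel offsets of a disc: centers within `radius` of the origin
disc_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g <- g[g$dx^2 + g$dy^2 <= radius^2, ]
  list(dx = g$dx, dy = g$dy)
}

#' Influx pipeline for one field of view
#'
#' Averages the three stacks, aligns sample and blank to the ionomycin frame
#' by cross-correlation, locates liposomes in the ionomycin frame, and
#' measures per-liposome influx.
#'
#' @param blank,sample,ionomycin Image stacks (list, array, or matrix).
#' @param threshold Peak-retention threshold above background (counts).
#' @param ... Passed to [measure_influx()].
#' @return An `agg_influx` tibble; attribute `shifts` records the applied
#'   alignment shifts.
#' @export
influx_fov <- function(blank, sample, ionomycin, threshold, ...) {
  fb <- average_stack(blank); fs <- average_stack(sample)
  fi <- average_stack(ionomycin)
  ab <- align_by_crosscorr(fi, fb)
  as_ <- align_by_crosscorr(fi, fs)
  peaks <- find_liposome_peaks(fi, threshold)
  out <- measure_influx(ab$aligned, as_$aligned, fi, peaks, ...)
  attr(out, "shifts") <- list(blank = ab$shift, sample = as_$shift)
  out
}

#' @rdname measure_influx
#' @param x An `agg_influx` tibble.
#' @param ... Unused.
#' @export
glance.agg_influx <- function(x, ...) {
  v <- x$influx_percent[x$valid]
  tibble(
    n_liposomes = nrow(x), n_valid = sum(x$valid),
    median_influx_percent = if (length(v)) median(v) else NA_real_
  )
}
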