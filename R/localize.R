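#' Localize blinking emitters in an image stack
#'
#' A minimal single-emitter localizer: per frame, candidate spots are local
#' maxima (3x3) above `mean + threshold_k * sd` of the frame; each candidate
#' is refined in a 7x7 window by least-squares 2-D Gaussian fitting
#' (Levenberg-Marquardt; amplitude, center, width, offset), falling back to a
#' background-subtracted intensity-weighted centroid when the fit diverges or
#' `fit_method = "centroid"`. Sub-pixel positions are converted to nm with
#' the camera pixel size.
#'
#' @param stack An `sr_stack`, a 3-D array, or a list of frames.
#' @param threshold_k Candidate threshold in frame SDs above the frame mean.
#' @param pixel_nm Camera pixel size in nm (100 for simulated data; real
#'   acquisitions here use 101.2).
#' @param fit_method `"gaussian"` (default) or `"centroid"`.
#' @param window Odd fitting window size (default 7).
#' @return A tibble of class `agg_localizations`: `id`, `frame` (0-based),
#'   `x_nm`, `y_nm`, `intensity`, `sigma_nm`. Attribute `n_dropped` counts
#'   candidates discarded for fit divergence; attribute `pixel_nm` records
#'   the conversion.
#' @export
localize_stack <- function(stack, threshold_k = 5, pixel_nm = 100,
                           fit_method = c("gaussian", "centroid"),
                           window = 7L) {
  fit_method <- match.arg(fit_method)
  if (inherits(stack, "sr_stack")) stack <- stack$frames
  frames <- stack_to_frames(stack)
  check_number(threshold_k, "threshold_k", min = 1e-6)
  check_number(pixel_nm, "pixel_nm", min = 1e-9)
  check_number(window, "window", min = 3, integer = TRUE)
  if (window %% 2L == 0L) abort("`window` must be odd.")
  half <- (window - 1L) %/% 2L

  res <- vector("list", length(frames))
  dropped <- 0L
  for (f in seq_along(frames)) {
    img <- frames[[f]]
    thr <- mean(img) + threshold_k * sd(img)
    cand <- local_maxima_3x3(img, thr)
    if (!nrow(cand)) next
    # keep candidates whose full window fits inside the frame
    nr <- nrow(img); nc <- ncol(img)
    cand <- cand[cand$row > half & cand$row <= nr - half &
                   cand$col > half & cand$col <= nc - half, , drop = FALSE]
    if (!nrow(cand)) next
    out <- vector("list", nrow(cand))
    for (i in seq_len(nrow(cand))) {
      win <- img[(cand$row[i] - half):(cand$row[i] + half),
                 (cand$col[i] - half):(cand$col[i] + half)]
      fit <- fit_spot(win, fit_method)
      if (is.null(fit)) { dropped <- dropped + 1L; next }
      # window-local (0-based) -> frame 0-based coords
      x0 <- (cand$col[i] - 1L - half) + fit$x
      y0 <- (cand$row[i] - 1L - half) + fit$y
      out[[i]] <- tibble(
        frame = f - 1L, x_nm = x0 * pixel_nm, y_nm = y0 * pixel_nm,
        intensity = fit$intensity, sigma_nm = fit$sigma * pixel_nm
      )
    }
    res[[f]] <- dplyr::bind_rows(out)
  }
  locs <- dplyr::bind_rows(res)
  if (!nrow(locs)) {
    locs <- tibble(frame = integer(), x_nm = numeric(), y_nm = numeric(),
                   intensity = numeric(), sigma_nm = numeric())
  }
  locs <- dplyr::mutate(locs, id = dplyr::row_number(), .before = 1)
  attr(locs, "n_dropped") <- dropped
  attr(locs, "pixel_nm") <- pixel_nm
  class(locs) <- c("agg_localizations", class(locs))
  locs
}

# strict 3x3 local maxima above a threshold; returns 1-based row/col tibble
local_maxima_3x3 <- function(img, thr) {
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 3 || nc < 3) return(tibble(row = integer(), col = integer()))
  ctr <- img[2:(nr - 1), 2:(nc - 1)]
  is_max <- ctr > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- img[(2 + dr):(nr - 1 + dr), (2 + dc):(nc - 1 + dc)]
    is_max <- is_max & (ctr >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  tibble(row = idx[, 1] + 1L, col = idx[, 2] + 1L)
}

# fit one window; returns list(x, y, sigma, intensity) in 0-based window
# coordinates (x along columns), or NULL on divergence
fit_spot <- function(win, method) {
  w <- ncol(win)
  bg <- min(win)
  sub <- win - bg
  tot <- sum(sub)
  if (tot <= 0) return(NULL)
  ax <- seq_len(w) - 1
  cx <- sum(colSums(sub) * ax) / tot
  cy <- sum(rowSums(sub) * ax) / tot
  if (method == "centroid") {
    return(list(x = cx, y = cy, sigma = 1, intensity = tot))
  }
  X <- matrix(rep(ax, each = w), w, w)
  Y <- matrix(rep(ax, times = w), w, w)
  amp0 <- max(sub)
  par0 <- c(A = amp0, x = cx, y = cy, s = 1.2, b = bg)
  resid_fn <- function(p) {
    as.vector(win - (p[5] + p[1] * exp(-((X - p[2])^2 + (Y - p[3])^2) / (2 * p[4]^2))))
  }
  # maxiter-limited fits are kept if they pass the sanity checks below
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 60))
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  p <- fit$par
  if (!all(is.finite(p)) || p[1] <= 0 || p[4] <= 0 || p[4] > w ||
      p[2] < -1 || p[2] > w || p[3] < -1 || p[3] > w) {
    return(NULL)
  }
  list(x = unname(p[2]), y = unname(p[3]), sigma = unname(abs(p[4])),
       intensity = unname(2 * pi * p[1] * p[4]^2))
}

#' Identify fiducial tracks among localizations
#'
#' Fiducials are identified by persistence, not brightness: localizations are
#' chained by proximity (within one camera pixel) across frames, and chains
#' present in at least `min_occupancy` of all frames are fiducial tracks.
#' A persistent chain must additionally be point-like — its spatial extent
#' on each axis may not exceed `max_extent_px` camera pixels (drift plus
#' localization noise). Without this constraint a densely sampled extended
#' structure, whose sites collectively light up in nearly every frame, would
#' masquerade as a fiducial.
#'
#' @param locs An `agg_localizations` tibble.
#' @param n_frames Total number of frames in the source stack.
#' @param pixel_nm Camera pixel size (nm); defaults to the value recorded on
#'   `locs`.
#' @param min_occupancy Minimum fraction of frames a chain must appear in.
#' @param max_extent_px Maximum per-axis extent of a track, camera px.
#' @return Tibble with `track`, `frame`, `x_nm`, `y_nm`, `id` rows of the
#'   member localizations.
#' @export
find_fiducials <- function(locs, n_frames, pixel_nm = attr(locs, "pixel_nm"),
                           min_occupancy = 0.9, max_extent_px = 2) {
  if (is.null(pixel_nm)) pixel_nm <- 100
  if (!nrow(locs)) {
    return(tibble(track = integer(), frame = integer(), x_nm = numeric(),
                  y_nm = numeric(), id = integer()))
  }
  lab <- cpp_dbscan(locs$x_nm, locs$y_nm, eps = pixel_nm, min_pts = 1L)
  members <- locs |>
    dplyr::mutate(track = lab) |>
    dplyr::group_by(.data$track) |>
    dplyr::filter(dplyr::n_distinct(.data$frame) >= min_occupancy * n_frames,
                  diff(range(.data$x_nm)) <= max_extent_px * pixel_nm,
                  diff(range(.data$y_nm)) <= max_extent_px * pixel_nm) |>
    dplyr::ungroup()
  # one localization per track per frame (brightest) defines the trajectory;
  # every member id is recorded so all fiducial localizations can be removed
  out <- members |>
    dplyr::group_by(.data$track, .data$frame) |>
    dplyr::slice_max(.data$intensity, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(track = match(.data$track, unique(.data$track))) |>
    dplyr::select("track", "frame", "x_nm", "y_nm", "id")
  attr(out, "member_ids") <- members$id
  out
}

#' Drift-correct localizations using fiducial tracks
#'
#' Per-frame drift is the mean fiducial displacement from each track's
#' first-frame position, smoothed with a centered moving average (window 10
#' frames) and interpolated across frames a fiducial missed. The estimated
#' drift is subtracted from every localization and fiducial localizations
#' are removed from the output. With no fiducial track, correction is
#' skipped with a warning.
#'
#' @param locs An `agg_localizations` tibble.
#' @param n_frames Total frames in the stack (default: max frame + 1).
#' @param fiducials Optional precomputed [find_fiducials()] table.
#' @param smooth_window Moving-average window (frames).
#' @return Drift-corrected `agg_localizations` (fiducials removed);
#'   attribute `drift` holds the estimated per-frame drift tibble (`frame`,
#'   `dx_nm`, `dy_nm`).
#' @export
correct_drift <- function(locs, n_frames = max(locs$frame) + 1L,
                          fiducials = NULL, smooth_window = 10L) {
  if (is.null(fiducials)) fiducials <- find_fiducials(locs, n_frames)
  if (!nrow(fiducials)) {
    warn("No fiducial track found; drift correction skipped.")
    attr(locs, "drift") <- tibble(frame = seq_len(n_frames) - 1L,
                                  dx_nm = 0, dy_nm = 0)
    return(locs)
  }
  disp <- fiducials |>
    dplyr::group_by(.data$track) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(ddx = .data$x_nm - dplyr::first(.data$x_nm),
                  ddy = .data$y_nm - dplyr::first(.data$y_nm)) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(dx = mean(.data$ddx), dy = mean(.data$ddy))
  all_frames <- seq_len(n_frames) - 1L
  dx <- approx(disp$frame, disp$dx, xout = all_frames, rule = 2)$y
  dy <- approx(disp$frame, disp$dy, xout = all_frames, rule = 2)$y
  dx <- moving_average(dx, smooth_window)
  dy <- moving_average(dy, smooth_window)
  drift <- tibble(frame = all_frames, dx_nm = dx, dy_nm = dy)

  drop_ids <- attr(fiducials, "member_ids") %||% fiducials$id
  out <- locs |>
    dplyr::filter(!.data$id %in% drop_ids) |>
    dplyr::mutate(
      x_nm = .data$x_nm - dx[.data$frame + 1L],
      y_nm = .data$y_nm - dy[.data$frame + 1L]
    )
  for (a in c("n_dropped", "pixel_nm")) attr(out, a) <- attr(locs, a)
  attr(out, "drift") <- drift
  class(out) <- unique(c("agg_localizations", class(out)))
  out
}

# centered moving average with shrinking windows at the edges
moving_average <- function(x, window) {
  if (window <= 1L || length(x) < 2L) return(x)
  half <- window %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

# ---- localization table I/O ------------------------------------------------

#' Read and write localization tables
#'
#' The native dialect is a CSV with columns `frame`, `x_nm`, `y_nm`,
#' `intensity`, `sigma_nm`. ThunderSTORM-style tables (columns labelled with
#' `[nm]` units, e.g. `x [nm]`) and GDSC-style tables (`X`, `Y` in px plus
#' `Frame`) are read into the same representation. Writing always uses the
#' native dialect (round-trip lossless); unknown columns are preserved where
#' possible.
#'
#' @param path CSV file path.
#' @param dialect `"auto"`, `"native"`, `"thunderstorm"` or `"gdsc"`.
#' @param pixel_nm Pixel size used to convert px columns (GDSC dialect).
#' @return An `agg_localizations` tibble.
#' @export
read_localizations <- function(path, dialect = c("auto", "native", "thunderstorm", "gdsc"),
                               pixel_nm = 100) {
  dialect <- match.arg(dialect)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  nms <- names(df)
  if (dialect == "auto") {
    dialect <- if (any(grepl("\\[nm\\]", nms))) "thunderstorm"
      else if (all(c("frame", "x_nm", "y_nm") %in% nms)) "native"
      else if (any(tolower(nms) == "x") && any(tolower(nms) == "y")) "gdsc"
      else "native"
  }
  pick <- function(patterns) {
    for (p in patterns) {
      hit <- grep(p, nms, ignore.case = TRUE, value = TRUE)
      if (length(hit)) return(hit[1])
    }
    NULL
  }
  if (dialect == "native") {
    need <- c("frame", "x_nm", "y_nm")
    miss <- setdiff(need, nms)
    if (length(miss)) {
      abort(sprintf("Localization file is missing column(s): %s",
                    paste(miss, collapse = ", ")))
    }
    out <- df
    if (!"intensity" %in% nms) out$intensity <- NA_real_
    if (!"sigma_nm" %in% nms) out$sigma_nm <- NA_real_
  } else if (dialect == "thunderstorm") {
    xcol <- pick("^x ?\\[nm\\]$"); ycol <- pick("^y ?\\[nm\\]$")
    if (is.null(xcol) || is.null(ycol)) {
      abort("ThunderSTORM table is missing `x [nm]` / `y [nm]` columns.")
    }
    fcol <- pick("^frame$"); icol <- pick("^intensity"); scol <- pick("^sigma ?\\[nm\\]$")
    out <- tibble(
      frame = if (!is.null(fcol)) as.integer(df[[fcol]]) else 0L,
      x_nm = df[[xcol]], y_nm = df[[ycol]],
      intensity = if (!is.null(icol)) df[[icol]] else NA_real_,
      sigma_nm = if (!is.null(scol)) df[[scol]] else NA_real_
    )
  } else { # gdsc: px coordinates
    xcol <- pick("^x$"); ycol <- pick("^y$")
    if (is.null(xcol) || is.null(ycol)) {
      abort("GDSC table is missing `X` / `Y` columns.")
    }
    fcol <- pick("^frame$"); icol <- pick("signal|intensity")
    out <- tibble(
      frame = if (!is.null(fcol)) as.integer(df[[fcol]]) else 0L,
      x_nm = df[[xcol]] * pixel_nm, y_nm = df[[ycol]] * pixel_nm,
      intensity = if (!is.null(icol)) df[[icol]] else NA_real_,
      sigma_nm = NA_real_
    )
  }
  if (!"id" %in% names(out)) out <- dplyr::mutate(out, id = dplyr::row_number(), .before = 1)
  attr(out, "pixel_nm") <- pixel_nm
  class(out) <- c("agg_localizations", class(out))
  out
}

#' @rdname read_localizations
#' @param locs An `agg_localizations` tibble.
#' @return `write_localizations()` returns `path` invisibly.
#' @export
write_localizations <- function(locs, path) {
  readr::write_csv(as_tibble(locs), path)
  invisible(path)
}

#' @export
print.agg_localizations <- function(x, ...) {
  cat(sprintf("<agg_localizations> %d localizations over %s frame(s)\n",
              nrow(x), if (nrow(x)) length(unique(x$frame)) else 0L))
  NextMethod()
}
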