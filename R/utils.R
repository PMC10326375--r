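# internal input checks ------------------------------------------------------

check_number <- function(x, name, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (integer && x != round(x)) {
    abort(sprintf("`%s` must be a whole number.", name))
  }
  if (x < min || x > max) {
    abort(sprintf("`%s` must be in [%s, %s].", name, format(min), format(max)))
  }
  invisible(x)
}

check_frame <- function(x, name = "frame") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix (one image frame).", name))
  }
  invisible(x)
}

# seed handling: all simulators accept `seed`; NULL leaves the RNG state alone
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# derive a reproducible 32-bit sub-seed from a base seed and an index
derive_seed <- function(seed, index) {
  (as.integer(seed) * 1000003L + as.integer(index) * 7919L) %% 2147483562L
}

# pixel-center coordinate grids (0-based, matching image conventions where
# the first pixel center sits at 0)
pixel_grid <- function(nr, nc) {
  list(
    x = matrix(rep(seq_len(nc) - 1, each = nr), nr, nc),
    y = matrix(rep(seq_len(nr) - 1, times = nc), nr, nc)
  )
}

# render isotropic 2-D Gaussians with continuous centers onto a frame by
# stamped accumulation; x/y are 0-based pixel coordinates (x = column axis)
render_gaussians <- function(frame, x, y, amplitude, sigma, stamp_radius = NULL) {
  nr <- nrow(frame); nc <- ncol(frame)
  n <- length(x)
  if (n == 0L) return(frame)
  if (length(sigma) == 1L) sigma <- rep(sigma, n)
  if (length(amplitude) == 1L) amplitude <- rep(amplitude, n)
  if (is.null(stamp_radius)) stamp_radius <- ceiling(3 * sigma)
  if (length(stamp_radius) == 1L) stamp_radius <- rep(stamp_radius, n)
  for (i in seq_len(n)) {
    r <- stamp_radius[i]
    c0 <- floor(x[i]); r0 <- floor(y[i])
    cols <- max(0, c0 - r):min(nc - 1, c0 + r + 1)
    rows <- max(0, r0 - r):min(nr - 1, r0 + r + 1)
    if (!length(cols) || !length(rows)) next
    gx <- exp(-((cols - x[i])^2) / (2 * sigma[i]^2))
    gy <- exp(-((rows - y[i])^2) / (2 * sigma[i]^2))
    frame[rows + 1, cols + 1] <- frame[rows + 1, cols + 1] +
      amplitude[i] * outer(gy, gx)
  }
  frame
}
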