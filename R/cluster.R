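#' DBSCAN clustering of localizations
#'
#' Standard DBSCAN semantics: a core point has at least `min_pts` neighbors
#' (itself included) within `eps`; clusters are maximal sets of
#' density-connected core points plus their border points; everything else is
#' noise. Deterministic given input order; the partition is invariant under
#' point-order permutation and global translation (labels may permute).
#'
#' @param points A two-column matrix or data frame of coordinates (nm), or an
#'   `agg_localizations` tibble (uses `x_nm`, `y_nm`).
#' @param eps Search radius in nm (> 0).
#' @param min_pts Minimum neighborhood size for a core point (>= 1), self
#'   included.
#' @return Integer vector of labels: 0 = noise, clusters numbered from 1.
#' @export
dbscan_points <- function(points, eps = 60, min_pts = 5L) {
  xy <- as_xy(points)
  check_number(eps, "eps", min = 1e-12)
  check_number(min_pts, "min_pts", min = 1, integer = TRUE)
  if (!nrow(xy)) return(integer())
  if (!all(is.finite(xy))) abort("Coordinates must be finite.")
  cpp_dbscan(xy[, 1], xy[, 2], eps, as.integer(min_pts))
}

as_xy <- function(points) {
  if (is.data.frame(points)) {
    if (all(c("x_nm", "y_nm") %in% names(points))) {
      return(cbind(points$x_nm, points$y_nm))
    }
    return(as.matrix(points[, 1:2]))
  }
  if (is.matrix(points)) return(points[, 1:2, drop = FALSE])
  abort("`points` must be a matrix or data frame of x/y coordinates.")
}

#' Rasterize a cluster into a binary occupancy mask
#'
#' Bins localizations onto a grid of `render_pixel_nm` resolution over the
#' cluster's bounding box (plus a 1-px pad); a pixel is ON when at least one
#' localization falls in it. One 3x3 binary closing fills 1-px gaps.
#'
#' @param points Coordinates as in [dbscan_points()]; at least one point.
#' @param render_pixel_nm Rendering pixel size in nm (default 20).
#' @return Logical matrix; attributes `origin_nm` (grid origin) and
#'   `render_pixel_nm`.
#' @export
render_cluster <- function(points, render_pixel_nm = 20) {
  xy <- as_xy(points)
  if (!nrow(xy)) abort("Cannot render an empty point set.")
  check_number(render_pixel_nm, "render_pixel_nm", min = 1e-12)
  ix <- floor(xy[, 1] / render_pixel_nm)
  iy <- floor(xy[, 2] / render_pixel_nm)
  x0 <- min(ix) - 1L; y0 <- min(iy) - 1L
  nc <- max(ix) - x0 + 2L; nr <- max(iy) - y0 + 2L
  mask <- matrix(FALSE, nr, nc)
  mask[cbind(iy - y0 + 1L, ix - x0 + 1L)] <- TRUE
  # single 3x3 closing; background padding keeps the border erosion honest
  pad <- 2L
  m <- matrix(0, nr + 2L * pad, nc + 2L * pad)
  m[pad + seq_len(nr), pad + seq_len(nc)] <- mask
  closed <- EBImage::closing(m, matrix(1L, 3L, 3L)) > 0.5
  closed <- closed[pad + seq_len(nr), pad + seq_len(nc), drop = FALSE]
  structure(closed, origin_nm = c(x0, y0) * render_pixel_nm,
            render_pixel_nm = render_pixel_nm)
}

# Zhang-Suen thinning to a 1-px-wide skeleton (vectorized over the mask)
thin_mask <- function(mask) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3 || nc < 3) {
    pad <- matrix(FALSE, nr + 2L, nc + 2L)
    pad[2:(nr + 1), 2:(nc + 1)] <- m
    m <- pad; nr <- nr + 2L; nc <- nc + 2L
  }
  shift <- function(x, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- x[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # neighbors P2..P9 clockwise from north (row-1)
      p2 <- shift(m, 1, 0);  p3 <- shift(m, 1, -1); p4 <- shift(m, 0, -1)
      p5 <- shift(m, -1, -1); p6 <- shift(m, -1, 0); p7 <- shift(m, -1, 1)
      p8 <- shift(m, 0, 1);  p9 <- shift(m, 1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (pass == 1) {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

#' Skeleton-based length of a binary mask
#'
#' Thins the mask to a 1-px-wide skeleton (Zhang-Suen thinning) and measures
#' total branch length by repeated nearest-neighbor traversal: from an
#' endpoint, hop to the nearest unvisited skeleton pixel (axial steps count
#' 1 pixel, diagonal steps sqrt(2)), summing step distances; each remaining
#' branch is traversed the same way, and a branch terminating next to an
#' already visited junction adds its connecting hop, so a Y-shaped skeleton's
#' length is the sum of its three arms. A single-pixel skeleton reports one
#' render pixel (the minimum resolvable size).
#'
#' @param mask Logical/binary matrix with at least one ON pixel.
#' @param render_pixel_nm Physical pixel size of the mask (nm).
#' @return Length in nm.
#' @export
skeleton_length <- function(mask, render_pixel_nm = 20) {
  if (!is.matrix(mask) || !any(mask != 0)) {
    abort("`mask` must be a matrix with at least one ON pixel.")
  }
  check_number(render_pixel_nm, "render_pixel_nm", min = 1e-12)
  skel <- thin_mask(mask)
  idx <- which(skel, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 1L) return(render_pixel_nm)
  # adjacency by 8-neighborhood
  key <- paste(idx[, 1], idx[, 2])
  lookup <- setNames(seq_len(n), key)
  nb_of <- function(i) {
    r <- idx[i, 1]; c <- idx[i, 2]
    cand <- cbind(rep(r + (-1:1), times = 3), rep(c + (-1:1), each = 3))
    cand <- cand[!(cand[, 1] == r & cand[, 2] == c), , drop = FALSE]
    hits <- lookup[paste(cand[, 1], cand[, 2])]
    hits[!is.na(hits)]
  }
  neighbors <- lapply(seq_len(n), nb_of)
  deg <- lengths(neighbors)
  visited <- logical(n)
  total_steps <- 0
  step_dist <- function(i, j) {
    if (abs(idx[i, 1] - idx[j, 1]) + abs(idx[i, 2] - idx[j, 2]) == 2L &&
        idx[i, 1] != idx[j, 1] && idx[i, 2] != idx[j, 2]) sqrt(2) else 1
  }
  first_branch <- TRUE
  while (any(!visited)) {
    open <- which(!visited)
    # start at an endpoint (fewest unvisited neighbors), row-major tie-break
    un_deg <- vapply(open, function(i) sum(!visited[neighbors[[i]]]), numeric(1))
    start <- open[order(un_deg, idx[open, 1], idx[open, 2])][1]
    cur <- start; prev <- NA_integer_
    # a later branch departing from the traversed skeleton counts its
    # junction hop at whichever end touches the visited part
    start_join <- NA_integer_
    if (!first_branch) {
      joins <- neighbors[[start]][visited[neighbors[[start]]]]
      if (length(joins)) {
        d <- vapply(joins, function(j) step_dist(start, j), numeric(1))
        start_join <- joins[which.min(d)]
        total_steps <- total_steps + min(d)
      }
    }
    visited[cur] <- TRUE
    repeat {
      nxt <- neighbors[[cur]][!visited[neighbors[[cur]]]]
      if (!length(nxt)) break
      d <- vapply(nxt, function(j) step_dist(cur, j), numeric(1))
      j <- nxt[order(d, idx[nxt, 1], idx[nxt, 2])][1]
      total_steps <- total_steps + step_dist(cur, j)
      prev <- cur; cur <- j; visited[cur] <- TRUE
    }
    if (!first_branch) {
      joins <- setdiff(neighbors[[cur]], c(prev, start_join))
      joins <- joins[visited[joins] & joins != cur]
      if (length(joins)) {
        d <- vapply(joins, function(j) step_dist(cur, j), numeric(1))
        total_steps <- total_steps + min(d)
      }
    }
    first_branch <- FALSE
  }
  if (total_steps == 0) return(render_pixel_nm)
  total_steps * render_pixel_nm
}

#' Morphometrics of one cluster of localizations
#'
#' Computes, for a single cluster's point set: the number of localizations;
#' area (ON-pixel count of the rendered mask times the render pixel area);
#' exact convex-hull area of the points (0 for degenerate sets); major axis
#' length and eccentricity from the eigenvalues of the point covariance
#' (ellipse-equivalent: axis length `4 * sqrt(lambda)`, eccentricity
#' `sqrt(1 - lambda_minor / lambda_major)`); and skeleton-based length of the
#' rendered mask.
#'
#' @param points Coordinates (nm) as in [dbscan_points()].
#' @param render_pixel_nm Rendering pixel size (nm).
#' @return One-row tibble: `n_localizations`, `area_nm2`, `hull_area_nm2`,
#'   `major_axis_nm`, `eccentricity`, `length_nm`.
#' @export
cluster_metrics <- function(points, render_pixel_nm = 20) {
  xy <- as_xy(points)
  n <- nrow(xy)
  if (!n) abort("Cannot compute metrics of an empty cluster.")
  mask <- render_cluster(xy, render_pixel_nm)
  area <- sum(mask) * render_pixel_nm^2
  hull <- convex_hull_area(xy)
  if (n >= 2) {
    cv <- stats::cov(xy)
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev[ev < 0] <- 0
    major <- 4 * sqrt(ev[1])
    ecc <- if (ev[1] > 0) sqrt(1 - ev[2] / ev[1]) else 0
  } else {
    major <- 0; ecc <- 0
  }
  tibble(
    n_localizations = n, area_nm2 = area, hull_area_nm2 = hull,
    major_axis_nm = major, eccentricity = ecc,
    length_nm = skeleton_length(mask, render_pixel_nm)
  )
}

# exact convex hull area (shoelace over chull vertices); 0 when degenerate
convex_hull_area <- function(xy) {
  xy <- unique(xy)
  if (nrow(xy) < 3) return(0)
  h <- grDevices::chull(xy[, 1], xy[, 2])
  v <- xy[h, , drop = FALSE]
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Cluster localizations and characterize every aggregate
#'
#' Runs DBSCAN on a localization table, discards noise, and computes
#' [cluster_metrics()] per cluster.
#'
#' @param locs An `agg_localizations` tibble (or any table with `x_nm`,
#'   `y_nm`).
#' @param eps,min_pts DBSCAN parameters (nm / count).
#' @param render_pixel_nm Rendering pixel size for area and skeleton length.
#' @return A tibble of class `agg_clusters`, one row per cluster:
#'   `cluster_id` plus the [cluster_metrics()] columns. Attributes `n_noise`
#'   and `params` record discarded localizations and the parameters used.
#' @export
cluster_localizations <- function(locs, eps = 60, min_pts = 5L,
                                  render_pixel_nm = 20) {
  xy <- as_xy(locs)
  labels <- dbscan_points(xy, eps, min_pts)
  ids <- sort(unique(labels[labels > 0]))
  res <- purrr::map_dfr(ids, function(k) {
    dplyr::bind_cols(tibble(cluster_id = k),
                     cluster_metrics(xy[labels == k, , drop = FALSE],
                                     render_pixel_nm))
  })
  if (!length(ids)) {
    res <- tibble(cluster_id = integer(), n_localizations = integer(),
                  area_nm2 = numeric(), hull_area_nm2 = numeric(),
                  major_axis_nm = numeric(), eccentricity = numeric(),
                  length_nm = numeric())
  }
  attr(res, "n_noise") <- sum(labels == 0)
  attr(res, "params") <- list(eps = eps, min_pts = min_pts,
                              render_pixel_nm = render_pixel_nm)
  class(res) <- c("agg_clusters", class(res))
  res
}

#' @rdname cluster_localizations
#' @param x An `agg_clusters` tibble.
#' @param ... Unused.
#' @export
glance.agg_clusters <- function(x, ...) {
  tibble(
    n_clusters = nrow(x),
    n_noise = attr(x, "n_noise") %||% NA_integer_,
    median_length_nm = if (nrow(x)) median(x$length_nm) else NA_real_,
    median_eccentricity = if (nrow(x)) median(x$eccentricity) else NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
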