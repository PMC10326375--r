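blob <- function(n, cx, cy, spread = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cbind(rnorm(n, cx, spread), rnorm(n, cy, spread))
}

test_that("well-separated blobs form separate clusters and small sets are noise", {
  pts <- rbind(blob(20, 0, 0, seed = 1), blob(20, 6000, 0))
  labels <- dbscan_points(pts, eps = 60, min_pts = 5)
  expect_identical(length(unique(labels[labels > 0])), 2L)
  expect_true(all(labels[1:20] == labels[1]))
  expect_true(all(labels[21:40] == labels[21]))
  # fewer points than min_pts can never form a cluster
  few <- blob(3, 0, 0, seed = 2)
  expect_true(all(dbscan_points(few, eps = 60, min_pts = 5) == 0L))
  expect_identical(dbscan_points(matrix(numeric(), ncol = 2), 60, 5), integer())
})

test_that("the partition is invariant under translation and permutation", {
  set.seed(8)
  pts <- rbind(blob(30, 0, 0, 25), blob(25, 300, 300, 25), blob(10, -400, 100, 80))
  ref <- canonical_labels(dbscan_points(pts, eps = 60, min_pts = 5))
  moved <- canonical_labels(dbscan_points(pts + 1e5, eps = 60, min_pts = 5))
  expect_identical(ref, moved)
  perm <- sample(nrow(pts))
  shuffled <- dbscan_points(pts[perm, ], eps = 60, min_pts = 5)
  # same partition: co-membership must agree for every pair
  back <- integer(nrow(pts)); back[perm] <- shuffled
  expect_identical(outer(ref, ref, "==") & ref > 0,
                   outer(back, back, "==") & back > 0)
  expect_identical(ref > 0, back > 0)
})

test_that("every point is in exactly one cluster or noise", {
  set.seed(10)
  pts <- matrix(runif(300, 0, 1500), ncol = 2)
  labels <- dbscan_points(pts, eps = 80, min_pts = 4)
  sizes <- table(labels[labels > 0])
  expect_identical(sum(sizes) + sum(labels == 0), nrow(pts))
})

test_that("neighborhood counting includes the point itself", {
  # two points eps apart: each has 2 neighbors (self + other)
  pts <- rbind(c(0, 0), c(50, 0))
  expect_true(all(dbscan_points(pts, eps = 60, min_pts = 2) == 1L))
  expect_true(all(dbscan_points(pts, eps = 60, min_pts = 3) == 0L))
})

test_that("rendering produces a closed, translation-consistent occupancy grid", {
  one <- render_cluster(cbind(110, 70), render_pixel_nm = 20)
  expect_identical(sum(one), 1L)
  # collinear points closer than one render pixel give an unbroken line
  xs <- seq(0, 900, by = 15)
  line <- render_cluster(cbind(xs, 500), render_pixel_nm = 20)
  lab <- label_components(line)
  expect_identical(max(lab), 1L)
  # shifting by exactly one render pixel shifts the mask, not its shape
  shifted <- render_cluster(cbind(xs + 20, 500), render_pixel_nm = 20)
  expect_identical(dim(line), dim(shifted))
  expect_identical(sum(line), sum(shifted))
})

test_that("skeleton length handles junctions, loners and bad input", {
  # Y shape: one straight arm, two diagonal arms, all meeting at the center
  m <- matrix(FALSE, 41, 41)
  m[21, 21:31] <- TRUE
  for (i in 0:10) { m[21 - i, 21 - i] <- TRUE; m[21 + i, 21 - i] <- TRUE }
  expect_equal(skeleton_length(m, 20), (10 + 20 * sqrt(2)) * 20,
               tolerance = 1e-9)
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_equal(skeleton_length(single, 20), 20)
  expect_error(skeleton_length(matrix(FALSE, 4, 4), 20), "ON pixel")
})

test_that("cluster metrics match closed-form values on constructed sets", {
  square <- rbind(c(0, 0), c(100, 0), c(0, 100), c(100, 100))
  m <- cluster_metrics(square, render_pixel_nm = 20)
  expect_equal(m$hull_area_nm2, 10000)
  expect_equal(m$eccentricity, 0, tolerance = 1e-9)
  expect_identical(m$n_localizations, 4L)

  coll <- cbind(seq(0, 980, by = 20), seq(0, 980, by = 20) * 0.5)
  mc <- cluster_metrics(coll, render_pixel_nm = 20)
  expect_gte(mc$eccentricity, 0.99)
  expect_equal(mc$hull_area_nm2, 0)

  # compact dot-like cluster (point spread ~ 80 nm equivalent diameter):
  # thinning can only shorten, so skeleton length stays below the major axis
  set.seed(3)
  roundish <- blob(60, 500, 500, 20)
  mr <- cluster_metrics(roundish, render_pixel_nm = 20)
  expect_lte(mr$length_nm, mr$major_axis_nm)
  expect_gt(mr$area_nm2, 0)
})

test_that("cluster tables summarize aggregates and discard noise", {
  set.seed(4)
  pts <- rbind(blob(40, 0, 0, 30), blob(30, 2000, 2000, 30),
               matrix(runif(20, 4000, 9000), ncol = 2))
  cl <- cluster_localizations(tibble::tibble(x_nm = pts[, 1], y_nm = pts[, 2]),
                              eps = 100, min_pts = 5)
  expect_s3_class(cl, "agg_clusters")
  expect_identical(nrow(cl), 2L)
  expect_true(all(cl$n_localizations >= 5))
  g <- glance(cl)
  expect_identical(g$n_clusters, 2L)
  expect_gt(attr(cl, "n_noise"), 0L)
})
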