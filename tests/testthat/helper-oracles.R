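# Independent brute-force references used as oracles by the unit and
# acceptance tests. These deliberately share no code with the package
# implementations: all-pairs distance matrices, recursive flood fills and
# direct convolution sums at tiny n.

# Textbook DBSCAN with all-pairs neighborhoods (O(n^2)); points processed in
# input order, cluster expansion by FIFO queue.
brute_dbscan <- function(x, y, eps, min_pts) {
  n <- length(x)
  labels <- integer(n)
  if (!n) return(labels)
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  nb <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps^2))
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    if (length(nb[[i]]) < min_pts) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb[[i]], i)
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (labels[j] == 0L) labels[j] <- cl
      if (!visited[j]) {
        visited[j] <- TRUE
        if (length(nb[[j]]) >= min_pts) {
          queue <- c(queue, setdiff(nb[[j]], which(visited & labels != 0L)))
        }
      }
    }
  }
  labels
}

# canonical form of a labeling: clusters renumbered by first appearance
canonical_labels <- function(labels) {
  pos <- labels > 0
  out <- labels
  out[pos] <- match(labels[pos], unique(labels[pos]))
  out
}

# 8-connected component labeling by queue-based flood fill over foreground
brute_label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r, c)); lab[r, c] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          queue <- c(queue, list(c(rr, cc)))
        }
      }
    }
  }
  lab
}

# exhaustive strict-ish local maxima scan (pixel above all 8 neighbours);
# valid as a maxima count only for well-separated single-pixel peaks
brute_separated_maxima <- function(frame, floor = 0) {
  nr <- nrow(frame); nc <- ncol(frame)
  count <- 0L
  for (r in 2:(nr - 1)) for (c in 2:(nc - 1)) {
    v <- frame[r, c]
    if (v <= floor) next
    nbv <- frame[(r - 1):(r + 1), (c - 1):(c + 1)]
    if (v >= max(nbv) && sum(nbv == v) == 1L) count <- count + 1L
  }
  count
}

# direct O(n^2 k^2) linear convolution with replicated borders
brute_convolve <- function(frame, kernel) {
  nr <- nrow(frame); nc <- ncol(frame)
  kr <- (nrow(kernel) - 1L) %/% 2L; kc <- (ncol(kernel) - 1L) %/% 2L
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    acc <- 0
    for (i in -kr:kr) for (j in -kc:kc) {
      rr <- min(max(r + i, 1L), nr); cc <- min(max(c + j, 1L), nc)
      acc <- acc + frame[rr, cc] * kernel[kr + 1L + i, kc + 1L + j]
    }
    out[r, c] <- acc
  }
  out
}

# a frame with isolated Gaussian dots at given 0-based centers
fixture_dot_frame <- function(size, centers, amplitude = 1000, sigma = 2,
                              offset = 0) {
  f <- matrix(offset, size, size)
  for (i in seq_len(nrow(centers))) {
    ax <- 0:(size - 1)
    gx <- exp(-((ax - centers[i, 1])^2) / (2 * sigma^2))
    gy <- exp(-((ax - centers[i, 2])^2) / (2 * sigma^2))
    f <- f + amplitude * outer(gy, gx)
  }
  f
}
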