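# Independent oracles and fixture generators used across the suite.
# Everything here is deliberately written from the definitions, not by
# calling the package internals it is meant to check.

# --- segment geometry (oracle-side reimplementation) -----------------

oracle_seg_len <- function(s) sqrt((s[3] - s[1])^2 + (s[4] - s[2])^2)

oracle_angle_deg <- function(a, b) {
  d <- abs(atan2(a[4] - a[2], a[3] - a[1]) -
           atan2(b[4] - b[2], b[3] - b[1])) %% pi
  min(d, pi - d) * 180 / pi
}

oracle_pt_line_dist <- function(qx, qy, s) {
  vx <- s[3] - s[1]; vy <- s[4] - s[2]
  len <- sqrt(vx^2 + vy^2)
  if (len == 0) return(sqrt((qx - s[1])^2 + (qy - s[2])^2))
  abs(vx * (qy - s[2]) - vy * (qx - s[1])) / len
}

oracle_mergeable <- function(a, b, angle_deg, dist) {
  if (oracle_angle_deg(a, b) >= angle_deg) return(FALSE)
  close_cnt <- (oracle_pt_line_dist(a[1], a[2], b) < dist) +
    (oracle_pt_line_dist(a[3], a[4], b) < dist) +
    (oracle_pt_line_dist(b[1], b[2], a) < dist) +
    (oracle_pt_line_dist(b[3], b[4], a) < dist)
  close_cnt >= 2
}

# axis segment spanned by a group of original segments: length-weighted
# doubled-angle mean direction, extremal projections of all endpoints
# through their centroid
oracle_span <- function(group) {
  ls <- apply(group, 1, oracle_seg_len)
  th2 <- 2 * atan2(group[, 4] - group[, 2], group[, 3] - group[, 1])
  th <- atan2(sum(ls * sin(th2)), sum(ls * cos(th2))) / 2
  px <- c(group[, 1], group[, 3]); py <- c(group[, 2], group[, 4])
  cx <- mean(px); cy <- mean(py)
  pr <- (px - cx) * cos(th) + (py - cy) * sin(th)
  c(cx + min(pr) * cos(th), cy + min(pr) * sin(th),
    cx + max(pr) * cos(th), cy + max(pr) * sin(th))
}

# canonical form of a segment set for comparison: order endpoints
# within each segment lexicographically, then sort rows
canon_segments <- function(m, digits = 6) {
  if (is.data.frame(m)) m <- as.matrix(m[, c("x1", "y1", "x2", "y2")])
  if (nrow(m) == 0) return(m)
  flip <- m[, 1] > m[, 3] | (m[, 1] == m[, 3] & m[, 2] > m[, 4])
  m[flip, ] <- m[flip, c(3, 4, 1, 2)]
  m <- round(m, digits)
  m[order(m[, 1], m[, 2], m[, 3], m[, 4]), , drop = FALSE]
}

# exhaustive-order merge oracle: explore every sequence of pair merges
# to a fixed point, tracking for every working segment the group of
# original segments it spans; returns the list of distinct outcomes
# (canonical form)
oracle_merge_all_orders <- function(m, angle_deg, dist, tol = 1e-6) {
  outcomes <- list()
  recurse <- function(segs, groups) {
    n <- nrow(segs)
    pairs <- list()
    if (n >= 2) {
      for (i in seq_len(n - 1)) for (j in (i + 1):n)
        if (oracle_mergeable(segs[i, ], segs[j, ], angle_deg, dist))
          pairs[[length(pairs) + 1]] <- c(i, j)
    }
    if (length(pairs) == 0) {
      cn <- canon_segments(segs)
      for (o in outcomes)
        if (nrow(o) == nrow(cn) && all(abs(o - cn) < tol)) return(invisible())
      outcomes[[length(outcomes) + 1]] <<- cn
      return(invisible())
    }
    for (p in pairs) {
      grp <- rbind(groups[[p[1]]], groups[[p[2]]])
      recurse(rbind(segs[-p, , drop = FALSE], oracle_span(grp)),
              c(groups[-p], list(grp)))
    }
  }
  m <- as.matrix(m)
  recurse(m, lapply(seq_len(nrow(m)), function(i) m[i, , drop = FALSE]))
  outcomes
}

# random small merge instances: clusters of near-collinear segments
# with gaps/jitter plus unrelated strays
random_merge_instance <- function(n_max = 5) {
  n <- sample(2:n_max, 1)
  segs <- matrix(0, n, 4)
  i <- 1
  while (i <= n) {
    if (runif(1) < 0.7 && i < n) {       # a near-collinear cluster of 2
      x0 <- runif(1, 0, 60); y0 <- runif(1, 0, 60)
      th <- runif(1, 0, pi)
      l1 <- runif(1, 5, 25); gap <- runif(1, -3, 8); l2 <- runif(1, 5, 25)
      jit <- runif(1, -2, 2); dth <- runif(1, -0.12, 0.12)
      segs[i, ] <- c(x0, y0, x0 + l1 * cos(th), y0 + l1 * sin(th))
      s2 <- c(x0 + (l1 + gap) * cos(th) - jit * sin(th),
              y0 + (l1 + gap) * sin(th) + jit * cos(th))
      segs[i + 1, ] <- c(s2[1], s2[2],
                         s2[1] + l2 * cos(th + dth), s2[2] + l2 * sin(th + dth))
      i <- i + 2
    } else {                              # a stray segment
      x0 <- runif(1, 0, 60); y0 <- runif(1, 0, 60)
      th <- runif(1, 0, pi); l <- runif(1, 5, 30)
      segs[i, ] <- c(x0, y0, x0 + l * cos(th), y0 + l * sin(th))
      i <- i + 1
    }
  }
  data.frame(x1 = segs[, 1], y1 = segs[, 2], x2 = segs[, 3], y2 = segs[, 4])
}

# random blob mask for skeleton property tests
random_blob_mask <- function(ny = 40, nx = 40, n_blobs = 3) {
  m <- matrix(FALSE, ny, nx)
  for (b in seq_len(n_blobs)) {
    cy <- runif(1, 5, ny - 5); cx <- runif(1, 5, nx - 5)
    ry <- runif(1, 2, 8); rx <- runif(1, 2, 8)
    yy <- matrix(seq_len(ny), ny, nx); xx <- matrix(seq_len(nx), ny, nx,
                                                    byrow = TRUE)
    m <- m | ((yy - cy)^2 / ry^2 + (xx - cx)^2 / rx^2 < 1)
  }
  m
}

# minimal independent STAR grammar check: one data_ block, one loop_,
# label lines, then rows of equal field count
star_grammar_ok <- function(path) {
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln)]
  if (!grepl("^data_", ln[1])) return(FALSE)
  i <- which(ln == "loop_")
  if (length(i) != 1) return(FALSE)
  j <- i + 1
  n_lab <- 0
  while (j <= length(ln) && grepl("^_\\S+", ln[j])) {
    n_lab <- n_lab + 1; j <- j + 1
  }
  if (n_lab == 0) return(FALSE)
  while (j <= length(ln)) {
    if (length(strsplit(ln[j], "\\s+")[[1]]) != n_lab) return(FALSE)
    j <- j + 1
  }
  TRUE
}
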