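#' Binarize a score map
#'
#' Step 1 of the trace extraction: threshold the figure-of-merit image.
#' The comparison is strict, so a pixel is foreground exactly when its
#' score is greater than `threshold_t`.
#'
#' @param score_map a [score_map()].
#' @param threshold_t numeric threshold on the figure-of-merit.
#' @return logical matrix of the same shape as the score map.
#' @export
binarize <- function(score_map, threshold_t) {
  stopifnot(inherits(score_map, "score_map"), is.finite(threshold_t))
  score_map$values > threshold_t
}

# Shift a padded logical matrix by (dy, dx); used for vectorized
# neighbourhood lookups during thinning.
.shift <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(FALSE, ny, nx)
  ys <- max(1L, 1L - dy):min(ny, ny - dy)
  xs <- max(1L, 1L - dx):min(nx, nx - dx)
  out[ys, xs] <- m[ys + dy, xs + dx]
  out
}

#' Skeletonize a binary mask
#'
#' Step 2 of the trace extraction: thin the binarized score map to a
#' one-pixel-wide, 8-connected medial line using Zhang--Suen iterative
#' thinning.  The two sub-iterations delete border pixels from
#' alternating sides until a fixed point is reached, which makes the
#' operation idempotent and connectivity-preserving.
#'
#' @param mask logical matrix (foreground = `TRUE`).
#' @return logical matrix of the same shape; `TRUE` pixels are a subset
#'   of the input foreground.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) return(mask)
  m <- mask
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours clockwise from north: P2..P9
      p2 <- .shift(m, -1L,  0L); p3 <- .shift(m, -1L,  1L)
      p4 <- .shift(m,  0L,  1L); p5 <- .shift(m,  1L,  1L)
      p6 <- .shift(m,  1L,  0L); p7 <- .shift(m,  1L, -1L)
      p8 <- .shift(m,  0L, -1L); p9 <- .shift(m, -1L, -1L)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      # number of 0 -> 1 transitions around the ring P2,P3,...,P9,P2
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (step == 1L) {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Empty segment table with the canonical columns.
.empty_segments <- function() {
  data.frame(x1 = numeric(0), y1 = numeric(0),
             x2 = numeric(0), y2 = numeric(0))
}

#' Detect straight lines in a skeleton by a probabilistic Hough transform
#'
#' Step 3 of the trace extraction.  Skeleton pixels are visited in a
#' pseudo-random order fixed by `params$rng_seed`; each visited pixel
#' votes into a (rho, theta) accumulator with theta sampled at 1 degree
#' steps over [-90, 90).  When a pixel's best bin reaches
#' `params$hough_threshold` votes, the transform walks along the
#' corresponding line in both directions, bridging gaps of up to
#' `params$line_gap` pixels, and accepts the resulting segment if it is
#' at least `params$line_length_fl` pixels long.  Pixels of accepted
#' segments are removed from further consideration (their votes are
#' subtracted).
#'
#' @param skeleton logical matrix, typically output of [skeletonize()].
#' @param params a [picker_params()].
#' @return data frame with columns `x1`, `y1`, `x2`, `y2` (0-based
#'   pixel coordinates of segment endpoints).  May have zero rows.
#' @export
detect_lines <- function(skeleton, params) {
  stopifnot(is.matrix(skeleton), is.logical(skeleton),
            inherits(params, "picker_params"))
  idx <- which(skeleton)
  if (length(idx) == 0L) return(.empty_segments())

  # keep the caller's RNG stream untouched
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(params$rng_seed)

  ny <- nrow(skeleton); nx <- ncol(skeleton)
  mask <- skeleton
  voted <- matrix(FALSE, ny, nx)
  thetas <- (seq_len(180L) - 91L) * pi / 180   # -90 .. 89 degrees
  cth <- cos(thetas); sth <- sin(thetas)
  d_off <- as.integer(ceiling(sqrt(nx^2 + ny^2))) + 1L
  accum <- matrix(0L, nrow = 2L * d_off + 1L, ncol = 180L)
  theta_cols <- seq_len(180L)

  rho_rows <- function(x, y) as.integer(round(x * cth + y * sth)) + d_off + 1L

  # walk from (x0, y0) along (dx, dy); returns last foreground pixel
  walk <- function(x0, y0, dx, dy, gap) {
    lx <- x0; ly <- y0
    cx <- x0; cy <- y0
    miss <- 0L
    repeat {
      cx <- cx + dx; cy <- cy + dy
      px <- as.integer(round(cx)); py <- as.integer(round(cy))
      if (px < 0L || px >= nx || py < 0L || py >= ny) break
      if (mask[py + 1L, px + 1L]) {
        lx <- px; ly <- py
        miss <- 0L
      } else {
        miss <- miss + 1L
        if (miss > gap) break
      }
    }
    c(lx, ly)
  }

  # clear foreground pixels in a one-pixel corridor around the line
  # between two endpoints (the walk rounds to the nearest pixel, so
  # the skeleton pixels it traced may sit one off the exact line),
  # subtracting the votes of pixels that had already voted
  clear_line <- function(x1, y1, x2, y2) {
    n <- max(abs(x2 - x1), abs(y2 - y1))
    ts <- if (n == 0) 0 else seq(0, 1, length.out = n + 1L)
    cx <- as.integer(round(x1 + ts * (x2 - x1)))
    cy <- as.integer(round(y1 + ts * (y2 - y1)))
    for (k in seq_along(cx)) {
      for (oy in -1L:1L) for (ox in -1L:1L) {
        px <- cx[k] + ox; py <- cy[k] + oy
        if (px < 0L || px >= nx || py < 0L || py >= ny) next
        if (mask[py + 1L, px + 1L]) {
          mask[py + 1L, px + 1L] <<- FALSE
          if (voted[py + 1L, px + 1L]) {
            rr <- rho_rows(px, py)
            accum[cbind(rr, theta_cols)] <<- accum[cbind(rr, theta_cols)] - 1L
            voted[py + 1L, px + 1L] <<- FALSE
          }
        }
      }
    }
  }

  order_idx <- sample(idx)
  segs <- list()
  for (ii in order_idx) {
    if (!mask[ii]) next
    y0 <- (ii - 1L) %% ny          # 0-based row
    x0 <- (ii - 1L) %/% ny         # 0-based column
    rr <- rho_rows(x0, y0)
    cells <- cbind(rr, theta_cols)
    accum[cells] <- accum[cells] + 1L
    voted[ii] <- TRUE
    votes <- accum[cells]
    best <- which.max(votes)
    if (votes[best] < params$hough_threshold) next
    th <- thetas[best]
    # direction along the line (perpendicular to the normal), scaled so
    # that the dominant component steps by one pixel
    dx <- -sin(th); dy <- cos(th)
    den <- max(abs(dx), abs(dy))
    dx <- dx / den; dy <- dy / den
    e1 <- walk(x0, y0,  dx,  dy, params$line_gap)
    e2 <- walk(x0, y0, -dx, -dy, params$line_gap)
    len <- sqrt((e1[1] - e2[1])^2 + (e1[2] - e2[2])^2)
    if (len >= params$line_length_fl) {
      segs[[length(segs) + 1L]] <- c(e2[1], e2[2], e1[1], e1[2])
      clear_line(e2[1], e2[2], e1[1], e1[2])
    }
  }
  if (length(segs) == 0L) return(.empty_segments())
  out <- do.call(rbind, segs)
  data.frame(x1 = out[, 1], y1 = out[, 2], x2 = out[, 3], y2 = out[, 4])
}

# undirected angle (degrees, in [0, 90]) between two segments
.segment_angle_deg <- function(a, b) {
  ta <- atan2(a[4] - a[2], a[3] - a[1])
  tb <- atan2(b[4] - b[2], b[3] - b[1])
  d <- abs(ta - tb) %% pi
  min(d, pi - d) * 180 / pi
}

# perpendicular distance from point q to the infinite line through p1, p2
.point_line_dist <- function(qx, qy, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  len <- sqrt(vx^2 + vy^2)
  if (len == 0) return(sqrt((qx - x1)^2 + (qy - y1)^2))
  abs(vx * (qy - y1) - vy * (qx - x1)) / len
}

# merge criterion: mutual angle smaller than merge_angle_deg AND at
# least two of the four endpoints lie closer than merge_dist to the
# infinite supporting line of the other segment
.mergeable <- function(a, b, merge_angle_deg, merge_dist) {
  if (.segment_angle_deg(a, b) >= merge_angle_deg) return(FALSE)
  n_close <-
    (.point_line_dist(a[1], a[2], b[1], b[2], b[3], b[4]) < merge_dist) +
    (.point_line_dist(a[3], a[4], b[1], b[2], b[3], b[4]) < merge_dist) +
    (.point_line_dist(b[1], b[2], a[1], a[2], a[3], a[4]) < merge_dist) +
    (.point_line_dist(b[3], b[4], a[1], a[2], a[3], a[4]) < merge_dist)
  n_close >= 2
}

# axis segment spanned by a set of constituent segments: the
# length-weighted mean direction over the constituents (doubled-angle
# average, since segments are undirected), with every constituent
# endpoint projected onto that axis through their centroid and the two
# extremal projections kept.  Working from the original constituents
# rather than intermediate merge results makes the outcome independent
# of the order in which pairs were merged.
.span_segment <- function(constituents) {
  segs <- constituents
  lens <- sqrt((segs[, 3] - segs[, 1])^2 + (segs[, 4] - segs[, 2])^2)
  th <- atan2(segs[, 4] - segs[, 2], segs[, 3] - segs[, 1])
  mean_th <- atan2(sum(lens * sin(2 * th)), sum(lens * cos(2 * th))) / 2
  ux <- cos(mean_th); uy <- sin(mean_th)
  px <- c(segs[, 1], segs[, 3]); py <- c(segs[, 2], segs[, 4])
  cx <- mean(px); cy <- mean(py)
  proj <- (px - cx) * ux + (py - cy) * uy
  t1 <- min(proj); t2 <- max(proj)
  c(cx + t1 * ux, cy + t1 * uy, cx + t2 * ux, cy + t2 * uy)
}

#' Merge near-collinear line segments
#'
#' Step 4 of the trace extraction.  Two segments are merged when the
#' undirected angle between them is smaller than `merge_angle_deg` and
#' at least two of their four endpoints lie within `merge_dist` of the
#' infinite supporting line of the respective other segment.  Merging
#' replaces the pair by a single segment spanning the extremal
#' projections of all constituent endpoints onto their length-weighted
#' mean direction.  Pairs are scanned in index order with a restart
#' after every accepted merge, until no pair satisfies the criterion,
#' so the result is a deterministic fixed point and the operation is
#' idempotent.
#'
#' @param segments data frame with columns `x1`, `y1`, `x2`, `y2`.
#' @param merge_angle_deg merge angle in degrees, in (0, 90).
#' @param merge_dist merge distance in pixels, > 0.
#' @return data frame of merged segments (same columns); never more
#'   rows than the input.  Zero-length input segments are dropped.
#' @export
merge_lines <- function(segments, merge_angle_deg = 10, merge_dist) {
  stopifnot(is.data.frame(segments),
            all(c("x1", "y1", "x2", "y2") %in% names(segments)),
            merge_angle_deg > 0, merge_angle_deg < 90, merge_dist > 0)
  m <- as.matrix(segments[, c("x1", "y1", "x2", "y2")])
  if (nrow(m) > 0) {
    lens <- sqrt((m[, 3] - m[, 1])^2 + (m[, 4] - m[, 2])^2)
    m <- m[lens > 0, , drop = FALSE]
  }
  # each working segment carries the set of original segments it spans
  parts <- lapply(seq_len(nrow(m)), function(i) m[i, , drop = FALSE])
  repeat {
    n <- nrow(m)
    merged_any <- FALSE
    if (n >= 2L) {
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          if (.mergeable(m[i, ], m[j, ], merge_angle_deg, merge_dist)) {
            grp <- rbind(parts[[i]], parts[[j]])
            new_seg <- .span_segment(grp)
            m <- rbind(m[-c(i, j), , drop = FALSE], new_seg)
            parts <- c(parts[-c(i, j)], list(grp))
            merged_any <- TRUE
            break
          }
        }
        if (merged_any) break
      }
    }
    if (!merged_any) break
  }
  rownames(m) <- NULL
  data.frame(x1 = m[, 1], y1 = m[, 2], x2 = m[, 3], y2 = m[, 4])
}

#' Extract filament traces from a score map
#'
#' Runs the full four-step extraction -- [binarize()], [skeletonize()],
#' [detect_lines()], [merge_lines()] -- and rescales the merged segment
#' endpoints from down-sampled score-map pixels to original micrograph
#' pixels using the centre-preserving convention
#' `x_mic = (x_ds + 0.5) * downsample_factor - 0.5`.
#'
#' @param score_map a [score_map()].
#' @param params a [picker_params()].
#' @param details if `TRUE`, also return the intermediate results of
#'   the four steps (used by the diagnostic panel).
#' @return a data frame of filament traces with columns `x_start`,
#'   `y_start`, `x_end`, `y_end` (original-micrograph pixels) and
#'   `tube_id` (consecutive from 1).  With `details = TRUE`, a list
#'   with elements `traces`, `mask`, `skeleton`, `segments`, `merged`.
#' @examples
#' v <- matrix(-10, 40, 60)
#' v[19:21, 6:55] <- 0            # one horizontal high-scoring band
#' sm <- score_map(v, downsample_factor = 8)
#' extract_traces(sm, picker_params(threshold_t = -6, radius_r = 6))
#' @export
extract_traces <- function(score_map, params, details = FALSE) {
  stopifnot(inherits(score_map, "score_map"),
            inherits(params, "picker_params"))
  mask <- binarize(score_map, params$threshold_t)
  skel <- skeletonize(mask)
  segs <- detect_lines(skel, params)
  merged <- merge_lines(segs, params$merge_angle_deg, params$merge_dist)
  f <- score_map$downsample_factor
  traces <- data.frame(
    x_start = (merged$x1 + 0.5) * f - 0.5,
    y_start = (merged$y1 + 0.5) * f - 0.5,
    x_end   = (merged$x2 + 0.5) * f - 0.5,
    y_end   = (merged$y2 + 0.5) * f - 0.5,
    tube_id = seq_len(nrow(merged)))
  if (!details) return(traces)
  list(traces = traces, mask = mask, skeleton = skel,
       segments = segs, merged = merged)
}
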