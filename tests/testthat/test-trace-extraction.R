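test_that("binarization is a strict per-pixel threshold", {
  sm <- score_map(matrix(-10, 5, 5))
  expect_false(any(binarize(sm, -6)))

  v <- matrix(-10, 3, 3); v[2, 2] <- 0
  m <- binarize(score_map(v), -6)
  expect_identical(sum(m), 1L)
  expect_true(m[2, 2])

  # brute-force per-pixel comparison oracle on a random map at a
  # threshold inside the typical figure-of-merit operating range
  set.seed(42)
  v <- matrix(rnorm(64 * 64, mean = -6, sd = 2), 64, 64)
  m <- binarize(score_map(v), -6)
  n_oracle <- 0L
  for (i in seq_len(64)) for (j in seq_len(64))
    if (v[i, j] > -6) n_oracle <- n_oracle + 1L
  expect_identical(sum(m), n_oracle)
  # boundary pixels: exactly equal scores are background
  v[1, 1] <- -6
  expect_false(binarize(score_map(v), -6)[1, 1])
})

test_that("skeletonization thins a bar to its centre row, matching the reference thinning", {
  expect_false(any(skeletonize(matrix(FALSE, 8, 8))))

  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  expect_identical(skeletonize(m), m)

  # 3-pixel-wide horizontal bar spanning a 7x40 grid; frozen output of
  # an independent Zhang-style thinning implementation on the same bar
  bar <- matrix(FALSE, 7, 40); bar[3:5, 4:37] <- TRUE
  sk <- skeletonize(bar)
  got <- which(sk, arr.ind = TRUE) - 1L          # 0-based (y, x)
  ref <- rbind(c(2L, 35L), cbind(3L, 3:34))      # reference thinning
  expect_true(all(sk[bar == FALSE] == FALSE))    # skeleton within mask
  # agreement up to 2 px at the bar ends (end-pixel conventions of
  # Zhang-variant thinners differ), exact along the centre row
  dmat <- function(a, b) outer(seq_len(nrow(a)), seq_len(nrow(b)),
    function(i, j) pmax(abs(a[i, 1] - b[j, 1]), abs(a[i, 2] - b[j, 2])))
  expect_lte(max(apply(dmat(got, ref), 1, min)), 2)
  expect_lte(max(apply(dmat(ref, got), 1, min)), 2)
  expect_true(all(got[, 1] %in% 2:4))
  centre <- got[got[, 1] == 3L, , drop = FALSE]
  expect_gte(nrow(centre), 28)                   # ~the 1-px centre row
})

test_that("skeletonization is idempotent and stays inside the mask", {
  set.seed(7)
  for (rep in 1:10) {
    m <- random_blob_mask()
    sk <- skeletonize(m)
    expect_true(all(m[sk]))                      # skeleton subset of mask
    expect_identical(skeletonize(sk), sk)        # fixed point
  }
})

test_that("line detection recovers a straight run and honours the minimum length", {
  skel <- matrix(FALSE, 60, 60)
  skel[30, 6:55] <- TRUE                         # 50-px horizontal run
  p <- picker_params(threshold_t = 0, radius_r = 12)
  segs <- detect_lines(skel, p)
  expect_identical(nrow(segs), 1L)
  # least-squares fit oracle: run is y = 29 (0-based), x in [5, 54]
  expect_lte(abs(segs$y1[1] - 29), 1)
  expect_lte(abs(segs$y2[1] - 29), 1)
  xs <- sort(c(segs$x1[1], segs$x2[1]))
  expect_lte(abs(xs[1] - 5), 1)
  expect_lte(abs(xs[2] - 54), 1)
  ang <- atan2(segs$y2[1] - segs$y1[1], segs$x2[1] - segs$x1[1]) * 180 / pi
  expect_lte(min(abs(ang), abs(180 - abs(ang))), 1)

  # longest straight run below the minimum length: nothing is returned
  skel2 <- matrix(FALSE, 60, 60)
  skel2[30, 10:19] <- TRUE                       # 10 px < fl = 24
  expect_identical(nrow(detect_lines(skel2, p)), 0L)
})

test_that("picker parameter defaults follow the radius-derived rules", {
  p <- picker_params(threshold_t = -6, radius_r = 12)
  expect_identical(p$line_length_fl, 24L)
  expect_identical(p$hough_threshold, 2L)
  expect_identical(p$line_gap, 12L)
  expect_identical(p$merge_dist, 12)
  expect_identical(p$merge_angle_deg, 10)
  # the accumulator threshold never drops below one
  expect_identical(picker_params(0, radius_r = 2)$hough_threshold, 1L)
})

test_that("line detection is deterministic for a fixed seed", {
  set.seed(99)
  skel <- random_blob_mask(60, 60, 4)
  skel <- skeletonize(skel)
  p <- picker_params(threshold_t = 0, radius_r = 3, rng_seed = 5)
  expect_identical(detect_lines(skel, p), detect_lines(skel, p))
})

test_that("segment endpoints lie on or within one pixel of the skeleton", {
  set.seed(11)
  skel <- matrix(FALSE, 80, 80)
  for (k in 1:3) {
    y0 <- sample(10:70, 1)
    skel[y0, 10:70] <- TRUE
  }
  skel <- skeletonize(skel)
  p <- picker_params(threshold_t = 0, radius_r = 8)
  segs <- detect_lines(skel, p)
  expect_gt(nrow(segs), 0L)
  on_skel <- which(skel, arr.ind = TRUE) - 1L
  for (i in seq_len(nrow(segs))) {
    for (ep in list(c(segs$x1[i], segs$y1[i]), c(segs$x2[i], segs$y2[i]))) {
      d <- min(pmax(abs(on_skel[, 1] - ep[2]), abs(on_skel[, 2] - ep[1])))
      expect_lte(d, 1)
    }
  }
})

test_that("merging obeys the angle and distance criterion on worked examples", {
  seg <- function(...) {
    m <- matrix(c(...), ncol = 4, byrow = TRUE)
    data.frame(x1 = m[, 1], y1 = m[, 2], x2 = m[, 3], y2 = m[, 4])
  }
  # collinear, abutting: merged into a single span
  out <- merge_lines(seg(0, 0, 10, 0, 12, 0, 30, 0), 10, 5)
  expect_identical(nrow(out), 1L)
  expect_equal(canon_segments(out), canon_segments(seg(0, 0, 30, 0)),
               tolerance = 1e-6, ignore_attr = TRUE)
  # perpendicular, crossing: 90 degrees is not smaller than 10
  out <- merge_lines(seg(0, 0, 20, 0, 10, -10, 10, 10), 10, 5)
  expect_identical(nrow(out), 2L)
  # parallel but offset beyond the merge distance
  out <- merge_lines(seg(0, 0, 20, 0, 0, 7, 20, 7), 10, 5)
  expect_identical(nrow(out), 2L)
  # chain of three near-collinear segments collapses to one, equal to
  # the exhaustive-order oracle
  chain <- seg(0, 0, 10, 0.2,  12, 0.1, 21, -0.1,  23.5, 0, 35, 0.3)
  out <- merge_lines(chain, 10, 5)
  expect_identical(nrow(out), 1L)
  oc <- oracle_merge_all_orders(chain[, 1:4], 10, 5)
  expect_length(oc, 1L)
  expect_equal(canon_segments(out), oc[[1]], tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("merging is idempotent, never increases counts, respects the angle bound", {
  set.seed(123)
  for (rep in 1:50) {
    segs <- random_merge_instance()
    out <- merge_lines(segs, 10, 5)
    expect_lte(nrow(out), nrow(segs))
    out2 <- merge_lines(out, 10, 5)
    expect_equal(canon_segments(out2), canon_segments(out),
                 tolerance = 1e-9, ignore_attr = TRUE)
    # no remaining pair satisfies the merge criterion
    m <- as.matrix(out)
    if (nrow(m) >= 2) {
      for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):nrow(m))
        expect_false(oracle_mergeable(m[i, ], m[j, ], 10, 5))
    }
  }
})

test_that("merging drops zero-length segments before merging", {
  segs <- data.frame(x1 = c(0, 5), y1 = c(0, 5), x2 = c(0, 25), y2 = c(0, 5))
  out <- merge_lines(segs, 10, 5)
  expect_identical(nrow(out), 1L)
  expect_equal(unname(as.numeric(out[1, ])), c(5, 5, 25, 5))
})

test_that("trace extraction composes the four steps and rescales to micrograph pixels", {
  # all-background map
  sm <- score_map(matrix(-10, 32, 32), downsample_factor = 8)
  p <- picker_params(threshold_t = -6, radius_r = 6)
  expect_identical(nrow(extract_traces(sm, p)), 0L)

  # one high-scoring straight band; manual rescaling oracle at factor 8
  v <- matrix(-10, 40, 60)
  v[19:21, 6:55] <- 0
  sm <- score_map(v, downsample_factor = 8)
  det <- extract_traces(sm, p, details = TRUE)
  expect_identical(nrow(det$traces), 1L)
  expect_equal(det$traces$x_start[1], (det$merged$x1[1] + 0.5) * 8 - 0.5)
  expect_equal(det$traces$y_start[1], (det$merged$y1[1] + 0.5) * 8 - 0.5)
  expect_equal(det$traces$x_end[1], (det$merged$x2[1] + 0.5) * 8 - 0.5)
  expect_identical(det$traces$tube_id, 1L)
})

test_that("clean high-scoring bands are traced to within a pixel and two degrees", {
  # three well-separated straight bands painted directly into a score
  # map: the contract domain of the four extraction steps
  ny <- 192L; nx <- 192L
  v <- matrix(-5, ny, nx)
  lines <- list(c(20, 30, 160, 55),      # shallow
                c(35, 170, 120, 65),     # steep diagonal
                c(150, 170, 175, 40))    # near-vertical
  paint <- function(v, g) {
    n <- ceiling(max(abs(g[3] - g[1]), abs(g[4] - g[2])))
    for (t in seq(0, 1, length.out = n + 1L))
      for (oy in -2:2) for (ox in -2:2) {
        px <- round(g[1] + t * (g[3] - g[1])) + ox
        py <- round(g[2] + t * (g[4] - g[2])) + oy
        if (px >= 0 && px < nx && py >= 0 && py < ny) v[py + 1, px + 1] <- 5
      }
    v
  }
  for (g in lines) v <- paint(v, g)
  sm <- score_map(v, downsample_factor = 1L)
  traces <- extract_traces(sm, picker_params(threshold_t = 0, radius_r = 6))
  expect_identical(nrow(traces), 3L)
  total_len <- 0; truth_len <- 0
  for (i in seq_len(nrow(traces))) {
    ta <- atan2(traces$y_end[i] - traces$y_start[i],
                traces$x_end[i] - traces$x_start[i]) * 180 / pi
    best_d <- Inf; best_a <- Inf
    for (g in lines) {
      vx <- g[3] - g[1]; vy <- g[4] - g[2]
      mx <- (traces$x_start[i] + traces$x_end[i]) / 2
      my <- (traces$y_start[i] + traces$y_end[i]) / 2
      d <- abs(vx * (my - g[2]) - vy * (mx - g[1])) / sqrt(vx^2 + vy^2)
      a <- abs(ta - atan2(vy, vx) * 180 / pi) %% 180
      a <- min(a, 180 - a)
      if (d < best_d) { best_d <- d; best_a <- a }
    }
    expect_lte(best_d, 1)          # within one (down-sampled) pixel
    expect_lte(best_a, 2)          # within two degrees
    total_len <- total_len + sqrt((traces$x_end[i] - traces$x_start[i])^2 +
                                  (traces$y_end[i] - traces$y_start[i])^2)
  }
  for (g in lines)
    truth_len <- truth_len + sqrt((g[3] - g[1])^2 + (g[4] - g[2])^2)
  expect_gte(total_len / truth_len, 0.95)
})

test_that("zero-noise simulated micrographs are covered nearly completely", {
  for (s in c(21L, 22L)) {
    spec <- simulation_spec(image_shape = c(1024L, 1024L), n_filaments = 3L,
                            curvature_max = 0, noise_sigma = 0, rng_seed = s)
    sim <- simulate_micrograph(spec)
    sm <- surrogate_score_map(sim$image, width_A = 120,
                              downsample_factor = 4L)
    r <- radius_pixels(120, sim$image$pixel_size_A * 4)
    traces <- extract_traces(sm, picker_params(threshold_t = 1.5,
                                               radius_r = r))
    m <- evaluate_picks(traces, sim$truth, dist_tol_px = r * 4,
                        angle_tol_deg = 10)
    expect_gte(m$coverage, 0.95)
  }
})
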