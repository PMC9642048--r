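#' Specification of a synthetic filament micrograph
#'
#' Describes a simulated cryo-EM micrograph containing dark filaments
#' whose apparent width modulates along the filament axis.  A twisting
#' filament with an anisotropic cross-section repeats its projected
#' width twice per full crossover, so the width oscillates between
#' `width_min_A` and `width_max_A` with an arc-length period of
#' `crossover_A / 2`.  Three phenotypes are emulated: `"good"`
#' (sinusoidal width modulation), `"swollen"` (blobby, random smooth
#' width variation, as seen for damaged filaments) and `"ribbon"`
#' (non-twisting flat ribbons of constant projected width; forces
#' `width_min_A = width_max_A`).
#'
#' The defaults describe the study conditions used throughout the
#' package tests: a 1024 x 1024 px field at 2 A/px containing five
#' tau-like filaments of 60--160 A apparent width with a 720 A
#' crossover, unit filament contrast and additive Gaussian noise of
#' standard deviation 0.5.
#'
#' @param image_shape integer vector `(height, width)` in pixels.
#' @param pixel_size_A pixel size in Angstrom.
#' @param n_filaments number of filaments to draw.
#' @param width_max_A,width_min_A apparent-width extremes in Angstrom.
#' @param crossover_A crossover distance in Angstrom; the width
#'   modulation period is half of it.
#' @param curvature_max maximal centreline curvature, radians per
#'   100 Angstrom of arc.  The default corresponds to a curvature
#'   radius of 2 micrometres, at the floppy end of what amyloid
#'   filaments (persistence lengths of micrometres and above) show in
#'   micrographs.
#' @param contrast filament depth below the background at the mean
#'   apparent width, arbitrary density units; the local depth scales
#'   inversely with the local width (see [simulate_micrograph()]).
#' @param noise_sigma standard deviation of the additive Gaussian
#'   noise, same units as `contrast`.
#' @param phenotype one of `"good"`, `"swollen"`, `"ribbon"`.
#' @param rng_seed integer seed; simulation is bit-reproducible for a
#'   fixed seed and spec.
#' @return an object of class `simulation_spec`.
#' @export
simulation_spec <- function(image_shape = c(1024L, 1024L),
                            pixel_size_A = 2.0,
                            n_filaments = 5L,
                            width_max_A = 160,
                            width_min_A = 60,
                            crossover_A = 720,
                            curvature_max = 0.005,
                            contrast = 1.0,
                            noise_sigma = 0.5,
                            phenotype = c("good", "swollen", "ribbon"),
                            rng_seed = 1L) {
  phenotype <- match.arg(phenotype)
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape < 16L))
    stop("image_shape must be (height, width), both >= 16")
  if (phenotype == "ribbon") width_min_A <- width_max_A
  if (width_min_A > width_max_A)
    stop("width_min_A must not exceed width_max_A")
  if (width_min_A <= 0 || crossover_A <= 0 || pixel_size_A <= 0)
    stop("lengths must be positive")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (curvature_max < 0) stop("curvature_max must be >= 0")
  if (n_filaments < 0) stop("n_filaments must be >= 0")
  structure(
    list(image_shape = image_shape, pixel_size_A = pixel_size_A,
         n_filaments = as.integer(n_filaments),
         width_max_A = width_max_A, width_min_A = width_min_A,
         crossover_A = crossover_A, curvature_max = curvature_max,
         contrast = contrast, noise_sigma = noise_sigma,
         phenotype = phenotype, rng_seed = as.integer(rng_seed)),
    class = "simulation_spec")
}

# trace one circular-arc centreline through the field of view;
# returns a data frame with 0-based pixel coords and arc length in px
.trace_centreline <- function(x0, y0, phi0, kappa_px, nx, ny, step_px = 2) {
  walk_dir <- function(x, y, phi, kappa) {
    xs <- numeric(0); ys <- numeric(0)
    repeat {
      x <- x + step_px * cos(phi)
      y <- y + step_px * sin(phi)
      if (x < 0 || x > nx - 1 || y < 0 || y > ny - 1) break
      xs <- c(xs, x); ys <- c(ys, y)
      phi <- phi + kappa * step_px
      if (length(xs) > (nx + ny)) break   # safety for tight circles
    }
    cbind(xs, ys)
  }
  fwd <- walk_dir(x0, y0, phi0, kappa_px)
  bwd <- walk_dir(x0, y0, phi0 + pi, -kappa_px)
  pts <- rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
               c(x0, y0),
               fwd)
  data.frame(x = pts[, 1], y = pts[, 2],
             s_px = (seq_len(nrow(pts)) - 1L) * step_px)
}

# smooth random modulation profile in [-1, 1] for the swollen phenotype
.blob_profile <- function(s_A, ctrl_spacing_A = 150) {
  n_ctrl <- max(4L, ceiling(max(s_A) / ctrl_spacing_A) + 1L)
  ctrl_s <- seq(0, max(s_A) + ctrl_spacing_A, length.out = n_ctrl)
  ctrl_v <- rnorm(n_ctrl)
  v <- approx(ctrl_s, ctrl_v, xout = s_A, rule = 2)$y
  mx <- max(abs(v))
  if (mx > 0) v / mx else v
}

#' Simulate a filament micrograph with ground truth
#'
#' Renders `spec$n_filaments` dark filaments on a zero background.
#' Each filament is a circular-arc centreline (curvature drawn
#' uniformly within `spec$curvature_max`) crossing the field of view,
#' rendered as a Gaussian-profile ridge whose full width at half
#' maximum follows the phenotype's width profile along the arc.  The
#' ridge depth scales inversely with the local apparent width (the
#' projected mass per unit length is constant), so narrow edge-on
#' sections appear strong and wide flat-on sections appear weak --
#' the alternating strong/weak signal that twisted filaments show in
#' micrographs, and the uniformly faint appearance of non-twisting
#' flat ribbons.  `spec$contrast` is the depth at the mean of the two
#' width extremes.  Additive Gaussian pixel noise of standard
#' deviation `spec$noise_sigma` is applied last.
#'
#' @param spec a [simulation_spec()].
#' @return a list with elements `image` (a [micrograph()]) and `truth`
#'   (class `ground_truth`: `polylines`, a list of per-filament
#'   centreline data frames with 0-based pixel coordinates and arc
#'   length, plus the per-filament parameters as drawn).
#' @export
simulate_micrograph <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(spec$rng_seed)

  ny <- spec$image_shape[1]; nx <- spec$image_shape[2]
  pix <- spec$pixel_size_A
  canvas <- matrix(0, ny, nx)
  fwhm_to_sigma <- 1 / (2 * sqrt(2 * log(2)))
  polylines <- list()
  fil_params <- list()

  for (k in seq_len(spec$n_filaments)) {
    x0 <- runif(1, 0, nx - 1)
    y0 <- runif(1, 0, ny - 1)
    phi0 <- runif(1, 0, 2 * pi)
    kappa_A <- runif(1, -spec$curvature_max, spec$curvature_max) / 100
    kappa_px <- kappa_A * pix
    phase <- runif(1, 0, 2 * pi)
    cl <- .trace_centreline(x0, y0, phi0, kappa_px, nx, ny)
    s_A <- cl$s_px * pix
    mid <- (spec$width_max_A + spec$width_min_A) / 2
    amp <- (spec$width_max_A - spec$width_min_A) / 2
    w_A <- switch(spec$phenotype,
      good    = mid + amp * sin(2 * pi * s_A / (spec$crossover_A / 2) + phase),
      swollen = mid + amp * .blob_profile(s_A),
      ribbon  = rep(spec$width_max_A, length(s_A)))
    sigma_px <- pmax(w_A * fwhm_to_sigma / pix, 0.5)
    # constant mass per unit length: depth inversely tracks the width,
    # normalised so that depth = contrast at the mean width
    ref_w <- (spec$width_max_A + spec$width_min_A) / 2
    depth <- spec$contrast * ref_w / w_A

    for (i in seq_len(nrow(cl))) {
      s <- sigma_px[i]
      h <- ceiling(3 * s)
      cxi <- cl$x[i]; cyi <- cl$y[i]
      xs <- max(0L, floor(cxi - h)):min(nx - 1L, ceiling(cxi + h))
      ys <- max(0L, floor(cyi - h)):min(ny - 1L, ceiling(cyi + h))
      dx2 <- (xs - cxi)^2
      dy2 <- (ys - cyi)^2
      contrib <- depth[i] * exp(-outer(dy2, dx2, "+") / (2 * s^2))
      sub <- canvas[ys + 1L, xs + 1L, drop = FALSE]
      canvas[ys + 1L, xs + 1L] <- pmax(sub, contrib)
    }
    polylines[[k]] <- cl
    fil_params[[k]] <- list(curvature_per_100A = kappa_A * 100,
                            width_phase = phase)
  }

  img <- -canvas
  if (spec$noise_sigma > 0)
    img <- img + matrix(rnorm(ny * nx, sd = spec$noise_sigma), ny, nx)
  list(
    image = micrograph(img, pixel_size_A = pix,
                       source_name = sprintf("synthetic_seed%d", spec$rng_seed)),
    truth = structure(list(polylines = polylines, params = fil_params,
                           spec = spec),
                      class = "ground_truth"))
}

# block-average a matrix by an integer factor (trailing rows/cols
# beyond a full block are cropped)
.block_mean <- function(m, f) {
  if (f == 1L) return(m)
  ny <- (nrow(m) %/% f) * f
  nx <- (ncol(m) %/% f) * f
  m <- m[seq_len(ny), seq_len(nx), drop = FALSE]
  gy <- rep(seq_len(ny %/% f), each = f)
  gx <- rep(seq_len(nx %/% f), each = f)
  t(rowsum(t(rowsum(m, gy)), gx)) / f^2
}

.gauss_smooth <- function(m, sigma_px) {
  size <- 2L * as.integer(ceiling(3 * sigma_px)) + 1L
  size <- min(size, 2L * (min(dim(m)) %/% 2L) - 1L)
  if (size < 3L) return(m)
  br <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma_px)
  EBImage::filter2(m, br, boundary = "replicate")
}

# oriented matched line kernel: second derivative of a Gaussian across
# the filament (scale sigma_px) times a Gaussian along it (sigma_along),
# rotated to angle theta; positive response on dark ridges after
# convolving the negated image, scale-normalised by sigma^2
.line_kernel <- function(theta, sigma_px, sigma_along, max_h = Inf) {
  h <- min(ceiling(3 * sigma_along), max_h)
  ax <- seq(-h, h)
  xx <- matrix(ax, 2 * h + 1L, 2 * h + 1L, byrow = TRUE)
  yy <- matrix(ax, 2 * h + 1L, 2 * h + 1L)
  u <- -xx * sin(theta) + yy * cos(theta)   # across the line
  v <-  xx * cos(theta) + yy * sin(theta)   # along the line
  k <- sigma_px^2 * (u^2 / sigma_px^4 - 1 / sigma_px^2) *
    exp(-u^2 / (2 * sigma_px^2)) * exp(-v^2 / (2 * sigma_along^2))
  k - mean(k)                               # flat background scores zero
}

#' Surrogate ridge scorer
#'
#' Converts a micrograph into a figure-of-merit score map so that the
#' trace extraction can be exercised without an external neural-network
#' scorer.  The micrograph is block-averaged by `downsample_factor`,
#' then matched oriented line filters (second derivative of a Gaussian
#' across the filament, Gaussian-weighted integration along it) are
#' evaluated over a bank of orientations and over scales of half and
#' full `width_A`, and the strongest response per pixel is kept, so
#' that filaments whose apparent width modulates along the axis score
#' consistently.  The sign convention makes dark filaments score high,
#' and the result is standardised to zero mean and unit variance.  A
#' zero-variance (blank) image yields an all-zero score map.
#'
#' @param image a [micrograph()].
#' @param width_A expected filament width in Angstrom (the central
#'   matched scale of the ridge filter).
#' @param downsample_factor positive integer down-sampling factor.
#' @return a [score_map()] whose `pixel_size_A` is the micrograph's
#'   (original) pixel size.
#' @export
surrogate_score_map <- function(image, width_A, downsample_factor = 4L) {
  stopifnot(inherits(image, "micrograph"))
  downsample_factor <- as.integer(downsample_factor)
  if (is.na(downsample_factor) || downsample_factor < 1L)
    stop("downsample_factor must be >= 1")
  if (!is.finite(width_A) || width_A <= 0) stop("width_A must be > 0")
  ds_pix <- image$pixel_size_A * downsample_factor
  sigma_c <- width_A / (2 * sqrt(2 * log(2))) / ds_pix
  if (sigma_c < 0.5) {
    warning("filament width below one down-sampled pixel; clamping")
    sigma_c <- 0.5
  }
  ds <- .block_mean(image$values, downsample_factor)
  sigma_along <- 3 * sigma_c
  max_h <- (min(dim(ds)) - 1L) %/% 2L   # kernel must fit the image
  thetas <- seq(0, pi, length.out = 13L)[-13L]
  score <- NULL
  for (sigma in pmax(0.5, sigma_c * c(0.5, 1))) {
    for (th in thetas) {
      resp <- EBImage::filter2(ds,
                               .line_kernel(th, sigma, sigma_along, max_h),
                               boundary = "replicate")
      score <- if (is.null(score)) resp else pmax(score, resp)
    }
  }
  s <- sd(as.numeric(score))
  score <- if (s < 1e-12) score * 0 else (score - mean(score)) / s
  score_map(score, downsample_factor = downsample_factor,
            pixel_size_A = image$pixel_size_A)
}

# minimum distance from points (px, py) to segments (x1,y1)-(x2,y2);
# all arguments recycle
.point_segment_dist <- function(px, py, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  l2 <- pmax(vx^2 + vy^2, .Machine$double.eps)
  t <- pmin(1, pmax(0, ((px - x1) * vx + (py - y1) * vy) / l2))
  sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2)
}

# distance from one point to a polyline plus local tangent angle (deg)
.point_polyline_dist <- function(px, py, poly) {
  n <- nrow(poly)
  if (n == 1L)
    return(list(dist = sqrt((px - poly$x)^2 + (py - poly$y)^2), angle = 0))
  d <- .point_segment_dist(rep(px, n - 1L), rep(py, n - 1L),
                           poly$x[-n], poly$y[-n], poly$x[-1], poly$y[-1])
  i <- which.min(d)
  ang <- atan2(poly$y[i + 1L] - poly$y[i], poly$x[i + 1L] - poly$x[i]) *
    180 / pi
  list(dist = d[i], angle = ang)
}

.undirected_diff_deg <- function(a, b) {
  d <- abs(a - b) %% 180
  min(d, 180 - d)
}

#' Evaluate picked traces against simulation ground truth
#'
#' A trace counts as a true positive when both of its endpoints lie
#' within `dist_tol_px` of the same ground-truth centreline and its
#' direction is within `angle_tol_deg` of the local centreline
#' direction at both endpoints.  Traces are matched greedily in order
#' of decreasing length (ties broken by `tube_id`).  Coverage is the
#' fraction of ground-truth arc length lying within `dist_tol_px` of
#' some true-positive trace; `recall_by_length` is the length-weighted
#' fraction of ground-truth filaments at least half covered.  An empty
#' trace list yields precision 1 (by convention) and coverage 0.
#'
#' @param traces data frame of traces (micrograph pixels).
#' @param truth `ground_truth` object from [simulate_micrograph()].
#' @param dist_tol_px distance tolerance in micrograph pixels.
#' @param angle_tol_deg angular tolerance in degrees.
#' @return list with `precision`, `recall_by_length`, `coverage`,
#'   `n_traces`, `n_true_positive`.
#' @export
evaluate_picks <- function(traces, truth, dist_tol_px, angle_tol_deg = 10) {
  stopifnot(inherits(truth, "ground_truth"),
            dist_tol_px > 0, angle_tol_deg > 0)
  polys <- truth$polylines
  if (length(polys) == 0L) stop("empty ground truth")

  n_tr <- nrow(traces)
  tp <- logical(n_tr)
  if (n_tr > 0L) {
    lens <- sqrt((traces$x_end - traces$x_start)^2 +
                 (traces$y_end - traces$y_start)^2)
    ord <- order(-lens, traces$tube_id)
    for (i in ord) {
      ta <- atan2(traces$y_end[i] - traces$y_start[i],
                  traces$x_end[i] - traces$x_start[i]) * 180 / pi
      for (p in polys) {
        m1 <- .point_polyline_dist(traces$x_start[i], traces$y_start[i], p)
        if (m1$dist > dist_tol_px) next
        m2 <- .point_polyline_dist(traces$x_end[i], traces$y_end[i], p)
        if (m2$dist > dist_tol_px) next
        if (.undirected_diff_deg(ta, m1$angle) <= angle_tol_deg &&
            .undirected_diff_deg(ta, m2$angle) <= angle_tol_deg) {
          tp[i] <- TRUE
          break
        }
      }
    }
  }

  # coverage of truth arc length by true-positive traces
  tp_idx <- which(tp)
  cov_per <- numeric(length(polys))
  len_per <- numeric(length(polys))
  for (j in seq_along(polys)) {
    p <- polys[[j]]
    len_per[j] <- max(p$s_px)
    covered <- rep(FALSE, nrow(p))
    for (i in tp_idx) {
      d <- .point_segment_dist(p$x, p$y,
                               traces$x_start[i], traces$y_start[i],
                               traces$x_end[i], traces$y_end[i])
      covered <- covered | d <= dist_tol_px
    }
    cov_per[j] <- mean(covered)
  }
  total_len <- sum(len_per)
  coverage <- if (total_len > 0) sum(cov_per * len_per) / total_len else 0
  recall <- if (total_len > 0)
    sum(len_per[cov_per >= 0.5]) / total_len else 0
  list(precision = if (n_tr == 0L) 1 else sum(tp) / n_tr,
       recall_by_length = recall,
       coverage = coverage,
       n_traces = n_tr,
       n_true_positive = sum(tp))
}
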