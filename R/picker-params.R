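#' Picking parameters with paper-style defaults
#'
#' Bundles the tunable parameters of the four-step trace extraction.
#' Only the binarization threshold (`-t`) and the picking radius
#' (`-r`, half the expected filament width in down-sampled pixels)
#' normally need to be set; the remaining parameters default to the
#' standard derivations used in filament mode:
#' \itemize{
#'   \item minimum Hough line length `line_length_fl` = 2 * `radius_r`
#'     (the `--fl` argument),
#'   \item Hough accumulator threshold = `round(0.1 * line_length_fl)`,
#'     floored at 1,
#'   \item Hough line gap = `radius_r`,
#'   \item merge angle = 10 degrees, merge distance = `radius_r`.
#' }
#'
#' @param threshold_t binarization threshold on the figure-of-merit.
#' @param radius_r positive integer, picking radius in down-sampled
#'   pixels (half the particle diameter divided by the down-sampled
#'   pixel size; see [radius_pixels()]).
#' @param line_length_fl minimum accepted line length in down-sampled
#'   pixels; defaults to `2 * radius_r`.
#' @param hough_threshold accumulator vote threshold of the
#'   probabilistic Hough transform; defaults to
#'   `max(1, round(0.1 * line_length_fl))`.
#' @param line_gap largest gap (in pixels) bridged when walking along a
#'   candidate line; defaults to `radius_r`.
#' @param merge_angle_deg merge two segments only if their mutual angle
#'   is smaller than this, in degrees.
#' @param merge_dist merge distance in down-sampled pixels; defaults to
#'   `radius_r`.
#' @param rng_seed integer seed for the pseudo-random pixel visiting
#'   order of the Hough transform.
#' @return an object of class `picker_params`.
#' @examples
#' p <- picker_params(threshold_t = -6, radius_r = 12)
#' p$line_length_fl   # 24
#' p$hough_threshold  # 2
#' p$line_gap         # 12
#' @export
picker_params <- function(threshold_t,
                          radius_r,
                          line_length_fl = 2L * radius_r,
                          hough_threshold = max(1L, as.integer(round(0.1 * line_length_fl))),
                          line_gap = radius_r,
                          merge_angle_deg = 10,
                          merge_dist = radius_r,
                          rng_seed = 0L) {
  radius_r <- as.integer(radius_r)
  line_length_fl <- as.integer(line_length_fl)
  hough_threshold <- as.integer(hough_threshold)
  line_gap <- as.integer(line_gap)
  if (is.na(radius_r) || radius_r < 1L) stop("radius_r must be >= 1")
  if (line_length_fl < 1L) stop("line_length_fl must be >= 1")
  if (hough_threshold < 1L) stop("hough_threshold must be >= 1")
  if (line_gap < 1L) stop("line_gap must be >= 1")
  if (!is.finite(threshold_t)) stop("threshold_t must be finite")
  if (!is.finite(merge_angle_deg) || merge_angle_deg <= 0 || merge_angle_deg >= 90)
    stop("merge_angle_deg must lie in (0, 90)")
  if (!is.finite(merge_dist) || merge_dist <= 0)
    stop("merge_dist must be > 0")
  structure(
    list(threshold_t = as.numeric(threshold_t),
         radius_r = radius_r,
         line_length_fl = line_length_fl,
         hough_threshold = hough_threshold,
         line_gap = line_gap,
         merge_angle_deg = as.numeric(merge_angle_deg),
         merge_dist = as.numeric(merge_dist),
         rng_seed = as.integer(rng_seed)),
    class = "picker_params")
}

#' @export
print.picker_params <- function(x, ...) {
  cat(sprintf(paste0("<picker_params> -t %.3g, -r %d, --fl %d ",
                     "(hough thr %d, gap %d, merge < %.3g deg within %.3g px, seed %d)\n"),
              x$threshold_t, x$radius_r, x$line_length_fl,
              x$hough_threshold, x$line_gap, x$merge_angle_deg,
              x$merge_dist, x$rng_seed))
  invisible(x)
}
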