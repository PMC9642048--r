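# Batch orchestration: run the four-step extraction over sets of score
# maps or micrographs, write Relion-ready STAR output, and render the
# per-micrograph diagnostic panel.

.read_score_input <- function(path, mode, downsample_factor,
                              pixel_size_A, scorer_width_A) {
  is_mrc <- grepl("\\.mrcs?$", path, ignore.case = TRUE)
  if (mode == "scoremap") {
    if (is_mrc) {
      mg <- read_mrc(path)
      # header pixel size of a score map is the down-sampled one
      orig_pix <- if (is.null(pixel_size_A))
        mg$pixel_size_A / downsample_factor else pixel_size_A
      score_map(mg$values, downsample_factor, orig_pix)
    } else {
      vals <- as.matrix(utils::read.table(path))
      score_map(vals, downsample_factor,
                if (is.null(pixel_size_A)) 1.0 else pixel_size_A)
    }
  } else {
    mg <- if (is_mrc) read_mrc(path) else
      micrograph(as.matrix(utils::read.table(path)),
                 pixel_size_A = if (is.null(pixel_size_A)) 1.0
                                else pixel_size_A,
                 source_name = basename(path))
    if (!is.null(pixel_size_A)) mg$pixel_size_A <- pixel_size_A
    surrogate_score_map(mg, scorer_width_A, downsample_factor)
  }
}

#' Pick filaments in a batch of score maps or micrographs
#'
#' For every input file the score map is obtained (read directly, or
#' computed with the surrogate ridge scorer when `mode =
#' "micrograph"`), [extract_traces()] is run, and a pick STAR file with
#' start--end coordinates is written next to the requested output
#' directory.  Optionally, particle records with helical priors are
#' sampled along each trace and written as a particles STAR file, and
#' a diagnostic panel image of the four extraction steps is rendered.
#' Failures are isolated per input file: the batch continues and the
#' failure is reported in the summary.
#'
#' @param inputs character vector of input paths (MRC or whitespace
#'   delimited text matrices).
#' @param params a [picker_params()].
#' @param mode `"scoremap"` (inputs are figure-of-merit maps) or
#'   `"micrograph"` (inputs are raw images, scored by the surrogate
#'   scorer).
#' @param downsample_factor micrograph pixels per score-map pixel.
#' @param pixel_size_A original micrograph pixel size in Angstrom;
#'   when `NULL` it is taken from the MRC header.
#' @param scorer_width_A expected filament width in Angstrom; required
#'   in micrograph mode.
#' @param spacing_A if non-`NULL`, inter-particle distance in Angstrom
#'   at which particle records are sampled along each trace.
#' @param output_dir directory for STAR (and panel) output; created if
#'   missing.
#' @param panel if `TRUE`, write a `*_panel.png` diagnostic image per
#'   micrograph.
#' @return invisibly, a summary data frame with one row per input:
#'   `input`, `n_traces`, `total_length_px`, `status`.
#' @export
run_pick <- function(inputs, params,
                     mode = c("scoremap", "micrograph"),
                     downsample_factor = 1L,
                     pixel_size_A = NULL,
                     scorer_width_A = NULL,
                     spacing_A = NULL,
                     output_dir = ".",
                     panel = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "picker_params"))
  if (mode == "micrograph" && is.null(scorer_width_A))
    stop("micrograph mode requires scorer_width_A")
  if (!dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  rows <- lapply(inputs, function(path) {
    base <- sub("\\.[^.]*$", "", basename(path))
    tryCatch({
      sm <- .read_score_input(path, mode, downsample_factor,
                              pixel_size_A, scorer_width_A)
      det <- extract_traces(sm, params, details = TRUE)
      traces <- det$traces
      if (nrow(traces) == 0L)
        warning("no traces picked in ", basename(path),
                " (threshold above all scores?)", call. = FALSE)
      write_pick_star(traces, file.path(output_dir,
                                        paste0(base, "_picks.star")))
      if (!is.null(spacing_A) && nrow(traces) > 0L) {
        recs <- sample_all_particles(traces, spacing_A, sm$pixel_size_A)
        write_particles_star(recs, basename(path),
                             file.path(output_dir,
                                       paste0(base, "_particles.star")))
      }
      if (panel)
        plot_pick_panel(det, sm,
                        file.path(output_dir, paste0(base, "_panel.png")),
                        title = basename(path))
      tl <- if (nrow(traces) > 0L)
        sum(sqrt((traces$x_end - traces$x_start)^2 +
                 (traces$y_end - traces$y_start)^2)) else 0
      data.frame(input = path, n_traces = nrow(traces),
                 total_length_px = tl, status = "ok")
    }, error = function(e) {
      data.frame(input = path, n_traces = NA_integer_,
                 total_length_px = NA_real_,
                 status = paste("error:", conditionMessage(e)))
    })
  })
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  invisible(summary)
}

.panel_image <- function(m, main, col = gray.colors(64)) {
  # matrices are [y, x] with y downward: transpose and flip for image()
  image(t(m)[, rev(seq_len(nrow(m))), drop = FALSE], col = col,
        axes = FALSE, main = main, useRaster = TRUE)
}

.panel_segments <- function(segs, nx, ny, lwd = 2) {
  if (nrow(segs) == 0L) return(invisible())
  cols <- hcl.colors(max(3L, nrow(segs)), "Dark 3")
  # image() maps the unit square onto the matrix extent
  segments(segs$x1 / (nx - 1), 1 - segs$y1 / (ny - 1),
           segs$x2 / (nx - 1), 1 - segs$y2 / (ny - 1),
           col = cols[seq_len(nrow(segs))], lwd = lwd)
}

#' Diagnostic panel of the four extraction steps
#'
#' Renders a five-panel image per micrograph: the binarized score map,
#' its skeleton, the individual Hough segments in distinct colours,
#' the merged segments, and the final start--end coordinates overlaid
#' on the score map.
#'
#' @param details list from `extract_traces(..., details = TRUE)`.
#' @param score_map the [score_map()] the details were computed from.
#' @param path output PNG path.
#' @param title text placed above the overlay panel.
#' @return invisibly, `path`.
#' @export
plot_pick_panel <- function(details, score_map, path, title = "") {
  ny <- nrow(score_map$values); nx <- ncol(score_map$values)
  png(path, width = 5 * 320, height = 340)
  op <- par(mfrow = c(1, 5), mar = c(0.5, 0.5, 2, 0.5))
  on.exit({ par(op); dev.off() })
  .panel_image(details$mask * 1, "1: binarized",
               col = c("grey95", "darkred"))
  .panel_image(details$skeleton * 1, "2: skeleton",
               col = c("grey95", "black"))
  .panel_image(matrix(0, ny, nx), "3: Hough segments",
               col = "grey95")
  .panel_segments(details$segments, nx, ny)
  .panel_image(matrix(0, ny, nx), "4: merged", col = "grey95")
  .panel_segments(details$merged, nx, ny)
  .panel_image(score_map$values,
               if (nzchar(title)) title else "final picks")
  .panel_segments(details$merged, nx, ny, lwd = 3)
  invisible(path)
}

#' Write a simulated micrograph with its ground truth to disk
#'
#' Writes the micrograph as MRC, the ground-truth centrelines as a
#' pick STAR file (each polyline densely sampled, consecutive point
#' pairs forming the coordinate rows), and a sidecar `key = value`
#' text file recording the simulation parameters.
#'
#' @param spec a [simulation_spec()].
#' @param output_dir output directory, created if missing.
#' @param name basename for the three files.
#' @return invisibly, a list with the simulation result and the paths
#'   written.
#' @export
write_simulation <- function(spec, output_dir = ".", name = "synthetic") {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  sim <- simulate_micrograph(spec)
  mrc_path <- file.path(output_dir, paste0(name, ".mrc"))
  write_mrc(sim$image, mrc_path)
  gt <- do.call(rbind, lapply(seq_along(sim$truth$polylines), function(k) {
    p <- sim$truth$polylines[[k]]
    n <- nrow(p)
    if (n < 2L) return(NULL)
    data.frame(x_start = p$x[-n], y_start = p$y[-n],
               x_end = p$x[-1], y_end = p$y[-1],
               tube_id = k)
  }))
  star_path <- file.path(output_dir, paste0(name, "_truth.star"))
  write_pick_star(gt, star_path)
  side_path <- file.path(output_dir, paste0(name, "_spec.txt"))
  fields <- spec[setdiff(names(spec), "image_shape")]
  writeLines(c(sprintf("image_shape = %d %d", spec$image_shape[1],
                       spec$image_shape[2]),
               sprintf("%s = %s", names(fields),
                       vapply(fields, function(v) paste(format(v),
                                                        collapse = " "),
                              character(1)))),
             side_path)
  invisible(list(sim = sim, mrc = mrc_path, truth_star = star_path,
                 sidecar = side_path))
}
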