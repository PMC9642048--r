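# Minimal STAR (Self-defining Text Archive and Retrieval) loop reader
# and writer, covering the single-block, single-loop dialect used for
# Relion coordinate and particle metadata.

# Parse the first loop_ of the first data_ block into a data frame of
# character columns (callers convert types).
.read_star_loop <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  loop_at <- which(lines == "loop_")
  if (length(loop_at) == 0L) stop("format error: no loop_ block in ", path)
  i <- loop_at[1] + 1L
  cols <- character(0)
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    cols <- c(cols, sub("^(_\\S+).*$", "\\1", lines[i]))
    i <- i + 1L
  }
  if (length(cols) == 0L) stop("format error: loop_ without column labels")
  rows <- list()
  while (i <= length(lines)) {
    ln <- lines[i]
    if (nzchar(ln)) {
      if (startsWith(ln, "data_") || ln == "loop_") break
      f <- strsplit(ln, "\\s+")[[1]]
      if (length(f) != length(cols))
        stop("format error: row with ", length(f), " fields, expected ",
             length(cols))
      rows[[length(rows) + 1L]] <- f
    }
    i <- i + 1L
  }
  if (length(rows) == 0L) {
    df <- as.data.frame(matrix(character(0), ncol = length(cols)),
                        stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  }
  names(df) <- cols
  df
}

.write_star_loop <- function(df, path, block_name = "") {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("", paste0("data_", block_name), "", "loop_"), con)
  writeLines(sprintf("%s #%d", names(df), seq_along(df)), con)
  if (nrow(df) > 0L) {
    fmt <- vapply(df, function(col) {
      if (is.numeric(col)) sprintf("%.6f", col) else as.character(col)
    }, character(nrow(df)))
    if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1L)
    writeLines(apply(fmt, 1L, paste, collapse = "\t"), con)
  }
  writeLines("", con)
  invisible(path)
}

#' Write filament start--end coordinates as a pick STAR file
#'
#' Writes the manual-picking dialect consumed by Relion's particle
#' extraction: a single `loop_` with `_rlnCoordinateX` and
#' `_rlnCoordinateY`, where consecutive row pairs are the (start, end)
#' endpoints of one filament.  Traces are emitted in `tube_id` order
#' and coordinates are 0-based pixel-centre micrograph pixels, written
#' with 6 decimals.
#'
#' @param traces data frame of traces as produced by
#'   [extract_traces()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pick_star <- function(traces, path) {
  if (nrow(traces) > 0L) {
    len <- sqrt((traces$x_end - traces$x_start)^2 +
                (traces$y_end - traces$y_start)^2)
    if (any(len <= 0)) stop("degenerate (zero-length) trace")
    traces <- traces[order(traces$tube_id), , drop = FALSE]
  }
  n <- nrow(traces)
  xs <- numeric(2L * n); ys <- numeric(2L * n)
  if (n > 0L) {
    xs[seq(1L, 2L * n, 2L)] <- traces$x_start
    xs[seq(2L, 2L * n, 2L)] <- traces$x_end
    ys[seq(1L, 2L * n, 2L)] <- traces$y_start
    ys[seq(2L, 2L * n, 2L)] <- traces$y_end
  }
  .write_star_loop(
    data.frame(`_rlnCoordinateX` = xs, `_rlnCoordinateY` = ys,
               check.names = FALSE),
    path)
}

#' Read filament start--end coordinates from a pick STAR file
#'
#' Consecutive coordinate row pairs become one trace; tube identifiers
#' are assigned 1..n in file order.
#'
#' @param path path to a STAR file with `_rlnCoordinateX` and
#'   `_rlnCoordinateY` columns.
#' @return data frame of traces (`x_start`, `y_start`, `x_end`,
#'   `y_end`, `tube_id`).
#' @export
read_pick_star <- function(path) {
  df <- .read_star_loop(path)
  need <- c("_rlnCoordinateX", "_rlnCoordinateY")
  if (!all(need %in% names(df)))
    stop("format error: missing coordinate columns in ", path)
  x <- as.numeric(df[["_rlnCoordinateX"]])
  y <- as.numeric(df[["_rlnCoordinateY"]])
  if (length(x) %% 2L != 0L)
    stop("unpaired coordinate: ", length(x), " rows in ", path)
  n <- length(x) %/% 2L
  odd <- seq(1L, length.out = n, by = 2L)
  data.frame(x_start = x[odd], y_start = y[odd],
             x_end = x[odd + 1L], y_end = y[odd + 1L],
             tube_id = seq_len(n))
}

#' Write particle records with helical priors as a STAR file
#'
#' Writes the minimal helical-prior column set used by downstream
#' extraction and refinement: `_rlnMicrographName`, `_rlnCoordinateX`,
#' `_rlnCoordinateY`, `_rlnHelicalTubeID`, `_rlnAngleTiltPrior`,
#' `_rlnAnglePsiPrior`, `_rlnHelicalTrackLengthAngst`.
#'
#' @param records particle data frame from [sample_particles()] /
#'   [sample_all_particles()].
#' @param micrograph_name text written into `_rlnMicrographName`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_particles_star <- function(records, micrograph_name, path) {
  if (nrow(records) > 0L &&
      any(records$psi_prior_deg <= -180 | records$psi_prior_deg > 180))
    stop("psi prior out of range (-180, 180]")
  .write_star_loop(
    data.frame(
      `_rlnMicrographName` = rep(micrograph_name, nrow(records)),
      `_rlnCoordinateX` = records$x,
      `_rlnCoordinateY` = records$y,
      `_rlnHelicalTubeID` = as.numeric(records$tube_id),
      `_rlnAngleTiltPrior` = records$tilt_prior_deg,
      `_rlnAnglePsiPrior` = records$psi_prior_deg,
      `_rlnHelicalTrackLengthAngst` = records$track_length_A,
      check.names = FALSE),
    path)
}

#' Read particle records from a STAR file
#'
#' Inverse of [write_particles_star()]; additional columns are
#' ignored.
#'
#' @param path path to a particle STAR file.
#' @return data frame with the particle-record columns.
#' @export
read_particles_star <- function(path) {
  df <- .read_star_loop(path)
  need <- c("_rlnCoordinateX", "_rlnCoordinateY", "_rlnHelicalTubeID",
            "_rlnAngleTiltPrior", "_rlnAnglePsiPrior",
            "_rlnHelicalTrackLengthAngst")
  if (!all(need %in% names(df)))
    stop("format error: missing particle columns in ", path)
  data.frame(
    x = as.numeric(df[["_rlnCoordinateX"]]),
    y = as.numeric(df[["_rlnCoordinateY"]]),
    tube_id = as.integer(as.numeric(df[["_rlnHelicalTubeID"]])),
    psi_prior_deg = as.numeric(df[["_rlnAnglePsiPrior"]]),
    tilt_prior_deg = as.numeric(df[["_rlnAngleTiltPrior"]]),
    track_length_A = as.numeric(df[["_rlnHelicalTrackLengthAngst"]]),
    micrograph_name = if ("_rlnMicrographName" %in% names(df))
      df[["_rlnMicrographName"]] else rep("", nrow(df)))
}
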