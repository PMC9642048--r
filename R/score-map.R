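#' Score map container
#'
#' A score map holds the per-pixel figure-of-merit (FOM) values that a
#' sliding-window particle scorer assigns to each position of a
#' down-sampled micrograph, together with the down-sampling factor that
#' relates score-map pixels to original micrograph pixels and the
#' original pixel size in Angstrom.
#'
#' @param values numeric matrix of figure-of-merit values; rows index
#'   y, columns index x.
#' @param downsample_factor positive integer, micrograph pixels per
#'   score-map pixel.
#' @param pixel_size_A positive number, Angstrom per original
#'   micrograph pixel.
#' @return an object of class `score_map`.
#' @examples
#' sm <- score_map(matrix(rnorm(64 * 64), 64), downsample_factor = 8,
#'                 pixel_size_A = 0.824)
#' dim(sm$values)
#' @export
score_map <- function(values, downsample_factor = 1L, pixel_size_A = 1.0) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("score map must have both dimensions >= 1")
  downsample_factor <- as.integer(downsample_factor)
  if (is.na(downsample_factor) || downsample_factor < 1L)
    stop("downsample_factor must be a positive integer")
  if (!is.finite(pixel_size_A) || pixel_size_A <= 0)
    stop("pixel_size_A must be > 0")
  structure(
    list(values = values,
         downsample_factor = downsample_factor,
         pixel_size_A = as.numeric(pixel_size_A)),
    class = "score_map")
}

#' @export
print.score_map <- function(x, ...) {
  cat(sprintf("<score_map> %d x %d px, downsample factor %d, %.4g A/px (original)\n",
              nrow(x$values), ncol(x$values), x$downsample_factor,
              x$pixel_size_A))
  cat(sprintf("  FOM range: [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Micrograph image container
#'
#' @param values numeric matrix of densities; rows index y, columns
#'   index x.
#' @param pixel_size_A positive number, Angstrom per pixel.
#' @param source_name text identifier (typically the file name).
#' @return an object of class `micrograph`.
#' @export
micrograph <- function(values, pixel_size_A = 1.0, source_name = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("micrograph must have both dimensions >= 1")
  if (!is.finite(pixel_size_A) || pixel_size_A <= 0)
    stop("pixel_size_A must be > 0")
  structure(
    list(values = values, pixel_size_A = as.numeric(pixel_size_A),
         source_name = as.character(source_name)),
    class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph> %d x %d px at %.4g A/px%s\n",
              nrow(x$values), ncol(x$values), x$pixel_size_A,
              if (nzchar(x$source_name)) paste0(" [", x$source_name, "]")
              else ""))
  invisible(x)
}
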