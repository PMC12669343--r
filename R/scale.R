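#' Intensity scale
#'
#' The calibrated stimulus dimension: bounded below and above, optionally
#' quantised to a hardware grid (e.g. the frame duration of a monitor for
#' ISI calibration). The convention throughout is that larger intensity means
#' a more visible stimulus.
#'
#' @param minimum,maximum Bounds of the scale; `minimum < maximum`.
#' @param quantum Optional positive grid spacing. When set it must divide
#'   `maximum - minimum` (to within rounding), and proposed intensities are
#'   snapped to `minimum + k * quantum`; exact half-grid ties snap downward
#'   (toward the less visible stimulus).
#' @return An object of class `intensity_scale`.
#' @export
#' @examples
#' intensity_scale(0, 200)              # ISI in ms
#' intensity_scale(0.1, 1)              # prime contrast
#' intensity_scale(0, 200, 200 / 24)    # 120-Hz frame grid (8.33 ms)
intensity_scale <- function(minimum, maximum, quantum = NULL) {
  stopifnot(is.numeric(minimum), is.numeric(maximum))
  if (minimum >= maximum) stop("'minimum' must be < 'maximum'")
  if (!is.null(quantum)) {
    if (quantum <= 0) stop("'quantum' must be > 0")
    k <- (maximum - minimum) / quantum
    if (abs(k - round(k)) > 1e-6)
      stop("'quantum' must divide maximum - minimum")
  }
  structure(list(minimum = minimum, maximum = maximum, quantum = quantum),
            class = "intensity_scale")
}

#' @export
print.intensity_scale <- function(x, ...) {
  cat(sprintf("Intensity scale [%g, %g]%s\n", x$minimum, x$maximum,
              if (is.null(x$quantum)) "" else sprintf(", quantum %g", x$quantum)))
  invisible(x)
}

clamp <- function(x, lo, hi) min(max(x, lo), hi)

# snap to minimum + k*quantum; exact half-grid ties go downward
snap_to_grid <- function(x, scale) {
  if (is.null(scale$quantum)) return(x)
  r <- (x - scale$minimum) / scale$quantum
  f <- r - floor(r)
  k <- if (abs(f - 0.5) < 1e-9) floor(r) else round(r)
  scale$minimum + k * scale$quantum
}
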