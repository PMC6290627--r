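#' Pitch coordinate model
#'
#' Describes the playing field as an axis-aligned rectangle with the origin at
#' one corner: `x` runs longitudinally (toward the analysed attacking goal)
#' in `[0, length]`, `y` transversally in `[0, width]`, both in meters. All
#' metrics are computed in these real field measures, so hull areas come out
#' in square meters.
#'
#' @param length Longitudinal extent in meters (default 105, a standard
#'   full-size pitch).
#' @param width Transverse extent in meters (default 68).
#' @return An object of class `pitch_model` with fields `length` and `width`.
#' @examples
#' pitch_model()         # 105 x 68 m
#' pitch_model(100, 64)
#' @export
pitch_model <- function(length = 105, width = 68) {
  if (!is.numeric(length) || length(length) != 1 || !is.finite(length) || length <= 0)
    abort_domain("pitch length must be a single positive number")
  if (!is.numeric(width) || length(width) != 1 || !is.finite(width) || width <= 0)
    abort_domain("pitch width must be a single positive number")
  structure(list(length = as.numeric(length), width = as.numeric(width)),
            class = "pitch_model")
}

#' @export
print.pitch_model <- function(x, ...) {
  cat(sprintf("<pitch_model> %.1f m x %.1f m\n", x$length, x$width))
  invisible(x)
}

#' Pace discretisation scheme
#'
#' Maps instantaneous speed (m/s) to one of five ordered pace classes. The
#' default boundaries are the application-standard 0.2 / 2.1 / 3.8 / 6.1 m/s
#' cut points separating Standing, Walking, Jogging, Running and Sprinting.
#' Intervals are half-open `[lower, upper)`: a speed exactly at a boundary is
#' assigned to the faster class, which makes the classification total and
#' monotone in speed.
#'
#' @param thresholds Strictly increasing vector of 4 speeds in m/s.
#' @param labels Character vector of 5 ordered pace names, slowest first.
#' @return An object of class `pace_scheme`.
#' @examples
#' sc <- pace_scheme()
#' classify_pace(c(0.1, 1, 3, 5, 8), sc)
#' @export
pace_scheme <- function(thresholds = c(0.2, 2.1, 3.8, 6.1),
                        labels = c("Standing", "Walking", "Jogging",
                                   "Running", "Sprinting")) {
  if (length(thresholds) != 4 || any(!is.finite(thresholds)))
    abort_domain("pace scheme needs exactly 4 finite thresholds")
  if (any(diff(thresholds) <= 0))
    abort_domain("pace thresholds must be strictly increasing")
  if (any(thresholds < 0))
    abort_domain("pace thresholds must be non-negative speeds")
  if (length(labels) != 5 || anyDuplicated(labels))
    abort_domain("pace scheme needs exactly 5 distinct labels")
  structure(list(thresholds = as.numeric(thresholds),
                 labels = as.character(labels)),
            class = "pace_scheme")
}

#' @export
print.pace_scheme <- function(x, ...) {
  bounds <- c(0, x$thresholds, Inf)
  cat("<pace_scheme>\n")
  for (i in seq_len(5))
    cat(sprintf("  %-10s [%g, %g) m/s\n", x$labels[i], bounds[i], bounds[i + 1]))
  invisible(x)
}

#' Classify speeds into pace classes
#'
#' @param speed Numeric vector of speeds in m/s (must be >= 0).
#' @param scheme A [pace_scheme()].
#' @return Ordered factor of pace labels, same length as `speed`.
#' @export
classify_pace <- function(speed, scheme = pace_scheme()) {
  stopifnot(inherits(scheme, "pace_scheme"))
  if (any(!is.finite(speed)) || any(speed < 0))
    abort_domain("speeds must be finite and non-negative")
  idx <- findInterval(speed, scheme$thresholds) + 1L  # [t_k, t_{k+1}) -> k+1
  factor(scheme$labels[idx], levels = scheme$labels, ordered = TRUE)
}
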