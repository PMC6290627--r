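# Individual kinematics: speed, pace discretisation, distance by pace,
# occupancy / pace heat maps, distance to a point.

#' Per-frame speed of a player
#'
#' Speed at frame i is the Euclidean step distance from frame i-1 divided by
#' the step duration; the first value is duplicated from the second so the
#' series has one speed per sample. Raw fixed-rate differentiation amplifies
#' tracking jitter, so a centered moving average (default window 0.5 s) is
#' applied; set `smoothing_window = 0` for raw finite differences. At the
#' series ends the average shrinks to the available samples.
#'
#' @param dataset A `positional_dataset`.
#' @param player Player id.
#' @param smoothing_window Moving-average window in seconds (0 disables).
#' @return A `speed_series`: data frame with `time_s`, `speed_mps` and the
#'   player id as attribute.
#' @export
compute_speed <- function(dataset, player, smoothing_window = 0.5) {
  p <- dataset[dataset$player_id == player, , drop = FALSE]
  if (nrow(p) == 0)
    abort_validation(sprintf("player '%s' not in dataset", player))
  if (nrow(p) < 2)
    abort_data(sprintf("player '%s' has a single sample; speed undefined", player))
  p <- p[order(p$time_s), , drop = FALSE]
  step <- sqrt(diff(p$x_m)^2 + diff(p$y_m)^2)
  v <- step / diff(p$time_s)
  v <- c(v[1], v)
  if (smoothing_window > 0) {
    k <- max(1L, round(smoothing_window * sampling_rate(dataset)))
    if (k %% 2 == 0) k <- k + 1L
    v <- moving_average(v, k)
  }
  structure(data.frame(time_s = p$time_s, speed_mps = v),
            player_id = player,
            class = c("speed_series", "data.frame"))
}

# centered moving average with shrinking (partial) windows at the ends
moving_average <- function(x, k) {
  if (k <= 1) return(x)
  h <- (k - 1) %/% 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Distance covered per pace class
#'
#' Accumulates each inter-frame step's distance (speed x step duration) into
#' the pace class of that step's speed. The per-class distances sum exactly
#' to the total covered distance.
#'
#' @param speed_series A `speed_series` from [compute_speed()].
#' @param scheme A [pace_scheme()].
#' @return A `pace_distance_summary`: named per-class distances (m), plus
#'   `total` in meters.
#' @export
distance_by_pace <- function(speed_series, scheme = pace_scheme()) {
  if (!is.data.frame(speed_series) || nrow(speed_series) == 0)
    abort_empty("empty speed series")
  n <- nrow(speed_series)
  if (n < 2) {
    d <- stats::setNames(numeric(5), scheme$labels)
    return(structure(list(distance_m = d, total_m = 0,
                          player_id = attr(speed_series, "player_id")),
                     class = "pace_distance_summary"))
  }
  dt <- diff(speed_series$time_s)
  v <- speed_series$speed_mps[-1]          # speed of the step ending at frame i
  step_d <- v * dt
  pace <- classify_pace(v, scheme)
  d <- vapply(scheme$labels, function(l) sum(step_d[pace == l]), numeric(1))
  structure(list(distance_m = d, total_m = sum(step_d),
                 player_id = attr(speed_series, "player_id")),
            class = "pace_distance_summary")
}

#' @export
print.pace_distance_summary <- function(x, ...) {
  cat(sprintf("<pace_distance_summary>%s total %.1f m\n",
              if (is.null(x$player_id)) "" else paste0(" player ", x$player_id),
              x$total_m))
  for (l in names(x$distance_m))
    cat(sprintf("  %-10s %8.1f m\n", l, x$distance_m[[l]]))
  invisible(x)
}

#' Spatial occupancy / pace heat map
#'
#' Bins a player's samples on a regular grid over the pitch. In `occupancy`
#' mode each cell counts samples (the grand total equals the number of
#' samples); in `pace` mode each cell accumulates the time (seconds, one
#' sampling period per sample) the player spent there at the requested pace
#' class, using the pace cached at import. The last row/column may be a
#' partial bin clipped at the pitch boundary; samples exactly on the far
#' boundary fall in the last bin.
#'
#' @param dataset A `positional_dataset`.
#' @param player Player id.
#' @param bin_size Bin edge length in meters (default 1).
#' @param mode `"occupancy"` or `"pace"`.
#' @param pace Pace label (required in `pace` mode).
#' @return A `heatmap_grid`: matrix of values (rows = x bins, cols = y bins)
#'   with `x_breaks`/`y_breaks` attributes.
#' @export
heatmap_grid <- function(dataset, player, bin_size = 1,
                         mode = c("occupancy", "pace"), pace = NULL) {
  mode <- match.arg(mode)
  p <- dataset[dataset$player_id == player, , drop = FALSE]
  if (nrow(p) == 0)
    abort_validation(sprintf("player '%s' not in dataset", player))
  pm <- pitch(dataset)
  if (!is.finite(bin_size) || bin_size <= 0 ||
      bin_size > max(pm$length, pm$width))
    abort_domain("bin_size must be positive and no larger than the pitch")

  xb <- unique(c(seq(0, pm$length, by = bin_size), pm$length))
  yb <- unique(c(seq(0, pm$width, by = bin_size), pm$width))
  ix <- pmin(findInterval(p$x_m, xb, rightmost.closed = TRUE), length(xb) - 1)
  iy <- pmin(findInterval(p$y_m, yb, rightmost.closed = TRUE), length(yb) - 1)

  if (mode == "pace") {
    scheme <- attr(dataset, "pace_scheme")
    if (is.null(pace) || !(pace %in% scheme$labels))
      abort_domain(paste0("pace must be one of: ",
                          paste(scheme$labels, collapse = ", ")))
    sel <- !is.na(p$pace) & p$pace == pace
    ix <- ix[sel]; iy <- iy[sel]
    w <- 1 / sampling_rate(dataset)    # seconds per sample
  } else {
    w <- 1
  }
  m <- matrix(0, nrow = length(xb) - 1, ncol = length(yb) - 1)
  if (length(ix)) {
    tab <- table(factor(ix, levels = seq_len(nrow(m))),
                 factor(iy, levels = seq_len(ncol(m))))
    m <- unclass(tab) * w
    dimnames(m) <- NULL
  }
  structure(m, x_breaks = xb, y_breaks = yb, mode = mode, pace = pace,
            bin_size = bin_size, player_id = player,
            class = c("heatmap_grid", "matrix", "array"))
}

#' Write a heat map as a dense matrix CSV
#'
#' Two comment header lines record the bin size and pitch dimensions; then the
#' dense value matrix, x bins as rows.
#' @param grid A `heatmap_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_heatmap_csv <- function(grid, path) {
  stopifnot(inherits(grid, "heatmap_grid"))
  xb <- attr(grid, "x_breaks"); yb <- attr(grid, "y_breaks")
  con <- tryCatch(file(path, "w"), error = function(e) NULL)
  if (is.null(con)) abort_io(sprintf("cannot write %s", path))
  on.exit(close(con))
  writeLines(c(sprintf("# bin_size_m,%g,mode,%s", attr(grid, "bin_size"),
                       attr(grid, "mode")),
               sprintf("# pitch_length_m,%g,pitch_width_m,%g",
                       max(xb), max(yb))), con)
  utils::write.table(unclass(grid), con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Distance of selected players to a fixed point
#'
#' @param dataset A `positional_dataset`.
#' @param group A [group_selection()] or character vector of player ids.
#' @param point Numeric `(x, y)` in meters, inside the pitch unless
#'   `allow_outside`.
#' @param allow_outside Permit points outside pitch bounds.
#' @return Data frame `time_s` + one distance column (m) per player, named
#'   `dist_<id>_m`.
#' @export
distance_to_point <- function(dataset, group, point, allow_outside = FALSE) {
  group <- as_group(group, min_size = 1)
  check_group_present(dataset, group)
  pm <- pitch(dataset)
  if (length(point) != 2 || any(!is.finite(point)))
    abort_domain("point must be finite (x, y)")
  if (!allow_outside &&
      (point[1] < 0 || point[1] > pm$length || point[2] < 0 || point[2] > pm$width))
    abort_domain("point lies outside the pitch bounds")
  wide <- positions_by_frame(dataset, group)
  out <- data.frame(time_s = wide$times)
  for (i in seq_along(group$player_ids)) {
    id <- group$player_ids[i]
    out[[paste0("dist_", id, "_m")]] <-
      sqrt((wide$x[, i] - point[1])^2 + (wide$y[, i] - point[2])^2)
  }
  out
}

# common frame-aligned wide layout: times plus x/y matrices (frames x players);
# errors if any member is missing at any frame of the selection
positions_by_frame <- function(dataset, group) {
  ids <- group$player_ids
  times <- sort(unique(dataset$time_s[dataset$player_id %in% ids]))
  n <- length(times)
  x <- matrix(NA_real_, n, length(ids))
  y <- matrix(NA_real_, n, length(ids))
  dt <- 1 / sampling_rate(dataset)
  for (i in seq_along(ids)) {
    p <- dataset[dataset$player_id == ids[i], , drop = FALSE]
    idx <- match(round(times / dt * 2), round(p$time_s / dt * 2))
    if (anyNA(idx))
      abort_validation(sprintf(
        "player '%s' is missing at %d of %d frames of the selection",
        ids[i], sum(is.na(idx)), n))
    x[, i] <- p$x_m[idx]
    y[, i] <- p$y_m[idx]
  }
  list(times = times, x = x, y = y, ids = ids)
}
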