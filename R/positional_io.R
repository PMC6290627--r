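# Positional dataset: long-form table of fixed-rate 2-D tracking samples.
# Columns: time_s, player_id, team, x_m, y_m (+ cached pace factor).
# Attributes: rate (Hz), pitch (pitch_model), pace_scheme.

POSITIONAL_COLUMNS <- c("time_s", "player_id", "team", "x_m", "y_m")

#' Construct a positional dataset from a records table
#'
#' Validates, aligns and annotates a long-form table of tracking samples.
#' Each player's timestamps are snapped to the common sampling grid (the grid
#' of the first player, extended to cover all players); a sample further than
#' half a sampling period from any grid point is an error. Interior gaps in a
#' player's samples are filled by linear interpolation up to `max_gap`
#' seconds; longer gaps are a validation error. Samples outside the pitch are
#' clamped to its bounds with a warning (or rejected when `strict = TRUE`).
#'
#' Pace classes are discretised once here, at import, and cached with the
#' dataset (column `pace`); analysing under a different scheme requires
#' re-importing with that scheme.
#'
#' @param records Data frame with columns `time_s`, `player_id`, `team`,
#'   `x_m`, `y_m`.
#' @param rate Sampling rate in Hz.
#' @param pitch A [pitch_model()].
#' @param scheme [pace_scheme()] used for the cached pace classification.
#' @param clamp Clamp out-of-bounds samples to the pitch (default) instead of
#'   rejecting them.
#' @param max_gap Longest interior gap (seconds) bridged by linear
#'   interpolation.
#' @param smoothing_window Moving-average window (seconds) used for the
#'   cached pace classification's speeds.
#' @return A `positional_dataset` (a data frame with metadata attributes).
#' @export
positional_dataset <- function(records, rate, pitch = pitch_model(),
                               scheme = pace_scheme(), clamp = TRUE,
                               max_gap = 0.5, smoothing_window = 0.5) {
  if (!is.data.frame(records))
    abort_format("records must be a data frame")
  missing_cols <- setdiff(POSITIONAL_COLUMNS, names(records))
  if (length(missing_cols))
    abort_format(paste0("missing required columns: ",
                        paste(missing_cols, collapse = ", ")))
  if (nrow(records) == 0)
    abort_empty("records table is empty")
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0)
    abort_domain("rate must be a single positive number (Hz)")
  stopifnot(inherits(pitch, "pitch_model"))

  df <- data.frame(time_s = as.numeric(records$time_s),
                   player_id = as.character(records$player_id),
                   team = as.character(records$team),
                   x_m = as.numeric(records$x_m),
                   y_m = as.numeric(records$y_m),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$time_s)) || any(!is.finite(df$x_m)) || any(!is.finite(df$y_m)))
    abort_validation("non-finite time or coordinate values")
  if (any(df$time_s < 0))
    abort_validation("negative timestamps")

  dup <- duplicated(df[c("player_id", "time_s")])
  if (any(dup)) {
    d <- df[which(dup)[1], ]
    abort_validation(sprintf(
      "duplicated timestamp for player '%s' at t = %g s", d$player_id, d$time_s))
  }

  # order players by first appearance so "the first player" defines the grid
  first_seen <- df$player_id[!duplicated(df$player_id)]
  df <- df[order(match(df$player_id, first_seen), df$time_s), , drop = FALSE]

  dt <- 1 / rate
  t0 <- min(df$time_s[df$player_id == first_seen[1]])
  phase <- t0 - floor(t0 / dt) * dt  # grid anchored at first player's start

  snap <- function(t) round((t - phase) / dt) * dt + phase
  snapped <- snap(df$time_s)
  off <- abs(df$time_s - snapped)
  if (any(off > dt / 2 + 1e-9)) {
    d <- df[which.max(off), ]
    abort_validation(sprintf(
      "player '%s' sample at t = %g s is off the common %g Hz grid",
      d$player_id, d$time_s, rate))
  }
  df$time_s <- snapped
  # snapping can merge near-duplicate stamps
  dup <- duplicated(df[c("player_id", "time_s")])
  if (any(dup)) {
    d <- df[which(dup)[1], ]
    abort_validation(sprintf(
      "duplicated timestamp (after grid alignment) for player '%s' at t = %g s",
      d$player_id, d$time_s))
  }

  # fill interior gaps per player by linear interpolation, up to max_gap
  pieces <- lapply(split(df, df$player_id), function(p) {
    p <- p[order(p$time_s), , drop = FALSE]
    n_expect <- round((max(p$time_s) - min(p$time_s)) / dt) + 1
    if (nrow(p) == n_expect) return(p)
    grid <- min(p$time_s) + (seq_len(n_expect) - 1) * dt
    have_idx <- round((p$time_s - min(p$time_s)) / dt) + 1
    have <- seq_len(n_expect) %in% have_idx
    runs <- rle(have)
    gap_len <- max(runs$lengths[!runs$values]) * dt
    if (gap_len > max_gap + 1e-9)
      abort_validation(sprintf(
        "player '%s' has a %.2f s gap, longer than max_gap = %g s",
        p$player_id[1], gap_len, max_gap))
    data.frame(time_s = grid,
               player_id = p$player_id[1],
               team = p$team[1],
               x_m = stats::approx(p$time_s, p$x_m, xout = grid)$y,
               y_m = stats::approx(p$time_s, p$y_m, xout = grid)$y,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces[unique(first_seen)])
  rownames(df) <- NULL

  out_x <- df$x_m < 0 | df$x_m > pitch$length
  out_y <- df$y_m < 0 | df$y_m > pitch$width
  n_out <- sum(out_x | out_y)
  if (n_out > 0) {
    if (!clamp)
      abort_validation(sprintf("%d samples outside pitch bounds (strict mode)", n_out))
    warning(sprintf("clamped %d out-of-bounds samples to pitch limits", n_out),
            call. = FALSE)
    df$x_m <- pmin(pmax(df$x_m, 0), pitch$length)
    df$y_m <- pmin(pmax(df$y_m, 0), pitch$width)
  }

  ds <- structure(df,
                  rate = rate, pitch = pitch, pace_scheme = scheme,
                  class = c("positional_dataset", "data.frame"))
  ds$pace <- cached_pace(ds, scheme, smoothing_window)
  ds
}

# eager per-record pace classification (one discretisation per dataset)
cached_pace <- function(ds, scheme, smoothing_window) {
  pace <- factor(rep(scheme$labels[1], nrow(ds)),
                 levels = scheme$labels, ordered = TRUE)
  for (p in players(ds)) {
    sel <- ds$player_id == p
    if (sum(sel) < 2) next
    sp <- compute_speed(ds, p, smoothing_window = smoothing_window)
    pace[sel] <- classify_pace(sp$speed_mps, scheme)
  }
  pace
}

#' @export
print.positional_dataset <- function(x, ...) {
  cat(sprintf(
    "<positional_dataset> %d records, %d players, %g Hz, pitch %.0fx%.0f m, t in [%g, %g] s\n",
    nrow(x), length(players(x)), attr(x, "rate"),
    attr(x, "pitch")$length, attr(x, "pitch")$width,
    min(x$time_s), max(x$time_s)))
  invisible(x)
}

#' Player identifiers in a dataset
#' @param dataset A `positional_dataset`.
#' @return Character vector of player ids in order of first appearance.
#' @export
players <- function(dataset) unique(dataset$player_id)

#' Sampling rate of a dataset
#' @param dataset A `positional_dataset`.
#' @return Sampling rate in Hz.
#' @export
sampling_rate <- function(dataset) attr(dataset, "rate")

#' Pitch model of a dataset
#' @param dataset A `positional_dataset`.
#' @return The dataset's [pitch_model()].
#' @export
pitch <- function(dataset) attr(dataset, "pitch")

#' Time interval
#'
#' Half-open analysis interval `[start, end)` in seconds from period start.
#' @param start,end Interval bounds in seconds; `0 <= start < end`.
#' @return A `time_interval` object.
#' @export
time_interval <- function(start, end) {
  if (!is.finite(start) || !is.finite(end) || start < 0 || start >= end)
    abort_domain("need 0 <= start < end")
  structure(list(start = as.numeric(start), end = as.numeric(end)),
            class = "time_interval")
}

#' Group selection
#'
#' An ordered set of player ids defining an analysis group. The only
#' constraint on composition is a minimum size (the caller decides who is an
#' outfield player); hull-based metrics require at least 3 members.
#' @param player_ids Character vector of distinct player ids.
#' @param min_size Minimum group size this selection must satisfy.
#' @return A `group_selection` object.
#' @export
group_selection <- function(player_ids, min_size = 2) {
  player_ids <- as.character(player_ids)
  if (anyDuplicated(player_ids))
    abort_domain("duplicated player ids in group")
  if (length(player_ids) < min_size)
    abort_group_size(sprintf("group has %d players; minimum is %d",
                             length(player_ids), min_size))
  structure(list(player_ids = player_ids, min_size = as.integer(min_size)),
            class = "group_selection")
}

as_group <- function(group, min_size = 2) {
  if (inherits(group, "group_selection")) {
    if (length(group$player_ids) < min_size)
      abort_group_size(sprintf("group has %d players; this metric needs at least %d",
                               length(group$player_ids), min_size))
    return(group)
  }
  group_selection(group, min_size = min_size)
}

check_group_present <- function(dataset, group) {
  missing <- setdiff(group$player_ids, players(dataset))
  if (length(missing))
    abort_validation(paste0("players not in dataset: ",
                            paste(missing, collapse = ", ")))
  invisible(TRUE)
}

#' Read a positional tracking CSV
#'
#' Expects the comma-separated dialect `time_s,player_id,team,x_m,y_m`
#' (UTF-8, dot decimal, header row) with times in seconds, coordinates in
#' meters in pitch coordinates. Validation and alignment behave as in
#' [positional_dataset()].
#'
#' @param path CSV file path.
#' @param pitch A [pitch_model()] giving the field dimensions.
#' @param rate Sampling rate in Hz.
#' @param ... Passed to [positional_dataset()] (`scheme`, `clamp`,
#'   `max_gap`, `smoothing_window`).
#' @return A `positional_dataset`.
#' @export
read_positional_csv <- function(path, pitch = pitch_model(), rate = 10, ...) {
  if (!file.exists(path))
    abort_io(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0)
    abort_empty(sprintf("no data rows in %s", path))
  positional_dataset(raw, rate = rate, pitch = pitch, ...)
}

#' Write a positional dataset to CSV
#'
#' Inverse of [read_positional_csv()]: writes the canonical
#' `time_s,player_id,team,x_m,y_m` dialect. The cached pace column is not
#' written (it is derived data, recomputed at import).
#'
#' @param dataset A `positional_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_positional_csv <- function(dataset, path) {
  df <- as.data.frame(dataset)[POSITIONAL_COLUMNS]
  ok <- tryCatch({
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort_io(sprintf("cannot write %s", path))
  invisible(path)
}

#' Slice a dataset by time interval and player group
#'
#' Keeps records of the selected players with `start <= time < end`.
#' Sampling rate, pitch and pace cache are preserved.
#'
#' @param dataset A `positional_dataset`.
#' @param interval A [time_interval()], or `NULL` for the full span.
#' @param group A [group_selection()] or character vector of player ids, or
#'   `NULL` for all players.
#' @return A `positional_dataset` restricted to the selection.
#' @export
slice_dataset <- function(dataset, interval = NULL, group = NULL) {
  keep <- rep(TRUE, nrow(dataset))
  if (!is.null(interval)) {
    stopifnot(inherits(interval, "time_interval"))
    keep <- keep & dataset$time_s >= interval$start & dataset$time_s < interval$end
  }
  if (!is.null(group)) {
    ids <- if (inherits(group, "group_selection")) group$player_ids else as.character(group)
    keep <- keep & dataset$player_id %in% ids
  }
  if (!any(keep))
    abort_empty("selection matches no records (interval/group do not overlap the data)")
  out <- dataset[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("rate", "pitch", "pace_scheme")] <-
    attributes(dataset)[c("rate", "pitch", "pace_scheme")]
  class(out) <- c("positional_dataset", "data.frame")
  out
}

#' Write a per-frame metric series to CSV
#'
#' One row per frame, `time_s` first, numeric values in SI units. The file
#' re-reads (via [read_series_csv()]) to an equal series up to float
#' formatting tolerance.
#'
#' @param series Data frame with a `time_s` column.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  if (!is.data.frame(series) || nrow(series) == 0)
    abort_empty("series is empty; nothing to write")
  if (!"time_s" %in% names(series))
    abort_format("series must have a time_s column")
  series <- series[c("time_s", setdiff(names(series), "time_s"))]
  ok <- tryCatch({
    utils::write.csv(series, path, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort_io(sprintf("cannot write %s", path))
  invisible(path)
}

#' Read a metric series CSV written by [write_series_csv()]
#' @param path CSV file path.
#' @return Data frame with `time_s` first.
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  utils::read.csv(path, stringsAsFactors = FALSE)
}
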