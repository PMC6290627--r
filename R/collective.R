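# Group-level geometry per frame: centroid and derived distances, stretch
# index (+ rate of change), hull surface area and overlap, team length/width.

#' Group centroid per frame
#'
#' The team centre: unweighted mean of the members' x and y coordinates at
#' each frame, every player contributing equally. All members must be present
#' at every frame of the selection.
#'
#' @param dataset A `positional_dataset` (slice it first to restrict the
#'   interval).
#' @param group A [group_selection()] or character vector of >= 2 player ids.
#' @return Data frame `time_s`, `centroid_x_m`, `centroid_y_m`.
#' @export
centroid_series <- function(dataset, group) {
  group <- as_group(group, min_size = 2)
  check_group_present(dataset, group)
  w <- positions_by_frame(dataset, group)
  data.frame(time_s = w$times,
             centroid_x_m = rowMeans(w$x),
             centroid_y_m = rowMeans(w$y))
}

#' Radial distances of members to the group centroid
#'
#' @inheritParams centroid_series
#' @return Data frame `time_s` + one column `dist_<id>_m` per member.
#' @export
radial_distances <- function(dataset, group) {
  group <- as_group(group, min_size = 2)
  check_group_present(dataset, group)
  w <- positions_by_frame(dataset, group)
  cx <- rowMeans(w$x); cy <- rowMeans(w$y)
  out <- data.frame(time_s = w$times)
  for (i in seq_along(w$ids))
    out[[paste0("dist_", w$ids[i], "_m")]] <-
      sqrt((w$x[, i] - cx)^2 + (w$y[, i] - cy)^2)
  out
}

#' Stretch index per frame, with its rate of change
#'
#' The stretch index is the mean radial distance of group members to the
#' group centroid; it tracks the contraction/expansion of the group. Its
#' first time derivative (centered finite differences at interior frames,
#' one-sided at the ends) gives the speed at which the group stretches or
#' shortens.
#'
#' @inheritParams centroid_series
#' @return Data frame `time_s`, `stretch_index_m`, `stretch_rate_mps`.
#' @export
stretch_index_series <- function(dataset, group) {
  rd <- radial_distances(dataset, group)
  si <- rowMeans(as.matrix(rd[, -1, drop = FALSE]))
  data.frame(time_s = rd$time_s,
             stretch_index_m = si,
             stretch_rate_mps = finite_diff(si, rd$time_s))
}

# d/dt by centered differences; forward/backward at the boundaries
finite_diff <- function(v, t) {
  n <- length(v)
  if (n == 1) return(0)
  d <- numeric(n)
  d[1] <- (v[2] - v[1]) / (t[2] - t[1])
  d[n] <- (v[n] - v[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (v[i + 1] - v[i - 1]) / (t[i + 1] - t[i - 1])
  }
  d
}

#' Distances between two groups' centroids
#'
#' Per frame: the Euclidean distance between the two group centroids, plus
#' each member of `group_a`'s distance to `group_b`'s centroid (the distance
#' to the opponents' centre).
#'
#' @param dataset A `positional_dataset`.
#' @param group_a,group_b Disjoint groups of >= 2 players each.
#' @return Data frame `time_s`, `centroid_dist_m`, then `dist_<id>_m` for
#'   each member of `group_a` to `group_b`'s centroid.
#' @export
centroid_distances <- function(dataset, group_a, group_b) {
  group_a <- as_group(group_a, min_size = 2)
  group_b <- as_group(group_b, min_size = 2)
  if (length(intersect(group_a$player_ids, group_b$player_ids)))
    abort_domain("groups overlap; they must be disjoint")
  check_group_present(dataset, group_a)
  check_group_present(dataset, group_b)
  wa <- positions_by_frame(dataset, group_a)
  wb <- positions_by_frame(dataset, group_b)
  if (!identical(wa$times, wb$times))
    abort_validation("the two groups cover different frames")
  bx <- rowMeans(wb$x); by <- rowMeans(wb$y)
  out <- data.frame(
    time_s = wa$times,
    centroid_dist_m = sqrt((rowMeans(wa$x) - bx)^2 + (rowMeans(wa$y) - by)^2))
  for (i in seq_along(wa$ids))
    out[[paste0("dist_", wa$ids[i], "_m")]] <-
      sqrt((wa$x[, i] - bx)^2 + (wa$y[, i] - by)^2)
  out
}

#' Effective playing space (hull area) per frame
#'
#' Area of the convex hull of the group's positions, in real field square
#' meters. Frames where the group is collinear give area 0.
#'
#' @inheritParams centroid_series
#' @param group A group of >= 3 players.
#' @return Data frame `time_s`, `area_m2`.
#' @export
surface_area_series <- function(dataset, group) {
  group <- as_group(group, min_size = 3)
  check_group_present(dataset, group)
  w <- positions_by_frame(dataset, group)
  area <- vapply(seq_along(w$times), function(i)
    convex_hull(cbind(w$x[i, ], w$y[i, ]))$area, numeric(1))
  data.frame(time_s = w$times, area_m2 = area)
}

#' Overlapped hull area of two groups per frame
#'
#' Area of the intersection of the two groups' convex hulls, by convex
#' polygon clipping. Always `0 <= overlap <= min(area_a, area_b)`.
#'
#' @param dataset A `positional_dataset`.
#' @param group_a,group_b Groups of >= 3 players each.
#' @return Data frame `time_s`, `overlap_m2`.
#' @export
overlap_area_series <- function(dataset, group_a, group_b) {
  group_a <- as_group(group_a, min_size = 3)
  group_b <- as_group(group_b, min_size = 3)
  check_group_present(dataset, group_a)
  check_group_present(dataset, group_b)
  wa <- positions_by_frame(dataset, group_a)
  wb <- positions_by_frame(dataset, group_b)
  if (!identical(wa$times, wb$times))
    abort_validation("the two groups cover different frames")
  ov <- vapply(seq_along(wa$times), function(i) {
    ha <- convex_hull(cbind(wa$x[i, ], wa$y[i, ]))
    hb <- convex_hull(cbind(wb$x[i, ], wb$y[i, ]))
    if (ha$degenerate || hb$degenerate) return(0)
    convex_intersection_area(ha$vertices, hb$vertices)
  }, numeric(1))
  data.frame(time_s = wa$times, overlap_m2 = ov)
}

#' Team length and width per frame
#'
#' Team spread: the max-min difference of member positions along the
#' longitudinal axis (length) and the transverse axis (width).
#'
#' @inheritParams centroid_series
#' @return Data frame `time_s`, `length_m`, `width_m`.
#' @export
length_width_series <- function(dataset, group) {
  group <- as_group(group, min_size = 2)
  check_group_present(dataset, group)
  w <- positions_by_frame(dataset, group)
  rng <- function(m) apply(m, 1, max) - apply(m, 1, min)
  data.frame(time_s = w$times, length_m = rng(w$x), width_m = rng(w$y))
}

#' Full collective series for a group
#'
#' Convenience wrapper assembling centroid, stretch index (+ rate), hull
#' area, and length/width into one per-frame table. Area needs >= 3 players;
#' for 2-player groups it is reported as `NA`.
#'
#' @inheritParams centroid_series
#' @return Data frame `time_s, stretch_index_m, stretch_rate_mps, area_m2,
#'   length_m, width_m, centroid_x_m, centroid_y_m`.
#' @export
collective_series <- function(dataset, group) {
  group <- as_group(group, min_size = 2)
  cen <- centroid_series(dataset, group)
  si <- stretch_index_series(dataset, group)
  lw <- length_width_series(dataset, group)
  area <- if (length(group$player_ids) >= 3)
    surface_area_series(dataset, group)$area_m2 else NA_real_
  data.frame(time_s = cen$time_s,
             stretch_index_m = si$stretch_index_m,
             stretch_rate_mps = si$stretch_rate_mps,
             area_m2 = area,
             length_m = lw$length_m,
             width_m = lw$width_m,
             centroid_x_m = cen$centroid_x_m,
             centroid_y_m = cen$centroid_y_m)
}
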