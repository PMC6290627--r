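square4 <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))

test_that("centroid is the unweighted mean of member positions", {
  ds <- static_dataset(square4, nf = 3)
  cen <- centroid_series(ds, paste0("P", 1:4))
  expect_equal(cen$centroid_x_m, rep(1, 3))
  expect_equal(cen$centroid_y_m, rep(1, 3))

  two <- static_dataset(rbind(c(0, 0), c(4, 0)), nf = 2)
  cen2 <- centroid_series(two, c("P1", "P2"))
  expect_equal(cen2$centroid_x_m, rep(2, 2))

  # permutation invariance
  cen3 <- centroid_series(ds, c("P3", "P1", "P4", "P2"))
  expect_equal(cen3, cen)

  expect_error(centroid_series(ds, "P1"), class = "teamdyn_group_size_error")
})

test_that("a member missing at some frames is a validation error", {
  recs <- rbind(
    data.frame(time_s = seq(0, 0.4, 0.1), player_id = "a", team = "T",
               x_m = 10, y_m = 10),
    data.frame(time_s = seq(0, 0.2, 0.1), player_id = "b", team = "T",
               x_m = 20, y_m = 20))
  ds <- positional_dataset(recs, rate = 10)
  expect_error(centroid_series(ds, c("a", "b")),
               class = "teamdyn_validation_error")
  expect_error(centroid_series(ds, c("a", "zz")),
               class = "teamdyn_validation_error")
})

test_that("radial distances and stretch index follow the centroid geometry", {
  ds <- static_dataset(square4, nf = 3)
  rd <- radial_distances(ds, paste0("P", 1:4))
  for (p in paste0("P", 1:4))
    expect_equal(rd[[paste0("dist_", p, "_m")]], rep(sqrt(2), 3))
  si <- stretch_index_series(ds, paste0("P", 1:4))
  expect_equal(si$stretch_index_m, rep(sqrt(2), 3))
  expect_equal(si$stretch_rate_mps, rep(0, 3))

  same <- static_dataset(rbind(c(5, 5), c(5, 5) + 1e-15), nf = 3)
  expect_equal(stretch_index_series(same, c("P1", "P2"))$stretch_index_m,
               rep(0, 3), tolerance = 1e-12)

  set.seed(5)
  pts <- cbind(runif(6, 0, 105), runif(6, 0, 68))
  dsr <- static_dataset(pts, nf = 1)
  rdr <- radial_distances(dsr, paste0("P", 1:6))
  ctr <- colMeans(pts)
  expect_equal(unlist(rdr[1, -1], use.names = FALSE),
               sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2),
               tolerance = 1e-12)
})

test_that("stretch rate of a linearly expanding square matches the closed form", {
  # square with corners at center +- (t+1, t+1): SI(t) = sqrt(2) (t+1)
  nf <- 51
  t <- (seq_len(nf) - 1) / 10
  ctr <- c(50, 34)
  pos <- list(P1 = cbind(ctr[1] - (t + 1), ctr[2] - (t + 1)),
              P2 = cbind(ctr[1] + (t + 1), ctr[2] - (t + 1)),
              P3 = cbind(ctr[1] - (t + 1), ctr[2] + (t + 1)),
              P4 = cbind(ctr[1] + (t + 1), ctr[2] + (t + 1)))
  ds <- toy_dataset(pos)
  si <- stretch_index_series(ds, paste0("P", 1:4))
  expect_equal(si$stretch_index_m, sqrt(2) * (t + 1), tolerance = 1e-9)
  # linear growth: centered and one-sided differences are both exact
  expect_equal(si$stretch_rate_mps, rep(sqrt(2), nf), tolerance = 1e-9)
})

test_that("inter-centroid distances handle symmetry, coincidence and overlap", {
  ctr <- c(52.5, 34)
  a <- rbind(c(40, 24), c(44, 34), c(40, 44))
  b <- 2 * matrix(ctr, 3, 2, byrow = TRUE) - a   # mirror image about center
  ds <- static_dataset(rbind(a, b), nf = 2)
  ga <- paste0("P", 1:3); gb <- paste0("P", 4:6)
  cd <- centroid_distances(ds, ga, gb)
  da <- sqrt(sum((colMeans(a) - ctr)^2))
  expect_equal(cd$centroid_dist_m, rep(2 * da, 2), tolerance = 1e-12)
  expect_equal(cd$dist_P1_m,
               rep(sqrt(sum((a[1, ] - colMeans(b))^2)), 2), tolerance = 1e-12)

  coin <- static_dataset(rbind(a, a), nf = 2)
  expect_equal(centroid_distances(coin, ga, gb)$centroid_dist_m, rep(0, 2))

  expect_error(centroid_distances(ds, ga, c("P3", "P4", "P5")),
               class = "teamdyn_domain_error")
})

test_that("surface area series tracks the hull in field meters", {
  ds <- static_dataset(square4, nf = 4)
  sa <- surface_area_series(ds, paste0("P", 1:4))
  expect_equal(sa$area_m2, rep(4, 4))
  expect_error(surface_area_series(ds, c("P1", "P2")),
               class = "teamdyn_group_size_error")

  # uniform contraction: area scales as s^2 and shrinks monotonically
  nf <- 20
  s <- seq(1, 0.05, length.out = nf)
  ctr <- c(52.5, 34)
  pos <- lapply(seq_len(4), function(i)
    cbind(ctr[1] + (square4[i, 1] - 1) * 10 * s,
          ctr[2] + (square4[i, 2] - 1) * 10 * s))
  names(pos) <- paste0("P", 1:4)
  sa2 <- surface_area_series(toy_dataset(pos), paste0("P", 1:4))
  expect_equal(sa2$area_m2, 400 * s^2, tolerance = 1e-9)
  expect_true(all(diff(sa2$area_m2) < 0))
})

test_that("hull overlap series respects containment bounds", {
  outer <- square4 * 10 + 20
  inner <- square4 * 2 + 36            # 4 m^2 square inside the 400 m^2 one
  far <- sweep(square4, 2, c(90, 60), "+")
  ds <- static_dataset(rbind(outer, inner, far), nf = 2)
  go <- paste0("P", 1:4); gi <- paste0("P", 5:8); gf <- paste0("P", 9:12)
  expect_equal(overlap_area_series(ds, go, gi)$overlap_m2, rep(16, 2))
  expect_equal(overlap_area_series(ds, go, gf)$overlap_m2, rep(0, 2))
  expect_equal(overlap_area_series(ds, go, go)$overlap_m2, rep(400, 2))
})

test_that("team length and width are the axis spreads", {
  ds <- static_dataset(square4, nf = 2)
  lw <- length_width_series(ds, paste0("P", 1:4))
  expect_equal(lw$length_m, rep(2, 2))
  expect_equal(lw$width_m, rep(2, 2))

  line <- static_dataset(cbind(c(10, 20, 30), 34), nf = 2)
  lw2 <- length_width_series(line, paste0("P", 1:3))
  expect_equal(lw2$width_m, rep(0, 2))
  expect_equal(lw2$length_m, rep(20, 2))

  set.seed(6)
  pts <- cbind(runif(7, 0, 105), runif(7, 0, 68))
  lw3 <- length_width_series(static_dataset(pts, nf = 1), paste0("P", 1:7))
  expect_equal(lw3$length_m, diff(range(pts[, 1])))
  expect_equal(lw3$width_m, diff(range(pts[, 2])))
})

test_that("collective metrics transform correctly under translation, rotation and scaling", {
  set.seed(8)
  pts <- cbind(runif(6, 30, 70), runif(6, 20, 50))
  g <- paste0("P", 1:6)
  big <- pitch_model(400, 400)
  base <- static_dataset(pts, nf = 1, pitch = big)

  shift <- c(13, -7)
  moved <- static_dataset(sweep(pts, 2, -shift), nf = 1, pitch = big)
  expect_equal(centroid_series(moved, g)$centroid_x_m,
               centroid_series(base, g)$centroid_x_m + shift[1])
  expect_equal(stretch_index_series(moved, g)$stretch_index_m,
               stretch_index_series(base, g)$stretch_index_m)
  expect_equal(surface_area_series(moved, g)$area_m2,
               surface_area_series(base, g)$area_m2, tolerance = 1e-9)
  expect_equal(length_width_series(moved, g)$length_m,
               length_width_series(base, g)$length_m)

  th <- 0.6
  R <- rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  rot <- static_dataset(pts %*% R + 150, nf = 1, pitch = big)
  expect_equal(stretch_index_series(rot, g)$stretch_index_m,
               stretch_index_series(base, g)$stretch_index_m, tolerance = 1e-9)
  expect_equal(surface_area_series(rot, g)$area_m2,
               surface_area_series(base, g)$area_m2, tolerance = 1e-9)
  # axis-aligned by definition: length/width need not be rotation-invariant
  expect_false(isTRUE(all.equal(
    length_width_series(rot, g)$length_m,
    length_width_series(base, g)$length_m, tolerance = 1e-6)))

  s <- 1.7
  ctr <- colMeans(pts)
  scl <- static_dataset(sweep(sweep(pts, 2, ctr) * s, 2, -ctr), nf = 1,
                        pitch = big)
  expect_equal(stretch_index_series(scl, g)$stretch_index_m,
               s * stretch_index_series(base, g)$stretch_index_m,
               tolerance = 1e-9)
  expect_equal(surface_area_series(scl, g)$area_m2,
               s^2 * surface_area_series(base, g)$area_m2, tolerance = 1e-9)
  expect_equal(length_width_series(scl, g)$length_m,
               s * length_width_series(base, g)$length_m, tolerance = 1e-9)
})

test_that("area never exceeds length x width, and the combined series is consistent", {
  ds <- generate_dataset(generator_config(duration = 20, seed = 9))
  g <- players(ds)[1:6]
  cs <- collective_series(ds, g)
  expect_true(all(cs$area_m2 <= cs$length_m * cs$width_m + 1e-9))
  expect_true(all(cs$stretch_index_m >= 0))
  expect_equal(cs$area_m2, surface_area_series(ds, g)$area_m2)
  expect_equal(cs$centroid_x_m, centroid_series(ds, g)$centroid_x_m)
  # centroid stays inside the group's bounding box
  pb <- teamdyn:::positions_by_frame(ds, group_selection(g))
  expect_true(all(cs$centroid_x_m >= apply(pb$x, 1, min) &
                  cs$centroid_x_m <= apply(pb$x, 1, max)))
})
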