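# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals.

# Brute-force convex hull: a point is a hull vertex iff it is not contained
# in the closed triangle of any three other points. O(n^4).
bf_hull <- function(pts) {
  n <- nrow(pts)
  keep <- rep(TRUE, n)
  for (p in seq_len(n)) {
    others <- setdiff(seq_len(n), p)
    if (length(others) < 3) next
    tri <- utils::combn(others, 3)
    px <- pts[p, 1]; py <- pts[p, 2]
    for (k in seq_len(ncol(tri))) {
      a <- pts[tri[1, k], ]; b <- pts[tri[2, k], ]; c <- pts[tri[3, k], ]
      s1 <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
      s2 <- (c[1] - b[1]) * (py - b[2]) - (c[2] - b[2]) * (px - b[1])
      s3 <- (a[1] - c[1]) * (py - c[2]) - (a[2] - c[2]) * (px - c[1])
      eps <- 1e-12
      if ((s1 >= -eps && s2 >= -eps && s3 >= -eps) ||
          (s1 <= eps && s2 <= eps && s3 <= eps)) {
        keep[p] <- FALSE
        break
      }
    }
  }
  v <- pts[keep, , drop = FALSE]
  ctr <- colMeans(v)
  v <- v[order(atan2(v[, 2] - ctr[2], v[, 1] - ctr[1])), , drop = FALSE]
  m <- nrow(v)
  j <- c(2:m, 1)
  list(vertices = v,
       area = abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2)
}

# Literal double-loop Approximate Entropy (Pincus convention, self-matches
# included), Chebyshev distance.
apen_ref <- function(x, m, r) {
  N <- length(x)
  phi <- function(k) {
    nw <- N - k + 1
    logC <- numeric(nw)
    for (i in seq_len(nw)) {
      cnt <- 0
      for (j in seq_len(nw)) {
        d <- 0
        for (l in 0:(k - 1)) d <- max(d, abs(x[i + l] - x[j + l]))
        if (d <= r) cnt <- cnt + 1
      }
      logC[i] <- log(cnt / nw)
    }
    mean(logC)
  }
  phi(m) - phi(m + 1)
}

# Independent analytic-signal phase: Hilbert transform as the frequency-domain
# -i*sign(f) filter giving the quadrature component, then atan2.
hilbert_phase_ref <- function(x) {
  xc <- x - mean(x)
  n <- length(xc)
  f <- c(0, seq_len(n - 1))
  sgn <- ifelse(f == 0 | (n %% 2 == 0 & f == n / 2), 0,
                ifelse(f < n / 2 + (n %% 2), 1, -1))
  H <- Re(stats::fft(stats::fft(xc) * complex(imaginary = -sgn),
                     inverse = TRUE) / n)
  atan2(H, xc) * 180 / pi
}

wrap180 <- function(d) {
  w <- d %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

# Build a positional dataset from per-player coordinate matrices (n x 2),
# all on the same grid.
toy_dataset <- function(pos, rate = 10, pitch = pitch_model(), team = NULL) {
  ids <- names(pos)
  n <- nrow(pos[[1]])
  t <- (seq_len(n) - 1) / rate
  recs <- do.call(rbind, lapply(seq_along(ids), function(i) {
    data.frame(time_s = t, player_id = ids[i],
               team = if (is.null(team)) "T" else team[i],
               x_m = pos[[i]][, 1], y_m = pos[[i]][, 2],
               stringsAsFactors = FALSE)
  }))
  suppressWarnings(positional_dataset(recs, rate = rate, pitch = pitch))
}

# static group: every player fixed at a point, nf frames
static_dataset <- function(points, nf = 5, rate = 10, ...) {
  pos <- lapply(seq_len(nrow(points)), function(i)
    matrix(rep(points[i, ], each = nf), ncol = 2))
  names(pos) <- paste0("P", seq_len(nrow(points)))
  toy_dataset(pos, rate = rate, ...)
}
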