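# Inter-player coordination: analytic-signal instantaneous phase, pairwise
# relative phase, circular summaries, Approximate Entropy.

# analytic signal via FFT: zero the negative frequencies, double the positive
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

wrap_degrees <- function(d) {
  w <- d %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

#' Instantaneous phase of a uniformly sampled signal
#'
#' Phase of the analytic signal (Hilbert-transform construction) of the
#' mean-centered, optionally detrended input, in degrees wrapped to
#' (-180, 180]. The phase of a non-centered oscillation is distorted, hence
#' the centering; a constant signal has no defined phase and is rejected.
#'
#' @param signal Numeric vector, uniformly sampled, length >= 8.
#' @param detrend Remove a linear trend before the transform.
#' @return Numeric vector of phases in degrees, one per sample.
#' @export
instantaneous_phase <- function(signal, detrend = FALSE) {
  if (length(signal) < 8)
    abort_data("need at least 8 samples for a phase estimate")
  if (any(!is.finite(signal)))
    abort_domain("signal contains non-finite values")
  if (stats::sd(signal) < 1e-12)
    abort_degenerate("constant signal: instantaneous phase is undefined")
  x <- signal - mean(signal)
  if (detrend) x <- stats::residuals(stats::lm(x ~ seq_along(x)))
  a <- analytic_signal(x)
  wrap_degrees(atan2(Im(a), Re(a)) * 180 / pi)
}

#' Relative phase between two oscillating signals
#'
#' Per-frame difference of the two signals' instantaneous phases, wrapped to
#' (-180, 180] degrees: values near 0 degrees indicate in-phase
#' (simultaneous) movement patterns, values near 180 degrees anti-phase
#' (asynchronous) ones. Relative phase is amplitude-free: rescaling or
#' offsetting either input does not change it. The analytic signal is
#' unreliable near the series ends, so the first and last `edge_trim`
#' fraction of frames are flagged (`interior` column) and excluded from
#' circular summaries downstream.
#'
#' @param signal_a,signal_b Equal-length uniformly sampled numeric vectors.
#' @param times Optional per-frame times in seconds (default frame index).
#' @param edge_trim Fraction of frames flagged as edge at each end
#'   (default 0.05).
#' @param pair Optional labels `c(label_a, label_b)` for the signal pair.
#' @return A `phase_series`: data frame `time_s`, `relative_phase_deg`,
#'   `interior`, with the pair labels as attribute.
#' @export
relative_phase <- function(signal_a, signal_b, times = NULL,
                           edge_trim = 0.05, pair = c("a", "b")) {
  if (length(signal_a) != length(signal_b))
    abort_validation("signals have different lengths")
  pa <- instantaneous_phase(signal_a)
  pb <- instantaneous_phase(signal_b)
  n <- length(pa)
  if (is.null(times)) times <- seq_len(n) - 1
  k <- floor(n * edge_trim)
  interior <- rep(TRUE, n)
  if (k > 0) interior[c(seq_len(k), n - seq_len(k) + 1)] <- FALSE
  structure(data.frame(time_s = times,
                       relative_phase_deg = wrap_degrees(pa - pb),
                       interior = interior),
            pair = pair,
            class = c("phase_series", "data.frame"))
}

#' Circular mean and resultant length of a set of angles
#'
#' Angle of the mean unit vector, with the mean resultant length as a
#' concentration measure (1 = all angles identical, 0 = no preferred
#' direction). When the resultant is numerically zero (e.g. antipodal
#' angles) the mean direction is undefined and reported as `NA`.
#'
#' @param phases_deg Numeric vector of angles in degrees.
#' @return List with `mean_deg` (in (-180, 180], or `NA` if undefined) and
#'   `resultant` in `[0, 1]`.
#' @export
circular_mean <- function(phases_deg) {
  if (length(phases_deg) == 0)
    abort_empty("no angles given")
  rad <- phases_deg * pi / 180
  z <- complex(real = mean(cos(rad)), imaginary = mean(sin(rad)))
  r <- Mod(z)
  if (r < 1e-12)
    return(list(mean_deg = NA_real_, resultant = 0))
  list(mean_deg = wrap_degrees(Arg(z) * 180 / pi), resultant = r)
}

#' Approximate Entropy (ApEn) of a time series
#'
#' Regularity statistic `ApEn = Phi^m(r) - Phi^(m+1)(r)` where
#' `Phi^k(r) = (N-k+1)^-1 sum_i log C_i^k(r)` and `C_i^k(r)` is the fraction
#' of length-`k` windows within Chebyshev distance `r` of window `i`.
#' Self-matches are included (the classic formulation), which guarantees
#' `ApEn >= 0` and no `log(0)`. A perfectly repeatable (constant) series has
#' ApEn exactly 0; more irregular series score higher (typically up to about
#' 2 for this class of data).
#'
#' @param series Numeric vector, length > m + 1.
#' @param m Embedding (pattern) length, default 2.
#' @param r Tolerance, in the units of the series; default 0.2 times the
#'   series SD (the field-standard choice). Must be positive, so for a
#'   constant series pass an absolute `r`.
#' @return Non-negative scalar.
#' @export
apen <- function(series, m = 2, r = 0.2 * stats::sd(series)) {
  N <- length(series)
  if (m < 1) abort_domain("m must be >= 1")
  if (!is.finite(r) || r <= 0)
    abort_domain("tolerance r must be positive (pass an absolute r for constant series)")
  if (N <= m + 1)
    abort_data(sprintf("series of length %d too short for m = %d (need > m+1)", N, m))
  phi <- function(k) {
    nw <- N - k + 1
    W <- vapply(seq_len(k), function(j) series[j:(j + nw - 1)], numeric(nw))
    W <- matrix(W, nrow = nw)
    C <- vapply(seq_len(nw), function(i) {
      dmax <- abs(W[, 1] - W[i, 1])
      for (j in seq_len(k)[-1]) dmax <- pmax(dmax, abs(W[, j] - W[i, j]))
      sum(dmax <= r) / nw
    }, numeric(1))
    mean(log(C))
  }
  phi(m) - phi(m + 1)
}

#' Pairwise coordination profile from distances to the group centroid
#'
#' Builds each player's distance-to-group-centroid series over the dataset's
#' span, computes the relative phase between the two, and summarises it with
#' the circular mean/resultant over interior frames plus the Approximate
#' Entropy of the relative-phase series (a measure of how unpredictable the
#' coordination is).
#'
#' @param dataset A `positional_dataset` (slice it to the interval of
#'   interest first).
#' @param player_a,player_b The pair to analyse; must belong to `group`.
#' @param group The [group_selection()] whose centroid defines the radial
#'   signals.
#' @param edge_trim Fraction of frames flagged as edge per end.
#' @param apen_m,apen_r ApEn parameters (default m = 2,
#'   r = 0.2 x SD of the interior relative-phase series).
#' @return List with `phase` (a `phase_series`), `mean_deg`, `resultant`,
#'   `apen`.
#' @export
coordination_profile <- function(dataset, player_a, player_b, group,
                                 edge_trim = 0.05, apen_m = 2, apen_r = NULL) {
  group <- as_group(group, min_size = 2)
  if (!all(c(player_a, player_b) %in% group$player_ids))
    abort_domain("both players must belong to the group")
  rd <- radial_distances(dataset, group)
  sa <- rd[[paste0("dist_", player_a, "_m")]]
  sb <- rd[[paste0("dist_", player_b, "_m")]]
  for (p in c(player_a, player_b)) {
    s <- rd[[paste0("dist_", p, "_m")]]
    if (stats::sd(s) < 1e-12)
      abort_degenerate(sprintf(
        "player '%s' has a constant distance-to-centroid signal; phase undefined", p))
  }
  ph <- relative_phase(sa, sb, times = rd$time_s, edge_trim = edge_trim,
                       pair = c(player_a, player_b))
  int <- ph$relative_phase_deg[ph$interior]
  cm <- circular_mean(int)
  if (is.null(apen_r)) apen_r <- 0.2 * stats::sd(int)
  ae <- if (is.finite(apen_r) && apen_r > 0) apen(int, m = apen_m, r = apen_r) else 0
  list(phase = ph, mean_deg = cm$mean_deg, resultant = cm$resultant, apen = ae)
}
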