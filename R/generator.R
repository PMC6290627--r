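# Synthetic match-like positional data with known ground truth, so every
# metric is testable without external tracking data. Agents follow prescribed
# kinematics: an anchor (or linear waypoint drift), sinusoidal oscillation
# per axis, optional piecewise-constant speed shuttles, plus additive
# Gaussian position noise emulating tracking jitter.

#' Agent specification for the trajectory generator
#'
#' @param id Player id (unique within a config).
#' @param team Team label.
#' @param anchor `(x, y)` base position in meters.
#' @param amplitude Oscillation amplitude in meters per axis `(ax, ay)`.
#' @param frequency Oscillation frequency in Hz per axis.
#' @param phase_deg Oscillation phase offset in degrees per axis.
#' @param noise_sd SD (meters) of additive i.i.d. Gaussian position noise,
#'   applied after trajectory construction and before clamping to the pitch.
#' @param waypoints Optional data frame `time_s, x_m, y_m`; the anchor then
#'   drifts along the piecewise-linear path through these points.
#' @param speed_profile Optional numeric vector of target speeds (m/s); the
#'   agent runs a longitudinal shuttle, switching speed at equal-duration
#'   segments and reflecting off the pitch ends. Overrides x oscillation.
#' @return An `agent_spec` list.
#' @export
agent_spec <- function(id, team, anchor,
                       amplitude = c(0, 0), frequency = c(0, 0),
                       phase_deg = c(0, 0), noise_sd = 0,
                       waypoints = NULL, speed_profile = NULL) {
  if (length(anchor) != 2 || any(!is.finite(anchor)))
    abort_config("anchor must be finite (x, y)")
  rep2 <- function(v) if (length(v) == 1) c(v, v) else v
  structure(list(id = as.character(id), team = as.character(team),
                 anchor = as.numeric(anchor),
                 amplitude = rep2(as.numeric(amplitude)),
                 frequency = rep2(as.numeric(frequency)),
                 phase_deg = rep2(as.numeric(phase_deg)),
                 noise_sd = as.numeric(noise_sd),
                 waypoints = waypoints, speed_profile = speed_profile),
            class = "agent_spec")
}

#' Generator configuration
#'
#' Defaults emulate one half of a match: 2700 s at 10 Hz on a standard
#' 105 x 68 m pitch (27,000 samples per agent), two teams of 10 oscillating
#' outfield agents with realistic tracking jitter.
#'
#' @param duration Seconds of data to generate (default 2700, one half).
#' @param rate Sampling rate in Hz (default 10).
#' @param pitch A [pitch_model()] (default 105 x 68 m).
#' @param teams List of two lists of [agent_spec()]s; default
#'   [default_teams()].
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A `generator_config` list.
#' @export
generator_config <- function(duration = 2700, rate = 10,
                             pitch = pitch_model(), teams = NULL, seed = 1) {
  if (!is.finite(duration) || duration <= 0) abort_config("duration must be > 0")
  if (!is.finite(rate) || rate <= 0) abort_config("rate must be > 0")
  if (is.null(teams)) teams <- default_teams(pitch = pitch)
  ids <- unlist(lapply(teams, function(tt) vapply(tt, `[[`, "", "id")))
  if (anyDuplicated(ids)) abort_config("duplicated agent ids across teams")
  structure(list(duration = duration, rate = rate, pitch = pitch,
                 teams = teams, seed = as.integer(seed)),
            class = "generator_config")
}

#' Two default teams of oscillating agents
#'
#' `n_per_team` agents per side on a staggered formation grid, oscillating
#' with individual amplitudes (2-6 m), frequencies (0.05-0.2 Hz) and phase
#' offsets, with 0.2 m tracking jitter.
#'
#' @param n_per_team Agents per team (default 10 outfield players).
#' @param pitch A [pitch_model()].
#' @param noise_sd Position noise SD in meters.
#' @return List of two lists of [agent_spec()]s, named `home` and `away`.
#' @export
default_teams <- function(n_per_team = 10, pitch = pitch_model(),
                          noise_sd = 0.2) {
  make_side <- function(team, x0) {
    lapply(seq_len(n_per_team), function(i) {
      row <- (i - 1) %/% 5
      col <- (i - 1) %% 5
      agent_spec(
        id = paste0(team, i), team = team,
        anchor = c(x0 + row * 12, pitch$width * (col + 1) / 6),
        amplitude = c(2 + (i %% 3) * 2, 2 + ((i + 1) %% 3) * 2),
        frequency = c(0.05 + 0.03 * (i %% 5), 0.04 + 0.025 * ((i + 2) %% 5)),
        phase_deg = c(36 * i, 36 * i + 90),
        noise_sd = noise_sd)
    })
  }
  list(home = make_side("H", pitch$length * 0.25),
       away = make_side("A", pitch$length * 0.55))
}

# deterministic per-agent substream: adding an agent never perturbs others
agent_seed <- function(seed, id) {
  h <- 0
  for (ch in utf8ToInt(id)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + (seed %% 2147483647) * 1000003) %% 2147483647)
}

# fold an unbounded coordinate into [lo, hi] by reflection (triangle wave)
reflect_into <- function(z, lo, hi) {
  w <- hi - lo
  m <- (z - lo) %% (2 * w)
  lo + ifelse(m <= w, m, 2 * w - m)
}

agent_trajectory <- function(spec, t, pitch, seed) {
  n <- length(t)
  if (!is.null(spec$waypoints)) {
    wp <- spec$waypoints
    bx <- stats::approx(wp$time_s, wp$x_m, xout = t, rule = 2)$y
    by <- stats::approx(wp$time_s, wp$y_m, xout = t, rule = 2)$y
  } else {
    bx <- rep(spec$anchor[1], n)
    by <- rep(spec$anchor[2], n)
  }
  x <- bx + spec$amplitude[1] *
    sin(2 * pi * spec$frequency[1] * t + spec$phase_deg[1] * pi / 180)
  y <- by + spec$amplitude[2] *
    sin(2 * pi * spec$frequency[2] * t + spec$phase_deg[2] * pi / 180)
  if (!is.null(spec$speed_profile)) {
    v <- spec$speed_profile
    seg <- pmin(floor(t / (max(t) + 1e-9) * length(v)) + 1, length(v))
    dt <- c(0, diff(t))
    x <- reflect_into(spec$anchor[1] + cumsum(v[seg] * dt), 1, pitch$length - 1)
  }
  if (spec$noise_sd > 0) {
    set.seed(agent_seed(seed, spec$id))
    x <- x + stats::rnorm(n, sd = spec$noise_sd)
    y <- y + stats::rnorm(n, sd = spec$noise_sd)
  }
  cx <- pmin(pmax(x, 0), pitch$length)
  cy <- pmin(pmax(y, 0), pitch$width)
  if (all(x != cx | y != cy))
    abort_config(sprintf("agent '%s' trajectory lies entirely out of bounds", spec$id))
  data.frame(time_s = t, player_id = spec$id, team = spec$team,
             x_m = cx, y_m = cy, stringsAsFactors = FALSE)
}

#' Generate a synthetic positional dataset
#'
#' Deterministic under the config seed: the same config yields an identical
#' dataset (and byte-identical CSV via [write_positional_csv()]). Each agent
#' contributes `duration x rate` samples at times `0, 1/rate, ...`.
#'
#' @param config A [generator_config()].
#' @return A `positional_dataset`.
#' @examples
#' ds <- generate_dataset(generator_config(duration = 30, seed = 7))
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- round(config$duration * config$rate)
  t <- (seq_len(n) - 1) / config$rate
  specs <- do.call(c, unname(config$teams))
  recs <- do.call(rbind, lapply(specs, agent_trajectory,
                                t = t, pitch = config$pitch, seed = config$seed))
  suppressWarnings(
    positional_dataset(recs, rate = config$rate, pitch = config$pitch))
}

#' Scripted scenarios with injected ground truth
#'
#' Each scenario produces a dataset plus an event log of what was injected,
#' for recovery tests and worked examples:
#'
#' * `goal_buildup` - an attacking trio drifts forward while a defending trio
#'   retreats; their centroids cross at a known time (the classic scoring-
#'   opportunity signature). Event: `centroid_crossover` with `time_s`.
#' * `coordination_break` - two defenders oscillate radially in phase about
#'   their group's centre; for a known window one flips to anti-phase (one
#'   moves toward the centroid while the other moves away). Event:
#'   `coordination_break` with `start_s`, `end_s`, `players`.
#' * `expansion_contraction` - a group uniformly expands about its centre,
#'   then contracts; the stretch-index rate is positive during expansion and
#'   negative during contraction. Events: `expansion` / `contraction` phases
#'   with boundaries.
#'
#' @param name One of `"goal_buildup"`, `"coordination_break"`,
#'   `"expansion_contraction"`.
#' @param seed Integer seed for the noise streams.
#' @param noise_sd Position noise SD in meters (default 0.1).
#' @return List with `dataset` (a `positional_dataset`), `events` (list of
#'   event records) and `groups` (named lists of player ids).
#' @export
scenario <- function(name = c("goal_buildup", "coordination_break",
                              "expansion_contraction"),
                     seed = 1, noise_sd = 0.1) {
  name <- tryCatch(match.arg(name), error = function(e)
    abort_domain(sprintf("unknown scenario '%s'", name[1])))
  switch(name,
         goal_buildup = scenario_goal_buildup(seed, noise_sd),
         coordination_break = scenario_coordination_break(seed, noise_sd),
         expansion_contraction = scenario_expansion_contraction(seed, noise_sd))
}

scenario_goal_buildup <- function(seed, noise_sd) {
  duration <- 60; rate <- 10
  pm <- pitch_model()
  # attacking trio advances 40 -> 70 m, defending trio retreats 62 -> 52 m;
  # centroid x lines cross at t* = (62 - 40) / (0.5 + 1/6) = 33 s
  va <- 30 / duration; vd <- -10 / duration
  t_cross <- (62 - 40) / (va - vd)
  mk <- function(id, team, x0, v, y) {
    agent_spec(id, team, anchor = c(x0, y),
               amplitude = c(0, 2), frequency = c(0, 0.1),
               phase_deg = c(0, 40 * match(id, c("A1", "A2", "A3", "D1", "D2", "D3"))),
               noise_sd = noise_sd,
               waypoints = data.frame(time_s = c(0, duration),
                                      x_m = c(x0, x0 + v * duration),
                                      y_m = c(y, y)))
  }
  atk <- list(mk("A1", "attack", 36, va, 24), mk("A2", "attack", 40, va, 34),
              mk("A3", "attack", 44, va, 44))
  dfn <- list(mk("D1", "defend", 58, vd, 26), mk("D2", "defend", 62, vd, 34),
              mk("D3", "defend", 66, vd, 42))
  cfg <- generator_config(duration = duration, rate = rate, pitch = pm,
                          teams = list(attack = atk, defend = dfn), seed = seed)
  list(dataset = generate_dataset(cfg),
       events = list(list(type = "centroid_crossover", time_s = t_cross)),
       groups = list(attack = c("A1", "A2", "A3"), defend = c("D1", "D2", "D3")))
}

scenario_coordination_break <- function(seed, noise_sd) {
  duration <- 120; rate <- 10
  pm <- pitch_model()
  t <- (seq_len(duration * rate) - 1) / rate
  win <- c(50, 70)           # anti-phase window for D2
  f <- 0.2; amp <- 3; ramp <- 2
  center <- c(30, 34)        # approximate group centre
  anchors <- list(D1 = c(22, 34), D2 = c(38, 34), D3 = c(30, 26),
                  D4 = c(30, 42), D5 = c(24, 28), D6 = c(36, 40))
  # phase flip for D2: 0 outside the window, pi inside, linear 2 s ramps
  flip <- pi * pmin(1, pmax(0, (t - win[1]) / ramp)) *
    pmin(1, pmax(0, (win[2] - t) / ramp))
  recs <- do.call(rbind, lapply(names(anchors), function(id) {
    a <- anchors[[id]]
    u <- (a - center) / sqrt(sum((a - center)^2))  # outward radial direction
    osc <- if (id %in% c("D1", "D2")) {
      extra <- if (id == "D2") flip else 0
      amp * sin(2 * pi * f * t + extra)
    } else 0
    x <- a[1] + u[1] * osc
    y <- a[2] + u[2] * osc
    set.seed(agent_seed(seed, id))
    if (noise_sd > 0) {
      x <- x + stats::rnorm(length(t), sd = noise_sd)
      y <- y + stats::rnorm(length(t), sd = noise_sd)
    }
    data.frame(time_s = t, player_id = id, team = "defend",
               x_m = pmin(pmax(x, 0), pm$length),
               y_m = pmin(pmax(y, 0), pm$width), stringsAsFactors = FALSE)
  }))
  list(dataset = suppressWarnings(positional_dataset(recs, rate = rate, pitch = pm)),
       events = list(list(type = "coordination_break",
                          start_s = win[1], end_s = win[2],
                          players = c("D1", "D2"))),
       groups = list(defend = names(anchors)))
}

scenario_expansion_contraction <- function(seed, noise_sd) {
  duration <- 60; rate <- 10
  pm <- pitch_model()
  t <- (seq_len(duration * rate) - 1) / rate
  # uniform scaling about the group centre: 1 -> 2 over [0,30], back over [30,60]
  s <- ifelse(t <= 30, 1 + t / 30, 2 - (t - 30) / 30)
  center <- c(52.5, 34)
  ang <- 2 * pi * (0:5) / 6
  recs <- do.call(rbind, lapply(seq_along(ang), function(i) {
    id <- paste0("P", i)
    set.seed(agent_seed(seed, id))
    x <- center[1] + 8 * cos(ang[i]) * s
    y <- center[2] + 8 * sin(ang[i]) * s
    if (noise_sd > 0) {
      x <- x + stats::rnorm(length(t), sd = noise_sd)
      y <- y + stats::rnorm(length(t), sd = noise_sd)
    }
    data.frame(time_s = t, player_id = id, team = "grp",
               x_m = pmin(pmax(x, 0), pm$length),
               y_m = pmin(pmax(y, 0), pm$width), stringsAsFactors = FALSE)
  }))
  list(dataset = suppressWarnings(positional_dataset(recs, rate = rate, pitch = pm)),
       events = list(list(type = "expansion", start_s = 0, end_s = 30),
                     list(type = "contraction", start_s = 30, end_s = 60)),
       groups = list(grp = paste0("P", 1:6)))
}
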