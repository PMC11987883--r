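#' Configuration for the synthetic pre-farrowing activity simulator
#'
#' Describes a cohort of late-pregnancy sows monitored at 5-minute resolution
#' over the 96 hours before farrowing onset. Each simulated series is the sum
#' of a stable baseline, a diurnal sinusoid, a monotone activity ramp that
#' begins about a day before onset, and Gaussian noise whose dispersion is
#' inflated on the final day; values are clipped at zero because activity is
#' non-negative.
#'
#' Defaults emulate the activity regime reported for farrowing sows on a
#' normalized 0--100 scale: a baseline near 15 with day-to-day dispersion
#' around 6, a sustained rise starting roughly 24 h (288 points) before
#' onset that lifts the final-day mean into the 30--40 range, and strongly
#' increased final-day variance.
#'
#' @param n_sows Number of sows in the cohort.
#' @param horizon_points Series length; 1152 points = 96 h at 5-min steps.
#' @param baseline Mean activity level far from onset (normalized units).
#' @param diurnal_amplitude Amplitude of the 24-h sinusoid.
#' @param diurnal_period Diurnal period in points (288 = 24 h).
#' @param diurnal_phase Common diurnal phase in radians at the start of the
#'   series, or `"random"` for an independent uniform phase per sow. The
#'   default is a shared phase: farrowings in a monitored batch are
#'   synchronized (commonly prostaglandin-induced), so onset-anchored series
#'   share their day-night alignment — this is what gives real cohorts their
#'   high cross-sow activity correlation.
#' @param diurnal_phase_sd Per-sow Gaussian jitter (radians) around the
#'   common phase; ignored when `diurnal_phase = "random"`.
#' @param ramp_start Points before onset at which the activity ramp starts.
#' @param ramp_shape `"sigmoid"` (smooth rise, default) or `"linear"`.
#' @param ramp_midpoint For the sigmoid shape: position of the inflection as a
#'   fraction of the ramp (0 = ramp start, 1 = onset).
#' @param ramp_steepness Sigmoid steepness; larger is sharper.
#' @param ramp_magnitude Activity gained from ramp start to onset.
#' @param bout_sd Stationary SD of a per-sow AR(1) "activity bout" process
#'   (slow, autocorrelated fluctuations from feeding and posture changes);
#'   this component is independent across sows and is what keeps cross-sow
#'   activity correlation below 1 in real cohorts.
#' @param bout_timescale Autocorrelation timescale of the bout process in
#'   points (24 = 2 h).
#' @param noise_sd Point-wise Gaussian noise SD.
#' @param final_day_extra_sd Additional noise SD applied to the last
#'   `diurnal_period` points (the final-day dispersion burst).
#' @param baseline_jitter_sd Between-sow SD of the baseline level.
#' @param ramp_start_jitter_sd Between-sow SD (in points) of the ramp start;
#'   real sows begin their activity rise at somewhat different lead times.
#' @param seed Master seed; per-sow streams are derived with [derive_seed()].
#' @return A `sim_config` list.
#' @seealso [simulate_cohort()], [simulate_activity_series()]
#' @export
sim_config <- function(n_sows = 20L,
                       horizon_points = 1152L,
                       baseline = 15,
                       diurnal_amplitude = 6,
                       diurnal_period = 288L,
                       diurnal_phase = 0,
                       diurnal_phase_sd = 0.5,
                       ramp_start = 288L,
                       ramp_shape = c("sigmoid", "linear"),
                       ramp_midpoint = 0.65,
                       ramp_steepness = 7,
                       ramp_magnitude = 60,
                       bout_sd = 5,
                       bout_timescale = 24L,
                       noise_sd = 6,
                       final_day_extra_sd = 5,
                       baseline_jitter_sd = 2,
                       ramp_start_jitter_sd = 24,
                       seed = 1L) {
  ramp_shape <- match.arg(ramp_shape)
  check_count(n_sows, "n_sows")
  check_count(horizon_points, "horizon_points", min = 2L)
  check_scalar_number(baseline, "baseline", min = 0)
  check_scalar_number(diurnal_amplitude, "diurnal_amplitude", min = 0)
  check_count(diurnal_period, "diurnal_period", min = 2L)
  check_count(ramp_start, "ramp_start", min = 0L)
  check_scalar_number(ramp_midpoint, "ramp_midpoint", min = 0)
  check_scalar_number(ramp_steepness, "ramp_steepness", min = 0)
  check_scalar_number(ramp_magnitude, "ramp_magnitude", min = 0)
  check_scalar_number(bout_sd, "bout_sd", min = 0)
  check_count(bout_timescale, "bout_timescale", min = 1L)
  check_scalar_number(noise_sd, "noise_sd", min = 0)
  check_scalar_number(final_day_extra_sd, "final_day_extra_sd", min = 0)
  check_scalar_number(baseline_jitter_sd, "baseline_jitter_sd", min = 0)
  check_scalar_number(ramp_start_jitter_sd, "ramp_start_jitter_sd", min = 0)
  check_count(seed, "seed", min = 0L)
  if (ramp_start >= horizon_points) {
    fc_abort("`ramp_start` must be smaller than `horizon_points`.",
             class = "farrowcast_config_error")
  }
  if (!identical(diurnal_phase, "random")) {
    check_scalar_number(diurnal_phase, "diurnal_phase")
  }
  check_scalar_number(diurnal_phase_sd, "diurnal_phase_sd", min = 0)
  structure(
    list(
      n_sows = as.integer(n_sows),
      horizon_points = as.integer(horizon_points),
      baseline = baseline,
      diurnal_amplitude = diurnal_amplitude,
      diurnal_period = as.integer(diurnal_period),
      diurnal_phase = diurnal_phase,
      diurnal_phase_sd = diurnal_phase_sd,
      ramp_start = as.integer(ramp_start),
      ramp_shape = ramp_shape,
      ramp_midpoint = ramp_midpoint,
      ramp_steepness = ramp_steepness,
      ramp_magnitude = ramp_magnitude,
      bout_sd = bout_sd,
      bout_timescale = as.integer(bout_timescale),
      noise_sd = noise_sd,
      final_day_extra_sd = final_day_extra_sd,
      baseline_jitter_sd = baseline_jitter_sd,
      ramp_start_jitter_sd = ramp_start_jitter_sd,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d sows, %d points (%.0f h at 5-min steps)\n",
              x$n_sows, x$horizon_points, x$horizon_points / 12))
  cat(sprintf("  baseline %.1f, diurnal amp %.1f (period %d), %s ramp of %.1f from %d points pre-onset\n",
              x$baseline, x$diurnal_amplitude, x$diurnal_period,
              x$ramp_shape, x$ramp_magnitude, x$ramp_start))
  cat(sprintf("  noise sd %.1f (+%.1f final day), seed %d\n",
              x$noise_sd, x$final_day_extra_sd, x$seed))
  invisible(x)
}

# ramp profile on u in [0, 1] (0 = ramp start, 1 = onset), rising 0 -> 1
ramp_profile <- function(u, shape, midpoint, steepness) {
  switch(shape,
    linear = u,
    sigmoid = {
      s <- function(z) 1 / (1 + exp(-z))
      lo <- s(steepness * (0 - midpoint))
      hi <- s(steepness * (1 - midpoint))
      (s(steepness * (u - midpoint)) - lo) / (hi - lo)
    }
  )
}

#' Simulate one sow's pre-farrowing activity series
#'
#' Generates a single 5-min-resolution activity series anchored so that the
#' last point falls at farrowing onset (its remaining-time label is 0
#' minutes). Reproducible: the sow's RNG stream depends only on
#' `cfg$seed` and `sow_index`.
#'
#' @param cfg A [sim_config()].
#' @param sow_index Zero-based index of the sow within the cohort.
#' @return A tibble with columns `sow_id`, `point_index` (1-based),
#'   `minutes_to_onset` (ending at 0) and `activity`.
#' @export
#' @examples
#' s <- simulate_activity_series(sim_config(noise_sd = 0), 0)
#' tail(s, 3)
simulate_activity_series <- function(cfg, sow_index = 0L) {
  stopifnot(inherits(cfg, "sim_config"))
  check_count(sow_index, "sow_index", min = 0L)
  n <- cfg$horizon_points
  sow_seed <- derive_seed(cfg$seed, sow_index)
  with_seed(sow_seed, {
    baseline_i <- cfg$baseline +
      if (cfg$baseline_jitter_sd > 0) rnorm(1, 0, cfg$baseline_jitter_sd) else 0
    ramp_start_i <- cfg$ramp_start +
      if (cfg$ramp_start_jitter_sd > 0) round(rnorm(1, 0, cfg$ramp_start_jitter_sd)) else 0
    ramp_start_i <- max(1L, min(n - 1L, as.integer(ramp_start_i)))
    phase_i <- if (identical(cfg$diurnal_phase, "random")) {
      runif(1, 0, 2 * pi)
    } else {
      cfg$diurnal_phase +
        if (cfg$diurnal_phase_sd > 0) rnorm(1, 0, cfg$diurnal_phase_sd) else 0
    }

    idx <- seq_len(n)
    points_to_onset <- n - idx                 # n-1 ... 0
    diurnal <- cfg$diurnal_amplitude * sin(2 * pi * idx / cfg$diurnal_period + phase_i)

    ramp <- numeric(n)
    in_ramp <- points_to_onset < ramp_start_i
    u <- 1 - points_to_onset[in_ramp] / ramp_start_i
    ramp[in_ramp] <- cfg$ramp_magnitude *
      ramp_profile(u, cfg$ramp_shape, cfg$ramp_midpoint, cfg$ramp_steepness)

    bout <- if (cfg$bout_sd > 0) {
      rho <- exp(-1 / cfg$bout_timescale)
      innov <- rnorm(n, 0, cfg$bout_sd * sqrt(1 - rho^2))
      as.numeric(stats::filter(innov, rho, method = "recursive",
                               init = rnorm(1, 0, cfg$bout_sd)))
    } else {
      numeric(n)
    }
    noise <- if (cfg$noise_sd > 0) rnorm(n, 0, cfg$noise_sd) else numeric(n)
    if (cfg$final_day_extra_sd > 0) {
      k <- min(n, cfg$diurnal_period)
      last <- (n - k + 1):n
      noise[last] <- noise[last] + rnorm(k, 0, cfg$final_day_extra_sd)
    }

    activity <- pmax(0, baseline_i + diurnal + ramp + bout + noise)
    tibble::tibble(
      sow_id = sprintf("sow_%02d", sow_index + 1L),
      point_index = idx,
      minutes_to_onset = points_to_onset * 5,
      activity = activity
    )
  })
}

#' Simulate a cohort of sows
#'
#' @param cfg A [sim_config()].
#' @return A long tibble stacking [simulate_activity_series()] for sow
#'   indices `0:(n_sows-1)`; `n_sows * horizon_points` rows.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_sows = 3, horizon_points = 48,
#'                                      diurnal_period = 12, ramp_start = 12))
#' dplyr::count(cohort, sow_id)
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  purrr::map_dfr(seq_len(cfg$n_sows) - 1L,
                 function(i) simulate_activity_series(cfg, i))
}

#' Generate a synthetic frame pair with known optical-flow ground truth
#'
#' Builds a random-texture frame, its circularly-translated counterpart, and
#' the ground-truth flow field (constant, equal to `displacement`, plus
#' optional Gaussian perturbation). Useful for exercising flow metrics and
#' the block-matching reference estimator against a known answer.
#'
#' @param height,width Frame size in pixels (each at least 8).
#' @param displacement Integer 2-vector `c(u, v)`: horizontal (columns) and
#'   vertical (rows) displacement applied to every pixel.
#' @param noise_sd SD of Gaussian noise added to the returned flow field
#'   (the frames themselves stay an exact translation).
#' @param seed RNG seed for the texture (and field noise).
#' @return A list with `frame_a`, `frame_b` (numeric matrices) and `flow`
#'   (a [flow_field()]).
#' @export
generate_flow_pair <- function(height, width, displacement = c(0, 0),
                               noise_sd = 0, seed = 1L) {
  check_count(height, "height", min = 8L)
  check_count(width, "width", min = 8L)
  if (length(displacement) != 2L || any(displacement != round(displacement))) {
    fc_abort("`displacement` must be an integer 2-vector c(u, v).",
             class = "farrowcast_config_error")
  }
  if (abs(displacement[1]) >= width || abs(displacement[2]) >= height) {
    fc_abort("`displacement` exceeds the frame extent.",
             class = "farrowcast_config_error")
  }
  check_scalar_number(noise_sd, "noise_sd", min = 0)
  u0 <- as.integer(displacement[1])
  v0 <- as.integer(displacement[2])
  with_seed(seed, {
    frame_a <- matrix(runif(height * width), nrow = height, ncol = width)
    # pixel (y, x) in frame_a appears at (y + v, x + u) in frame_b
    rows <- ((seq_len(height) - 1L - v0) %% height) + 1L
    cols <- ((seq_len(width) - 1L - u0) %% width) + 1L
    frame_b <- frame_a[rows, cols, drop = FALSE]
    u <- matrix(as.numeric(u0), height, width)
    v <- matrix(as.numeric(v0), height, width)
    if (noise_sd > 0) {
      u <- u + matrix(rnorm(height * width, 0, noise_sd), height, width)
      v <- v + matrix(rnorm(height * width, 0, noise_sd), height, width)
    }
    list(frame_a = frame_a, frame_b = frame_b, flow = flow_field(u, v))
  })
}

#' Write / read a cohort activity table as CSV
#'
#' Plain-text interchange for activity series: one row per sow and time
#' point with columns `sow_id`, `point_index`, `minutes_to_onset`,
#' `activity`.
#'
#' @param cohort A cohort tibble as produced by [simulate_cohort()].
#' @param path File path.
#' @return `write_activity_csv()` returns `path` invisibly;
#'   `read_activity_csv()` returns the cohort tibble.
#' @export
write_activity_csv <- function(cohort, path) {
  need <- c("sow_id", "point_index", "minutes_to_onset", "activity")
  if (!all(need %in% names(cohort))) {
    fc_abort(sprintf("cohort must have columns %s.", paste(need, collapse = ", ")))
  }
  utils::write.csv(cohort[need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_activity_csv
#' @export
read_activity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}
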