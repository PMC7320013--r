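# Simulation of self-paced object-location memory sessions in a circular
# virtual arena, and the behavioral measures computed from them.

#' Configuration for a simulated virtual-navigation session
#'
#' Bundles the kinematic and task parameters of the virtual-reality
#' object-location memory task: a circular arena surrounded by equally spaced
#' landmarks, key-press navigation with a fixed rotation quantum and ramped
#' constant-speed translation, self-paced trials (cue, drop, feedback,
#' collection) interleaved with fixation blocks, and a scanner grid of
#' `n_runs` runs of `trs_per_run` volumes at repetition time `tr`.
#'
#' Angles are degrees in `[0, 360)`, with 0 = arena north and angles
#' increasing clockwise. Positions and distances are in arbitrary virtual
#' units; memory errors are reported in the same units.
#'
#' @param arena_radius Arena radius in virtual units.
#' @param n_landmarks Number of perimeter landmarks.
#' @param landmark_spacing Angular spacing of landmarks in degrees; must
#'   divide 360.
#' @param sample_rate Behavioral logging rate in Hz.
#' @param rotation_quantum Smallest instantaneous rotation in degrees; must
#'   divide 360.
#' @param rotation_speed Sustained rotation speed in degrees/s (one
#'   `rotation_quantum` step per key press).
#' @param translation_ramp Ramp-up time to full translation speed, in ms.
#' @param translation_speed Constant translation speed after the ramp, in
#'   virtual units/s.
#' @param n_objects Number of objects whose locations are memorized.
#' @param trials_per_fixation Integer range (length 2): a fixation block is
#'   inserted after a number of trials drawn uniformly from this range.
#' @param fixation_duration Fixation block duration in s.
#' @param drop_pause Pause at the drop response, in s.
#' @param feedback_duration Duration of location feedback, in s.
#' @param n_runs,trs_per_run,tr Scanner grid: number of runs, volumes per
#'   run, and repetition time in s.
#' @param error_start,error_asymptote Expected memory error (virtual units)
#'   on the first trial and its asymptote after learning.
#' @param learning_rate Per-trial exponential decay rate of the expected
#'   memory error towards its asymptote. Presets: a fast learner is roughly
#'   0.04, a slow learner roughly 0.01.
#' @param error_shape Shape of the mean-one gamma jitter multiplying the
#'   expected per-trial error.
#' @param seed Optional integer seed used by [simulate_session()].
#'
#' @return An object of class `"sim_config"` (a named list).
#' @seealso [simulate_session()]
#' @export
sim_config <- function(arena_radius = 100,
                       n_landmarks = 12,
                       landmark_spacing = 30,
                       sample_rate = 50,
                       rotation_quantum = 10,
                       rotation_speed = 50,
                       translation_ramp = 500,
                       translation_speed = 10,
                       n_objects = 6,
                       trials_per_fixation = c(2L, 4L),
                       fixation_duration = 4,
                       drop_pause = 1,
                       feedback_duration = 2,
                       n_runs = 5,
                       trs_per_run = 210,
                       tr = 2.756,
                       error_start = 40,
                       error_asymptote = 8,
                       learning_rate = 0.02,
                       error_shape = 6,
                       seed = NULL) {
  cfg <- list(
    arena_radius = arena_radius, n_landmarks = n_landmarks,
    landmark_spacing = landmark_spacing, sample_rate = sample_rate,
    rotation_quantum = rotation_quantum, rotation_speed = rotation_speed,
    translation_ramp = translation_ramp, translation_speed = translation_speed,
    n_objects = n_objects, trials_per_fixation = as.integer(trials_per_fixation),
    fixation_duration = fixation_duration, drop_pause = drop_pause,
    feedback_duration = feedback_duration, n_runs = n_runs,
    trs_per_run = trs_per_run, tr = tr, error_start = error_start,
    error_asymptote = error_asymptote, learning_rate = learning_rate,
    error_shape = error_shape, seed = seed
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (360 %% cfg$rotation_quantum != 0) {
    stop("`rotation_quantum` must divide 360 (got ", cfg$rotation_quantum, ")")
  }
  if (360 %% cfg$landmark_spacing != 0) {
    stop("`landmark_spacing` must divide 360 (got ", cfg$landmark_spacing, ")")
  }
  durs <- c(cfg$sample_rate, cfg$rotation_speed, cfg$translation_ramp,
            cfg$translation_speed, cfg$fixation_duration, cfg$drop_pause,
            cfg$feedback_duration, cfg$tr, cfg$trs_per_run, cfg$n_runs)
  if (any(!is.finite(durs)) || any(durs <= 0)) {
    stop("all rates and durations in a sim_config must be positive")
  }
  if (length(cfg$trials_per_fixation) != 2 ||
      any(cfg$trials_per_fixation < 1) ||
      cfg$trials_per_fixation[1] > cfg$trials_per_fixation[2]) {
    stop("`trials_per_fixation` must be an increasing integer range of length 2")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Virtual-navigation simulation config\n")
  cat(sprintf("  arena radius %g, %d landmarks every %g deg\n",
              x$arena_radius, x$n_landmarks, x$landmark_spacing))
  cat(sprintf("  %d run(s) x %d TRs at TR %.3f s (%.0f s total)\n",
              x$n_runs, x$trs_per_run, x$tr, x$n_runs * x$trs_per_run * x$tr))
  cat(sprintf("  rotation quantum %g deg, translation %g units/s (%g ms ramp)\n",
              x$rotation_quantum, x$translation_speed, x$translation_ramp))
  invisible(x)
}

#' Simulate a virtual-navigation session
#'
#' Generates a full scanning session of self-paced object-location memory
#' trials. An agent rotates in `rotation_quantum` steps towards a target,
#' translates to it at constant speed after a linear ramp, indicates the
#' remembered object location (drop), receives feedback at the true location,
#' collects the object there, and continues; fixation blocks are interleaved
#' after 2-4 trials. Remembered locations are displaced from the true
#' location by an error whose expectation decays exponentially across trials
#' (learning), multiplied by mean-one gamma jitter.
#'
#' The virtual head direction (vHD) is piecewise constant and, relative to
#' its start, always a multiple of the rotation quantum. The log spans
#' exactly `n_runs * trs_per_run * tr` seconds at `sample_rate` Hz.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#'
#' @return An object of class `"behavior_log"`: a list with
#'   `samples` (data frame: `t`, `x`, `y`, `vhd`, `translating`, `rotating`,
#'   `trial`, `event`), `trial_events` (one row per completed trial:
#'   cued object, drop and true locations, drop and feedback times), and the
#'   scanner grid metadata (`tr`, `trs_per_run`, `n_runs`, `sample_rate`,
#'   `arena_radius`).
#' @export
simulate_session <- function(config = sim_config(), seed = config$seed) {
  validate_sim_config(config)
  with_seed(seed, simulate_session_impl(config))
}

simulate_session_impl <- function(cfg) {
  total_dur <- cfg$n_runs * cfg$trs_per_run * cfg$tr
  rate <- cfg$sample_rate
  n_samp <- floor(total_dur * rate)
  quantum <- cfg$rotation_quantum
  step_dt <- quantum / cfg$rotation_speed
  ramp <- cfg$translation_ramp / 1000
  v <- cfg$translation_speed
  R <- cfg$arena_radius

  # object locations, uniform in the central 80% of the arena
  obj_r <- 0.8 * R * sqrt(stats::runif(cfg$n_objects))
  obj_a <- stats::runif(cfg$n_objects, 0, 360)
  objects <- cbind(x = obj_r * sinpi(obj_a / 180), y = obj_r * cospi(obj_a / 180))

  segs <- vector("list", 4096)
  n_seg <- 0
  add_seg <- function(seg) {
    n_seg <<- n_seg + 1
    segs[[n_seg]] <<- seg
  }

  t_now <- 0
  pos <- c(0, 0.5 * R)
  vhd <- 0
  trial_idx <- 0L

  rotate_to <- function(target) {
    bearing <- wrap_deg(atan2(target[1] - pos[1], target[2] - pos[2]) * 180 / pi)
    snapped <- wrap_deg(round(bearing / quantum) * quantum)
    delta <- circ_diff_deg(snapped, vhd)
    n_steps <- round(abs(delta) / quantum)
    if (n_steps > 0) {
      dur <- n_steps * step_dt
      add_seg(list(type = "rotate", t0 = t_now, t1 = t_now + dur,
                   x = pos[1], y = pos[2], vhd0 = vhd,
                   dir = sign(delta), step_dt = step_dt, n_steps = n_steps,
                   trial = trial_idx))
      t_now <<- t_now + dur
      vhd <<- snapped
    }
  }

  translate_towards <- function(target) {
    dist <- sqrt(sum((target - pos)^2))
    if (dist < 1e-9) return(invisible())
    u <- c(sinpi(vhd / 180), cospi(vhd / 180))
    # movement follows the (quantized) facing direction; clip at the wall
    end <- pos + dist * u
    if (sqrt(sum(end^2)) > 0.98 * R) {
      # largest travel along u that stays inside 0.98 R
      b <- sum(pos * u)
      dist <- max(0, -b + sqrt(max(0, b^2 + (0.98 * R)^2 - sum(pos^2))))
      end <- pos + dist * u
    }
    dur <- if (dist >= v * ramp / 2) ramp + (dist - v * ramp / 2) / v
           else sqrt(2 * ramp * dist / v)
    add_seg(list(type = "translate", t0 = t_now, t1 = t_now + dur,
                 x = pos[1], y = pos[2], vhd0 = vhd, heading = vhd,
                 speed = v, ramp = ramp, dist = dist, trial = trial_idx))
    t_now <<- t_now + dur
    pos <<- end
  }

  pause_for <- function(dur, type) {
    add_seg(list(type = type, t0 = t_now, t1 = t_now + dur,
                 x = pos[1], y = pos[2], vhd0 = vhd, trial = trial_idx))
    t_now <<- t_now + dur
  }

  events <- list()
  trials_since_fix <- 0L
  fix_after <- sample(seq(cfg$trials_per_fixation[1], cfg$trials_per_fixation[2]), 1)

  while (t_now < total_dur) {
    trial_idx <- trial_idx + 1L
    cued <- sample.int(cfg$n_objects, 1)
    true_loc <- objects[cued, ]

    expected <- cfg$error_asymptote +
      (cfg$error_start - cfg$error_asymptote) *
      exp(-cfg$learning_rate * (trial_idx - 1))
    mag <- expected * stats::rgamma(1, shape = cfg$error_shape,
                                    rate = cfg$error_shape)
    ang <- stats::runif(1, 0, 360)
    target <- true_loc + mag * c(sinpi(ang / 180), cospi(ang / 180))
    tr_norm <- sqrt(sum(target^2))
    if (tr_norm > 0.95 * R) target <- target * (0.95 * R / tr_norm)

    rotate_to(target)
    translate_towards(target)
    drop_time <- t_now
    drop_loc <- pos
    pause_for(cfg$drop_pause, "drop")
    feedback_time <- t_now
    pause_for(cfg$feedback_duration, "feedback")
    rotate_to(true_loc)
    translate_towards(true_loc)

    if (drop_time < total_dur) {
      events[[trial_idx]] <- data.frame(
        trial = trial_idx, cued_object = cued,
        drop_x = drop_loc[1], drop_y = drop_loc[2],
        true_x = true_loc[1], true_y = true_loc[2],
        drop_time = drop_time, feedback_time = feedback_time
      )
    }

    trials_since_fix <- trials_since_fix + 1L
    if (trials_since_fix >= fix_after) {
      old_trial <- trial_idx
      trial_idx <- NA_integer_
      pause_for(cfg$fixation_duration, "fixation")
      trial_idx <- old_trial
      trials_since_fix <- 0L
      fix_after <- sample(seq(cfg$trials_per_fixation[1],
                              cfg$trials_per_fixation[2]), 1)
    }
  }

  segs <- segs[seq_len(n_seg)]

  # render the segment script onto the global sample grid
  x <- numeric(n_samp); y <- numeric(n_samp); vhd_s <- numeric(n_samp)
  translating <- logical(n_samp); rotating <- logical(n_samp)
  trial_s <- rep(NA_integer_, n_samp); event <- character(n_samp)
  for (seg in segs) {
    i0 <- ceiling(seg$t0 * rate - 1e-9) + 1  # 1-based sample index
    i1 <- min(ceiling(seg$t1 * rate - 1e-9), n_samp)
    if (i0 > i1) next
    idx <- i0:i1
    ts <- (idx - 1) / rate - seg$t0
    event[idx] <- seg$type
    trial_s[idx] <- seg$trial
    if (seg$type == "rotate") {
      k <- pmin(floor(ts / seg$step_dt) + 1, seg$n_steps)
      vhd_s[idx] <- wrap_deg(seg$vhd0 + seg$dir * k * quantum)
      x[idx] <- seg$x; y[idx] <- seg$y
      rotating[idx] <- TRUE
    } else if (seg$type == "translate") {
      s <- ifelse(ts <= seg$ramp,
                  seg$speed * ts^2 / (2 * seg$ramp),
                  seg$speed * seg$ramp / 2 + seg$speed * (ts - seg$ramp))
      s <- pmin(s, seg$dist)
      x[idx] <- seg$x + s * sinpi(seg$heading / 180)
      y[idx] <- seg$y + s * cospi(seg$heading / 180)
      vhd_s[idx] <- seg$vhd0
      translating[idx] <- TRUE
    } else {
      x[idx] <- seg$x; y[idx] <- seg$y; vhd_s[idx] <- seg$vhd0
    }
  }

  samples <- data.frame(
    t = (seq_len(n_samp) - 1) / rate,
    x = x, y = y, vhd = wrap_deg(vhd_s),
    translating = translating, rotating = rotating,
    trial = trial_s, event = event
  )
  trial_events <- do.call(rbind, events)

  log <- list(
    samples = samples, trial_events = trial_events,
    tr = cfg$tr, trs_per_run = cfg$trs_per_run, n_runs = cfg$n_runs,
    sample_rate = cfg$sample_rate, arena_radius = cfg$arena_radius,
    config = cfg
  )
  class(log) <- "behavior_log"
  log
}

#' @export
print.behavior_log <- function(x, ...) {
  cat("Behavior log:", nrow(x$samples), "samples at", x$sample_rate, "Hz,",
      nrow(x$trial_events) %||% 0, "completed trials\n")
  cat(sprintf("  %d run(s) x %d TRs at TR %.3f s\n",
              x$n_runs, x$trs_per_run, x$tr))
  invisible(x)
}

#' Per-trial memory errors and their summaries
#'
#' Computes, for every completed trial, the Euclidean distance between the
#' remembered (drop) and the true object location, smooths the series with a
#' five-trial moving average (windows shrink at the series ends so the
#' smoothed series keeps the trial count), and reports the across-trial
#' median.
#'
#' @param log A [simulate_session()] behavior log (or any list with a
#'   `trial_events` data frame carrying `drop_x/y` and `true_x/y`).
#' @param window Moving-average window in trials.
#'
#' @return A list of class `"memory_record"` with `memory_error`,
#'   `smoothed_error` (same length), and `participant_median_error`.
#' @export
compute_memory_errors <- function(log, window = 5) {
  ev <- log$trial_events
  if (is.null(ev) || nrow(ev) == 0) {
    stop("behavior log contains no completed trials")
  }
  err <- sqrt((ev$drop_x - ev$true_x)^2 + (ev$drop_y - ev$true_y)^2)
  n <- length(err)
  half <- (window - 1) %/% 2
  smoothed <- vapply(seq_len(n), function(i) {
    mean(err[max(1, i - half):min(n, i + half)])
  }, numeric(1))
  out <- list(memory_error = err, smoothed_error = smoothed,
              participant_median_error = stats::median(err))
  class(out) <- "memory_record"
  out
}

#' Label samples as locomotion or stationary
#'
#' A sample counts as locomotion when its instantaneous translational speed
#' (forward difference of position times the sampling rate) exceeds
#' `speed_threshold`; everything else, including rotation in place, is
#' stationary. Rotation can therefore occur in either state.
#'
#' @param log A behavior log.
#' @param speed_threshold Speed threshold in virtual units/s.
#'
#' @return Character vector (`"locomotion"`/`"stationary"`), one per sample.
#' @export
label_states <- function(log, speed_threshold = 0) {
  s <- log$samples
  n <- nrow(s)
  speed <- c(sqrt(diff(s$x)^2 + diff(s$y)^2) * log$sample_rate, 0)
  if (n > 1) speed[n] <- speed[n - 1]
  ifelse(speed > speed_threshold, "locomotion", "stationary")
}

#' Write / read a behavior log as tab-separated files
#'
#' `write_behavior_log()` writes `samples.tsv`, `trials.tsv` and `meta.tsv`
#' into `dir`; `read_behavior_log()` reconstructs the log from them.
#'
#' @param log A behavior log.
#' @param dir Directory to write into (created if missing).
#' @return `write_behavior_log()` returns `dir` invisibly;
#'   `read_behavior_log()` returns a `"behavior_log"` object.
#' @export
write_behavior_log <- function(log, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(log$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(log$trial_events, file.path(dir, "trials.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- data.frame(
    key = c("tr", "trs_per_run", "n_runs", "sample_rate", "arena_radius"),
    value = c(log$tr, log$trs_per_run, log$n_runs, log$sample_rate,
              log$arena_radius)
  )
  utils::write.table(meta, file.path(dir, "meta.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_behavior_log
#' @export
read_behavior_log <- function(dir) {
  samples <- utils::read.delim(file.path(dir, "samples.tsv"))
  trials <- utils::read.delim(file.path(dir, "trials.tsv"))
  meta <- utils::read.delim(file.path(dir, "meta.tsv"))
  m <- stats::setNames(meta$value, meta$key)
  log <- list(samples = samples, trial_events = trials,
              tr = m[["tr"]], trs_per_run = as.integer(m[["trs_per_run"]]),
              n_runs = as.integer(m[["n_runs"]]),
              sample_rate = m[["sample_rate"]],
              arena_radius = m[["arena_radius"]])
  class(log) <- "behavior_log"
  log
}
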