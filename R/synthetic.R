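#' Configuration for a synthetic decoding study
#'
#' Defines the study conditions for the simulated movie-viewing experiment
#' (runs of 32 s rest, ~270 s movie, 30 s rest at TR = 2 s, sparse reported
#' events) and the device-manipulation control experiment (32 s rest then
#' six 16 s manipulation / 16 s rest cycles per run).
#'
#' Informative ROIs (see `roi_spec`) carry an anticipatory neural signal:
#' a boxcar starting `signal_lead` seconds before each event and ending at
#' the event, convolved with the HRF, scaled by `signal_amplitude` (as a
#' fraction of the voxel baseline of 100) and by a per-voxel weight that is
#' non-zero for `informative_voxel_fraction` of the ROI's voxels.  Any ROI
#' whose name contains "motor" instead responds to the report itself (a
#' boxcar over the slider hold).  All other ROIs carry noise only.  Noise is
#' AR(1) (coefficient `ar1_coef`, marginal sd `noise_sd`) plus white noise
#' of sd `noise_sd / 2`, both as fractions of baseline.
#'
#' @param n_subjects Number of subjects.
#' @param n_runs Runs per subject (movie experiment: 10; control: 8).
#' @param movie_duration Movie period length in seconds.
#' @param initial_rest,closing_rest Rest period lengths in seconds.
#' @param tr Volume repetition time in seconds; must divide the 2 s bin.
#' @param event_rate Expected reported events per run.
#' @param min_event_gap Minimum separation between events in seconds.
#' @param hold_duration_range Range (min, max) of slider hold durations, s.
#' @param roi_spec Data frame with columns `roi_name`, `n_voxels`,
#'   `informative`.
#' @param signal_lead Anticipatory signal onset, seconds before each event.
#' @param signal_amplitude Signal scale as a fraction of baseline.
#' @param informative_voxel_fraction Fraction of signal-carrying voxels in
#'   informative ROIs.
#' @param noise_sd Marginal sd of voxel noise as a fraction of baseline.
#' @param ar1_coef AR(1) coefficient of the temporal noise.
#' @param hrf_params HRF parameters, see [hrf_parameters()].
#' @param slider_noise_sd Additive noise sd on the slider trace (plateau
#'   height is 1).
#' @param slider_delay Reaction delay between event and slider rise, s.
#' @param marker_rate Facial-marker sampling rate, Hz.
#' @param generate_aux Also generate marker and laughter traces (disable to
#'   speed up simulations that only use slider reports).
#' @param seed Master seed; per-subject and per-run streams are derived
#'   from it by fixed offsets so any subset is reproducible independently.
#' @return A list of class `synthetic_study_config`.
#' @export
synthetic_study_config <- function(n_subjects = 10,
                                   n_runs = 10,
                                   movie_duration = 270,
                                   initial_rest = 32,
                                   closing_rest = 30,
                                   tr = 2,
                                   event_rate = 3,
                                   min_event_gap = 20,
                                   hold_duration_range = c(0.5, 3),
                                   roi_spec = default_roi_spec(),
                                   signal_lead = 2,
                                   signal_amplitude = 0.03,
                                   informative_voxel_fraction = 0.5,
                                   noise_sd = 0.02,
                                   ar1_coef = 0.3,
                                   hrf_params = hrf_parameters(),
                                   slider_noise_sd = 0.02,
                                   slider_delay = 0,
                                   marker_rate = 60,
                                   generate_aux = TRUE,
                                   seed = 1) {
  stopifnot(n_subjects >= 1, n_runs >= 1, movie_duration > 0,
            initial_rest > 0, closing_rest > 0, tr > 0,
            event_rate >= 0, min_event_gap >= 0,
            length(hold_duration_range) == 2,
            all(hold_duration_range > 0),
            diff(hold_duration_range) >= 0,
            signal_lead >= 0, signal_amplitude >= 0,
            informative_voxel_fraction >= 0,
            informative_voxel_fraction <= 1,
            noise_sd >= 0, abs(ar1_coef) < 1)
  if (BIN_WIDTH %% tr != 0) {
    stop("tr must divide the 2 s bin width evenly")
  }
  stopifnot(is.data.frame(roi_spec),
            all(c("roi_name", "n_voxels", "informative") %in% names(roi_spec)),
            all(roi_spec$n_voxels >= 1))
  structure(as.list(environment()), class = "synthetic_study_config")
}

#' @rdname synthetic_study_config
#' @export
default_roi_spec <- function() {
  data.frame(roi_name = c("dlpfc_r", "temporal_l", "motor_l"),
             n_voxels = c(200L, 200L, 150L),
             informative = c(TRUE, FALSE, FALSE))
}

# Deterministic derived seeds (kept under 2^31 - 1).
derive_seed <- function(master, subject = 0, run = 0, extra = 0) {
  (as.numeric(master) + 100003 * subject + 1009 * run + 7 * extra) %%
    2147483647
}

#' Sample sparse event onset times
#'
#' Events follow a homogeneous Poisson process thinned by a hard minimum
#' gap.  The candidate intensity is dead-time corrected so the expected
#' number of retained events approximates `rate`.
#'
#' @param duration Interval length in seconds; onsets lie in `[0, duration)`.
#' @param rate Expected number of events in the interval.
#' @param min_gap Minimum separation between consecutive onsets, seconds.
#' @param seed Optional seed for this draw.
#' @return Sorted numeric vector of onset times.
#' @export
generate_event_train <- function(duration, rate, min_gap = 0, seed = NULL) {
  stopifnot(duration > 0, rate >= 0, min_gap >= 0)
  if (rate == 0) return(numeric(0))
  if (min_gap > 0 && rate > floor(duration / min_gap) + 1) {
    stop_humordec("humordec_infeasible_events",
                  "cannot place ", rate, " events with ", min_gap,
                  " s gaps in ", duration, " s")
  }
  if (!is.null(seed)) set.seed(seed)
  dens <- rate / duration
  # dead-time corrected candidate intensity so the retained count tracks
  # `rate`; the correction is capped as the request nears the packing bound
  lambda <- dens / max(1 - dens * min_gap, 0.1)
  n_cand <- rpois(1, lambda * duration)
  if (n_cand == 0) return(numeric(0))
  cand <- sort(runif(n_cand, 0, duration))
  keep <- cand[1]
  for (t in cand[-1]) {
    if (t - keep[length(keep)] >= min_gap) keep <- c(keep, t)
  }
  keep
}

# --- internal builders -----------------------------------------------------

# Period table for one movie run.
movie_periods <- function(config) {
  d0 <- config$initial_rest
  d1 <- d0 + config$movie_duration
  d2 <- d1 + config$closing_rest
  data.frame(name = c("initial_rest", "movie", "closing_rest"),
             start_s = c(0, d0, d1), end_s = c(d0, d1, d2),
             is_task = c(FALSE, TRUE, FALSE))
}

# Period table for one control run: 32 s rest then 6 x (16 s manipulation +
# 16 s rest).  Everything after the initial rest is the task period for
# labelling purposes.
control_periods <- function(config) {
  starts <- config$initial_rest + 32 * (0:5)
  data.frame(name = c("initial_rest",
                      paste0(rep(c("manipulation", "block_rest"), 6),
                             rep(1:6, each = 2))),
             start_s = c(0, as.vector(rbind(starts, starts + 16))),
             end_s = c(config$initial_rest,
                       as.vector(rbind(starts + 16, starts + 32))),
             is_task = c(FALSE, rep(TRUE, 12)))
}

# ROI masks over the stacked voxel matrix.
build_roi_masks <- function(roi_spec) {
  ends <- cumsum(roi_spec$n_voxels)
  starts <- c(1, head(ends, -1) + 1)
  masks <- lapply(seq_len(nrow(roi_spec)), function(i) {
    roi_mask(roi_spec$roi_name[i], seq.int(starts[i], ends[i]))
  })
  names(masks) <- roi_spec$roi_name
  masks
}

# Per-subject voxel weight maps: which voxels carry signal and how strongly.
draw_voxel_weights <- function(config) {
  spec <- config$roi_spec
  total <- sum(spec$n_voxels)
  w <- numeric(total)
  masks <- build_roi_masks(spec)
  for (i in seq_len(nrow(spec))) {
    idx <- masks[[i]]$voxels
    nm <- spec$roi_name[i]
    if (isTRUE(spec$informative[i]) || grepl("motor", nm, ignore.case = TRUE)) {
      k <- round(config$informative_voxel_fraction * length(idx))
      if (k > 0) {
        chosen <- sample(idx, k)
        w[chosen] <- runif(k, 0.5, 1.5)
      }
    }
  }
  w
}

# AR(1) + white noise matrix (n_vol x n_vox), marginal sd ~ noise_sd plus a
# white component of sd noise_sd / 2, as fractions of baseline.
draw_noise <- function(n_vol, n_vox, noise_sd, phi) {
  if (noise_sd == 0) return(matrix(0, n_vol, n_vox))
  innov <- matrix(rnorm(n_vol * n_vox, 0, noise_sd * sqrt(1 - phi^2)),
                  n_vol, n_vox)
  ar <- stats::filter(innov, phi, method = "recursive",
                      init = matrix(rnorm(n_vox, 0, noise_sd), 1))
  ar <- matrix(as.numeric(ar), n_vol, n_vox)
  ar + matrix(rnorm(n_vol * n_vox, 0, noise_sd / 2), n_vol, n_vox)
}

# Bin a fine-grid series into per-volume means.
fine_to_volumes <- function(x, grid_step, tr, n_vol) {
  idx <- floor((seq_along(x) - 1) * grid_step / tr)
  keep <- idx < n_vol
  as.numeric(tapply(x[keep], idx[keep], mean))
}

# Slider trace for one movie run: baseline noise with plateaus of height 1
# over each hold.
movie_slider <- function(config, onsets_abs, holds, duration, periods,
                         run_id) {
  n <- round(duration * 100)
  t_s <- (seq_len(n) - 1) / 100
  v <- rnorm(n, 0, config$slider_noise_sd)
  for (i in seq_along(onsets_abs)) {
    on <- onsets_abs[i] + config$slider_delay
    sel <- t_s >= on & t_s < on + holds[i]
    v[sel] <- v[sel] + 1
  }
  response_trace(v, sample_rate = 100, run_id = run_id, periods = periods)
}

# Facial-marker coordinate traces: 4 markers x 2 axes with resting jitter
# and motion bursts around event times plus independent spurious bursts.
movie_markers <- function(config, onsets_abs, duration, run_id) {
  rate <- config$marker_rate
  n <- round(duration * rate)
  t_s <- (seq_len(n) - 1) / rate
  centers <- runif(8, 100, 200)
  coords <- sapply(centers, function(cc) cc + rnorm(n, 0, 0.05))
  burst_times <- c(onsets_abs + rnorm(length(onsets_abs), 0, 0.3),
                   runif(rpois(1, 1), 0, duration))
  for (bt in burst_times) {
    sel <- t_s >= bt & t_s < bt + runif(1, 0.5, 1.5)
    if (any(sel)) {
      coords[sel, ] <- coords[sel, ] + rnorm(sum(sel) * 8, 0, 2)
    }
  }
  list(coords = coords, sample_rate = rate, run_id = run_id)
}

# Laughter annotation: boxcars overlapping but not identical to the
# subject's events (jittered, occasionally missing, with extra bursts).
movie_laughter <- function(config, onsets_abs, duration, periods, run_id) {
  n <- round(duration * 100)
  t_s <- (seq_len(n) - 1) / 100
  v <- rnorm(n, 0, 0.02)
  kept <- onsets_abs[runif(length(onsets_abs)) < 0.7]
  extra <- runif(rpois(1, 1), periods$start_s[periods$is_task][1], duration)
  for (on in c(kept + rnorm(length(kept), 0, 0.5), extra)) {
    sel <- t_s >= on & t_s < on + runif(1, 1, 2.5)
    v[sel] <- v[sel] + 1
  }
  response_trace(v, sample_rate = 100, run_id = run_id, periods = periods)
}

# Voxel x volume matrix for one run given fine-grid neural indicators.
build_run_matrix <- function(config, duration, n_vol, weights,
                             neural_informative, neural_motor, grid_step) {
  spec <- config$roi_spec
  masks <- build_roi_masks(spec)
  total <- sum(spec$n_voxels)
  baseline <- 100
  sig_inf <- convolve_hrf(neural_informative, grid_step, config$hrf_params)
  sig_mot <- convolve_hrf(neural_motor, grid_step, config$hrf_params)
  vol_inf <- fine_to_volumes(sig_inf, grid_step, config$tr, n_vol)
  vol_mot <- fine_to_volumes(sig_mot, grid_step, config$tr, n_vol)

  signal <- matrix(0, n_vol, total)
  for (i in seq_len(nrow(spec))) {
    idx <- masks[[i]]$voxels
    nm <- spec$roi_name[i]
    if (grepl("motor", nm, ignore.case = TRUE)) {
      src <- vol_mot
    } else if (isTRUE(spec$informative[i])) {
      src <- vol_inf
    } else {
      next
    }
    signal[, idx] <- outer(src, config$signal_amplitude * weights[idx])
  }
  noise <- draw_noise(n_vol, total, config$noise_sd, config$ar1_coef)
  t(baseline * (1 + signal + noise)) # voxels x volumes
}

generate_run <- function(config, subject, run, weights, experiment) {
  set.seed(derive_seed(config$seed, subject, run))
  grid_step <- 0.1
  if (experiment == "movie") {
    periods <- movie_periods(config)
    duration <- max(periods$end_s)
    events <- generate_event_train(config$movie_duration, config$event_rate,
                                   config$min_event_gap)
    holds <- runif(length(events), config$hold_duration_range[1],
                   config$hold_duration_range[2])
    onsets_abs <- config$initial_rest + events
    tfine <- seq(0, duration - grid_step, by = grid_step)
    neural_inf <- numeric(length(tfine))
    neural_mot <- numeric(length(tfine))
    for (i in seq_along(onsets_abs)) {
      on <- onsets_abs[i]
      neural_inf[tfine >= on - config$signal_lead & tfine < on] <- 1
      neural_mot[tfine >= on & tfine < on + holds[i]] <- 1
    }
    slider <- movie_slider(config, onsets_abs, holds, duration, periods, run)
    markers <- if (config$generate_aux) {
      movie_markers(config, onsets_abs, duration, run)
    }
    laughter <- if (config$generate_aux) {
      movie_laughter(config, onsets_abs, duration, periods, run)
    }
  } else { # control
    periods <- control_periods(config)
    duration <- max(periods$end_s)
    manip <- periods[grepl("^manipulation", periods$name), , drop = FALSE]
    onsets_abs <- manip$start_s
    tfine <- seq(0, duration - grid_step, by = grid_step)
    neural_inf <- numeric(length(tfine)) # no anticipatory humor signal
    neural_mot <- numeric(length(tfine))
    for (i in seq_len(nrow(manip))) {
      neural_mot[tfine >= manip$start_s[i] & tfine < manip$end_s[i]] <- 1
    }
    n <- round(duration * 100)
    t_s <- (seq_len(n) - 1) / 100
    v <- rnorm(n, 0, config$slider_noise_sd)
    for (i in seq_len(nrow(manip))) {
      sel <- t_s >= manip$start_s[i] & t_s < manip$end_s[i]
      tau <- t_s[sel] - manip$start_s[i]
      v[sel] <- v[sel] + (1 - cos(2 * pi * 0.5 * tau)) / 2 # 0.5 Hz cycle
    }
    slider <- response_trace(v, sample_rate = 100, run_id = run,
                             periods = periods)
    markers <- if (config$generate_aux) movie_markers(config, numeric(0),
                                                      duration, run)
    laughter <- if (config$generate_aux) {
      response_trace(rnorm(n, 0, 0.02), sample_rate = 100, run_id = run,
                     periods = periods)
    }
  }
  n_vol <- round(duration / config$tr)
  mat <- build_run_matrix(config, duration, n_vol, weights, neural_inf,
                          neural_mot, grid_step)
  rts <- run_time_series(mat, tr = config$tr, run_id = run,
                         periods = periods, discard_count = 0L)
  list(run = rts, slider = slider, markers = markers, laughter = laughter,
       onsets_s = onsets_abs,
       onset_bins = as.integer(floor(onsets_abs / BIN_WIDTH)))
}

generate_study <- function(config, experiment) {
  subjects <- lapply(seq_len(config$n_subjects), function(s) {
    set.seed(derive_seed(config$seed, s))
    weights <- draw_voxel_weights(config)
    runs <- lapply(seq_len(config$n_runs), function(r) {
      generate_run(config, s, r, weights, experiment)
    })
    list(subject_id = s, voxel_weights = weights, runs = runs)
  })
  structure(list(config = config, experiment = experiment,
                 roi_masks = build_roi_masks(config$roi_spec),
                 subjects = subjects),
            class = "synthetic_study")
}

#' Generate a synthetic movie-viewing experiment
#'
#' Simulates `n_subjects` subjects, each with `n_runs` runs of
#' rest / movie / rest structure, sparse reported events, a 100 Hz slider
#' trace, optional facial-marker and laughter traces, and voxel x volume
#' BOLD matrices in which informative ROIs carry an HRF-convolved
#' anticipatory signal beginning `signal_lead` seconds before each event
#' (see [synthetic_study_config()]).  Ground-truth onset times are stored
#' per run for recovery tests.
#'
#' @param config A [synthetic_study_config()].
#' @return An object of class `synthetic_study`.
#' @export
generate_movie_experiment <- function(config) {
  stopifnot(inherits(config, "synthetic_study_config"))
  generate_study(config, "movie")
}

#' Generate a synthetic control (device-manipulation) experiment
#'
#' Each run is 32 s rest followed by six cycles of a 16 s manipulation
#' block and a 16 s rest block; the slider oscillates at 0.5 Hz during
#' manipulation blocks, motor-ROI voxels respond to manipulation, and no
#' anticipatory signal is injected anywhere.
#'
#' @param config A [synthetic_study_config()]; `n_runs` defaults to 8 for
#'   this design if left at the movie default of 10 it is kept as given.
#' @return An object of class `synthetic_study`.
#' @export
generate_control_experiment <- function(config) {
  stopifnot(inherits(config, "synthetic_study_config"))
  generate_study(config, "control")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %s experiment: %d subjects x %d runs, %d voxels in %d ROIs\n",
              x$experiment, length(x$subjects),
              length(x$subjects[[1]]$runs),
              sum(x$config$roi_spec$n_voxels), nrow(x$config$roi_spec)))
  invisible(x)
}
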